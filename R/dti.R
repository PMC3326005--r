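#' Combine two repeated DWI acquisitions
#'
#' Volume-wise arithmetic mean of two scans acquired with identical schemes
#' and grids (repeat averaging to increase SNR).
#'
#' @param dwi_a,dwi_b `dwi_volume` objects.
#' @return a `dwi_volume` with averaged signal.
#' @export
combine_repeats <- function(dwi_a, dwi_b) {
  stopifnot(inherits(dwi_a, "dwi_volume"), inherits(dwi_b, "dwi_volume"))
  if (!all(dim(dwi_a$data) == dim(dwi_b$data)))
    stop("DWI grids/volume counts differ")
  db <- abs(dwi_a$scheme$bvals - dwi_b$scheme$bvals) > 1e-6
  dv <- rowSums(abs(dwi_a$scheme$bvecs - dwi_b$scheme$bvecs)) > 1e-6
  if (any(db | dv))
    stop("gradient schemes differ at volume index ", which(db | dv)[1])
  out <- dwi_a
  out$data <- (dwi_a$data + dwi_b$data) / 2
  out
}

#' Fit diffusion tensors to a DWI volume
#'
#' Log-linear weighted least squares per voxel on the single-tensor model
#' `log S = log S0 - b g' D g` (`method = "ols"`; one reweighting pass with
#' weights equal to the squared fitted signal, the standard linearization of
#' the nonlinear model), or a robust iteratively-reweighted variant
#' (`method = "robust"`) that down-weights outlier measurements with
#' Geman-McClure weights on the log-domain residuals, the residual scale
#' re-estimated from the MAD at every iteration (at most `max_iter`
#' iterations, stopping when the largest weight change drops below `tol`).
#' Voxels with nonpositive b0 signal or fewer than 7 usable volumes are
#' flagged unfit (`NA` tensor).
#'
#' @param dwi a `dwi_volume`.
#' @param scheme gradient scheme (defaults to the one carried by `dwi`).
#' @param method `"ols"` or `"robust"`.
#' @param mask optional logical array restricting the fit.
#' @param max_iter,tol robust-fit controls.
#' @return a `tensor_field`: array `(nx, ny, nz, 6)` of components in
#'   lower-triangular order (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz), the estimated
#'   `s0` map and an `unfit` flag array.
#' @export
fit_tensor <- function(dwi, scheme = dwi$scheme, method = c("ols", "robust"),
                       mask = NULL, max_iter = 50, tol = 1e-6) {
  method <- match.arg(method)
  sh <- dim(dwi$data)[1:3]
  nvol <- dim(dwi$data)[4]
  stopifnot(length(scheme$bvals) == nvol)
  S <- matrix(dwi$data, prod(sh), nvol)
  vox <- if (is.null(mask)) seq_len(nrow(S)) else which(as.vector(mask))

  X <- cbind(1, -bmatrix(scheme))                 # coefficients: (log S0, D6)
  D6 <- matrix(NA_real_, nrow(S), 6)
  s0 <- rep(NA_real_, nrow(S))
  unfit <- rep(FALSE, nrow(S))
  b0 <- scheme$bvals == 0

  for (v in vox) {
    s <- S[v, ]
    usable <- is.finite(s) & s > 0
    if (sum(usable) < 7 || !any(usable & b0)) { unfit[v] <- TRUE; next }
    y <- log(s[usable])
    Xu <- X[usable, , drop = FALSE]
    beta <- stats::lm.fit(Xu, y)$coefficients
    w <- exp(Xu %*% beta)^2                        # predicted-signal^2 weights
    beta <- stats::lm.wfit(Xu, y, as.vector(w))$coefficients
    if (method == "robust") {
      w_old <- rep(1, length(y))
      for (it in seq_len(max_iter)) {
        r <- y - as.vector(Xu %*% beta)
        sc <- stats::mad(r)
        if (sc < 1e-12) break
        w_rob <- 1 / (1 + (r / sc)^2)^2            # Geman-McClure
        w <- as.vector(exp(Xu %*% beta)^2) * w_rob
        beta <- stats::lm.wfit(Xu, y, w)$coefficients
        if (max(abs(w_rob - w_old)) < tol) break
        w_old <- w_rob
      }
    }
    D6[v, ] <- beta[2:7]
    s0[v] <- exp(beta[1])
  }
  # the paper-style b0 estimate (geometric mean of unweighted volumes) is
  # reported alongside the regression S0
  gm_b0 <- exp(rowMeans(log(pmax(S[, b0, drop = FALSE], .Machine$double.xmin))))
  structure(list(D = array(D6, c(sh, 6)), geom = dwi$geom,
                 s0 = array(s0, sh), b0_geometric_mean = array(gm_b0, sh),
                 unfit = array(unfit, sh), method = method),
            class = "tensor_field")
}

# lower-triangular 6-vector to symmetric 3x3
d6_to_mat <- function(d6) {
  matrix(c(d6[1], d6[2], d6[4],
           d6[2], d6[3], d6[5],
           d6[4], d6[5], d6[6]), 3, 3)
}

#' Eigendecomposition of a tensor field
#'
#' Per-voxel eigenvalues in descending order and the principal eigenvector.
#' The eigenvector sign is fixed deterministically (largest-magnitude
#' component positive) for reproducibility under eigenvalue ties.
#'
#' @param tensors a `tensor_field`.
#' @return list with `evals` (array `(dims, 3)`, descending) and `e1`
#'   (array `(dims, 3)`).
#' @export
tensor_eigen <- function(tensors) {
  sh <- dim(tensors$D)[1:3]
  nv <- prod(sh)
  D6 <- matrix(tensors$D, nv, 6)
  evals <- matrix(NA_real_, nv, 3)
  e1 <- matrix(NA_real_, nv, 3)
  for (v in seq_len(nv)) {
    if (any(is.na(D6[v, ]))) next
    e <- eigen(d6_to_mat(D6[v, ]), symmetric = TRUE)
    evals[v, ] <- e$values
    vec <- e$vectors[, 1]
    if (vec[which.max(abs(vec))] < 0) vec <- -vec
    e1[v, ] <- vec
  }
  list(evals = array(evals, c(sh, 3)), e1 = array(e1, c(sh, 3)),
       geom = tensors$geom)
}

#' Fractional anisotropy from eigenvalues
#'
#' `FA = sqrt(3/2) * sqrt(sum((l - lbar)^2)) / sqrt(sum(l^2))`: the
#' normalized standard deviation of the eigenvalues, 0 for isotropic
#' diffusion and 1 in the rank-1 limit. Scale-invariant. An all-zero tensor
#' gives `NA`.
#'
#' @param l1,l2,l3 eigenvalues (any common units); vectorized.
#' @export
fa_from_eigenvalues <- function(l1, l2, l3) {
  ss <- l1^2 + l2^2 + l3^2
  lb <- (l1 + l2 + l3) / 3
  fa <- sqrt(1.5 * ((l1 - lb)^2 + (l2 - lb)^2 + (l3 - lb)^2) / ss)
  fa[ss == 0] <- NA_real_
  fa
}

#' Scalar maps from a fitted tensor field
#'
#' FA, axial diffusivity (AD = l1), radial diffusivity (RD = (l2 + l3) / 2)
#' and mean diffusivity (MD). Negative eigenvalues (a noise artifact) are
#' clamped to 0 for the FA and RD computations, keeping FA in [0, 1]; the
#' raw values remain in the tensor field and affected voxels are flagged in
#' the returned `negative_eigenvalue` array. Unfit voxels carry `NA`.
#'
#' @param tensors a `tensor_field` (or the result of [tensor_eigen()]).
#' @return list of [scalar_map()]s `FA`, `AD`, `RD`, `MD` plus flag array
#'   `negative_eigenvalue`.
#' @export
scalar_maps <- function(tensors) {
  eig <- if (is.list(tensors) && !is.null(tensors$evals)) tensors
         else tensor_eigen(tensors)
  sh <- dim(eig$evals)[1:3]
  ev <- matrix(eig$evals, prod(sh), 3)
  neg <- !is.na(ev[, 3]) & ev[, 3] < 0
  evc <- pmax(ev, 0)
  fa <- fa_from_eigenvalues(evc[, 1], evc[, 2], evc[, 3])
  list(FA = scalar_map(array(fa, sh), eig$geom, "FA"),
       AD = scalar_map(array(ev[, 1], sh), eig$geom, "AD"),
       RD = scalar_map(array((evc[, 2] + evc[, 3]) / 2, sh), eig$geom, "RD"),
       MD = scalar_map(array(rowMeans(ev), sh), eig$geom, "MD"),
       negative_eigenvalue = array(neg, sh))
}
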