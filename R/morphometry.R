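#' Jacobian-determinant map of a deformation field
#'
#' Computes `det(I + du/dx)` per voxel, with derivatives taken in mm using
#' the voxel size: central differences at interior voxels, one-sided at grid
#' borders. `|J| > 1` marks local tissue expansion from baseline to
#' follow-up, `|J| < 1` contraction.
#'
#' @param field a `deformation_field` (see [generate_deformation()]) or a
#'   4D array `(nx, ny, nz, 3)` of mm displacements with `geom` supplied.
#' @param geom grid geometry if `field` is a bare array.
#' @return a [scalar_map()] with semantics `"Jacobian"`.
#' @export
jacobian_determinant <- function(field, geom = NULL) {
  if (inherits(field, "deformation_field")) {
    u <- field$u; geom <- field$geom
  } else u <- field
  stopifnot(!is.null(geom), length(dim(u)) == 4, dim(u)[4] == 3)
  if (any(!is.finite(u))) {
    bad <- which(!is.finite(u), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite displacement at voxel (%d, %d, %d)",
                 bad[1], bad[2], bad[3]))
  }
  sh <- dim(u)[1:3]
  if (any(sh < 3)) stop("grid must be at least 3 voxels per axis")
  # d/d(axis) of a 3D array: central interior, one-sided at borders, in mm
  d_axis <- function(a, axis) {
    h <- geom$voxel_size[axis]
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    n <- dim(ap)[1]
    m <- matrix(ap, n)
    out <- m
    if (n >= 3)
      out[2:(n - 1), ] <- (m[3:n, , drop = FALSE] -
                             m[1:(n - 2), , drop = FALSE]) / (2 * h)
    out[1, ] <- (m[2, ] - m[1, ]) / h
    out[n, ] <- (m[n, ] - m[n - 1, ]) / h
    aperm(array(out, dim(ap)), order(perm))
  }
  g <- array(0, c(sh, 3, 3))                        # g[,,,i,j] = d u_i / d x_j
  for (i in 1:3) for (j in 1:3)
    g[, , , i, j] <- d_axis(u[, , , i], j)
  J11 <- 1 + g[, , , 1, 1]; J12 <- g[, , , 1, 2]; J13 <- g[, , , 1, 3]
  J21 <- g[, , , 2, 1]; J22 <- 1 + g[, , , 2, 2]; J23 <- g[, , , 2, 3]
  J31 <- g[, , , 3, 1]; J32 <- g[, , , 3, 2]; J33 <- 1 + g[, , , 3, 3]
  det <- J11 * (J22 * J33 - J23 * J32) -
    J12 * (J21 * J33 - J23 * J31) +
    J13 * (J21 * J32 - J22 * J31)
  scalar_map(det, geom, "Jacobian")
}

#' Voxelwise test for volumetric change
#'
#' At each voxel, a one-sample two-sided t-test of `|J| - 1` against zero
#' across subjects (expansion or contraction, |J| != 1). Voxels with zero
#' between-subject variance are flagged degenerate, with p forced to 0 when
#' the common value differs from 1 and to 1 otherwise.
#'
#' @param jacobians list of per-subject Jacobian [scalar_map()]s on a common
#'   grid, or a matrix (voxels x subjects).
#' @param use_log test `log |J|` against 0 instead of `|J| - 1`.
#' @return list with arrays `t`, `p`, `degenerate`, plus `n` and `df`.
#' @export
voxelwise_change_test <- function(jacobians, use_log = FALSE) {
  if (is.list(jacobians)) {
    sh <- dim(if (inherits(jacobians[[1]], "scalar_map")) jacobians[[1]]$data
              else jacobians[[1]])
    M <- vapply(jacobians, function(j) {
      d <- if (inherits(j, "scalar_map")) j$data else j
      stopifnot(all(dim(d) == sh))
      as.vector(d)
    }, numeric(prod(sh)))
  } else {
    M <- jacobians; sh <- NULL
  }
  n <- ncol(M)
  if (n < 3) stop("need at least 3 subjects")
  X <- if (use_log) log(M) else M - 1
  mu <- rowMeans(X)
  sdv <- sqrt(rowSums((X - mu)^2) / (n - 1))
  degen <- sdv == 0
  tval <- ifelse(degen, 0, mu / (sdv / sqrt(n)))
  p <- 2 * stats::pt(-abs(tval), df = n - 1)
  p[degen] <- ifelse(mu[degen] != 0, 0, 1)
  shape_or <- function(v) if (is.null(sh)) v else array(v, sh)
  list(t = shape_or(tval), p = shape_or(p), degenerate = shape_or(degen),
       n = n, df = n - 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg FDR voxel selection
#'
#' Step-up procedure: sort the m p-values ascending, find the largest i with
#' `p(i) <= (i/m) q`; the FDR threshold is that `p(i)` (0 when no p-value
#' qualifies) and the significance mask keeps voxels with `p <= threshold`.
#' Implemented through [stats::p.adjust()] BH-adjusted p-values, which mark
#' exactly the step-up rejection set.
#'
#' @param p_map array or vector of p-values in [0, 1].
#' @param q FDR level, default 0.05.
#' @return list with `threshold`, `mask` (same shape as `p_map`), `q` and
#'   `n_significant`.
#' @export
fdr_select <- function(p_map, q = 0.05) {
  p <- as.vector(if (inherits(p_map, "scalar_map")) p_map$data else p_map)
  if (length(p) == 0) stop("empty p-value set")
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  reject <- stats::p.adjust(p, method = "BH") <= q
  thr <- if (any(reject)) max(p[reject]) else 0
  mask <- p <= thr & thr > 0
  dim(mask) <- dim(if (inherits(p_map, "scalar_map")) p_map$data else p_map)
  list(threshold = thr, mask = mask, q = q, n_significant = sum(mask))
}
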