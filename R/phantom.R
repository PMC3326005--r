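#' Diffusion gradient scheme
#'
#' b-values (s/mm^2) and unit gradient directions, one per acquired volume.
#' Non-unit directions on weighted volumes are normalized with a warning.
#' Tensor fitting requires at least 6 non-collinear weighted directions and
#' one unweighted (b0) volume.
#'
#' @param bvals numeric vector of b-values.
#' @param bvecs n x 3 matrix of gradient directions (rows; b0 rows may be 0).
#' @return object of class `gradient_scheme`.
#' @export
gradient_scheme <- function(bvals, bvecs) {
  bvecs <- as.matrix(bvecs)
  stopifnot(length(bvals) == nrow(bvecs), ncol(bvecs) == 3)
  nrm <- sqrt(rowSums(bvecs^2))
  w <- bvals > 0
  if (any(w & abs(nrm - 1) > 1e-6)) {
    warning("non-unit gradient directions normalized")
    bvecs[w, ] <- bvecs[w, , drop = FALSE] / nrm[w]
  }
  if (sum(w) < 6) stop("need at least 6 diffusion-weighted directions")
  if (sum(!w) < 1) stop("need at least 1 unweighted (b0) volume")
  structure(list(bvals = as.numeric(bvals), bvecs = bvecs),
            class = "gradient_scheme")
}

#' Default acquisition scheme: 32 directions at b = 1000 plus 8 b0 volumes
#'
#' Directions are spread over the hemisphere by a spherical Fibonacci
#' lattice, a deterministic well-separated (non-collinear) point set.
#'
#' @param n_dir number of weighted directions.
#' @param n_b0 number of unweighted volumes (placed first).
#' @param b diffusion weighting in s/mm^2.
#' @export
default_scheme <- function(n_dir = 32, n_b0 = 8, b = 1000) {
  i <- seq_len(n_dir) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- i / n_dir                       # upper hemisphere only
  r <- sqrt(1 - z^2)
  dirs <- cbind(r * cos(phi), r * sin(phi), z)
  gradient_scheme(c(rep(0, n_b0), rep(b, n_dir)),
                  rbind(matrix(0, n_b0, 3), dirs))
}

# design matrix rows: b * (gx^2, 2 gx gy, gy^2, 2 gx gz, 2 gy gz, gz^2),
# matching the lower-triangular tensor component order
# (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz)
bmatrix <- function(scheme) {
  g <- scheme$bvecs
  scheme$bvals * cbind(g[, 1]^2, 2 * g[, 1] * g[, 2], g[, 2]^2,
                       2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3], g[, 3]^2)
}

# symmetric tensor from direction e1 with eigenvalues (l1, l2, l2-plane):
# D = l3 I + (l1 - l3) e1 e1' only valid for l2 == l3; general form built
# from an orthonormal frame
tensor_from_tangent <- function(tangent, evals) {
  e1 <- tangent / sqrt(sum(tangent^2))
  # deterministic perpendicular frame
  ref <- if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e2 <- ref - sum(ref * e1) * e1
  e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  D <- evals[1] * tcrossprod(e1) + evals[2] * tcrossprod(e2) +
    evals[3] * tcrossprod(e3)
  c(D[1, 1], D[1, 2], D[2, 2], D[1, 3], D[2, 3], D[3, 3])
}

#' Specification of a diffusion phantom
#'
#' A bundle of anisotropic tensors following a parametric center line inside
#' an isotropic background, imaged with a given gradient scheme. The white
#' matter fraction is 1 inside the bundle radius and falls off linearly over
#' one voxel at the boundary (or drops to 0 with `edge = "hard"`), exercising
#' the pure-white-matter >= 90% mask rule downstream.
#'
#' @param grid_shape voxel counts, default `c(30, 14, 14)`.
#' @param voxel_size mm, default 2.5 isotropic (DTI acquisition resolution).
#' @param bundle_geometry list with `kind` in `{"straight", "arc", "helix"}`,
#'   `radius` (mm) and kind-specific parameters: straight runs along x
#'   through the grid center; `arc` takes `arc_radius` (mm) and `arc_span`
#'   (radians, default pi/2) in the xy-plane; `helix` additionally `pitch`
#'   (mm per turn) and `turns`.
#' @param bundle_eigenvalues tensor eigenvalues in the bundle, mm^2/s,
#'   descending; default `c(1.6, 0.5, 0.5) * 1e-3` (prolate, white-matter
#'   like).
#' @param background_eigenvalue isotropic background diffusivity, default
#'   0.7e-3 mm^2/s.
#' @param s0 unweighted signal level.
#' @param noise_sigma noise level in signal units.
#' @param noise_model `"none"`, `"gaussian"`, or `"rician"` (magnitude of a
#'   complex Gaussian, the standard MR magnitude model).
#' @param scheme a [gradient_scheme()]; default [default_scheme()].
#' @param edge `"ramp"` (1-voxel linear partial-volume falloff) or `"hard"`.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(30, 14, 14), voxel_size = 2.5,
                         bundle_geometry = list(kind = "straight", radius = 6),
                         bundle_eigenvalues = c(1.6, 0.5, 0.5) * 1e-3,
                         background_eigenvalue = 0.7e-3,
                         s0 = 1000, noise_sigma = 0,
                         noise_model = c("none", "gaussian", "rician"),
                         scheme = default_scheme(),
                         edge = c("ramp", "hard")) {
  noise_model <- match.arg(noise_model)
  edge <- match.arg(edge)
  ev <- bundle_eigenvalues
  if (!(ev[1] >= ev[2] && ev[2] >= ev[3] && ev[3] > 0))
    stop("bundle eigenvalues must satisfy l1 >= l2 >= l3 > 0")
  stopifnot(noise_sigma >= 0, background_eigenvalue > 0, s0 > 0)
  structure(list(geom = grid_geometry(grid_shape, voxel_size),
                 bundle_geometry = bundle_geometry,
                 bundle_eigenvalues = ev,
                 background_eigenvalue = background_eigenvalue,
                 s0 = s0, noise_sigma = noise_sigma,
                 noise_model = noise_model, scheme = scheme, edge = edge),
            class = "phantom_spec")
}

# center-line sample points and tangents for each bundle geometry
bundle_centerline <- function(bg, geom, step = 0.5) {
  ctr <- geom$origin + geom$shape * geom$voxel_size / 2
  ext <- geom$shape * geom$voxel_size
  if (bg$kind == "straight") {
    x <- seq(geom$origin[1], geom$origin[1] + ext[1], by = step)
    pts <- cbind(x, ctr[2], ctr[3])
    tans <- matrix(rep(c(1, 0, 0), each = length(x)), ncol = 3)
  } else if (bg$kind == "arc") {
    R <- bg$arc_radius
    span <- if (!is.null(bg$arc_span)) bg$arc_span else pi / 2
    th <- seq(0, span, by = step / R)
    cc <- c(ctr[1] - R, ctr[2], ctr[3])    # arc center; arc passes through ctr
    pts <- cbind(cc[1] + R * cos(th), cc[2] + R * sin(th), cc[3])
    tans <- cbind(-sin(th), cos(th), 0)
  } else if (bg$kind == "helix") {
    R <- bg$arc_radius
    pitch <- bg$pitch
    turns <- if (!is.null(bg$turns)) bg$turns else 1
    dl <- sqrt(R^2 + (pitch / (2 * pi))^2)
    th <- seq(0, 2 * pi * turns, by = step / dl)
    pts <- cbind(ctr[1] + R * cos(th), ctr[2] + R * sin(th),
                 ctr[3] + pitch * th / (2 * pi) - pitch * turns / 2)
    tans <- cbind(-R * sin(th), R * cos(th), pitch / (2 * pi))
    tans <- tans / sqrt(rowSums(tans^2))
  } else stop("unknown bundle geometry kind: ", bg$kind)
  list(points = pts, tangents = tans)
}

#' Generate a diffusion-weighted phantom
#'
#' Noise-free signal follows the single-tensor model
#' `S = s0 exp(-b g' D g)` per voxel and direction, with the bundle tensor
#' oriented along the local center-line tangent and an isotropic background
#' tensor elsewhere; partial-volume voxels mix the two signals by the white
#' matter fraction. Gaussian or Rician noise is added afterwards. Ground
#' truth (tensor field and wm fraction) is returned alongside.
#'
#' @param spec a [phantom_spec()].
#' @param seed seed for the noise draw (RNG state restored on exit).
#' @return list with `dwi` (class `dwi_volume`: 4D signal array + scheme +
#'   geometry), `wm_fraction` ([scalar_map()]) and `tensors` (a
#'   `tensor_field` holding the ground-truth tensors).
#' @export
generate_dwi_phantom <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  geom <- spec$geom
  sh <- geom$shape
  nv <- prod(sh)
  ijk <- as.matrix(expand.grid(seq_len(sh[1]), seq_len(sh[2]), seq_len(sh[3])))
  pts <- voxel_center(ijk, geom)

  cl <- bundle_centerline(spec$bundle_geometry, geom)
  # nearest center-line sample per voxel (chunked distance computation)
  np <- nrow(cl$points)
  nearest <- integer(nv); dist <- numeric(nv)
  chunk <- 20000L
  for (s in seq(1L, nv, by = chunk)) {
    idx <- s:min(s + chunk - 1L, nv)
    d2 <- outer(rowSums(pts[idx, , drop = FALSE]^2), rowSums(cl$points^2), `+`) -
      2 * pts[idx, , drop = FALSE] %*% t(cl$points)
    nearest[idx] <- max.col(-d2, ties.method = "first")
    dist[idx] <- sqrt(pmax(d2[cbind(seq_along(idx), nearest[idx])], 0))
  }
  radius <- spec$bundle_geometry$radius
  frac <- if (spec$edge == "hard") as.numeric(dist <= radius)
          else clamp(1 - (dist - radius) / min(geom$voxel_size), 0, 1)

  # ground-truth tensors: bundle tensor where wm fraction >= 0.5
  bg6 <- spec$background_eigenvalue * c(1, 0, 1, 0, 0, 1)
  D6 <- matrix(bg6, nv, 6, byrow = TRUE)
  in_bundle <- frac >= 0.5
  for (v in which(in_bundle))
    D6[v, ] <- tensor_from_tangent(cl$tangents[nearest[v], ],
                                   spec$bundle_eigenvalues)

  B <- bmatrix(spec$scheme)                       # nvol x 6
  S_bundle <- spec$s0 * exp(-tcrossprod(D6, B))   # nv x nvol
  S_bg <- spec$s0 * exp(-tcrossprod(matrix(bg6, 1), B))[1, ]
  S <- frac * S_bundle + (1 - frac) * matrix(S_bg, nv, length(S_bg), byrow = TRUE)

  if (spec$noise_model != "none" && spec$noise_sigma > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    if (spec$noise_model == "gaussian") {
      S <- S + stats::rnorm(length(S), 0, spec$noise_sigma)
    } else {
      S <- sqrt((S + stats::rnorm(length(S), 0, spec$noise_sigma))^2 +
                  stats::rnorm(length(S), 0, spec$noise_sigma)^2)
    }
  }

  nvol <- length(spec$scheme$bvals)
  dwi <- structure(list(data = array(S, c(sh, nvol)), scheme = spec$scheme,
                        geom = geom), class = "dwi_volume")
  tensors <- structure(list(D = array(D6, c(sh, 6)), geom = geom,
                            unfit = array(FALSE, sh)), class = "tensor_field")
  list(dwi = dwi, wm_fraction = scalar_map(array(frac, sh), geom, "WMfraction"),
       tensors = tensors)
}
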