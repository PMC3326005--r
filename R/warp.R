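#' Specification of a synthetic deformation
#'
#' Analytic displacement fields with known Jacobian determinants, used as
#' oracles for the morphometry stage. Kinds:
#' \describe{
#'   \item{identity}{zero displacement, |J| = 1.}
#'   \item{uniform_scale}{`u = (s - 1) (x - c)` per axis about the grid
#'     center; `parameters$scale` is a scalar or 3-vector; |J| = prod(s).}
#'   \item{shear}{`u = (alpha (y - c_y), 0, 0)`; `parameters$alpha`; |J| = 1.}
#'   \item{radial}{Gaussian radial bump `u = a exp(-r^2 / (2 sigma^2)) (x - c)`
#'     with `parameters$amplitude`, `parameters$sigma` (mm) and optional
#'     `parameters$center`; |J| = (1 + f)^2 (1 + f - r^2 f / sigma^2).}
#'   \item{composite}{`parameters$specs`, a list of warp specs composed left
#'     to right: total displacement u2(x + u1(x)) + u1(x), determinant
#'     |J2|(x + u1(x)) |J1|(x).}
#' }
#'
#' @param kind one of the above.
#' @param parameters kind-specific list.
#' @param grid_shape,voxel_size grid definition (voxel size in mm; default
#'   the 2 x 2 x 2.4 mm morphometry analysis grid).
#' @return object of class `warp_spec`.
#' @export
warp_spec <- function(kind = c("identity", "uniform_scale", "radial", "shear",
                               "composite"),
                      parameters = list(), grid_shape = c(16, 16, 16),
                      voxel_size = c(2, 2, 2.4)) {
  kind <- match.arg(kind)
  if (kind == "uniform_scale") {
    s <- rep_len(parameters$scale, 3)
    if (any(s <= 0)) stop("scale factors must be > 0")
    parameters$scale <- s
  }
  if (kind == "composite") {
    stopifnot(length(parameters$specs) >= 1,
              all(vapply(parameters$specs, inherits, TRUE, "warp_spec")))
  }
  structure(list(kind = kind, parameters = parameters,
                 geom = grid_geometry(grid_shape, voxel_size)),
            class = "warp_spec")
}

# displacement and analytic |J| at arbitrary mm points (n x 3 matrix)
warp_eval <- function(spec, pts) {
  geom <- spec$geom
  ctr <- geom$origin + geom$shape * geom$voxel_size / 2
  p <- spec$parameters
  switch(spec$kind,
    identity = list(u = pts * 0, detj = rep(1, nrow(pts))),
    uniform_scale = {
      x <- sweep(pts, 2, ctr)
      list(u = sweep(x, 2, p$scale - 1, `*`), detj = rep(prod(p$scale), nrow(pts)))
    },
    shear = {
      u <- pts * 0
      u[, 1] <- p$alpha * (pts[, 2] - ctr[2])
      list(u = u, detj = rep(1, nrow(pts)))
    },
    radial = {
      c0 <- if (!is.null(p$center)) p$center else ctr
      x <- sweep(pts, 2, c0)
      r2 <- rowSums(x^2)
      f <- p$amplitude * exp(-r2 / (2 * p$sigma^2))
      list(u = x * f, detj = (1 + f)^2 * (1 + f - r2 * f / p$sigma^2))
    },
    composite = {
      u <- pts * 0
      detj <- rep(1, nrow(pts))
      cur <- pts
      for (s in p$specs) {
        e <- warp_eval(s, cur)
        u <- u + e$u
        detj <- detj * e$detj
        cur <- cur + e$u
      }
      list(u = u, detj = detj)
    })
}

#' Generate a deformation field with its analytic Jacobian map
#'
#' Evaluates the analytic displacement at every voxel center and returns the
#' field together with the closed-form Jacobian-determinant map, which serves
#' as ground truth for the finite-difference estimate in
#' [jacobian_determinant()].
#'
#' @param spec a [warp_spec()].
#' @return list with `field` (class `deformation_field`: array
#'   `(nx, ny, nz, 3)` of mm displacements plus geometry) and
#'   `analytic_jacobian` (a [scalar_map()]).
#' @export
generate_deformation <- function(spec) {
  stopifnot(inherits(spec, "warp_spec"))
  geom <- spec$geom
  sh <- geom$shape
  ijk <- as.matrix(expand.grid(i = seq_len(sh[1]), j = seq_len(sh[2]),
                               k = seq_len(sh[3])))
  pts <- voxel_center(ijk, geom)
  e <- warp_eval(spec, pts)
  u <- array(e$u, c(sh, 3))
  field <- structure(list(u = u, geom = geom), class = "deformation_field")
  list(field = field,
       analytic_jacobian = scalar_map(array(e$detj, sh), geom, "Jacobian"))
}
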