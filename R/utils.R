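#' @keywords internal
"_PACKAGE"

#' Grid geometry for voxel volumes
#'
#' Lightweight description of a regular voxel grid: dimensions, voxel size in
#' mm and world-space origin. Voxel `(i, j, k)` (1-based) has its center at
#' `origin + (c(i, j, k) - 0.5) * voxel_size`.
#'
#' @param shape integer 3-vector of voxel counts per axis.
#' @param voxel_size mm per voxel; scalar (isotropic) or 3-vector.
#' @param origin world coordinate of the grid corner (mm).
#' @return an object of class `grid_geometry`.
#' @export
grid_geometry <- function(shape, voxel_size = 1, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  structure(list(shape = shape, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "grid_geometry")
}

#' Voxel centers in world (mm) coordinates
#' @param ijk n x 3 matrix (or 3-vector) of 1-based voxel indices.
#' @param geom a [grid_geometry()].
#' @return n x 3 matrix of mm coordinates.
#' @export
voxel_center <- function(ijk, geom) {
  ijk <- rbind_pts(ijk)
  sweep(sweep(ijk - 0.5, 2, geom$voxel_size, `*`), 2, geom$origin, `+`)
}

#' Voxel containing each world point
#' @param pts n x 3 matrix (or 3-vector) of mm coordinates.
#' @param geom a [grid_geometry()].
#' @return n x 3 integer matrix of 1-based voxel indices (may fall outside
#'   the grid; see [in_grid()]).
#' @export
point_to_voxel <- function(pts, geom) {
  pts <- rbind_pts(pts)
  v <- sweep(sweep(pts, 2, geom$origin, `-`), 2, geom$voxel_size, `/`)
  storage.mode(v) <- "double"
  iv <- floor(v) + 1L
  storage.mode(iv) <- "integer"
  iv
}

#' @rdname point_to_voxel
#' @export
in_grid <- function(ijk, geom) {
  ijk <- rbind_pts(ijk)
  ijk[, 1] >= 1L & ijk[, 1] <= geom$shape[1] &
    ijk[, 2] >= 1L & ijk[, 2] <= geom$shape[2] &
    ijk[, 3] >= 1L & ijk[, 3] <= geom$shape[3]
}

# coerce a bare 3-vector to a 1 x 3 matrix
rbind_pts <- function(x) {
  if (is.null(dim(x))) matrix(x, ncol = 3L) else as.matrix(x)
}

#' Scalar map on a voxel grid
#'
#' @param data 3D numeric array; `NA` marks voxels where the quantity is
#'   undefined (undefined voxels are flagged, never silently zeroed).
#' @param geom a [grid_geometry()] matching `dim(data)`.
#' @param semantics one of `"FA"`, `"AD"`, `"RD"`, `"MD"`, `"Jacobian"`,
#'   `"WMfraction"`, or a free label.
#' @return object of class `scalar_map`.
#' @export
scalar_map <- function(data, geom, semantics = "value") {
  stopifnot(identical(dim(data), as.integer(geom$shape)) ||
              all(dim(data) == geom$shape))
  structure(list(data = data, geom = geom, semantics = semantics),
            class = "scalar_map")
}

#' @export
print.scalar_map <- function(x, ...) {
  cat(sprintf("<scalar_map [%s]> %s voxels of %s mm, range [%.4g, %.4g], %d undefined\n",
              x$semantics, paste(x$geom$shape, collapse = "x"),
              paste(signif(x$geom$voxel_size, 3), collapse = "x"),
              suppressWarnings(min(x$data, na.rm = TRUE)),
              suppressWarnings(max(x$data, na.rm = TRUE)),
              sum(is.na(x$data))))
  invisible(x)
}

# positive-definite symmetry check used by spec validators
is_psd <- function(m, tol = 1e-10) {
  if (any(abs(m - t(m)) > 1e-8)) return(FALSE)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  all(ev > -tol * max(1, abs(ev[1])))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
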