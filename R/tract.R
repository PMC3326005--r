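#' Seed points for tractography
#'
#' Places 8 seed points per masked voxel at the corners of a small cube
#' inside the voxel: offsets of +/- 0.25 voxel along each axis from the
#' voxel center, so the small cubes of neighboring voxels form a regular
#' grid and no two seeds coincide.
#'
#' @param mask logical array (or [scalar_map()] treated as nonzero = in).
#' @param geom grid geometry (taken from the map when available).
#' @return n x 3 matrix of mm seed coordinates (0 rows for an empty mask).
#' @export
seed_points <- function(mask, geom = NULL) {
  if (inherits(mask, "scalar_map")) {
    geom <- mask$geom
    mask <- !is.na(mask$data) & mask$data != 0
  }
  stopifnot(!is.null(geom))
  vox <- which(mask, arr.ind = TRUE)
  if (nrow(vox) == 0) return(matrix(numeric(0), 0, 3))
  centers <- voxel_center(vox, geom)
  offs <- as.matrix(expand.grid(c(-0.25, 0.25), c(-0.25, 0.25), c(-0.25, 0.25)))
  offs <- sweep(offs, 2, geom$voxel_size, `*`)
  out <- matrix(0, nrow(vox) * 8, 3)
  for (k in 1:8)
    out[seq(k, by = 8, length.out = nrow(vox)), ] <-
      sweep(centers, 2, offs[k, ], `+`)
  out
}

#' Precompute tracking peaks (principal directions and FA)
#'
#' @param tensors a `tensor_field`.
#' @return list with per-voxel principal eigenvector, FA and geometry, the
#'   inputs [fact_track()] consumes.
#' @export
tensor_peaks <- function(tensors) {
  eig <- tensor_eigen(tensors)
  sm <- scalar_maps(eig)
  list(e1 = eig$e1, fa = sm$FA$data, geom = eig$geom)
}

# exit point of the current voxel from p along unit direction d; returns
# list(point, t). Voxel v spans [(v-1) vs, v vs] + origin per axis.
voxel_exit <- function(p, d, v, geom) {
  lo <- geom$origin + (v - 1) * geom$voxel_size
  hi <- lo + geom$voxel_size
  tt <- rep(Inf, 3)
  for (ax in 1:3) {
    if (d[ax] > 1e-12) tt[ax] <- (hi[ax] - p[ax]) / d[ax]
    else if (d[ax] < -1e-12) tt[ax] <- (lo[ax] - p[ax]) / d[ax]
  }
  t <- max(min(tt), 0)
  list(point = p + t * d, t = t)
}

#' FACT streamline tracking
#'
#' Fiber Assignment by Continuous Tracking: from the seed, propagate along
#' the principal eigenvector of the current voxel, changing direction only
#' at voxel boundaries. Tracking runs in both directions from the seed and
#' the half-tracks are concatenated (seed interior). Propagation terminates
#' on leaving the grid, on entering a voxel with FA below `fa_threshold`, or
#' when the turn between successive voxel directions exceeds `max_angle_deg`
#' (continuing at exactly the threshold angle). The eigenvector sign is
#' aligned with the incoming direction at every step. A seed in a
#' sub-threshold voxel yields an empty (0-point) streamline.
#'
#' @param peaks result of [tensor_peaks()] (a `tensor_field` is accepted and
#'   converted).
#' @param seed mm coordinate.
#' @param fa_threshold stopping FA, default 0.1.
#' @param max_angle_deg maximal turning angle, default 45.
#' @param max_steps safety cap on steps per half-track.
#' @return n x 3 matrix of ordered mm points (class `streamline`).
#' @export
fact_track <- function(peaks, seed, fa_threshold = 0.1, max_angle_deg = 45,
                       max_steps = 10000) {
  if (inherits(peaks, "tensor_field")) peaks <- tensor_peaks(peaks)
  geom <- peaks$geom
  cosmin <- cos(max_angle_deg * pi / 180)
  fa_at <- function(v) peaks$fa[v[1], v[2], v[3]]
  e1_at <- function(v) peaks$e1[v[1], v[2], v[3], ]

  v0 <- as.vector(point_to_voxel(seed, geom))
  if (!in_grid(v0, geom) || is.na(fa_at(v0)) || fa_at(v0) < fa_threshold)
    return(structure(matrix(numeric(0), 0, 3), class = "streamline"))

  half <- function(sgn) {
    v <- v0
    d <- e1_at(v) * sgn
    p <- seed
    pts <- NULL
    for (step in seq_len(max_steps)) {
      ex <- voxel_exit(p, d, v, geom)
      pts <- rbind(pts, ex$point)
      nxt_p <- ex$point + 1e-6 * d
      v2 <- as.vector(point_to_voxel(nxt_p, geom))
      if (!in_grid(v2, geom)) break
      f2 <- fa_at(v2)
      if (is.na(f2) || f2 < fa_threshold) break
      d2 <- e1_at(v2)
      if (any(is.na(d2))) break
      if (sum(d2 * d) < 0) d2 <- -d2
      if (sum(d2 * d) < cosmin - 1e-9) break       # angle > max: terminate
      v <- v2; p <- ex$point; d <- d2
    }
    pts
  }
  fwd <- half(1)
  bwd <- half(-1)
  pts <- rbind(bwd[rev(seq_len(nrow(bwd))), , drop = FALSE],
               matrix(seed, 1, 3), fwd)
  structure(unname(pts), class = "streamline")
}

#' Track from many seeds
#'
#' @param peaks see [fact_track()].
#' @param seeds n x 3 matrix of seed coordinates.
#' @param min_points streamlines with fewer points are dropped.
#' @inheritParams fact_track
#' @return list of streamlines.
#' @export
track_all <- function(peaks, seeds, fa_threshold = 0.1, max_angle_deg = 45,
                      min_points = 2) {
  if (inherits(peaks, "tensor_field")) peaks <- tensor_peaks(peaks)
  out <- lapply(seq_len(nrow(seeds)), function(i)
    fact_track(peaks, seeds[i, ], fa_threshold, max_angle_deg))
  out[vapply(out, nrow, 0L) >= min_points]
}

#' ROI set for bundle selection
#'
#' @param include list of logical include masks (a streamline must intersect
#'   every one); must be non-empty and each mask must select voxels.
#' @param exclude list of logical exclude masks (intersecting any rejects).
#' @param geom grid geometry of the masks (model space).
#' @export
roi_set <- function(include, exclude = list(), geom) {
  stopifnot(length(include) >= 1)
  if (any(!vapply(include, any, TRUE))) stop("include ROI with empty mask")
  structure(list(include = include, exclude = exclude, geom = geom),
            class = "roi_set")
}

# voxels crossed by a polyline: dense sampling along each segment at a
# quarter of the smallest voxel dimension (digital line traversal)
polyline_voxels <- function(pts, geom) {
  if (nrow(pts) == 0) return(matrix(integer(0), 0, 3))
  step <- min(geom$voxel_size) / 4
  seg <- diff(pts)
  len <- sqrt(rowSums(seg^2))
  samp <- pts[1, , drop = FALSE]
  for (i in seq_len(nrow(seg))) {
    if (len[i] < 1e-12) next
    tt <- seq(0, len[i], by = step) / len[i]
    samp <- rbind(samp, matrix(pts[i, ], length(tt), 3, byrow = TRUE) +
                    outer(tt, seg[i, ]))
  }
  v <- point_to_voxel(samp, geom)
  v <- v[in_grid(v, geom), , drop = FALSE]
  unique(v)
}

streamline_hits <- function(pts, mask, geom) {
  v <- polyline_voxels(pts, geom)
  if (nrow(v) == 0) return(FALSE)
  any(mask[v])
}

#' Select a named bundle with include/exclude ROIs
#'
#' Retains exactly the streamlines that intersect every include ROI and no
#' exclude ROI, after optionally warping streamline geometry into the ROI
#' (model) space. The returned bundle carries its geometry in model space.
#'
#' @param streamlines list of streamlines (native space).
#' @param rois a [roi_set()] in model space.
#' @param warp_to_model optional function mapping an n x 3 point matrix from
#'   native to model space (identity when `NULL`).
#' @param name bundle label.
#' @return object of class `bundle`: list of selected streamlines (model
#'   space) plus `name`.
#' @export
select_bundle <- function(streamlines, rois, warp_to_model = NULL,
                          name = "bundle") {
  warped <- if (is.null(warp_to_model)) streamlines
            else lapply(streamlines, function(s) {
              out <- warp_to_model(unclass(s))
              attributes(out)$scalars <- attr(s, "scalars")
              class(out) <- "streamline"
              out
            })
  keep <- vapply(warped, function(s) {
    all(vapply(rois$include, function(m) streamline_hits(s, m, rois$geom), TRUE)) &&
      !any(vapply(rois$exclude, function(m) streamline_hits(s, m, rois$geom), TRUE))
  }, TRUE)
  structure(list(streamlines = warped[keep], name = name), class = "bundle")
}

#' Attach per-point scalar values to a bundle
#'
#' Samples each map at every streamline point by nearest-neighbor (the voxel
#' containing the point, matching the voxel-wise FACT logic); points outside
#' the map are flagged missing (`NA`). Maps must be in the frame the
#' streamline geometry currently uses (sample before warping).
#'
#' @param bundle a `bundle` (or plain list of streamlines).
#' @param maps named list of [scalar_map()]s, e.g. `list(FA = ..., AD = ...,
#'   RD = ...)`.
#' @return the bundle with a `scalars` attribute (data.frame per streamline).
#' @export
superimpose_scalars <- function(bundle, maps) {
  sls <- if (inherits(bundle, "bundle")) bundle$streamlines else bundle
  out <- lapply(sls, function(s) {
    vals <- lapply(maps, function(m) {
      v <- point_to_voxel(unclass(s), m$geom)
      ok <- in_grid(v, m$geom)
      x <- rep(NA_real_, nrow(v))
      x[ok] <- m$data[v[ok, , drop = FALSE]]
      x
    })
    attr(s, "scalars") <- as.data.frame(vals)
    s
  })
  if (inherits(bundle, "bundle")) {
    bundle$streamlines <- out
    bundle
  } else out
}
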