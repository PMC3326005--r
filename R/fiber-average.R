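#' Resample a polyline at regular arc-length steps
#'
#' Linear interpolation of coordinates (and any attached per-point scalars)
#' at arc positions `0, step, 2 step, ...` along the line; the final point is
#' kept so total length is preserved to within one step.
#'
#' @param pts n x 3 point matrix (a `streamline` works).
#' @param step arc step in mm.
#' @return point matrix with attribute `scalars` carried through when
#'   present.
#' @export
resample_polyline <- function(pts, step = 0.5) {
  sc <- attr(pts, "scalars")
  pts <- unclass(pts)
  if (nrow(pts) < 2) return(pts)
  cum <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  L <- cum[length(cum)]
  s <- unique(c(seq(0, L, by = step), L))
  out <- vapply(1:3, function(ax) stats::approx(cum, pts[, ax], xout = s,
                                                ties = "ordered")$y,
                numeric(length(s)))
  if (!is.null(sc)) {
    attr(out, "scalars") <- as.data.frame(lapply(sc, function(col)
      stats::approx(cum, col, xout = s, ties = "ordered")$y))
  }
  out
}

# point (and scalars) at a given arc position along a polyline
point_at_arc <- function(pts, s) {
  cum <- c(0, cumsum(sqrt(rowSums(diff(unclass(pts))^2))))
  out <- vapply(1:3, function(ax) stats::approx(cum, unclass(pts)[, ax],
                                                xout = s, ties = "ordered")$y,
                numeric(length(s)))
  matrix(out, ncol = 3)
}

# consistent orientation: flip streamlines whose end-to-end vector opposes
# the dominant direction of all midpoint-to-endpoint vectors
orient_polylines <- function(pls) {
  vecs <- do.call(rbind, lapply(pls, function(p) {
    p <- unclass(p)
    cum <- c(0, cumsum(sqrt(rowSums(diff(p)^2))))
    mid <- point_at_arc(p, cum[length(cum)] / 2)[1, ]
    rbind(p[nrow(p), ] - mid, mid - p[1, ])
  }))
  M <- crossprod(vecs)
  u <- eigen(M, symmetric = TRUE)$vectors[, 1]
  if (u[which.max(abs(u))] < 0) u <- -u
  flipped <- lapply(pls, function(p) {
    ee <- unclass(p)[nrow(p), ] - unclass(p)[1, ]
    if (sum(ee * u) < 0) {
      sc <- attr(p, "scalars")
      q <- unclass(p)[rev(seq_len(nrow(p))), , drop = FALSE]
      if (!is.null(sc)) attr(q, "scalars") <- sc[rev(seq_len(nrow(sc))), , drop = FALSE]
      q
    } else p
  })
  list(polylines = flipped, direction = u)
}

# centered moving average; the window shrinks symmetrically near the ends so
# endpoints stay fixed and straight polylines are left exactly unchanged
moving_average <- function(m, window = 5) {
  if (is.null(dim(m))) m <- matrix(m, ncol = 1)
  half <- window %/% 2
  n <- nrow(m)
  out <- m
  for (i in seq_len(n)) {
    h <- min(half, i - 1, n - i)
    if (h == 0) next
    out[i, ] <- colMeans(m[(i - h):(i + h), , drop = FALSE])
  }
  out
}

#' Individual average fiber of a bundle
#'
#' Streamlines are resampled to a fine arc step and consistently oriented;
#' the spatial average of their arc-length midpoints is the start node (node
#' 0), and node n is the mean over streamlines of the point at arc distance
#' `2n` mm (signed) from each streamline's own midpoint — so short
#' streamlines stop contributing beyond their ends and the per-node
#' contributor count drops. Node coordinates are then smoothed with a
#' moving-average window and resampled back to the 2-mm node spacing.
#' Per-point scalars attached by [superimpose_scalars()] are averaged into
#' per-node means.
#'
#' @param bundle a `bundle` or list of streamlines (non-empty).
#' @param step_mm node spacing, default 2.
#' @param presample_mm fine resampling step before arc computations.
#' @param smooth_window moving-average window in nodes (odd; 1 disables).
#' @param resample logical; resample the smoothed polyline back to `step_mm`
#'   arc spacing.
#' @return object of class `average_fiber`: `nodes` (matrix), `index`
#'   (signed integers, 0 = start), `count` (contributors per node), optional
#'   `scalars` (data.frame of per-node means).
#' @export
individual_average_fiber <- function(bundle, step_mm = 2, presample_mm = 0.5,
                                     smooth_window = 5, resample = TRUE) {
  sls <- if (inherits(bundle, "bundle")) bundle$streamlines else bundle
  if (length(sls) == 0) stop("empty bundle")
  sls <- lapply(sls, resample_polyline, step = presample_mm)
  ori <- orient_polylines(sls)
  sls <- ori$polylines
  lens <- vapply(sls, function(p)
    sum(sqrt(rowSums(diff(unclass(p))^2))), 0)
  nmax <- ceiling(max(lens) / 2 / step_mm)
  idx <- seq(-nmax, nmax)
  has_sc <- !is.null(attr(sls[[1]], "scalars"))
  sc_names <- if (has_sc) names(attr(sls[[1]], "scalars"))
  acc <- matrix(0, length(idx), 3)
  acc_sc <- if (has_sc) matrix(0, length(idx), length(sc_names))
  cnt <- integer(length(idx))
  for (s in seq_along(sls)) {
    p <- sls[[s]]
    arcs <- lens[s] / 2 + idx * step_mm
    ok <- arcs >= -1e-9 & arcs <= lens[s] + 1e-9
    pa <- point_at_arc(p, pmin(pmax(arcs[ok], 0), lens[s]))
    acc[ok, ] <- acc[ok, ] + pa
    cnt[ok] <- cnt[ok] + 1L
    if (has_sc) {
      cum <- c(0, cumsum(sqrt(rowSums(diff(unclass(p))^2))))
      sc <- attr(p, "scalars")
      vals <- vapply(sc_names, function(nm)
        stats::approx(cum, sc[[nm]], xout = pmin(pmax(arcs[ok], 0), lens[s]),
                      ties = "ordered")$y, numeric(sum(ok)))
      acc_sc[ok, ] <- acc_sc[ok, ] + vals
    }
  }
  keep <- cnt > 0
  nodes <- acc[keep, , drop = FALSE] / cnt[keep]
  index <- idx[keep]
  count <- cnt[keep]
  scal <- if (has_sc) acc_sc[keep, , drop = FALSE] / cnt[keep]
  if (smooth_window > 1) nodes <- moving_average(nodes, smooth_window)
  fiber <- new_average_fiber(nodes, index, count,
                             if (has_sc) stats::setNames(as.data.frame(scal), sc_names))
  if (resample) fiber <- resample_average_fiber(fiber, step_mm)
  fiber
}

new_average_fiber <- function(nodes, index, count, scalars = NULL) {
  structure(list(nodes = nodes, index = as.integer(index),
                 count = as.numeric(count), scalars = scalars),
            class = "average_fiber")
}

# re-space nodes at step_mm arc intervals, keeping node 0 fixed
resample_average_fiber <- function(fiber, step_mm = 2) {
  nodes <- fiber$nodes
  if (nrow(nodes) < 2) return(fiber)
  cum <- c(0, cumsum(sqrt(rowSums(diff(nodes)^2))))
  i0 <- which(fiber$index == 0)
  s0 <- cum[i0]
  L <- cum[length(cum)]
  n_lo <- floor(s0 / step_mm + 1e-9)
  n_hi <- floor((L - s0) / step_mm + 1e-9)
  new_idx <- seq(-n_lo, n_hi)
  s <- pmin(pmax(s0 + new_idx * step_mm, 0), L)
  pts <- vapply(1:3, function(ax) stats::approx(cum, nodes[, ax], xout = s,
                                                ties = "ordered")$y,
                numeric(length(s)))
  nearest <- vapply(s, function(x) which.min(abs(cum - x)), 0L)
  scal <- if (!is.null(fiber$scalars))
    fiber$scalars[nearest, , drop = FALSE]
  new_average_fiber(pts, new_idx, fiber$count[nearest], scal)
}

#' @export
print.average_fiber <- function(x, ...) {
  cat(sprintf("<average_fiber> %d nodes (index %d..%d), contributors %g..%g\n",
              nrow(x$nodes), min(x$index), max(x$index),
              min(x$count), max(x$count)))
  invisible(x)
}

#' Group average fiber
#'
#' Averages individual average fibers node-wise, matching nodes by their
#' signed index after aligning orientations across individuals. Nodes to
#' which strictly less than `min_fraction` of the sample contributes are
#' trimmed from the ends (node 0 is never removed): the outer ends of fiber
#' bundles differ across individuals near gray matter, so only parts common
#' to most of the sample are kept.
#'
#' @param individual_fibers non-empty list of `average_fiber`s in a common
#'   (model) space.
#' @param min_fraction minimum contribution fraction, default 0.25.
#' @return an `average_fiber`; `count` holds the number of contributing
#'   individuals per node and `fraction` the corresponding fraction.
#' @export
group_average_fiber <- function(individual_fibers, min_fraction = 0.25) {
  if (length(individual_fibers) == 0) stop("no individual fibers supplied")
  nf <- length(individual_fibers)
  ori <- orient_polylines(lapply(individual_fibers, `[[`, "nodes"))
  fibers <- individual_fibers
  for (i in seq_len(nf)) {
    flipped <- !identical(ori$polylines[[i]], individual_fibers[[i]]$nodes)
    if (flipped) {
      f <- fibers[[i]]
      ord <- rev(seq_len(nrow(f$nodes)))
      fibers[[i]] <- new_average_fiber(f$nodes[ord, , drop = FALSE],
                                       -f$index[ord], f$count[ord],
                                       if (!is.null(f$scalars))
                                         f$scalars[ord, , drop = FALSE])
    }
  }
  rng <- range(unlist(lapply(fibers, `[[`, "index")))
  idx <- seq(rng[1], rng[2])
  acc <- matrix(0, length(idx), 3)
  cnt <- integer(length(idx))
  sc_names <- if (!is.null(fibers[[1]]$scalars)) names(fibers[[1]]$scalars)
  acc_sc <- if (!is.null(sc_names)) matrix(0, length(idx), length(sc_names))
  for (f in fibers) {
    pos <- match(f$index, idx)
    acc[pos, ] <- acc[pos, ] + f$nodes
    cnt[pos] <- cnt[pos] + 1L
    if (!is.null(sc_names) && !is.null(f$scalars))
      acc_sc[pos, ] <- acc_sc[pos, ] + as.matrix(f$scalars)
  }
  frac <- cnt / nf
  keep <- frac >= min_fraction | idx == 0
  # trim only from the ends: keep the contiguous run around node 0
  i0 <- match(0L, idx)
  lo <- i0; while (lo > 1 && keep[lo - 1]) lo <- lo - 1
  hi <- i0; while (hi < length(idx) && keep[hi + 1]) hi <- hi + 1
  sel <- lo:hi
  sel <- sel[cnt[sel] > 0]
  out <- new_average_fiber(acc[sel, , drop = FALSE] / cnt[sel], idx[sel],
                           cnt[sel],
                           if (!is.null(sc_names))
                             stats::setNames(as.data.frame(
                               acc_sc[sel, , drop = FALSE] / cnt[sel]), sc_names))
  out$fraction <- frac[sel]
  out
}

#' Project an individual fiber onto the group average
#'
#' Assigns every individual node to its nearest group node, summarizes the
#' node-to-group distances (mean by default, switchable to max), and flags
#' the measurement unreliable when the summary exceeds `max_dist_mm` (1 cm):
#' unreliable projections carry no scalar summaries. Otherwise per-group-node
#' scalar means and equal-weight bundle-level means are returned.
#'
#' @param fiber individual `average_fiber` (with per-node scalars for scalar
#'   summaries).
#' @param group group-level `average_fiber`.
#' @param max_dist_mm unreliability cutoff, default 10.
#' @param summary `"mean"` or `"max"` distance summary.
#' @return object of class `projection_result`: `reliable`, `distance`,
#'   `assignment`, `node_means`, `bundle_means`.
#' @export
project_bundle <- function(fiber, group, max_dist_mm = 10,
                           summary = c("mean", "max")) {
  summary <- match.arg(summary)
  d2 <- outer(rowSums(fiber$nodes^2), rowSums(group$nodes^2), `+`) -
    2 * fiber$nodes %*% t(group$nodes)
  nearest <- max.col(-d2, ties.method = "first")
  dmin <- sqrt(pmax(d2[cbind(seq_len(nrow(fiber$nodes)), nearest)], 0))
  dsum <- if (summary == "mean") mean(dmin) else max(dmin)
  reliable <- dsum <= max_dist_mm
  node_means <- bundle_means <- NULL
  if (reliable && !is.null(fiber$scalars)) {
    sc <- as.matrix(fiber$scalars)
    node_means <- apply(sc, 2, function(col)
      tapply(col, factor(nearest, levels = seq_len(nrow(group$nodes))),
             mean, na.rm = TRUE))
    bundle_means <- colMeans(sc, na.rm = TRUE)
  }
  structure(list(reliable = reliable, distance = dsum,
                 distances = dmin, assignment = nearest,
                 node_means = node_means, bundle_means = bundle_means,
                 summary = summary),
            class = "projection_result")
}

#' Voxel mask of a fiber (bundle) in model space
#'
#' Flags every voxel that any fiber segment passes through (digital line
#' traversal of the node polyline).
#'
#' @param fiber an `average_fiber` (or any n x 3 point matrix).
#' @param geom model-space grid geometry.
#' @return logical array.
#' @export
bundle_mask <- function(fiber, geom) {
  pts <- if (inherits(fiber, "average_fiber")) fiber$nodes else rbind_pts(fiber)
  v <- polyline_voxels(pts, geom)
  m <- array(FALSE, geom$shape)
  m[v] <- TRUE
  m
}

#' Group count map from individual bundle masks
#'
#' @param masks list of logical arrays on a common grid.
#' @return integer array of per-voxel counts (at most `length(masks)`).
#' @export
group_count_map <- function(masks) {
  Reduce(`+`, lapply(masks, function(m) m * 1L))
}

#' Group-weighted Jacobian average over a subject's bundle mask
#'
#' Mean of the Jacobian determinant over the subject's bundle-mask voxels,
#' weighted by the group count map (weight = group count at the voxel /
#' total count over the subject's mask), so voxels traversed by many
#' individuals dominate.
#'
#' @param mask subject's logical bundle mask.
#' @param group_counts group count map ([group_count_map()]).
#' @param jacobian Jacobian [scalar_map()] or array on the same grid.
#' @return weighted mean |J|; `NA` with attribute `undefined` for an empty
#'   mask.
#' @export
bundle_jacobian_summary <- function(mask, group_counts, jacobian) {
  j <- if (inherits(jacobian, "scalar_map")) jacobian$data else jacobian
  stopifnot(all(dim(mask) == dim(j)), all(dim(mask) == dim(group_counts)))
  w <- group_counts[mask]
  if (length(w) == 0 || sum(w) == 0)
    return(structure(NA_real_, undefined = TRUE))
  sum(w * j[mask]) / sum(w)
}
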