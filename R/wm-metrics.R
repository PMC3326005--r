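#' Pure white matter mask
#'
#' Selects voxels whose white-matter partial-volume fraction is at least the
#' threshold (inclusive: a voxel with exactly 90% content is "pure" white
#' matter under the default).
#'
#' @param wm_fraction a [scalar_map()] of fractions in [0, 1].
#' @param threshold minimum fraction, default 0.90.
#' @return logical array of the grid shape.
#' @export
pure_wm_mask <- function(wm_fraction, threshold = 0.90) {
  d <- if (inherits(wm_fraction, "scalar_map")) wm_fraction$data else wm_fraction
  if (any(d < -1e-9 | d > 1 + 1e-9, na.rm = TRUE))
    stop("wm fractions must lie in [0, 1]")
  !is.na(d) & d >= threshold
}

#' Mean of a scalar map inside a mask
#'
#' Arithmetic mean over masked voxels; voxels flagged undefined (`NA`) are
#' excluded. An empty mask yields `NA` with attribute `undefined = TRUE`.
#'
#' @param map a [scalar_map()] or array.
#' @param mask logical array of the same shape.
#' @export
mean_in_mask <- function(map, mask) {
  d <- if (inherits(map, "scalar_map")) map$data else map
  stopifnot(all(dim(d) == dim(mask)))
  v <- d[mask]
  v <- v[!is.na(v)]
  if (length(v) == 0)
    return(structure(NA_real_, undefined = TRUE))
  mean(v)
}

#' Extreme-growth groups
#'
#' Splits subjects by relative change into a high group (change strictly
#' above mean + k sd) and a low group (strictly below mean - k sd), with the
#' sample (n-1) standard deviation. With zero variance both groups are empty.
#'
#' @param changes named vector of per-subject relative changes (names are
#'   subject ids; indices used if unnamed).
#' @param k cutoff multiplier, default 1.
#' @return list with `high` and `low` id vectors, `mean`, `sd`.
#' @export
extreme_groups <- function(changes, k = 1) {
  if (length(changes) < 3) stop("need at least 3 subjects")
  ids <- if (is.null(names(changes))) as.character(seq_along(changes)) else names(changes)
  m <- mean(changes); s <- stats::sd(changes)
  if (s == 0) return(list(high = character(0), low = character(0), mean = m, sd = s))
  list(high = ids[changes > m + k * s], low = ids[changes < m - k * s],
       mean = m, sd = s)
}

#' FA histogram over a mask, voxels pooled across subjects
#'
#' @param maps list of [scalar_map()]s (or arrays), one per subject.
#' @param mask common-space logical mask.
#' @param breaks histogram bin edges (default 64 equal bins on [0, 1]).
#' @return list with `breaks`, `counts`, `density` (normalized frequencies),
#'   `mean` and `n_values`.
#' @export
fa_histogram <- function(maps, mask, breaks = seq(0, 1, length.out = 65)) {
  vals <- unlist(lapply(maps, function(m) {
    d <- if (inherits(m, "scalar_map")) m$data else m
    v <- d[mask]
    v[!is.na(v)]
  }))
  h <- graphics::hist(clamp(vals, min(breaks), max(breaks)), breaks = breaks,
                      plot = FALSE)
  list(breaks = breaks, counts = h$counts, density = h$counts / length(vals),
       mean = mean(vals), n_values = length(vals))
}

#' Compare FA histograms between extreme-growth groups
#'
#' Pools pure-white-matter FA values per group and session, and reports the
#' per-group mean FA at each session, the within-group histogram shift
#' (difference of session means), the between-group difference of those
#' shifts, and the probability mass below a low-FA cutoff (a rise there would
#' indicate newly included crossing-fiber voxels).
#'
#' @param group_a_maps,group_b_maps lists with elements `age9` and `age12`,
#'   each a list of per-subject FA maps in common space.
#' @param mask common pure-white-matter mask.
#' @param breaks histogram bin edges.
#' @param low_fa cutoff for the low-FA tail mass, default 0.25.
#' @return nested list of histograms and summary statistics.
#' @export
compare_histograms <- function(group_a_maps, group_b_maps, mask,
                               breaks = seq(0, 1, length.out = 65),
                               low_fa = 0.25) {
  for (g in list(group_a_maps, group_b_maps))
    if (length(g$age9) == 0 || length(g$age12) == 0)
      stop("each group needs maps at both sessions")
  one_group <- function(g) {
    h9 <- fa_histogram(g$age9, mask, breaks)
    h12 <- fa_histogram(g$age12, mask, breaks)
    low_mass <- function(h) sum(h$density[h$breaks[-1] <= low_fa])
    list(age9 = h9, age12 = h12,
         mean_9 = h9$mean, mean_12 = h12$mean,
         shift = h12$mean - h9$mean,
         low_tail_9 = low_mass(h9), low_tail_12 = low_mass(h12))
  }
  a <- one_group(group_a_maps); b <- one_group(group_b_maps)
  list(group_a = a, group_b = b,
       shift_difference = a$shift - b$shift,
       low_tail_change_a = a$low_tail_12 - a$low_tail_9,
       low_tail_change_b = b$low_tail_12 - b$low_tail_9)
}
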