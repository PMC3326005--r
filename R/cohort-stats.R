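#' Relative change in percent
#'
#' `100 * (x12 - x9) / x9`, the percent change from the age-9 to the age-12
#' measurement. Vectorized; a zero baseline yields `NA` with a warning rather
#' than an infinite value.
#'
#' @param x9,x12 baseline and follow-up values (same units).
#' @export
relative_change <- function(x9, x12) {
  out <- 100 * (x12 - x9) / x9
  if (any(x9 == 0, na.rm = TRUE)) {
    warning("relative change undefined where baseline is 0; returning NA")
    out[x9 == 0] <- NA_real_
  }
  out
}

#' Paired t-test on longitudinal measurements
#'
#' Classical paired t-test on within-subject differences. By default degrees
#' of freedom are per child (`n - 1`); with `family_adjust = TRUE` the df are
#' replaced by (number of distinct families) - 1 to account for familial
#' dependency, the same device applied to correlations in
#' [family_adjusted_pearson()].
#'
#' @param x9,x12 paired values; only subjects with both sessions enter.
#' @param family_ids optional family identifiers (required for
#'   `family_adjust`).
#' @param family_adjust replace df by families - 1.
#' @return list with `t`, `df`, `p`, `mean_diff`, `n`, and `degenerate` flag
#'   (zero difference variance).
#' @export
paired_t <- function(x9, x12, family_ids = NULL, family_adjust = FALSE) {
  ok <- stats::complete.cases(x9, x12)
  x9 <- x9[ok]; x12 <- x12[ok]
  if (!is.null(family_ids)) family_ids <- family_ids[ok]
  n <- length(x9)
  if (n < 2) stop("need at least 2 complete pairs")
  d <- x12 - x9
  if (stats::sd(d) == 0)
    return(list(t = NA_real_, df = n - 1L, p = NA_real_, mean_diff = mean(d),
                n = n, degenerate = TRUE))
  tt <- stats::t.test(x12, x9, paired = TRUE)
  df <- unname(tt$parameter)
  tval <- unname(tt$statistic)
  if (family_adjust) {
    if (is.null(family_ids)) stop("family_ids required for family adjustment")
    df <- length(unique(family_ids)) - 1L
  }
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df),
       mean_diff = unname(tt$estimate), n = n, degenerate = FALSE)
}

#' Pearson correlation with family-adjusted degrees of freedom
#'
#' The correlation coefficient is the ordinary Pearson r over individuals;
#' the p-value, however, uses df = (number of distinct families) - 2 instead
#' of (number of children) - 2, so that twins from the same family do not
#' inflate the effective sample size.
#'
#' @param x,y trait vectors over individuals.
#' @param family_ids family identifier per individual.
#' @return list with `r`, `df`, `t`, `p`, `n_individuals`, `n_families`.
#' @export
family_adjusted_pearson <- function(x, y, family_ids) {
  ok <- stats::complete.cases(x, y, family_ids)
  x <- x[ok]; y <- y[ok]; family_ids <- family_ids[ok]
  nf <- length(unique(family_ids))
  if (nf < 3) stop("need at least 3 families")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, df = nf - 2L, t = NA_real_, p = NA_real_,
                n_individuals = length(x), n_families = nf, degenerate = TRUE))
  r <- stats::cor(x, y)
  df <- nf - 2L
  tval <- r * sqrt(df / (1 - r^2))
  list(r = r, df = df, t = tval, p = 2 * stats::pt(-abs(tval), df),
       n_individuals = length(x), n_families = nf, degenerate = FALSE)
}

#' Longitudinal change summary for a set of traits
#'
#' For each trait, the group-level percent change of means (matching how
#' printed cohort tables report change) together with the mean of individual
#' percent changes, and the paired t-test.
#'
#' @param data data.frame with columns `<trait>_9` and `<trait>_12` per trait
#'   plus optional `family_id`.
#' @param traits base trait names.
#' @param family_adjust passed to [paired_t()].
#' @return data.frame, one row per trait.
#' @export
change_table <- function(data, traits, family_adjust = FALSE) {
  rows <- lapply(traits, function(tr) {
    x9 <- data[[paste0(tr, "_9")]]; x12 <- data[[paste0(tr, "_12")]]
    ok <- stats::complete.cases(x9, x12)
    tt <- paired_t(x9, x12, family_ids = data$family_id[ok],
                   family_adjust = family_adjust)
    data.frame(trait = tr, n = tt$n,
               mean_9 = mean(x9[ok]), sd_9 = stats::sd(x9[ok]),
               mean_12 = mean(x12[ok]), sd_12 = stats::sd(x12[ok]),
               pct_change_of_means = relative_change(mean(x9[ok]), mean(x12[ok])),
               mean_pct_change = mean(relative_change(x9[ok], x12[ok])),
               t = tt$t, df = tt$df, p = tt$p)
  })
  do.call(rbind, rows)
}
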