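#' Variance components for a twin model
#'
#' Holds trait-by-trait additive-genetic (A), common-environment (C) and
#' unique-environment (E) covariance matrices together with the mean model
#' (per-trait intercept plus fixed effects of sex and handedness on the
#' means). Matrices are validated as symmetric positive semidefinite; model
#' fitting parameterizes them through Cholesky factors so this holds by
#' construction.
#'
#' @param A,C,E trait x trait covariance matrices (scalars accepted for one
#'   trait). `C` defaults to zero (an AE model).
#' @param beta 3 x n_trait matrix of mean coefficients, rows = (intercept,
#'   male offset, non-right-handed offset). Defaults to zero means.
#' @param traits optional trait names.
#' @return object of class `variance_components`.
#' @export
variance_components <- function(A, E, C = NULL, beta = NULL, traits = NULL) {
  A <- as.matrix(A); E <- as.matrix(E)
  nt <- nrow(A)
  if (is.null(C)) C <- matrix(0, nt, nt) else C <- as.matrix(C)
  stopifnot(all(dim(A) == nt), all(dim(C) == nt), all(dim(E) == nt))
  for (m in list(A = A, C = C, E = E))
    if (!is_psd(m, tol = 1e-8)) stop("A, C and E must be symmetric PSD")
  if (is.null(beta)) beta <- matrix(0, 3, nt)
  beta <- as.matrix(beta)
  stopifnot(nrow(beta) == 3, ncol(beta) == nt)
  if (is.null(traits)) traits <- paste0("trait", seq_len(nt))
  structure(list(A = A, C = C, E = E, beta = beta, traits = traits),
            class = "variance_components")
}

#' Model-implied twin-pair covariance
#'
#' The 2n x 2n covariance of the stacked (twin 1 traits, twin 2 traits)
#' vector: diagonal blocks `A + C + E`; cross-twin blocks `A + C` for MZ
#' pairs (sharing all segregating genes) and `0.5 A + C` for DZ pairs
#' (sharing on average half).
#'
#' @param vc a [variance_components()].
#' @param zygosity `"MZ"` or `"DZ"`.
#' @export
implied_covariance <- function(vc, zygosity) {
  k <- switch(as.character(zygosity), MZ = 1, DZ = 0.5,
              stop("unknown zygosity label: ", zygosity))
  P <- vc$A + vc$C + vc$E
  W <- k * vc$A + vc$C
  rbind(cbind(P, W), cbind(W, P))
}

# ---- data preparation -------------------------------------------------------

#' Prepare a phenotype table for likelihood evaluation
#'
#' Canonicalizes a phenotype table into per-family stacked trait vectors
#' (twin 1 traits then twin 2 traits) and groups families by zygosity and
#' missingness pattern, so the full-information ML likelihood can be
#' evaluated with one Cholesky per pattern instead of one per family.
#' Families with a single recorded individual or blank trait values enter
#' through their observed marginal.
#'
#' @param data phenotype `data.frame` (see [generate_twin_cohort()]).
#' @param traits trait columns to model.
#' @return object of class `twin_data` (a list of pattern groups).
#' @export
prepare_twin_data <- function(data, traits) {
  stopifnot(all(traits %in% names(data)),
            all(c("family_id", "twin_index", "zygosity") %in% names(data)))
  nt <- length(traits)
  fid <- factor(data$family_id)
  if (any(tapply(seq_along(fid), fid, length) > 2))
    stop("at most 2 individuals per family are supported")
  nfam <- nlevels(fid)
  fi <- as.integer(fid)
  w <- as.integer(data$twin_index)
  stopifnot(all(w %in% 1:2))
  zyg_by_fam <- rep(NA_character_, nfam)
  zyg_by_fam[fi] <- as.character(data$zygosity)
  chk <- tapply(as.character(data$zygosity), fid, function(z) length(unique(z)))
  if (any(chk > 1)) stop("zygosity must be constant within family")

  Y <- matrix(NA_real_, nfam, 2 * nt)
  X <- array(0, c(nfam, 2, 3))                     # intercept, male, left
  X[, , 1] <- NA                                   # mark absent rows
  for (t in seq_len(nt))
    Y[cbind(fi, (w - 1L) * nt + t)] <- data[[traits[t]]]
  X[cbind(fi, w, 1L)] <- 1
  X[cbind(fi, w, 2L)] <- as.numeric(data$sex == "M")
  hand <- if ("handedness" %in% names(data)) as.numeric(data$handedness != "R") else 0
  X[cbind(fi, w, 3L)] <- hand

  obs <- !is.na(Y)
  key <- paste(zyg_by_fam, apply(obs, 1, function(o) paste(which(o), collapse = ",")))
  keep <- rowSums(obs) > 0
  groups <- lapply(split(which(keep), key[keep]), function(idx) {
    coords <- which(obs[idx[1], ])
    list(zygosity = zyg_by_fam[idx[1]], coords = coords,
         twin_of = (coords - 1L) %/% nt + 1L,
         trait_of = (coords - 1L) %% nt + 1L,
         Y = Y[idx, coords, drop = FALSE],
         X = X[idx, , , drop = FALSE],
         n = length(idx))
  })
  structure(list(groups = groups, traits = traits, n_families = sum(keep),
                 n_obs = sum(obs)),
            class = "twin_data")
}

# fast FIML -2 log likelihood over prepared pattern groups
nll_components <- function(A, C, E, beta, prep, penalty = 1e10) {
  total <- 0
  for (g in prep$groups) {
    k <- if (g$zygosity == "MZ") 1 else 0.5
    P <- A + C + E
    W <- k * A + C
    nt <- nrow(A)
    S_full <- rbind(cbind(P, W), cbind(W, P))
    S <- S_full[g$coords, g$coords, drop = FALSE]
    cS <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(cS)) return(penalty + sum(abs(S)))   # singular implied covariance
    m <- length(g$coords)
    MU <- matrix(0, g$n, m)
    for (j in seq_len(m))
      MU[, j] <- g$X[, g$twin_of[j], , drop = TRUE] %*% beta[, g$trait_of[j]]
    R <- g$Y - MU
    V <- backsolve(cS, t(R), transpose = TRUE)       # solve t(cS) v = r
    quad <- colSums(V * V)
    total <- total + g$n * (m * log(2 * pi) + 2 * sum(log(diag(cS)))) + sum(quad)
  }
  total
}

#' Twin-model -2 log-likelihood (full-information ML)
#'
#' Sum over families of the multivariate-normal -2 log-density of the
#' observed trait values given the mean model and the zygosity-specific
#' implied covariance; missing values are marginalized (FIML), so incomplete
#' pairs contribute the marginal density of the observed co-twin. A singular
#' implied covariance yields a large finite penalty rather than an error so
#' optimizers can recover.
#'
#' @param vc a [variance_components()].
#' @param data phenotype table or a prepared [prepare_twin_data()] object.
#' @param traits trait columns (ignored when `data` is already prepared).
#' @return scalar -2 log-likelihood.
#' @export
neg2_loglik <- function(vc, data, traits = vc$traits) {
  prep <- if (inherits(data, "twin_data")) data else prepare_twin_data(data, traits)
  nll_components(vc$A, vc$C, vc$E, vc$beta, prep)
}

# ---- fitting ----------------------------------------------------------------

vech_index <- function(nt) which(lower.tri(diag(nt), diag = TRUE))

unpack_chol <- function(theta, nt) {
  L <- matrix(0, nt, nt)
  L[lower.tri(L, diag = TRUE)] <- theta
  L %*% t(L)
}

#' Fit a twin variance-component model by maximum likelihood
#'
#' Minimizes the FIML -2 log-likelihood over Cholesky factors of the A (and,
#' for ACE, C) and E covariance matrices plus mean coefficients (per-trait
#' intercept, sex and handedness fixed effects on the means). The Cholesky
#' parameterization guarantees positive semidefinite components; standardized
#' quantities (heritability a2 = A/(A+C+E) per trait, genetic/environmental
#' correlations r_g/r_e) are derived after the fit. Optimization uses
#' Nelder-Mead followed by a BFGS polish from several jittered starts.
#'
#' @param data phenotype `data.frame`.
#' @param traits trait column(s); one trait gives the univariate model, two
#'   or more the (bivariate/multivariate) Cholesky model.
#' @param model `"ACE"`, `"AE"` (no common environment) or `"E"`.
#' @param n_starts number of jittered starting points (first start is
#'   moment-based and un-jittered).
#' @param seed seed for start jitter (RNG state is restored on exit).
#' @return object of class `twin_fit`: estimates (`vc`), `minus2_loglik`,
#'   `npar`, `aic`, standardized components and convergence diagnostics.
#' @export
fit_model <- function(data, traits, model = c("AE", "ACE", "E"),
                      n_starts = 5, seed = 1L) {
  model <- match.arg(model)
  prep <- prepare_twin_data(data, traits)
  nt <- length(traits)
  zygs <- unique(vapply(prep$groups, `[[`, "", "zygosity"))
  if (model != "E" && !all(c("MZ", "DZ") %in% zygs))
    stop("both zygosity groups are required to separate A from E")
  ncl <- nt * (nt + 1) / 2
  use_a <- model %in% c("AE", "ACE")
  use_c <- model == "ACE"
  npar_var <- ncl * (use_a + use_c + 1)
  nbeta <- 3 * nt

  unpack <- function(theta) {
    i <- 0
    A <- if (use_a) unpack_chol(theta[i + seq_len(ncl)], nt) else matrix(0, nt, nt)
    if (use_a) i <- i + ncl
    C <- if (use_c) unpack_chol(theta[i + seq_len(ncl)], nt) else matrix(0, nt, nt)
    if (use_c) i <- i + ncl
    E <- unpack_chol(theta[i + seq_len(ncl)], nt)
    i <- i + ncl
    beta <- matrix(theta[i + seq_len(nbeta)], 3, nt)
    list(A = A, C = C, E = E, beta = beta)
  }
  obj <- function(theta) {
    p <- unpack(theta)
    nll_components(p$A, p$C, p$E, p$beta, prep)
  }

  # moment-based start: split the observed variance evenly across components
  sds <- vapply(traits, function(tr) stats::sd(data[[tr]], na.rm = TRUE), 0)
  mns <- vapply(traits, function(tr) mean(data[[tr]], na.rm = TRUE), 0)
  ncomp <- use_a + use_c + 1
  chol_start <- function() {
    L <- diag(sds / sqrt(ncomp), nt)
    L[lower.tri(L, diag = TRUE)]
  }
  base_start <- c(if (use_a) chol_start(), if (use_c) chol_start(), chol_start(),
                  as.vector(rbind(mns, 0, 0)))

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    th0 <- base_start
    if (s > 1) {
      jit <- stats::runif(npar_var, 0.6, 1.4)
      th0[seq_len(npar_var)] <- th0[seq_len(npar_var)] * jit
      th0[npar_var + seq_len(nbeta)] <- th0[npar_var + seq_len(nbeta)] +
        stats::rnorm(nbeta, 0, 0.05 * max(sds))
    }
    o1 <- stats::optim(th0, obj, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-10))
    o2 <- tryCatch(stats::optim(o1$par, obj, method = "BFGS",
                                control = list(maxit = 500, reltol = 1e-12)),
                   error = function(e) o1)
    cand <- if (o2$value <= o1$value) o2 else o1
    if (is.null(best) || cand$value < best$value) best <- cand
  }

  p <- unpack(best$par)
  vc <- variance_components(p$A, p$E, p$C, p$beta, traits)
  npar <- npar_var + nbeta
  std <- standardize_components(vc)
  structure(list(model = model, traits = traits, vc = vc,
                 minus2_loglik = best$value, npar = npar,
                 aic = best$value + 2 * npar,
                 standardized = std,
                 convergence = best$convergence,
                 theta = best$par, prep = prep, data = data,
                 n_starts = n_starts, seed = seed),
            class = "twin_fit")
}

standardize_components <- function(vc) {
  P <- vc$A + vc$C + vc$E
  tv <- diag(P)
  safe_cor <- function(M) {
    d <- sqrt(pmax(diag(M), 0))
    R <- M / outer(d, d)
    R[outer(d, d) < 1e-12] <- NA
    diag(R) <- ifelse(d > 1e-6, 1, NA)
    R
  }
  list(a2 = diag(vc$A) / tv, c2 = diag(vc$C) / tv, e2 = diag(vc$E) / tv,
       total_variance = tv,
       rg = safe_cor(vc$A), rc = safe_cor(vc$C), re = safe_cor(vc$E))
}

#' @export
print.twin_fit <- function(x, ...) {
  s <- x$standardized
  cat(sprintf("Twin %s model, traits: %s\n", x$model,
              paste(x$traits, collapse = ", ")))
  cat(sprintf("  -2lnL = %.3f  AIC = %.3f  (%d parameters)\n",
              x$minus2_loglik, x$aic, x$npar))
  for (i in seq_along(x$traits))
    cat(sprintf("  %s: a2 = %.3f  c2 = %.3f  e2 = %.3f\n",
                x$traits[i], s$a2[i], s$c2[i], s$e2[i]))
  if (length(x$traits) > 1)
    cat(sprintf("  r_g = %.3f  r_e = %.3f\n", s$rg[1, 2], s$re[1, 2]))
  invisible(x)
}

# ---- profiling --------------------------------------------------------------

# Constrained reparameterizations used for profiling. Each returns the -2lnL
# minimized over nuisance parameters with the target quantity held at `value`.
# Univariate: total variance + means free. Bivariate AE: the model is
# re-expressed as (total sd, a2 proportion) per trait plus r_g, r_e, which has
# the same dimension as the Cholesky AE parameterization.

#' Profiled -2 log-likelihood at a fixed parameter value
#'
#' Re-optimizes all nuisance parameters with one standardized quantity held
#' fixed. Supported targets: `"a2"` (univariate, AE or ACE; `"c2"` for ACE)
#' and, for bivariate AE fits, `"rg"`, `"re"`, `"a2.1"`, `"a2.2"`.
#'
#' @param fit a converged [fit_model()] result.
#' @param parameter target name (see above).
#' @param value value at which to constrain it.
#' @return minimized -2 log-likelihood under the constraint.
#' @export
profile_deviance <- function(fit, parameter, value) {
  prep <- fit$prep
  nt <- length(fit$traits)
  s <- fit$standardized
  if (nt == 1) {
    V0 <- s$total_variance[1]
    beta0 <- as.vector(fit$vc$beta)
    if (fit$model == "AE" && parameter == "a2") {
      obj <- function(th) {
        V <- exp(th[1])
        nll_components(matrix(value * V), matrix(0), matrix((1 - value) * V),
                       matrix(th[1 + 1:3], 3, 1), prep)
      }
      th0 <- c(log(V0), beta0)
    } else if (fit$model == "ACE" && parameter %in% c("a2", "c2")) {
      obj <- function(th) {
        V <- exp(th[1])
        other <- (1 - value) * stats::plogis(th[2])
        rest <- 1 - value - other
        p <- if (parameter == "a2") c(value, other, rest) else c(other, value, rest)
        nll_components(matrix(p[1] * V), matrix(p[2] * V), matrix(p[3] * V),
                       matrix(th[2 + 1:3], 3, 1), prep)
      }
      o2 <- if (parameter == "a2") s$c2[1] else s$a2[1]
      th0 <- c(log(V0), stats::qlogis(clamp(o2 / max(1 - value, 1e-8), 1e-6, 1 - 1e-6)),
               beta0)
    } else stop("unsupported profile target '", parameter, "' for this model")
  } else if (nt == 2 && fit$model == "AE") {
    # nuisance: log s1, log s2, qlogis a2_1, qlogis a2_2, atanh rg, atanh re
    # minus whichever is fixed
    free <- setdiff(c("s1", "s2", "a2.1", "a2.2", "rg", "re"),
                    switch(parameter, rg = "rg", re = "re",
                           a2.1 = "a2.1", a2.2 = "a2.2",
                           stop("unsupported profile target '", parameter, "'")))
    start_full <- c(s1 = log(sqrt(s$total_variance[1])),
                    s2 = log(sqrt(s$total_variance[2])),
                    a2.1 = stats::qlogis(clamp(s$a2[1], 1e-4, 1 - 1e-4)),
                    a2.2 = stats::qlogis(clamp(s$a2[2], 1e-4, 1 - 1e-4)),
                    rg = atanh(clamp(ifelse(is.na(s$rg[1, 2]), 0, s$rg[1, 2]),
                                     -1 + 1e-6, 1 - 1e-6)),
                    re = atanh(clamp(ifelse(is.na(s$re[1, 2]), 0, s$re[1, 2]),
                                     -1 + 1e-6, 1 - 1e-6)))
    beta0 <- as.vector(fit$vc$beta)
    obj <- function(th) {
      q <- start_full
      q[free] <- th[seq_along(free)]
      q[[parameter]] <- switch(parameter,
                               rg = atanh(clamp(value, -1 + 1e-9, 1 - 1e-9)),
                               re = atanh(clamp(value, -1 + 1e-9, 1 - 1e-9)),
                               stats::qlogis(clamp(value, 1e-9, 1 - 1e-9)))
      sdv <- exp(q[c("s1", "s2")])
      a2 <- stats::plogis(q[c("a2.1", "a2.2")])
      if (parameter %in% c("a2.1", "a2.2"))      # exact boundary values allowed
        a2[[parameter]] <- value
      rg <- tanh(q[["rg"]]); re <- tanh(q[["re"]])
      if (parameter == "rg") rg <- value
      if (parameter == "re") re <- value
      da <- sqrt(a2) * sdv; de <- sqrt(1 - a2) * sdv
      A <- outer(da, da) * matrix(c(1, rg, rg, 1), 2)
      E <- outer(de, de) * matrix(c(1, re, re, 1), 2)
      beta <- matrix(th[length(free) + seq_len(6)], 3, 2)
      nll_components(A, matrix(0, 2, 2), E, beta, prep)
    }
    th0 <- c(start_full[free], beta0)
  } else stop("profiling implemented for univariate fits and bivariate AE fits")
  o1 <- stats::optim(th0, obj, method = "Nelder-Mead",
                     control = list(maxit = 1500, reltol = 1e-10))
  o2 <- tryCatch(stats::optim(o1$par, obj, method = "BFGS",
                              control = list(maxit = 300, reltol = 1e-12)),
                 error = function(e) o1)
  min(o1$value, o2$value)
}

#' Profile-likelihood confidence interval
#'
#' Bounds are the parameter values at which the profiled -2 log-likelihood
#' exceeds its minimum by `delta`. The default `delta = 2.71` is the Mx
#' convention (the chi-square(1) 90th percentile, giving one-bound 95%
#' coverage for variance components); `delta = 3.84` gives the two-sided 95%
#' convention. Bounds are found by root bisection with nuisance parameters
#' re-optimized at every evaluation, and are clipped to the parameter's
#' natural range ([0,1] for standardized components, [-1,1] for
#' correlations) with a boundary flag when the profile never crosses.
#'
#' @param fit a converged [fit_model()].
#' @param parameter see [profile_deviance()].
#' @param delta deviance increase defining the interval.
#' @param tol bisection tolerance on the parameter scale.
#' @return named vector `c(lower, upper)` with attributes `boundary` (logical
#'   pair) and `estimate`.
#' @export
profile_ci <- function(fit, parameter, delta = 2.71, tol = 1e-3) {
  rng <- if (parameter %in% c("rg", "re")) c(-1, 1) else c(0, 1)
  est <- profile_estimate(fit, parameter)
  if (delta == 0)
    return(structure(c(lower = est, upper = est),
                     boundary = c(FALSE, FALSE), estimate = est))
  m0 <- fit$minus2_loglik
  g <- function(v) max(profile_deviance(fit, parameter, v) - m0, 0) - delta
  solve_side <- function(bound, lower_side) {
    gb <- g(bound)
    if (gb <= 0) return(list(x = bound, boundary = TRUE))
    r <- if (lower_side)
      stats::uniroot(g, lower = bound, upper = est, f.lower = gb,
                     f.upper = -delta, tol = tol)
    else
      stats::uniroot(g, lower = est, upper = bound, f.lower = -delta,
                     f.upper = gb, tol = tol)
    list(x = r$root, boundary = FALSE)
  }
  lo <- solve_side(rng[1], TRUE)
  hi <- solve_side(rng[2], FALSE)
  structure(c(lower = lo$x, upper = hi$x),
            boundary = c(lo$boundary, hi$boundary), estimate = est)
}

profile_estimate <- function(fit, parameter) {
  s <- fit$standardized
  switch(parameter,
         a2 = s$a2[1], c2 = s$c2[1],
         a2.1 = s$a2[1], a2.2 = s$a2[2],
         rg = s$rg[1, 2], re = s$re[1, 2],
         stop("unknown parameter '", parameter, "'"))
}

#' Likelihood-ratio and AIC comparison of nested twin models
#'
#' @param full,nested [fit_model()] results; `nested`'s free parameters must
#'   be a subset of `full`'s.
#' @param tol tolerance for a negative chi-square before the full model is
#'   re-fitted with more starts.
#' @return list with `chi2`, `df`, `p` and `delta_aic` (AIC(nested) -
#'   AIC(full); positive favors the full model).
#' @export
compare_models <- function(full, nested, tol = 1e-6) {
  if (nested$npar > full$npar) stop("'nested' has more parameters than 'full'")
  chi2 <- nested$minus2_loglik - full$minus2_loglik
  if (chi2 < -tol) {
    full <- fit_model(full$data, full$traits, model = full$model,
                      n_starts = full$n_starts + 5, seed = full$seed + 1)
    chi2 <- nested$minus2_loglik - full$minus2_loglik
    if (chi2 < -tol)
      stop("nested model fits better than full model (chi2 = ", signif(chi2, 4),
           "); check convergence")
  }
  chi2 <- max(chi2, 0)
  df <- full$npar - nested$npar
  p <- if (df == 0) 1 else stats::pchisq(chi2, df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p = p,
       delta_aic = nested$aic - full$aic)
}

#' Twin correlations and the Falconer heritability summary
#'
#' Pearson correlations within zygosity groups after double entry (each
#' complete pair entered twice, order-swapped, the standard device making the
#' correlation symmetric in twin ordering), plus cross-twin cross-trait
#' correlation matrices and the Falconer orientation summary
#' `2 (rMZ - rDZ)` per trait. Incomplete pairs are excluded.
#'
#' @param data phenotype table.
#' @param traits trait column(s).
#' @return list with `rMZ`, `rDZ` (per-trait), `cross_MZ`, `cross_DZ`
#'   (trait x trait cross-twin matrices) and `falconer_h2`.
#' @export
twin_correlations <- function(data, traits) {
  pair_mats <- function(zyg) {
    d <- data[data$zygosity == zyg, , drop = FALSE]
    d1 <- d[d$twin_index == 1, c("family_id", traits)]
    d2 <- d[d$twin_index == 2, c("family_id", traits)]
    m <- merge(d1, d2, by = "family_id", suffixes = c(".1", ".2"))
    ok <- stats::complete.cases(m)
    m <- m[ok, , drop = FALSE]
    y1 <- as.matrix(m[paste0(traits, ".1")])
    y2 <- as.matrix(m[paste0(traits, ".2")])
    list(y1 = rbind(y1, y2), y2 = rbind(y2, y1), n_pairs = nrow(m))
  }
  one <- function(zyg) {
    p <- pair_mats(zyg)
    if (p$n_pairs < 3)
      return(list(r = rep(NA_real_, length(traits)),
                  cross = matrix(NA_real_, length(traits), length(traits)),
                  n_pairs = p$n_pairs))
    r <- vapply(seq_along(traits), function(t) stats::cor(p$y1[, t], p$y2[, t]), 0)
    cross <- stats::cor(p$y1, p$y2)
    list(r = stats::setNames(r, traits), cross = cross, n_pairs = p$n_pairs)
  }
  mz <- one("MZ"); dz <- one("DZ")
  list(rMZ = mz$r, rDZ = dz$r, cross_MZ = mz$cross, cross_DZ = dz$cross,
       n_pairs = c(MZ = mz$n_pairs, DZ = dz$n_pairs),
       falconer_h2 = 2 * (mz$r - dz$r))
}
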