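uni_vc <- function(a2, e2 = 1 - a2, c2 = 0, beta = NULL)
  variance_components(A = a2, E = e2, C = c2, beta = beta)

test_that("implied pair covariance has the classical twin structure", {
  vc <- uni_vc(0.86)
  mz <- implied_covariance(vc, "MZ")
  dz <- implied_covariance(vc, "DZ")
  expect_equal(mz[1, 2], 0.86)
  expect_equal(dz[1, 2], 0.43)
  expect_equal(diag(mz), c(1, 1))
  # C = 0: MZ cross-twin block equals A exactly
  expect_equal(mz[1, 2], vc$A[1, 1])
  expect_error(implied_covariance(vc, "XZ"), "zygosity")

  A <- matrix(c(1, 0.5, 0.5, 1), 2)
  vcb <- variance_components(A = A, E = diag(2))
  expect_equal(stats::cov2cor(vcb$A)[1, 2], 0.5)   # r_g = A12 / sqrt(A11 A22)
})

test_that("-2 lnL matches closed forms and is additive over families", {
  # one MZ pair at the model mean, unit variance, zero covariance
  d <- data.frame(family_id = 1, twin_index = 1:2, zygosity = "MZ",
                  sex = "F", handedness = "R", y = c(0, 0))
  vc <- variance_components(A = 0, E = 1, traits = "y")
  expect_equal(neg2_loglik(vc, d, "y"), 2 * log(2 * pi), tolerance = 1e-12)

  spec <- cohort_spec(20, 20, a2 = 0.5, seed = 2)
  d1 <- generate_twin_cohort(spec)
  d2 <- d1
  d2$family_id <- d2$family_id + 1000
  both <- rbind(d1, d2)
  vc2 <- uni_vc(0.5)
  vc2$traits <- "trait"
  expect_equal(neg2_loglik(vc2, both, "trait"),
               2 * neg2_loglik(vc2, d1, "trait"), tolerance = 1e-9)
})

test_that("FIML reduces an incomplete pair to the observed marginal", {
  d <- data.frame(family_id = 1, twin_index = 1:2, zygosity = "MZ",
                  sex = "F", handedness = "R", y = c(1.3, NA))
  vc <- variance_components(A = 0.4, E = 0.6, traits = "y")
  expect_equal(neg2_loglik(vc, d, "y"),
               log(2 * pi) + log(1) + 1.3^2, tolerance = 1e-12)
})

test_that("univariate AE recovery works across the heritability grid", {
  errs <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(a2) {
    spec <- cohort_spec(2000, 2000, a2 = a2, seed = round(1000 * a2))
    d <- generate_twin_cohort(spec)
    f <- fit_model(d, "trait", model = "AE", n_starts = 1)
    abs(f$standardized$a2[1] - a2)
  }, 0)
  expect_lt(stats::median(errs), 0.03)
})

test_that("a null trait yields a boundary heritability estimate", {
  spec <- cohort_spec(2000, 2000, a2 = 0, seed = 4)
  d <- generate_twin_cohort(spec)
  f <- fit_model(d, "trait", model = "AE", n_starts = 1)
  expect_lte(f$standardized$a2[1], 0.02)
})

test_that("heritability is invariant to affine rescaling of the trait", {
  spec <- cohort_spec(500, 500, a2 = 0.6, seed = 6)
  d <- generate_twin_cohort(spec)
  f1 <- fit_model(d, "trait", model = "AE", n_starts = 1)
  d$trait <- d$trait * 10
  f2 <- fit_model(d, "trait", model = "AE", n_starts = 1)
  expect_equal(f1$standardized$a2[1], f2$standardized$a2[1], tolerance = 1e-3)
  expect_equal(f2$standardized$total_variance[1],
               100 * f1$standardized$total_variance[1], tolerance = 0.5)
})

test_that("sex and handedness fixed effects on the means are recovered", {
  spec <- cohort_spec(2000, 2000, a2 = 0.5, sex_effect = 0.5,
                      handedness_effect = -0.3, seed = 8)
  d <- generate_twin_cohort(spec)
  f <- fit_model(d, "trait", model = "AE", n_starts = 1)
  expect_about(f$vc$beta[2, 1], 0.5, 0.05)
  expect_about(f$vc$beta[3, 1], -0.3, 0.08)
})

test_that("bivariate AE fit recovers the environmental correlation", {
  re <- matrix(c(1, -0.67, -0.67, 1), 2)
  spec <- cohort_spec(1500, 1500, traits = c("dvol", "dfa"), a2 = c(0.1, 0.1),
                      rho_e = re, seed = 12)
  d <- generate_twin_cohort(spec)
  f <- fit_model(d, c("dvol", "dfa"), model = "AE", n_starts = 1)
  expect_about(f$standardized$re[1, 2], -0.67, 0.06)
})

test_that("profile CI collapses at delta 0 and widens as n shrinks", {
  spec_big <- cohort_spec(1000, 1000, a2 = 0.6, seed = 21)
  spec_small <- cohort_spec(50, 50, a2 = 0.6, seed = 21)
  f_big <- fit_model(generate_twin_cohort(spec_big), "trait",
                     model = "AE", n_starts = 1)
  f_small <- fit_model(generate_twin_cohort(spec_small), "trait",
                       model = "AE", n_starts = 1)
  ci0 <- profile_ci(f_big, "a2", delta = 0)
  expect_equal(unname(ci0["lower"]), unname(ci0["upper"]))
  ci_big <- profile_ci(f_big, "a2")
  ci_small <- profile_ci(f_small, "a2")
  expect_lt(ci_small["lower"], ci_big["lower"])
  expect_gt(ci_small["upper"], ci_big["upper"])
  expect_true(ci_big["lower"] < attr(ci_big, "estimate"))
  expect_true(ci_big["upper"] > attr(ci_big, "estimate"))
})

test_that("model comparison behaves under the null and the alternative", {
  cmp_self <- local({
    spec <- cohort_spec(300, 300, a2 = 0.5, seed = 31)
    d <- generate_twin_cohort(spec)
    f <- fit_model(d, "trait", model = "AE", n_starts = 1)
    compare_models(f, f)
  })
  expect_equal(cmp_self$chi2, 0)
  expect_equal(cmp_self$p, 1)

  # strong common environment: ACE must beat AE decisively
  spec_c <- cohort_spec(2000, 2000, a2 = 0.3, c2 = 0.4, seed = 32)
  d <- generate_twin_cohort(spec_c)
  ace <- fit_model(d, "trait", model = "ACE", n_starts = 1)
  ae <- fit_model(d, "trait", model = "AE", n_starts = 1)
  cmp <- compare_models(ace, ae)
  expect_equal(cmp$df, 1)
  expect_lt(cmp$p, 0.01)
  expect_gt(cmp$delta_aic, 0)
})

test_that("AIC prefers AE when common environment is absent", {
  wins <- 0L
  n_rep <- 200L
  for (r in seq_len(n_rep)) {
    spec <- cohort_spec(100, 100, a2 = 0.5, seed = 5000 + r)
    d <- generate_twin_cohort(spec)
    ace <- fit_model(d, "trait", model = "ACE", n_starts = 1)
    ae <- fit_model(d, "trait", model = "AE", n_starts = 1)
    if (compare_models(ace, ae)$delta_aic <= 0) wins <- wins + 1L
  }
  expect_gte(wins / n_rep, 0.8)
})

test_that("double-entry twin correlations hit their limits", {
  d <- data.frame(family_id = rep(1:10, each = 2), twin_index = rep(1:2, 10),
                  zygosity = "MZ", sex = "F", handedness = "R",
                  y = rep(stats::rnorm(10), each = 2))
  tc <- twin_correlations(d, "y")
  expect_equal(unname(tc$rMZ), 1, tolerance = 1e-12)

  set.seed(99)
  d$y <- stats::rnorm(20)
  tc2 <- twin_correlations(d, "y")
  expect_lt(abs(tc2$rMZ), 0.5)
  expect_true(is.na(twin_correlations(d[d$family_id < 3, ], "y")$rDZ))
})
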