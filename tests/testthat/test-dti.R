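test_that("FA closed forms hold", {
  expect_equal(fa_from_eigenvalues(1, 1, 1), 0)
  expect_equal(fa_from_eigenvalues(1, 0, 0), 1)
  expect_equal(fa_from_eigenvalues(2e-3, 2e-3, 2e-3), 0)
  # splenium age-9 eigenvalue means: AD 1.582e-3, RD 0.547e-3
  expect_about(fa_from_eigenvalues(1.582e-3, 0.547e-3, 0.547e-3), 0.588, 5e-4)
  expect_true(is.na(fa_from_eigenvalues(0, 0, 0)))
})

test_that("FA is scale-invariant and monotone in radial shrinkage", {
  l <- c(1.7, 0.6, 0.4)
  expect_equal(fa_from_eigenvalues(l[1], l[2], l[3]),
               fa_from_eigenvalues(10 * l[1], 10 * l[2], 10 * l[3]))
  rads <- seq(0.9, 0.1, by = -0.1)
  fas <- fa_from_eigenvalues(1, rads, rads)
  expect_true(all(diff(fas) > 0))
})

test_that("MD and the eigenvalue power sum are rotation invariant", {
  set.seed(42)
  l <- c(1.6, 0.5, 0.3) * 1e-3
  for (r in 1:5) {
    q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
    D <- q %*% diag(l) %*% t(q)
    ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(mean(ev), mean(l), tolerance = 1e-12)
    expect_equal(sum(ev^2), sum(l^2), tolerance = 1e-12)
  }
})

test_that("noiseless phantom tensors are recovered to machine precision", {
  ph <- make_straight_phantom()
  tf <- fit_tensor(ph$dwi, method = "ols")
  inb <- ph$wm_fraction$data == 1
  err <- abs(tf$D - ph$tensors$D)
  for (c6 in 1:6)
    expect_lt(max(err[, , , c6][inb]), 1e-10)
  # background voxels are isotropic at 0.7e-3
  eig <- tensor_eigen(tf)
  bg <- ph$wm_fraction$data == 0
  for (c3 in 1:3)
    expect_lt(max(abs(eig$evals[, , , c3][bg] - 0.7e-3)), 1e-10)
  # principal eigenvector along x everywhere in the bundle
  e1x <- abs(eig$e1[, , , 1])
  expect_gt(min(e1x[inb]), 1 - 1e-8)
})

test_that("ols and robust fits agree on noiseless data", {
  ph <- make_straight_phantom(grid = c(10, 5, 5))
  tols <- fit_tensor(ph$dwi, method = "ols")
  trob <- fit_tensor(ph$dwi, method = "robust")
  expect_lt(max(abs(tols$D - trob$D)), 1e-8)
})

test_that("robust fit beats ols under a corrupted direction", {
  ph <- make_straight_phantom(grid = c(8, 5, 5))
  dwi <- ph$dwi
  dwi$data[, , , 20] <- dwi$data[, , , 20] * 10   # one weighted volume x10
  tols <- fit_tensor(dwi, method = "ols")
  trob <- fit_tensor(dwi, method = "robust")
  frob <- function(tf) sqrt(sum((tf$D - ph$tensors$D)^2))
  expect_lt(frob(trob), frob(tols))
})

test_that("rician noise biases the b0 signal upward, shrinking with sigma", {
  bias_at <- function(sigma) {
    ph <- make_straight_phantom(grid = c(10, 6, 6), noise_sigma = sigma,
                                noise_model = "rician", seed = 9)
    mean(ph$dwi$data[, , , 1]) - 1000
  }
  b_big <- bias_at(200)
  b_small <- bias_at(20)
  expect_gt(b_big, 0)
  expect_gt(b_big, b_small)
})

test_that("scalar maps expose the eigenvalue summaries with clamping", {
  ph <- make_straight_phantom(grid = c(8, 5, 5))
  sm <- scalar_maps(ph$tensors)
  inb <- ph$wm_fraction$data == 1
  fa_true <- fa_from_eigenvalues(1.6e-3, 0.5e-3, 0.5e-3)
  expect_lt(max(abs(sm$FA$data[inb] - fa_true)), 1e-10)
  expect_lt(max(abs(sm$AD$data[inb] - 1.6e-3)), 1e-12)
  expect_lt(max(abs(sm$RD$data[inb] - 0.5e-3)), 1e-12)
  expect_true(all(sm$FA$data >= 0 & sm$FA$data <= 1, na.rm = TRUE))
})

test_that("repeat combination averages signals and enforces matching schemes", {
  ph <- make_straight_phantom(grid = c(6, 4, 4))
  same <- combine_repeats(ph$dwi, ph$dwi)
  expect_equal(same$data, ph$dwi$data)
  b <- ph$dwi
  b$data[] <- 200
  a <- ph$dwi
  a$data[] <- 100
  expect_true(all(combine_repeats(a, b)$data == 150))
  bad <- ph$dwi
  bad$scheme$bvecs[10, ] <- c(0, 0, 1)
  expect_error(combine_repeats(ph$dwi, bad), "index 10")
})

test_that("too few usable volumes flags a voxel unfit", {
  ph <- make_straight_phantom(grid = c(4, 3, 3))
  dwi <- ph$dwi
  dwi$data[1, 1, 1, 5:40] <- -1          # only 4 usable volumes left
  tf <- fit_tensor(dwi)
  expect_true(tf$unfit[1, 1, 1])
  expect_true(all(is.na(tf$D[1, 1, 1, ])))
  expect_false(tf$unfit[2, 2, 2])
})
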