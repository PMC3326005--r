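interior <- function(sh) {
  m <- array(FALSE, sh)
  m[2:(sh[1] - 1), 2:(sh[2] - 1), 2:(sh[3] - 1)] <- TRUE
  m
}

test_that("analytic and numerical Jacobians agree for canonical warps", {
  # identity
  w <- generate_deformation(warp_spec("identity"))
  expect_true(all(w$analytic_jacobian$data == 1))
  num <- jacobian_determinant(w$field)
  expect_lt(max(abs(num$data - 1)), 1e-12)

  # uniform 2% scaling: |J| = 1.02^3 = 1.061208, exact for a linear field
  w <- generate_deformation(warp_spec("uniform_scale",
                                      list(scale = 1.02)))
  expect_equal(w$analytic_jacobian$data[3, 3, 3], 1.061208, tolerance = 1e-12)
  num <- jacobian_determinant(w$field)
  expect_lt(max(abs(num$data - 1.061208)), 1e-9)

  # pure shear has unit determinant
  w <- generate_deformation(warp_spec("shear", list(alpha = 0.3)))
  expect_true(all(abs(w$analytic_jacobian$data - 1) < 1e-12))
  num <- jacobian_determinant(w$field)
  expect_lt(max(abs(num$data - 1)), 1e-9)
})

test_that("numerical Jacobian converges at second order to the analytic radial warp", {
  err_at <- function(h, n) {
    sp <- warp_spec("radial", list(amplitude = 0.05, sigma = 20),
                    grid_shape = rep(n, 3), voxel_size = h)
    w <- generate_deformation(sp)
    num <- jacobian_determinant(w$field)
    inn <- interior(sp$geom$shape)
    max(abs(num$data[inn] - w$analytic_jacobian$data[inn]))
  }
  e2 <- err_at(2, 14)          # same 28 mm field of view at both resolutions
  e1 <- err_at(1, 28)
  expect_lt(e2, 5e-3)
  expect_gt(e2 / e1, 3)        # halving the voxel cuts the error ~4x
})

test_that("determinants of composed scalings multiply", {
  s1 <- warp_spec("uniform_scale", list(scale = 1.02))
  s2 <- warp_spec("uniform_scale", list(scale = 1.05))
  comp <- warp_spec("composite", list(specs = list(s1, s2)))
  w <- generate_deformation(comp)
  num <- jacobian_determinant(w$field)
  expected <- 1.02^3 * 1.05^3
  inn <- interior(comp$geom$shape)
  expect_lt(max(abs(num$data[inn] - expected)), 1e-6)
  expect_lt(max(abs(w$analytic_jacobian$data - expected)), 1e-12)
})

test_that("affine warps conserve integrated volume", {
  sp <- warp_spec("uniform_scale", list(scale = c(1.1, 1, 1)),
                  grid_shape = c(10, 10, 10), voxel_size = 2)
  w <- generate_deformation(sp)
  vox_vol <- prod(sp$geom$voxel_size)
  region <- sum(w$analytic_jacobian$data) * vox_vol
  expect_equal(region, prod(sp$geom$shape) * vox_vol * 1.1, tolerance = 1e-9)
})

test_that("non-finite displacements are rejected with the voxel named", {
  w <- generate_deformation(warp_spec("identity", grid_shape = c(4, 4, 4)))
  w$field$u[2, 3, 1, 2] <- NaN
  expect_error(jacobian_determinant(w$field), "\\(2, 3, 1\\)")
})

test_that("the voxelwise change test matches hand-computed t statistics", {
  M <- rbind(c(1.1, 1.2, 1.3),      # t = 0.2 / (0.1 / sqrt(3)) = 3.464
             c(1, 1, 1),            # all at 1: t = 0, p = 1
             c(0.9, 1.1, 1.0))      # symmetric about 1: t = 0
  r <- voxelwise_change_test(M)
  expect_equal(r$t[1], 3.4641016, tolerance = 1e-6)
  expect_equal(r$df, 2)
  expect_equal(r$t[2], 0)
  expect_equal(r$p[2], 1)
  expect_equal(r$t[3], 0, tolerance = 1e-12)
  expect_true(r$degenerate[2])
  # degenerate voxel away from 1 gets p = 0
  r2 <- voxelwise_change_test(rbind(c(1.2, 1.2, 1.2), c(1, 1.1, 1.2)))
  expect_true(r2$degenerate[1])
  expect_equal(r2$p[1], 0)
})

test_that("BH selection reproduces hand examples", {
  r <- fdr_select(c(0.01, 0.02, 0.04, 0.05), q = 0.05)
  expect_equal(r$n_significant, 4L)
  expect_equal(r$threshold, 0.05)
  r2 <- fdr_select(c(0.2, 0.5, 0.9), q = 0.05)
  expect_equal(r2$n_significant, 0L)
  expect_equal(r2$threshold, 0)
  r3 <- fdr_select(0.04, q = 0.05)
  expect_equal(r3$n_significant, 1L)
  expect_error(fdr_select(numeric(0)), "empty")
  expect_error(fdr_select(c(0.5, 1.2)), "0, 1")
})

test_that("BH controls false rejections under the global null", {
  set.seed(123)
  any_rejection <- vapply(1:200, function(r) {
    fdr_select(stats::runif(1000), q = 0.05)$n_significant > 0
  }, TRUE)
  # with all nulls FDR equals the probability of any rejection <= q
  expect_lte(mean(any_rejection), 0.05 + 2.5 * sqrt(0.05 * 0.95 / 200))
})

test_that("a simulated expansion focus is recovered with Dice > 0.8", {
  set.seed(7)
  sh <- c(16, 16, 16)
  geom <- grid_geometry(sh, 2)
  ctr <- sh * 2 / 2
  ijk <- as.matrix(expand.grid(1:sh[1], 1:sh[2], 1:sh[3]))
  d <- sqrt(rowSums(sweep(voxel_center(ijk, geom), 2, ctr)^2))
  sphere <- array(d <= 8, sh)
  jac <- lapply(1:20, function(s)
    array(ifelse(sphere, 1.1, 1.0) + stats::rnorm(prod(sh), 0, 0.02), sh))
  vt <- voxelwise_change_test(jac)
  sel <- fdr_select(vt$p, q = 0.05)
  dice <- 2 * sum(sel$mask & sphere) / (sum(sel$mask) + sum(sphere))
  expect_gt(dice, 0.8)
})
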