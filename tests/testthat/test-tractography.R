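test_that("seed placement puts 8 distinct seeds per voxel on a regular grid", {
  geom <- grid_geometry(c(4, 4, 4), 2.5)
  m1 <- array(FALSE, c(4, 4, 4)); m1[2, 2, 2] <- TRUE
  s1 <- seed_points(m1, geom)
  expect_equal(nrow(s1), 8L)
  ctr <- voxel_center(c(2, 2, 2), geom)
  expect_equal(colMeans(s1), as.vector(ctr), tolerance = 1e-12)
  expect_true(all(abs(abs(sweep(s1, 2, ctr)) - 0.25 * 2.5) < 1e-12))

  m10 <- array(FALSE, c(4, 4, 4)); m10[1:10] <- TRUE
  expect_equal(nrow(seed_points(m10, geom)), 80L)

  madj <- array(FALSE, c(4, 4, 4)); madj[2, 2, 2] <- TRUE; madj[3, 2, 2] <- TRUE
  sadj <- seed_points(madj, geom)
  expect_equal(nrow(unique(round(sadj, 9))), 16L)   # no coincident seeds

  expect_equal(nrow(seed_points(array(FALSE, c(4, 4, 4)), geom)), 0L)
})

test_that("FACT spans a straight bundle end to end", {
  ph <- make_straight_phantom(grid = c(20, 9, 9))
  peaks <- tensor_peaks(ph$tensors)
  geom <- ph$dwi$geom
  seed <- c(10 * 2.5 - 1.25, 4.5 * 2.5, 4.5 * 2.5)   # mid-bundle
  s <- fact_track(peaks, seed)
  expect_gte(nrow(s), 2)
  expect_equal(min(s[, 1]), 0, tolerance = 1e-6)
  expect_equal(max(s[, 1]), 50, tolerance = 1e-6)
  # lateral deviation under half a voxel
  expect_lt(max(abs(s[, 2] - seed[2])), 1.25)
  expect_lt(max(abs(s[, 3] - seed[3])), 1.25)
})

test_that("FACT terminates at a 90-degree elbow and below the FA threshold", {
  tf <- make_elbow_field()
  peaks <- tensor_peaks(tf)
  seed <- c(3, 11, 3)                   # x-aligned half, mid slab
  s <- fact_track(peaks, seed)
  # may turn the corner voxel boundary but never propagates along y
  expect_lt(max(s[, 2]) - min(s[, 2]), 2 + 1e-6)

  ph <- make_straight_phantom(grid = c(12, 9, 9))
  peaks2 <- tensor_peaks(ph$tensors)
  bg_seed <- c(6 * 2.5, 1 * 2.5, 1 * 2.5)           # isotropic background
  expect_equal(nrow(fact_track(peaks2, bg_seed)), 0L)
})

test_that("tracking is deterministic and direction-reversal symmetric", {
  ph <- make_straight_phantom(grid = c(14, 7, 7))
  peaks <- tensor_peaks(ph$tensors)
  seed <- c(17.3, 8.9, 8.1)
  s1 <- fact_track(peaks, seed)
  s2 <- fact_track(peaks, seed)
  expect_identical(s1, s2)
})

test_that("raising the FA threshold never lengthens a streamline", {
  tf <- make_elbow_field()
  peaks <- tensor_peaks(tf)
  seeds <- rbind(c(3, 11, 3), c(5, 5, 3), c(20, 20, 3))
  for (i in seq_len(nrow(seeds))) {
    lens <- vapply(c(0.05, 0.1, 0.3, 0.6), function(thr) {
      s <- fact_track(peaks, seeds[i, ], fa_threshold = thr)
      if (nrow(s) < 2) 0 else sum(sqrt(rowSums(diff(unclass(s))^2)))
    }, 0)
    expect_true(all(diff(lens) <= 1e-9))
  }
})

test_that("liberal tracking yields one streamline per seed in the bundle", {
  ph <- make_straight_phantom(grid = c(12, 7, 7), radius = 4)
  peaks <- tensor_peaks(ph$tensors)
  bundle_mask_arr <- ph$wm_fraction$data == 1
  seeds <- seed_points(bundle_mask_arr, ph$dwi$geom)
  trks <- track_all(peaks, seeds)
  expect_equal(length(trks), 8L * sum(bundle_mask_arr))
})

test_that("ROI logic selects exactly the intended streamlines", {
  geom <- grid_geometry(c(10, 10, 3), 2)
  mk_mask <- function(xr, yr) {
    m <- array(FALSE, c(10, 10, 3)); m[xr, yr, ] <- TRUE; m
  }
  t_low <- straight_streamline(y = 3, z = 3, to = 19)
  t_high <- straight_streamline(y = 17, z = 3, to = 19)
  t_short <- straight_streamline(y = 3, z = 3, to = 7)

  # box around the low track only
  sel <- select_bundle(list(t_low, t_high), roi_set(list(mk_mask(1:10, 1:3)),
                                                    geom = geom))
  expect_length(sel$streamlines, 1L)
  expect_equal(sel$streamlines[[1]][1, 2], 3)

  # include ROIs at both ends retain only spanning tracks
  ends <- roi_set(list(mk_mask(1, 1:10), mk_mask(10, 1:10)), geom = geom)
  sel2 <- select_bundle(list(t_low, t_high, t_short), ends)
  expect_length(sel2$streamlines, 2L)

  # an exclude ROI on the midline removes crossing tracks
  sel3 <- select_bundle(list(t_low, t_short),
                        roi_set(list(mk_mask(1:10, 1:10)),
                                exclude = list(mk_mask(5:6, 1:10)), geom = geom))
  expect_length(sel3$streamlines, 1L)
  expect_equal(nrow(sel3$streamlines[[1]]), nrow(t_short))

  expect_error(roi_set(list(array(FALSE, c(10, 10, 3))), geom = geom), "empty")
})

test_that("scalar superimposition samples by containing voxel", {
  geom <- grid_geometry(c(10, 4, 4), 2)
  const <- scalar_map(array(0.5, c(10, 4, 4)), geom, "FA")
  s <- straight_streamline(y = 4, z = 4, to = 19)
  out <- superimpose_scalars(list(s), list(FA = const))
  expect_true(all(attr(out[[1]], "scalars")$FA == 0.5))

  two <- array(0.2, c(10, 4, 4)); two[6:10, , ] <- 0.8
  m2 <- scalar_map(two, geom, "FA")
  out2 <- superimpose_scalars(list(s), list(FA = m2))
  vals <- attr(out2[[1]], "scalars")$FA
  expect_true(all(vals[s[, 1] < 10] == 0.2))
  expect_true(all(vals[s[, 1] > 10.01] == 0.8))

  # points outside the grid are flagged missing
  s_out <- straight_streamline(y = 4, z = 4, from = -6, to = 5)
  out3 <- superimpose_scalars(list(s_out), list(FA = const))
  expect_true(any(is.na(attr(out3[[1]], "scalars")$FA)))
})

test_that("sampled FA on the phantom bundle equals the closed form", {
  ph <- make_straight_phantom(grid = c(12, 7, 7), radius = 4)
  peaks <- tensor_peaks(ph$tensors)
  sm <- scalar_maps(ph$tensors)
  seed <- c(15, 8.75, 8.75)
  s <- fact_track(peaks, seed)
  out <- superimpose_scalars(list(s), list(FA = sm$FA))
  fa_true <- fa_from_eigenvalues(1.6e-3, 0.5e-3, 0.5e-3)
  vals <- attr(out[[1]], "scalars")$FA
  expect_about(mean(vals, na.rm = TRUE), fa_true, 1e-6)
})
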