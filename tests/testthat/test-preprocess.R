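test_that("static-tissue detection keeps still voxels and rejects flow", {
  ph <- make_uniform_phantom(100, grid = c(10, 10, 10), n_phases = 5,
                             roi_shape = "box", box_dim = c(4, 4, 4))
  st <- detect_static_tissue(ph$field)
  # zero-velocity background is static, the 100 cm/s ROI is not
  roi <- array(FALSE, c(10, 10, 10)); roi[1:4, 1:4, 1:4] <- TRUE
  expect_true(all(st$mask[!roi]))
  expect_false(any(st$mask[roi]))
  expect_equal(st$sd_threshold, 5)    # 5% of venc
  expect_equal(st$mean_threshold, 10) # 10% of venc

  noisy <- ph$field
  set.seed(1)
  noisy$values <- noisy$values + array(rnorm(length(noisy$values)),
                                       dim = dim(noisy$values))
  expect_error(detect_static_tissue(noisy, sd_threshold = 0), "relax")
})

test_that("eddy-current fit recovers an injected plane exactly", {
  # noise-free polynomial data lie in the least-squares model class
  ph <- make_uniform_phantom(0, grid = c(8, 8, 8), n_phases = 4)
  plane <- matrix(c(3, 0.1, -0.05, 0,
                    -2, 0.02, 0.01, -0.03,
                    1, 0, 0.05, 0.02), 3, 4, byrow = TRUE)
  f2 <- inject_eddy_offset(ph$field, plane)
  st <- detect_static_tissue(f2)
  ec <- correct_eddy_currents(f2, st)
  expect_lt(max(abs(ec$fit$coefficients - plane)) / max(abs(plane)), 1e-8)
  expect_lt(max(abs(ec$field$values)), 1e-9)
  # post-correction static-tissue time-averaged mean ~ 0
  mu <- apply(ec$field$values, 5, mean)
  expect_lt(max(abs(mu)), 1e-9)

  # zero injected plane: identity, fit ~ 0
  st0 <- detect_static_tissue(ph$field)
  ec0 <- correct_eddy_currents(ph$field, st0)
  expect_equal(ec0$field$values, ph$field$values)
  expect_equal(max(abs(ec0$fit$coefficients)), 0)
})

test_that("eddy correction is linear and noise-robust", {
  ph <- make_uniform_phantom(0, grid = c(8, 8, 8), n_phases = 4)
  plane <- matrix(c(2, 0.05, -0.02, 0.01, rep(0, 8)), 3, 4, byrow = TRUE)
  st <- detect_static_tissue(inject_eddy_offset(ph$field, plane))
  # correcting (field + plane) equals correcting field (plane removed exactly)
  c1 <- correct_eddy_currents(inject_eddy_offset(ph$field, plane), st)
  c0 <- correct_eddy_currents(ph$field, detect_static_tissue(ph$field))
  expect_equal(c1$field$values, c0$field$values, tolerance = 1e-12)

  # coefficient error shrinks ~ 1/sqrt(N) with static-voxel count
  err_at_n <- function(grid, seed) {
    set.seed(seed)
    ph <- make_uniform_phantom(0, grid = grid, n_phases = 4)
    f <- inject_eddy_offset(ph$field, plane)
    f$values <- f$values + array(rnorm(length(f$values)), dim = dim(f$values))
    ec <- correct_eddy_currents(f, detect_static_tissue(
      f, sd_threshold = 10, mean_threshold = 20))
    abs(ec$fit$coefficients[1, 1] - plane[1, 1])
  }
  e_small <- mean(vapply(1:6, function(s) err_at_n(c(6, 6, 6), s), numeric(1)))
  e_large <- mean(vapply(1:6, function(s) err_at_n(c(16, 16, 16), s), numeric(1)))
  expect_lt(e_large, e_small)

  # degenerate static set: rank deficiency reported
  f <- make_uniform_phantom(0, grid = c(8, 8, 8), n_phases = 3)$field
  st_cop <- structure(list(mask = array(FALSE, c(8, 8, 8)), n_static = 8,
                           sd_threshold = 5, mean_threshold = 10),
                      class = "static_tissue_mask")
  st_cop$mask[, 1, 1] <- TRUE  # collinear voxels
  expect_error(correct_eddy_currents(f, st_cop), "rank")
})

test_that("temporal unwrapping matches the brute-force minimizer", {
  # (80, -80, 80) at venc 100: the -160 step triggers a +200 correction
  uw <- unwrap_velocity(series_field(c(80, -80, 80)))
  expect_equal(uw$field$values[, 1, 1, 1, 1], c(80, 120, 80))
  expect_equal(uw$report$n_wraps, 1)  # only the phase-2 step needed a shift

  # oracle: total-variation minimization over all shift assignments
  set.seed(42)
  for (i in 1:20) {
    true_series <- cumsum(runif(5, -90, 90))
    wrapped <- ((true_series + 100) %% 200) - 100
    uw <- unwrap_velocity(series_field(wrapped))
    expect_equal(uw$field$values[, 1, 1, 1, 1],
                 bf_unwrap(wrapped, 100, k_range = -3:3), tolerance = 1e-12)
  }

  # all steps within venc pass through untouched
  f <- series_field(c(10, 90, 0, -90, 5))
  uw <- unwrap_velocity(f)
  expect_identical(uw$field$values, f$values)
  expect_equal(uw$report$n_wraps, 0)
})

test_that("injected wraps at speeds below 1.8 venc are recovered exactly", {
  ph <- make_uniform_phantom(0, grid = c(8, 8, 8), n_phases = 16)
  truth <- ph$field
  amp <- 180 * sin(2 * pi * (0:15) / 16)   # peaks at 1.8 x venc
  for (p in 1:16) truth$values[p, , , , 1] <- amp[p]
  wrapped <- inject_aliasing(truth)
  expect_gt(nrow(attr(wrapped, "wrap_sites")), 0)
  rec <- unwrap_velocity(wrapped)
  expect_equal(rec$field$values, truth$values, tolerance = 1e-12)
  # unwrapping only ever shifts by integer multiples of 2 venc
  shifts <- (rec$field$values - wrapped$values) / 200
  expect_equal(shifts, round(shifts))
})

test_that("phase reconstruction interpolates periodically and preserves means", {
  # aligned output grid: identity
  ph <- make_ventricle_phantom("systolic_dominant", grid = c(12, 12, 12),
                               n_phases = 10, seed = 2)
  same <- reconstruct_phases(ph$field, 10)
  expect_equal(same$values, ph$field$values)

  # constant-in-time field stays constant for any n_out
  cf <- make_uniform_phantom(60, grid = c(6, 6, 6), n_phases = 5)$field
  up <- reconstruct_phases(cf, 13)
  expect_equal(dim(up$values)[1], 13)
  expect_true(all(abs(up$values[, 2, 2, 2, 1] - up$values[1, 2, 2, 2, 1]) == 0))

  # sinusoid: max linear-interpolation error bounded by (pi*dt)^2/8 per cycle
  n_in <- 20
  f <- series_field(50 * sin(2 * pi * (0:(n_in - 1)) / n_in))
  out <- reconstruct_phases(f, 40)
  t_out <- out$phase_times / 1000
  analytic <- 50 * sin(2 * pi * t_out)
  bound <- 50 * (pi * 2 / n_in)^2 / 8
  expect_lt(max(abs(out$values[, 1, 1, 1, 1] - analytic)), bound * 1.01)
  # cycle mean preserved within 1% of amplitude
  expect_lt(abs(mean(out$values[, 1, 1, 1, 1]) - mean(f$values[, 1, 1, 1, 1])),
            0.5)
  expect_equal(out$metadata$n_phases_reconstructed, 40L)
})

test_that("full preprocessing of an already-clean field is the identity", {
  ph <- make_uniform_phantom(100, grid = c(10, 10, 10), n_phases = 8)
  res <- preprocess_flow(ph$field, n_phases = 8)
  expect_lt(max(abs(res$field$values - ph$field$values)), 1e-9)
  expect_equal(res$report$wrap_count, 0)
  expect_gt(res$report$static_voxels, 0)
})
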