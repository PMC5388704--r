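test_that("voxel KE converts acquisition units correctly", {
  expect_equal(voxel_ke(c(0, 0, 0), 8), 0)
  # 8 mm^3 at 1.05 g/cm^3 is 8.4e-6 kg; (100 cm/s)^2 = (1 m/s)^2 -> 4.2e-3 mJ
  expect_equal(voxel_ke(c(100, 0, 0), 8), 4.2e-3)
  # rotational invariance: same speed, same KE
  expect_equal(voxel_ke(c(60, 80, 0), 8), voxel_ke(c(100, 0, 0), 8))
  # quadratic scaling
  expect_equal(voxel_ke(c(0, 50, 0), 8), voxel_ke(c(0, 100, 0), 8) / 4)
  # density and volume are linear factors
  expect_equal(voxel_ke(c(100, 0, 0), 8, density = 2.1),
               2 * voxel_ke(c(100, 0, 0), 8))
  expect_error(voxel_ke(c(NaN, 0, 0), 8), "finite")
  expect_error(voxel_ke(c(1, 0, 0), -1), "voxel_volume")
})

test_that("ROI curves sum voxel KE and are additive over partitions", {
  ph <- make_uniform_phantom(100, grid = c(12, 12, 12), n_phases = 5,
                             roi_shape = "box", box_dim = c(6, 6, 6))
  cv <- roi_ke_curve(ph$field, ph$masks)
  expect_equal(cv$ke_per_phase, ph$truth$true_ke_curve)
  expect_equal(cv$mean_ke, ph$truth$true_ke_curve[1])

  # split the ROI into two labels: sub-curves sum to the whole exactly
  lab <- unclass(ph$masks)
  lab_split <- lab
  lab_split[, 1:3, , ][lab[, 1:3, , ] == 1L] <- 2L
  m2 <- mask_series(lab_split, ph$field)
  part1 <- roi_ke_curve(ph$field, m2, "ventricle")$ke_per_phase
  part2 <- roi_ke_curve(ph$field, m2, "svc")$ke_per_phase
  expect_equal(part1 + part2, cv$ke_per_phase)

  # velocity scaling scales every KE output quadratically
  f2 <- ph$field
  f2$values <- f2$values * 3
  expect_equal(roi_ke_curve(f2, ph$masks)$ke_per_phase, 9 * cv$ke_per_phase)

  # absent region names the phases
  expect_error(roi_ke_curve(ph$field, ph$masks, "lpa"), "absent in phase")
})

test_that("cycle landmarks come from the volume extrema with earliest ties", {
  lm <- find_cycle_landmarks(c(100, 80, 60, 70, 90))
  expect_equal(lm$end_systole_idx, 3)
  expect_equal(lm$end_diastole_idx, 1)
  # ties break to the earliest index
  lm2 <- find_cycle_landmarks(c(100, 60, 70, 60, 90))
  expect_equal(lm2$end_systole_idx, 2)
  expect_error(find_cycle_landmarks(rep(50, 8)), "constant")
  expect_error(find_cycle_landmarks(c(1, 2)), ">= 4")
})

test_that("peak analysis finds E/A peaks, fusion and plateaus", {
  mk_curve <- function(ke) {
    structure(list(roi = "ventricle", ke_per_phase = ke,
                   phase_times = seq(0, length.out = length(ke), by = 50),
                   mean_ke = mean(ke)),
              class = "ke_curve")
  }
  lm <- structure(list(end_diastole_idx = 1L, end_systole_idx = 9L),
                  class = "cycle_landmarks")

  # distinct E and A bumps with a deep trough -> late peak found
  dia <- c(0.1, 0.3, 0.8, 1.0, 0.7, 0.5, 0.4, 0.35, 0.3, 0.78, 0.4, 0.2)
  ke <- c(0.2, 0.6, 1.2, 1.5, 1.1, 0.7, 0.4, 0.25, dia)
  pk <- analyze_peaks(mk_curve(ke), lm)
  expect_equal(pk$systolic_peak$value, 1.5)
  expect_equal(pk$early_diastolic_peak$value, 1.0)
  expect_false(pk$fused)
  expect_equal(pk$late_diastolic_peak$value, 0.78)
  expect_equal(pk$sd_ratio, 1.5)

  # monotone decay after the early peak -> fused, no late peak
  dia2 <- c(0.1, 0.4, 1.0, 0.8, 0.6, 0.45, 0.35, 0.28, 0.22, 0.18, 0.14, 0.1)
  pk2 <- analyze_peaks(mk_curve(c(ke[1:8], dia2)), lm)
  expect_true(pk2$fused)
  expect_null(pk2$late_diastolic_peak)

  # a late bump behind a shallow (< 10%) trough does not count as separate
  dia3 <- c(0.1, 0.4, 1.0, 0.97, 0.95, 0.93, 0.92, 0.93, 0.95, 0.96, 0.9, 0.8)
  pk3 <- analyze_peaks(mk_curve(c(ke[1:8], dia3)), lm)
  expect_true(pk3$fused)
})

test_that("phantom patterns round-trip through peak analysis", {
  for (pat in c("systolic_dominant", "diastolic_dominant", "plateau")) {
    ph <- make_ventricle_phantom(pat, seed = 11, grid = c(18, 18, 18))
    cv <- roi_ke_curve(ph$field, ph$masks)
    pk <- analyze_peaks(cv, find_cycle_landmarks(volume_curve(ph$masks)))
    expect_equal(pk$plateau$flag, pat == "plateau", info = pat)
    expect_equal(pk$systolic_peak$value, ph$truth$peak_systolic_mJ,
                 tolerance = 0.02, info = pat)
    expect_equal(pk$diastolic_peak$value, ph$truth$peak_diastolic_mJ,
                 tolerance = 0.02, info = pat)
    # peak values are attained curve values
    expect_true(pk$systolic_peak$value %in% cv$ke_per_phase)
    # classification agrees with the generator pattern
    if (pat != "plateau")
      expect_equal(classify_pattern(pk), pat)
  }
  # a phantom with a true atrial bump reports a separate late peak
  ph <- make_ventricle_phantom("diastolic_dominant", late_peak_frac = 0.6,
                               seed = 12, grid = c(18, 18, 18))
  pk <- analyze_peaks(roi_ke_curve(ph$field, ph$masks),
                      find_cycle_landmarks(volume_curve(ph$masks)))
  expect_false(pk$fused)
  expect_equal(pk$late_diastolic_peak$value,
               0.6 * ph$truth$peak_diastolic_mJ, tolerance = 0.02)
})

test_that("pattern classification follows the systole/diastole ratio", {
  mk_peaks <- function(sys, dia) {
    structure(list(systolic_peak = list(value = sys, idx = 1L),
                   diastolic_peak = list(value = dia, idx = 2L),
                   sd_ratio = sys / dia),
              class = "ke_peaks")
  }
  # short-outflow LV-type values: diastolic dominant
  expect_equal(classify_pattern(mk_peaks(0.022, 0.033)), "diastolic_dominant")
  # RV-type values: systolic dominant
  expect_equal(classify_pattern(mk_peaks(0.043, 0.025)), "systolic_dominant")
  expect_error(classify_pattern(mk_peaks(0.5, 0.5)), "indeterminate")
  expect_error(classify_pattern(mk_peaks(0.5, 0)), "zero diastolic")
})

test_that("indexing divides by each denominator and inverts exactly", {
  idx <- index_ke(0.36, sv = 10)
  expect_equal(idx$ke_per_sv, 0.036)
  expect_null(idx$ke_per_bsa)   # absent denominators stay absent
  expect_equal(idx$ke_per_sv * 10, 0.36)

  full <- index_ke(1.2, sv = 45, bsa = 1.5, ci = 3.2, vessel_volume = 8.6)
  expect_equal(full$ke_per_bsa, 0.8)
  expect_equal(full$ke_per_ci, 0.375)
  # vessel-volume indexing gives the mJ/ml scale used for conduit KE
  expect_equal(index_ke(0.05, vessel_volume = 8.6)$ke_per_vessel_volume,
               0.005814, tolerance = 1e-4)
  expect_error(index_ke(1, sv = 0), "sv")
  expect_error(index_ke(1, ci = -2), "ci")
})
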