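test_that("uniform phantom matches the closed-form kinetic energy", {
  # 1000 voxels of 2x2x2 mm at 100 cm/s: mass 8.4 g, KE = 4.2 mJ per phase
  ph <- make_uniform_phantom(100, grid = c(16, 16, 16), n_phases = 4,
                             roi_shape = "box", box_dim = c(10, 10, 10))
  expect_equal(ph$truth$roi_voxels, 1000)
  expect_equal(ph$truth$true_ke_curve, rep(4.2, 4))

  expect_equal(make_uniform_phantom(0, grid = c(8, 8, 8),
                                    n_phases = 3)$truth$true_ke_curve,
               rep(0, 3))
  # KE is quadratic in speed
  k1 <- make_uniform_phantom(40, grid = c(8, 8, 8), n_phases = 2)
  k2 <- make_uniform_phantom(80, grid = c(8, 8, 8), n_phases = 2)
  expect_equal(k2$truth$true_ke_curve, 4 * k1$truth$true_ke_curve)
  # velocity direction does not matter, only speed
  kd <- make_uniform_phantom(40, direction = c(0.6, 0.8, 0),
                             grid = c(8, 8, 8), n_phases = 2)
  expect_equal(kd$truth$true_ke_curve, k1$truth$true_ke_curve)

  expect_error(make_uniform_phantom(10, direction = c(1, 1, 0)), "unit")
})

test_that("Poiseuille phantom reproduces the analytic parabolic-profile KE", {
  # continuum KE = 1/2 rho (v_max^2/3) pi R^2 L = 2.749 mJ for
  # R = 10 mm, L = 50 mm, v_max = 100 cm/s
  po <- make_poiseuille_vessel(10, 50, 100, spacing = c(1, 1, 1))
  expect_equal(po$truth$ke_continuum_mJ, 2.748894, tolerance = 1e-6)
  expect_lt(abs(po$truth$true_ke_curve[1] - po$truth$ke_continuum_mJ) /
              po$truth$ke_continuum_mJ, 0.03)
  # the field realizes the discretized sum exactly
  cv <- roi_ke_curve(po$field, po$masks, "ivc_tunnel")
  expect_equal(cv$ke_per_phase[1], po$truth$true_ke_curve[1])

  expect_equal(make_poiseuille_vessel(10, 30, 0,
                                      spacing = c(2, 2, 2))$truth$true_ke_curve[1],
               0)
  expect_error(make_poiseuille_vessel(10, 50, 100, spacing = c(1, 1, 1),
                                      grid = c(10, 10, 10)), "exceeds")
  expect_error(make_poiseuille_vessel(3, 50, 100, spacing = c(2, 2, 2)),
               "resolvable")
})

test_that("Poiseuille discretization error shrinks monotonically", {
  errs <- vapply(c(2, 1, 0.5), function(h) {
    po <- make_poiseuille_vessel(10, 40, 100, spacing = c(h, h, h))
    abs(po$truth$true_ke_curve[1] - po$truth$ke_continuum_mJ) /
      po$truth$ke_continuum_mJ
  }, numeric(1))
  expect_lt(errs[2], 0.03)
  expect_true(all(diff(errs) < 0))
})

test_that("ventricle phantom realizes the requested KE pattern", {
  sys <- make_ventricle_phantom("systolic_dominant", seed = 1,
                                grid = c(20, 20, 20))
  expect_gt(sys$truth$sd_ratio, 1)
  dia <- make_ventricle_phantom("diastolic_dominant", seed = 1,
                                grid = c(20, 20, 20))
  expect_lt(dia$truth$sd_ratio, 1)
  # ROI-summed KE equals the stored truth template (realization is exact)
  cv <- roi_ke_curve(sys$field, sys$masks)
  expect_equal(cv$ke_per_phase, sys$truth$true_ke_curve, tolerance = 1e-12)
  # truth curves are nonnegative
  expect_true(all(sys$truth$true_ke_curve >= 0))
  # volume curve: one maximum at phase 1, minimum at end-systole
  expect_equal(which.max(sys$truth$true_volume_curve), 1)
  expect_equal(which.min(sys$truth$true_volume_curve),
               round(sys$truth$t_es * 20) + 1)
  expect_error(make_ventricle_phantom("flat"), "arg")
})

test_that("ventricle phantom is bit-reproducible under a seed", {
  a <- make_ventricle_phantom("plateau", seed = 7, noise_sigma = 1,
                              grid = c(14, 14, 14))
  b <- make_ventricle_phantom("plateau", seed = 7, noise_sigma = 1,
                              grid = c(14, 14, 14))
  expect_identical(a$field$values, b$field$values)
  c <- make_ventricle_phantom("plateau", seed = 8, noise_sigma = 1,
                              grid = c(14, 14, 14))
  expect_false(identical(a$field$values, c$field$values))
})

test_that("eddy injector adds a static plane and leaves masks untouched", {
  ph <- make_uniform_phantom(50, grid = c(8, 8, 8), n_phases = 3)
  plane <- matrix(c(2, 0.1, -0.05, 0,
                    0, 0, 0, 0,
                    -1, 0, 0, 0.02), 3, 4, byrow = TRUE)
  f2 <- inject_eddy_offset(ph$field, plane)
  # zero coefficients: identity
  expect_identical(inject_eddy_offset(ph$field, matrix(0, 3, 4))$values,
                   ph$field$values)
  # offset-only component shifts uniformly
  f3 <- inject_eddy_offset(ph$field, matrix(c(0, 0, 0, 0,
                                              5, 0, 0, 0,
                                              0, 0, 0, 0), 3, 4, byrow = TRUE))
  expect_equal(f3$values[, , , , 2] - ph$field$values[, , , , 2],
               array(5, dim(ph$field$values)[1:4]))
  # the plane is identical across phases
  expect_equal(f2$values[1, , , , 1] - ph$field$values[1, , , , 1],
               f2$values[3, , , , 1] - ph$field$values[3, , , , 1])
})

test_that("aliasing injector wraps into [-venc, venc) and is idempotent", {
  f <- series_field(c(0, 120, -130, 80, 99.9, -100))
  fw <- inject_aliasing(f)
  expect_equal(fw$values[, 1, 1, 1, 1], c(0, -80, 70, 80, 99.9, -100))
  sites <- attr(fw, "wrap_sites")
  expect_equal(sort(sites$phase), c(2, 3))
  fw2 <- inject_aliasing(fw)
  expect_identical(fw2$values, fw$values)
  expect_equal(nrow(attr(fw2, "wrap_sites")), 0)
  # wraps only change values by multiples of 2 venc
  shifts <- (fw$values - f$values) / 200
  expect_equal(shifts, round(shifts))
})

test_that("cohort draws follow the group distributions and the seed", {
  spec <- cohort_spec(n_per_group = c(fontan = 100, control = 100), seed = 5)
  p1 <- cohort_params(spec)
  p2 <- cohort_params(spec)
  expect_identical(p1, p2)
  p3 <- cohort_params(cohort_spec(n_per_group = c(fontan = 100, control = 100),
                                  seed = 6))
  expect_false(identical(p1$true_sys_per_sv, p3$true_sys_per_sv))

  # law of large numbers: sample means within 3 SE of the spec means
  g <- default_cohort_groups()
  for (grp in c("fontan", "control")) {
    d <- p1[p1$group == grp, ]
    expect_lt(abs(mean(d$true_sys_per_sv) - g[[grp]]$sys_mean),
              3 * g[[grp]]$sys_sd / sqrt(100))
    expect_lt(abs(mean(d$true_dia_per_sv) - g[[grp]]$dia_mean),
              3 * g[[grp]]$dia_sd / sqrt(100))
  }

  # degenerate SD 0: all subjects share the group truth
  gz <- default_cohort_groups()
  gz$fontan$sys_sd <- 0; gz$fontan$dia_sd <- 0
  pz <- cohort_params(cohort_spec(n_per_group = c(fontan = 5, control = 2),
                                  groups = gz, seed = 2))
  expect_equal(unique(pz$true_sys_per_sv[pz$group == "fontan"]),
               gz$fontan$sys_mean)
})

test_that("simulate_cohort materializes subjects that realize their draws", {
  spec <- cohort_spec(n_per_group = c(fontan = 2, control = 2), seed = 3,
                      grid = c(16, 16, 16))
  subj <- simulate_cohort(spec)
  expect_length(subj, 4)
  params <- attr(subj, "params")
  for (i in seq_along(subj)) {
    s <- subj[[i]]
    expect_s3_class(s$field, "velocity_field")
    expect_equal(s$truth$peak_systolic_per_sv, params$true_sys_per_sv[i],
                 tolerance = 1e-12)
  }
})
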