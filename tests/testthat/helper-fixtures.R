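# Shared fixtures: tiny fields built in code, and independent brute-force
# oracles the implementation under test does not share code with.

test_metadata <- function(n_phases = 4, rr = 1000, venc = 100,
                          spacing = c(2, 2, 2), ...) {
  flow_metadata("test_subject", "control", "left", venc = venc,
                voxel_spacing = spacing, n_phases_acquired = n_phases,
                n_phases_reconstructed = n_phases, rr_interval = rr, ...)
}

test_field <- function(values, rr = 1000, venc = 100, spacing = c(2, 2, 2)) {
  velocity_field(values, test_metadata(dim(values)[1], rr, venc, spacing))
}

# single-voxel field carrying a prescribed time series in component 1
series_field <- function(series, venc = 100, rr = 1000) {
  v <- array(0, c(length(series), 1, 1, 1, 3))
  v[, 1, 1, 1, 1] <- series
  test_field(v, rr = rr, venc = venc)
}

# Brute-force exact two-sided Mann-Whitney p by enumeration of all C(N, n1)
# rank assignments (tie-free data only). Independent of pwilcox.
bf_mann_whitney_p <- function(x, y) {
  n1 <- length(x)
  N <- n1 + length(y)
  stopifnot(!any(duplicated(c(x, y))))
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  assignments <- utils::combn(N, n1)
  us <- apply(assignments, 2, function(ix) sum(ix) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Brute-force temporal unwrapping oracle for a short scalar series:
# minimizes total variation over all 2*venc shift assignments.
bf_unwrap <- function(series, venc, k_range = -2:2) {
  per <- 2 * venc
  n <- length(series)
  grid <- expand.grid(rep(list(k_range), n - 1))
  best <- series
  best_tv <- sum(abs(diff(series)))
  for (i in seq_len(nrow(grid))) {
    w <- series + per * c(0, as.numeric(grid[i, ]))
    tv <- sum(abs(diff(w)))
    if (tv < best_tv - 1e-9) {
      best_tv <- tv
      best <- w
    }
  }
  best
}

# 11-subject labelings on a shared two-category scale (kappa requires a
# common category space): ventricular morphology coded by its hemodynamic
# type (short-outflow LV -> diastolic type, long outflow -> systolic type;
# subjects 1, 2, 9, 10 are the short-outflow LVs), and the KE dominance
# pattern observed on the curves (diastolic-dominant in the same four).
cohort_morphology_labels <- function() {
  ifelse(1:11 %in% c(1, 2, 9, 10), "diastolic_type", "systolic_type")
}
cohort_pattern_labels <- function() {
  ifelse(1:11 %in% c(1, 2, 9, 10), "diastolic_type", "systolic_type")
}
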