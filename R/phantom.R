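# Synthetic 4D flow phantoms with known ground truth.
#
# Every generator returns (field, masks, truth): a velocity_field, a
# mask_series on the same grid, and a phantom_truth carrying the analytic
# KE curve and any injected corruption, so each downstream stage can be
# tested against a value it did not compute.

# kinetic energy of one voxel in mJ from squared speed (cm/s)^2,
# voxel volume (mm^3) and density (g/cm^3); see voxel_ke() for the units
.ke_mj <- function(speed2, vol_mm3, density) 0.5e-7 * vol_mm3 * density * speed2

.coord_arrays <- function(grid, spacing, centered = TRUE) {
  nx <- grid[1]; ny <- grid[2]; nz <- grid[3]
  off <- if (centered) grid * spacing / 2 else c(0, 0, 0)
  xs <- (seq_len(nx) - 0.5) * spacing[1] - off[1]
  ys <- (seq_len(ny) - 0.5) * spacing[2] - off[2]
  zs <- (seq_len(nz) - 0.5) * spacing[3] - off[3]
  list(X = array(rep(xs, times = ny * nz), grid),
       Y = array(rep(rep(ys, each = nx), times = nz), grid),
       Z = array(rep(zs, each = nx * ny), grid))
}

.empty_wrap_sites <- function() {
  data.frame(phase = integer(), x = integer(), y = integer(), z = integer(),
             component = integer())
}

new_phantom_truth <- function(true_ke_curve, true_volume_curve,
                              noise_sigma = 0, ...) {
  structure(c(list(true_ke_curve = true_ke_curve,
                   true_volume_curve = true_volume_curve,
                   eddy_plane = matrix(0, 3, 4,
                                       dimnames = list(c("vx", "vy", "vz"),
                                                       c("offset", "gx", "gy", "gz"))),
                   wrap_sites = .empty_wrap_sites(),
                   noise_sigma = noise_sigma),
              list(...)),
            class = "phantom_truth")
}

#' Uniform-flow phantom
#'
#' A spherical or box ROI in which every voxel carries the same velocity
#' vector, surrounded by zero-velocity background. The ROI kinetic energy
#' has the closed form KE = 1/2 * rho * V_roi * v^2, making this the
#' analytic oracle for the voxel-summation chain.
#'
#' @param speed Speed in cm/s (>= 0).
#' @param direction Unit 3-vector; an error if its norm deviates from 1 by
#'   more than 1e-6.
#' @param grid Grid dimensions (x, y, z).
#' @param spacing Voxel spacing (mm).
#' @param n_phases Number of phases (velocity is time-constant).
#' @param roi_shape `"sphere"` (radius `roi_radius_mm`, default 35% of the
#'   smallest grid extent) or `"box"` (`box_dim` voxels in the grid corner,
#'   giving an exactly known voxel count).
#' @param roi_radius_mm Sphere radius in mm (ignored for `"box"`).
#' @param box_dim Length-3 integer, box extent in voxels (ignored for
#'   `"sphere"`).
#' @param venc,rr_interval Metadata for the generated field.
#' @return List with elements `field`, `masks`, `truth`.
#' @export
#' @examples
#' ph <- make_uniform_phantom(100, grid = c(16, 16, 16), n_phases = 4,
#'                            roi_shape = "box", box_dim = c(10, 10, 10))
#' ph$truth$true_ke_curve[1]  # 1000 voxels * 8 mm^3 at 1 m/s -> 4.2 mJ
make_uniform_phantom <- function(speed, direction = c(1, 0, 0),
                                 grid = c(32, 32, 32), spacing = c(2, 2, 2),
                                 n_phases = 20,
                                 roi_shape = c("sphere", "box"),
                                 roi_radius_mm = NULL,
                                 box_dim = c(10, 10, 10),
                                 venc = 100, rr_interval = 1000) {
  roi_shape <- match.arg(roi_shape)
  if (speed < 0) stop("speed must be >= 0", call. = FALSE)
  if (abs(sqrt(sum(direction^2)) - 1) > 1e-6)
    stop("direction must be a unit vector (|norm - 1| <= 1e-6)", call. = FALSE)
  if (any(grid < 1)) stop("grid must be nonempty", call. = FALSE)
  roi <- if (roi_shape == "sphere") {
    r <- roi_radius_mm %||% (0.35 * min(grid * spacing))
    co <- .coord_arrays(grid, spacing)
    co$X^2 + co$Y^2 + co$Z^2 <= r^2
  } else {
    a <- array(FALSE, grid)
    a[seq_len(box_dim[1]), seq_len(box_dim[2]), seq_len(box_dim[3])] <- TRUE
    a
  }
  md <- flow_metadata("uniform_phantom", "control", "left", venc = venc,
                      voxel_spacing = spacing, n_phases_acquired = n_phases,
                      n_phases_reconstructed = n_phases,
                      rr_interval = rr_interval)
  values <- array(0, dim = c(n_phases, grid, 3))
  for (k in 1:3) {
    comp <- array(0, grid)
    comp[roi] <- speed * direction[k]
    for (p in seq_len(n_phases)) values[p, , , , k] <- comp
  }
  labels <- array(0L, dim = c(n_phases, grid))
  for (p in seq_len(n_phases)) labels[p, , , ][roi] <- .REGION_LABELS[["ventricle"]]
  field <- velocity_field(values, md)
  masks <- mask_series(labels, field)
  nvox <- sum(roi)
  vol_ml <- nvox * voxel_volume_mm3(spacing) / 1000
  ke <- .ke_mj(speed^2, voxel_volume_mm3(spacing), md$blood_density) * nvox
  truth <- new_phantom_truth(rep(ke, n_phases), rep(vol_ml, n_phases),
                             roi_voxels = nvox)
  list(field = field, masks = masks, truth = truth)
}

#' Poiseuille vessel phantom
#'
#' A straight cylindrical vessel along the z axis carrying a steady
#' parabolic (Poiseuille) axial profile v(r) = v_max (1 - r^2/R^2). The
#' continuum kinetic energy is 1/2 * rho * (v_max^2/3) * pi R^2 L (the
#' cross-sectional mean of v^2 for a parabola is v_max^2/3); the truth also
#' carries the discretized voxel sum, which converges to the continuum
#' value as spacing shrinks.
#'
#' @param radius Vessel radius R in mm; must be at least twice the in-plane
#'   spacing to be resolvable.
#' @param length Vessel length L in mm; the cylinder must fit the grid.
#' @param v_max Centerline speed in cm/s.
#' @param spacing Voxel spacing (mm).
#' @param n_phases Number of (identical) phases.
#' @param grid Grid dimensions; `NULL` auto-fits the cylinder with a margin.
#' @param venc,rr_interval Metadata for the generated field.
#' @return List with `field`, `masks` (vessel labeled `ivc_tunnel`) and
#'   `truth`; `truth$ke_continuum_mJ` is the closed-form value,
#'   `truth$true_ke_curve` the discretized sum the field realizes.
#' @export
make_poiseuille_vessel <- function(radius, length, v_max,
                                   spacing = c(1, 1, 1), n_phases = 2,
                                   grid = NULL, venc = 100,
                                   rr_interval = 1000) {
  if (radius < 2 * max(spacing[1:2]))
    stop("radius must be >= 2x the in-plane spacing to be resolvable",
         call. = FALSE)
  if (is.null(grid))
    grid <- c(ceiling(2 * radius / spacing[1]) + 4,
              ceiling(2 * radius / spacing[2]) + 4,
              ceiling(length / spacing[3]) + 2)
  if (2 * radius > grid[1] * spacing[1] || 2 * radius > grid[2] * spacing[2] ||
      length > grid[3] * spacing[3])
    stop("cylinder (R = ", radius, " mm, L = ", length,
         " mm) exceeds the grid extent", call. = FALSE)
  co <- .coord_arrays(grid, spacing)
  r2 <- co$X^2 + co$Y^2
  inside <- r2 <= radius^2 & abs(co$Z) <= length / 2
  vz <- array(0, grid)
  vz[inside] <- v_max * (1 - r2[inside] / radius^2)
  md <- flow_metadata("poiseuille_phantom", "control", "left", venc = venc,
                      voxel_spacing = spacing, n_phases_acquired = n_phases,
                      n_phases_reconstructed = n_phases,
                      rr_interval = rr_interval)
  values <- array(0, dim = c(n_phases, grid, 3))
  for (p in seq_len(n_phases)) values[p, , , , 3] <- vz
  labels <- array(0L, dim = c(n_phases, grid))
  for (p in seq_len(n_phases))
    labels[p, , , ][inside] <- .REGION_LABELS[["ivc_tunnel"]]
  field <- velocity_field(values, md)
  masks <- mask_series(labels, field)
  voxvol <- voxel_volume_mm3(spacing)
  ke_disc <- sum(.ke_mj(vz[inside]^2, voxvol, md$blood_density))
  # continuum: 1/2 * rho[kg/m^3] * (v_max[m/s]^2 / 3) * pi R[m]^2 L[m], in mJ
  ke_cont <- 1000 * 0.5 * (md$blood_density * 1000) * ((v_max / 100)^2 / 3) *
    pi * (radius / 1000)^2 * (length / 1000)
  truth <- new_phantom_truth(rep(ke_disc, n_phases),
                             rep(sum(inside) * voxvol / 1000, n_phases),
                             ke_continuum_mJ = ke_cont,
                             radius_mm = radius, length_mm = length)
  list(field = field, masks = masks, truth = truth)
}

# snap a normalized cycle time to the sampled phase grid so template peaks
# are attained exactly at a sample
.snap <- function(t, n) round(t * n) / n

.gauss_bump <- function(t, center, width) {
  d <- abs((t - center) %% 1)
  d <- pmin(d, 1 - d)
  exp(-d^2 / (2 * width^2))
}

# Two-peak / plateau KE template over normalized cycle time t in [0, 1).
# Peaks: systolic at ~0.2, early diastolic at ~0.65 (0.5 for plateau, which
# then holds 97% of the early peak until late diastole), optional atrial
# bump at ~0.9. Bump maxima are combined with pmax so the curve attains the
# requested amplitudes exactly.
ke_template <- function(t, pattern, amp_sys, amp_dia, late_peak_frac = 0,
                        n_phases = length(t)) {
  n <- n_phases
  sysb <- amp_sys * .gauss_bump(t, .snap(0.20, n), 0.07)
  if (pattern == "plateau") {
    c_e <- .snap(0.50, n)
    e <- amp_dia * .gauss_bump(t, c_e, 0.05)
    hold <- ifelse(t >= c_e & t <= 0.9, 0.97 * amp_dia, 0)
    tail <- ifelse(t > 0.9, 0.97 * amp_dia * .gauss_bump(t, 0.9, 0.045), 0)
    pmax(sysb, e, hold, tail)
  } else {
    e <- amp_dia * .gauss_bump(t, .snap(0.65, n), 0.055)
    a <- if (late_peak_frac > 0)
      late_peak_frac * amp_dia * .gauss_bump(t, .snap(0.90, n), 0.035)
    else 0
    pmax(sysb, e, a)
  }
}

# Ventricular volume over normalized cycle time: monotone fall to end-systole
# at t_es, monotone refill; single minimum, maximum at t = 0.
volume_template <- function(t, edv, esv, t_es = 0.4) {
  g <- ifelse(t <= t_es,
              (1 + cos(pi * t / t_es)) / 2,
              (1 - cos(pi * (t - t_es) / (1 - t_es))) / 2)
  esv + (edv - esv) * g
}

#' Single-ventricle KE phantom
#'
#' An ellipsoidal "ventricle" whose per-phase volume follows a one-minimum
#' filling/ejection curve and whose voxel velocities are a fixed
#' inflow/outflow jet profile rescaled each phase so that the ROI-summed
#' kinetic energy equals a prescribed two-peak (or plateau) template
#' exactly. This realizes KE-level ground truth without solving flow
#' physics: the pipeline under test is a measurement chain, and what its
#' tests need is a known KE curve.
#'
#' Patterns mirror the morphology-linked curve shapes seen clinically:
#' `systolic_dominant` (systole/diastole peak ratio > 1, the right-ventricle
#' type with a long outflow tract), `diastolic_dominant` (ratio < 1, the
#' short-outflow left-ventricle type), and `plateau` (early-diastolic KE
#' held nearly constant through mid-diastole, the shape associated with
#' significant aortopulmonary collateral flow).
#'
#' @param pattern `"systolic_dominant"`, `"diastolic_dominant"` or
#'   `"plateau"`.
#' @param edv_ml,esv_ml End-diastolic and end-systolic volume (ml).
#' @param peak_systolic_mJ,peak_diastolic_mJ Target peak KE (mJ). Defaults
#'   are pattern-consistent. Alternatively give the stroke-volume-indexed
#'   targets below.
#' @param peak_systolic_per_sv,peak_diastolic_per_sv Optional targets in
#'   mJ/ml of stroke volume; realized against the discretized
#'   (voxel-counted) stroke volume of the generated masks so that measured
#'   KE/SV equals the target exactly.
#' @param late_peak_frac Amplitude of a late-diastolic (atrial) bump as a
#'   fraction of the early peak; 0 (default) omits it, giving a fused curve.
#' @param grid Grid dimensions. @param spacing Voxel spacing (mm); `NULL`
#'   picks an isotropic spacing (>= 2 mm) that fits the end-diastolic
#'   ellipsoid with a margin.
#' @param n_phases Number of acquired phases (>= 10).
#' @param heart_rate Heart rate (beats/min). @param venc venc (cm/s).
#' @param bsa Body surface area (m^2) carried in metadata.
#' @param noise_sigma Gaussian velocity noise SD (cm/s) added everywhere.
#' @param seed Optional integer seed; identical seeds give bit-identical
#'   phantoms.
#' @param subject_id,group_label,morphology Metadata fields.
#' @return List with `field`, `masks`, `truth` (class `phantom_truth`; the
#'   template curve, discretized volume curve, peak targets and
#'   systole/diastole ratio) and `metadata`.
#' @export
make_ventricle_phantom <- function(pattern = c("systolic_dominant",
                                               "diastolic_dominant",
                                               "plateau"),
                                   edv_ml = 100, esv_ml = 55,
                                   peak_systolic_mJ = NULL,
                                   peak_diastolic_mJ = NULL,
                                   peak_systolic_per_sv = NULL,
                                   peak_diastolic_per_sv = NULL,
                                   late_peak_frac = 0,
                                   grid = c(32, 32, 32), spacing = NULL,
                                   n_phases = 20, heart_rate = 75,
                                   venc = 100, bsa = NA_real_,
                                   noise_sigma = 0, seed = NULL,
                                   subject_id = "ventricle_phantom",
                                   group_label = "fontan",
                                   morphology = c("left", "right",
                                                  "left_long_outflow")) {
  pattern <- match.arg(pattern)
  morphology <- match.arg(morphology)
  if (n_phases < 10) stop("n_phases must be >= 10", call. = FALSE)
  if (esv_ml <= 0 || edv_ml <= esv_ml)
    stop("need edv_ml > esv_ml > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  # ellipsoid semi-axes at end-diastole; short axes 0.7 * long axis
  aspect <- 0.7
  a0 <- (edv_ml * 1000 / ((4 / 3) * pi * aspect^2))^(1 / 3)
  if (is.null(spacing)) {
    sp <- max(2, 2 * a0 * 1.12 / grid[1])
    spacing <- rep(sp, 3)
  }
  if (2 * a0 * 1.05 > grid[1] * spacing[1] ||
      2 * a0 * aspect * 1.05 > min(grid[2] * spacing[2], grid[3] * spacing[3]))
    stop("end-diastolic ellipsoid does not fit the grid; enlarge grid or ",
         "spacing", call. = FALSE)

  md <- flow_metadata(subject_id, group_label, morphology, venc = venc,
                      voxel_spacing = spacing, n_phases_acquired = n_phases,
                      n_phases_reconstructed = 40,
                      heart_rate = heart_rate, bsa = bsa)
  tnorm <- uniform_phase_times(n_phases, md$rr_interval) / md$rr_interval
  t_es <- .snap(0.4, n_phases)
  vol_target <- volume_template(tnorm, edv_ml, esv_ml, t_es)

  co <- .coord_arrays(grid, spacing)
  voxvol <- voxel_volume_mm3(spacing)
  labels <- array(0L, dim = c(n_phases, grid))
  inside_list <- vector("list", n_phases)
  w_list <- vector("list", n_phases)
  vol_disc <- numeric(n_phases)
  for (p in seq_len(n_phases)) {
    s <- (vol_target[p] / edv_ml)^(1 / 3)
    a <- a0 * s; b <- a0 * aspect * s
    inside <- (co$X / a)^2 + (co$Y / b)^2 + (co$Z / b)^2 <= 1
    if (!any(inside)) stop("empty ventricle mask at phase ", p, call. = FALSE)
    labels[p, , , ][inside] <- .REGION_LABELS[["ventricle"]]
    sigma <- 0.35 * b
    w <- exp(-(co$Y^2 + co$Z^2) / (2 * sigma^2))
    inside_list[[p]] <- inside
    w_list[[p]] <- w
    vol_disc[p] <- sum(inside) * voxvol / 1000
  }
  sv_disc <- max(vol_disc) - min(vol_disc)

  if (!is.null(peak_systolic_per_sv)) peak_systolic_mJ <- peak_systolic_per_sv * sv_disc
  if (!is.null(peak_diastolic_per_sv)) peak_diastolic_mJ <- peak_diastolic_per_sv * sv_disc
  if (is.null(peak_systolic_mJ) || is.null(peak_diastolic_mJ)) {
    defaults <- switch(pattern,
                       systolic_dominant = c(1.5, 1.0),
                       diastolic_dominant = c(1.0, 1.5),
                       plateau = c(1.2, 1.0))
    if (is.null(peak_systolic_mJ)) peak_systolic_mJ <- defaults[1]
    if (is.null(peak_diastolic_mJ)) peak_diastolic_mJ <- defaults[2]
  }
  target <- ke_template(tnorm, pattern, peak_systolic_mJ, peak_diastolic_mJ,
                        late_peak_frac, n_phases)

  values <- array(0, dim = c(n_phases, grid, 3))
  for (p in seq_len(n_phases)) {
    inside <- inside_list[[p]]; w <- w_list[[p]]
    uk <- .ke_mj(sum(w[inside]^2), voxvol, md$blood_density)
    sgn <- if (tnorm[p] <= t_es) 1 else -1   # outflow vs inflow jet
    sc <- if (target[p] > 0) sqrt(target[p] / uk) else 0
    comp <- array(0, grid)
    comp[inside] <- sgn * sc * w[inside]
    values[p, , , , 1] <- comp
  }
  if (noise_sigma > 0)
    values <- values + array(rnorm(base::length(values), sd = noise_sigma),
                             dim = dim(values))

  field <- velocity_field(values, md)
  masks <- mask_series(labels, field)
  truth <- new_phantom_truth(target, vol_disc, noise_sigma = noise_sigma,
                             pattern = pattern,
                             peak_systolic_mJ = peak_systolic_mJ,
                             peak_diastolic_mJ = peak_diastolic_mJ,
                             sv_ml = sv_disc,
                             peak_systolic_per_sv = peak_systolic_mJ / sv_disc,
                             peak_diastolic_per_sv = peak_diastolic_mJ / sv_disc,
                             sd_ratio = peak_systolic_mJ / peak_diastolic_mJ,
                             t_es = t_es)
  list(field = field, masks = masks, truth = truth, metadata = md)
}

#' Inject a static first-order eddy-current offset
#'
#' Adds, to every phase, the spatial first-order polynomial
#' `offset + gx*x + gy*y + gz*z` per component, emulating residual
#' eddy-current velocity offsets. Coordinates are voxel centers in mm
#' (0-based voxel index times spacing), matching the convention of
#' [correct_eddy_currents()], so injection followed by correction on
#' noise-free data recovers the coefficients exactly.
#'
#' @param field A `velocity_field`.
#' @param plane 3x4 numeric matrix: rows are components (vx, vy, vz),
#'   columns (offset cm/s, gx, gy, gz in cm/s per mm).
#' @return The corrupted `velocity_field` (masks are untouched by design).
#' @export
inject_eddy_offset <- function(field, plane) {
  stopifnot(inherits(field, "velocity_field"))
  plane <- matrix(as.numeric(plane), 3, 4)
  grid <- dim(field$values)[2:4]
  sp <- field$metadata$voxel_spacing
  co <- .coord_arrays(grid, sp, centered = FALSE)
  # voxel centers at 0-based index * spacing
  X <- co$X - 0.5 * sp[1]; Y <- co$Y - 0.5 * sp[2]; Z <- co$Z - 0.5 * sp[3]
  n_phases <- dim(field$values)[1]
  for (k in 1:3) {
    P <- plane[k, 1] + plane[k, 2] * X + plane[k, 3] * Y + plane[k, 4] * Z
    for (p in seq_len(n_phases))
      field$values[p, , , , k] <- field$values[p, , , , k] + P
  }
  field
}

#' Inject velocity aliasing (venc wrapping)
#'
#' Maps every component value into the phase-encodable range
#' `[-venc, venc)` the way the scanner's phase signal would: values beyond
#' the velocity-encoding limit wrap by multiples of 2*venc. Values already
#' in range are untouched, so the operation is idempotent.
#'
#' @param field A `velocity_field` with `venc` set in its metadata.
#' @return The wrapped `velocity_field`, with a `wrap_sites` attribute: a
#'   data frame of (phase, x, y, z, component) indices where wrapping
#'   occurred.
#' @export
#' @examples
#' # 120 cm/s at venc 100 is stored as -80; -130 as +70
inject_aliasing <- function(field) {
  stopifnot(inherits(field, "velocity_field"))
  venc <- field$metadata$venc
  wrapped <- ((field$values + venc) %% (2 * venc)) - venc
  changed <- which(wrapped != field$values, arr.ind = TRUE)
  sites <- if (nrow(changed)) {
    data.frame(phase = changed[, 1], x = changed[, 2], y = changed[, 3],
               z = changed[, 4], component = changed[, 5])
  } else .empty_wrap_sites()
  field$values <- wrapped
  attr(field, "wrap_sites") <- sites
  field
}

#' Cohort simulation specification
#'
#' Describes a two-group study: per-group distributions of peak systolic and
#' diastolic KE indexed to stroke volume (mJ/ml), ventricular morphology
#' mix, heart-rate and body-size ranges, and an aortopulmonary-collateral
#' flow fraction distribution. Defaults mirror a Fontan-vs-control study
#' design (11 vs 8 subjects; Fontan KE/SV 0.036/0.028, control LV
#' 0.048/0.058 mJ/ml).
#'
#' @param n_per_group Subjects per group (>= 1).
#' @param groups Named list of group parameter lists, each with `sys_mean`,
#'   `sys_sd`, `dia_mean`, `dia_sd` (mJ/ml), `morphology_mix` (named
#'   probabilities over morphologies), `hr_range` (beats/min), `bsa_range`
#'   (m^2), `edvi_mean`, `edvi_sd` (ml/m^2), `ef_mean`, `ef_sd` (%),
#'   `apc_mean`, `apc_sd` (% of SV).
#' @param seed Integer seed; all draws flow from it.
#' @param grid,n_phases,noise_sigma Phantom geometry settings passed through
#'   to [make_ventricle_phantom()].
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(fontan = 11, control = 8),
                        groups = default_cohort_groups(),
                        seed = 1L,
                        grid = c(24, 24, 24), n_phases = 20,
                        noise_sigma = 0) {
  if (is.null(names(n_per_group)))
    names(n_per_group) <- names(groups)[seq_along(n_per_group)]
  if (any(n_per_group < 1)) stop("n_per_group must be >= 1", call. = FALSE)
  for (g in names(groups)) {
    gr <- groups[[g]]
    if (any(c(gr$sys_sd, gr$dia_sd, gr$apc_sd) < 0))
      stop("SDs must be >= 0 (group ", g, ")", call. = FALSE)
    if (gr$apc_mean < 0 || gr$apc_mean > 100)
      stop("apc_mean must lie in [0, 100] (group ", g, ")", call. = FALSE)
  }
  structure(list(n_per_group = n_per_group, groups = groups,
                 seed = as.integer(seed), grid = grid, n_phases = n_phases,
                 noise_sigma = noise_sigma),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_cohort_groups <- function() {
  list(
    fontan = list(sys_mean = 0.036, sys_sd = 0.018,
                  dia_mean = 0.028, dia_sd = 0.010,
                  morphology_mix = c(left = 4 / 11, right = 6 / 11,
                                     left_long_outflow = 1 / 11),
                  hr_range = c(60, 110), bsa_range = c(0.56, 1.72),
                  edvi_mean = 95, edvi_sd = 20, ef_mean = 41, ef_sd = 6,
                  apc_mean = 27, apc_sd = 12),
    control = list(sys_mean = 0.048, sys_sd = 0.012,
                   dia_mean = 0.058, dia_sd = 0.010,
                   morphology_mix = c(left = 1),
                   hr_range = c(55, 80), bsa_range = c(1.6, 2.1),
                   edvi_mean = 101, edvi_sd = 11, ef_mean = 57, ef_sd = 5,
                   apc_mean = 0, apc_sd = 0)
  )
}

# truncated-normal draw by redraw; lo/hi are hard physical bounds
.rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf, what = "value") {
  x <- rnorm(n, mean, sd)
  redraws <- 0L
  while (any(bad <- x < lo | x > hi)) {
    redraws <- redraws + sum(bad)
    if (sd == 0) { x[bad] <- pmin(pmax(mean, lo), hi); break }
    x[bad] <- rnorm(sum(bad), mean, sd)
  }
  if (redraws > 0)
    message("redrew ", redraws, " out-of-range draw(s) for ", what,
            " (truncated at [", lo, ", ", hi, "])")
  x
}

#' Draw per-subject cohort parameters
#'
#' The random half of [simulate_cohort()]: draws every subject's heart
#' rate, body size, volumes, KE/SV peak targets, morphology and APC
#' fraction from the spec's distributions, without building the (large)
#' velocity fields. Subjects whose fields are needed can then be
#' synthesized one at a time (see [run_cohort()]), which keeps memory flat
#' for large simulated cohorts.
#'
#' @param spec A [cohort_spec()].
#' @return Data frame with one row per subject: `subject_id`, `group`,
#'   `morphology`, `pattern`, `heart_rate`, `bsa`, `edv_ml`, `esv_ml`,
#'   `true_sys_per_sv`, `true_dia_per_sv`, `apc_fraction`, `seed`.
#' @export
cohort_params <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  rows <- list()
  sid <- 0L
  for (g in names(spec$n_per_group)) {
    gr <- spec$groups[[g]]
    n <- spec$n_per_group[[g]]
    sys <- .rtrunc_norm(n, gr$sys_mean, gr$sys_sd, lo = 1e-4,
                        what = paste0(g, " systolic KE/SV"))
    dia <- .rtrunc_norm(n, gr$dia_mean, gr$dia_sd, lo = 1e-4,
                        what = paste0(g, " diastolic KE/SV"))
    morph <- sample(names(gr$morphology_mix), n, replace = TRUE,
                    prob = gr$morphology_mix)
    hr <- runif(n, gr$hr_range[1], gr$hr_range[2])
    bsa <- runif(n, gr$bsa_range[1], gr$bsa_range[2])
    edvi <- .rtrunc_norm(n, gr$edvi_mean, gr$edvi_sd, lo = 40, hi = 220,
                         what = paste0(g, " EDVI"))
    ef <- .rtrunc_norm(n, gr$ef_mean, gr$ef_sd, lo = 20, hi = 75,
                       what = paste0(g, " EF"))
    apc <- if (gr$apc_sd == 0 && gr$apc_mean == 0) rep(0, n)
           else .rtrunc_norm(n, gr$apc_mean, gr$apc_sd, lo = 0, hi = 100,
                             what = paste0(g, " APC fraction"))
    edv <- edvi * bsa
    esv <- edv * (1 - ef / 100)
    rows[[g]] <- data.frame(
      subject_id = sprintf("%s_%03d", g, seq_len(n) + sid),
      group = g, morphology = morph,
      pattern = ifelse(sys > dia, "systolic_dominant", "diastolic_dominant"),
      heart_rate = hr, bsa = bsa, edv_ml = edv, esv_ml = esv,
      true_sys_per_sv = sys, true_dia_per_sv = dia, apc_fraction = apc,
      seed = (spec$seed + 7919L * (seq_len(n) + sid)) %% .Machine$integer.max,
      stringsAsFactors = FALSE
    )
    sid <- sid + n
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

# build one subject's phantom from a cohort_params row
.build_cohort_subject <- function(row, spec) {
  ph <- make_ventricle_phantom(
    pattern = row$pattern,
    edv_ml = row$edv_ml, esv_ml = row$esv_ml,
    peak_systolic_per_sv = row$true_sys_per_sv,
    peak_diastolic_per_sv = row$true_dia_per_sv,
    grid = spec$grid, n_phases = spec$n_phases,
    heart_rate = row$heart_rate, bsa = row$bsa,
    noise_sigma = spec$noise_sigma, seed = row$seed,
    subject_id = row$subject_id, group_label = row$group,
    morphology = row$morphology
  )
  ph$truth$apc_fraction <- row$apc_fraction
  ph
}

#' Simulate a two-group 4D flow cohort
#'
#' Draws per-subject KE/SV peak targets from the group distributions of a
#' [cohort_spec()] and builds a ventricle phantom realizing each. Fully
#' materializes every subject's velocity field; intended for small cohorts
#' (for large n, iterate over [cohort_params()] rows instead, as
#' [run_cohort()] does).
#'
#' @param spec A [cohort_spec()].
#' @return List of subjects, each a list with `field`, `masks`, `truth`,
#'   `metadata`, plus a `params` attribute holding the [cohort_params()]
#'   data frame.
#' @export
simulate_cohort <- function(spec) {
  params <- cohort_params(spec)
  subjects <- lapply(seq_len(nrow(params)),
                     function(i) .build_cohort_subject(params[i, ], spec))
  attr(subjects, "params") <- params
  subjects
}
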