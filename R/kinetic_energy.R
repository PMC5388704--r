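# Voxel-wise and region-summed kinetic energy, the KE time curve, its
# systolic/diastolic landmarks, pattern classification, and indexing.

#' Kinetic energy of a voxel
#'
#' KE = 1/2 m v^2 with m the blood mass in the voxel (volume times density)
#' and v the magnitude of the three-directional velocity vector. Inputs use
#' acquisition units (cm/s, mm^3, g/cm^3); the result is in millijoules.
#'
#' @param velocity Numeric length-3 velocity vector (cm/s), or an n x 3
#'   matrix of vectors.
#' @param voxel_volume Voxel volume in mm^3 (> 0).
#' @param density Blood density in g/cm^3 (> 0); 1.05 by default.
#' @return KE in mJ (vectorized over rows when `velocity` is a matrix).
#' @export
#' @examples
#' voxel_ke(c(100, 0, 0), 8)      # 4.2e-3 mJ
#' voxel_ke(c(60, 80, 0), 8)      # same speed, same KE
voxel_ke <- function(velocity, voxel_volume, density = 1.05) {
  if (voxel_volume <= 0) stop("voxel_volume must be > 0", call. = FALSE)
  if (density <= 0) stop("density must be > 0", call. = FALSE)
  if (!all(is.finite(velocity)))
    stop("non-finite velocity component", call. = FALSE)
  v <- if (is.matrix(velocity)) velocity else matrix(velocity, ncol = 3)
  if (ncol(v) != 3) stop("velocity must have 3 components", call. = FALSE)
  ke <- .ke_mj(rowSums(v^2), voxel_volume, density)
  if (is.matrix(velocity)) ke else ke[[1]]
}

#' Region-summed kinetic-energy curve
#'
#' Sums the per-voxel kinetic energy over all voxels labeled `roi` in each
#' phase, yielding the KE of the entire ventricle or vessel segment across
#' the cardiac cycle.
#'
#' @param field A `velocity_field`.
#' @param masks A `mask_series` on the same grid and phase count.
#' @param roi Region name (see [region_labels()]) or code.
#' @return An object of class `ke_curve`: list with `roi`, `ke_per_phase`
#'   (mJ), `phase_times` (ms), and `mean_ke` (the time average weighted by
#'   phase durations over one RR interval).
#' @export
roi_ke_curve <- function(field, masks, roi = "ventricle") {
  stopifnot(inherits(field, "velocity_field"), inherits(masks, "mask_series"))
  d <- dim(field$values)
  if (!all(dim(masks) == d[1:4]))
    stop("mask dimensions do not match field", call. = FALSE)
  code <- .region_code(roi)
  roi_name <- names(.REGION_LABELS)[match(code, .REGION_LABELS)]
  np <- d[1]
  voxvol <- voxel_volume_mm3(field)
  rho <- field$metadata$blood_density
  lab <- unclass(masks)
  ke <- numeric(np)
  empty <- integer()
  for (p in seq_len(np)) {
    sel <- lab[p, , , ] == code
    if (!any(sel)) { empty <- c(empty, p); next }
    s2 <- field$values[p, , , , 1][sel]^2 +
          field$values[p, , , , 2][sel]^2 +
          field$values[p, , , , 3][sel]^2
    ke[p] <- .ke_mj(sum(s2), voxvol, rho)
  }
  if (length(empty))
    stop("region '", roi_name, "' absent in phase(s) ",
         paste(empty, collapse = ", "), call. = FALSE)
  t <- field$phase_times
  rr <- field$metadata$rr_interval
  durations <- c(diff(t), rr - t[np] + t[1])
  structure(list(roi = roi_name, ke_per_phase = ke, phase_times = t,
                 mean_ke = sum(ke * durations) / rr),
            class = "ke_curve")
}

#' @export
print.ke_curve <- function(x, ...) {
  cat("<ke_curve> roi ", x$roi, ", ", length(x$ke_per_phase),
      " phases; peak ", signif(max(x$ke_per_phase), 4), " mJ, mean ",
      signif(x$mean_ke, 4), " mJ\n", sep = "")
  invisible(x)
}

#' Locate end-diastole and end-systole on a volume curve
#'
#' End-diastole is the phase of maximum ventricular volume (cycle start),
#' end-systole the phase of minimum volume; ties break to the earliest
#' phase. These landmarks split the cycle into its ejection (systolic) and
#' filling (diastolic) halves for peak analysis.
#'
#' @param volume_curve A [volume_curve()] object or numeric vector of
#'   per-phase volumes (>= 4 phases).
#' @return An object of class `cycle_landmarks`: list with
#'   `end_diastole_idx` and `end_systole_idx` (1-based phase indices).
#' @export
find_cycle_landmarks <- function(volume_curve) {
  v <- if (inherits(volume_curve, "volume_curve"))
    volume_curve$volume_per_phase else as.numeric(volume_curve)
  if (length(v) < 4) stop("volume curve needs >= 4 phases", call. = FALSE)
  if (max(v) == min(v))
    stop("constant volume curve: no cardiac cycle to segment", call. = FALSE)
  structure(list(end_diastole_idx = which.max(v),   # earliest tie by which.max
                 end_systole_idx = which.min(v)),
            class = "cycle_landmarks")
}

# cyclic index sequence from a to the element before b (half-open window)
.cyclic_window <- function(from, to, n) {
  len <- (to - from) %% n
  if (len == 0) return(integer())
  ((from - 1 + seq_len(len) - 1) %% n) + 1
}

# local maxima of a sequence (first index of a plateau run counts); endpoints
# included when they dominate their single neighbour
.local_maxima <- function(d) {
  m <- length(d)
  if (m == 1) return(1L)
  peaks <- integer()
  if (d[1] > d[2]) peaks <- 1L
  if (m > 2)
    for (j in 2:(m - 1))
      if (d[j] > d[j - 1] && d[j] >= d[j + 1]) peaks <- c(peaks, j)
  if (d[m] > d[m - 1]) peaks <- c(peaks, m)
  peaks
}

#' Systolic and diastolic peak analysis of a KE curve
#'
#' Splits the cycle at the volume-derived landmarks, then locates the
#' systolic KE peak (maximum over the systolic window), the early
#' diastolic peak (first local maximum of the diastolic window, the E-type
#' inflow peak), and - when present - a late diastolic peak corresponding
#' to atrial contraction: a second local maximum in the final
#' `late_window_frac` of diastole separated from the early peak by a trough
#' at least `trough_frac` below the smaller of the two. Without such a
#' separated late peak the early and atrial peaks are reported as fused.
#' A diastolic plateau is flagged when the KE range over the central
#' `plateau_window_frac` of diastole stays below `plateau_tol` of the
#' diastolic peak.
#'
#' @param curve A [roi_ke_curve()] result.
#' @param landmarks A [find_cycle_landmarks()] result.
#' @param late_window_frac Final fraction of diastole searched for the
#'   atrial peak (default 0.3).
#' @param trough_frac Required relative trough depth between the early and
#'   late peaks (default 0.10).
#' @param min_late_frac Minimum height of any diastolic peak candidate as a
#'   fraction of the diastolic maximum (default 0.05); guards against
#'   boundary tails and numerically tiny ripples counting as peaks.
#' @param plateau_window_frac Central fraction of diastole tested for
#'   flatness (default 0.5).
#' @param plateau_tol Relative KE range below which the central diastole
#'   counts as a plateau (default 0.15).
#' @return An object of class `ke_peaks`: `systolic_peak`,
#'   `early_diastolic_peak`, `late_diastolic_peak` (each `list(value, idx)`
#'   in mJ / phase index; late may be `NULL`), `fused`, `plateau`
#'   (`list(flag, flatness)`), and `sd_ratio` (systolic peak over the
#'   largest diastolic peak).
#' @export
analyze_peaks <- function(curve, landmarks,
                          late_window_frac = 0.3, trough_frac = 0.10,
                          min_late_frac = 0.05,
                          plateau_window_frac = 0.5, plateau_tol = 0.15) {
  stopifnot(inherits(curve, "ke_curve"), inherits(landmarks, "cycle_landmarks"))
  ke <- curve$ke_per_phase
  n <- length(ke)
  ed <- landmarks$end_diastole_idx
  es <- landmarks$end_systole_idx
  if (ed == es || ed > n || es > n)
    stop("landmarks must be distinct phase indices within the curve",
         call. = FALSE)
  sys_win <- .cyclic_window(ed, es, n)
  dia_win <- .cyclic_window(es, ed, n)
  if (!length(dia_win)) stop("empty diastolic window", call. = FALSE)
  if (!length(sys_win)) stop("empty systolic window", call. = FALSE)

  s_at <- sys_win[which.max(ke[sys_win])]
  systolic_peak <- list(value = ke[s_at], idx = s_at)

  d <- ke[dia_win]
  m <- length(d)
  # candidate diastolic peaks: interior local maxima (the window's first
  # sample is the end-systolic boundary, not a filling peak) of height at
  # least min_late_frac of the diastolic maximum
  peaks <- setdiff(.local_maxima(d), 1L)
  peaks <- peaks[d[peaks] >= min_late_frac * max(d)]
  if (!length(peaks)) peaks <- which.max(d)
  e_j <- peaks[1]
  early <- list(value = d[e_j], idx = dia_win[e_j])

  late <- NULL
  late_start <- m - ceiling(late_window_frac * m) + 1
  cand <- peaks[peaks >= late_start & peaks > e_j]
  for (j in cand[order(d[cand], decreasing = TRUE)]) {
    trough <- min(d[e_j:j])
    if (trough <= (1 - trough_frac) * min(d[e_j], d[j])) {
      late <- list(value = d[j], idx = dia_win[j])
      break
    }
  }
  fused <- is.null(late)

  c0 <- floor((0.5 - plateau_window_frac / 2) * m) + 1
  c1 <- ceiling((0.5 + plateau_window_frac / 2) * m)
  central <- d[c0:c1]
  dia_peak <- max(d)
  flatness <- if (dia_peak > 0) (max(central) - min(central)) / dia_peak else Inf
  plateau <- list(flag = flatness < plateau_tol, flatness = flatness)

  structure(list(systolic_peak = systolic_peak,
                 early_diastolic_peak = early,
                 late_diastolic_peak = late,
                 fused = fused, plateau = plateau,
                 sd_ratio = systolic_peak$value / dia_peak,
                 diastolic_peak = list(value = dia_peak,
                                       idx = dia_win[which.max(d)]),
                 windows = list(systolic = sys_win, diastolic = dia_win),
                 thresholds = list(late_window_frac = late_window_frac,
                                   trough_frac = trough_frac,
                                   min_late_frac = min_late_frac,
                                   plateau_window_frac = plateau_window_frac,
                                   plateau_tol = plateau_tol)),
            class = "ke_peaks")
}

#' @export
print.ke_peaks <- function(x, ...) {
  cat("<ke_peaks> systolic ", signif(x$systolic_peak$value, 4),
      " mJ @", x$systolic_peak$idx,
      "; diastolic ", signif(x$diastolic_peak$value, 4),
      " mJ @", x$diastolic_peak$idx,
      "; S/D ratio ", signif(x$sd_ratio, 3),
      if (x$fused) "; E/A fused" else "; separate late peak",
      if (x$plateau$flag) "; diastolic plateau" else "", "\n", sep = "")
  invisible(x)
}

#' Classify the KE curve pattern
#'
#' Curves with a systole/diastole peak ratio above 1 are systolic-dominant
#' (the right-ventricle-type pattern); below 1, diastolic-dominant (the
#' short-outflow left-ventricle type). A ratio within 1e-6 of unity is
#' indeterminate.
#'
#' @param peaks A [analyze_peaks()] result.
#' @return `"systolic_dominant"` or `"diastolic_dominant"`.
#' @export
classify_pattern <- function(peaks) {
  stopifnot(inherits(peaks, "ke_peaks"))
  if (peaks$diastolic_peak$value <= 0)
    stop("zero diastolic peak: pattern undefined", call. = FALSE)
  r <- peaks$sd_ratio
  if (abs(r - 1) <= 1e-6)
    stop("systole/diastole ratio indistinguishable from 1: indeterminate",
         call. = FALSE)
  if (r > 1) "systolic_dominant" else "diastolic_dominant"
}

#' Index a KE value to physiological denominators
#'
#' Divides a kinetic-energy value by stroke volume, body surface area,
#' cardiac index, and/or vessel-segment volume, the indexings used to
#' compare subjects of different body size. Absent denominators yield
#' absent (NULL) fields, never zeros.
#'
#' @param value KE in mJ.
#' @param sv Stroke volume (ml). @param bsa Body surface area (m^2).
#' @param ci Cardiac index (l/min/m^2). @param vessel_volume Vessel segment
#'   volume (ml), for vessel ROIs.
#' @return An object of class `indexed_ke`: list with `ke_per_sv` (mJ/ml),
#'   `ke_per_bsa` (mJ/m^2), `ke_per_ci` (mJ/(l/min/m^2)),
#'   `ke_per_vessel_volume` (mJ/ml); only the requested entries are
#'   non-NULL.
#' @export
#' @examples
#' index_ke(0.36, sv = 10)$ke_per_sv  # 0.036 mJ/ml
index_ke <- function(value, sv = NULL, bsa = NULL, ci = NULL,
                     vessel_volume = NULL) {
  chk <- function(x, name) {
    if (!is.null(x) && (!is.finite(x) || x <= 0))
      stop("denominator ", name, " must be positive, got ", x, call. = FALSE)
    x
  }
  structure(list(
    value = value,
    ke_per_sv = if (!is.null(chk(sv, "sv"))) value / sv,
    ke_per_bsa = if (!is.null(chk(bsa, "bsa"))) value / bsa,
    ke_per_ci = if (!is.null(chk(ci, "ci"))) value / ci,
    ke_per_vessel_volume =
      if (!is.null(chk(vessel_volume, "vessel_volume"))) value / vessel_volume
  ), class = "indexed_ke")
}
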