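# Ventricular volumes and global hemodynamics: EDV/ESV/SV/EF, plane flow
# and effective stroke volume, cardiac output and index, aortopulmonary
# collateral (APC) flow with the >25%-of-SV significance rule, and vessel
# cross-sectional area.

#' Ventricular volume curve and derived indices
#'
#' Per-phase ventricular volume from segmentation masks (voxel count times
#' voxel volume), with end-diastolic volume (EDV, the maximum),
#' end-systolic volume (ESV, the minimum), stroke volume SV = EDV - ESV,
#' ejection fraction EF = 100 SV / EDV, and BSA-indexed EDVI/ESVI when the
#' body surface area is known.
#'
#' @param x A `mask_series`, or a numeric vector of per-phase volumes (ml).
#' @param bsa Body surface area (m^2); required for the indexed values.
#' @param roi Region whose voxels are counted (default `"ventricle"`).
#' @return An object of class `volume_curve`: `volume_per_phase` (ml),
#'   `edv`, `esv`, `sv` (ml), `ef` (%), and `edvi`, `esvi` (ml/m^2, `NULL`
#'   without BSA).
#' @export
#' @examples
#' vc <- volume_curve(c(150, 120, 90, 110, 140))
#' c(vc$edv, vc$esv, vc$sv, vc$ef)  # 150 90 60 40
volume_curve <- function(x, bsa = NULL, roi = "ventricle") {
  if (inherits(x, "mask_series")) {
    code <- .region_code(roi)
    lab <- unclass(x)
    np <- dim(lab)[1]
    voxvol <- voxel_volume_mm3(x)
    vols <- vapply(seq_len(np),
                   function(p) sum(lab[p, , , ] == code) * voxvol / 1000,
                   numeric(1))
    if (any(vols == 0))
      stop("region '", roi, "' absent in phase(s) ",
           paste(which(vols == 0), collapse = ", "), call. = FALSE)
  } else {
    vols <- as.numeric(x)
    if (any(vols < 0)) stop("volumes must be >= 0", call. = FALSE)
  }
  edv <- max(vols); esv <- min(vols)
  sv <- edv - esv
  ef <- if (edv > 0) 100 * sv / edv else 0
  if (!is.null(bsa) && is.na(bsa)) bsa <- NULL
  if (!is.null(bsa) && bsa <= 0)
    stop("bsa must be positive for indexed volumes", call. = FALSE)
  structure(list(volume_per_phase = vols, edv = edv, esv = esv, sv = sv,
                 ef = ef,
                 edvi = if (!is.null(bsa)) edv / bsa,
                 esvi = if (!is.null(bsa)) esv / bsa),
            class = "volume_curve")
}

#' @export
print.volume_curve <- function(x, ...) {
  cat("<volume_curve> EDV ", round(x$edv, 1), " ml, ESV ", round(x$esv, 1),
      " ml, SV ", round(x$sv, 1), " ml, EF ", round(x$ef, 1), "%\n", sep = "")
  invisible(x)
}

#' Through-plane flow curve and net forward volume
#'
#' Flow through a 2-D plane ROI: per phase, the sum of pixel velocity times
#' pixel area; the net forward volume per beat (the effective stroke volume
#' when measured in the ascending aorta) is the trapezoidal time integral
#' over one closed cycle.
#'
#' @param velocities Matrix of through-plane velocities (cm/s), phases in
#'   rows, ROI pixels in columns.
#' @param pixel_area Pixel area in mm^2.
#' @param phase_times Per-phase times (ms), starting at 0, within one RR.
#' @param rr_interval RR interval (ms) closing the cycle.
#' @param positive_direction +1 or -1: which through-plane direction counts
#'   as forward. Must be stated explicitly; there is no default sign
#'   convention.
#' @return An object of class `flow_curve`: `flow_per_phase` (ml/s),
#'   `phase_times`, `net_forward_volume` (ml/beat).
#' @export
#' @examples
#' # uniform 100 cm/s over 5 cm^2 for a 1 s cycle -> 500 ml
#' f <- plane_flow(matrix(100, 10, 500), pixel_area = 1,
#'                 phase_times = seq(0, 900, by = 100), rr_interval = 1000,
#'                 positive_direction = 1)
#' f$net_forward_volume
plane_flow <- function(velocities, pixel_area, phase_times, rr_interval,
                       positive_direction) {
  if (missing(positive_direction))
    stop("positive_direction must be declared (+1 or -1): no default sign ",
         "convention", call. = FALSE)
  if (!positive_direction %in% c(-1, 1))
    stop("positive_direction must be +1 or -1", call. = FALSE)
  velocities <- as.matrix(velocities)
  if (ncol(velocities) < 1) stop("plane ROI is empty", call. = FALSE)
  if (nrow(velocities) != length(phase_times))
    stop("velocities rows (", nrow(velocities), ") != phase count (",
         length(phase_times), ")", call. = FALSE)
  # cm/s * mm^2 = 10 mm^3/s = 0.01 ml/s
  flow <- positive_direction * rowSums(velocities) * pixel_area * 0.01
  t_s <- c(phase_times, rr_interval) / 1000
  f_closed <- c(flow, flow[1])
  net <- sum(diff(t_s) * (f_closed[-1] + f_closed[-length(f_closed)]) / 2)
  structure(list(flow_per_phase = flow, phase_times = phase_times,
                 net_forward_volume = net),
            class = "flow_curve")
}

#' Cardiac output and cardiac index
#'
#' CO = SV x HR / 1000 (l/min); CI = CO / BSA (l/min/m^2).
#'
#' @param sv Stroke volume (ml, > 0).
#' @param heart_rate Heart rate (beats/min, > 0).
#' @param bsa Body surface area (m^2, > 0).
#' @return List with `co` (l/min) and `ci` (l/min/m^2).
#' @export
#' @examples
#' cardiac_indices(50, 70, 1.0)  # CO 3.5 l/min, CI 3.5
cardiac_indices <- function(sv, heart_rate, bsa) {
  if (sv <= 0 || heart_rate <= 0) stop("sv and heart_rate must be > 0",
                                       call. = FALSE)
  if (!is.finite(bsa) || bsa <= 0) stop("bsa must be > 0", call. = FALSE)
  co <- sv * heart_rate / 1000
  list(co = co, ci = co / bsa)
}

#' Aortopulmonary collateral (APC) flow
#'
#' APC flow is the systemic blood reaching the lungs outside the caval
#' pathway, estimated per beat by subtraction: aortic stroke volume minus
#' total caval flow volume (method `aortic_minus_caval`), or - when aortic
#' flow is unavailable - pulmonary venous minus caval volume
#' (`pulmonary_minus_caval`). The APC fraction is expressed relative to the
#' reference (minuend) volume, and is hemodynamically significant when it
#' strictly exceeds `threshold` percent.
#'
#' Small negative estimates (measurement noise) are floored at zero with a
#' warning.
#'
#' @param caval_volume Combined SVC + IVC flow volume per beat (ml).
#' @param aortic_sv Aortic stroke volume (ml); method A reference.
#' @param pulmonary_venous_volume Total pulmonary venous volume (ml);
#'   method B reference. Exactly one of the two references must be given.
#' @param threshold Significance threshold in % of the reference (default
#'   25; strict inequality).
#' @return An object of class `apc_result`: `apc_volume` (ml/beat),
#'   `apc_fraction` (%), `method`, `significant`, `threshold`.
#' @export
#' @examples
#' apc_flow(caval_volume = 30, aortic_sv = 40)$apc_fraction   # 25: not significant
#' apc_flow(caval_volume = 24, aortic_sv = 40)$significant    # 40% > 25
apc_flow <- function(caval_volume, aortic_sv = NULL,
                     pulmonary_venous_volume = NULL, threshold = 25) {
  has_a <- !is.null(aortic_sv)
  has_b <- !is.null(pulmonary_venous_volume)
  if (has_a == has_b)
    stop("supply exactly one of aortic_sv or pulmonary_venous_volume",
         call. = FALSE)
  reference <- if (has_a) aortic_sv else pulmonary_venous_volume
  method <- if (has_a) "aortic_minus_caval" else "pulmonary_minus_caval"
  if (reference <= 0) stop("reference volume must be > 0", call. = FALSE)
  apc <- reference - caval_volume
  if (apc < 0) {
    warning("negative APC estimate (", round(apc, 2),
            " ml) floored at 0; caval volume exceeds the reference")
    apc <- 0
  }
  fraction <- 100 * apc / reference
  structure(list(apc_volume = apc, apc_fraction = fraction, method = method,
                 significant = fraction > threshold, threshold = threshold),
            class = "apc_result")
}

#' Vessel cross-sectional area
#'
#' Lumen area perpendicular to the vessel axis. For a 2-D mask this is the
#' pixel count times pixel area; for a 3-D label volume the per-slice areas
#' along the vessel axis (the dimension with the largest labeled extent)
#' are averaged over slices containing the vessel.
#'
#' @param mask Logical/integer 2-D or 3-D array (nonzero = lumen).
#' @param spacing Pixel/voxel spacing in mm (length 2 or 3).
#' @return Area in cm^2.
#' @export
#' @examples
#' cross_sectional_area(matrix(1, 10, 10), c(1, 1))  # 100 px of 1 mm^2 = 1 cm^2
cross_sectional_area <- function(mask, spacing) {
  mask <- mask != 0
  if (!any(mask)) stop("empty vessel label", call. = FALSE)
  d <- dim(mask)
  if (is.null(d) || length(d) == 2) {
    if (length(spacing) < 2) stop("need in-plane spacing (mm)", call. = FALSE)
    return(sum(mask) * spacing[1] * spacing[2] / 100)
  }
  if (length(d) != 3) stop("mask must be 2-D or 3-D", call. = FALSE)
  extents <- vapply(1:3, function(ax) {
    hit <- apply(mask, ax, any)
    diff(range(which(hit))) + 1
  }, numeric(1))
  axis <- which.max(extents * spacing[1:3])
  inplane <- prod(spacing[-axis])
  per_slice <- apply(mask, axis, sum) * inplane / 100
  mean(per_slice[per_slice > 0])
}
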