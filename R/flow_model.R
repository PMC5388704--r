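#' Acquisition metadata for a 4D flow study
#'
#' Collects the acquisition parameters every downstream computation needs:
#' the velocity-encoding limit (venc), voxel spacing, timing, and the blood
#' density used to convert voxel volume to mass.
#'
#' @param subject_id Subject identifier (character).
#' @param group_label `"fontan"` or `"control"`.
#' @param ventricular_morphology `"left"`, `"right"`, or
#'   `"left_long_outflow"` (morphological LV whose outflow runs through a
#'   VSD and rudimentary chamber).
#' @param venc Velocity-encoding limit in cm/s (> 0). Velocities beyond
#'   +/-venc alias. Default 100.
#' @param voxel_spacing Length-3 numeric, voxel edge lengths in mm.
#' @param n_phases_acquired Number of cardiac phases acquired (>= 2).
#' @param n_phases_reconstructed Phase count after temporal reconstruction
#'   (default 40).
#' @param rr_interval RR interval in ms (> 0). If missing it is derived from
#'   `heart_rate`.
#' @param heart_rate Heart rate in beats/min. If missing it is derived from
#'   `rr_interval`; when both are given they must agree within 1%.
#' @param bsa Body surface area in m^2 (optional, `NA` if unknown).
#' @param blood_density Blood mass density in g/cm^3. Default 1.05.
#'
#' @return An object of class `flow_metadata`.
#' @export
#' @examples
#' md <- flow_metadata("s01", "fontan", "left", n_phases_acquired = 20,
#'                     rr_interval = 1000)
#' md$heart_rate  # 60 bpm, derived
flow_metadata <- function(subject_id,
                          group_label = c("fontan", "control"),
                          ventricular_morphology = c("left", "right",
                                                     "left_long_outflow"),
                          venc = 100,
                          voxel_spacing = c(2, 2, 2),
                          n_phases_acquired = 20,
                          n_phases_reconstructed = 40,
                          rr_interval = NULL,
                          heart_rate = NULL,
                          bsa = NA_real_,
                          blood_density = 1.05) {
  group_label <- match.arg(group_label)
  ventricular_morphology <- match.arg(ventricular_morphology)
  if (is.null(rr_interval) && is.null(heart_rate))
    stop("one of rr_interval or heart_rate must be given", call. = FALSE)
  if (is.null(rr_interval)) rr_interval <- 60000 / heart_rate
  if (is.null(heart_rate)) heart_rate <- 60000 / rr_interval
  md <- structure(list(
    subject_id = as.character(subject_id),
    group_label = group_label,
    ventricular_morphology = ventricular_morphology,
    venc = venc,
    voxel_spacing = as.numeric(voxel_spacing),
    n_phases_acquired = as.integer(n_phases_acquired),
    n_phases_reconstructed = as.integer(n_phases_reconstructed),
    rr_interval = rr_interval,
    heart_rate = heart_rate,
    bsa = as.numeric(bsa),
    blood_density = blood_density
  ), class = "flow_metadata")
  validate_flow_metadata(md)
  md
}

validate_flow_metadata <- function(md) {
  stopifnot(inherits(md, "flow_metadata"))
  if (!is.numeric(md$venc) || length(md$venc) != 1 || md$venc <= 0)
    stop("venc must be a single positive number (cm/s)", call. = FALSE)
  if (length(md$voxel_spacing) != 3 || any(md$voxel_spacing <= 0))
    stop("voxel_spacing must be three positive lengths (mm)", call. = FALSE)
  if (md$n_phases_acquired < 2)
    stop("n_phases_acquired must be >= 2", call. = FALSE)
  if (md$rr_interval <= 0) stop("rr_interval must be > 0", call. = FALSE)
  if (md$blood_density <= 0) stop("blood_density must be > 0", call. = FALSE)
  # heart rate and RR interval must describe the same rhythm
  if (abs(60000 / md$heart_rate - md$rr_interval) > 0.01 * md$rr_interval)
    stop("heart_rate and rr_interval disagree by more than 1% ",
         "(60000/HR = ", round(60000 / md$heart_rate, 1), " ms vs rr_interval = ",
         round(md$rr_interval, 1), " ms)", call. = FALSE)
  invisible(md)
}

#' Physical voxel volume
#'
#' @param x A `flow_metadata`, `velocity_field` or numeric length-3 spacing
#'   (mm).
#' @return Voxel volume in mm^3 (product of the spacings).
#' @export
voxel_volume_mm3 <- function(x) {
  sp <- if (inherits(x, "flow_metadata")) x$voxel_spacing
        else if (inherits(x, "velocity_field")) x$metadata$voxel_spacing
        else if (inherits(x, "mask_series")) attr(x, "spacing")
        else as.numeric(x)
  prod(sp)
}

#' Time-resolved three-directional velocity field
#'
#' The central data object: per-voxel blood velocity (cm/s) in three
#' directions over one cardiac cycle, on a regular grid.
#'
#' @param values 5-D numeric array with dimensions
#'   `(phase, x, y, z, component)`; the component axis has length 3 and is
#'   ordered (vx, vy, vz). Units cm/s.
#' @param metadata A [flow_metadata()] object.
#' @param phase_times Optional numeric vector of per-phase time offsets (ms)
#'   starting at 0 and strictly increasing within one RR interval. When
#'   `NULL`, uniform spacing over the RR interval is assumed.
#'
#' @return An object of class `velocity_field` with elements `values`,
#'   `phase_times`, `metadata`.
#' @export
velocity_field <- function(values, metadata, phase_times = NULL) {
  validate_flow_metadata(metadata)
  d <- dim(values)
  if (length(d) != 5)
    stop("values must be a 5-D array (phase, x, y, z, component); got ",
         length(d), " dimensions", call. = FALSE)
  if (d[5] != 3)
    stop("component axis must have length 3, got ", d[5], call. = FALSE)
  if (is.null(phase_times))
    phase_times <- uniform_phase_times(d[1], metadata$rr_interval)
  fld <- structure(list(values = values, phase_times = phase_times,
                        metadata = metadata),
                   class = "velocity_field")
  validate_velocity_field(fld)
  fld
}

uniform_phase_times <- function(n, rr) (seq_len(n) - 1) * rr / n

validate_velocity_field <- function(fld) {
  v <- fld$values
  t <- fld$phase_times
  rr <- fld$metadata$rr_interval
  if (!all(is.finite(v))) {
    bad <- which(!is.finite(v), arr.ind = TRUE)[1, ]
    stop("non-finite velocity at (phase, x, y, z, component) = (",
         paste(bad, collapse = ", "), ")", call. = FALSE)
  }
  if (length(t) != dim(v)[1])
    stop("phase_times length (", length(t), ") != phase count (",
         dim(v)[1], ")", call. = FALSE)
  if (t[1] != 0) stop("phase_times must start at 0", call. = FALSE)
  if (any(diff(t) <= 0)) stop("phase_times must be strictly increasing",
                              call. = FALSE)
  if (any(t >= rr)) stop("phase_times must all be below the RR interval",
                         call. = FALSE)
  invisible(fld)
}

#' @export
print.velocity_field <- function(x, ...) {
  d <- dim(x$values)
  cat("<velocity_field> ", d[1], " phases, grid ", d[2], "x", d[3], "x", d[4],
      ", spacing ", paste(x$metadata$voxel_spacing, collapse = "x"),
      " mm, venc ", x$metadata$venc, " cm/s, RR ",
      round(x$metadata$rr_interval), " ms\n", sep = "")
  invisible(x)
}

#' Per-phase region label volumes
#'
#' Voxel labels delineating the ventricle and Fontan-pathway vessel segments
#' on the same grid as a paired [velocity_field()]. A voxel belongs to a
#' region iff its label equals that region's code (voxel-center membership).
#'
#' @param labels Integer array, either 4-D `(phase, x, y, z)` or 3-D
#'   `(x, y, z)`; a 3-D (single-phase) mask is broadcast to all phases of
#'   `field` with a message.
#' @param field The paired `velocity_field` (used for geometry checks and
#'   broadcasting). May be `NULL` if `spacing` and the label array are
#'   already 4-D and self-consistent.
#' @param spacing Voxel spacing (mm); defaults to the field's.
#'
#' @return An object of class `mask_series` (the validated 4-D label array
#'   with a `spacing` attribute).
#' @export
mask_series <- function(labels, field = NULL, spacing = NULL) {
  d <- dim(labels)
  if (!is.null(field)) {
    stopifnot(inherits(field, "velocity_field"))
    fd <- dim(field$values)
    if (length(d) == 3) {
      if (!all(d == fd[2:4]))
        stop("single-phase mask grid ", paste(d, collapse = "x"),
             " does not match field grid ", paste(fd[2:4], collapse = "x"),
             call. = FALSE)
      message("single-phase mask broadcast to ", fd[1], " phases")
      labels <- array(rep(as.integer(labels), each = fd[1]), dim = c(fd[1], d))
      d <- dim(labels)
    }
    if (length(d) != 4 || !all(d == fd[1:4]))
      stop("mask dimensions (", paste(d, collapse = ", "),
           ") do not match field (", paste(fd[1:4], collapse = ", "), ")",
           call. = FALSE)
    if (is.null(spacing)) spacing <- field$metadata$voxel_spacing
  } else if (length(d) != 4) {
    stop("labels must be a 4-D (phase, x, y, z) array when no field is given",
         call. = FALSE)
  }
  if (is.null(spacing))
    stop("voxel spacing unknown: supply field or spacing", call. = FALSE)
  storage.mode(labels) <- "integer"
  bad <- setdiff(unique(as.vector(labels)), .REGION_LABELS)
  if (length(bad))
    stop("unknown label code(s): {", paste(sort(bad), collapse = ", "),
         "}; allowed: {", paste(.REGION_LABELS, collapse = ", "), "}",
         call. = FALSE)
  structure(labels, spacing = as.numeric(spacing), class = "mask_series")
}

#' @export
print.mask_series <- function(x, ...) {
  d <- dim(x)
  present <- names(.REGION_LABELS)[.REGION_LABELS %in% unique(as.vector(x))]
  cat("<mask_series> ", d[1], " phases, grid ",
      paste(d[2:4], collapse = "x"), "; regions: ",
      paste(present, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Phase-wise logical mask for one region. Returns (phase, x, y, z) logical.
.roi_mask <- function(masks, roi) {
  code <- .region_code(roi)
  m <- unclass(masks) == code
  attributes(m) <- list(dim = dim(masks))
  m
}
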