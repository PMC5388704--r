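# Reading and writing 4D flow studies.
#
# On disk a study is three NIfTI scalar volumes (x, y, z, phase; one per
# velocity component, stored as doubles so round trips are bit-exact), a
# JSON metadata sidecar, and optionally phase_times.json for non-uniform
# phase timing. Masks are integer NIfTI label volumes with a JSON label
# dictionary. Voxel spacing in the sidecar is authoritative.

.SIDECAR_KEYS <- c("subject_id", "group_label", "ventricular_morphology",
                   "venc_cm_s", "voxel_spacing_mm", "n_phases_acquired",
                   "n_phases_reconstructed", "rr_interval_ms",
                   "heart_rate_bpm", "bsa_m2", "blood_density_g_cm3")

metadata_to_sidecar <- function(md) {
  list(subject_id = md$subject_id,
       group_label = md$group_label,
       ventricular_morphology = md$ventricular_morphology,
       venc_cm_s = md$venc,
       voxel_spacing_mm = md$voxel_spacing,
       n_phases_acquired = md$n_phases_acquired,
       n_phases_reconstructed = md$n_phases_reconstructed,
       rr_interval_ms = md$rr_interval,
       heart_rate_bpm = md$heart_rate,
       bsa_m2 = md$bsa,
       blood_density_g_cm3 = md$blood_density)
}

sidecar_to_metadata <- function(sc, path = "<sidecar>") {
  required <- c("venc_cm_s", "rr_interval_ms")
  missing <- setdiff(required, names(sc))
  if (length(missing))
    stop("sidecar ", path, " is missing required key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  flow_metadata(
    subject_id = sc$subject_id %||% "unknown",
    group_label = sc$group_label %||% "fontan",
    ventricular_morphology = sc$ventricular_morphology %||% "left",
    venc = sc$venc_cm_s,
    voxel_spacing = unlist(sc$voxel_spacing_mm %||% c(2, 2, 2)),
    n_phases_acquired = sc$n_phases_acquired %||% 2L,
    n_phases_reconstructed = sc$n_phases_reconstructed %||% 40L,
    rr_interval = sc$rr_interval_ms,
    heart_rate = sc$heart_rate_bpm,
    bsa = sc$bsa_m2 %||% NA_real_,
    blood_density = sc$blood_density_g_cm3 %||% 1.05
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a 4D flow study from disk
#'
#' Assembles a [velocity_field()] from three per-component NIfTI volumes
#' (dimensions x, y, z, phase) and a JSON metadata sidecar. When no
#' `phase_times.json` sits beside the sidecar, phase times are reconstructed
#' uniformly over the RR interval.
#'
#' @param volume_paths Character vector of three file paths, ordered
#'   (vx, vy, vz).
#' @param sidecar_path Path to the JSON sidecar (keys `subject_id`,
#'   `group_label`, `ventricular_morphology`, `venc_cm_s`,
#'   `voxel_spacing_mm`, `n_phases_acquired`, `n_phases_reconstructed`,
#'   `rr_interval_ms`, `heart_rate_bpm`, `bsa_m2`, `blood_density_g_cm3`).
#'   `venc_cm_s` and `rr_interval_ms` are required; there is no silent venc
#'   default on load.
#'
#' @return A `velocity_field`.
#' @seealso [save_flow_study()] for the inverse; the pair round-trips values
#'   bit-exactly.
#' @export
load_flow_study <- function(volume_paths, sidecar_path) {
  if (length(volume_paths) != 3)
    stop("expected 3 component volume paths, got ", length(volume_paths),
         call. = FALSE)
  if (!all(file.exists(volume_paths)))
    stop("missing volume file(s): ",
         paste(volume_paths[!file.exists(volume_paths)], collapse = ", "),
         call. = FALSE)
  if (!file.exists(sidecar_path))
    stop("missing sidecar: ", sidecar_path, call. = FALSE)
  md <- sidecar_to_metadata(jsonlite::read_json(sidecar_path,
                                                simplifyVector = TRUE),
                            sidecar_path)
  vols <- lapply(volume_paths, function(p) {
    a <- as.array(RNifti::readNifti(p))
    if (length(dim(a)) == 3) dim(a) <- c(dim(a), 1L)  # single phase
    a
  })
  dims <- vapply(vols, function(a) dim(a), integer(4))
  for (ax in 1:4) {
    if (length(unique(dims[ax, ])) != 1) {
      axname <- c("x", "y", "z", "phase")[ax]
      stop("component volumes disagree on axis ", axname, ": extents ",
           paste(dims[ax, ], collapse = " vs "), call. = FALSE)
    }
  }
  d <- dims[, 1]
  values <- array(NA_real_, dim = c(d[4], d[1], d[2], d[3], 3))
  for (k in 1:3)                       # disk order (x,y,z,phase) -> memory
    values[, , , , k] <- aperm(vols[[k]], c(4, 1, 2, 3))
  times_path <- file.path(dirname(sidecar_path), "phase_times.json")
  phase_times <- if (file.exists(times_path))
    as.numeric(unlist(jsonlite::read_json(times_path))) else NULL
  velocity_field(values, md, phase_times)
}

#' Save a 4D flow study to disk
#'
#' Writes `vx.nii.gz`, `vy.nii.gz`, `vz.nii.gz` (double precision),
#' `sidecar.json` and `phase_times.json` into `out_dir`. Loading the written
#' set with [load_flow_study()] reproduces the field bit-exactly and the
#' metadata field-for-field.
#'
#' @param field A `velocity_field`. Fields containing non-finite values are
#'   refused (the offending voxel index is reported).
#' @param out_dir Output directory; created if absent. An empty path is an
#'   error.
#' @return Invisibly, the named character vector of written paths.
#' @export
save_flow_study <- function(field, out_dir) {
  stopifnot(inherits(field, "velocity_field"))
  if (!is.character(out_dir) || length(out_dir) != 1 || !nzchar(out_dir))
    stop("out_dir must be a non-empty directory path", call. = FALSE)
  if (!all(is.finite(field$values))) {
    bad <- which(!is.finite(field$values), arr.ind = TRUE)[1, ]
    stop("refusing to save non-finite velocity at ",
         "(phase, x, y, z, component) = (", paste(bad, collapse = ", "), ")",
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  sp <- field$metadata$voxel_spacing
  comp_files <- file.path(out_dir, c("vx.nii.gz", "vy.nii.gz", "vz.nii.gz"))
  for (k in 1:3) {
    vol <- aperm(field$values[, , , , k, drop = FALSE][, , , , 1],
                 c(2, 3, 4, 1))                     # -> (x,y,z,phase)
    img <- RNifti::asNifti(vol)
    img <- RNifti::`pixdim<-`(img, c(sp, field$metadata$rr_interval /
                                       dim(field$values)[1]))
    RNifti::writeNifti(img, comp_files[k], datatype = "double")
  }
  sidecar <- file.path(out_dir, "sidecar.json")
  jsonlite::write_json(metadata_to_sidecar(field$metadata), sidecar,
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  times <- file.path(out_dir, "phase_times.json")
  jsonlite::write_json(field$phase_times, times, digits = NA)
  invisible(c(vx = comp_files[1], vy = comp_files[2], vz = comp_files[3],
              sidecar = sidecar, phase_times = times))
}

#' Load a mask series aligned to a velocity field
#'
#' Reads an integer NIfTI label volume (3-D or 4-D; a 3-D single-phase mask
#' is broadcast to all phases with a message) and validates its codes
#' against [region_labels()].
#'
#' @param path Path to the label NIfTI.
#' @param field The `velocity_field` the mask indexes.
#' @return A [mask_series()].
#' @export
load_mask_series <- function(path, field) {
  if (!file.exists(path)) stop("missing mask file: ", path, call. = FALSE)
  a <- as.array(RNifti::readNifti(path))
  if (length(dim(a)) == 4) a <- aperm(a, c(4, 1, 2, 3))
  mask_series(a, field)
}

#' Save a mask series
#'
#' Writes the labels as an integer NIfTI (x, y, z, phase) plus a JSON label
#' dictionary beside it.
#'
#' @param masks A `mask_series`.
#' @param path Output NIfTI path (e.g. `masks.nii.gz`).
#' @return Invisibly, the written paths.
#' @export
save_mask_series <- function(masks, path) {
  stopifnot(inherits(masks, "mask_series"))
  vol <- aperm(unclass(masks), c(2, 3, 4, 1))
  img <- RNifti::asNifti(vol)
  img <- RNifti::`pixdim<-`(img, c(attr(masks, "spacing"), 1))
  RNifti::writeNifti(img, path, datatype = "uint8")
  dict <- sub("\\.nii(\\.gz)?$", "_labels.json", path)
  jsonlite::write_json(as.list(.REGION_LABELS), dict, auto_unbox = TRUE)
  invisible(c(labels = path, dictionary = dict))
}
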