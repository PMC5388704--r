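# End-to-end orchestration: synthesize or load a subject, preprocess,
# quantify KE and hemodynamics, assemble subject records and cohort tables.
# All randomness flows from the single config seed; identical config + seed
# give byte-identical numeric outputs.

.stage <- function(name, subject_id, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' [subject ", subject_id, "]: ",
         conditionMessage(e), call. = FALSE)
  })
}

#' Validate a subject run configuration
#'
#' A run config is a plain list (readable from JSON/YAML) with elements:
#' `subject` (either `list(source = "synthetic", ...)` with
#' [make_ventricle_phantom()] arguments, or `list(source = "files",
#' volumes, sidecar, masks)`), `preprocess` (optional:
#' `n_phases`, `sd_threshold`, `mean_threshold`, `skip_unwrap`,
#' `skip_eddy`, or `enabled = FALSE`), `rois` (region names to quantify),
#' `indexing` (subset of `"sv"`, `"bsa"`, `"ci"`), and `seed`. Validation
#' happens before any computation.
#'
#' @param config The configuration list.
#' @return The config, invisibly, with defaults filled in.
#' @export
validate_run_config <- function(config) {
  if (!is.list(config)) stop("config must be a list", call. = FALSE)
  if (is.null(config$subject) || is.null(config$subject$source))
    stop("config$subject$source is required ('synthetic' or 'files')",
         call. = FALSE)
  if (!config$subject$source %in% c("synthetic", "files"))
    stop("unknown subject source: ", config$subject$source, call. = FALSE)
  config$rois <- config$rois %||% "ventricle"
  unknown <- setdiff(config$rois, names(.REGION_LABELS))
  if (length(unknown))
    stop("unknown ROI(s) in config: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  config$indexing <- config$indexing %||% c("sv", "bsa", "ci")
  bad_idx <- setdiff(config$indexing, c("sv", "bsa", "ci"))
  if (length(bad_idx))
    stop("unknown indexing denominator(s): ", paste(bad_idx, collapse = ", "),
         call. = FALSE)
  config$preprocess <- config$preprocess %||% list()
  config$seed <- as.integer(config$seed %||% 1L)
  invisible(config)
}

# Measurement core shared by run_subject and run_cohort: volumes, KE curves,
# peaks, pattern and indexing for one subject already in memory.
.measure_subject <- function(field, masks, rois = "ventricle",
                             peak_opts = list()) {
  md <- field$metadata
  vc <- volume_curve(masks, bsa = md$bsa)
  lm <- find_cycle_landmarks(vc)
  co <- vc$sv * md$heart_rate / 1000
  ci <- if (is.finite(md$bsa) && md$bsa > 0) co / md$bsa else NA_real_

  curves <- list(); peaks <- NULL; pattern <- NA_character_
  indexed <- list()
  record <- list(subject_id = md$subject_id, group = md$group_label,
                 morphology = md$ventricular_morphology,
                 heart_rate = md$heart_rate, bsa = md$bsa,
                 edv = vc$edv, esv = vc$esv, sv = vc$sv, ef = vc$ef,
                 edvi = vc$edvi %||% NA_real_, esvi = vc$esvi %||% NA_real_,
                 co = co, ci = ci)
  for (roi in rois) {
    curve <- roi_ke_curve(field, masks, roi)
    curves[[roi]] <- curve
    if (roi == "ventricle") {
      peaks <- do.call(analyze_peaks, c(list(curve, lm), peak_opts))
      pattern <- classify_pattern(peaks)
      idx_sys <- index_ke(peaks$systolic_peak$value, sv = vc$sv,
                          bsa = if (is.finite(md$bsa)) md$bsa,
                          ci = if (is.finite(ci)) ci)
      idx_dia <- index_ke(peaks$diastolic_peak$value, sv = vc$sv,
                          bsa = if (is.finite(md$bsa)) md$bsa,
                          ci = if (is.finite(ci)) ci)
      indexed$ventricle <- list(systolic = idx_sys, diastolic = idx_dia)
      record <- c(record, list(
        pattern = pattern,
        peak_systolic_ke = peaks$systolic_peak$value,
        peak_diastolic_ke = peaks$diastolic_peak$value,
        peak_systolic_ke_sv = idx_sys$ke_per_sv %||% NA_real_,
        peak_diastolic_ke_sv = idx_dia$ke_per_sv %||% NA_real_,
        peak_systolic_ke_bsa = idx_sys$ke_per_bsa %||% NA_real_,
        peak_diastolic_ke_bsa = idx_dia$ke_per_bsa %||% NA_real_,
        peak_systolic_ke_ci = idx_sys$ke_per_ci %||% NA_real_,
        peak_diastolic_ke_ci = idx_dia$ke_per_ci %||% NA_real_,
        fused = peaks$fused, plateau = peaks$plateau$flag,
        mean_ke_ventricle = curve$mean_ke))
    } else {
      # vessel segments: mean KE indexed to the time-averaged segment volume
      vvol <- mean(volume_curve(masks, roi = roi)$volume_per_phase)
      idx <- index_ke(curve$mean_ke, vessel_volume = vvol)
      indexed[[roi]] <- idx
      rec_add <- list(curve$mean_ke, idx$ke_per_vessel_volume)
      names(rec_add) <- paste0(c("mean_ke_", "ke_per_vessel_volume_"), roi)
      record <- c(record, rec_add)
    }
  }
  list(record = as.data.frame(record, stringsAsFactors = FALSE),
       curves = curves, peaks = peaks, pattern = pattern, indexed = indexed,
       volume_curve = vc, landmarks = lm)
}

#' Run the full analysis for one subject
#'
#' Orchestrates: synthesize (or load) the 4D flow study, preprocess
#' (unwrap, eddy-correct, reconstruct), compute the ventricular volume
#' curve and cycle landmarks, the KE curve, peaks, pattern and indexings
#' for each requested ROI, and global hemodynamics. Deterministic given the
#' config seed. When `out_dir` is given, writes the resolved config, the
#' preprocessing report, per-ROI KE curve CSVs, a peaks/indexing JSON and
#' the subject record beside each other.
#'
#' @param config See [validate_run_config()].
#' @param out_dir Optional output directory.
#' @return List with `record` (one-row data frame), `curves`, `peaks`,
#'   `pattern`, `indexed`, `volume_curve`, `landmarks`,
#'   `preprocess_report`, `truth` (for synthetic subjects), `config`.
#' @export
run_subject <- function(config, out_dir = NULL) {
  config <- validate_run_config(config)
  sid <- config$subject$subject_id %||% "subject"
  set.seed(config$seed)

  if (config$subject$source == "synthetic") {
    args <- config$subject
    args$source <- NULL
    if (is.null(args$seed)) args$seed <- config$seed
    ph <- .stage("synthesize", sid, do.call(make_ventricle_phantom, args))
    field <- ph$field; masks <- ph$masks; truth <- ph$truth
  } else {
    field <- .stage("load", sid, load_flow_study(
      unlist(config$subject$volumes), config$subject$sidecar))
    masks <- .stage("load", sid, load_mask_series(config$subject$masks, field))
    truth <- NULL
  }
  sid <- field$metadata$subject_id

  pp <- config$preprocess
  if (!isFALSE(pp$enabled)) {
    res <- .stage("preprocess", sid, preprocess_flow(
      field, n_phases = pp$n_phases,
      sd_threshold = pp$sd_threshold, mean_threshold = pp$mean_threshold,
      skip_unwrap = isTRUE(pp$skip_unwrap),
      skip_eddy = isTRUE(pp$skip_eddy)))
    field <- res$field
    report <- res$report
    masks <- .stage("preprocess", sid, resample_mask_phases(masks, field))
  } else {
    report <- list(skipped = TRUE)
  }

  meas <- .stage("quantify", sid,
                 .measure_subject(field, masks, config$rois,
                                  config$peak_options %||% list()))
  out <- c(meas, list(preprocess_report = report, truth = truth,
                      config = config))
  if (!is.null(out_dir)) .stage("write", sid, .write_subject(out, out_dir))
  out
}

.report_for_json <- function(report) {
  if (!is.null(report$eddy_fit)) {
    fit <- report$eddy_fit
    report$eddy_fit <- list(coefficients = unclass(fit$coefficients),
                            residual_rms = fit$residual_rms,
                            n_static = fit$n_static)
  }
  report
}

.write_subject <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(out$config, file.path(out_dir, "config_resolved.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", force = TRUE)
  jsonlite::write_json(.report_for_json(out$preprocess_report),
                       file.path(out_dir, "preprocess_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", force = TRUE)
  for (roi in names(out$curves)) {
    cv <- out$curves[[roi]]
    write.csv(data.frame(phase_time_ms = cv$phase_times,
                         ke_mJ = cv$ke_per_phase),
              file.path(out_dir, paste0("ke_", roi, ".csv")),
              row.names = FALSE)
  }
  jsonlite::write_json(
    list(peaks = out$peaks, pattern = out$pattern, indexed = out$indexed),
    file.path(out_dir, "peaks_indexed.json"),
    auto_unbox = TRUE, digits = NA, null = "null", na = "null", force = TRUE)
  vc <- out$volume_curve
  jsonlite::write_json(
    list(edv_ml = vc$edv, esv_ml = vc$esv, sv_ml = vc$sv, ef_pct = vc$ef,
         edvi = vc$edvi, esvi = vc$esvi,
         co_l_min = out$record$co, ci_l_min_m2 = out$record$ci),
    file.path(out_dir, "hemodynamics.json"),
    auto_unbox = TRUE, digits = NA, null = "null", na = "null", force = TRUE)
  write.csv(out$record, file.path(out_dir, "record.csv"), row.names = FALSE)
  invisible(out_dir)
}

#' Run a cohort analysis
#'
#' Simulates (or assembles) a multi-subject cohort, runs the per-subject
#' measurement chain on each, and produces the subject-record table, the
#' group-by-morphology summary table, and the requested between-group
#' comparisons (suppressed below the minimum subgroup size). Subjects are
#' synthesized, measured and discarded one at a time, so memory stays flat
#' in cohort size.
#'
#' @param config List with either `cohort` (arguments for [cohort_spec()])
#'   or `subjects` (a list of per-subject configs for [run_subject()]),
#'   plus optional `metrics` (record columns to compare; default peak
#'   systolic and diastolic KE/SV), `groups`, `min_n` (default 5),
#'   `preprocess` (passed to each subject), `rois`, and `seed`.
#' @param out_dir Optional directory for `records.csv`,
#'   `cohort_table.csv`, `stats.json` and `manifest.json`.
#' @return List with `records`, `table`, `tests`, `params` (the generator
#'   draws, for synthetic cohorts), `manifest`.
#' @export
run_cohort <- function(config, out_dir = NULL) {
  seed <- as.integer(config$seed %||% 1L)
  metrics <- config$metrics %||% c("peak_systolic_ke_sv",
                                   "peak_diastolic_ke_sv")
  min_n <- config$min_n %||% 5
  rois <- config$rois %||% "ventricle"

  if (!is.null(config$cohort)) {
    spec <- do.call(cohort_spec, c(config$cohort, list(seed = seed)))
    params <- cohort_params(spec)
    records <- vector("list", nrow(params))
    for (i in seq_len(nrow(params))) {
      ph <- .build_cohort_subject(params[i, ], spec)
      sub_cfg <- list(subject = list(source = "synthetic"),
                      preprocess = config$preprocess %||% list(),
                      rois = rois, seed = params$seed[i])
      pp <- sub_cfg$preprocess
      field <- ph$field; masks <- ph$masks
      if (!isFALSE(pp$enabled)) {
        res <- preprocess_flow(field, n_phases = pp$n_phases,
                               sd_threshold = pp$sd_threshold,
                               mean_threshold = pp$mean_threshold,
                               skip_unwrap = isTRUE(pp$skip_unwrap),
                               skip_eddy = isTRUE(pp$skip_eddy))
        field <- res$field
        masks <- resample_mask_phases(masks, field)
      }
      meas <- .measure_subject(field, masks, rois)
      rec <- meas$record
      rec$true_sys_per_sv <- params$true_sys_per_sv[i]
      rec$true_dia_per_sv <- params$true_dia_per_sv[i]
      rec$true_pattern <- params$pattern[i]
      rec$apc_fraction <- params$apc_fraction[i]
      records[[i]] <- rec
    }
    records <- do.call(rbind, records)
  } else if (!is.null(config$subjects)) {
    params <- NULL
    records <- do.call(rbind, lapply(config$subjects, function(sc) {
      run_subject(c(list(subject = sc$subject %||% sc),
                    config[c("preprocess", "rois")],
                    list(seed = sc$seed %||% seed)))$record
    }))
  } else {
    stop("config needs either $cohort or $subjects", call. = FALSE)
  }

  tbl <- cohort_table(records)
  groups <- config$groups %||% unique(records$group)
  tests <- list()
  if (length(groups) >= 2) {
    for (m in metrics)
      tests[[m]] <- compare_groups(records, m, groups = groups[1:2],
                                   min_n = min_n)
  }
  manifest <- list(package = "flowke",
                   version = as.character(utils::packageVersion("flowke")),
                   seed = seed, n_subjects = nrow(records),
                   metrics = metrics, config = config)
  out <- list(records = records, table = tbl, tests = tests,
              params = params, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(records, file.path(out_dir, "records.csv"), row.names = FALSE)
    write.csv(tbl, file.path(out_dir, "cohort_table.csv"), row.names = FALSE)
    jsonlite::write_json(tests, file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null", force = TRUE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null", force = TRUE)
  }
  out
}
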