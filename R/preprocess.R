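# Corrections applied to raw velocity fields before any KE quantification:
# static-tissue detection, first-order eddy-current compensation, temporal
# phase unwrapping, and periodic reconstruction to the analysis phase count.
# Fixed order: unwrap -> eddy-correct -> reconstruct. The eddy fit assumes
# wrap-free static tissue, and interpolation assumes jump-free series.

#' Detect static (stationary) tissue
#'
#' Flags voxels whose velocity is both temporally stable and near zero on
#' average; these serve as the reference for the eddy-current fit. A voxel
#' is static iff the temporal standard deviation of each velocity component
#' is below `sd_threshold` and the magnitude of its temporal-mean velocity
#' vector is below `mean_threshold`.
#'
#' Defaults scale with the velocity-encoding limit: 5% of venc for the SD
#' threshold and 10% of venc for the mean threshold.
#'
#' @param field A `velocity_field`.
#' @param sd_threshold Per-component temporal SD threshold (cm/s);
#'   `NULL` = 0.05 * venc.
#' @param mean_threshold Temporal-mean speed threshold (cm/s);
#'   `NULL` = 0.10 * venc.
#' @return An object of class `static_tissue_mask`: list with `mask`
#'   (3-D logical), `n_static`, and the thresholds used.
#' @export
detect_static_tissue <- function(field, sd_threshold = NULL,
                                 mean_threshold = NULL) {
  stopifnot(inherits(field, "velocity_field"))
  venc <- field$metadata$venc
  sd_threshold <- sd_threshold %||% (0.05 * venc)
  mean_threshold <- mean_threshold %||% (0.10 * venc)
  d <- dim(field$values)
  np <- d[1]; nvox <- prod(d[2:4])
  m <- matrix(field$values, nrow = np)          # columns: voxel x component
  mu <- colMeans(m)
  sdv <- sqrt(pmax(colMeans(m^2) - mu^2, 0))    # population SD over phases
  sd_ok <- matrix(sdv < sd_threshold, nvox, 3)
  mu_mat <- matrix(mu, nvox, 3)
  mean_speed <- sqrt(rowSums(mu_mat^2))
  static <- sd_ok[, 1] & sd_ok[, 2] & sd_ok[, 3] & mean_speed < mean_threshold
  if (!any(static))
    stop("no static tissue found; relax sd_threshold (", sd_threshold,
         " cm/s) and/or mean_threshold (", mean_threshold, " cm/s)",
         call. = FALSE)
  structure(list(mask = array(static, d[2:4]), n_static = sum(static),
                 sd_threshold = sd_threshold,
                 mean_threshold = mean_threshold),
            class = "static_tissue_mask")
}

#' Compensate eddy-current velocity offsets
#'
#' Fits, per velocity component, a first-order spatial polynomial
#' (offset + linear terms in x, y, z) to the time-averaged velocity over
#' static-tissue voxels by least squares, and subtracts the fitted plane
#' from every phase. Least squares is exact for data in its model class, so
#' an injected plane on an otherwise zero field is recovered to numerical
#' precision and the post-correction static-tissue mean vanishes.
#'
#' Spatial gradients are expressed per mm (voxel-center coordinates,
#' 0-based index times spacing) so fits are spacing-invariant.
#'
#' @param field A `velocity_field`.
#' @param static A [detect_static_tissue()] result (needs >= 4 non-coplanar
#'   voxels).
#' @return List with `field` (corrected) and `fit` (class `eddy_fit`:
#'   3x4 coefficient matrix, per-component residual RMS over static voxels
#'   in cm/s, static voxel count).
#' @export
correct_eddy_currents <- function(field, static) {
  stopifnot(inherits(field, "velocity_field"),
            inherits(static, "static_tissue_mask"))
  d <- dim(field$values)
  grid <- d[2:4]; np <- d[1]
  sp <- field$metadata$voxel_spacing
  sel <- which(static$mask)
  if (length(sel) < 4)
    stop("need >= 4 static voxels for a first-order fit, got ", length(sel),
         call. = FALSE)
  co <- .coord_arrays(grid, sp, centered = FALSE)
  X <- co$X - 0.5 * sp[1]; Y <- co$Y - 0.5 * sp[2]; Z <- co$Z - 0.5 * sp[3]
  A <- cbind(1, X[sel], Y[sel], Z[sel])
  if (qr(A)$rank < 4)
    stop("static voxels are coplanar/degenerate; the first-order fit is ",
         "rank-deficient", call. = FALSE)
  coef <- matrix(NA_real_, 3, 4,
                 dimnames = list(c("vx", "vy", "vz"),
                                 c("offset", "gx", "gy", "gz")))
  rms <- numeric(3)
  for (k in 1:3) {
    comp_mean <- array(colMeans(matrix(field$values[, , , , k], nrow = np)),
                       grid)
    fitk <- lm.fit(A, comp_mean[sel])
    coef[k, ] <- fitk$coefficients
    rms[k] <- sqrt(mean(fitk$residuals^2))
    plane <- coef[k, 1] + coef[k, 2] * X + coef[k, 3] * Y + coef[k, 4] * Z
    for (p in seq_len(np))
      field$values[p, , , , k] <- field$values[p, , , , k] - plane
  }
  fit <- structure(list(coefficients = coef, residual_rms = rms,
                        n_static = length(sel)),
                   class = "eddy_fit")
  list(field = field, fit = fit)
}

#' @export
print.eddy_fit <- function(x, ...) {
  cat("<eddy_fit> first-order plane per component (cm/s, cm/s per mm):\n")
  print(round(x$coefficients, 6))
  cat("residual RMS (cm/s):", paste(signif(x$residual_rms, 4), collapse = ", "),
      "over", x$n_static, "static voxels\n")
  invisible(x)
}

#' Temporal phase unwrapping of aliased velocities
#'
#' Velocities beyond the encoding limit alias by multiples of 2*venc. For
#' each voxel and component the phases are walked in time order starting
#' from phase 1 (trusted as unwrapped); whenever the step to the next phase
#' exceeds venc in magnitude, a multiple of 2*venc is added to minimize the
#' step (temporal-continuity criterion). Unwrapped values may legitimately
#' exceed venc.
#'
#' @param field A `velocity_field` with venc set.
#' @return List with `field` (unwrapped) and `report`: list with `n_wraps`
#'   and a `sites` data frame (phase, x, y, z, component, shift in units of
#'   2*venc).
#' @export
unwrap_velocity <- function(field) {
  stopifnot(inherits(field, "velocity_field"))
  venc <- field$metadata$venc
  period <- 2 * venc
  v <- field$values
  d <- dim(v)
  np <- d[1]
  sites <- list()
  prev <- array(v[1, , , , ], dim = d[2:5])
  for (p in 2:np) {
    cur <- array(v[p, , , , ], dim = d[2:5])
    k <- round((cur - prev) / period)
    if (any(k != 0)) {
      idx <- which(k != 0, arr.ind = TRUE)
      sites[[length(sites) + 1]] <-
        data.frame(phase = p, x = idx[, 1], y = idx[, 2], z = idx[, 3],
                   component = idx[, 4], shift = -k[k != 0])
      cur <- cur - period * k
      v[p, , , , ] <- cur
    }
    prev <- cur
  }
  field$values <- v
  report <- if (length(sites)) {
    s <- do.call(rbind, sites)
    list(n_wraps = nrow(s), sites = s)
  } else {
    list(n_wraps = 0L,
         sites = cbind(.empty_wrap_sites(), shift = integer()))
  }
  list(field = field, report = report)
}

#' Reconstruct the cardiac cycle to a new phase count
#'
#' Periodic linear interpolation in normalized cycle time to `n_out`
#' uniformly spaced phases over the RR interval (the conventional
#' retrospective reconstruction target is 40). When the output grid aligns
#' with the input samples the operation is the identity; the cycle mean of
#' band-limited inputs is preserved to within the linear-interpolation
#' error bound.
#'
#' @param field A `velocity_field`.
#' @param n_out Output phase count (>= 2); `NULL` uses the metadata's
#'   `n_phases_reconstructed`.
#' @return A `velocity_field` with `n_out` phases and updated metadata.
#' @export
reconstruct_phases <- function(field, n_out = NULL) {
  stopifnot(inherits(field, "velocity_field"))
  n_out <- n_out %||% field$metadata$n_phases_reconstructed
  if (n_out < 2) stop("n_out must be >= 2", call. = FALSE)
  rr <- field$metadata$rr_interval
  t_in <- field$phase_times
  n_in <- length(t_in)
  t_out <- uniform_phase_times(n_out, rr)
  t_ext <- c(t_in, t_in[1] + rr)         # close the cycle periodically
  i0 <- findInterval(t_out, t_ext, rightmost.closed = TRUE)
  w <- (t_out - t_ext[i0]) / (t_ext[i0 + 1] - t_ext[i0])
  i1 <- ifelse(i0 == n_in, 1L, i0 + 1L)
  d <- dim(field$values)
  out <- array(0, dim = c(n_out, d[2:5]))
  for (j in seq_len(n_out)) {
    out[j, , , , ] <- if (w[j] == 0) field$values[i0[j], , , , ]
    else (1 - w[j]) * field$values[i0[j], , , , ] +
      w[j] * field$values[i1[j], , , , ]
  }
  md <- field$metadata
  md$n_phases_reconstructed <- as.integer(n_out)
  velocity_field(out, md, t_out)
}

#' Resample a mask series to a new phase count
#'
#' Nearest-phase resampling of the label volumes in normalized cycle time,
#' for pairing per-phase masks with a phase-reconstructed velocity field.
#' Labels are categorical, so nearest-neighbour (not linear) interpolation
#' is used.
#'
#' @param masks A `mask_series`.
#' @param field The reconstructed `velocity_field` supplying the target
#'   phase times and RR interval.
#' @param rr_interval RR interval (ms) of the cycle the masks sample;
#'   defaults to the field's.
#' @return A `mask_series` aligned to `field`.
#' @export
resample_mask_phases <- function(masks, field, rr_interval = NULL) {
  stopifnot(inherits(masks, "mask_series"), inherits(field, "velocity_field"))
  rr <- rr_interval %||% field$metadata$rr_interval
  n_in <- dim(masks)[1]
  t_in <- uniform_phase_times(n_in, rr)
  t_out <- field$phase_times
  # cyclic nearest input phase for each output time
  idx <- vapply(t_out, function(t) {
    d <- abs(t_in - t)
    which.min(pmin(d, rr - d))
  }, integer(1))
  mask_series(unclass(masks)[idx, , , , drop = FALSE], field)
}

#' Full preprocessing chain
#'
#' Applies, in fixed order: temporal phase unwrapping, eddy-current plane
#' subtraction (fit to auto-detected static tissue), and periodic phase
#' reconstruction. An already-clean field passes through unchanged (to
#' numerical precision) when `n_phases` equals its phase count.
#'
#' @param field A `velocity_field`.
#' @param n_phases Reconstruction target; `NULL` uses metadata (default 40).
#' @param sd_threshold,mean_threshold Passed to [detect_static_tissue()].
#' @param skip_unwrap,skip_eddy Disable individual stages.
#' @return List with `field` (processed) and `report` (static voxel count,
#'   `eddy_fit`, wrap count, thresholds, phase counts).
#' @export
preprocess_flow <- function(field, n_phases = NULL,
                            sd_threshold = NULL, mean_threshold = NULL,
                            skip_unwrap = FALSE, skip_eddy = FALSE) {
  stopifnot(inherits(field, "velocity_field"))
  report <- list(n_phases_in = dim(field$values)[1])
  if (!skip_unwrap) {
    uw <- unwrap_velocity(field)
    field <- uw$field
    report$wrap_count <- uw$report$n_wraps
  }
  if (!skip_eddy) {
    static <- detect_static_tissue(field, sd_threshold, mean_threshold)
    ec <- correct_eddy_currents(field, static)
    field <- ec$field
    report$static_voxels <- static$n_static
    report$sd_threshold <- static$sd_threshold
    report$mean_threshold <- static$mean_threshold
    report$eddy_fit <- ec$fit
  }
  field <- reconstruct_phases(field, n_phases)
  report$n_phases_out <- dim(field$values)[1]
  list(field = field, report = report)
}
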