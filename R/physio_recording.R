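# Multichannel physiological recordings: container, CSV dialect, imaging
# window extraction from MR gradient activity, and resampling.

#' Multichannel physiological recording
#'
#' Container for synchronized physiological channels sampled on a uniform
#' time grid, as produced by a hemodynamic recording system in the CMR
#' environment: one or more ECG leads (mV), left-ventricular pressure
#' (mmHg), optional aortic pressure (mmHg), and one or more MR
#' gradient-activity channels (arbitrary units).
#'
#' @param time Numeric vector of timestamps in seconds, strictly increasing
#'   with uniform spacing `1/sample_rate` (tolerance 1e-6 s).
#' @param ecg Numeric vector or matrix (one column per lead), millivolts.
#' @param lvp Numeric vector, left-ventricular pressure in mmHg.
#' @param sample_rate Sampling frequency in Hz.
#' @param aop Optional numeric vector, aortic pressure in mmHg.
#' @param gradient Optional numeric vector or matrix of MR gradient-activity
#'   channels (arbitrary units).
#' @param meta Named list of free-form annotations.
#' @return An object of class `physio_recording`.
#' @export
physio_recording <- function(time, ecg, lvp, sample_rate,
                             aop = NULL, gradient = NULL, meta = list()) {
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0)
    cmrpv_stop("argument_error", "sample_rate must be a single positive number")
  ecg <- as.matrix(ecg)
  if (!is.null(gradient)) gradient <- as.matrix(gradient)
  n <- length(time)
  lens <- c(nrow(ecg), length(lvp),
            if (!is.null(aop)) length(aop),
            if (!is.null(gradient)) nrow(gradient))
  if (any(lens != n))
    cmrpv_stop("format_error", "all channels must have the same length as time (%d)", n)
  if (n >= 2) {
    dt <- diff(time)
    if (any(dt <= 0) || max(abs(dt - 1 / sample_rate)) > 1e-6)
      cmrpv_stop("timing_error",
                 "timestamps must increase uniformly at 1/sample_rate (max deviation %.3g s)",
                 if (any(dt <= 0)) NA else max(abs(dt - 1 / sample_rate)))
  }
  structure(list(time = as.numeric(time), ecg = ecg, lvp = as.numeric(lvp),
                 aop = if (!is.null(aop)) as.numeric(aop), gradient = gradient,
                 sample_rate = sample_rate, meta = meta),
            class = "physio_recording")
}

#' @export
print.physio_recording <- function(x, ...) {
  cat(sprintf("physio_recording: %d samples at %g Hz (%.3f s)\n",
              length(x$time), x$sample_rate,
              x$time[length(x$time)] - x$time[1]))
  cat(sprintf("  channels: %d ECG lead(s), lvp%s%s\n", ncol(x$ecg),
              if (!is.null(x$aop)) ", aop" else "",
              if (!is.null(x$gradient))
                sprintf(", %d gradient axis/axes", ncol(x$gradient)) else ""))
  invisible(x)
}

#' @export
length.physio_recording <- function(x) length(x$time)

#' Closed time interval
#'
#' @param start,end Interval bounds in seconds, `end > start`.
#' @return An object of class `time_interval`.
#' @export
time_interval <- function(start, end) {
  if (!is.numeric(start) || !is.numeric(end) || end <= start)
    cmrpv_stop("argument_error", "time_interval requires end > start")
  structure(list(start = start, end = end), class = "time_interval")
}

# CSV dialect ------------------------------------------------------------

.csv_cols <- list(
  required = c("time_s", "ecg_i", "lvp_mmhg"),
  optional = c("ecg_ii", "aop_mmhg", "grad_x", "grad_y", "grad_z"))

#' Read a physiological recording from CSV
#'
#' The dialect is a UTF-8 CSV with header
#' `time_s,ecg_i,ecg_ii,lvp_mmhg,aop_mmhg,grad_x,grad_y,grad_z`
#' (`ecg_ii`, `aop_mmhg`, `grad_y`, `grad_z` optional), decimal point, one
#' row per sample. The sampling rate is inferred from the median timestamp
#' spacing; non-uniform spacing beyond 1e-6 s is rejected.
#'
#' @param path Path to a CSV file.
#' @return A [physio_recording()].
#' @export
read_recording <- function(path) {
  if (!file.exists(path))
    cmrpv_stop("format_error", "recording file not found: %s", path)
  df <- read.csv(path, check.names = FALSE)
  missing <- setdiff(.csv_cols$required, names(df))
  if (length(missing) > 0)
    cmrpv_stop("format_error", "missing required column(s): %s",
               paste(missing, collapse = ", "))
  tm <- df$time_s
  if (length(tm) < 2)
    cmrpv_stop("format_error", "recording must contain at least 2 samples")
  fs <- 1 / median(diff(tm))
  ecg <- as.matrix(df[, intersect(c("ecg_i", "ecg_ii"), names(df)), drop = FALSE])
  gcols <- intersect(c("grad_x", "grad_y", "grad_z"), names(df))
  physio_recording(
    time = tm, ecg = ecg, lvp = df$lvp_mmhg, sample_rate = fs,
    aop = if ("aop_mmhg" %in% names(df)) df$aop_mmhg,
    gradient = if (length(gcols) > 0) as.matrix(df[, gcols, drop = FALSE]),
    meta = list(path = path))
}

#' Write a physiological recording to CSV
#'
#' Emits the dialect documented in [read_recording()], 9 significant digits.
#'
#' @param rec A [physio_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "physio_recording"))
  df <- data.frame(time_s = rec$time)
  enames <- c("ecg_i", "ecg_ii")[seq_len(min(2, ncol(rec$ecg)))]
  for (j in seq_along(enames)) df[[enames[j]]] <- rec$ecg[, j]
  df$lvp_mmhg <- rec$lvp
  if (!is.null(rec$aop)) df$aop_mmhg <- rec$aop
  if (!is.null(rec$gradient)) {
    gnames <- c("grad_x", "grad_y", "grad_z")[seq_len(min(3, ncol(rec$gradient)))]
    for (j in seq_along(gnames)) df[[gnames[j]]] <- rec$gradient[, j]
  }
  df[] <- lapply(df, function(col) signif(col, 9))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Imaging window ---------------------------------------------------------

#' Detect the image-acquisition window from MR gradient activity
#'
#' The recorded gradient waveforms act as a temporal fiducial for the
#' interval in which imaging (and hence the volume measurement) took place.
#' Gradient axes are combined by root-sum-of-squares, enveloped by a sliding
#' RMS (50 ms window), and thresholded at `threshold_frac` of the envelope
#' maximum. Sub-threshold gaps shorter than `min_gap` (sequence dead times)
#' are merged. Window edges are then refined to the first/last raw sample
#' whose combined gradient magnitude exceeds the same threshold.
#'
#' @param rec A [physio_recording()] with a gradient channel.
#' @param threshold_frac Detection threshold as a fraction of the envelope
#'   maximum, in (0, 1). Default 0.1.
#' @param min_gap Maximum sub-threshold gap (s) merged into the window.
#'   Default 0.2.
#' @param rms_window RMS envelope window length in seconds. Default 0.05.
#' @return A [time_interval()].
#' @export
detect_imaging_window <- function(rec, threshold_frac = 0.1, min_gap = 0.2,
                                  rms_window = 0.05) {
  stopifnot(inherits(rec, "physio_recording"))
  if (is.null(rec$gradient))
    cmrpv_stop("no_window_error", "recording has no gradient channel")
  if (threshold_frac <= 0 || threshold_frac >= 1)
    cmrpv_stop("argument_error", "threshold_frac must be in (0, 1)")
  g2 <- rowSums(rec$gradient^2)
  w <- max(1L, round(rms_window * rec$sample_rate))
  env <- sqrt(pmax(as.numeric(zoo::rollmean(zoo::zoo(g2), w, fill = 0,
                                            align = "center")), 0))
  emax <- max(env)
  if (emax <= 0)
    cmrpv_stop("no_window_error", "gradient envelope never exceeds threshold")
  above <- env > threshold_frac * emax
  if (!any(above))
    cmrpv_stop("no_window_error", "gradient envelope never exceeds threshold")
  idx <- which(above)
  # merge gaps shorter than min_gap
  gaps <- which(diff(idx) > 1)
  runs <- cbind(start = idx[c(1, gaps + 1)], end = idx[c(gaps, length(idx))])
  if (nrow(runs) > 1) {
    keep <- rep(TRUE, nrow(runs))
    for (i in seq_len(nrow(runs) - 1)) {
      gap_s <- (runs[i + 1, "start"] - runs[i, "end"]) / rec$sample_rate
      if (gap_s < min_gap) {
        runs[i + 1, "start"] <- runs[i, "start"]
        keep[i] <- FALSE
      }
    }
    runs <- runs[keep, , drop = FALSE]
  }
  # take the longest merged run
  len <- runs[, "end"] - runs[, "start"]
  r <- runs[which.max(len), ]
  # refine edges on the raw magnitude (the RMS envelope leaks half a window
  # outside the burst)
  gmag <- sqrt(g2)
  thr <- threshold_frac * max(gmag)
  lo <- r["start"]; hi <- r["end"]
  cand <- which(gmag > thr)
  cand <- cand[cand >= max(1, lo - w) & cand <= min(length(gmag), hi + w)]
  if (length(cand) > 0) { lo <- min(cand); hi <- max(cand) }
  if (hi <= lo)
    cmrpv_stop("no_window_error", "degenerate imaging window")
  time_interval(rec$time[lo], rec$time[hi])
}

#' Crop a recording to a time interval
#'
#' All channels are cropped to the closed interval; the sampling rate is
#' unchanged.
#'
#' @param rec A [physio_recording()].
#' @param win A [time_interval()] inside the recording's time range.
#' @return A cropped [physio_recording()].
#' @export
extract_window <- function(rec, win) {
  stopifnot(inherits(rec, "physio_recording"), inherits(win, "time_interval"))
  tol <- 0.5 / rec$sample_rate
  if (win$start < rec$time[1] - tol ||
      win$end > rec$time[length(rec$time)] + tol)
    cmrpv_stop("bounds_error",
               "window [%.3f, %.3f] outside recording range [%.3f, %.3f]",
               win$start, win$end, rec$time[1], rec$time[length(rec$time)])
  keep <- rec$time >= win$start - 1e-9 & rec$time <= win$end + 1e-9
  physio_recording(
    time = rec$time[keep], ecg = rec$ecg[keep, , drop = FALSE],
    lvp = rec$lvp[keep], sample_rate = rec$sample_rate,
    aop = if (!is.null(rec$aop)) rec$aop[keep],
    gradient = if (!is.null(rec$gradient)) rec$gradient[keep, , drop = FALSE],
    meta = rec$meta)
}

#' Downsample a recording by an integer factor
#'
#' Applies a zero-phase anti-alias low-pass (4th-order Butterworth at 0.8 x
#' the output Nyquist frequency, forward-backward) to every channel before
#' decimation, so fiducial timing is preserved.
#'
#' @param rec A [physio_recording()].
#' @param factor Positive integer decimation factor.
#' @return A [physio_recording()] at `sample_rate / factor`.
#' @export
downsample <- function(rec, factor) {
  stopifnot(inherits(rec, "physio_recording"))
  if (!is.numeric(factor) || length(factor) != 1 || factor < 1 ||
      abs(factor - round(factor)) > 1e-9)
    cmrpv_stop("argument_error", "factor must be a positive integer")
  factor <- as.integer(round(factor))
  if (factor == 1L) return(rec)
  if (length(rec$time) < factor)
    cmrpv_stop("argument_error", "recording shorter than decimation factor")
  bf <- signal::butter(4, 0.8 / factor)
  # filter around the channel mean so DC passes exactly and edge
  # transients stay small
  lp <- function(x) mean(x) + signal::filtfilt(bf, x - mean(x))
  keep <- seq(1L, length(rec$time), by = factor)
  physio_recording(
    time = rec$time[keep],
    ecg = apply(rec$ecg, 2, lp)[keep, , drop = FALSE],
    lvp = lp(rec$lvp)[keep],
    sample_rate = rec$sample_rate / factor,
    aop = if (!is.null(rec$aop)) lp(rec$aop)[keep],
    gradient = if (!is.null(rec$gradient))
      apply(rec$gradient, 2, lp)[keep, , drop = FALSE],
    meta = rec$meta)
}
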