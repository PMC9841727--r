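# Per-beat fiducials on the pressure side: end-diastole from ECG R-peaks,
# end-systole from the LV pressure waveform, and occlusion-onset detection.

#' Detect ECG R-peaks
#'
#' Band-passes the dominant lead at 5-25 Hz (zero-phase), squares it, and
#' thresholds at 0.4 x a rolling 2 s maximum with a refractory period.
#' Candidate peaks are refined to the local maximum of the raw lead within
#' +/- 40 ms, so the reported time is the R-wave apex.
#'
#' @param ecg Numeric vector, one ECG lead (mV).
#' @param sample_rate Sampling rate in Hz.
#' @param refractory Minimum gap between detections in seconds. Default 0.2.
#' @param time Optional timestamps; defaults to seconds from the first sample.
#' @return Strictly increasing numeric vector of R-peak times (s).
#' @export
detect_r_peaks <- function(ecg, sample_rate, refractory = 0.2, time = NULL) {
  if (length(ecg) < sample_rate)
    cmrpv_stop("detection_error", "need at least 1 s of ECG")
  if (refractory <= 0)
    cmrpv_stop("argument_error", "refractory must be positive")
  if (is.null(time)) time <- (seq_along(ecg) - 1) / sample_rate
  bf <- signal::butter(2, c(5, 25) / (sample_rate / 2), type = "pass")
  f <- signal::filtfilt(bf, ecg - mean(ecg))
  sq <- f^2
  w <- max(3L, round(2 * sample_rate))
  if (w < length(sq)) {
    roll <- zoo::rollmax(zoo::zoo(sq), w, fill = NA, align = "center")
    roll <- as.numeric(zoo::na.fill(roll, "extend"))
  } else {
    roll <- rep(max(sq), length(sq))
  }
  thr <- 0.4 * roll
  above <- sq > thr & sq > 1e-12
  if (!any(above))
    cmrpv_stop("detection_error", "no QRS candidates above threshold")
  idx <- which(above)
  gaps <- which(diff(idx) > 1)
  starts <- idx[c(1, gaps + 1)]; ends <- idx[c(gaps, length(idx))]
  cand <- mapply(function(s, e) s + which.max(sq[s:e]) - 1L, starts, ends)
  # refine to raw-signal local maximum (R apex)
  half <- round(0.04 * sample_rate)
  cand <- vapply(cand, function(i) {
    lo <- max(1, i - half); hi <- min(length(ecg), i + half)
    as.integer(lo + which.max(ecg[lo:hi]) - 1)
  }, integer(1))
  cand <- sort(unique(cand))
  # enforce refractory period, keeping the larger raw peak
  keep <- integer(0)
  for (i in cand) {
    if (length(keep) == 0 || time[i] - time[keep[length(keep)]] >= refractory) {
      keep <- c(keep, i)
    } else if (ecg[i] > ecg[keep[length(keep)]]) {
      keep[length(keep)] <- i
    }
  }
  if (length(keep) == 0)
    cmrpv_stop("detection_error", "no R-peaks found")
  time[keep]
}

#' Detect end-systole from the LV pressure waveform
#'
#' End-systole is taken at the onset of isovolumic relaxation. Within each
#' beat (excluding the first 100 ms after end-diastole), the smoothed
#' pressure derivative dP/dt (central differences, zero-phase 25 ms moving
#' average) is scanned for its minimum; the detection is then backtracked to
#' the earliest contiguous sample at or below `onset_frac` x that minimum,
#' i.e. the onset of the relaxation dip rather than its middle.
#'
#' @param lvp Numeric vector, LV pressure (mmHg).
#' @param sample_rate Sampling rate in Hz.
#' @param ed_times End-diastolic (R-peak) times in seconds, length >= 2.
#' @param time Optional timestamps; defaults to seconds from first sample.
#' @param smooth_ms Moving-average width for dP/dt smoothing (ms). Default 25.
#' @param onset_frac Backtracking threshold as a fraction of the dP/dt
#'   minimum. Default 0.5.
#' @return List with `es_times` (one per complete beat, `NA` for rejected
#'   beats) and logical `flag` marking rejected beats.
#' @export
detect_es_pressure <- function(lvp, sample_rate, ed_times, time = NULL,
                               smooth_ms = 25, onset_frac = 0.5) {
  if (length(ed_times) < 2)
    cmrpv_stop("argument_error", "need at least 2 end-diastolic times")
  if (is.null(time)) time <- (seq_along(lvp) - 1) / sample_rate
  dP <- c(NA, (lvp[-(1:2)] - lvp[seq_len(length(lvp) - 2)]) * sample_rate / 2, NA)
  w <- max(1L, round(smooth_ms / 1000 * sample_rate))
  if (w %% 2 == 0) w <- w + 1L
  sdv <- as.numeric(stats::filter(dP, rep(1 / w, w), sides = 2))
  nb <- length(ed_times) - 1
  es <- rep(NA_real_, nb)
  flag <- rep(FALSE, nb)
  for (k in seq_len(nb)) {
    if (ed_times[k + 1] - ed_times[k] < 0.2) {
      flag[k] <- TRUE
      cmrpv_warn("short_beat", "beat %d shorter than 0.2 s rejected", k)
      next
    }
    win <- which(time > ed_times[k] + 0.1 & time < ed_times[k + 1] & !is.na(sdv))
    if (length(win) < 3) {
      flag[k] <- TRUE
      cmrpv_warn("short_beat", "beat %d window too short for ES detection", k)
      next
    }
    m <- min(sdv[win])
    if (m >= 0) {
      flag[k] <- TRUE
      cmrpv_warn("no_relaxation", "beat %d has no pressure decay; flagged", k)
      next
    }
    i <- i0 <- win[which.min(sdv[win])]
    thr <- onset_frac * m
    while (i > win[1] && !is.na(sdv[i - 1]) && sdv[i - 1] <= thr) i <- i - 1
    es[k] <- time[i]
  }
  list(es_times = es, flag = flag)
}

#' Pressure-side fiducials and per-beat table
#'
#' Populates end-diastolic detections (ECG R-peaks) onto the simultaneously
#' sampled LV pressure signal, detects end-systole per beat, and tabulates
#' per-beat pressures and intervals.
#'
#' @param rec A [physio_recording()] with ECG and LV pressure channels.
#' @param exclude Integer vector of beat numbers to flag manually (kept in
#'   the table, excluded from downstream fitting).
#' @param ... Passed to [detect_es_pressure()].
#' @return List with `fiducials` (class `fiducial_set`: `ed_times`,
#'   `es_times`, `source = "pressure"`) and `beats` (class `beat_table`,
#'   a data frame with columns `beat`, `ed_start_s`, `es_s`, `ed_end_s`,
#'   `peak_lvp_mmhg`, `edp_mmhg`, `esp_mmhg`, `rr_s`, `flag`).
#' @export
populate_pressure_fiducials <- function(rec, exclude = integer(0), ...) {
  stopifnot(inherits(rec, "physio_recording"))
  ed <- detect_r_peaks(rec$ecg[, 1], rec$sample_rate, time = rec$time)
  if (length(ed) < 4)
    cmrpv_stop("insufficient_data_error",
               "fewer than 3 complete beats detected (%d R-peaks)", length(ed))
  esr <- detect_es_pressure(rec$lvp, rec$sample_rate, ed, time = rec$time, ...)
  nb <- length(ed) - 1
  at <- function(tq) approx(rec$time, rec$lvp, tq)$y
  peak <- vapply(seq_len(nb), function(k) {
    max(rec$lvp[rec$time >= ed[k] & rec$time < ed[k + 1]])
  }, numeric(1))
  beats <- data.frame(
    beat = seq_len(nb),
    ed_start_s = ed[seq_len(nb)],
    es_s = esr$es_times,
    ed_end_s = ed[-1],
    peak_lvp_mmhg = peak,
    edp_mmhg = at(ed[seq_len(nb)]),
    esp_mmhg = ifelse(is.na(esr$es_times), NA, at(esr$es_times)),
    rr_s = diff(ed),
    flag = esr$flag | seq_len(nb) %in% exclude)
  class(beats) <- c("beat_table", "data.frame")
  fids <- structure(list(ed_times = ed, es_times = esr$es_times,
                         source = "pressure"),
                    class = "fiducial_set")
  list(fiducials = fids, beats = beats)
}

#' Export a beat table to CSV
#'
#' @param beats A `beat_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_beat_table <- function(beats, path) {
  write.csv(as.data.frame(beats), path, row.names = FALSE)
  invisible(path)
}

#' Locate the first post-occlusion beat
#'
#' With a configured occlusion time, returns the first beat starting at or
#' after it. Otherwise auto-detects the onset as the first beat whose peak
#' LV pressure falls below the baseline mean minus 2 baseline standard
#' deviations (baseline = first 3 beats).
#'
#' @param beats A `beat_table` from [populate_pressure_fiducials()].
#' @param config_time Optional occlusion timestamp (s).
#' @return Integer beat index.
#' @export
find_occlusion_onset <- function(beats, config_time = NULL) {
  if (nrow(beats) < 12)
    cmrpv_stop("insufficient_data_error",
               "need at least 12 beats to locate the occlusion onset")
  if (!is.null(config_time)) {
    i <- which(beats$ed_start_s >= config_time)
    if (length(i) == 0)
      cmrpv_stop("onset_not_found_error",
                 "no beat starts at or after configured time %.2f s", config_time)
    return(i[1])
  }
  base <- beats$peak_lvp_mmhg[1:3]
  thr <- mean(base) - 2 * sd(base)
  i <- which(beats$peak_lvp_mmhg < thr)
  i <- i[i > 3]
  if (length(i) == 0)
    cmrpv_stop("onset_not_found_error",
               paste("no beat falls below the baseline threshold;",
                     "configure the occlusion time manually"))
  i[1]
}
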