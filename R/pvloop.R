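# Pair pressure and volume into per-beat PV loops, fit ESPVR/EDPVR, and
# compute hemodynamic summaries and occlusion-response metrics.

#' Pair pressure and volume into per-beat PV loops
#'
#' Checks that the same number of heartbeats was detected independently in
#' the pressure and volume signals over the common analysis window, then,
#' for each analysis beat, warps the volume timeline piecewise-linearly so
#' that its ED/ES/next-ED fiducials coincide with the pressure fiducials,
#' and interpolates volume onto the (finer) pressure time grid.
#'
#' @param pressure_fids `fiducial_set` from [populate_pressure_fiducials()].
#' @param beats The matching `beat_table`.
#' @param lvp,time,sample_rate The pressure series and its time grid (the
#'   250 Hz down-sampled signal).
#' @param volume_fids A [detect_ed_es_volume()] result.
#' @param volume A [volume_series()] (native frame resolution; it is
#'   up-sampled internally to the pressure rate).
#' @param onset First analysis beat (index into `beats`), e.g. from
#'   [find_occlusion_onset()].
#' @param n_beats Number of beats to include (>= 3). Default 10. Flagged
#'   beats are skipped and later beats pulled in, up to availability.
#' @param hr_drift_warn Warn if heart rate rises by more than this fraction
#'   across the included beats. Default 0.05.
#' @return Object of class `pv_loopset`: per-beat data frames of paired
#'   `(time, volume, pressure)` on the pressure grid, `ed_points` /
#'   `es_points` matrices (V ml, P mmHg), and `n_beats`.
#' @export
pair_pv <- function(pressure_fids, beats, lvp, time, sample_rate,
                    volume_fids, volume, onset, n_beats = 10,
                    hr_drift_warn = 0.05) {
  stopifnot(inherits(pressure_fids, "fiducial_set"),
            inherits(volume_fids, "volume_fiducials"),
            inherits(volume, "volume_series"))
  if (n_beats < 3)
    cmrpv_stop("argument_error", "n_beats must be >= 3")
  edP <- pressure_fids$ed_times
  esP <- pressure_fids$es_times
  edV_t <- volume$frame_times[volume_fids$ed_indices]
  esV_t <- volume$frame_times[volume_fids$es_indices]
  # beat-count consistency over the common window
  nP <- length(edP); nV <- length(edV_t)
  if (nP != nV)
    cmrpv_stop("pairing_error",
               "beat-count mismatch: %d pressure vs %d volume beats", nP, nV)
  if (max(abs(edV_t - edP)) > 0.5 * median(diff(edP)))
    cmrpv_stop("pairing_error",
               "pressure and volume end-diastolic detections do not align")
  # smoothed volume on the pressure grid
  vs <- volume_series(volume$frame_times, volume_fids$smoothed)
  vu <- upsample_volume(vs, sample_rate)
  v_at <- function(tq) approx(vu$frame_times, vu$volumes, tq, rule = 2)$y
  p_at <- function(tq) approx(time, lvp, tq)$y
  usable <- which(!beats$flag & seq_len(nrow(beats)) >= onset)
  usable <- usable[!is.na(esP[usable])]
  if (length(usable) < 3)
    cmrpv_stop("insufficient_data_error",
               "fewer than 3 usable beats from onset %d", onset)
  ks <- head(usable, n_beats)
  hr_first <- 1 / beats$rr_s[ks[1]]; hr_last <- 1 / beats$rr_s[ks[length(ks)]]
  if ((hr_last - hr_first) / hr_first > hr_drift_warn)
    cmrpv_warn("hr_drift",
               "heart rate rises %.1f%% across included beats; inotropy may be altered",
               100 * (hr_last - hr_first) / hr_first)
  loops <- lapply(ks, function(k) {
    anchors_p <- c(edP[k], esP[k], edP[k + 1])
    anchors_v <- c(edV_t[k], esV_t[k], edV_t[k + 1])
    tp <- time[time >= anchors_p[1] & time <= anchors_p[3]]
    tv <- approx(anchors_p, anchors_v, tp)$y  # piecewise-linear time warp
    data.frame(time = tp, volume = v_at(tv), pressure = p_at(tp))
  })
  ed_pts <- cbind(v = v_at(edV_t[ks]), p = p_at(edP[ks]))
  es_pts <- cbind(v = v_at(esV_t[ks]), p = p_at(esP[ks]))
  structure(list(beats = loops, beat_index = ks,
                 ed_points = ed_pts, es_points = es_pts,
                 n_beats = length(ks)),
            class = "pv_loopset")
}

#' @export
print.pv_loopset <- function(x, ...) {
  cat(sprintf("pv_loopset: %d beats, EDV %.1f-%.1f ml, ESV %.1f-%.1f ml\n",
              x$n_beats, min(x$ed_points[, "v"]), max(x$ed_points[, "v"]),
              min(x$es_points[, "v"]), max(x$es_points[, "v"])))
  invisible(x)
}

# shared OLS core for the two PV relationships
.pvr_ols <- function(pts, kind) {
  if (nrow(pts) < 3)
    cmrpv_stop("insufficient_points_error",
               "%s fit needs >= 3 points (%d given)", kind, nrow(pts))
  v <- pts[, 1]; p <- pts[, 2]
  if (var(v) == 0)
    cmrpv_stop("degenerate_fit_error", "zero volume variance in %s fit", kind)
  fit <- lm(p ~ v)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  ss_res <- sum(fit$residuals^2); ss_tot <- sum((p - mean(p))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  structure(list(slope = slope, intercept = intercept,
                 v0 = if (slope > 0) -intercept / slope else NA_real_,
                 r2 = r2, n_points = nrow(pts), kind = kind,
                 derived_metric = NA_real_),
            class = "pvr_fit")
}

#' Fit the end-systolic pressure-volume relationship (ESPVR)
#'
#' Ordinary least squares of end-systolic pressure on end-systolic volume.
#' The slope is the contractility index (end-systolic elastance, mmHg/ml);
#' `v0` is the volume-axis intercept.
#'
#' @param es_points Matrix/data frame of (V ml, P mmHg) end-systolic points.
#' @return A `pvr_fit` with `kind = "espvr"` and
#'   `derived_metric` = contractility (mmHg/ml).
#' @export
fit_espvr <- function(es_points) {
  fit <- .pvr_ols(as.matrix(es_points), "espvr")
  fit$derived_metric <- fit$slope
  fit
}

#' Fit the end-diastolic pressure-volume relationship (EDPVR)
#'
#' Ordinary least squares of end-diastolic pressure on end-diastolic
#' volume; compliance is the inverse slope (ml/mmHg). A non-positive slope
#' is reported as an error, never silently clamped.
#'
#' @param ed_points Matrix/data frame of (V ml, P mmHg) end-diastolic points.
#' @return A `pvr_fit` with `kind = "edpvr"` and
#'   `derived_metric` = compliance (ml/mmHg).
#' @export
fit_edpvr <- function(ed_points) {
  fit <- .pvr_ols(as.matrix(ed_points), "edpvr")
  if (fit$slope <= 0)
    cmrpv_stop("non_physiological_fit_error",
               "EDPVR slope %.3g <= 0; compliance undefined", fit$slope)
  fit$derived_metric <- 1 / fit$slope
  fit
}

#' @export
print.pvr_fit <- function(x, ...) {
  lab <- if (x$kind == "espvr") "contractility" else "compliance"
  unit <- if (x$kind == "espvr") "mmHg/ml" else "ml/mmHg"
  cat(sprintf("%s fit: slope %.3f mmHg/ml, intercept %.2f mmHg, r2 %.4f (n = %d)\n",
              toupper(x$kind), x$slope, x$intercept, x$r2, x$n_points))
  cat(sprintf("  %s = %.3f %s%s\n", lab, x$derived_metric, unit,
              if (!is.na(x$v0)) sprintf(", V0 = %.1f ml", x$v0) else ""))
  invisible(x)
}

#' Hemodynamic summary of one beat
#'
#' @param edv,esv End-diastolic and end-systolic volume (ml), e.g. from the
#'   paired loop's fiducial points.
#' @param beat_row One row of a `beat_table` supplying the pressures and RR
#'   interval of the same beat.
#' @return Object of class `hemo_summary` with `edv`, `esv`, `sv` (ml),
#'   `ef` (%), `hr` (bpm), `co` (l/min), `edp`, `esp`, `peak_lvp` (mmHg).
#' @export
hemodynamic_summary <- function(edv, esv, beat_row) {
  if (any(is.na(c(edv, esv, beat_row$rr_s, beat_row$edp_mmhg,
                  beat_row$esp_mmhg, beat_row$peak_lvp_mmhg))))
    cmrpv_stop("incomplete_beat_error", "beat is missing a fiducial")
  sv <- edv - esv
  hr <- 60 / beat_row$rr_s
  structure(list(edv = edv, esv = esv, sv = sv,
                 ef = 100 * sv / edv, hr = hr, co = sv * hr / 1000,
                 edp = beat_row$edp_mmhg, esp = beat_row$esp_mmhg,
                 peak_lvp = beat_row$peak_lvp_mmhg),
            class = "hemo_summary")
}

#' @export
print.hemo_summary <- function(x, ...) {
  cat(sprintf("EDV %.1f ml  ESV %.1f ml  SV %.1f ml  EF %.1f%%  HR %.0f bpm  CO %.2f l/min\n",
              x$edv, x$esv, x$sv, x$ef, x$hr, x$co))
  cat(sprintf("EDP %.1f  ESP %.1f  peak LVP %.1f mmHg\n", x$edp, x$esp, x$peak_lvp))
  invisible(x)
}

#' Occlusion response metrics
#'
#' Percent changes from the first to the last included beat: reductions in
#' peak systolic LV pressure and end-systolic volume
#' (\eqn{100 (x_{first} - x_{last}) / x_{first}}), and the heart-rate
#' increase (sign-flipped).
#'
#' @param loops A [pair_pv()] loop set.
#' @param beats The `beat_table` the loops were built from.
#' @return Named list: `peak_lvp_reduction_pct`, `esv_reduction_pct`,
#'   `hr_increase_pct`.
#' @export
occlusion_response <- function(loops, beats) {
  stopifnot(inherits(loops, "pv_loopset"))
  if (loops$n_beats < 2)
    cmrpv_stop("argument_error", "need at least 2 loops")
  k1 <- loops$beat_index[1]; k2 <- loops$beat_index[loops$n_beats]
  red <- function(a, b) 100 * (a - b) / a
  list(peak_lvp_reduction_pct = red(beats$peak_lvp_mmhg[k1], beats$peak_lvp_mmhg[k2]),
       esv_reduction_pct = unname(red(loops$es_points[1, "v"],
                                      loops$es_points[loops$n_beats, "v"])),
       hr_increase_pct = -red(60 / beats$rr_s[k1], 60 / beats$rr_s[k2]))
}

#' Plot PV loops with fitted ESPVR and EDPVR lines
#'
#' @param x A `pv_loopset`.
#' @param espvr,edpvr Optional `pvr_fit` objects to overlay.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pv_loopset <- function(x, espvr = NULL, edpvr = NULL, ...) {
  vr <- range(vapply(x$beats, function(b) range(b$volume), numeric(2)))
  pr <- range(vapply(x$beats, function(b) range(b$pressure), numeric(2)))
  plot(NA, xlim = vr, ylim = pr, xlab = "LV volume (ml)",
       ylab = "LV pressure (mmHg)", main = "Dynamic PV loops", ...)
  for (b in x$beats) lines(b$volume, b$pressure, col = "grey25")
  points(x$es_points, col = "blue", pch = 16)
  points(x$ed_points, col = "red", pch = 16)
  if (!is.null(espvr)) abline(espvr$intercept, espvr$slope, col = "blue", lwd = 2)
  if (!is.null(edpvr)) abline(edpvr$intercept, edpvr$slope, col = "red", lwd = 2)
  legend("topleft", bty = "n", pch = c(16, 16), col = c("blue", "red"),
         legend = c("end-systole (ESPVR)", "end-diastole (EDPVR)"))
  invisible(x)
}

#' Export per-beat fiducial PV points to CSV
#'
#' @param loops A `pv_loopset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pv_points <- function(loops, path) {
  df <- data.frame(beat = loops$beat_index,
                   edv_ml = loops$ed_points[, "v"],
                   edp_mmhg = loops$ed_points[, "p"],
                   esv_ml = loops$es_points[, "v"],
                   esp_mmhg = loops$es_points[, "p"])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
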