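# Lumped-parameter cardiovascular simulator: time-varying elastance LV with
# diode valves and a windkessel afterload, IVC-occlusion preload decay with
# balloon deflation, and renderers for pressure/ECG/gradient recordings and
# contour sequences realizing a prescribed volume trace.

#' Simulator parameters
#'
#' Ground-truth parameters of the time-varying elastance model
#' \eqn{P_{LV}(t) = E(t)\,(V(t) - V_0)} with
#' \eqn{E(t) = E_{min} + (E_{max} - E_{min})\,\hat e(t)}. The normalized
#' activation \eqn{\hat e} rises as a raised cosine from 0 to 1 over the
#' systolic interval (`t_peak_frac` of the beat period) and relaxes
#' exponentially with time constant `tau_r`, so that peak elastance
#' coincides with the onset of isovolumic relaxation. Filling and ejection
#' are resistive diode valves; the arterial side is a single-compartment
#' windkessel. Venous (preload) pressure is constant before the occlusion
#' time, decays exponentially during the occlusion, and recovers after
#' balloon deflation.
#'
#' @param emax End-systolic elastance, mmHg/ml (true ESPVR slope).
#' @param emin Passive stiffness, mmHg/ml (true compliance = 1/emin).
#' @param v0 Unstressed volume, ml.
#' @param hr Heart rate, bpm.
#' @param t_peak_frac Fraction of the beat period at which elastance peaks.
#' @param tau_r Relaxation time constant, s.
#' @param r_mv,r_av Mitral/aortic valve resistances, mmHg s/ml.
#' @param r_per Peripheral resistance, mmHg s/ml.
#' @param c_ao Arterial compliance, ml/mmHg.
#' @param p_ven0 Baseline venous pressure, mmHg.
#' @param t_occ Occlusion (balloon inflation) time, s.
#' @param tau_occ Preload decay time constant during occlusion, s.
#' @param t_defl Balloon deflation time, s (default `t_occ + 15`).
#' @param tau_rec Venous pressure recovery time constant after deflation, s.
#' @param noise_p Pressure measurement noise SD, mmHg.
#' @param noise_v Volume measurement noise SD, ml.
#' @param seed Random seed used by the renderers.
#' @return Object of class `elastance_params`.
#' @export
elastance_params <- function(emax = 0.6, emin = 0.2, v0 = 10, hr = 77,
                             t_peak_frac = 0.3, tau_r = 0.04,
                             r_mv = 0.05, r_av = 0.01, r_per = 0.55,
                             c_ao = 3, p_ven0 = 22,
                             t_occ = 7, tau_occ = 15,
                             t_defl = t_occ + 15, tau_rec = 2,
                             noise_p = 1, noise_v = 2, seed = 1L) {
  p <- as.list(environment())
  if (!(emax > emin && emin > 0))
    cmrpv_stop("configuration_error", "need emax > emin > 0")
  pos <- c("hr", "tau_r", "r_mv", "r_av", "r_per", "c_ao", "tau_occ", "tau_rec")
  for (nm in pos) if (p[[nm]] <= 0)
    cmrpv_stop("configuration_error", "%s must be positive", nm)
  if (t_peak_frac <= 0 || t_peak_frac >= 1)
    cmrpv_stop("configuration_error", "t_peak_frac must be in (0, 1)")
  if (noise_p < 0 || noise_v < 0)
    cmrpv_stop("configuration_error", "noise SDs must be non-negative")
  structure(p, class = "elastance_params")
}

# normalized activation, vectorized over phase within one beat
.activation <- function(phi, Tbeat, t_peak_frac, tau_r) {
  tp <- t_peak_frac * Tbeat
  ifelse(phi < tp,
         0.5 * (1 - cos(pi * phi / tp)),
         exp(-(phi - tp) / tau_r))
}

# venous pressure trajectory
.p_ven <- function(t, p) {
  out <- rep(p$p_ven0, length(t))
  occ <- t >= p$t_occ & t < p$t_defl
  out[occ] <- p$p_ven0 * exp(-(t[occ] - p$t_occ) / p$tau_occ)
  late <- t >= p$t_defl
  if (any(late)) {
    pd <- p$p_ven0 * exp(-(p$t_defl - p$t_occ) / p$tau_occ)
    out[late] <- p$p_ven0 - (p$p_ven0 - pd) * exp(-(t[late] - p$t_defl) / p$tau_rec)
  }
  out
}

#' Simulate the ground-truth hemodynamics
#'
#' Integrates the elastance-windkessel model with a fixed-step fourth-order
#' Runge-Kutta scheme on a fine grid. Beat boundaries sit at activation
#' onsets; the true end-systolic time of each beat is the elastance peak, so
#' true per-beat ES points lie exactly on the line
#' \eqn{P = E_{max}(V - V_0)}, and true ED points on
#' \eqn{P = E_{min}(V - V_0)}.
#'
#' @param params An [elastance_params()].
#' @param duration Simulation length in seconds; must cover at least 5 beats
#'   before and 12 after the occlusion. Default 30.
#' @param fine_rate Integration rate in Hz (>= 2000). Default 2000.
#' @return Object of class `lv_ground_truth` with fine-grid `time`, `v`
#'   (ml), `p_lv`, `p_ao`, `p_ven` (mmHg), `q_in`, `q_out` (ml/s), beat
#'   bookkeeping (`beat_starts`, `ed_times`, `es_times`,
#'   `occlusion_beat`), and `espvr_slope` (= emax), `compliance` (= 1/emin).
#' @export
simulate_lv <- function(params, duration = 30, fine_rate = 2000) {
  stopifnot(inherits(params, "elastance_params"))
  p <- params
  Tb <- 60 / p$hr
  if (fine_rate < 2000)
    cmrpv_stop("configuration_error", "fine_rate must be >= 2000 Hz")
  if (p$t_occ < 5 * Tb || duration - p$t_occ < 12 * Tb)
    cmrpv_stop("configuration_error",
               "duration must cover >= 5 beats before and >= 12 after t_occ")
  deriv <- function(t, y, parms) {
    V <- y[1]; Pao <- y[2]
    E <- p$emin + (p$emax - p$emin) * .activation(t %% Tb, Tb, p$t_peak_frac, p$tau_r)
    Plv <- E * (V - p$v0)
    qin <- max(.p_ven(t, p) - Plv, 0) / p$r_mv
    qout <- max(Plv - Pao, 0) / p$r_av
    list(c(qin - qout, (qout - Pao / p$r_per) / p$c_ao))
  }
  times <- seq(0, duration, by = 1 / fine_rate)
  y0 <- c(V = p$v0 + 0.8 * p$p_ven0 / p$emin, Pao = 1.2 * p$p_ven0)
  out <- deSolve::ode(y0, times, deriv, NULL, method = "rk4")
  tt <- out[, 1]; V <- out[, 2]; Pao <- out[, 3]
  E <- p$emin + (p$emax - p$emin) *
    .activation(tt %% Tb, Tb, p$t_peak_frac, p$tau_r)
  Plv <- E * (V - p$v0)
  if (any(!is.finite(Plv)) || any(!is.finite(Pao)))
    cmrpv_stop("configuration_error", "integration diverged")
  Pven <- .p_ven(tt, p)
  # every activation onset with data, including a trailing incomplete beat
  beat_starts <- seq(0, duration - 1e-9, by = Tb)
  structure(list(
    time = tt, v = V, p_lv = Plv, p_ao = Pao, p_ven = Pven,
    q_in = pmax(Pven - Plv, 0) / p$r_mv,
    q_out = pmax(Plv - Pao, 0) / p$r_av,
    beat_period = Tb, beat_starts = beat_starts,
    ed_times = beat_starts,
    es_times = (beat_starts + p$t_peak_frac * Tb)[
      beat_starts + p$t_peak_frac * Tb <= duration],
    occlusion_beat = which(beat_starts >= p$t_occ)[1],
    espvr_slope = p$emax, compliance = 1 / p$emin,
    params = p, fine_rate = fine_rate),
    class = "lv_ground_truth")
}

#' @export
print.lv_ground_truth <- function(x, ...) {
  cat(sprintf(paste0("lv_ground_truth: %.1f s at %g Hz, %d beats ",
                     "(occlusion at beat %d)\n"),
              x$time[length(x$time)], x$fine_rate, length(x$beat_starts),
              x$occlusion_beat))
  cat(sprintf("  Emax %.3g mmHg/ml, compliance %.3g ml/mmHg\n",
              x$espvr_slope, x$compliance))
  invisible(x)
}

# second-order catheter (fluid column) model, causal bilinear discretization
.catheter_filter <- function(x, fn, zeta, fs) {
  wn <- 2 * pi * fn
  # bilinear transform of wn^2 / (s^2 + 2 zeta wn s + wn^2)
  K <- 2 * fs
  b0 <- wn^2; a0 <- K^2 + 2 * zeta * wn * K + wn^2
  b <- b0 * c(1, 2, 1) / a0
  a <- c(1, (2 * wn^2 - 2 * K^2) / a0, (K^2 - 2 * zeta * wn * K + wn^2) / a0)
  as.numeric(signal::filter(signal::Arma(b = b, a = a), x))
}

#' Render a physiological recording from simulator ground truth
#'
#' Samples the fine-grid LV and aortic pressures at `sample_rate`, adds
#' Gaussian measurement noise, optionally passes the LV pressure through a
#' causal second-order fluid-filled-catheter model (natural frequency `fn`,
#' damping ratio `zeta`), synthesizes an ECG as a Gaussian-template train
#' with R-peaks at activation onsets, and emits trapezoidal gradient bursts
#' confined to the imaging window.
#'
#' @param gt An [simulate_lv()] ground truth.
#' @param sample_rate Output rate in Hz (<= fine rate). Default 1000.
#' @param imaging_window A [time_interval()] within the simulated span.
#' @param damping Optional `c(fn, zeta)` catheter model; `NULL` disables.
#' @param seed Random seed for the measurement noise; defaults to the
#'   simulator parameter seed.
#' @return A [physio_recording()] with 2 ECG leads, lvp, aop and 3 gradient
#'   axes.
#' @export
render_recording <- function(gt, sample_rate = 1000, imaging_window,
                             damping = NULL, seed = NULL) {
  stopifnot(inherits(gt, "lv_ground_truth"),
            inherits(imaging_window, "time_interval"))
  p <- gt$params
  if (sample_rate > gt$fine_rate)
    cmrpv_stop("configuration_error", "sample_rate must not exceed fine_rate")
  if (imaging_window$start < gt$time[1] ||
      imaging_window$end > gt$time[length(gt$time)])
    cmrpv_stop("bounds_error", "imaging window outside the simulated span")
  set.seed(seed %||% p$seed)
  tt <- seq(gt$time[1], gt$time[length(gt$time)], by = 1 / sample_rate)
  n <- length(tt)
  lvp <- approx(gt$time, gt$p_lv, tt)$y
  if (!is.null(damping))
    lvp <- .catheter_filter(lvp, damping[1], damping[2], sample_rate)
  lvp <- lvp + rnorm(n, 0, p$noise_p)
  aop <- approx(gt$time, gt$p_ao, tt)$y + rnorm(n, 0, p$noise_p)
  # ECG: per-beat Gaussian P-QRS-T template, R apex at the activation onset
  Tb <- gt$beat_period
  phi <- tt %% Tb
  phi_c <- pmin(phi, Tb - phi)  # distance to nearest beat boundary
  ecg_clean <- exp(-0.5 * (phi_c / 0.012)^2) +                # R (sigma 12 ms)
    0.15 * exp(-0.5 * ((phi - (Tb - 0.16)) / 0.025)^2) +     # P
    0.25 * exp(-0.5 * ((phi - 0.30) / 0.050)^2)              # T
  ecg1 <- ecg_clean + rnorm(n, 0, 0.02)
  ecg2 <- 0.8 * ecg_clean + rnorm(n, 0, 0.02)
  # gradient: alternating trapezoid lobes (20 ms period), zero outside window
  grad <- function(phase0, axis_amp) {
    u <- ((tt + phase0) %% 0.02) / 0.02
    tri <- pmin(1, pmin(u, 1 - u) / 0.1) * ifelse(((tt + phase0) %/% 0.02) %% 2 == 0, 1, -1)
    inwin <- tt >= imaging_window$start & tt <= imaging_window$end
    axis_amp * tri * inwin
  }
  physio_recording(
    time = tt, ecg = cbind(ecg1, ecg2), lvp = lvp,
    sample_rate = sample_rate, aop = aop,
    gradient = cbind(grad(0, 1), grad(0.005, 0.8), grad(0.01, 0.6)),
    meta = list(source = "cmrpv simulator"))
}

#' Elliptical contours realizing a prescribed volume trace
#'
#' For each frame, emits a full-ellipse long-axis contour with long
#' semi-axis `a` and short semi-axis \eqn{b = \sqrt{3000 V / (4 \pi a)}}
#' (V in ml, axes in mm), so that ideal centerline rotation recovers the
#' prescribed volume (prolate spheroid, \eqn{V = \tfrac{4}{3}\pi a b^2}).
#' The basal annulus chord degenerates to the basal vertex and the apex is
#' the opposite vertex.
#'
#' @param volume_trace A [volume_series()] prescription (ml).
#' @param a Long semi-axis in mm. Default 40.
#' @param n_points Number of contour vertices (>= 128). Default 256.
#' @return List of [lv_contour()].
#' @export
contours_from_volume <- function(volume_trace, a = 40, n_points = 256) {
  stopifnot(inherits(volume_trace, "volume_series"))
  if (a <= 0) cmrpv_stop("argument_error", "a must be positive")
  n_points <- max(128L, as.integer(n_points))
  th <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
  lapply(seq_along(volume_trace$frame_times), function(i) {
    V <- volume_trace$volumes[i]
    b <- sqrt(3000 * V / (4 * pi * a))
    pts <- cbind(a * cos(th), b * sin(th))
    lv_contour(pts, annulus_a = c(a, 0), annulus_b = c(a, 0),
               apex = c(-a, 0), frame_time = volume_trace$frame_times[i],
               validate = FALSE)
  })
}

#' Write a complete matched fixture dataset
#'
#' Simulates the model, renders the physiological recording and the contour
#' sequence over the imaging window, and writes three files into `dir`:
#' `recording.csv` (the CSV dialect of [write_recording()]),
#' `contours.json` ([write_contours()]), and `truth.json` (ground-truth
#' sidecar with the true ESPVR slope, compliance, per-beat fiducials and
#' occlusion beat).
#'
#' @param params An [elastance_params()].
#' @param dir Output directory (created if needed).
#' @param duration,fine_rate Passed to [simulate_lv()].
#' @param imaging_window A [time_interval()]; default `[2, 26.8]` s
#'   (326 frames at 76 ms).
#' @param frame_dt Contour frame spacing in seconds. Default 0.076.
#' @param damping Optional catheter model passed to [render_recording()].
#' @return Invisibly, a named list of the three file paths.
#' @export
make_fixture <- function(params = elastance_params(), dir,
                         duration = 30, fine_rate = 2000,
                         imaging_window = time_interval(2, 26.8),
                         frame_dt = 0.076, damping = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gt <- simulate_lv(params, duration, fine_rate)
  rec <- render_recording(gt, 1000, imaging_window, damping = damping)
  ft <- seq(imaging_window$start, imaging_window$end, by = frame_dt)
  v_true <- approx(gt$time, gt$v, ft)$y
  set.seed(params$seed + 1L)
  v_meas <- v_true + rnorm(length(ft), 0, params$noise_v)
  contours <- contours_from_volume(volume_series(ft, v_meas))
  paths <- list(recording = file.path(dir, "recording.csv"),
                contours = file.path(dir, "contours.json"),
                truth = file.path(dir, "truth.json"))
  write_recording(rec, paths$recording)
  write_contours(contours, paths$contours)
  jsonlite::write_json(
    list(espvr_slope = gt$espvr_slope, compliance = gt$compliance,
         v0 = params$v0, hr = params$hr, t_occ = params$t_occ,
         occlusion_beat = gt$occlusion_beat,
         ed_times = gt$ed_times, es_times = gt$es_times,
         params = unclass(params)),
    paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
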