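# Elastance simulator ground truth, renderers, and fixture generation.

test_that("parameter invariants are enforced", {
  expect_error(elastance_params(emax = 0.1, emin = 0.2),
               class = "cmrpv_configuration_error")
  expect_error(elastance_params(r_mv = -1), class = "cmrpv_configuration_error")
  expect_error(simulate_lv(elastance_params(t_occ = 1)),
               class = "cmrpv_configuration_error")
})

test_that("pre-occlusion beats reach a periodic steady state", {
  gt <- default_gt()
  pre <- gt$ed_times[gt$ed_times > 2 & gt$ed_times < gt$params$t_occ]
  edv <- vapply(pre, function(b) {
    max(gt$v[gt$time >= b - 0.05 & gt$time <= b + 0.05])
  }, numeric(1))
  expect_lt(diff(range(edv)), 0.5)
})

test_that("true ES points are collinear on the ESPVR line", {
  gt <- default_gt()
  use <- gt$es_times > 2 & gt$es_times < 27
  v <- approx(gt$time, gt$v, gt$es_times[use])$y
  p <- approx(gt$time, gt$p_lv, gt$es_times[use])$y
  resid <- p - gt$espvr_slope * (v - gt$params$v0)
  expect_lt(max(abs(resid)), 0.5)
  # regression of the occlusion sweep recovers emax within 2%
  occ <- gt$es_times >= gt$params$t_occ & gt$es_times < gt$params$t_defl
  fit <- fit_espvr(cbind(approx(gt$time, gt$v, gt$es_times[occ])$y,
                         approx(gt$time, gt$p_lv, gt$es_times[occ])$y))
  expect_equal(fit$slope, gt$espvr_slope, tolerance = 0.02)
  # true ED points recover emin the same way
  occ_ed <- gt$ed_times >= gt$params$t_occ & gt$ed_times < gt$params$t_defl
  fit_ed <- fit_edpvr(cbind(approx(gt$time, gt$v, gt$ed_times[occ_ed])$y,
                            approx(gt$time, gt$p_lv, gt$ed_times[occ_ed])$y))
  expect_equal(fit_ed$derived_metric, gt$compliance, tolerance = 0.02)
})

test_that("flow is conserved over a steady-state beat", {
  gt <- default_gt()
  b <- gt$ed_times[6]
  sel <- gt$time >= b & gt$time < b + gt$beat_period
  dt <- 1 / gt$fine_rate
  vin <- sum(gt$q_in[sel]) * dt
  vout <- sum(gt$q_out[sel]) * dt
  expect_equal(vin, vout, tolerance = 0.01)
  # stroke volume matches the time-integrated ejection flow within 2%;
  # the diastolic volume crest spills just past the activation onset, so
  # EDV is read over a window extended by 100 ms
  edv <- max(gt$v[gt$time >= b & gt$time < b + gt$beat_period + 0.1])
  esv <- min(gt$v[sel])
  expect_equal(vout, edv - esv, tolerance = 0.02)
})

test_that("an infinitely slow occlusion leaves the beats unchanged", {
  p <- elastance_params(tau_occ = 1e9, t_defl = 1e12)
  gt <- simulate_lv(p, duration = 18, fine_rate = 2000)
  beat <- function(b) {
    sel <- gt$time >= b & gt$time < b + gt$beat_period
    gt$p_lv[sel][1:1500]
  }
  pre <- gt$ed_times[9]            # windkessel settled, pre-occlusion
  post <- gt$ed_times[c(15, 21)]   # well after t_occ = 7
  for (b in post) expect_lt(max(abs(beat(b) - beat(pre))), 0.2)
})

test_that("rendering is deterministic in the seed and faithful when clean", {
  gt <- default_gt()
  win <- default_window()
  r1 <- render_recording(gt, 1000, win, seed = 5)
  r2 <- render_recording(gt, 1000, win, seed = 5)
  expect_identical(r1$lvp, r2$lvp)
  expect_identical(r1$ecg, r2$ecg)
  r3 <- render_recording(gt, 1000, win, seed = 6)
  expect_false(identical(r1$lvp, r3$lvp))
  # noise-free, undamped pressure equals the fine-grid truth at sample times
  gt0 <- gt; gt0$params$noise_p <- 0
  clean <- render_recording(gt0, 1000, win)
  expect_lt(max(abs(clean$lvp - approx(gt$time, gt$p_lv, clean$time)$y)), 1e-6)
  # gradient channels vanish outside the imaging window
  out <- clean$time < win$start | clean$time > win$end
  expect_true(all(clean$gradient[out, ] == 0))
  expect_true(any(clean$gradient[!out, ] != 0))
})

test_that("an underdamped catheter overshoots peak systolic pressure", {
  gt <- default_gt()
  win <- default_window()
  gt0 <- gt; gt0$params$noise_p <- 0
  clean <- render_recording(gt0, 1000, win)
  damped <- render_recording(gt0, 1000, win, damping = c(15, 0.3))
  for (b in gt$ed_times[gt$ed_times > 3 & gt$ed_times < 6]) {
    sel <- clean$time >= b & clean$time < b + gt$beat_period
    expect_gte(max(damped$lvp[sel]), max(clean$lvp[sel]))
  }
})

test_that("ECG template puts the R apex at the activation onset", {
  gt <- default_gt()
  gt0 <- gt; gt0$params$noise_p <- 0
  rec <- render_recording(gt0, 1000, default_window())
  peaks <- detect_r_peaks(rec$ecg[, 1], rec$sample_rate, time = rec$time)
  truth <- gt$ed_times[gt$ed_times >= rec$time[1] &
                         gt$ed_times <= rec$time[length(rec$time)]]
  expect_equal(length(peaks), length(truth))
  expect_lt(max(abs(peaks - truth)), 0.004)
})

test_that("prescribed-volume contours honour the spheroid inversion", {
  cc <- contours_from_volume(volume_series(c(0, 0.076), rep(67.0, 2)), a = 40)
  b <- max(cc[[1]]$points[, 2])
  expect_equal(b, sqrt(3000 * 67 / (4 * pi * 40)), tolerance = 1e-9)
  expect_equal(b, 20, tolerance = 0.01)
})

test_that("fixture files are complete, parseable and seed-deterministic", {
  d1 <- file.path(tempdir(), "fxa"); d2 <- file.path(tempdir(), "fxb")
  p <- list(seed = 3, emin = 0.1, t_occ = 7, tau_occ = 15)
  win <- time_interval(2, 16)
  f1 <- cmd_simulate(d1, seed = 3, emin = 0.1, duration = 18,
                     imaging_window = win)
  f2 <- cmd_simulate(d2, seed = 3, emin = 0.1, duration = 18,
                     imaging_window = win)
  for (f in unlist(f1)) expect_true(file.exists(f))
  expect_identical(unname(tools::md5sum(unlist(f1))),
                   unname(tools::md5sum(unlist(f2))))
  rec <- read_recording(f1$recording)
  expect_s3_class(rec, "physio_recording")
  truth <- jsonlite::fromJSON(f1$truth)
  expect_equal(truth$compliance, 10)  # 1 / emin
  expect_equal(truth$espvr_slope, 0.6)
  cts <- read_contours(f1$contours, validate = FALSE)
  expect_gt(length(cts), 100)
})
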