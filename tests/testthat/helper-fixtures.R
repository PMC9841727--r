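# Shared simulator fixtures. The ground truth is deterministic and
# noise-seed independent, so it is computed once per test run and reused;
# renders differ only in their measurement-noise seed.

.fixture_cache <- new.env(parent = emptyenv())

default_gt <- function() {
  if (is.null(.fixture_cache$gt))
    .fixture_cache$gt <- simulate_lv(elastance_params(), duration = 30,
                                     fine_rate = 2000)
  .fixture_cache$gt
}

default_window <- function() time_interval(2, 26.8)

# noise-free 1 kHz render of the default ground truth (cached)
clean_recording <- function() {
  if (is.null(.fixture_cache$clean_rec)) {
    p0 <- elastance_params(noise_p = 0, noise_v = 0)
    gt <- default_gt()
    gt$params <- p0
    .fixture_cache$clean_rec <- render_recording(gt, 1000, default_window())
  }
  .fixture_cache$clean_rec
}

# render recording + contour files for a given noise seed, reusing the
# cached ground truth; returns paths plus the ground truth
render_fixture <- function(seed, dir = tempfile("fx"), noise_p = 1,
                           noise_v = 2, frame_dt = 0.076) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gt <- default_gt()
  gt$params$noise_p <- noise_p
  gt$params$noise_v <- noise_v
  win <- default_window()
  rec <- render_recording(gt, 1000, win, seed = seed)
  ft <- seq(win$start, win$end, by = frame_dt)
  v_true <- approx(gt$time, gt$v, ft)$y
  set.seed(seed + 1000L)
  v_meas <- v_true + rnorm(length(ft), 0, noise_v)
  contours <- contours_from_volume(volume_series(ft, v_meas))
  paths <- list(recording = file.path(dir, "recording.csv"),
                contours = file.path(dir, "contours.json"))
  write_recording(rec, paths$recording)
  write_contours(contours, paths$contours)
  c(paths, list(gt = gt, dir = dir))
}

# full pipeline on a rendered fixture; returns the cmd_run result
run_fixture_pipeline <- function(seed, ...) {
  fx <- render_fixture(seed, ...)
  cfg <- run_config(fx$recording, fx$contours, occlusion = "auto",
                    outdir = file.path(fx$dir, "out"), seed = seed)
  res <- cmd_run(cfg)
  res$gt <- fx$gt
  res
}

# an analytic full-ellipse contour (long semi-axis a along x, short b)
ellipse_contour <- function(a = 40, b = 20, n = 720, frame_time = 0,
                            rot = 0, shift = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  pts <- cbind(a * cos(th), b * sin(th))
  R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2)
  tf <- function(p) {
    p <- if (is.matrix(p)) p %*% t(R) else as.numeric(R %*% p)
    if (is.matrix(p)) sweep(p, 2, shift, `+`) else p + shift
  }
  lv_contour(tf(pts), annulus_a = tf(c(a, 0)), annulus_b = tf(c(a, 0)),
             apex = tf(c(-a, 0)), frame_time = frame_time, validate = FALSE)
}
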