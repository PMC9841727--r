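# Centerline-rotation volumetry, contour I/O, volume fiducials, upsampling.

test_that("analytic phantoms are reproduced within 0.5% at 200 slabs", {
  # prolate spheroid a = 40, b = 20 mm: 4/3 pi a b^2 = 67.02 ml
  sph <- ellipse_contour(a = 40, b = 20)
  expect_equal(centerline_rotation_volume(sph, 200),
               4 / 3 * pi * 40 * 20^2 / 1000, tolerance = 0.005)
  # sphere r = 20 mm rotated about a diameter: 33.51 ml
  ball <- ellipse_contour(a = 20, b = 20)
  expect_equal(centerline_rotation_volume(ball, 200),
               4 / 3 * pi * 20^3 / 1000, tolerance = 0.005)
  # cylinder: rectangle 50 mm along the axis, half-width 15 mm
  rect <- lv_contour(rbind(c(25, -15), c(25, 15), c(-25, 15), c(-25, -15)),
                     annulus_a = c(25, -15), annulus_b = c(25, 15),
                     apex = c(-25, 0), frame_time = 0)
  expect_equal(centerline_rotation_volume(rect, 200),
               pi * 15^2 * 50 / 1000, tolerance = 0.005)
})

test_that("volume scales as k^3 and is rigid-motion invariant", {
  base <- ellipse_contour(a = 38, b = 21)
  v1 <- centerline_rotation_volume(base, 200)
  for (k in c(0.5, 2, 3)) {
    sc <- lv_contour(base$points * k, base$annulus_a * k, base$annulus_b * k,
                     base$apex * k, 0, validate = FALSE)
    expect_equal(centerline_rotation_volume(sc, 200), k^3 * v1,
                 tolerance = 1e-6)
  }
  moved <- ellipse_contour(a = 38, b = 21, rot = 0.7, shift = c(13, -41))
  expect_equal(centerline_rotation_volume(moved, 200), v1, tolerance = 1e-3)
})

test_that("slab refinement converges for smooth contours", {
  cc <- ellipse_contour(a = 40, b = 20, n = 2000)
  v_true <- 4 / 3 * pi * 40 * 20^2 / 1000
  errs <- vapply(c(25, 50, 100, 200), function(ns)
    abs(centerline_rotation_volume(cc, ns) - v_true), numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("degenerate contours raise geometry errors", {
  expect_error(lv_contour(rbind(c(0, 0), c(1, 0)), c(0, 0), c(0, 0), c(1, 0), 0),
               class = "cmrpv_geometry_error")
  # landmark off the polygon
  expect_error(lv_contour(rbind(c(1, 0), c(0, 1), c(-1, 0), c(0, -1)),
                          c(5, 5), c(5, 5), c(-1, 0), 0),
               class = "cmrpv_geometry_error")
  # self-intersecting bow-tie
  expect_error(lv_contour(rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1)),
                          c(0, 0), c(0, 0), c(1, 1), 0),
               class = "cmrpv_geometry_error")
})

test_that("a contour sequence yields a volume series that inverts the generator", {
  ft <- seq(0, 2, by = 0.076)
  v_true <- 90 + 20 * sin(2 * pi * ft / 0.8)
  contours <- contours_from_volume(volume_series(ft, v_true))
  vs <- volume_timeseries(contours, n_slabs = 200)
  expect_equal(vs$temporal_resolution, 0.076, tolerance = 1e-9)
  expect_lt(max(abs(vs$volumes - v_true) / v_true), 0.01)
  # identical contours give a constant series
  same <- contours_from_volume(volume_series(c(0, 0.076, 0.152), rep(80, 3)))
  vs2 <- volume_timeseries(same)
  expect_lt(diff(range(vs2$volumes)), 1e-9)
  expect_error(volume_timeseries(contours[1]), class = "cmrpv_timing_error")
  # non-uniform frame spacing
  bad <- contours_from_volume(volume_series(c(0, 0.076, 0.152), rep(80, 3)))
  bad[[3]]$frame_time <- 0.160
  expect_error(volume_timeseries(bad), class = "cmrpv_timing_error")
})

test_that("round-trip volume recovery holds from 30 to 277 ml", {
  for (V in c(30, 67, 120, 277)) {
    cc <- contours_from_volume(volume_series(c(0, 0.076), rep(V, 2)))[[1]]
    expect_equal(centerline_rotation_volume(cc, 200), V, tolerance = 0.01)
  }
  # b follows sqrt scaling: doubling V multiplies b by sqrt(2)
  b_of <- function(V) max(contours_from_volume(
    volume_series(c(0, 0.076), rep(V, 2)))[[1]]$points[, 2])
  expect_equal(b_of(134) / b_of(67), sqrt(2), tolerance = 1e-6)
  expect_equal(b_of(67.02), 20, tolerance = 1e-3)
})

test_that("volume ED/ES fiducials sit on per-beat extrema", {
  # sinusoid sampled at 76 ms: ED at crests, ES at troughs, one pair/cycle
  ft <- seq(0, 4, by = 0.076)
  vs <- volume_series(ft, 90 + 20 * sin(2 * pi * ft / 0.8))
  fid <- detect_ed_es_volume(vs, min_rr = 0.4, smooth = FALSE)
  expect_equal(length(fid$es_indices), length(fid$ed_indices) - 1)
  expect_gte(length(fid$ed_indices), 4)
  # crests/troughs of the sinusoid: value close to extremes
  expect_true(all(vs$volumes[fid$ed_indices] > 108))
  expect_true(all(vs$volumes[fid$es_indices] < 72))
  # monotone series has no beats
  expect_error(detect_ed_es_volume(volume_series(ft, 200 - 10 * ft)),
               class = "cmrpv_detection_error")
})

test_that("simulator volume fiducials match the brute-force per-beat extrema", {
  gt <- default_gt()
  win <- default_window()
  ft <- seq(win$start, win$end, by = 0.076)
  vs <- volume_series(ft, approx(gt$time, gt$v, ft)$y)
  fid <- detect_ed_es_volume(vs, smooth = TRUE)
  # oracle: per-beat argmax/argmin over frames between true beat boundaries
  eds_t <- gt$ed_times[gt$ed_times >= win$start & gt$ed_times <= win$end]
  ed_oracle <- vapply(eds_t, function(b) {
    sel <- which(ft >= b - 0.35 & ft <= b + 0.35)
    sel[which.max(vs$volumes[sel])]
  }, integer(1))
  expect_equal(length(fid$ed_indices), length(ed_oracle))
  expect_lte(max(abs(fid$ed_indices - ed_oracle)), 1)
  es_oracle <- vapply(seq_len(length(ed_oracle) - 1), function(k) {
    sel <- ed_oracle[k]:ed_oracle[k + 1]
    sel[which.min(vs$volumes[sel])]
  }, integer(1))
  expect_equal(fid$es_indices, es_oracle)
  # ED volume >= ES volume for every beat
  nb <- length(fid$es_indices)
  expect_true(all(vs$volumes[fid$ed_indices[1:nb]] >= vs$volumes[fid$es_indices]))
})

test_that("volume upsampling is exact linear interpolation", {
  vs <- volume_series(c(0, 0.076), c(100, 108))
  up <- upsample_volume(vs, 250)
  expect_equal(approx(up$frame_times, up$volumes, 0.038)$y, 104, tolerance = 1e-9)
  # original samples reproduced exactly on the 4 ms grid (76 = 19 x 4 ms)
  ft <- seq(0, 2, by = 0.076)
  vs2 <- volume_series(ft, 90 + 20 * sin(2 * pi * ft / 0.8))
  up2 <- upsample_volume(vs2, 250)
  at <- approx(up2$frame_times, up2$volumes, ft)$y
  expect_equal(at, vs2$volumes, tolerance = 1e-9)
  # sample count multiplies by 19 +/- 1 (76 ms -> 4 ms grid)
  ratio <- length(up2$volumes) / length(vs2$volumes)
  expect_gte(ratio, 18); expect_lte(ratio, 20)
  expect_error(upsample_volume(vs2, 10), class = "cmrpv_argument_error")
})

test_that("contour files round-trip through the versioned JSON format", {
  ft <- seq(0, 0.308, by = 0.076)
  contours <- contours_from_volume(volume_series(ft, c(80, 95, 90, 70, 85)))
  f <- tempfile(fileext = ".json")
  write_contours(contours, f)
  back <- read_contours(f)
  expect_length(back, 5)
  for (i in seq_along(back)) {
    expect_equal(back[[i]]$points, unname(contours[[i]]$points), tolerance = 1e-12)
    expect_equal(back[[i]]$frame_time, contours[[i]]$frame_time)
    expect_equal(back[[i]]$apex, contours[[i]]$apex)
  }
  expect_error(read_contours(tempfile()), class = "cmrpv_format_error")
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(format = "other"), bad, auto_unbox = TRUE)
  expect_error(read_contours(bad), class = "cmrpv_format_error")
})

test_that("pixel contours convert through the spacing metadata", {
  th <- seq(0, 2 * pi, length.out = 129)[-129]
  pts_px <- cbind(20 * cos(th) + 40, 10 * sin(th) + 40)
  cc <- contour_from_pixels(pts_px, 2.3, c(60, 40), c(60, 40), c(20, 40), 0)
  expect_equal(max(cc$points[, 1]) - min(cc$points[, 1]), 2 * 20 * 2.3,
               tolerance = 1e-9)
  expect_equal(cc$apex, c(20 * 2.3, 40 * 2.3))
})
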