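# LV volume from time-resolved long-axis 2D endocardial contours via
# centerline rotation, volume-based ED/ES detection, and up-sampling to the
# pressure time grid.

#' Long-axis LV endocardial contour
#'
#' A closed 2D polygon (mm) for one cine frame, with the two basal mitral
#' annulus points, the apical point, and the frame timestamp. Orientation is
#' normalized counter-clockwise on construction.
#'
#' @param points Two-column matrix of ordered (x, y) vertices in mm; the
#'   closing edge from the last to the first vertex is implicit.
#' @param annulus_a,annulus_b The two basal (mitral annulus) contour points
#'   (mm); they may coincide for a degenerate basal chord.
#' @param apex Apical contour point (mm).
#' @param frame_time Frame timestamp (s).
#' @param validate Check polygon simplicity (O(n^2)). Default `TRUE`.
#' @return Object of class `lv_contour`.
#' @export
lv_contour <- function(points, annulus_a, annulus_b, apex, frame_time,
                       validate = TRUE) {
  points <- as.matrix(points)
  if (ncol(points) != 2 || nrow(points) < 3)
    cmrpv_stop("geometry_error", "contour needs >= 3 two-column points")
  mid <- (annulus_a + annulus_b) / 2
  if (sqrt(sum((apex - mid)^2)) <= 0)
    cmrpv_stop("geometry_error", "apex coincides with the annulus midpoint")
  for (p in list(annulus_a, annulus_b, apex)) {
    if (.dist_to_polygon(p, points)^2 > 1e-6 * max(1, sum((apex - mid)^2)))
      cmrpv_stop("geometry_error", "landmark does not lie on the contour")
  }
  # normalize to counter-clockwise (positive signed area)
  x <- points[, 1]; y <- points[, 2]
  a2 <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
  if (a2 < 0) points <- points[rev(seq_len(nrow(points))), ]
  if (validate && .self_intersects(points))
    cmrpv_stop("geometry_error", "contour polygon is self-intersecting")
  structure(list(points = points, annulus_a = as.numeric(annulus_a),
                 annulus_b = as.numeric(annulus_b), apex = as.numeric(apex),
                 frame_time = frame_time),
            class = "lv_contour")
}

# minimum distance from a point to the closed polygon boundary
.dist_to_polygon <- function(p, pts) {
  a <- pts
  b <- pts[c(2:nrow(pts), 1), ]
  abx <- b[, 1] - a[, 1]; aby <- b[, 2] - a[, 2]
  apx <- p[1] - a[, 1]; apy <- p[2] - a[, 2]
  len2 <- pmax(abx^2 + aby^2, .Machine$double.eps)
  t <- pmin(pmax((apx * abx + apy * aby) / len2, 0), 1)
  dx <- apx - t * abx; dy <- apy - t * aby
  sqrt(min(dx^2 + dy^2))
}

# Segment-pair intersection test for polygon simplicity (vectorized over
# one index; adjacent edges share endpoints and are skipped).
.self_intersects <- function(pts) {
  n <- nrow(pts)
  p1 <- pts; p2 <- pts[c(2:n, 1), ]
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2)) {
    j <- (i + 2):n
    j <- j[!(i == 1 & j == n)]
    if (length(j) == 0) next
    d1 <- cross(p1[i, 1], p1[i, 2], p2[i, 1], p2[i, 2], p1[j, 1], p1[j, 2])
    d2 <- cross(p1[i, 1], p1[i, 2], p2[i, 1], p2[i, 2], p2[j, 1], p2[j, 2])
    d3 <- cross(p1[j, 1], p1[j, 2], p2[j, 1], p2[j, 2], rep(p1[i, 1], length(j)), rep(p1[i, 2], length(j)))
    d4 <- cross(p1[j, 1], p1[j, 2], p2[j, 1], p2[j, 2], rep(p2[i, 1], length(j)), rep(p2[i, 2], length(j)))
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

#' LV volume by centerline rotation
#'
#' Approximates the ventricle as circularly symmetric about its long axis.
#' The centerline runs from the annulus midpoint to the apex; the cavity
#' between the (flat) basal annulus chord and the apex is partitioned into
#' `n_slabs` slabs of equal thickness perpendicular to the centerline. For
#' each slab the perpendicular distances from the centerline to the contour
#' on either side give two half-disc radii, and the volume is the sum of the
#' averaged half-solids of revolution:
#' \deqn{V = \sum_i \frac{\pi}{2}\left(r_{L,i}^2 + r_{R,i}^2\right)\Delta h}
#'
#' @param contour An [lv_contour()].
#' @param n_slabs Number of slabs (>= 10). Default 200.
#' @return Volume in ml.
#' @export
centerline_rotation_volume <- function(contour, n_slabs = 200) {
  stopifnot(inherits(contour, "lv_contour"))
  if (n_slabs < 10)
    cmrpv_stop("argument_error", "n_slabs must be >= 10")
  mid <- (contour$annulus_a + contour$annulus_b) / 2
  axis <- contour$apex - mid
  L <- sqrt(sum(axis^2))
  u_hat <- axis / L
  v_hat <- c(-u_hat[2], u_hat[1])
  # contour in centerline coordinates: u along axis (0 at base), v across
  rel <- sweep(contour$points, 2, mid)
  u <- rel %*% u_hat
  v <- rel %*% v_hat
  n <- length(u)
  nxt <- c(2:n, 1)
  dh <- L / n_slabs
  uc <- (seq_len(n_slabs) - 0.5) * dh
  vol_mm3 <- 0
  for (i in seq_len(n_slabs)) {
    ui <- uc[i]
    straddle <- which((u - ui) * (u[nxt] - ui) <= 0 & u != u[nxt])
    if (length(straddle) == 0) {
      if (ui > 0.95 * L) {
        cmrpv_warn("apex_slab", "slab %d near apex has no crossing; radius 0", i)
        next
      }
      cmrpv_stop("geometry_error", "slab %d has no contour crossing", i)
    }
    tt <- (ui - u[straddle]) / (u[nxt[straddle]] - u[straddle])
    vv <- v[straddle] + tt * (v[nxt[straddle]] - v[straddle])
    pos <- vv[vv > 0]; neg <- vv[vv < 0]
    rl <- if (length(neg) > 0) max(-neg) else {
      if (ui > 0.95 * L) {
        cmrpv_warn("apex_slab", "slab %d near apex misses one side; radius 0", i)
        0
      } else cmrpv_stop("geometry_error", "slab %d misses the contour on one side", i)
    }
    rr <- if (length(pos) > 0) max(pos) else {
      if (ui > 0.95 * L) {
        cmrpv_warn("apex_slab", "slab %d near apex misses one side; radius 0", i)
        0
      } else cmrpv_stop("geometry_error", "slab %d misses the contour on one side", i)
    }
    vol_mm3 <- vol_mm3 + (pi / 2) * (rl^2 + rr^2) * dh
  }
  if (vol_mm3 <= 0) cmrpv_stop("geometry_error", "non-positive volume")
  vol_mm3 / 1000
}

#' Volume series from a contour sequence
#'
#' @param contours List of [lv_contour()] with strictly increasing,
#'   uniformly spaced frame times (tolerance 1 ms).
#' @param n_slabs Passed to [centerline_rotation_volume()].
#' @return Object of class `volume_series` with `frame_times`, `volumes`
#'   (ml) and `temporal_resolution` (s).
#' @export
volume_timeseries <- function(contours, n_slabs = 200) {
  if (length(contours) < 2)
    cmrpv_stop("timing_error", "need at least 2 frames")
  ft <- vapply(contours, function(cc) cc$frame_time, numeric(1))
  dt <- diff(ft)
  if (any(dt <= 0) || max(dt) - min(dt) > 1e-3)
    cmrpv_stop("timing_error", "frame times must increase uniformly (1 ms tolerance)")
  vols <- vapply(contours, centerline_rotation_volume, numeric(1),
                 n_slabs = n_slabs)
  volume_series(ft, vols)
}

#' Construct a volume series
#'
#' @param frame_times Strictly increasing, uniformly spaced timestamps (s).
#' @param volumes Positive LV volumes (ml).
#' @return Object of class `volume_series`.
#' @export
volume_series <- function(frame_times, volumes) {
  if (length(frame_times) != length(volumes))
    cmrpv_stop("argument_error", "frame_times and volumes differ in length")
  if (any(volumes <= 0))
    cmrpv_stop("argument_error", "volumes must be positive")
  dt <- diff(frame_times)
  if (length(dt) > 0 && (any(dt <= 0) || max(dt) - min(dt) > 1e-3))
    cmrpv_stop("timing_error", "frame times must increase uniformly (1 ms tolerance)")
  structure(list(frame_times = as.numeric(frame_times),
                 volumes = as.numeric(volumes),
                 temporal_resolution = median(dt)),
            class = "volume_series")
}

#' @export
print.volume_series <- function(x, ...) {
  cat(sprintf("volume_series: %d frames at %.1f ms, %.1f-%.1f ml\n",
              length(x$volumes), 1000 * x$temporal_resolution,
              min(x$volumes), max(x$volumes)))
  invisible(x)
}

#' Detect end-diastole and end-systole from a volume series
#'
#' End-diastole is the per-beat maximum and end-systole the per-beat minimum
#' volume. Frames are lightly smoothed (zero-phase Savitzky-Golay, quadratic,
#' 5 frames) to suppress frame-to-frame measurement noise, candidate maxima
#' are picked with a minimum spacing of `min_rr`, and peaks whose prominence
#' relative to the adjacent troughs falls below a quarter of the median beat
#' amplitude are discarded. Fiducial frames are refined to the raw-series
#' local extremum within one frame.
#'
#' @param series A [volume_series()] spanning at least 3 beats.
#' @param min_rr Minimum beat period in seconds. Default 0.4.
#' @param smooth Apply the Savitzky-Golay pre-smoothing. Default `TRUE`.
#' @return Object of class `volume_fiducials`: integer `ed_indices`,
#'   `es_indices`, and `smoothed` (the smoothed volume trace used for
#'   amplitude readout).
#' @export
detect_ed_es_volume <- function(series, min_rr = 0.4, smooth = TRUE) {
  stopifnot(inherits(series, "volume_series"))
  if (min_rr <= 0) cmrpv_stop("argument_error", "min_rr must be positive")
  v <- series$volumes
  vs <- if (smooth && length(v) >= 5) signal::sgolayfilt(v, p = 2, n = 5) else v
  mind <- max(1L, round(min_rr / series$temporal_resolution))
  pk <- tryCatch(pracma::findpeaks(vs, minpeakdistance = mind),
                 error = function(e) NULL)
  if (is.null(pk) || nrow(pk) < 2)
    cmrpv_stop("detection_error", "no alternating volume extrema found")
  edi <- sort(pk[, 2])
  # prominence filter against adjacent troughs
  repeat {
    if (length(edi) < 2) break
    tr <- vapply(seq_len(length(edi) - 1), function(k)
      min(vs[edi[k]:edi[k + 1]]), numeric(1))
    amp <- vapply(seq_along(edi), function(k) {
      l <- if (k > 1) vs[edi[k]] - tr[k - 1] else Inf
      r <- if (k < length(edi)) vs[edi[k]] - tr[k] else Inf
      min(l, r)
    }, numeric(1))
    thr <- 0.25 * median(amp[is.finite(amp)])
    bad <- which(amp < thr)
    if (length(bad) == 0) break
    edi <- edi[-bad[1]]
  }
  if (length(edi) < 4)
    cmrpv_stop("detection_error",
               "series must span at least 3 beats (%d maxima found)", length(edi))
  esi <- vapply(seq_len(length(edi) - 1), function(k)
    edi[k] + which.min(vs[edi[k]:edi[k + 1]]) - 1L, numeric(1))
  refine <- function(idx, fun) vapply(idx, function(i) {
    lo <- max(1L, i - 1L); hi <- min(length(v), i + 1L)
    lo + fun(v[lo:hi]) - 1L
  }, numeric(1))
  edi <- refine(edi, which.max)
  esi <- refine(esi, which.min)
  if (any(diff(edi) <= 0) || any(esi <= edi[-length(edi)]) || any(esi >= edi[-1]))
    cmrpv_stop("detection_error", "ED/ES alternation violated")
  structure(list(ed_indices = as.integer(edi), es_indices = as.integer(esi),
                 smoothed = vs),
            class = "volume_fiducials")
}

#' Up-sample a volume series by linear interpolation
#'
#' Interpolates onto a uniform `1/target_rate` grid spanning the original
#' time range, starting at the first frame time so that original samples are
#' reproduced exactly whenever the grid passes through them.
#'
#' @param series A [volume_series()].
#' @param target_rate Target sampling rate in Hz, above the native rate.
#' @return A [volume_series()] at the target resolution.
#' @export
upsample_volume <- function(series, target_rate) {
  stopifnot(inherits(series, "volume_series"))
  if (target_rate <= 1 / series$temporal_resolution)
    cmrpv_stop("argument_error", "target_rate must exceed the native frame rate")
  tt <- seq(series$frame_times[1], series$frame_times[length(series$frame_times)],
            by = 1 / target_rate)
  volume_series(tt, approx(series$frame_times, series$volumes, tt)$y)
}

# Contour file format ----------------------------------------------------

#' Read or write a contour sequence
#'
#' The contour file is a versioned JSON document:
#' `{"format": "lv-contours", "version": 1, "units": "mm", "frames": [...]}`
#' where each frame holds `frame_time_s`, `points` (n x 2), `annulus_a`,
#' `annulus_b`, and `apex`.
#'
#' @param path File path.
#' @param validate Passed to [lv_contour()].
#' @return `read_contours`: list of [lv_contour()].
#' @export
read_contours <- function(path, validate = TRUE) {
  if (!file.exists(path))
    cmrpv_stop("format_error", "contour file not found: %s", path)
  doc <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  if (!identical(doc$format, "lv-contours"))
    cmrpv_stop("format_error", "not an lv-contours file: %s", path)
  if (!identical(as.integer(doc$version), 1L))
    cmrpv_stop("format_error", "unsupported lv-contours version")
  frames <- doc$frames
  get_pts <- if (is.list(frames$points)) {
    function(i) frames$points[[i]]
  } else {
    function(i) frames$points[i, , ]  # equal-length frames simplify to 3-D
  }
  lapply(seq_along(frames$frame_time_s), function(i)
    lv_contour(get_pts(i), frames$annulus_a[i, ],
               frames$annulus_b[i, ], frames$apex[i, ],
               frames$frame_time_s[i], validate = validate))
}

#' @rdname read_contours
#' @param contours List of [lv_contour()].
#' @export
write_contours <- function(contours, path) {
  frames <- list(
    frame_time_s = vapply(contours, function(cc) cc$frame_time, numeric(1)),
    points = lapply(contours, function(cc) unname(cc$points)),
    annulus_a = do.call(rbind, lapply(contours, function(cc) cc$annulus_a)),
    annulus_b = do.call(rbind, lapply(contours, function(cc) cc$annulus_b)),
    apex = do.call(rbind, lapply(contours, function(cc) cc$apex)))
  doc <- list(format = "lv-contours", version = 1L, units = "mm",
              frames = frames)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Convert pixel coordinates to a contour in mm
#'
#' @param points_px Two-column matrix of pixel coordinates.
#' @param pixel_spacing Pixel size in mm (scalar or length-2 c(x, y)).
#' @param annulus_a_px,annulus_b_px,apex_px Landmark pixel coordinates.
#' @param frame_time Frame timestamp (s).
#' @param validate Passed to [lv_contour()].
#' @return An [lv_contour()] in mm.
#' @export
contour_from_pixels <- function(points_px, pixel_spacing, annulus_a_px,
                                annulus_b_px, apex_px, frame_time,
                                validate = TRUE) {
  sp <- rep(pixel_spacing, length.out = 2)
  if (any(sp <= 0)) cmrpv_stop("argument_error", "pixel_spacing must be positive")
  scale2 <- function(p) as.numeric(p) * sp
  pts <- sweep(as.matrix(points_px), 2, sp, `*`)
  lv_contour(pts, scale2(annulus_a_px), scale2(annulus_b_px),
             scale2(apex_px), frame_time, validate = validate)
}
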