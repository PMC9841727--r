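# Agreement statistics: Bland-Altman bias / limits of agreement and the
# two-way absolute-agreement single-measure intraclass correlation, with
# the categorical agreement banding used for reporting.

#' Bland-Altman analysis
#'
#' @param x,y Paired measurement vectors (equal length >= 2).
#' @return List with `bias` (mean of `x - y`), `loa_low`, `loa_high`
#'   (bias -/+ 1.96 x sample SD of the differences), `sd_diff` and `n`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y))
    cmrpv_stop("argument_error", "x and y must have equal length")
  if (length(x) < 2)
    cmrpv_stop("argument_error", "need at least 2 pairs")
  d <- x - y
  s <- sd(d)
  list(bias = mean(d), loa_low = mean(d) - 1.96 * s,
       loa_high = mean(d) + 1.96 * s, sd_diff = s, n = length(d))
}

# agreement bands on the rounded (half-up, 2 decimals) coefficient
.icc_label <- function(icc) {
  r <- floor(icc * 100 + 0.5) / 100
  if (r < 0) return("poor")
  if (r <= 0.30) "poor"
  else if (r <= 0.50) "weak"
  else if (r <= 0.70) "moderate"
  else if (r <= 0.90) "strong"
  else "excellent"
}

#' Intraclass correlation coefficient, ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC for two
#' paired raters/methods, computed from the two-way ANOVA mean squares:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \tfrac{k}{n}(MS_C - MS_E)}}
#' with k = 2 methods and n subjects. The label follows the banding
#' poor (0.00-0.30), weak (0.31-0.50), moderate (0.51-0.70),
#' strong (0.71-0.90), excellent (0.91-1.00).
#'
#' @param x,y Paired measurement vectors (equal length >= 3).
#' @return List with `icc`, `icc_label`, `r` (Pearson), `n`.
#' @export
icc_agreement <- function(x, y) {
  if (length(x) != length(y))
    cmrpv_stop("argument_error", "x and y must have equal length")
  n <- length(x)
  if (n < 3)
    cmrpv_stop("argument_error", "need at least 3 pairs")
  m <- cbind(x, y)
  k <- 2
  grand <- mean(m)
  if (sum((m - grand)^2) == 0)
    cmrpv_stop("undefined_icc_error", "zero total variance; ICC undefined")
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ss_r <- k * sum((row_m - grand)^2)
  ss_c <- n * sum((col_m - grand)^2)
  ss_e <- sum((m - outer(row_m, rep(1, k)) -
                 outer(rep(1, n), col_m) + grand)^2)
  ms_r <- ss_r / (n - 1)
  ms_c <- ss_c / (k - 1)
  ms_e <- ss_e / ((n - 1) * (k - 1))
  icc <- (ms_r - ms_e) / (ms_r + (k - 1) * ms_e + k * (ms_c - ms_e) / n)
  list(icc = icc, icc_label = .icc_label(icc),
       r = if (sd(x) > 0 && sd(y) > 0) stats::cor(x, y) else NA_real_,
       n = n)
}

#' Combined method-agreement report
#'
#' @param x,y Paired measurement vectors.
#' @return Object of class `agreement_result` merging [bland_altman()] and
#'   [icc_agreement()] fields.
#' @export
agreement_stats <- function(x, y) {
  ba <- bland_altman(x, y)
  ic <- icc_agreement(x, y)
  structure(c(ba, ic[c("icc", "icc_label", "r")]),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("agreement (n = %d): bias %.2f [%.2f, %.2f]\n",
              x$n, x$bias, x$loa_low, x$loa_high))
  cat(sprintf("  ICC %.3f (%s), Pearson r %.3f\n", x$icc, x$icc_label, x$r))
  invisible(x)
}
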