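#' Intra-class correlation between two measurement methods
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC (ICC(2,1)
#' in the Shrout--Fleiss taxonomy), computed from the mean squares of a
#' subjects-by-methods decomposition, with a 95% confidence interval from
#' the standard F-distribution bounds (McGraw & Wong). Absolute agreement --
#' not consistency -- is the relevant form when two gain methods are to be
#' used interchangeably in the clinic; an ICC of at least 0.90 is read as
#' excellent concordance.
#'
#' @param a,b Paired measurements of the same subjects by the two methods
#'   (equal length, at least 3 pairs, finite).
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return An object of class `vvor_agreement` with `icc`, `icc_ci_low`,
#'   `icc_ci_high`, `icc_form`, `n_pairs` (Bland--Altman fields `NA`; see
#'   [bland_altman()]).
#' @export
#' @examples
#' a <- c(0.95, 0.84, 0.78, 0.45, 1.02, 0.66)
#' b <- c(0.97, 0.80, 0.75, 0.43, 1.01, 0.70)
#' icc_agreement(a, b)
icc_agreement <- function(a, b, conf_level = 0.95) {
  if (length(a) != length(b))
    vvor_stop("paired vectors must have equal length", "vvor_insufficient_error")
  n <- length(a)
  if (n < 3L)
    vvor_stop("at least 3 pairs are required for the ICC",
              "vvor_insufficient_error")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    vvor_stop("paired measurements must be finite", "vvor_insufficient_error")
  x <- cbind(a, b)
  k <- 2L
  gm <- mean(x)
  sst <- sum((x - gm)^2)
  if (sst < .Machine$double.eps * n)
    vvor_stop("zero total variance: ICC undefined", "vvor_undefined_error")
  ssr <- k * sum((rowMeans(x) - gm)^2)
  ssc <- n * sum((colMeans(x) - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))

  alpha <- 1 - conf_level
  if (mse <= .Machine$double.eps * msr && msc <= .Machine$double.eps * msr) {
    ci <- c(1, 1)  # degenerate perfect agreement
  } else {
    a_ <- (k * icc) / (n * (1 - icc))
    b_ <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a_ * msc + b_ * mse)^2 /
      ((a_ * msc)^2 / (k - 1) + (b_ * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    ci <- c(lo, hi)
  }
  structure(list(icc = icc, icc_ci_low = ci[1], icc_ci_high = ci[2],
                 icc_form = "ICC(2,1) two-way random, absolute agreement, single measure",
                 n_pairs = n,
                 bias = NA_real_, loa_low = NA_real_, loa_high = NA_real_,
                 sd_diff = NA_real_),
            class = "vvor_agreement")
}

#' Bland--Altman agreement statistics
#'
#' Bias (mean of the pairwise differences `a - b`) and 95% limits of
#' agreement (bias +/- 1.96 sample standard deviations of the differences).
#'
#' @param a,b Paired measurements (equal length, at least 2 pairs).
#' @return An object of class `vvor_agreement` with `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `n_pairs` (ICC fields `NA`; see
#'   [icc_agreement()]).
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b))
    vvor_stop("paired vectors must have equal length", "vvor_insufficient_error")
  if (length(a) < 2L)
    vvor_stop("at least 2 pairs are required for Bland-Altman limits",
              "vvor_insufficient_error")
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(icc = NA_real_, icc_ci_low = NA_real_, icc_ci_high = NA_real_,
                 icc_form = NA_character_, n_pairs = length(d),
                 bias = bias, sd_diff = s,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s),
            class = "vvor_agreement")
}

#' Full two-method agreement summary
#'
#' Convenience wrapper combining [icc_agreement()] and [bland_altman()] on
#' the same pairs, as used by the `agree` command-line subcommand.
#'
#' @inheritParams icc_agreement
#' @return A `vvor_agreement` with both the ICC and Bland--Altman fields.
#' @export
method_agreement <- function(a, b, conf_level = 0.95) {
  icc <- icc_agreement(a, b, conf_level)
  ba <- bland_altman(a, b)
  icc$bias <- ba$bias
  icc$sd_diff <- ba$sd_diff
  icc$loa_low <- ba$loa_low
  icc$loa_high <- ba$loa_high
  icc
}

#' @export
print.vvor_agreement <- function(x, ...) {
  cat(sprintf("<vvor_agreement> %d pairs\n", x$n_pairs))
  if (!is.na(x$icc))
    cat(sprintf("  ICC = %.4f (95%% CI %.4f-%.4f) [%s]\n",
                x$icc, x$icc_ci_low, x$icc_ci_high, x$icc_form))
  if (!is.na(x$bias))
    cat(sprintf("  bias = %.4f, limits of agreement [%.4f, %.4f]\n",
                x$bias, x$loa_low, x$loa_high))
  invisible(x)
}
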