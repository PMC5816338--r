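#' Construct a head/eye velocity trace
#'
#' The unit of analysis: time-aligned head and eye angular-velocity series
#' from a VVOR recording, with sampling metadata.
#'
#' @param t Numeric vector of time stamps in seconds, strictly increasing.
#' @param head_vel Head angular velocity in deg/s, same length as `t`.
#' @param eye_vel Eye angular velocity in deg/s, same length as `t`.
#' @param sample_rate Nominal sampling rate in Hz. If `NULL`, inferred from
#'   the median inter-sample interval.
#' @param source Free-text provenance string.
#' @param labels Length-2 character vector naming the positive and negative
#'   head-movement directions. Defaults to neutral labels; set via
#'   [apply_sign_convention()] when device laterality is known.
#'
#' @return An object of class `vvor_trace`: a list with elements `t`,
#'   `head_vel`, `eye_vel`, `sample_rate`, `source`, `labels`.
#' @export
#' @examples
#' t <- seq(0, 2, by = 0.01)
#' tr <- velocity_trace(t, 100 * sin(2 * pi * t), -100 * sin(2 * pi * t))
#' tr
velocity_trace <- function(t, head_vel, eye_vel, sample_rate = NULL,
                           source = "unspecified",
                           labels = c("positive-direction", "negative-direction")) {
  t <- as.numeric(t)
  head_vel <- as.numeric(head_vel)
  eye_vel <- as.numeric(eye_vel)
  n <- length(t)
  if (n < 2L || length(head_vel) != n || length(eye_vel) != n)
    vvor_stop("t, head_vel and eye_vel must have identical length >= 2",
              "vvor_malformed_error")
  if (anyNA(t) || anyNA(head_vel) || anyNA(eye_vel))
    vvor_stop("velocity trace contains missing values", "vvor_malformed_error")
  dt <- diff(t)
  if (any(dt <= 0))
    vvor_stop("time stamps must be strictly increasing", "vvor_malformed_error")
  med_dt <- stats::median(dt)
  if (is.null(sample_rate)) {
    sample_rate <- 1 / med_dt
  } else {
    if (!is_number(sample_rate) || sample_rate <= 0)
      vvor_stop("sample_rate must be a positive number", "vvor_parameter_error")
    if (abs(med_dt - 1 / sample_rate) > 0.2 / sample_rate)
      vvor_stop(sprintf(
        "median inter-sample interval %.4g s is not within 20%% of 1/sample_rate (%.4g s)",
        med_dt, 1 / sample_rate), "vvor_malformed_error")
  }
  structure(list(t = t, head_vel = head_vel, eye_vel = eye_vel,
                 sample_rate = sample_rate, source = source,
                 labels = labels),
            class = "vvor_trace")
}

#' @export
print.vvor_trace <- function(x, ...) {
  cat(sprintf("<vvor_trace> %d samples, %.2f s at %.1f Hz nominal\n",
              length(x$t), diff(range(x$t)), x$sample_rate))
  cat(sprintf("  head velocity: [%.1f, %.1f] deg/s\n",
              min(x$head_vel), max(x$head_vel)))
  cat(sprintf("  eye velocity:  [%.1f, %.1f] deg/s\n",
              min(x$eye_vel), max(x$eye_vel)))
  cat(sprintf("  source: %s\n", x$source))
  invisible(x)
}

trace_duration <- function(trace) diff(range(trace$t))

# Subset a trace by an index vector, preserving metadata.
trace_subset <- function(trace, idx, rebase = FALSE) {
  t <- trace$t[idx]
  if (rebase) t <- t - t[1]
  velocity_trace(t, trace$head_vel[idx], trace$eye_vel[idx],
                 sample_rate = trace$sample_rate, source = trace$source,
                 labels = trace$labels)
}
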