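#' Median-filter (desaccading) parameters
#'
#' @param n Window length in samples (not milliseconds); its effect on the
#'   trace therefore depends on the sampling rate. Default 30, chosen for
#'   ~220 Hz goggle recordings: shorter windows leave fast phases in the
#'   filtered trace, longer ones flatten the compensatory response.
#' @param edge_mode Edge handling: `"zero-pad"` (the behaviour of the
#'   classical medfilt1 routine; default) or `"reflect"`, which mirrors the
#'   signal at its ends and produces a smaller edge transient.
#' @return An object of class `desaccade_params`.
#' @export
desaccade_params <- function(n = 30, edge_mode = c("zero-pad", "reflect")) {
  edge_mode <- match.arg(edge_mode)
  if (!is_number(n) || n < 3 || n != round(n))
    vvor_stop("filter window n must be an integer >= 3", "vvor_parameter_error")
  structure(list(n = as.integer(n), edge_mode = edge_mode),
            class = "desaccade_params")
}

#' Sign convention for head and eye channels
#'
#' Some goggle systems record rightward head movement as negative velocity
#' and laterality is often undocumented. Directional outputs are therefore
#' labelled neutrally ("positive-direction"/"negative-direction") unless the
#' user asserts device laterality via the label arguments.
#'
#' @param invert_head,invert_eye Multiply the channel by -1 before analysis.
#' @param positive_label,negative_label Labels attached to directional
#'   outputs (e.g. "rightward"/"leftward" when laterality is known).
#' @return An object of class `sign_convention`.
#' @export
sign_convention <- function(invert_head = FALSE, invert_eye = FALSE,
                            positive_label = "positive-direction",
                            negative_label = "negative-direction") {
  structure(list(invert_head = isTRUE(invert_head),
                 invert_eye = isTRUE(invert_eye),
                 positive_label = as.character(positive_label),
                 negative_label = as.character(negative_label)),
            class = "sign_convention")
}

#' Apply a sign convention to a trace
#'
#' @param trace A [velocity_trace()].
#' @param conv A [sign_convention()].
#' @return The trace with channels flipped per the convention and direction
#'   labels propagated to downstream outputs.
#' @export
apply_sign_convention <- function(trace, conv = sign_convention()) {
  h <- if (conv$invert_head) -trace$head_vel else trace$head_vel
  e <- if (conv$invert_eye) -trace$eye_vel else trace$eye_vel
  velocity_trace(trace$t, h, e, sample_rate = trace$sample_rate,
                 source = trace$source,
                 labels = c(conv$positive_label, conv$negative_label))
}

#' Select the analysis window
#'
#' Discards the first second of the recording (test onset, examiner
#' settling) and returns the following `duration` seconds, with time stamps
#' re-based to start at 0. A 10-s window is the default analysis size. If
#' the recording is too short for the requested window the full post-discard
#' trace is returned with a warning.
#'
#' @param trace A [velocity_trace()].
#' @param duration Window length in seconds (default 10).
#' @return A [velocity_trace()] covering the window.
#' @export
select_window <- function(trace, duration = 10) {
  if (!is_number(duration) || duration <= 0)
    vvor_stop("duration must be a positive number", "vvor_parameter_error")
  total <- trace_duration(trace)
  if (total < 2)
    vvor_stop("recording shorter than 2 s cannot be windowed",
              "vvor_tooshort_error")
  t0 <- trace$t[1] + 1
  if (total - 1 >= duration) {
    idx <- which(trace$t >= t0 & trace$t < t0 + duration)
  } else {
    warning(sprintf(
      "select_window: %.2f s available after onset discard, < requested %.2f s; using full remainder",
      total - 1, duration))
    idx <- which(trace$t >= t0)
  }
  trace_subset(trace, idx, rebase = TRUE)
}

#' One-dimensional median filter
#'
#' Windowed median with the classical asymmetric window for even lengths:
#' output `y(i)` is the median of `x` over indices `[i - n/2, i + n/2 - 1]`
#' for even `n`, and the centred window for odd `n`. The median of an even
#' count of samples is the mean of the two middle order statistics. Edges
#' are handled by zero-padding (default) or reflection.
#'
#' @param x Numeric vector.
#' @param n Window length in samples.
#' @param edge_mode `"zero-pad"` or `"reflect"`.
#' @return Filtered vector, same length as `x`.
#' @export
median_filter_1d <- function(x, n, edge_mode = c("zero-pad", "reflect")) {
  edge_mode <- match.arg(edge_mode)
  N <- length(x)
  if (n > N)
    vvor_stop("filter window n exceeds signal length", "vvor_parameter_error")
  if (n %% 2 == 0) { lo <- -n %/% 2; hi <- n %/% 2 - 1L }
  else             { lo <- -(n - 1L) %/% 2; hi <- (n - 1L) %/% 2 }
  pad <- max(-lo, hi)
  xp <- switch(edge_mode,
    "zero-pad" = c(rep(0, pad), x, rep(0, pad)),
    "reflect"  = c(rev(x[seq_len(pad)]), x, rev(x[(N - pad + 1L):N]))
  )
  # rows of m are the filter windows: m[i, ] = xp over [i + lo, i + hi]
  centre <- seq_len(N) + pad
  m <- vapply(lo:hi, function(o) xp[centre + o], numeric(N))
  apply(m, 1L, stats::median)
}

#' Desaccade the eye-velocity channel
#'
#' Removes nystagmus fast phases from the eye channel with a one-dimensional
#' median filter, leaving the smooth compensatory component. The saccadic
#' residual (raw minus filtered eye velocity) is retained for saccade
#' detection. The head channel is untouched.
#'
#' @param trace A [velocity_trace()].
#' @param params A [desaccade_params()].
#' @return An object of class `vvor_desaccaded`: list with `base` (the input
#'   trace), `eye_filtered`, `residual` and `params`.
#' @export
#' @examples
#' sim <- simulate_vvor(vvor_preset("unilateral", seed = 1))
#' d <- desaccade(sim$trace)
#' d
desaccade <- function(trace, params = desaccade_params()) {
  if (length(trace$t) < params$n)
    vvor_stop("trace shorter than the filter window", "vvor_parameter_error")
  ef <- median_filter_1d(trace$eye_vel, params$n, params$edge_mode)
  structure(list(base = trace, eye_filtered = ef,
                 residual = trace$eye_vel - ef, params = params),
            class = "vvor_desaccaded")
}

#' @export
print.vvor_desaccaded <- function(x, ...) {
  cat(sprintf("<vvor_desaccaded> n=%d (%s), %d samples\n",
              x$params$n, x$params$edge_mode, length(x$eye_filtered)))
  cat(sprintf("  max |residual| = %.1f deg/s\n", max(abs(x$residual))))
  invisible(x)
}
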