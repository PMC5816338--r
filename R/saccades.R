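#' Saccade-detection parameters
#'
#' The detection thresholds are physiological defaults, exposed as explicit,
#' auditable configuration (every report records them): fast phases reach
#' hundreds of deg/s, far above smooth-response residuals, and consecutive
#' saccades are separated by a refractory interval of tens of milliseconds.
#'
#' @param min_peak_height Minimum residual amplitude in deg/s (default 30).
#' @param min_separation Minimum interval between detected peaks in seconds
#'   (default 0.05); when two candidates are closer, the larger survives.
#' @param detect_both_polarities Count leftward and rightward fast phases
#'   alike by detecting on |residual| (default `TRUE`); polarity is recorded
#'   per event.
#' @return An object of class `saccade_params`.
#' @export
saccade_params <- function(min_peak_height = 30, min_separation = 0.05,
                           detect_both_polarities = TRUE) {
  if (!is_number(min_peak_height) || min_peak_height <= 0)
    vvor_stop("min_peak_height must be > 0", "vvor_parameter_error")
  if (!is_number(min_separation) || min_separation <= 0)
    vvor_stop("min_separation must be > 0", "vvor_parameter_error")
  structure(list(min_peak_height = min_peak_height,
                 min_separation = min_separation,
                 detect_both_polarities = isTRUE(detect_both_polarities)),
            class = "saccade_params")
}

#' Detect fast-phase saccades in the desaccading residual
#'
#' Saccades appear in the residual (raw minus median-filtered eye velocity)
#' as brief high-velocity peaks. Local maxima of |residual| (or of the
#' positive residual only, if `detect_both_polarities` is off) with height
#' at least `min_peak_height` and mutual separation at least
#' `min_separation` are counted; of two conflicting candidates the larger
#' survives. Peaks inside the median filter's edge transient (the first and
#' last `n` samples, where the padded window distorts the filter output) are
#' excluded as filter artifacts.
#'
#' @param dtrace A `vvor_desaccaded` object.
#' @param params A [saccade_params()].
#' @return An object of class `vvor_saccades`: `peak_times` (s),
#'   `peak_amplitudes` (signed residual, deg/s), `polarity`, `total_count`,
#'   `per_second` (count / analysed duration) and `per_cycle` (`NA` until
#'   [saccades_per_cycle()] supplies the stimulation frequency). Zero
#'   detections is a valid outcome.
#' @export
detect_saccades <- function(dtrace, params = saccade_params()) {
  stopifnot(inherits(dtrace, "vvor_desaccaded"))
  t <- dtrace$base$t
  res <- dtrace$residual
  sig <- if (params$detect_both_polarities) abs(res) else pmax(res, 0)
  fs <- dtrace$base$sample_rate
  min_dist <- max(1L, as.integer(ceiling(params$min_separation * fs)))
  pk <- pracma::findpeaks(sig, minpeakheight = params$min_peak_height,
                          minpeakdistance = min_dist)
  idx <- if (is.null(pk)) integer(0) else sort(pk[, 2])
  guard <- dtrace$params$n
  idx <- idx[idx > guard & idx <= length(sig) - guard]
  duration <- diff(range(t))
  structure(list(peak_times = t[idx], peak_amplitudes = res[idx],
                 polarity = sign(res[idx]), total_count = length(idx),
                 per_second = length(idx) / duration, per_cycle = NA_real_,
                 params = params, duration = duration),
            class = "vvor_saccades")
}

#' Express the saccade rate per stimulation cycle
#'
#' Combines the saccade rate with the dominant head-oscillation frequency:
#' saccades per cycle = saccades per second / dominant frequency.
#'
#' @param summary A `vvor_saccades` object from [detect_saccades()].
#' @param spectral A `vvor_spectrum` object from [fft_spectrum()].
#' @return `summary` with `per_cycle` filled in.
#' @export
saccades_per_cycle <- function(summary, spectral) {
  if (missing(spectral) || !inherits(spectral, "vvor_spectrum"))
    vvor_stop("a spectral result is required to express saccades per cycle",
              "vvor_dependency_error")
  if (!is_number(spectral$dominant_freq) || spectral$dominant_freq <= 0)
    vvor_stop("dominant frequency must be positive", "vvor_dependency_error")
  summary$per_cycle <- summary$per_second / spectral$dominant_freq
  summary
}

#' @export
print.vvor_saccades <- function(x, ...) {
  cat(sprintf("<vvor_saccades> %d event(s) in %.2f s (%.2f /s",
              x$total_count, x$duration, x$per_second))
  if (!is.na(x$per_cycle)) cat(sprintf(", %.2f /cycle", x$per_cycle))
  cat(")\n")
  invisible(x)
}

#' Peak head and eye velocity
#'
#' @param trace A [velocity_trace()] (or `vvor_desaccaded`, whose raw base
#'   trace is used).
#' @return List with `head` and `eye`: maximum absolute velocity in deg/s
#'   over the analysed window.
#' @export
peak_velocities <- function(trace) {
  if (inherits(trace, "vvor_desaccaded")) trace <- trace$base
  list(head = max(abs(trace$head_vel)), eye = max(abs(trace$eye_vel)))
}
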