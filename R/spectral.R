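#' Amplitude spectrum and dominant stimulation frequency
#'
#' Computes the one-sided amplitude spectrum (|DFT| * 2/N, rectangular
#' window, no zero-padding) of the head and eye velocity channels. The
#' dominant frequency is the bin of maximal head amplitude, searched above
#' `min_freq` so that slow examiner drift cannot masquerade as the stimulus;
#' ties break toward the lowest frequency. The head channel contains no
#' saccades, so the dominant frequency is insensitive to whether the raw or
#' desaccaded eye channel accompanies it.
#'
#' @param trace A [velocity_trace()] or a `vvor_desaccaded` object.
#' @param use_raw_eye For a desaccaded input, use the raw (`TRUE`, default)
#'   or median-filtered (`FALSE`) eye channel for the eye spectrum.
#' @param min_freq Lower bound (Hz) of the dominance search; default 0.2.
#' @return An object of class `vvor_spectrum`: list with `freqs` (Hz,
#'   one-sided including DC), `head_amp`, `eye_amp`, `dominant_freq` (Hz)
#'   and `bin_width` (Hz, = 1/duration).
#' @export
#' @examples
#' sim <- simulate_vvor(vvor_preset("healthy", seed = 1))
#' sp <- fft_spectrum(sim$trace)
#' sp$dominant_freq
fft_spectrum <- function(trace, use_raw_eye = TRUE, min_freq = 0.2) {
  if (inherits(trace, "vvor_desaccaded")) {
    eye <- if (use_raw_eye) trace$base$eye_vel else trace$eye_filtered
    trace <- trace$base
  } else {
    eye <- trace$eye_vel
  }
  N <- length(trace$t)
  if (N < 64L)
    vvor_stop("at least 64 samples are required for spectral analysis",
              "vvor_tooshort_error")
  dt <- stats::median(diff(trace$t))
  k <- 0:(N %/% 2)
  freqs <- k / (N * dt)
  amp <- function(x) (2 / N) * Mod(stats::fft(x))[k + 1L]
  head_amp <- amp(trace$head_vel)
  eye_amp <- amp(eye)
  search <- which(freqs >= min_freq & k > 0)
  if (length(search) == 0L)
    vvor_stop("no frequency bins above min_freq", "vvor_tooshort_error")
  dominant <- freqs[search[which.max(head_amp[search])]]
  structure(list(freqs = freqs, head_amp = head_amp, eye_amp = eye_amp,
                 dominant_freq = dominant, bin_width = 1 / (N * dt)),
            class = "vvor_spectrum")
}

#' @export
print.vvor_spectrum <- function(x, ...) {
  cat(sprintf("<vvor_spectrum> %d bins, resolution %.3f Hz\n",
              length(x$freqs), x$bin_width))
  cat(sprintf("  dominant head frequency: %.3f Hz\n", x$dominant_freq))
  invisible(x)
}
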