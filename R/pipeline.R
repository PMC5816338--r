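#' Assemble the configuration for a full analysis
#'
#' @param dialect A [csv_dialect()].
#' @param window_seconds Analysis-window length, s (default 10).
#' @param desaccade A [desaccade_params()].
#' @param saccade A [saccade_params()].
#' @param sign A [sign_convention()].
#' @param method Gain method(s): `"both"`, `"auc"` or `"scp"`. The report
#'   writer requires both, so `"both"` is needed for [write_report()].
#' @param min_freq Lower bound of the spectral dominance search, Hz.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(dialect = csv_dialect(), window_seconds = 10,
                            desaccade = desaccade_params(),
                            saccade = saccade_params(),
                            sign = sign_convention(),
                            method = c("both", "auc", "scp"),
                            min_freq = 0.2) {
  method <- match.arg(method)
  stopifnot(inherits(dialect, "csv_dialect"),
            inherits(desaccade, "desaccade_params"),
            inherits(saccade, "saccade_params"),
            inherits(sign, "sign_convention"))
  if (!is_number(window_seconds) || window_seconds <= 0)
    vvor_stop("window_seconds must be positive", "vvor_parameter_error")
  structure(list(dialect = dialect, window_seconds = window_seconds,
                 desaccade = desaccade, saccade = saccade, sign = sign,
                 method = method, min_freq = min_freq),
            class = "analysis_config")
}

config_as_list <- function(config) {
  list(
    window_seconds = config$window_seconds,
    filter_window = config$desaccade$n,
    edge_mode = config$desaccade$edge_mode,
    saccade_min_height = config$saccade$min_peak_height,
    saccade_min_separation = config$saccade$min_separation,
    detect_both_polarities = config$saccade$detect_both_polarities,
    invert_head = config$sign$invert_head,
    invert_eye = config$sign$invert_eye,
    positive_label = config$sign$positive_label,
    negative_label = config$sign$negative_label,
    min_freq = config$min_freq,
    method = config$method
  )
}

#' Analyse an in-memory velocity trace
#'
#' Runs the fixed pipeline on a trace that is already in memory: window
#' selection, sign convention, desaccading, directional gains by the
#' requested method(s), head-frequency spectrum, saccade detection and the
#' per-second / per-cycle saccade metrics, plus peak velocities.
#'
#' @param trace A [velocity_trace()].
#' @param config An [analysis_config()].
#' @return An object of class `vvor_analysis`.
#' @export
#' @examples
#' sim <- simulate_vvor(vvor_preset("healthy", seed = 1))
#' analyze_trace(sim$trace)
analyze_trace <- function(trace, config = analysis_config()) {
  win <- select_window(trace, config$window_seconds)
  win <- apply_sign_convention(win, config$sign)
  dtr <- desaccade(win, config$desaccade)
  gain_auc <- if (config$method %in% c("both", "auc")) auc_gain(dtr) else NULL
  gain_scp <- if (config$method %in% c("both", "scp")) scp_gain(dtr) else NULL
  spect <- fft_spectrum(dtr, min_freq = config$min_freq)
  sacc <- detect_saccades(dtr, config$saccade)
  sacc <- saccades_per_cycle(sacc, spect)
  structure(list(
    input = trace$source,
    parameters = config_as_list(config),
    window = win, desaccaded = dtr,
    gain_auc = gain_auc, gain_scp = gain_scp,
    spectral = spect, saccades = sacc,
    peak_velocities = peak_velocities(win)
  ), class = "vvor_analysis")
}

#' Run the full analysis pipeline on a CSV recording
#'
#' Reads the last VVOR test from `input`, runs [analyze_trace()] under the
#' configuration, and (optionally) writes the machine-readable report. The
#' pipeline is a pure function of the input file and configuration: reports
#' contain no clock or locale dependence and identical runs produce
#' byte-identical files.
#'
#' @param input Path to a CSV recording.
#' @param config An [analysis_config()].
#' @param output Optional report path for [write_report()].
#' @return A `vvor_analysis` object, invisibly when `output` is given.
#' @export
run_analyze <- function(input, config = analysis_config(), output = NULL) {
  trace <- read_vvor_csv(input, config$dialect)
  res <- analyze_trace(trace, config)
  if (!is.null(output)) {
    write_report(res, output)
    return(invisible(res))
  }
  res
}

#' @export
print.vvor_analysis <- function(x, ...) {
  cat("<vvor_analysis>\n")
  cat(sprintf("  input: %s\n", x$input))
  if (!is.null(x$gain_auc))
    cat(sprintf("  G_AUCp = %.3f  G_AUCn = %.3f\n",
                x$gain_auc$g_pos, x$gain_auc$g_neg))
  if (!is.null(x$gain_scp))
    cat(sprintf("  G_SPp  = %.3f  G_SPn  = %.3f\n",
                x$gain_scp$g_pos, x$gain_scp$g_neg))
  cat(sprintf("  dominant frequency: %.2f Hz\n", x$spectral$dominant_freq))
  cat(sprintf("  saccades: %d (%.2f /s, %.2f /cycle)\n",
              x$saccades$total_count, x$saccades$per_second,
              x$saccades$per_cycle))
  cat(sprintf("  peak velocity: head %.1f, eye %.1f deg/s\n",
              x$peak_velocities$head, x$peak_velocities$eye))
  invisible(x)
}
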