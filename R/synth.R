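#' Parameters for the synthetic VVOR trace generator
#'
#' The generator emulates the clinical VVOR protocol: an examiner oscillates
#' the head sinusoidally at 1--2 Hz to a peak velocity of 150--200 deg/s
#' while the goggle records head and eye angular velocity. The defaults
#' encode that protocol (20-s recording at a 220 Hz nominal goggle rate,
#' 1.5 Hz oscillation, 150 deg/s peak). Manual oscillation is not perfectly
#' periodic, so each half-cycle period is jittered multiplicatively;
#' measurement noise is additive white noise on the eye channel (2 deg/s SD
#' by default, typical of video-oculography velocity traces).
#'
#' @param duration Recording length, s.
#' @param sample_rate Sampling rate, Hz.
#' @param freq Nominal head-oscillation frequency, Hz (protocol range 1--2).
#' @param peak_head_vel Peak head velocity, deg/s (protocol 150--200).
#' @param g_pos,g_neg True directional gains in \[0, 1.2\].
#' @param saccades_per_cycle Expected injected fast phases per oscillation
#'   cycle.
#' @param saccade_amp Fast-phase peak velocity, deg/s.
#' @param saccade_width Fast-phase duration, s; the Gaussian velocity pulse
#'   spans roughly plus/minus two SD, so its SD is `saccade_width / 4`.
#' @param noise_sd SD of additive white measurement noise on the eye
#'   channel, deg/s.
#' @param freq_jitter SD of the log-normal cycle-to-cycle period jitter
#'   (examiner imperfection); each half-cycle period is multiplied by
#'   `exp(e)`, `e ~ Normal(0, freq_jitter)`.
#' @param seed Random seed; identical seeds give identical traces.
#' @return An object of class `synth_params`.
#' @export
synth_params <- function(duration = 20, sample_rate = 220, freq = 1.5,
                         peak_head_vel = 150, g_pos = 1, g_neg = 1,
                         saccades_per_cycle = 0, saccade_amp = 150,
                         saccade_width = 0.04, noise_sd = 2,
                         freq_jitter = 0.03, seed = NULL) {
  if (duration * freq < 5)
    vvor_stop("recording must span at least 5 oscillation cycles",
              "vvor_parameter_error")
  if (sample_rate < 20 * freq)
    vvor_stop("sample_rate must be at least 20x the oscillation frequency",
              "vvor_parameter_error")
  if (peak_head_vel <= 0 || saccade_amp < 0 || saccade_width < 0 ||
      noise_sd < 0 || freq_jitter < 0 || saccades_per_cycle < 0)
    vvor_stop("velocities, widths, rates and SDs must be non-negative",
              "vvor_parameter_error")
  if (g_pos < 0 || g_pos > 1.2 || g_neg < 0 || g_neg > 1.2)
    vvor_stop("true gains must lie in [0, 1.2]", "vvor_parameter_error")
  structure(list(duration = duration, sample_rate = sample_rate, freq = freq,
                 peak_head_vel = peak_head_vel, g_pos = g_pos, g_neg = g_neg,
                 saccades_per_cycle = saccades_per_cycle,
                 saccade_amp = saccade_amp, saccade_width = saccade_width,
                 noise_sd = noise_sd, freq_jitter = freq_jitter, seed = seed),
            class = "synth_params")
}

#' Pathology presets for the synthetic generator
#'
#' Returns a [synth_params()] whose directional gains, saccade rate and
#' oscillation frequency represent a clinical group: `"healthy"` (gains
#' 1.00/1.00, no fast phases, 1.52 Hz), `"bilateral"` vestibulopathy
#' (0.84/0.82, 3 saccades/cycle, 1.0 Hz), `"unilateral"` vestibular
#' hypofunction (0.85 on the intact side, 0.69 on the lesioned side, 2
#' saccades/cycle, 1.76 Hz) and `"canvas"` (cerebellar ataxia, neuropathy
#' and vestibular areflexia syndrome: 0.45/0.40, 4 saccades/cycle, 1.35 Hz).
#'
#' @param name One of `"healthy"`, `"bilateral"`, `"unilateral"`, `"canvas"`.
#' @param ... Overrides passed on to [synth_params()] (e.g. `seed`).
#' @return A [synth_params()] object.
#' @export
vvor_preset <- function(name, ...) {
  presets <- list(
    healthy    = list(g_pos = 1.00, g_neg = 1.00, saccades_per_cycle = 0, freq = 1.52),
    bilateral  = list(g_pos = 0.84, g_neg = 0.82, saccades_per_cycle = 3, freq = 1.00),
    unilateral = list(g_pos = 0.85, g_neg = 0.69, saccades_per_cycle = 2, freq = 1.76),
    canvas     = list(g_pos = 0.45, g_neg = 0.40, saccades_per_cycle = 4, freq = 1.35)
  )
  if (!is.character(name) || length(name) != 1L || !name %in% names(presets))
    vvor_stop(sprintf("unknown preset '%s' (use healthy, bilateral, unilateral or canvas)",
                      as.character(name)[1]), "vvor_parameter_error")
  do.call(synth_params, utils::modifyList(presets[[name]], list(...)))
}

#' Simulate a VVOR recording with known ground truth
#'
#' Head velocity is a sinusoid of the configured peak velocity whose
#' half-cycle periods are jittered to mimic manual oscillation. The smooth
#' eye component is `-g * head`, with `g_pos` during positive and `g_neg`
#' during negative head movement. Fast phases are injected as Gaussian
#' velocity pulses oriented in the catch-up (compensatory) direction for
#' gains below 1 and in the backup (anti-compensatory) direction for gains
#' above 1, with per-half-cycle counts drawn to match `saccades_per_cycle`
#' and centres kept at least 30 ms from head-velocity zero crossings so the
#' ground truth stays unambiguous after median filtering. White noise is
#' added to the eye channel last, so the same seed yields the same stimulus
#' and saccade placement at any noise level.
#'
#' @param params A [synth_params()] or [vvor_preset()] object.
#' @return A list of class `vvor_sim`: `trace` (a [velocity_trace()]) and
#'   `truth` (true gains, nominal frequency, injected saccade times and
#'   count, and the parameters).
#' @export
#' @examples
#' sim <- simulate_vvor(vvor_preset("canvas", seed = 42))
#' sim$truth$saccade_count
simulate_vvor <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  p <- params
  dt <- 1 / p$sample_rate
  t <- seq(0, p$duration, by = dt)
  N <- length(t)

  # jittered half-cycle periods covering the full recording
  th <- 1 / (2 * p$freq)
  K <- ceiling(p$duration / (th * 0.6)) + 4L
  periods <- th * exp(stats::rnorm(K, 0, p$freq_jitter))
  bounds <- c(0, cumsum(periods))
  k <- findInterval(t, bounds, rightmost.closed = FALSE)
  phase <- (k - 1) * pi + pi * (t - bounds[k]) / periods[k]
  head <- p$peak_head_vel * sin(phase)

  g <- ifelse(head > 0, p$g_pos, p$g_neg)
  eye <- -g * head

  # fast-phase injection, per half-cycle
  sac_times <- numeric(0)
  if (p$saccades_per_cycle > 0) {
    per_half <- p$saccades_per_cycle / 2
    sigma <- p$saccade_width / 4  # pulse spans ~ +/- 2 SD = saccade_width
    margin <- 0.03
    for (kk in seq_len(K)) {
      if (bounds[kk + 1] > p$duration) break
      n_k <- floor(per_half) + stats::rbinom(1, 1, per_half - floor(per_half))
      if (n_k == 0) next
      lo <- bounds[kk] + margin
      hi <- bounds[kk + 1] - margin
      if (hi <= lo) next
      slot <- (hi - lo) / n_k
      centres <- lo + (seq_len(n_k) - 0.5) * slot +
        stats::runif(n_k, -0.1, 0.1) * slot
      s_head <- if (kk %% 2 == 1) 1 else -1     # head sign in this half-cycle
      g_dir <- if (s_head > 0) p$g_pos else p$g_neg
      orient <- if (g_dir > 1) s_head else -s_head  # backup vs catch-up
      for (cc in centres) {
        win <- which(abs(t - cc) <= 5 * sigma)
        eye[win] <- eye[win] +
          orient * p$saccade_amp * exp(-(t[win] - cc)^2 / (2 * sigma^2))
      }
      sac_times <- c(sac_times, centres)
    }
  }
  if (p$noise_sd > 0) eye <- eye + stats::rnorm(N, 0, p$noise_sd)

  trace <- velocity_trace(t, head, eye, sample_rate = p$sample_rate,
                          source = sprintf("simulate_vvor(seed=%s)",
                                           if (is.null(p$seed)) "NULL" else p$seed))
  truth <- list(g_pos = p$g_pos, g_neg = p$g_neg, freq = p$freq,
                saccade_times = sort(sac_times),
                saccade_count = length(sac_times), params = p)
  structure(list(trace = trace, truth = truth), class = "vvor_sim")
}

#' @export
print.vvor_sim <- function(x, ...) {
  cat(sprintf("<vvor_sim> true gains %.2f/%.2f at %.2f Hz, %d injected saccade(s)\n",
              x$truth$g_pos, x$truth$g_neg, x$truth$freq,
              x$truth$saccade_count))
  print(x$trace)
  invisible(x)
}

#' Write a velocity trace (or several test blocks) as a CSV fixture
#'
#' Emits a file readable by [read_vvor_csv()] under the same dialect. A list
#' of traces is written as consecutive test blocks; the dialect must then
#' configure a `test_marker` column, which receives the block number, and
#' [read_vvor_csv()] will return the last block.
#'
#' @param trace A [velocity_trace()] or a list of them (one per test block).
#' @param path Output path.
#' @param dialect A [csv_dialect()]; columns must be referenced by name.
#' @return `path`, invisibly.
#' @export
write_fixture_csv <- function(trace, path, dialect = csv_dialect()) {
  traces <- if (inherits(trace, "vvor_trace")) list(trace) else trace
  stopifnot(all(vapply(traces, inherits, TRUE, "vvor_trace")))
  if (!is.character(dialect$column_time))
    vvor_stop("write_fixture_csv requires named columns in the dialect",
              "vvor_config_error")
  if (length(traces) > 1L && is.null(dialect$test_marker))
    vvor_stop("writing multiple test blocks requires a test_marker column",
              "vvor_config_error")
  blocks <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    df <- data.frame(tr$t, tr$head_vel, tr$eye_vel, check.names = FALSE)
    names(df) <- c(dialect$column_time, dialect$column_head, dialect$column_eye)
    if (!is.null(dialect$test_marker)) df[[dialect$test_marker]] <- i
    df
  })
  df <- do.call(rbind, blocks)
  tryCatch(
    utils::write.table(df, path, sep = dialect$delimiter,
                       dec = dialect$decimal_mark, row.names = FALSE,
                       col.names = TRUE, quote = FALSE),
    error = function(e)
      vvor_stop(sprintf("cannot write fixture: %s", conditionMessage(e)),
                "vvor_io_error"))
  invisible(path)
}
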