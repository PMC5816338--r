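# Independent brute-force oracles, kept deliberately naive so they share no
# code path with the implementation they check.

# windowed median by explicit sort over each window
brute_median_filter <- function(x, n, edge_mode = "zero-pad") {
  N <- length(x)
  if (n %% 2 == 0) { lo <- -n / 2; hi <- n / 2 - 1 } else {
    lo <- -(n - 1) / 2; hi <- (n - 1) / 2
  }
  pad <- max(abs(lo), hi)
  xp <- if (edge_mode == "zero-pad") c(rep(0, pad), x, rep(0, pad))
        else c(rev(x[1:pad]), x, rev(x[(N - pad + 1):N]))
  out <- numeric(N)
  for (i in seq_len(N)) {
    w <- sort(xp[(i + pad + lo):(i + pad + hi)])
    m <- length(w)
    out[i] <- if (m %% 2 == 1) w[(m + 1) / 2] else (w[m / 2] + w[m / 2 + 1]) / 2
  }
  out
}

# trapezoid sum by explicit loop
brute_trapz <- function(t, y) {
  s <- 0
  for (i in seq_len(length(t) - 1)) s <- s + (t[i + 1] - t[i]) * (y[i] + y[i + 1]) / 2
  s
}

# O(N^2) DFT amplitude spectrum by direct summation
brute_dft_amp <- function(x) {
  N <- length(x)
  ks <- 0:(N %/% 2)
  vapply(ks, function(k) {
    re <- sum(x * cos(-2 * pi * k * (0:(N - 1)) / N))
    im <- sum(x * sin(-2 * pi * k * (0:(N - 1)) / N))
    (2 / N) * sqrt(re^2 + im^2)
  }, 0)
}

# desaccaded container whose filtered eye equals a supplied smooth signal;
# lets gain methods be tested against exact closed forms, bypassing the
# filter's peak-smoothing.
identity_desaccaded <- function(trace, eye_filtered = trace$eye_vel) {
  structure(list(base = trace, eye_filtered = eye_filtered,
                 residual = trace$eye_vel - eye_filtered,
                 params = desaccade_params()),
            class = "vvor_desaccaded")
}

# plain sinusoidal trace without any generator machinery
sine_trace <- function(duration = 10, fs = 100, freq = 1, peak = 100, gain = 1) {
  t <- seq(0, duration, by = 1 / fs)
  velocity_trace(t, peak * sin(2 * pi * freq * t),
                 -gain * peak * sin(2 * pi * freq * t), sample_rate = fs)
}
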