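#' Split a desaccaded trace into directional subsets
#'
#' Directional gain is computed separately for positive and negative head
#' movement. Samples are assigned by the sign of head velocity; samples with
#' head velocity exactly zero carry no directional label and are excluded.
#' Each subset is kept as its contiguous runs (half-cycles); runs shorter
#' than 2 samples are discarded because they span no time.
#'
#' @param dtrace A `vvor_desaccaded` object from [desaccade()].
#' @return An object of class `vvor_directions`: list with `pos_runs` and
#'   `neg_runs`, each a list of integer index vectors into the trace.
#' @export
split_directions <- function(dtrace) {
  stopifnot(inherits(dtrace, "vvor_desaccaded"))
  h <- dtrace$base$head_vel
  runs_of <- function(idx) {
    if (length(idx) == 0L) return(list())
    breaks <- c(0L, which(diff(idx) != 1L), length(idx))
    out <- lapply(seq_len(length(breaks) - 1L), function(k)
      idx[(breaks[k] + 1L):breaks[k + 1L]])
    out[lengths(out) >= 2L]
  }
  pos <- runs_of(which(h > 0))
  neg <- runs_of(which(h < 0))
  if (length(pos) == 0L)
    vvor_stop("no usable runs in the positive head-movement direction",
              "vvor_degenerate_error")
  if (length(neg) == 0L)
    vvor_stop("no usable runs in the negative head-movement direction",
              "vvor_degenerate_error")
  structure(list(pos_runs = pos, neg_runs = neg, labels = dtrace$base$labels),
            class = "vvor_directions")
}

new_gain_result <- function(method, g_pos, g_neg, n_runs_pos, n_runs_neg,
                            labels) {
  structure(list(method = method, g_pos = g_pos, g_neg = g_neg,
                 n_runs_pos = n_runs_pos, n_runs_neg = n_runs_neg,
                 labels = labels),
            class = "vvor_gain")
}

#' @export
print.vvor_gain <- function(x, ...) {
  cat(sprintf("<vvor_gain> method %s\n", x$method))
  cat(sprintf("  %s: %.3f (%d runs)\n", x$labels[1], x$g_pos, x$n_runs_pos))
  cat(sprintf("  %s: %.3f (%d runs)\n", x$labels[2], x$g_neg, x$n_runs_neg))
  invisible(x)
}

# Signed trapezoidal integral of one channel over a set of runs, each run
# integrated against its own time stamps (concatenating runs would fabricate
# trapezoids across the gaps between half-cycles).
sum_run_integrals <- function(t, y, runs) {
  sum(vapply(runs, function(idx) pracma::trapz(t[idx], y[idx]), 0))
}

#' Directional VVOR gain by area under the curve
#'
#' For each head-movement direction, head velocity and desaccaded eye
#' velocity are integrated run-by-run by the trapezoidal rule over the
#' actual time stamps; the gain is minus the ratio of the summed eye and
#' head integrals, so a compensatory response (eye opposing head) yields a
#' positive gain. Anti-compensatory responses yield negative gain and are
#' reported as such, never clipped.
#'
#' @param dtrace A `vvor_desaccaded` object.
#' @return A `vvor_gain` result with method `"AUC"` (fields `g_pos` =
#'   G_AUCp, `g_neg` = G_AUCn).
#' @export
#' @examples
#' sim <- simulate_vvor(vvor_preset("healthy", seed = 1))
#' auc_gain(desaccade(select_window(sim$trace)))
auc_gain <- function(dtrace) {
  dirs <- split_directions(dtrace)
  t <- dtrace$base$t
  h <- dtrace$base$head_vel
  e <- dtrace$eye_filtered
  gain_for <- function(runs, label) {
    hi <- sum_run_integrals(t, h, runs)
    if (abs(hi) < 1e-9)
      vvor_stop(sprintf("head-velocity integral degenerate in the %s direction",
                        label), "vvor_degenerate_error")
    -sum_run_integrals(t, e, runs) / hi
  }
  new_gain_result("AUC",
                  gain_for(dirs$pos_runs, dirs$labels[1]),
                  gain_for(dirs$neg_runs, dirs$labels[2]),
                  length(dirs$pos_runs), length(dirs$neg_runs), dirs$labels)
}

#' Directional VVOR gain by scatter-plot slope
#'
#' For each head-movement direction, desaccaded eye velocity is regressed on
#' head velocity by least squares through the origin (a single-column linear
#' solve: slope = sum(h*e)/sum(h^2)); the gain is minus the slope, so a
#' compensatory response yields a positive gain. An intercept variant is
#' available for sensitivity analysis but is never the default.
#'
#' @param dtrace A `vvor_desaccaded` object.
#' @param intercept If `TRUE`, fit `eye ~ head` with an intercept and use
#'   the slope coefficient.
#' @return A `vvor_gain` result with method `"SCP"` (fields `g_pos` = G_SPp,
#'   `g_neg` = G_SPn).
#' @export
scp_gain <- function(dtrace, intercept = FALSE) {
  dirs <- split_directions(dtrace)
  h <- dtrace$base$head_vel
  e <- dtrace$eye_filtered
  gain_for <- function(runs, label) {
    idx <- unlist(runs)
    if (length(idx) < 3L)
      vvor_stop(sprintf("fewer than 3 samples in the %s direction", label),
                "vvor_degenerate_error")
    hh <- h[idx]; ee <- e[idx]
    if (sum(hh^2) == 0)
      vvor_stop(sprintf("zero head-velocity energy in the %s direction", label),
                "vvor_degenerate_error")
    slope <- if (intercept) {
      stats::coef(stats::lm(ee ~ hh))[["hh"]]
    } else {
      sum(hh * ee) / sum(hh^2)
    }
    -slope
  }
  new_gain_result("SCP",
                  gain_for(dirs$pos_runs, dirs$labels[1]),
                  gain_for(dirs$neg_runs, dirs$labels[2]),
                  length(dirs$pos_runs), length(dirs$neg_runs), dirs$labels)
}
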