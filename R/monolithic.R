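# Scheduling-based monolithic reference implementation of the conduction
# system, reconstructing the original imperative design: a single schedule
# variable tracks the next contraction time, later-entering but
# earlier-acting beats take precedence, and the refractory check is applied
# to the SA signal *before* the conduction delay.

#' Simulate the monolithic conduction model
#'
#' Processes SA events and scheduled contractions in time order with a single
#' scheduling variable `t_sched`:
#' * an SA signal at `t` is accepted iff `t - t_last_accept > d_refrac`
#'   (refractory check before the delay); an accepted signal proposes a
#'   contraction at `t + delay_fn(t - t_last_contraction)` which replaces the
#'   schedule only if it is earlier ("later entering but earlier acting"
#'   beats win);
#' * when the schedule is reached a ventricular contraction is emitted and
#'   the escape fallback is re-armed at `t_contraction + period`.
#'
#' A contraction and an SA signal at the same instant are processed
#' contraction-first.
#'
#' This implementation exists as an equivalence oracle for
#' [build_modular_conduction()]: both produce identical ventricular traces
#' on constant-interval 1:1 protocols; divergences are confined to
#' blocked-beat / escape episodes where the two formulations genuinely
#' differ (the monolithic schedule measures refractoriness and escape
#' timing against different reference events than the modular chain).
#'
#' @param params A [conduction_params()] object (5 scalar parameters).
#' @param sa Numeric vector of SA-node event times (strictly increasing).
#' @param config A [sim_config()].
#' @param delay_fn Optional delay-function override (default: exponential
#'   recovery [av_delay_fn()] from `params$av`).
#' @return `list(v = <ventricular event times>, interbeat = <data frame
#'   time_s, d_interbeat_s>, params = params)`.
#' @export
monolithic_simulate <- function(params, sa = numeric(), config = sim_config(),
                                delay_fn = NULL) {
  stopifnot(inherits(params, "conduction_params"), inherits(config, "sim_config"))
  if (length(sa) && is.unsorted(sa, strictly = TRUE))
    stop("SA trace must be strictly increasing")
  if (is.null(delay_fn)) delay_fn <- av_delay_fn(params$av)
  tol <- config$time_tolerance

  t_sched <- config$t_start + params$period  # escape fallback
  t_last_accept <- -Inf
  t_last_contraction <- -Inf
  v <- numeric()
  i <- 1L
  n <- length(sa)
  repeat {
    t_sa <- if (i <= n) sa[i] else Inf
    t <- min(t_sched, t_sa)
    if (!is.finite(t) || t > config$t_stop + tol) break
    if (t_sched <= t_sa) {
      v <- c(v, t_sched)
      t_last_contraction <- t_sched
      t_sched <- t_last_contraction + params$period
    } else {
      i <- i + 1L
      if (t_sa - t_last_accept > params$d_refrac) {
        t_last_accept <- t_sa
        candidate <- t_sa + delay_fn(t_sa - t_last_contraction)
        if (candidate < t_sched) t_sched <- candidate
      }
    }
  }
  list(v = v, interbeat = extract_interbeat(v), params = params)
}

#' Compare two interbeat series
#'
#' Index-aligned comparison of two interbeat series (data frames with
#' columns `time_s` and `d_interbeat_s`, as produced by
#' [extract_interbeat()] or [interbeat_series()]). Samples are compared up
#' to the shorter length; contiguous runs of samples whose interval
#' difference exceeds `tol` are reported as divergent windows with their
#' time span in series `a`.
#'
#' @param a,b Interbeat series.
#' @param tol Absolute tolerance on the interval difference, seconds.
#' @return An object of class `interbeat_comparison`: list with `n_matched`
#'   (samples within `tol`), `n_compared`, `n_extra` (length difference),
#'   `max_abs_diff`, and `divergences` (data frame `t_start`, `t_end`,
#'   `max_diff` per window).
#' @export
compare_interbeat <- function(a, b, tol = 1e-9) {
  stopifnot(is.data.frame(a), is.data.frame(b), tol >= 0)
  k <- min(nrow(a), nrow(b))
  if (k == 0L) {
    return(structure(
      list(n_matched = 0L, n_compared = 0L, n_extra = abs(nrow(a) - nrow(b)),
           max_abs_diff = 0,
           divergences = data.frame(t_start = numeric(), t_end = numeric(),
                                    max_diff = numeric())),
      class = "interbeat_comparison"))
  }
  d <- abs(a$d_interbeat_s[seq_len(k)] - b$d_interbeat_s[seq_len(k)])
  bad <- d > tol
  windows <- data.frame(t_start = numeric(), t_end = numeric(),
                        max_diff = numeric())
  if (any(bad)) {
    r <- rle(bad)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      idx <- starts[j]:ends[j]
      windows <- rbind(windows, data.frame(
        t_start = a$time_s[starts[j]], t_end = a$time_s[ends[j]],
        max_diff = max(d[idx])))
    }
  }
  structure(
    list(n_matched = sum(!bad), n_compared = k,
         n_extra = abs(nrow(a) - nrow(b)),
         max_abs_diff = max(d), divergences = windows),
    class = "interbeat_comparison"
  )
}

#' @export
print.interbeat_comparison <- function(x, ...) {
  cat(sprintf("<interbeat_comparison> %d/%d samples matched (max |diff| = %.3g s)\n",
              x$n_matched, x$n_compared, x$max_abs_diff))
  if (x$n_extra) cat("  unmatched trailing samples:", x$n_extra, "\n")
  if (nrow(x$divergences)) {
    cat("  divergent windows:\n")
    print(x$divergences, row.names = FALSE)
  } else cat("  no divergences\n")
  invisible(x)
}
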