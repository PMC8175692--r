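# Stimulus protocols, interbeat extraction, conduction-ratio analysis, CSV
# trace I/O, and reproducible experiment runs.

#' SA stimulus protocol with piecewise-constant interval
#'
#' Describes a periodic SA-node drive whose inter-stimulus interval is
#' piecewise constant: `segments` lists the switch times and the interval in
#' force from each switch time onwards. The first switch time must equal
#' `t_start`.
#'
#' @param switch_times Strictly increasing numeric vector; first element
#'   equals `t_start`.
#' @param intervals Positive numeric vector, same length as `switch_times`.
#' @param t_start,t_stop Protocol window, seconds.
#' @return An object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(switch_times, intervals, t_start, t_stop) {
  stopifnot(length(switch_times) == length(intervals),
            length(switch_times) >= 1L,
            all(intervals > 0), t_start <= t_stop)
  if (is.unsorted(switch_times, strictly = TRUE))
    stop("switch_times must be strictly increasing")
  if (switch_times[1L] != t_start)
    stop("first switch time must equal t_start")
  structure(list(switch_times = switch_times, intervals = intervals,
                 t_start = t_start, t_stop = t_stop),
            class = "stimulus_protocol")
}

#' Generate the SA event trace of a protocol
#'
#' The first event is at `t_start`; each subsequent event follows the
#' previous one by the interval in force *at the previous event's time*
#' (a switch takes effect for events issued after it). Events beyond
#' `t_stop` are not generated.
#'
#' @param protocol A [stimulus_protocol()].
#' @return Numeric vector of SA event times.
#' @examples
#' p <- stimulus_protocol(c(0, 2.5), c(1.0, 0.5), t_start = 0, t_stop = 4)
#' generate_sa_stimulus(p)  # 0 1 2 3 3.5 4
#' @export
generate_sa_stimulus <- function(protocol) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  interval_at <- function(t) {
    i <- findInterval(t, protocol$switch_times)
    protocol$intervals[max(i, 1L)]
  }
  t <- protocol$t_start
  out <- t
  repeat {
    nxt <- t + interval_at(t)
    if (nxt > protocol$t_stop + 1e-12) break
    out <- c(out, nxt)
    t <- nxt
  }
  out
}

#' Sample a random interval-switching protocol
#'
#' Emulates an experiment in which the SA interval is switched every five to
#' ten seconds: switch times are spaced uniformly within `switch_gap_range`
#' and each segment's interval is drawn uniformly from `interval_choices`.
#' Fully determined by `seed`; the global RNG state is left untouched.
#'
#' @param seed Integer seed.
#' @param t_start,t_stop Protocol window, seconds.
#' @param interval_choices Non-empty vector of candidate intervals, seconds.
#' @param switch_gap_range Length-2 numeric range of gaps between switches,
#'   seconds (default 5-10 s).
#' @return A [stimulus_protocol()].
#' @export
sample_switching_protocol <- function(seed, t_start, t_stop,
                                      interval_choices,
                                      switch_gap_range = c(5, 10)) {
  stopifnot(length(interval_choices) >= 1L, all(interval_choices > 0),
            length(switch_gap_range) == 2L,
            switch_gap_range[1L] <= switch_gap_range[2L])
  withr::with_seed(as.integer(seed), {
    switches <- t_start
    t <- t_start
    repeat {
      t <- t + stats::runif(1, switch_gap_range[1L], switch_gap_range[2L])
      if (t >= t_stop) break
      switches <- c(switches, t)
    }
    ivals <- interval_choices[sample.int(length(interval_choices),
                                         length(switches), replace = TRUE)]
    stimulus_protocol(switches, ivals, t_start, t_stop)
  })
}

#' Interbeat series of an event trace
#'
#' @param v Numeric vector of contraction times (sorted).
#' @return Data frame with columns `time_s` (time of each contraction from
#'   the second onwards) and `d_interbeat_s` (interval to the previous one).
#' @export
extract_interbeat <- function(v) {
  if (length(v) < 2L)
    return(data.frame(time_s = numeric(), d_interbeat_s = numeric()))
  data.frame(time_s = v[-1L], d_interbeat_s = diff(v))
}

#' Reduced SA:V conduction ratio in a window
#'
#' Counts SA and ventricular events inside `window` (closed interval) and
#' reduces the count pair by their greatest common divisor, e.g. 8 SA and 4
#' V events give 2:1. With no ventricular events the ratio is undefined.
#'
#' @param sa,v Numeric event-time vectors.
#' @param window Length-2 numeric `c(from, to)`.
#' @return List with `n_sa`, `n_v` (reduced counts) and `defined`
#'   (FALSE when no V event lies in the window, in which case `n_sa`/`n_v`
#'   are `NA`).
#' @export
conduction_ratio <- function(sa, v, window) {
  stopifnot(length(window) == 2L, window[1L] <= window[2L])
  n_sa <- sum(sa >= window[1L] & sa <= window[2L])
  n_v <- sum(v >= window[1L] & v <= window[2L])
  if (n_v == 0L)
    return(list(n_sa = NA_integer_, n_v = NA_integer_, defined = FALSE))
  g <- function(a, b) if (b == 0) a else Recall(b, a %% b)
  d <- g(n_sa, n_v)
  list(n_sa = as.integer(n_sa / d), n_v = as.integer(n_v / d), defined = TRUE)
}

# ---------------------------------------------------------------------------
# CSV I/O (dialect: UTF-8, LF, header row, '%.9g' floats, rows sorted by
# time then port name -- diff-friendly and deterministic)

fmt9 <- function(x) sprintf("%.9g", x)

#' Write / read event traces as CSV
#'
#' `write_trace_csv()` writes a named list of event traces to a two-column
#' CSV (`time_s,port`), rows ordered by time then port name, floats
#' formatted `%.9g`. `read_trace_csv()` reads such a file back into a named
#' list and enforces strictly increasing times per port.
#'
#' @param traces Named list of numeric event-time vectors.
#' @param path File path.
#' @return `write_trace_csv()` returns `path` invisibly; `read_trace_csv()`
#'   the named list of traces.
#' @export
write_trace_csv <- function(traces, path) {
  stopifnot(is.list(traces))
  rows <- data.frame(time_s = numeric(), port = character())
  for (nm in names(traces)) {
    tr <- traces[[nm]]
    if (length(tr))
      rows <- rbind(rows, data.frame(time_s = tr, port = nm))
  }
  rows <- rows[order(rows$time_s, rows$port), , drop = FALSE]
  con <- file(path, open = "wb")  # binary: force LF on every platform
  on.exit(close(con))
  writeLines("time_s,port", con, sep = "\n")
  if (nrow(rows))
    writeLines(paste(fmt9(rows$time_s), rows$port, sep = ","), con, sep = "\n")
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), c("time_s", "port")))
    stop("malformed trace CSV (expected header time_s,port): ", path)
  if (nrow(df) == 0L) return(list())
  if (!is.numeric(df$time_s) || anyNA(df$time_s))
    stop("malformed trace CSV (non-numeric times): ", path)
  traces <- split(df$time_s, df$port)
  for (nm in names(traces)) {
    if (is.unsorted(traces[[nm]], strictly = TRUE))
      stop("non-monotone times for port '", nm, "' in ", path)
  }
  traces
}

#' Write an interbeat series as CSV
#'
#' Columns `time_s,d_interbeat_s`, same dialect as [write_trace_csv()].
#'
#' @param interbeat Data frame from [extract_interbeat()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_interbeat_csv <- function(interbeat, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("time_s,d_interbeat_s", con, sep = "\n")
  if (nrow(interbeat))
    writeLines(paste(fmt9(interbeat$time_s), fmt9(interbeat$d_interbeat_s),
                     sep = ","), con, sep = "\n")
  invisible(path)
}

# ---------------------------------------------------------------------------
# Experiment runner

default_experiment_config <- function() {
  list(
    model = "modular",           # modular | monolithic | pvc
    t_start = 0, t_stop = 60, seed = 1L,
    params = list(d_refrac_s = 0.3, period_s = 1.7,
                  av = list(d_min_s = 0.1, d_amp_s = 0.13, tau_s = 0.07),
                  d_refrac_ventricle_s = 0.25),
    stimulus = list(kind = "switching",   # switching | constant | csv | none
                    interval_s = 0.8,
                    interval_choices_s = c(0.5, 0.8, 1.1),
                    switch_gap_range_s = c(5, 10),
                    csv_path = NULL, csv_port = "inp"),
    pvc_times_s = numeric(),
    compare = FALSE, compare_tol_s = 1e-6,
    constant_delay_s = NULL      # set to use a recovery-independent delay
  )
}

read_experiment_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("YAML config requires the 'yaml' package; use JSON instead")
      config <- yaml::read_yaml(config)
    } else {
      config <- jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  stopifnot(is.list(config))
  cfg <- utils::modifyList(default_experiment_config(), config)
  if (!cfg$model %in% c("modular", "monolithic", "pvc"))
    stop("unknown model: ", cfg$model)
  cfg
}

config_params <- function(cfg) {
  p <- cfg$params
  conduction_params(
    d_refrac = p$d_refrac_s, period = p$period_s,
    av = av_delay_params(d_min = p$av$d_min_s, d_amp = p$av$d_amp_s,
                         tau = p$av$tau_s))
}

config_stimulus <- function(cfg) {
  st <- cfg$stimulus
  switch(st$kind,
    none = numeric(),
    constant = generate_sa_stimulus(
      stimulus_protocol(cfg$t_start, st$interval_s, cfg$t_start, cfg$t_stop)),
    switching = generate_sa_stimulus(
      sample_switching_protocol(cfg$seed, cfg$t_start, cfg$t_stop,
                                st$interval_choices_s,
                                st$switch_gap_range_s)),
    csv = {
      tr <- read_trace_csv(st$csv_path)
      tr[[st$csv_port]] %||% numeric()
    },
    stop("unknown stimulus kind: ", st$kind)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a reproducible conduction experiment
#'
#' Builds a model (`modular`, `monolithic` or `pvc`) from a configuration
#' (a named list, or a path to a JSON/YAML file with the same structure),
#' generates or loads the SA stimulus, simulates, and optionally writes
#' trace CSV, interbeat CSV and a provenance JSON into `out_dir`. Outputs
#' are bit-reproducible from `(config, seed)`.
#'
#' Configuration keys (defaults in parentheses): `model` ("modular"),
#' `t_start` (0), `t_stop` (60), `seed` (1), `params` (`d_refrac_s`,
#' `period_s`, `av$d_min_s`, `av$d_amp_s`, `av$tau_s`,
#' `d_refrac_ventricle_s`), `stimulus` (`kind` = "switching" | "constant" |
#' "csv" | "none" plus kind-specific fields), `pvc_times_s`, `compare`
#' (FALSE; additionally run the monolithic reference and report
#' [compare_interbeat()]), `compare_tol_s`, `constant_delay_s` (NULL; set
#' to replace the recovery-dependent AV delay with a constant one).
#'
#' @param config Named list or path to a JSON/YAML config file.
#' @param out_dir Output directory (created if needed); `NULL` to skip file
#'   output.
#' @return An object of class `experiment_result`: list with `v`
#'   (ventricular trace), `sa`, `interbeat`, `traces`, `comparison`
#'   (or `NULL`), `config`, and `provenance`.
#' @export
run_experiment <- function(config = list(), out_dir = NULL) {
  cfg <- read_experiment_config(config)
  params <- config_params(cfg)
  sa <- config_stimulus(cfg)
  delay_fn <- if (!is.null(cfg$constant_delay_s))
    constant_delay_fn(cfg$constant_delay_s) else NULL
  scfg <- sim_config(t_start = cfg$t_start, t_stop = cfg$t_stop,
                     seed = cfg$seed)

  if (cfg$model == "monolithic") {
    mono <- monolithic_simulate(params, sa, scfg, delay_fn = delay_fn)
    v <- mono$v
    traces <- list(inp = sa, outp = v)
    interbeat <- mono$interbeat
  } else {
    model <- if (cfg$model == "pvc") {
      build_pvc_conduction(
        pvc_model_params(params, cfg$params$d_refrac_ventricle_s),
        delay_fn = delay_fn, t_start = cfg$t_start)
    } else {
      build_modular_conduction(params, delay_fn = delay_fn,
                               t_start = cfg$t_start)
    }
    external <- list(inp = sa)
    if (cfg$model == "pvc") external$PVC <- as.numeric(cfg$pvc_times_s)
    res <- simulate_model(model, scfg, external = external)
    v <- port_trace(res, "outp")
    traces <- res$traces
    # boundary outputs mirror their source; include them under their own name
    for (bo in model$boundary_outputs) traces[[bo]] <- port_trace(res, bo)
    interbeat <- interbeat_series(res)
  }

  comparison <- NULL
  if (isTRUE(cfg$compare)) {
    mono <- monolithic_simulate(params, sa, scfg, delay_fn = delay_fn)
    comparison <- compare_interbeat(interbeat, mono$interbeat,
                                    tol = cfg$compare_tol_s)
  }

  provenance <- list(package = "condsim",
                     version = as.character(utils::packageVersion("condsim")),
                     model = cfg$model, seed = cfg$seed,
                     t_start = cfg$t_start, t_stop = cfg$t_stop)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trace_csv(traces, file.path(out_dir, "traces.csv"))
    write_interbeat_csv(interbeat, file.path(out_dir, "interbeat.csv"))
    jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    if (!is.null(comparison)) {
      jsonlite::write_json(
        list(n_matched = comparison$n_matched,
             n_compared = comparison$n_compared,
             max_abs_diff = comparison$max_abs_diff,
             divergences = comparison$divergences),
        file.path(out_dir, "comparison.json"),
        auto_unbox = TRUE, pretty = TRUE, digits = NA)
    }
  }

  structure(
    list(v = v, sa = sa, interbeat = interbeat, traces = traces,
         comparison = comparison, config = cfg, provenance = provenance),
    class = "experiment_result"
  )
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> model=%s, %d SA events, %d contractions\n",
              x$config$model, length(x$sa), length(x$v)))
  if (nrow(x$interbeat))
    cat(sprintf("  d_interbeat: mean %.3f s (last %.3f s)\n",
                mean(x$interbeat$d_interbeat_s),
                x$interbeat$d_interbeat_s[nrow(x$interbeat)]))
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}
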