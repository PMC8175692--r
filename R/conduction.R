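# Physiological components of the cardiac conduction model and the composite
# modular model: refractory gate (SA node), escape pacemaker (AV node),
# recovery-dependent AV conduction delay, and an interbeat-interval monitor.

#' AV conduction delay parameters
#'
#' The delay of the AV conduction component recovers exponentially with the
#' time since the last signal left it:
#' `d(t_rec) = d_min + d_amp * exp(-t_rec / tau)`.
#' A long-recovered node conducts with the minimal delay `d_min`; an input
#' arriving immediately after the previous output is delayed by
#' `d_min + d_amp`.
#'
#' @param d_min Minimal conduction delay, seconds (> 0). Default 0.1 s.
#' @param d_amp Amplitude of the recovery-dependent part, seconds (>= 0).
#'   Default 0.13 s.
#' @param tau Recovery time constant, seconds (> 0). Default 0.07 s.
#' @return A named list of class `av_delay_params`.
#' @export
av_delay_params <- function(d_min = 0.1, d_amp = 0.13, tau = 0.07) {
  stopifnot(d_min > 0, d_amp >= 0, tau > 0)
  structure(list(d_min = d_min, d_amp = d_amp, tau = tau),
            class = "av_delay_params")
}

#' Recovery-dependent AV conduction delay
#'
#' @param params An [av_delay_params()] object.
#' @param t_rec Recovery time, seconds: time elapsed between the last output
#'   of the delay component and the current input. `Inf` (never fired before)
#'   gives the minimal delay.
#' @return Delay duration in seconds, strictly positive and monotone
#'   non-increasing in `t_rec`.
#' @export
av_delay_duration <- function(params, t_rec) {
  stopifnot(inherits(params, "av_delay_params"))
  if (any(t_rec < 0)) stop("t_rec must be non-negative")
  params$d_min + params$d_amp * exp(-t_rec / params$tau)
}

#' Full parameter set of the modular conduction model
#'
#' Five scalar parameters in total: the SA refractory period, the AV escape
#' pacemaker period, and the three AV delay constants.
#'
#' @param d_refrac Refractory period of the gate, seconds (> 0).
#'   Default 0.3 s.
#' @param period Escape pacemaker period, seconds (> 0). Default 1.7 s
#'   (junctional escape rhythm of about 35 beats per minute).
#' @param av An [av_delay_params()] object.
#' @return A list of class `conduction_params`.
#' @export
conduction_params <- function(d_refrac = 0.3, period = 1.7,
                              av = av_delay_params()) {
  stopifnot(d_refrac > 0, period > 0, inherits(av, "av_delay_params"))
  structure(list(d_refrac = d_refrac, period = period, av = av),
            class = "conduction_params")
}

# ---------------------------------------------------------------------------
# RefractoryGate

#' Refractory gate component
#'
#' Passes an input signal to its output only if strictly more than `d_refrac`
#' seconds have elapsed since the last signal left the gate (an event at
#' exactly `d_refrac` is still blocked). The first signal always passes.
#' With `with_reset = TRUE` the gate additionally exposes a `reset` input
#' that restarts the refractory period without emitting an output (used by
#' the PVC extension, where an ectopic contraction renders tissue
#' refractory).
#'
#' State: `t_last`, the time the last signal left the gate (`-Inf` = never).
#'
#' @param id Component id.
#' @param d_refrac Refractory period, seconds (> 0).
#' @param with_reset Add a `reset` input port.
#' @return A [new_component()] of type `"RefractoryGate"` with ports
#'   `inp`/`outp` (plus `reset`).
#' @export
refractory_gate <- function(id, d_refrac, with_reset = FALSE) {
  stopifnot(d_refrac > 0)
  new_component(
    id = id, type = "RefractoryGate",
    inputs = c("inp", if (with_reset) "reset"), outputs = "outp",
    state = list(d_refrac = d_refrac, t_last = NEVER),
    params = c(d_refrac = d_refrac),
    handler = function(state, t, fired_inputs, timeout_fired, ctx) {
      fire <- character()
      s <- state
      if ("inp" %in% fired_inputs && (t - state$t_last) > state$d_refrac) {
        fire <- "outp"
        s$t_last <- t
      }
      if ("reset" %in% fired_inputs) s$t_last <- t
      list(state = s, fire = fire)
    }
  )
}

#' Independent brute-force refractory filter
#'
#' Reference oracle for the gate: walks a sorted event trace and keeps an
#' event iff its gap to the last *kept* event is strictly greater than
#' `d_refrac`. Used by the test-suite to cross-validate the event-driven
#' gate; kept exported so equivalence can be demonstrated by users.
#'
#' @param times Sorted numeric event times.
#' @param d_refrac Refractory period, seconds.
#' @return The filtered subset of `times`.
#' @export
refractory_filter <- function(times, d_refrac) {
  kept <- numeric()
  t_last <- -Inf
  for (t in times) {
    if (t - t_last > d_refrac) {
      kept <- c(kept, t)
      t_last <- t
    }
  }
  kept
}

# ---------------------------------------------------------------------------
# Pacemaker

#' Escape pacemaker component
#'
#' Lets incoming signals pass through unchanged and, when its output chain
#' has been silent, fires spontaneously at `t_last_reset + period`. Crucially
#' the timer reset is decoupled from the output: a separate `reset` input
#' restarts the timer, so that only signals which also clear the downstream
#' refractory gate reset the escape clock (signals falling into the
#' refractory period must not postpone the escape beat). A spontaneous firing
#' resets the timer itself.
#'
#' State: `t_last_reset`, the last timer reset (initially the start of the
#' window, configurable via `t_last_reset`).
#'
#' @param id Component id.
#' @param period Escape period, seconds (> 0).
#' @param t_last_reset Initial timer phase (default 0; set to the simulation
#'   start time).
#' @return A [new_component()] of type `"Pacemaker"` with ports `inp`,
#'   `reset` and `outp`.
#' @export
pacemaker <- function(id, period, t_last_reset = 0) {
  stopifnot(period > 0)
  new_component(
    id = id, type = "Pacemaker",
    inputs = c("inp", "reset"), outputs = "outp",
    state = list(period = period, t_last_reset = t_last_reset),
    params = c(period = period),
    timeout_fn = function(state) state$t_last_reset + state$period,
    handler = function(state, t, fired_inputs, timeout_fired, ctx) {
      fire <- character()
      s <- state
      if ("inp" %in% fired_inputs || timeout_fired) fire <- "outp"
      if (timeout_fired || "reset" %in% fired_inputs) s$t_last_reset <- t
      list(state = s, fire = fire)
    }
  )
}

# ---------------------------------------------------------------------------
# ConductionDelay

#' Recovery-dependent conduction delay component
#'
#' Puts an incoming signal on hold and releases it after a delay computed
#' from the recovery time `t - t_last_out` (time since the last signal left
#' the component) by `delay_fn`. The model assumes at most one signal is on
#' hold at any time; an input arriving while a signal is pending is handled
#' according to the simulation's `overlap_policy` (dropped with a warning by
#' default). With `with_reset = TRUE` a `reset` input cancels any pending
#' signal and restarts the recovery clock without emitting an output.
#'
#' State: `pending` (a signal is on hold), `t_next` (its release time),
#' `t_last_out` (last emission, `-Inf` = never), `d_delay` (last computed
#' delay).
#'
#' @param id Component id.
#' @param delay_fn `function(t_rec)` returning the delay in seconds;
#'   typically built from [av_delay_params()] via [av_delay_fn()].
#' @param params Named numeric vector of the scalar parameters behind
#'   `delay_fn` (introspection only).
#' @param with_reset Add a `reset` input port.
#' @return A [new_component()] of type `"ConductionDelay"`.
#' @export
conduction_delay <- function(id, delay_fn, params = numeric(),
                             with_reset = FALSE) {
  stopifnot(is.function(delay_fn))
  new_component(
    id = id, type = "ConductionDelay",
    inputs = c("inp", if (with_reset) "reset"), outputs = "outp",
    state = list(pending = FALSE, t_next = Inf, t_last_out = NEVER,
                 d_delay = NA_real_, delay_fn = delay_fn),
    params = params,
    timeout_fn = function(state) if (state$pending) state$t_next else Inf,
    handler = function(state, t, fired_inputs, timeout_fired, ctx) {
      fire <- character()
      s <- state
      if (timeout_fired) {
        if (!state$pending)
          stop("conduction delay released without a pending signal at t = ", t)
        fire <- "outp"
        s$pending <- FALSE
        s$t_next <- Inf
        s$t_last_out <- t
      }
      if ("inp" %in% fired_inputs) {
        if (state$pending) {
          # overlap with the signal on hold (pre-event state decides; a
          # release at this same instant does not free the slot)
          policy <- ctx$config$overlap_policy
          if (policy == "error")
            stop("input during pending conduction delay at t = ", t,
                 " violates the single-hold assumption")
          if (policy == "warn_drop")
            warning("input at t = ", t,
                    " dropped: conduction delay already holds a signal")
        } else {
          d <- state$delay_fn(t - state$t_last_out)
          if (!is.finite(d) || d < 0)
            stop("delay_fn returned an invalid delay at t = ", t)
          s$d_delay <- d
          s$t_next <- t + d
          s$pending <- TRUE
        }
      }
      if ("reset" %in% fired_inputs) {
        s$pending <- FALSE
        s$t_next <- Inf
        s$t_last_out <- t
      }
      list(state = s, fire = fire)
    }
  )
}

#' Build the exponential-recovery AV delay function
#'
#' @param av An [av_delay_params()] object.
#' @return `function(t_rec)` evaluating [av_delay_duration()].
#' @export
av_delay_fn <- function(av) {
  force(av)
  function(t_rec) av_delay_duration(av, t_rec)
}

#' Constant delay function
#'
#' Convenience for experiments and equivalence tests that require a
#' recovery-independent conduction delay.
#'
#' @param d Delay in seconds (>= 0).
#' @return `function(t_rec)` returning `d`.
#' @export
constant_delay_fn <- function(d) {
  stopifnot(d >= 0)
  function(t_rec) d
}

# ---------------------------------------------------------------------------
# Interbeat monitor

#' Interbeat-interval monitor component
#'
#' Observes a contraction trace and maintains the model's higher-level
#' readouts: `t_last_contraction` and `d_interbeat` (defined from the second
#' contraction onwards). It emits no output events.
#'
#' @param id Component id.
#' @return A [new_component()] of type `"InterbeatMonitor"` with one input
#'   `inp`.
#' @export
interbeat_monitor <- function(id) {
  new_component(
    id = id, type = "InterbeatMonitor",
    inputs = "inp", outputs = character(),
    state = list(t_last_contraction = NA_real_, d_interbeat = NA_real_,
                 sample_t = numeric(), sample_d = numeric()),
    handler = function(state, t, fired_inputs, timeout_fired, ctx) {
      s <- state
      if ("inp" %in% fired_inputs) {
        if (!is.na(state$t_last_contraction)) {
          s$d_interbeat <- t - state$t_last_contraction
          s$sample_t <- c(state$sample_t, t)
          s$sample_d <- c(state$sample_d, s$d_interbeat)
        }
        s$t_last_contraction <- t
      }
      list(state = s, fire = character())
    }
  )
}

# ---------------------------------------------------------------------------
# Composite model

#' Build the modular cardiac conduction model
#'
#' Wires the three physiological components into the composite model:
#' boundary input `inp` (SA-node signal) feeds the pacemaker; the pacemaker
#' output passes the refractory gate; the gate output feeds the AV conduction
#' delay *and* loops back to the pacemaker's reset, so that only signals
#' clearing the refractory gate restart the escape clock; the delay output is
#' the ventricular contraction trace exposed at boundary output `outp` and
#' observed by the interbeat monitor.
#'
#' @param params A [conduction_params()] object.
#' @param delay_fn Optional replacement for the AV delay function (e.g.
#'   [constant_delay_fn()]); defaults to the exponential recovery
#'   [av_delay_fn()] built from `params$av`.
#' @param t_start Simulation start time used to initialise the pacemaker
#'   phase.
#' @return A [model_graph()] with boundary ports `inp` and `outp`.
#' @examples
#' m <- build_modular_conduction(
#'   conduction_params(d_refrac = 0.3, period = 2),
#'   delay_fn = constant_delay_fn(0.1))
#' res <- simulate_model(m, sim_config(0, 3),
#'                       external = list(inp = c(0, 0.8, 1.6, 2.4)))
#' port_trace(res, "outp")  # 0.1 0.9 1.7 2.5
#' @export
build_modular_conduction <- function(params = conduction_params(),
                                     delay_fn = NULL, t_start = 0) {
  stopifnot(inherits(params, "conduction_params"))
  if (is.null(delay_fn)) delay_fn <- av_delay_fn(params$av)
  m <- model_graph()
  m <- add_boundary_input(m, "inp")
  m <- add_boundary_output(m, "outp")
  m <- add_component(m, pacemaker("pacemaker", params$period,
                                  t_last_reset = t_start))
  m <- add_component(m, refractory_gate("refractoryGate", params$d_refrac))
  m <- add_component(m, conduction_delay(
    "avConductionDelay", delay_fn,
    params = c(d_min = params$av$d_min, d_amp = params$av$d_amp,
               tau = params$av$tau)))
  m <- add_component(m, interbeat_monitor("interbeat"))
  m <- connect(m, "inp", "pacemaker.inp")
  m <- connect(m, "pacemaker.outp", "refractoryGate.inp")
  m <- connect(m, "refractoryGate.outp", "avConductionDelay.inp")
  m <- connect(m, "refractoryGate.outp", "pacemaker.reset")
  m <- connect(m, "avConductionDelay.outp", "outp")
  m <- connect(m, "avConductionDelay.outp", "interbeat.inp")
  m
}

#' Model readouts: interbeat series and last contraction
#'
#' `interbeat_series()` returns the samples collected by the model's
#' interbeat monitor as a data frame with columns `time_s` (contraction time)
#' and `d_interbeat_s`; `last_contraction()` returns the timestamp of the
#' most recent contraction (`NA` before the first beat).
#'
#' @param result A `sim_result` from [simulate_model()] of a model containing
#'   an `interbeat` monitor.
#' @return See description.
#' @export
interbeat_series <- function(result) {
  stopifnot(inherits(result, "sim_result"))
  st <- result$model$components[["interbeat"]]$state
  if (is.null(st)) stop("model has no 'interbeat' monitor component")
  data.frame(time_s = st$sample_t, d_interbeat_s = st$sample_d)
}

#' @rdname interbeat_series
#' @export
last_contraction <- function(result) {
  stopifnot(inherits(result, "sim_result"))
  st <- result$model$components[["interbeat"]]$state
  if (is.null(st)) stop("model has no 'interbeat' monitor component")
  st$t_last_contraction
}
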