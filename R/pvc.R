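# Premature-ventricular-contraction (PVC) extension: stateless logic gates
# and the extended model with a second (ventricular) refractory gate and a
# PVC trigger input.

#' Logic-gate components
#'
#' Stateless gates over instantaneous signals, evaluated per resolved event
#' instant. An OR gate fires once when at least one of its inputs fires at an
#' instant (simultaneous firings are merged into a single output event); an
#' AND gate fires only when *all* of its inputs fire at the same instant
#' (within the simulation's time tolerance).
#'
#' @param id Component id.
#' @param arity Number of input ports (`in1`, `in2`, ...; >= 2).
#' @return A [new_component()] of type `"OrGate"` / `"AndGate"`.
#' @export
or_gate <- function(id, arity = 2L) {
  stopifnot(arity >= 2L)
  new_component(
    id = id, type = "OrGate",
    inputs = paste0("in", seq_len(arity)), outputs = "outp",
    state = list(arity = as.integer(arity)),
    handler = function(state, t, fired_inputs, timeout_fired, ctx) {
      list(state = state,
           fire = if (length(fired_inputs) >= 1L) "outp" else character())
    }
  )
}

#' @rdname or_gate
#' @export
and_gate <- function(id, arity = 2L) {
  stopifnot(arity >= 2L)
  new_component(
    id = id, type = "AndGate",
    inputs = paste0("in", seq_len(arity)), outputs = "outp",
    state = list(arity = as.integer(arity)),
    handler = function(state, t, fired_inputs, timeout_fired, ctx) {
      list(state = state,
           fire = if (length(fired_inputs) == state$arity) "outp" else character())
    }
  )
}

#' Parameters of the PVC-extended conduction model
#'
#' @param base A [conduction_params()] object for the underlying conduction
#'   chain.
#' @param d_refrac_ventricle Refractory period of the ventricles, seconds
#'   (> 0). Default 0.25 s.
#' @return A list of class `pvc_model_params`.
#' @export
pvc_model_params <- function(base = conduction_params(),
                             d_refrac_ventricle = 0.25) {
  stopifnot(inherits(base, "conduction_params"), d_refrac_ventricle > 0)
  structure(list(base = base, d_refrac_ventricle = d_refrac_ventricle),
            class = "pvc_model_params")
}

#' Build the PVC-extended conduction model
#'
#' Extends the modular conduction model with a trigger input for premature
#' ventricular contractions. New parts relative to
#' [build_modular_conduction()]: a second refractory gate for the refractory
#' period of the ventricles, two OR gates, one AND gate, and reset inputs on
#' the SA refractory gate and the conduction delay.
#'
#' Wiring: `OR1(avConductionDelay.outp, PVC)` feeds the ventricular gate,
#' whose output is the ventricular contraction trace `outp`. The AND gate
#' receives the PVC trigger and the ventricular output, so it fires exactly
#' when a PVC *conducts* (trigger outside the ventricular refractory
#' period). A conducted PVC resets, retrogradely, the escape pacemaker
#' (via `OR2(refractoryGate.outp, AND)`), the SA refractory gate, and the
#' conduction delay (cancelling any signal on hold).
#'
#' Behavioural contract: a PVC trigger during the ventricular refractory
#' period produces no ventricular event (and no resets); a trigger outside
#' it produces an immediate ventricular event; every ventricular event,
#' normal or ectopic, starts a ventricular refractory period that also
#' blocks conducted beats.
#'
#' @param params A [pvc_model_params()] object.
#' @param delay_fn Optional replacement AV delay function (see
#'   [build_modular_conduction()]).
#' @param t_start Simulation start time (pacemaker phase).
#' @return A [model_graph()] with boundary inputs `inp` and `PVC` and
#'   boundary output `outp`.
#' @export
build_pvc_conduction <- function(params = pvc_model_params(),
                                 delay_fn = NULL, t_start = 0) {
  stopifnot(inherits(params, "pvc_model_params"))
  base <- params$base
  if (is.null(delay_fn)) delay_fn <- av_delay_fn(base$av)
  m <- model_graph()
  m <- add_boundary_input(m, "inp")
  m <- add_boundary_input(m, "PVC")
  m <- add_boundary_output(m, "outp")
  m <- add_component(m, pacemaker("pacemaker", base$period,
                                  t_last_reset = t_start))
  m <- add_component(m, refractory_gate("refractoryGate", base$d_refrac,
                                        with_reset = TRUE))
  m <- add_component(m, conduction_delay(
    "avConductionDelay", delay_fn,
    params = c(d_min = base$av$d_min, d_amp = base$av$d_amp,
               tau = base$av$tau),
    with_reset = TRUE))
  m <- add_component(m, refractory_gate("ventricularGate",
                                        params$d_refrac_ventricle))
  m <- add_component(m, or_gate("orVentIn"))
  m <- add_component(m, or_gate("orReset"))
  m <- add_component(m, and_gate("andPvcConducted"))
  m <- add_component(m, interbeat_monitor("interbeat"))

  m <- connect(m, "inp", "pacemaker.inp")
  m <- connect(m, "pacemaker.outp", "refractoryGate.inp")
  m <- connect(m, "refractoryGate.outp", "avConductionDelay.inp")
  m <- connect(m, "avConductionDelay.outp", "orVentIn.in1")
  m <- connect(m, "PVC", "orVentIn.in2")
  m <- connect(m, "orVentIn.outp", "ventricularGate.inp")
  m <- connect(m, "ventricularGate.outp", "outp")
  m <- connect(m, "ventricularGate.outp", "interbeat.inp")
  m <- connect(m, "ventricularGate.outp", "andPvcConducted.in1")
  m <- connect(m, "PVC", "andPvcConducted.in2")
  m <- connect(m, "refractoryGate.outp", "orReset.in1")
  m <- connect(m, "andPvcConducted.outp", "orReset.in2")
  m <- connect(m, "orReset.outp", "pacemaker.reset")
  m <- connect(m, "andPvcConducted.outp", "refractoryGate.reset")
  m <- connect(m, "andPvcConducted.outp", "avConductionDelay.reset")
  m
}
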