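# Shared fixtures: small ad-hoc models and random event traces.

# Strictly increasing random trace in [0, t_max] with a minimum gap well
# above the kernel's simultaneity tolerance.
random_trace <- function(n, t_max = 30, min_gap = 1e-4) {
  t <- sort(stats::runif(n, 0, t_max))
  if (length(t) > 1L) t <- t[c(TRUE, diff(t) > min_gap)]
  t
}

# Model with a single refractory gate between the boundary ports.
gate_only_model <- function(d_refrac) {
  m <- model_graph()
  m <- add_boundary_input(m, "inp")
  m <- add_boundary_output(m, "outp")
  m <- add_component(m, refractory_gate("gate", d_refrac))
  m <- connect(m, "inp", "gate.inp")
  m <- connect(m, "gate.outp", "outp")
  m
}

run_gate <- function(times, d_refrac, t_stop = max(c(times, 1)) + 1) {
  res <- simulate_model(gate_only_model(d_refrac), sim_config(0, t_stop),
                        external = list(inp = times))
  port_trace(res, "outp")
}

# Pure pass-through component, used to probe propagation semantics.
passthrough <- function(id) {
  new_component(
    id = id, type = "PassThrough", inputs = "inp", outputs = "outp",
    handler = function(state, t, fired_inputs, timeout_fired, ctx) {
      list(state = state,
           fire = if ("inp" %in% fired_inputs) "outp" else character())
    }
  )
}

identity_model <- function() {
  m <- model_graph()
  m <- add_boundary_input(m, "inp")
  m <- add_boundary_output(m, "outp")
  m <- add_component(m, passthrough("relay"))
  m <- connect(m, "inp", "relay.inp")
  m <- connect(m, "relay.outp", "outp")
  m
}

# Standard parameter sets used across tests.
params_const <- function(d_refrac = 0.3, period = 2.0) {
  conduction_params(d_refrac = d_refrac, period = period)
}

run_modular <- function(sa, params, delay_fn = NULL, t_stop, t_start = 0) {
  m <- build_modular_conduction(params, delay_fn = delay_fn, t_start = t_start)
  simulate_model(m, sim_config(t_start, t_stop), external = list(inp = sa))
}
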