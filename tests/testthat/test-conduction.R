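test_that("refractory gate blocks within d_refrac, strictly", {
  # first signal always passes
  expect_equal(run_gate(1, d_refrac = 1.5), 1)
  # brute-force hand case
  expect_equal(run_gate(1:6, d_refrac = 1.5), c(1, 3, 5))
  # boundary equality blocks: gap exactly d_refrac is still refractory
  expect_equal(run_gate(c(0, 1.0), d_refrac = 1.0), 0)
  expect_equal(run_gate(c(0, 1.0 + 1e-6), d_refrac = 1.0), c(0, 1.0 + 1e-6))
})

test_that("refractory gate equals the brute-force filter on random traces", {
  withr::with_seed(101, {
    for (k in 1:200) {
      d_refrac <- stats::runif(1, 0.05, 2)
      times <- random_trace(stats::rpois(1, 15), t_max = 20)
      out <- run_gate(times, d_refrac, t_stop = 21)
      expect_identical(out, refractory_filter(times, d_refrac))
      if (length(out) > 1L) expect_true(all(diff(out) > d_refrac))
      expect_true(all(out %in% times))  # output trace subset of input
    }
  })
})

test_that("pacemaker passes signals through without resetting its timer", {
  m <- model_graph()
  m <- add_boundary_input(m, "i")
  m <- add_boundary_output(m, "o")
  m <- add_component(m, pacemaker("pm", period = 2, t_last_reset = 0))
  m <- connect(m, "i", "pm.inp")
  m <- connect(m, "pm.outp", "o")

  # input at t=1 passes; timer not reset, so spontaneous output still at 2
  res <- simulate_model(m, sim_config(0, 2.5), external = list(i = 1))
  expect_equal(port_trace(res, "o"), c(1, 2))
  expect_equal(res$model$components$pm$state$t_last_reset, 2)

  # two inputs -> two outputs (pass-through)
  res2 <- simulate_model(m, sim_config(0, 1.5), external = list(i = c(0.5, 1.0)))
  expect_equal(port_trace(res2, "o"), c(0.5, 1.0))

  # input exactly at the expiry instant -> single deduplicated output
  res3 <- simulate_model(m, sim_config(0, 2.5), external = list(i = 2))
  expect_equal(port_trace(res3, "o"), 2)
})

test_that("pacemaker spontaneous firing and reset arithmetic", {
  m <- model_graph()
  m <- add_boundary_input(m, "r")
  m <- add_boundary_output(m, "o")
  m <- add_component(m, pacemaker("pm", period = 2, t_last_reset = 0))
  m <- connect(m, "r", "pm.reset")
  m <- connect(m, "pm.outp", "o")

  # silence -> arithmetic escape sequence
  res <- simulate_model(m, sim_config(0, 7))
  expect_equal(port_trace(res, "o"), c(2, 4, 6))

  # reset does not emit, and postpones the next spontaneous beat
  res2 <- simulate_model(m, sim_config(0, 3.6), external = list(r = 1.5))
  expect_equal(port_trace(res2, "o"), 3.5)

  # resets at {1, 1.8}: no spontaneous output before 3.8
  res3 <- simulate_model(m, sim_config(0, 4), external = list(r = c(1, 1.8)))
  expect_equal(port_trace(res3, "o"), 3.8)
})

test_that("pacemaker with its output wired to its own reset never gaps beyond period", {
  m <- model_graph()
  m <- add_boundary_input(m, "i")
  m <- add_boundary_output(m, "o")
  m <- add_component(m, pacemaker("pm", period = 1.3, t_last_reset = 0))
  m <- connect(m, "i", "pm.inp")
  m <- connect(m, "pm.outp", "pm.reset")
  m <- connect(m, "pm.outp", "o")
  withr::with_seed(11, sa <- random_trace(25, t_max = 18))
  res <- simulate_model(m, sim_config(0, 20), external = list(i = sa))
  out <- port_trace(res, "o")
  expect_true(all(diff(out) <= 1.3 + 1e-9))
})

test_that("av_delay_duration follows the exponential recovery curve", {
  p <- av_delay_params(d_min = 0.1, d_amp = 0.1, tau = 1.0)
  expect_equal(av_delay_duration(p, Inf), 0.1)
  expect_equal(av_delay_duration(p, 0), 0.2)
  expect_equal(av_delay_duration(p, 2), 0.1 + 0.1 * exp(-2), tolerance = 1e-12)
  expect_error(av_delay_duration(p, -0.1), "non-negative")
  # monotone non-increasing, strictly positive
  grid <- av_delay_duration(p, seq(0, 10, by = 0.1))
  expect_true(all(diff(grid) <= 0))
  expect_true(all(grid > 0))
})

test_that("conduction delay schedules, releases, and measures recovery", {
  m <- model_graph()
  m <- add_boundary_input(m, "i")
  m <- add_boundary_output(m, "o")
  m <- add_component(m, conduction_delay("delay", constant_delay_fn(0.2)))
  m <- connect(m, "i", "delay.inp")
  m <- connect(m, "delay.outp", "o")

  res <- simulate_model(m, sim_config(0, 4), external = list(i = c(1, 2, 3)))
  expect_equal(port_trace(res, "o"), c(1.2, 2.2, 3.2))
  expect_false(res$model$components$delay$state$pending)
  expect_equal(res$model$components$delay$state$t_last_out, 3.2)

  # recovery time measured from the last *emitted* output
  rec <- numeric()
  probe <- function(t_rec) { rec <<- c(rec, t_rec); 0.2 }
  m2 <- model_graph()
  m2 <- add_boundary_input(m2, "i")
  m2 <- add_boundary_output(m2, "o")
  m2 <- add_component(m2, conduction_delay("delay", probe))
  m2 <- connect(m2, "i", "delay.inp")
  m2 <- connect(m2, "delay.outp", "o")
  simulate_model(m2, sim_config(0, 4), external = list(i = c(1, 2.0)))
  expect_equal(rec, c(Inf, 2.0 - 1.2))
})

test_that("overlapping inputs honour the overlap policy", {
  mk <- function() {
    m <- model_graph()
    m <- add_boundary_input(m, "i")
    m <- add_boundary_output(m, "o")
    m <- add_component(m, conduction_delay("delay", constant_delay_fn(0.5)))
    m <- connect(m, "i", "delay.inp")
    m <- connect(m, "delay.outp", "o")
    m
  }
  # default: warn and drop the second input
  expect_warning(
    res <- simulate_model(mk(), sim_config(0, 2), external = list(i = c(1, 1.2))),
    "dropped")
  expect_equal(port_trace(res, "o"), 1.5)

  expect_error(
    suppressWarnings(simulate_model(
      mk(), sim_config(0, 2, overlap_policy = "error"),
      external = list(i = c(1, 1.2)))),
    "single-hold")

  expect_silent(
    res3 <- simulate_model(mk(), sim_config(0, 2, overlap_policy = "silent_drop"),
                           external = list(i = c(1, 1.2))))
  expect_equal(port_trace(res3, "o"), 1.5)
})

test_that("the modular model has the published structure", {
  m <- build_modular_conduction(params_const())
  phys <- Filter(function(c) c$type != "InterbeatMonitor", m$components)
  expect_length(phys, 3L)
  expect_setequal(vapply(phys, `[[`, "", "type"),
                  c("Pacemaker", "RefractoryGate", "ConductionDelay"))
  # reset feedback edge present
  expect_true(any(m$connections$from == "refractoryGate.outp" &
                  m$connections$to == "pacemaker.reset"))
  # boundary interface {inp, outp}; readouts available after a run
  expect_identical(m$boundary_inputs, "inp")
  expect_identical(m$boundary_outputs, "outp")
  # each physiological component exposes at most 3 interface variables
  n_ports <- vapply(phys, function(c) length(c$inputs) + length(c$outputs),
                    integer(1))
  expect_true(all(n_ports <= 3L))
  expect_equal(unname(n_ports[c("refractoryGate", "avConductionDelay")]),
               c(2L, 2L))
  expect_equal(unname(n_ports["pacemaker"]), 3L)
})

test_that("interbeat readouts track contractions", {
  params <- params_const()
  res <- run_modular(c(0, 0.8, 1.6, 2.4), params,
                     delay_fn = constant_delay_fn(0.1), t_stop = 3)
  # hand-traced pipeline: each SA beat conducts with 0.1 s delay
  expect_equal(port_trace(res, "outp"), c(0.1, 0.9, 1.7, 2.5))
  ib <- interbeat_series(res)
  expect_equal(ib$time_s, c(0.9, 1.7, 2.5))
  expect_equal(ib$d_interbeat_s, c(0.8, 0.8, 0.8))
  expect_equal(last_contraction(res), 2.5)

  # first contraction defines no sample
  res1 <- run_modular(0, params, delay_fn = constant_delay_fn(0.1), t_stop = 1)
  expect_equal(nrow(interbeat_series(res1)), 0L)
  expect_equal(last_contraction(res1), 0.1)

  # online samples equal offline extraction from the trace
  withr::with_seed(5, sa <- random_trace(30, t_max = 25))
  res2 <- run_modular(sa, params, t_stop = 30)
  expect_equal(interbeat_series(res2)$d_interbeat_s,
               extract_interbeat(port_trace(res2, "outp"))$d_interbeat_s)
})

test_that("escape rhythm converges to the pacemaker period", {
  # constant delay: exact from the second beat
  res <- run_modular(numeric(), params_const(period = 2),
                     delay_fn = constant_delay_fn(0.1), t_stop = 15)
  ib <- interbeat_series(res)
  expect_true(nrow(ib) >= 5)
  expect_equal(ib$d_interbeat_s, rep(2, nrow(ib)))

  # exponential recovery: fixed point d* = f(period - d*) of the recovery map
  params <- conduction_params(d_refrac = 0.3, period = 1.7,
                              av = av_delay_params(0.1, 0.13, 0.07))
  res2 <- run_modular(numeric(), params, t_stop = 1.7 * 30)
  ib2 <- interbeat_series(res2)$d_interbeat_s
  expect_true(length(ib2) >= 25)
  expect_lt(abs(ib2[length(ib2)] - params$period), 1e-9)
  # independent oracle: iterate the scalar recovery map
  # d_1 = f(Inf), d_{k+1} = f(period - d_k); the k-th beat is at k*period + d_k
  f <- av_delay_fn(params$av)
  d <- f(Inf)
  for (k in 1:25) d <- f(params$period - d)
  v_times <- port_trace(res2, "outp")
  expect_lt(abs((v_times[26] - 26 * params$period) - d), 1e-9)
})

test_that("1:1 conduction and 2:1 block reproduce AV-block ratios", {
  params <- conduction_params(d_refrac = 0.5, period = 2.0)
  # 1:1: T > d_refrac
  sa1 <- seq(0, 20, by = 0.8)
  r1 <- run_modular(sa1, params, delay_fn = constant_delay_fn(0.1), t_stop = 20.5)
  ib1 <- interbeat_series(r1)$d_interbeat_s
  expect_true(all(abs(ib1 - 0.8) < 1e-9))
  # 2:1: T < d_refrac <= 2T, 2T < period
  sa2 <- seq(0, 20, by = 0.4)
  r2 <- run_modular(sa2, params, delay_fn = constant_delay_fn(0.1), t_stop = 20.5)
  ib2 <- interbeat_series(r2)$d_interbeat_s
  expect_true(all(abs(ib2 - 0.8) < 1e-9))
  rr <- conduction_ratio(sa2, port_trace(r2, "outp"), c(0, 19.9))
  expect_equal(c(rr$n_sa, rr$n_v), c(2L, 1L))
})
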