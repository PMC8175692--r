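---
title: "A modular event-driven model of the cardiac conduction system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A modular event-driven model of the cardiac conduction system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condsim)
```

## The model

The cardiac conduction system relays the periodic excitation generated by
the sinoatrial (SA) node to the ventricles. `condsim` models this relay as a
chain of three discrete-event components, each representing one
physiological effect, connected by instantaneous boolean signals (a signal
is "true" only at isolated instants — an event trace is simply a strictly
increasing vector of timestamps):

* **Pacemaker** (AV-node escape): passes every input through and fires
  spontaneously at `t_last_reset + period` when its environment has been
  silent. The timer reset is *decoupled* from the output and exposed as a
  separate `reset` input: only signals that also clear the downstream
  refractory gate loop back and restart the escape clock. Signals that fall
  into the refractory period therefore do not postpone an escape beat,
  which is the physiologically correct behaviour.
* **RefractoryGate** (SA-node refractoriness): forwards an input iff
  strictly more than `d_refrac` seconds have passed since the last signal
  *left* the gate. Equality blocks. The first signal always passes (the
  initial "last output" is the sentinel `-Inf`).
* **AVConductionDelay**: holds an incoming signal and releases it after a
  delay that depends on the recovery time `t_rec`, the time since the last
  signal left the component:

  $$d(t_\mathrm{rec}) = d_\min + d_\mathrm{amp}\, e^{-t_\mathrm{rec}/\tau}.$$

  The component assumes at most one signal on hold at a time; an input
  arriving while one is pending is governed by the configurable
  `overlap_policy` (dropped with a warning by default).

The composite model (`build_modular_conduction()`) wires
`inp → pacemaker → refractoryGate → avConductionDelay → outp`, with the
feedback edge `refractoryGate.outp → pacemaker.reset`, and attaches an
interbeat monitor to the ventricular output. Its boundary interface is an
input, an output, and the readouts `d_interbeat` /
`t_last_contraction`.

```{r}
m <- build_modular_conduction(conduction_params(d_refrac = 0.3, period = 2),
                              delay_fn = constant_delay_fn(0.1))
res <- simulate_model(m, sim_config(0, 3),
                      external = list(inp = c(0, 0.8, 1.6, 2.4)))
port_trace(res, "outp")
interbeat_series(res)
```

## Simulation semantics

The kernel (`simulate_model()`) processes external events and component
time events chronologically. Everything within `time_tolerance` (default
`1e-9` s) of the earliest pending event is merged into one *instant*. An
instant is resolved to a zero-delay fixpoint: handlers are evaluated in
component insertion order against the **pre-event state** (the value just
before the instant), each output fires at most once per instant, and state
updates are committed only after the fixpoint is reached. This mirrors
synchronous event iteration in equation-based modelling runtimes, where a
`pre()` operator distinguishes values before and after an event.

Two consequences matter for this model:

* When the pacemaker fires spontaneously, its signal traverses the gate and
  arrives back at `pacemaker.reset` *at the same instant* without
  re-triggering a second output — the at-most-once rule plus pre-state
  evaluation make the feedback loop well defined.
* A reset coinciding with a spontaneous expiry yields a single output and a
  single timer restart.

The fixpoint assumes *monotone* handlers: firing decisions never retract
when more inputs arrive within the instant. All shipped components satisfy
this; `max_event_iterations` bounds the iteration and converts genuinely
cyclic zero-delay logic into an error.

How an equation-based runtime orders multiple simultaneous event clauses is
generally unspecified; the fixed insertion-order sweep used here is a
deliberate choice that makes runs bit-reproducible. Because handlers read
pre-event state only, the sweep order can affect at most the number of
iterations to the fixpoint, not the result.

## Parameters

| parameter | meaning | unit | default |
|---|---|---|---|
| `d_refrac` | SA refractory period | s | 0.3 |
| `period` | AV escape period | s | 1.7 |
| `av$d_min` | minimal AV delay | s | 0.1 |
| `av$d_amp` | recovery-dependent AV delay amplitude | s | 0.13 |
| `av$tau` | AV recovery time constant | s | 0.07 |
| `d_refrac_ventricle` | ventricular refractory period (PVC model) | s | 0.25 |

Defaults are chosen to be physiologically plausible for an adult human —
an atrial refractory period of a few hundred milliseconds, a junctional
escape rhythm near 35 beats/min, and AV-nodal recovery-curve constants of
the order reported in electrophysiology (AH-interval recovery with a time
constant of tens of milliseconds). They are *defaults*, not fitted values;
every test states its parameters explicitly, and the delay function is
injectable (`delay_fn`), so any recovery curve can be substituted without
touching the component.

The exponential form of the recovery curve is itself a design choice: the
delay must only be positive, recovery-dependent, and expressible with at
most three parameters; a saturating exponential is the standard choice for
AV-nodal recovery and satisfies the fixed-point argument below.

## Emergent behaviour the tests pin down

* **1:1 conduction**: for SA interval `T` with `d_refrac < T < period`,
  every beat conducts and `d_interbeat` settles at `T`.
* **2:1 block**: for `T < d_refrac ≤ 2T` (and `2T < period`) every second
  beat is absorbed by the gate and `d_interbeat = 2T` — second-degree AV
  block.
* **Escape rhythm**: without SA drive the pacemaker fires every `period`
  and the ventricular interval obeys
  `d_interbeat_k = period + d_k − d_{k−1}` with
  `d_{k+1} = d(period − d_k)`. The recovery map is a contraction, so
  `d_k → d*` geometrically and `d_interbeat → period`; with a constant
  delay the limit is exact from the second beat.
* **PVC extension**: a trigger inside the ventricular refractory period is
  absorbed without any side effect; a trigger outside it contracts the
  ventricles immediately, and — being conducted retrogradely — resets the
  escape clock, the SA gate, and the AV delay, producing the classic short
  coupling interval followed by a compensatory pause.

## The monolithic reference

`monolithic_simulate()` reconstructs the older scheduling formulation: one
variable carries the next scheduled contraction, an accepted SA beat may
overwrite it when it would act earlier, the refractory check is applied to
the SA signal *before* the delay, and the escape fallback is re-armed from
the contraction time. On constant 1:1 protocols it is provably identical to
the modular chain (both reduce to input + delay). The two formulations
genuinely differ once beats are blocked or escape beats occur: the
monolithic escape counts from the *post-delay* contraction, and an escape
beat does not render the monolithic refractory check refractory. The
equivalence tests therefore assert exact agreement on 1:1 protocols and
*confinement* of divergences to blocked-beat/escape episodes, not their
absence.

## Stimulus generation

`stimulus_protocol()` describes a piecewise-constant SA drive;
`sample_switching_protocol()` draws switch times every 5–10 s and intervals
from a user-supplied choice set, seed-deterministically. The interval in
force *at the previous event* determines the next event — a switch changes
the spacing of events issued after it, matching a sampled-clock
implementation re-armed at each tick. This emulates a bench protocol in
which the SA interval is stepped every few seconds; it does not emulate
respiratory sinus arrhythmia, autonomic modulation, or beat-to-beat
variability of a real heart. A green test therefore establishes the
event-level contract of the conduction chain, not physiological realism of
the drive.

## Numerical choices

* Time is a double in seconds. Events closer than `time_tolerance`
  (default 1 ns) are simultaneous; the canonical instant is the earliest
  merged time.
* Sentinels: "never fired" is `-Inf`, "no pending release" is `+Inf`;
  first signals therefore pass the gate and receive the minimal delay. The
  pacemaker phase starts at `t_start`.
* Strict inequality in the refractory test; boundary equality blocks.
* CSV output uses `%.9g` floats, LF line endings, and rows sorted by time
  then port, so identical runs produce byte-identical files; round-trips
  are faithful to nine significant digits (not to the last bit of a
  double).
* `d_interbeat` is undefined until the second contraction; the first beat
  produces no sample.

## Limitations

* The conduction chain is purely event-driven: no membrane potentials, no
  continuous dynamics, no autonomic feedback loop around it.
* The delay component refuses to model overlapping conduction; protocols
  fast enough to violate the single-hold assumption are reported, not
  resolved.
* The PVC reset wiring implements the documented behavioural contract; at
  the same contract other gate placements are possible and would be
  indistinguishable at the boundary.
* The monolithic reference reproduces the scheduling *design*, not any
  specific historical code byte-for-byte.
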