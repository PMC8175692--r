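# condsim

Deterministic discrete-event simulation of the human cardiac conduction
system, for modellers who want the rhythm-level behaviour of the
SA-node → AV-node → ventricle relay without solving membrane-level ODEs:
1:1 conduction, second-degree (n:1) AV block, AV escape rhythm, and
premature ventricular contractions (PVCs) with their compensatory pause.

## The model

Signals are instantaneous boolean events (an event trace is a strictly
increasing vector of times). Three components, each with at most three
parameters and at most three interface variables, are chained behind a
synchronous event kernel with zero-delay propagation and pre-event state
semantics:

```
          ┌───────────┐    ┌────────────────┐    ┌───────────────────┐
 SA ──────► Pacemaker ├────► RefractoryGate ├────► AVConductionDelay ├────► V
          └─────▲─────┘    └───────┬────────┘    └───────────────────┘
                └───── reset ──────┘
```

* `Pacemaker(period)` — passes inputs through; fires spontaneously at
  `t_last_reset + period`. Its reset is a *separate* input fed from the
  refractory gate's output, so blocked signals do not postpone escape
  beats.
* `RefractoryGate(d_refrac)` — forwards an event iff the time since the
  last event it emitted is `> d_refrac` (strict).
* `AVConductionDelay(d_min, d_amp, tau)` — releases a held signal after
  `d(t_rec) = d_min + d_amp · exp(−t_rec/τ)`, where `t_rec` is the time
  since its last output (the AV-nodal recovery curve).

The primary readout is the interbeat interval `d_interbeat`, the spacing of
consecutive ventricular events. A scheduling-based monolithic
implementation of the same physiology (5 scalar parameters) ships as an
equivalence oracle, and a PVC extension adds a ventricular refractory gate,
two OR gates, one AND gate and a trigger input.

## Worked example

```r
library(condsim)

m <- build_modular_conduction(conduction_params(d_refrac = 0.3, period = 2),
                              delay_fn = constant_delay_fn(0.1))
res <- simulate_model(m, sim_config(0, 3),
                      external = list(inp = c(0, 0.8, 1.6, 2.4)))
port_trace(res, "outp")
#> [1] 0.1 0.9 1.7 2.5
interbeat_series(res)
#>   time_s d_interbeat_s
#> 1    0.9           0.8
#> 2    1.7           0.8
#> 3    2.5           0.8
```

Every SA beat (interval 0.8 s > `d_refrac`) conducts with the 0.1 s delay:
1:1 conduction, `d_interbeat` = 0.8 s. Halving the SA interval to 0.4 s
(≤ `d_refrac`) makes the gate absorb every second beat — 2:1 block with
`d_interbeat` still 0.8 s. Removing the SA drive entirely leaves the
escape rhythm:

```r
res <- simulate_model(m, sim_config(0, 7))
port_trace(res, "outp")
#> [1] 2.1 4.1 6.1
```

A conducted PVC (trigger outside the ventricular refractory period) fires
the ventricles immediately and resets the conduction chain retrogradely,
yielding the classic short-coupling/compensatory-pause pair:

```r
pm <- build_pvc_conduction(
  pvc_model_params(conduction_params(d_refrac = 0.3, period = 5),
                   d_refrac_ventricle = 0.2),
  delay_fn = constant_delay_fn(0.1))
res <- simulate_model(pm, sim_config(0, 4),
                      external = list(inp = seq(0, 4, by = 0.8), PVC = 1.45))
interbeat_series(res)
#>   time_s d_interbeat_s
#> 1   0.90          0.80
#> 2   1.45          0.55
#> 3   2.50          1.05
#> 4   3.30          0.80
```

A trigger *inside* the refractory period (e.g. at `t = 0.95`, 50 ms after
the beat at 0.9) is absorbed without any effect.

## Command line

```sh
exec/condsim simulate --config cfg.json --out-dir out --seed 1
exec/condsim compare  --config cfg.json --out-dir out --tol 1e-6
exec/condsim pvc      --config cfg.json --out-dir out
exec/condsim diagram  --model pvc -o pvc.dot     # Graphviz wiring diagram
```

Experiment configs are JSON (or YAML) with keys `model`, `t_stop`, `seed`,
`params` (`d_refrac_s`, `period_s`, `av$…`), `stimulus` (constant interval,
random 5–10 s interval switching, or a CSV trace), and `pvc_times_s`.
Outputs (`traces.csv`, `interbeat.csv`, `provenance.json`) are
byte-reproducible from config + seed.

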