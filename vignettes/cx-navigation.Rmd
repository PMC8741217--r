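---
title: "Methods: a central-complex model of multimodal insect navigation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a central-complex model of multimodal insect navigation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cxnav)
```

## The model in one page

`cxnav` simulates point agents steered by an abstraction of the insect
central complex (CX). One population code carries every directional
signal: eight heading cells with preferred angles 45° apart, activated as a
raised-cosine bump `a_i = A (1 + cos(θ − φ_i)) / 2`. The model's claim is
architectural: chemotaxis, odour-gated anemotaxis, path integration (PI),
their integration, and displacement-recovery manoeuvres all reduce to
producing a *desired heading* in this one format and handing it to a single
steering circuit.

Desired headings come from a *copy-and-shift* operation: copy the current
compass bump, shift it laterally by an angle dictated by the sensory
context. A drop in odour concentration shifts by an amount proportional to
the drop (chemotaxis: the agent deviates when things get worse, and holds
course otherwise); the wind-projection-neuron (WPN) pathway shifts by the
egocentric upwind angle (anemotaxis); PI supplies its own bump whose
amplitude is the remaining home-vector fraction. A truth table over the
concentration `C` and its change `ΔC` — thresholds `Thr_o`, `Thr_on`,
`Thr_off` — selects which olfactory strategy is active (ON: surge upwind;
OFF: chemotactic recovery; otherwise an undirected walk). Where two cues
coexist (ant homing), a ring attractor settles their weighted combination
into a single bump. The steering circuit turns the desired-minus-current
offset into a signed turn; the agent advances one fixed step `SL` per time
step (all speeds are per step; no wall-clock mapping is defined).

## Simulated worlds

* **Gradient landscapes** (no wind). Outside the rim circle `d = r/2`:
  `C = k e^{τ(r/2−d)}`. Inside, the *volcano* dips as `k e^{τ(d−r/2)}` and
  the *linear* variant as `k − 0.2 e^{τ(d−r/2)}` (clamped at 0). We read
  the second branch of the linear form as `k` minus a small exponential
  term — the reading that keeps the rim the global maximum and the field
  continuous to within the 0.2 offset; the alternative grouping
  `(k−0.2)e^{...}` would explode toward the centre. Defaults `k = 10`,
  `τ = 0.1 cm⁻¹`, `r = 6 cm`.
* **Gaussian plume** under constant wind `u` toward `θ_w`. With downwind
  distance `dw` and crosswind distance `cw` of the query point from the
  source, `C = q/(u σ √2π) · exp(−cw²/(2σ²))`, `σ = K_s · dw`, and `C = 0`
  on the whole upwind side (`cos θ ≤ 0`). This is the standard steady-state
  plume: crosswind distance in the exponent, downwind distance setting the
  spread, the only combination that widens the plume downwind. Near the
  source `dw` is clamped to a guard radius `eps` (one step length), capping
  the `σ → 0` singularity at its value on the eps-circle. `K_s` tunes
  plume tightness; we fix 0.2, the midpoint of the admissible set
  {0.5, 0.3, 0.2, 0.15, 0.1}, for every preset.
* The geometry underlying the plume dots the *source→position* vector with
  the wind vector. The alternative (position→source) would put all odour
  upwind of the source, which no plume does; we therefore use the
  formulation whose downwind region carries odour.

Angles are radians, counter-clockwise from +x; `θ_w` is the direction air
flows *toward*. Arena units are centimetres for the fly experiments. For
the ant experiments the release points (±1.5, −10), the 10 m home vector
and `SL = 0.05` are only mutually consistent if positions and step length
share one unit, so the ant arena is metres with `SL = 0.05` m/step; the
route then takes ≈ 200 steps, matching the group-heading snapshots at
t = 20 and t = 250.

## Numerical and circuit-level choices

**Shift interpolation.** Shifts are quantised to 4.5° by upsampling the
ring 8 → 80 columns, rolling by the rounded shift, and downsampling every
10th column. We upsample by *trigonometric (band-limited) interpolation*:
for an 8-sample ring this makes the roll an exact rotation of the
population vector, so a one-column shift decodes to exactly 45° and a
one-fine-column shift to exactly 4.5°. Periodic linear interpolation
(available as `interp = "linear"`) distorts fractional shifts (a single
fine column decodes to ≈ 4.17° for a raised-cosine bump) because chord
interpolation in activation space is not a rotation.

**Steering bank offset.** Each steering bank receives the desired-heading
ring rolled by `offset_cols` native columns (counter-clockwise for the left
bank, clockwise for the right), minus the current bump, rectified at zero;
the turn is `k_motor (Σ_L − Σ_R)`. With rectified raised-cosine bumps the
one-column offset inherited from classic homing-circuit wiring produces a
command that *peaks at 45° and declines beyond* (turn(67.5°) < turn(45°)),
i.e. it is not monotone over a quarter turn. A two-column (90°) projection
yields a strictly monotone, sin-like command on (−90°, +90°) with the same
zero at alignment and exact sign antisymmetry; it is the default
(`offset_cols = 2`), with the one-column wiring kept as an option.

**Firing-rate scale.** The published motor gains (`k_motor` = 1.0 or 1.5)
refer to an unstated activation scale. With unit-amplitude bumps the
steering loop's slope at alignment is ≈ 1.75·A·k_motor per radian of
offset; `k_motor = 1.5` would put the heading servo in a sustained
oscillation (slope > 2), i.e. high angular velocity precisely while the
agent tracks a fixed upwind heading — the opposite of the surge behaviour
the ON response produces. All rings therefore share one rate currency
`compass_amp = 0.5`: the anemotaxis servo is well damped (slope ≈ 1.3)
while chemotactic turns remain strong enough to climb the volcano. The
Eq.-style turn law `k_motor (Σ_L − Σ_R)` is kept exact.

**Chemotaxis shift quantisation.** The shift is
`min(max(k_chemo·|ΔC|, 1), 3)` native columns on any sensed drop (zero
otherwise), with fractional columns realised at 4.5°. The minimum of one
column is load-bearing: per-step drops on the landscape flanks are of
order 10⁻³ a.u., so an integer-floored shift (deadband 0.01 a.u.) leaves
agents blind beyond ≈ 11 cm and a purely proportional shift produces
corrections so small that agents settle into slow near-circular contour
orbits instead of climbing. One guaranteed column per detected drop
restores the run-and-tumble regime; `chemo_min_shift = 0` recovers the
proportional variant. The turn direction on a drop is predefined
(default counter-clockwise, `chemo_direction`), and
`chemo_sign_convention = "rise"` preserves the literal alternative in which
an *increase* drives the shift (functionally broken: agents then go
straight whenever concentration falls, and straight lines eventually leave
any gradient).

**Ring attractor.** `τ dC/dt = −C + g(W C + X + w_I2E·mean(C))` with
`g(c) = max(0, ρ + c)` and kernel `W_ji = w0 + w1 cos(φ_j − φ_i)`.
Forward Euler, `dt = 0.2`, `τ = 1`, convergence when the max per-unit
change < 10⁻⁵, budget 500 steps, error (class
`cxnav_ra_nonconvergence`) on failure. The weights are not published; they
are fixed by two testable contracts: a single cue must settle into one bump
at the cue direction, and two cues must decode to their amplitude-weighted
circular mean within 5° over amplitude ratios 0.1–1 and separations up to
90°. The first-harmonic recurrent gain is `4·w1`; at `w1 = 0.25` the ring
is critical and winner-take-all dynamics pull the bump ≈ 6° toward the
stronger cue at large separations, violating the contract. We use the
subcritical `w1 = 0.15` (with `w0 = −0.05`, `w_I2E = −0.2`, `ρ = 0`): the
linearised fixed point then amplifies the input's first harmonic without
rotating it, rectification preserves its phase, and the residual decode
error (≈ 2° worst-case, from 8-sample aliasing of clipping harmonics) sits
well inside the contract. Inside simulation loops the attractor is
warm-started from the previous step's state, which only changes the number
of Euler steps, not the fixed point.

**Degenerate inputs.** An all-zero or uniform ring has no direction:
`decode_ring()` returns magnitude 0 with an `NA` sentinel. A plume query at
the source returns the capped centreline value; the upwind boundary
(`cos θ = 0`) is odour-free. Turns are capped at π/2 per step
(`turn_cap`) to stop numerical spin at extreme steering imbalances.

## Experiments and their presets

Each published experiment is a preset binding every parameter
(`cx_presets()`): fly chemotaxis (volcano/linear; 5 agents × 1500 steps ×
4 repeats, start zone ±12 cm, `k_chemo = 100`, `k_motor = 1`,
`SL = 0.02`); fly anemotaxis (4 agents × 200 steps × 5 repeats, start zone
(−1.5, 1.5) × (−13, −5), plume `q = 10`, `u = 10`, `θ_w = −π/2`,
`k_motor = 1.5`, `SL = 0.4`, odour gated ON during the second quarter of
the run); the integrated fly experiment (same, plus `Thr_o = 0.001`,
`Thr_on = 0.02`, `Thr_off = −2·10⁻⁴`); ant homing (10 ants per release
point (±1.5, −10), full 10 m home vector pointing north, nest plume
`q = 20` with `θ_w = π`, `Thr_o = 1.2`, `Thr_on = 0.5`, `k_o = 0.5`,
`SL = 0.05`); and the two manoeuvres (memory formed at a scripted trigger
from capture heading π/2, 10 agents with uniform random headings, 50
steps). Initial headings are uniform on (0, 2π) throughout; start
positions are uniform in the start zone.

Choices the source description leaves open, fixed here once:

* **Ant run length** 400 steps — covers the t = 250 group-heading snapshot
  and leaves a search margin after the PI vector is spent.
* **Distractor nest** at (−1.0, −8.0) with the home-nest emission rate
  (position/rate exposed in the config); it lies in the left release
  column's path so those ants are briefly captured by the conspecific
  plume before the home plume and PI take over.
* **RANDOM-mode kinematics**: a correlated random walk, heading jitter
  uniform within ±30°/step (`jitter`).
* **Lost-ant fallback**: when the integrated ring carries no appreciable
  direction (decoded magnitude < 0.05·`compass_amp`; PI spent, no odour),
  the runner applies the RANDOM-mode jitter directly — a zero steering
  signal would otherwise send lost agents straight forever, where the
  behaviour being modelled is an undirected search.
* **Arrival** is the first entry within 0.5 m of the nest. Agents do not
  stop (speed is constant by construction), so endpoint scatter after
  arrival reflects post-arrival search; path-length comparisons use the
  arrival-truncated walk.
* **Odour gating** multiplies the field by a 0/1 schedule, so `ΔC` spikes
  naturally at gate transitions and the switching circuit sees them.

Determinism: every run is a pure function of (config, seed). Each
(repeat, agent) pair gets an independent seed derived from the run seed, so
shrinking the agent count reproduces a prefix-subset of the larger run.

## What the simulations do and do not show

The analytic worlds are the laboratory idealisations the behavioural
literature itself uses: steady, smooth, noiseless fields. Real plumes are
turbulent and intermittent; real receptor pathways adapt and normalise;
none of that is modelled, so passing tests demonstrate the *circuit logic*
— frame alignment of cues, switching, weighted integration, memory
transfer — not robustness to naturalistic stimulus statistics. Valence is
raw concentration: no associative (mushroom-body) learning stands between
stimulus and steering. Speed is constant, motion is 2-D, there is no
collision or boundary physics, and working memories persist until the
script clears them (no decay). The truth table is evaluated on
single-step differences; sensors have no noise, so thresholds act as hard
switches. Within those limits, the test suite and `scripts/acceptance.R`
exercise the full pipeline at the published problem sizes (20 chemotaxis
agents, 20 anemotaxis agents × 5 repeats, 20 homing ants per condition)
and every number they report is recomputed at run time.
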