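---
title: "A lumped-parameter model of pumping in branched lymphatic networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lumped-parameter model of pumping in branched lymphatic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lymphnet)
```

## The model

Collecting lymphatic vessels return interstitial fluid to the venous
circulation without a central pump: the vessel wall itself contracts
rhythmically, and numerous one-way intraluminal valves partition each vessel
into unit pumps called *lymphangions*. `lymphnet` simulates lymph transport
through a symmetric converging tree of such vessels (generation `G` holds the
`2^(G-1)` inlet vessels at pressure `p_a`; sibling vessels merge at junctions
until a single outlet vessel discharges at `p_b`; default `G = 3`, seven
vessels). Every vessel holds `nv` lymphangions in series, each of length `L`
and time-varying diameter `D_i(t)`.

Each lymphangion is a 0D (lumped) compartment governed by three ingredients.

**Wall force balance.** The internal midpoint pressure is an explicit
function of state,

    p_m = p_e + f_p(D) + f_a(D, t),

where `p_e` is the steady external (tissue) pressure. The passive tube law
`f_p` is the empirical pressure-diameter relation of isolated rat mesenteric
collecting lymphatics: a quadratic-plus-exponential stiffening branch and a
cubic collapse term, scaled by `Pd = 732 dyn/cm2` with characteristic
diameter `c9` (~260 um). It is strictly increasing on the working branch, so
a relaxed vessel has a unique equilibrium diameter at any attainable
transmural pressure (`passive_equilibrium_diameter()`). The active pressure
is a Laplace-law tension `f_a = 2 M0 Md(D) Mt(t) / D`: `M0 = 250 dyn/cm`
scales contraction strength, `Md(D)` is a smooth bump in diameter expressing
the length-tension relation of lymphatic muscle (near 1 between `0.85*c9`
and `2*c9`, near 0 for collapsed or over-distended vessels) and `Mt(t)` is a
raised-cosine systolic waveform of duration `1/f` followed by a diastolic
rest of duration `tr`, repeating with period `T = 1/f + tr`.

**Valves.** Valve resistance is a smooth double-sigmoid in the pressure
difference across the valve: `RVn = 0.5e6 g/(cm^4 s)` when open under
forward pressure, rising to `RVn + RVx` (`RVx = 9.9e9`) once the difference
falls below the slightly negative closing threshold `dpo = -15 dyn/cm2`, and
collapsing back to `RVn` below the failure (prolapse) pressure
`dpf = -18.4 cmH2O`. Because the law is smooth, no event handling is needed
in the integrator, but the four-decade resistance range makes the system
stiff.

**Conservation laws.** Poiseuille flow with resistance
`Rves = 64 mu L / (pi D^4)` connects adjacent midpoints through the
intervening valve, and conservation of mass per lymphangion closes the
system as a nonlinear ODE in the diameters:

    dD/dt = 2 (Q_in - Q_out) / (pi D L).

At a junction the two children's terminal valves discharge into a shared
node whose pressure is found from mass balance; the parent vessel's first
half-resistance connects that node onward, so no additional valve is placed
at the junction itself (this is the literal reading of the junction momentum
balance, in which only the child paths carry valve terms).

Contraction timing is a wave: lymphangion `j` (1-based, upstream to
downstream) of a vessel in generation `g` starts contracting at
`(G - g) * ((nv - 1) dtv + dtg) + (j - 1) dtv` (mod `T`), so `dtv` is the
conduction delay within a vessel and `dtg` the extra delay per junction
crossing. Delays above `T/2` are equivalent to a reverse-propagating wave
with delay `T - dt`.

## Numerical scheme

Because `p_m` is explicit in `(D, t)`, the algebraic stage decomposes: every
valved path reduces to one scalar root-find for its flow (the root is
bracketed since the valve resistance is bounded; a safeguarded Newton
iteration converges it to ~1e-14 relative residual), and every junction to
one scalar root-find for its node pressure (strictly monotone mass-balance
residual). This decomposition was chosen over a monolithic
differential-algebraic formulation for robustness and testability; the test
suite retains a monolithic damped-Newton solver of the full simultaneous
system as an independent oracle and checks agreement to 1e-6 relative on
random states. Junction mass balance is exact by construction (the parent
flow is the sum of the child flows); the root-find residual lands in the
parent momentum equation, where the oracle comparison checks it.

The diameter ODEs are integrated with `deSolve::lsoda` (`rtol = 1e-6`,
`atol = 1e-10 cm`), the counterpart of the stiff MATLAB integrator commonly
used for such models. Initial diameters are the relaxed passive equilibrium
at transmural pressure `p_a - p_e`; the initial transient is discarded by
running cycle by cycle (at least 10, at most 200) until two successive
cycle-averaged outlet flows agree within 0.5% relative (or 2e-4 ml/hr
absolute, which governs near-stall runs). The reported output `Qbar` is the
trapezoidal time average of the flow through the final outlet valve over the
last full cycle, converted at 1 cm^3/s = 3600 ml/hr; a
perturbed-initial-condition test and a phase-shift test confirm the
transient policy makes both choices immaterial. Each cycle is sampled at 80
output points for the averages and series. Halving the grid step, shifting
the global phase, or tightening `rtol`/`atol` by two decades moves `Qbar` by
less than 0.1% in the regression checks.

## Choices where the source material is ambiguous

Four aspects of the published description admit more than one reading; the
package fixes each with an explicit, audited choice:

* **Characteristic diameter.** The tube-law constant is taken as
  `c9 = Dd / c11` (~0.026 cm), which reproduces physiological rat
  mesenteric diameters; the alternative product reading (~27 um) is
  retained behind `lymph_params(c9_mode = "product")` but is not
  physiological.
* **Muscle length-tension factor.** As printed, both sigmoids of `Md`
  are centred at `Da` and cancel identically to zero; the second sigmoid is
  taken to sit at `Db = 2*c9` (which is otherwise defined but unused),
  giving the intended bump. `lymph_params(md_form = "literal")` preserves
  the degenerate form for audit.
* **Half-segment resistance.** Both half-lymphangion pressure drops use the
  full-length resistance `64 mu L / (pi D^4)`, literally as written.
  `lymph_params(half_segment = TRUE)` provides the `L/2` convention of
  related earlier models; it raises favorable-head flows by ~50% and fits
  the published values distinctly worse, supporting the literal reading.
* **Units.** All internal computation is CGS; boundary and threshold
  pressures quoted in cmH2O convert at 980.665 dyn/cm2 per cmH2O. The valve
  failure pressure (-18.4 cmH2O) is converted before the slope `sf`
  (cm2/dyn) is applied; the closing threshold is used as printed in
  dyn/cm2. Switching 980.665 to 980 moves outputs well under 0.1%.

Two further conventions are fixed where the source is silent: the wave's
absolute phase starts at 0 at the inlet generation (irrelevant at the
periodic state, asserted by the phase-shift test), and `Qbar` is measured at
the outlet valve rather than the outlet lymphangion midpoint (their periodic
means coincide, asserted in the tests).

## What the simulations show

```{r example, eval = FALSE}
topo <- build_network(3, 4)
params <- lymph_params()
sched <- contraction_schedule(topo, dtv = 0.5, dtg = 0.5,
                              Tc = params$Tc, tr = params$tr)
sim <- run_simulation(topo, sched, boundary_conditions(6, 9, 2), params)
sim$qbar_ml_hr  # 1.15 ml/hr against a 3 cmH2O adverse head
```

The sweep drivers regenerate the published result families:
`pump_function_curve()` (flow vs outlet pressure for a given network size),
`sweep_external_pressure()` (the transmural-pressure optimum),
`sweep_diastolic_period()` and `sweep_time_delay()` (coordination effects),
with `reproduce()` enumerating the full condition grids. Where the source
states sweeps only as "incrementally increased", the grid steps are 0.05 s
for time delays (the published optima are multiples), 0.2 cmH2O for external
pressure, 0.5 s for the diastolic period and 1 cmH2O for outlet pressure;
peaks are always reported from the grid, never interpolated.

Representative checks computed by the test suite and the acceptance script
(all at baseline parameters): the single-lymphangion-per-vessel network
yields ~3.3 ml/hr under a 3 cmH2O favorable head, ~1.4 ml/hr at `nv = 14`;
`nv = 10` is the grid optimum at axial differences of 0, 10 and 16 cmH2O
(~1.39, 0.83 and 0.21 ml/hr here); a 0.15 s joint conduction delay
maximises flow under moderate loads (~2.0, 1.8, 1.2 ml/hr at -3, 0, 6
cmH2O); the external-pressure sweep for `nv = 2` against a 3 cmH2O adverse
head peaks at ~0.9 ml/hr at a transmural pressure of 4 cmH2O; and the
baseline 1.5 s diastolic period is the grid argmax under the baseline
adverse load. One published value falls outside a 10% relative band: the
near-stall flow of the `nv = 1` network against an 18 cmH2O adverse head
(published 0.012 ml/hr, simulated ~0.0145). The absolute difference is
~0.003 ml/hr in a regime where the pump is essentially stalled and the
output is dominated by brief systolic spurts; the value is insensitive to
integrator tolerances, cycle counts and output-grid resolution here, so the
residual gap is attributed to the formula ambiguities above and the
published value's own rounding. The companion ordering claim (the `nv = 14`
network pumps an order of magnitude more than `nv = 1` at that load) holds.

## Scope and limitations

The model deliberately omits shear- or stretch-dependent autoregulation of
contraction, transmural-pressure-dependent valve behavior, fluid inertia,
non-Newtonian rheology, vessel tethering gradients, time-varying external
pressure, and structural heterogeneity (asymmetric trees, anastomoses,
per-vessel parameter variation): every vessel shares one parameter set and
`nv`. Passing its tests therefore demonstrates faithful reproduction of this
idealised pump, not predictive accuracy for any particular in vivo network;
in particular the tube law and timing constants are specific to rat
mesenteric vessels. Problem sizes in the test suite are kept small (trees of
1-3 generations, 1-14 lymphangions per vessel, tens of contraction cycles),
matching the published study's scale.
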