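---
title: "Conductance-based modelling of ON and OFF retinal ganglion cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conductance-based modelling of ON and OFF retinal ganglion cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`rgcsim` simulates retinal ganglion cells (RGCs) as trees of cylindrical
compartments obeying a Hodgkin–Huxley-type current balance. Each compartment
carries nine membrane currents: leak, transient sodium (m³h), high-voltage
activated calcium (c³, with a dynamic calcium reversal potential), delayed
rectifier potassium (n⁴), A-type potassium (a³h_A), calcium-activated
potassium (conductance saturating in the submembrane calcium concentration,
half-maximal at the 1 µM dissociation constant), an h-current (l), a T-type
low-voltage-activated calcium current (m_T³h_T, whose inactivation has two
closed states), and a persistent sodium current (p). Compartments couple
through axial conductances computed from cylinder geometry and an axial
resistivity of 110 Ω·cm.

Intracellular calcium evolves in a 0.1 µm submembrane shell, driven by the
HVA calcium current and cleared toward a 0.1 µM residual level with a 1.5 ms
time constant; the calcium reversal potential follows the two-valence Nernst
relation at 32 °C. The T-current uses the fixed 120 mV reversal.

Three maximal densities are free parameters — persistent sodium
(`g_NaP`), T-type calcium (`g_T`) and the h-current (`g_h`) — while all other
densities are fixed per region: soma, dendrites, and a standardized
four-region axon (40 µm initial segment, 90 µm narrow segment of 0.4 µm
diameter, 5340 µm distal axon, and a sodium-channel band (SOCB) spanning arc
distances 30–70 µm with five-fold Na and NaP density). The leak is the
15-fold adjusted value 1.2×10⁻⁴ S/cm² everywhere except the distal axon
(25-fold); the distal-axon NaP multiplier of 0.05 keeps spike initiation in
the SOCB and propagation orthodromic.

## Reading the printed rate table

Two entries of the printed rate-constant table admit more than one reading,
and the package resolves them as follows:

* **β_mT** is implemented with the full printed numerator
  `1 + exp(−(V+63)/7.8)`, which caps the T-activation steady state at 0.5.
  The alternative (dropping the `1 +`, recovering the classical LVA
  activation midpoint at −63 mV) makes `g_T = 3×10⁻⁴ S/cm²` alone drive
  spontaneous firing on the reference cell, contradicting the reported
  behaviour of the model (a NaP threshold of 1–3×10⁻⁵ S/cm² at that `g_T`,
  and silence of low-conductance points). The printed form reproduces those
  quantitative behaviours and is used as-is.
* **α_p** as printed is the product of the NaP steady state and its time
  constant, which is not a rate; the package uses `α_p = p_inf/τ_p` with
  `p_inf = 1/(1+exp(−(V+48)/10))` and the printed branch-wise `τ_p`, the only
  dimensionally consistent reading (the printed `β_p` already equals
  `(1−p_inf)/τ_p`, confirming the conversion).

Removable singularities of the α functions (at −30, −13, −40 and −90 mV)
switch to a second-order series within 10⁻⁶ mV of the singular point. No
temperature scaling is applied to the rates: the printed values are used
directly, and temperature enters only the calcium Nernst potential. The
factor 3 in the calcium-shell drive is kept as printed.

## Numerics

The integrator advances, per time step (default `dt` = 0.025 ms): gates →
calcium → voltage. First-order gates relax by the exact exponential update at
frozen voltage; the coupled (h_T, d) inactivation pair takes one implicit
backward-Euler step of its linear two-state system; calcium takes its exact
linear update at frozen calcium current; and the voltage solves the
tree-structured linear system implicitly in one O(N) Hines sweep
(elimination from the leaves, back-substitution from the root). A
Crank–Nicolson voltage variant is available. With all active conductances
removed the solver reproduces the analytic RC response to better than 1 %,
and with every reversal pinned to the initial potential the voltage is
conserved to machine precision.

Inside the compiled stepper the gating rates are evaluated from
voltage-indexed lookup tables (0.05 mV grid, linear interpolation, rebuilt
for each `dt`); the interpolation error is orders of magnitude below the
time-discretization error. Halving `dt` from 0.025 to 0.0125 ms shifts spike
times on the reference cell by at most ≈0.15 ms over one second of activity
(a first-order phase accumulation of the implicit scheme), without changing
spike counts.

Morphologies must be discretized before simulation; the experiments in this
package split compartments at a 40 µm maximum length (about 210 compartments
for the reference cell), which is short relative to the ≈400 µm passive
space constant at the adjusted leak. The axon attachment pins compartment
boundaries at 30, 40, 70 and 130 µm so the SOCB is exactly representable
under any further discretization; SOCB membership is decided by compartment
midpoint arc distance, which is unambiguous for any split.

## The synthetic morphology generator

Real reconstructions are interchangeable with synthetic cells throughout the
package (`read_swc()` accepts the standard 7-column SWC format), but every
experiment and test runs on generated morphologies so the pipeline is
self-contained. The generator builds a soma cylinder plus binary-branching
dendritic trees: branch lengths are drawn from a truncated normal, diameters
taper geometrically with branch order, and the standard axon is attached.
Generation is a pure function of its parameter list (one private RNG stream
per cell) and rejects draws whose morphometry leaves the explored-population
ranges (total area 969–32457 µm², dendrite-to-total area ratio 0.30–0.99,
7–377 dendritic tips).

The `compliant` preset (soma 16.5 µm, four primaries, depth 3, mean branch
length 32 µm, taper 0.62, primary diameter 1.9 µm) targets the
population means of constraint-meeting cells — total area ≈5230 µm² and
dendrite-to-total ratio ≈0.84 — and the seed-1 cell of this preset is the
canonical reference fixture (shipped as `extdata/reference_cell.swc`, and
regenerated bit-identically). The `noncompliant` preset (small soma, uniform
thick dendrites, total area ≈15000 µm²) mirrors the morphology of cells that
fail the electrophysiological constraints. The generator emulates aggregate
statistics only: planarity, stratification, Sholl profiles and the
length scale of real dendritic fields are not modelled, so passing tests
demonstrate the behaviour of the model equations on realistic *area
budgets*, not agreement with any particular reconstruction.

## Measurements and constraint evaluation

Spikes are upward crossings of 0 mV (1 ms refractory); mean membrane
potentials exclude 2 ms after any point where dV/dt exceeds 10 mV/ms; the CV
of the inter-spike interval uses the sample (n−1) standard deviation, a
choice the source material leaves open. Step-response metrics take the
steady hyperpolarized potential over the last 20 % of the step (the exact
window is unstated in the source; this one is documented and fixed), the sag
as the nonnegative difference between the early minimum and that steady
state, and the rebound burst rate over the 200 ms after step offset.
Subthreshold oscillations are detected on the de-spiked, detrended,
500 Hz-decimated trace by a Welch periodogram (three Hann segments, 50 %
overlap): a peak in 0.5–12 Hz carrying at least three times the spectral
median power, with a band-passed peak-to-peak of at least 0.1 mV, counts as
present; it is sustained if the second half of the window retains half the
first half's amplitude. The presence and sustainment thresholds are package
choices; only the frequency and amplitude ranges come from the source data.

Input resistance is primarily the somatic steady-state ΔV/ΔI for a −10 pA
probe with spike-removed means over the last 500 ms of 1 s windows; a
secondary mode averages the deflections at each primary dendrite's first
compartment. Phenotype classification follows the constraint table: ON
(rest −70…−62 mV, silent, no step spikes, no rebound), OFF-transient
(rest −62…−50 mV, 15–23 Hz spontaneous, silent during the −0.2 nA step,
rebound ≥ 2× the spontaneous rate) and OFF-sustained (same with 40–48 Hz).
Spontaneous rates are measured over 1 s after a 500 ms settle, and OFF
points with zero spontaneous rate are labelled `none` (the ≥2× rebound rule
degenerates there). Connected valid sets use 6-neighbour (face) adjacency,
the strictest standard choice; 26-neighbour adjacency is available.

## Problem sizes and observed behaviour

The shipped experiments run single cells of ≈210 compartments for 1.5–20 s
of biological time per condition, and the conductance-space driver
classifies a 32-point lattice — deliberately desk-scale versions of what is,
at full population size, a cluster-scale computation. On the reference cell:
the NaP spontaneous-activity threshold at `g_T = 3×10⁻⁴` falls at
1.66×10⁻⁵ S/cm²; OFF-transient and OFF-sustained rate bands are reachable
(e.g. 23 Hz at (2.33×10⁻⁵, 2.7×10⁻⁴) and 41 Hz at (3×10⁻⁵, 4×10⁻⁴)); the
−0.2 nA step is spike-free with 60–100 Hz rebound bursts; evoked spikes
initiate in the SOCB 0.5 ms before the soma and reach the distal axon end
~15 ms later; and the somatic input resistance at the adjusted leak is
173 MΩ.

## Known limitations

* The reference cell rests near −55 mV at OFF-range conductances but never
  reaches the −62…−70 mV ON resting band, so the ON phenotype is empty on
  this fixture; ON classification is exercised through constructed reports.
* With the printed kinetics the firing-to-silence transition under
  increasing hyperpolarization is abrupt: the model shows no sustained
  subthreshold oscillations on the synthetic fixtures at the documented
  OFF-S points, and the rebound latent period (≈17 ms) sits just below the
  20–80 ms range reported for the source cells. Both are recorded as-is by
  the acceptance checks rather than adjusted.
* The h-current as printed activates with depolarization and relaxes on the
  millisecond scale, so hyperpolarization sag is well under 1 mV.
* Soma shrinkage strengthens rebound bursting on the compact fixture,
  whereas the source cells weaken; the dendritic-series trends (stronger
  bursts, taller and faster spikes with shrinking dendrites) reproduce.
* No synaptic input, extracellular stimulation, stochastic gating, or sodium
  channel subtypes; axon geometry is fixed across cells by design.
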