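# rgcsim

Multicompartment conductance-based models of ON and OFF retinal ganglion
cells (RGCs), for computational neuroscientists studying how dendritic and
somatic morphology shapes intrinsic firing.

ON and OFF RGCs differ intrinsically even without synaptic input: OFF cells
fire spontaneously, burst at the offset of hyperpolarization, and show 1–10 Hz
subthreshold oscillations, while ON cells are silent and rebound-free. This
package reproduces that dichotomy with Hodgkin–Huxley-type cable models on
compartmental trees. Each compartment obeys

C_m dV/dt = −[ ḡ_L(V−V_L) + ḡ_Na m³h(V−V_Na) + ḡ_Ca c³(V−V_Ca(t))
  + (ḡ_K n⁴ + ḡ_K,A a³h_A + g_K(Ca)([Ca²⁺]ᵢ))(V−V_K) + ḡ_h l(V−V_h)
  + ḡ_T m_T³h_T(V−V_T) + ḡ_NaP p(V−V_Na) ] + I_axial + I_stim

with first-order gate kinetics (the T-current inactivation pair (h_T, d) has
two closed states), a submembrane calcium shell driving the K(Ca) conductance
and the calcium Nernst potential, and a standardized four-region axon whose
sodium-channel band (SOCB, arc 30–70 µm, five-fold Na/NaP density) is the
spike initiation site. Three densities are free — ḡ_NaP, ḡ_T, ḡ_h — and a
constraint-driven grid search classifies each (ḡ_NaP, ḡ_T, ḡ_h) point as ON,
OFF-transient, OFF-sustained, or none, from its resting potential,
spontaneous rate, silence during a −0.2 nA step, and rebound burst rate.

The package covers: SWC morphology I/O and standardization, a seeded
generator of RGC-like synthetic trees (so everything runs without external
reconstructions), the implicit Hines-solver integrator (Rcpp), current-clamp
protocols, spike-train and subthreshold analysis (CV of the ISI, sag, latent
period, Welch-based oscillation detection), phenotype classification with
connected valid-set extraction, and the morphology-reduction experiment.
See `vignettes/rgc-conductance-model.Rmd` for the model details and numerical
choices, and `analysis/01…07` for the narrative experiment drivers (tables
land in `results/`).

## Worked example

```r
library(rgcsim)

# the canonical synthetic cell, discretized for the cable solver
cell_morph <- discretize(reference_fixture(), 40)
morphometry(cell_morph)
#> Morphometry: S_total 5233.6 um^2 (soma 855.3, dendrite 4378.3), S_axon 17014.9 um^2
#>   R_dend,total 0.837  R_soma,total 0.163  tips 32  bifurcations 28

# an OFF-transient candidate conductance point (S/cm2)
report <- evaluate_point(cell_morph, c(2.33e-5, 2.7e-4, 1e-11))
cat(sprintf("rest %.1f mV | spontaneous %.0f Hz | spikes during -0.2 nA step %d | rebound %.0f Hz\n",
            report$rest_mV, report$spont_Hz, report$spikes_during_hyp,
            report$rebound_rate_Hz))
#> rest -55.0 mV | spontaneous 23 Hz | spikes during -0.2 nA step 0 | rebound 70 Hz
classify_point(report)
#> [1] "OFF_T"
```

The cell's total surface area (soma + dendrites, axon excluded) and
dendrite-to-total area ratio sit at the population means of cells that meet
the electrophysiological constraints; the axon area is the fixed
π·5416 µm². The conductance point rests in the OFF band, fires spontaneously
at 23 Hz (inside the 15–23 Hz OFF-transient window), stays silent during the
hyperpolarizing step, and rebounds at three times its spontaneous rate — an
OFF-transient phenotype.

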