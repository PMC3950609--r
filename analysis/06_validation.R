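#!/usr/bin/env Rscript
# Validation protocols on an OFF-sustained point of the reference cell:
# the staircase of increasing hyperpolarizing steps (regime transitions and
# per-level subthreshold-oscillation analysis) and the CV-of-ISI protocol
# (spiking irregularity against the spike-removed membrane potential).

suppressPackageStartupMessages(library(rgcsim))
dir.create("results", showWarnings = FALSE)

morph <- discretize(reference_fixture(), 40)
cfg <- simulation_config()
triple <- c(3e-5, 4e-4, 1e-9)

rep0 <- evaluate_point(morph, triple, cfg)
cat(sprintf("point (%.2g, %.2g, %.2g): %s (rest %.1f mV, spont %.1f Hz, rebound %.0f Hz)\n",
            triple[1], triple[2], triple[3], classify_point(rep0),
            rep0$rest_mV, rep0$spont_Hz, rep0$rebound_rate_Hz))

vr <- validate_point(morph, triple, cfg, cv_hold_duration = 10000,
                     report = rep0)

osc <- data.frame(
  level = 1:7, amplitude = -0.02 * (1:7),
  regime = vr$v2,
  osc_present = vapply(vr$v1, function(o) o$present, TRUE),
  osc_sustained = vapply(vr$v1, function(o) o$sustained, TRUE),
  osc_freq_hz = vapply(vr$v1, function(o) o$frequency, 1.0),
  osc_p2p_mv = vapply(vr$v1, function(o) o$peak_to_peak, 1.0))
print(osc)
write.csv(osc, "results/06_staircase.csv", row.names = FALSE)

cat("\nCV of the ISI vs membrane potential (-20 pA steps to -80 pA):\n")
print(vr$v3)
write.csv(vr$v3, "results/06_cv_vs_vm.csv", row.names = FALSE)
cat(sprintf("fitted CV-vs-Vm slope: %s\n",
            if (is.na(vr$v3_slope)) "undefined (too few spiking levels)"
            else sprintf("%.3f per mV", vr$v3_slope)))
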