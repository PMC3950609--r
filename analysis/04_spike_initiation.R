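#!/usr/bin/env Rscript
# Action-potential initiation site: a spike evoked at the soma crosses
# threshold first in the high-density sodium-channel band (SOCB), then at the
# soma, and reaches the distal axon end after orthodromic conduction.

suppressPackageStartupMessages(library(rgcsim))
dir.create("results", showWarnings = FALSE)

morph <- discretize(reference_fixture(), 40)
cfg <- simulation_config(record_sites = c("soma", "socb", "distal_axon"))
cell <- build_cell(morph, c(1e-5, 3e-4, 1e-9), config = cfg)

proto <- make_protocol("on_depolarize", hold_duration = 5, amplitude = 0.15)
attr(proto, "tstop") <- 300
proto$t_start <- 100
rec <- simulate(cell, proto, cfg)

out <- data.frame(site = c("socb", "soma", "distal_axon"))
out$threshold_crossing_ms <- vapply(out$site, function(s)
  detect_spikes(rec$v[, s], rec$dt)$spike_times[1], 1.0)
out$peak_ms <- vapply(out$site, function(s)
  rec$time[which.max(rec$v[, s])], 1.0)
print(out)
write.csv(out, "results/04_spike_initiation.csv", row.names = FALSE)

cat(sprintf("\nSOCB leads the soma by %.3f ms; the distal end follows %.1f ms later (%.0f um axon).\n",
            out$peak_ms[2] - out$peak_ms[1],
            out$peak_ms[3] - out$peak_ms[2], 5470))
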