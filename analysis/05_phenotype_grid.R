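#!/usr/bin/env Rscript
# Desk-scale conductance-space search: classifies a small (g_NaP, g_T, g_h)
# lattice on the reference cell into ON / OFF-transient / OFF-sustained
# phenotypes and extracts the connected valid sets. The full logarithmic
# sweep over [1e-15, 1e-1] S/cm2 is a cluster-scale computation; this lattice
# covers the linear refinement region where the OFF sets live.

suppressPackageStartupMessages(library(rgcsim))
dir.create("results", showWarnings = FALSE)

morph <- discretize(reference_fixture(), 40)
cfg <- simulation_config()

gnap <- c(1e-6, 2e-5, 2.33e-5, 2.66e-5, 3e-5)
gt <- c(1e-5, 2.7e-4, 3.3e-4, 4e-4)
gh <- c(1e-11, 1e-6)

t0 <- Sys.time()
grid <- grid_search(morph, gnap, gt, gh, cfg)
cat(sprintf("evaluated %d lattice points in %.1f min\n", nrow(grid$points),
            as.numeric(Sys.time() - t0, units = "mins")))
write.csv(grid$points, "results/05_grid_labels.csv", row.names = FALSE)

print(table(grid$points$label))
vs <- extract_valid_sets(grid)
for (lab in names(vs)) {
  ncomp <- length(vs[[lab]]$components)
  nsing <- nrow(vs[[lab]]$singletons)
  cat(sprintf("%s: %d connected set(s), %d singleton(s)\n", lab, ncomp, nsing))
  for (comp in vs[[lab]]$components) {
    bb <- attr(comp, "bbox")
    cat(sprintf("  %d points, g_NaP [%.2g, %.2g], g_T [%.2g, %.2g]\n",
                nrow(comp), bb["gnap", 1], bb["gnap", 2],
                bb["gt", 1], bb["gt", 2]))
  }
}
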