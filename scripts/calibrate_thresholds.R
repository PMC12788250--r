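#!/usr/bin/env Rscript
# One-off calibration of the multiple-selection thresholds on the synthetic
# bed scene. Sweeps the 0-dimensional persistence floor (tau) and the
# 1-dimensional loop-strength floor (rhoMin) over a labelled small scene and
# prints, per candidate, the acceptance rate on true vital-sign bins and the
# false-accept rate on pure-noise bins. The shipped defaults in
# multipleThresholds() were frozen from this sweep: the largest thresholds
# whose true-bin acceptance stays above 90% with zero noise-bin accepts.
#
# Usage: Rscript scripts/calibrate_thresholds.R [seed]

suppressPackageStartupMessages(library(radarvitals))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 3L

cfg <- radarConfig(nRangeBins = 16, chirpsPerFrame = 8)
scene <- sceneConfig(seed = seed, durationS = 600, config = cfg,
                     heartbeatBins = 4:6, breathingBins = 9:13)
sim <- simulateScene(scene)
disp <- phaseToDisplacement(chirpMedianPhase(sim$cube))
grid <- epochGrid(600)
truthBins <- list(breathing = 9:13, heartbeat = 4:6)
noiseBins <- setdiff(1:16, c(4:6, 9:13))

sweep <- list(
  breathing = expand.grid(tau = c(0.3, 0.45, 0.6, 0.8),
                          rhoMin = c(1.2, 1.5, 2, 3)),
  heartbeat = expand.grid(tau = c(0.1, 0.15, 0.2, 0.3), rhoMin = NA))

for (kind in names(sweep)) {
  cat("##", kind, "\n")
  grid_ <- sweep[[kind]]
  for (i in seq_len(nrow(grid_))) {
    thr <- multipleThresholds(kind)
    thr$tau <- grid_$tau[i]
    if (!is.na(grid_$rhoMin[i])) thr$rhoMin <- grid_$rhoMin[i]
    sel <- selectBins(disp, grid, kind, "multiple", thresholds = thr)
    bins <- lapply(sel, selectedBins)
    truePass <- mean(vapply(bins, function(b)
      any(b %in% truthBins[[kind]]), logical(1)))
    falsePass <- mean(vapply(bins, function(b)
      any(b %in% noiseBins), logical(1)))
    cat(sprintf("  tau %.2f rho %4s: true-bin accept %.2f  noise accept %.3f\n",
                grid_$tau[i], grid_$rhoMin[i], truePass, falsePass))
  }
}
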