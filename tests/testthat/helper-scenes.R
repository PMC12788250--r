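# Canonical 30-minute fixture scenes (fixed seed) shared by the acceptance
# tests; computed once per test run.

nightRun <- function(variant = c("clean", "noisy")) {
  variant <- match.arg(variant)
  key <- paste0("night_", variant)
  if (is.null(.fixtureEnv[[key]])) {
    sc <- if (variant == "clean") sceneConfig(seed = 1)
          else noisyScene(seed = 1)
    sim <- simulateScene(sc)
    res <- runPipeline(sim$cube, reference = sim$truth,
                       config = pipelineConfig(crop = FALSE))
    .fixtureEnv[[key]] <- list(sim = sim, res = res)
  }
  .fixtureEnv[[key]]
}
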