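# Shared expensive fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# 1-Mb two-population simulation under the default demographic model,
# shared by the validation and refinement tests
validation_panels <- function() {
  if (is.null(.fixture_cache$panels)) {
    model <- demographic_model(L = 1e6)
    .fixture_cache$model <- model
    .fixture_cache$panels <- simulate_panels(model, seed = 42)
  }
  list(model = .fixture_cache$model, panels = .fixture_cache$panels)
}

validation_run <- function(g, seed = 43) {
  key <- paste0("run_g", g, "_s", seed)
  if (is.null(.fixture_cache[[key]])) {
    vp <- validation_panels()
    morgans <- vp$model$rho * vp$model$L / (4 * vp$model$n0)
    truth <- simulate_migrant_tracts(
      N = 5000L, m = 0.1 / g, g = g, morgans = morgans,
      n_haplotypes = vp$model$n_african, seed = seed,
      model = "continuous", L = vp$model$L)
    sp <- splice_admixture(vp$panels, truth)
    sim <- list(hs = sp$hs, truth = truth,
                african = vp$panels$meta$genome_id[
                  vp$panels$meta$role == "african_panel"],
                panels = vp$panels)
    .fixture_cache[[key]] <- validate_detection(sim, g = g)
  }
  .fixture_cache[[key]]
}
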