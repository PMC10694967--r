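# Shared simulated fixtures, computed once per test session.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (is.null(.sim_cache[[key]])) assign(key, fn(), envir = .sim_cache)
  .sim_cache[[key]]
}

# Desk-scale two-deme run with Nm = 1 (the low-migration structured cohort
# used by the structure/remedy tests).
two_demes_run <- function() cached("two_demes_run", function()
  run_scenario(scenario_preset("two_demes", desk = TRUE, nm = 1),
               seed = 101))

two_demes_gm_pooled <- function() cached("two_demes_gm_pooled", function()
  build_genotype_matrix(draw_sample(two_demes_run(), seed = 1)))

two_demes_gm_single <- function() cached("two_demes_gm_single", function() {
  run <- two_demes_run()
  build_genotype_matrix(draw_sample(
    run, spec = sample_spec(100, "single_deme", 1),
    genome = run$scenario$genome, seed = 2))
})

# Desk-scale panmictic run (scale 5: N = 200).
panmictic_run <- function() cached("panmictic_run", function()
  run_scenario(scenario_preset("panmictic", desk = TRUE, scale = 5),
               seed = 102))

panmictic_gm <- function() cached("panmictic_gm", function()
  build_genotype_matrix(draw_sample(panmictic_run(), seed = 3)))
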