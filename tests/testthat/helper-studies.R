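# Heavy replicate studies are shared across acceptance blocks through a
# session cache so each scenario is simulated once per test run.

.study_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (is.null(.study_cache[[key]])) .study_cache[[key]] <- fn()
  .study_cache[[key]]
}

neutral_recovery_study <- function() cached("neutral_recovery", function()
  replicate_ne_study(study_config("neutral_recovery"), n_reps = 20,
                     base_seed = 100))

bs_rr1_study <- function() cached("bs_rr1", function()
  replicate_ne_study(study_config("bs_rr1"), n_reps = 20, base_seed = 200))

neutral_rr1_study <- function() cached("neutral_rr1", function()
  replicate_ne_study(study_config("neutral_rr1"), n_reps = 20,
                     base_seed = 300))
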