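# Shared heavy computations for the acceptance suite: the planted-block
# fixture trainings are reused across several tests, so they are run
# once and memoised for the session.

.fixture_cache <- new.env(parent = emptyenv())

fixture_network <- function() {
  if (is.null(.fixture_cache$net))
    .fixture_cache$net <- generate_synthetic(synthetic_spec())$network
  .fixture_cache$net
}

# full-variant trainings on the default fixture, training seeds 1:3
fixture_full_runs <- function() {
  if (is.null(.fixture_cache$full)) {
    .fixture_cache$full <- lapply(1:3, function(s) {
      fit <- train_model(fixture_network(), training_config(seed = s))
      list(fit = fit, report = evaluate_model(fit, "test"))
    })
  }
  .fixture_cache$full
}

# single-metapath (sm) variant on the same fixture and seeds
fixture_sm_runs <- function() {
  if (is.null(.fixture_cache$sm)) {
    .fixture_cache$sm <- lapply(1:3, function(s)
      run_variant("sm", fixture_network(), training_config(seed = s)))
  }
  .fixture_cache$sm
}
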