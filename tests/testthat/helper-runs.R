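# shared, lazily computed expensive fixtures (one default pipeline run reused
# across test files)
.run_cache <- new.env(parent = emptyenv())

default_report <- function() {
  if (is.null(.run_cache$report)) {
    .run_cache$report <- suppressMessages(suppressWarnings(
      run_pipeline(config = study_config(seed = 101))
    ))
  }
  .run_cache$report
}

default_sim <- function() {
  if (is.null(.run_cache$sim)) {
    .run_cache$sim <- simulate_claims(seed = 202)
  }
  .run_cache$sim
}

ari <- function(a, b) {
  # adjusted Rand index via mclust (independent of the package's own code)
  mclust::adjustedRandIndex(a, b)
}
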