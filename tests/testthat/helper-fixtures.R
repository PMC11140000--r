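# Session-level cache: the default synthetic study and the full pipeline
# run on it are shared by the pipeline, profile, and acceptance tests.
.fixture_cache <- new.env(parent = emptyenv())

default_study <- function() {
  if (is.null(.fixture_cache$study))
    .fixture_cache$study <- simulate_study()
  .fixture_cache$study
}

default_pipeline <- function() {
  if (is.null(.fixture_cache$pipe)) {
    s <- default_study()
    .fixture_cache$pipe <- suppressMessages(
      run_pipeline(s$transcripts, s$proteome, s$counts, s$design))
  }
  .fixture_cache$pipe
}

default_evaluation <- function() {
  if (is.null(.fixture_cache$eval))
    .fixture_cache$eval <- evaluate_against_truth(default_pipeline(),
                                                  default_study())
  .fixture_cache$eval
}

# A small study (2 transcripts per class) for structural checks that do
# not need the full design's statistics.
small_study <- function() {
  if (is.null(.fixture_cache$small))
    .fixture_cache$small <- simulate_study(
      sim_params(transcripts_per_class = 2, rng_seed = 42))
  .fixture_cache$small
}
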