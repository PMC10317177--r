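# Small synthetic cohort shared by several test files, built once per run.
.cohort_cache <- new.env(parent = emptyenv())

small_cohort <- function() {
  if (is.null(.cohort_cache$cohort)) {
    sc <- sim_config(n_subjects = 3, duration_s = 300, seed = 42)
    .cohort_cache$cohort <- gen_cohort(sc)
  }
  .cohort_cache$cohort
}

small_cohort_features <- function() {
  if (is.null(.cohort_cache$features)) {
    .cohort_cache$features <-
      cohort_features(small_cohort(), run_config(seed = 42))
  }
  .cohort_cache$features
}
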