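# cohorts shared across acceptance tests, built once per test run
.acc_cache <- new.env(parent = emptyenv())

acc_noiseless <- function() {
  if (is.null(.acc_cache$noiseless)) {
    coh <- generate_cohort(cohort_spec(participant_sd = 0, noise_sd = 0,
                                       seed = 20))
    # noiseless synthetic trials are band-limited by construction, so the
    # measurement-noise filter is disabled for this arm
    .acc_cache$noiseless <- run_pipeline(coh, run_config(filter_cutoff = NULL))
  }
  .acc_cache$noiseless
}

acc_noisy <- function() {
  if (is.null(.acc_cache$noisy)) {
    coh <- generate_cohort(cohort_spec(participant_sd = 3, noise_sd = 2,
                                       seed = 21))
    .acc_cache$noisy <- run_pipeline(coh, run_config())
  }
  .acc_cache$noisy
}
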