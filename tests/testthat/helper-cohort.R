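# Shared expensive fixtures, built once per test run. The calibrated
# 500-plan painted cohort backs both the median-recovery and the
# correlation-sign-recovery checks.

.planqm_test_cache <- new.env(parent = emptyenv())

default_phantom_cached <- function() {
  if (is.null(.planqm_test_cache$phantom))
    .planqm_test_cache$phantom <- build_phantom()
  .planqm_test_cache$phantom
}

calibrated_cohort_500 <- function() {
  if (is.null(.planqm_test_cache$cohort500)) {
    phantom <- default_phantom_cached()
    scheme <- load_scheme()
    profiles <- sample_cohort_profiles(500, load_calibration(), seed = 20260101)
    res <- evaluate_cohort(profiles, phantom, scheme)
    .planqm_test_cache$cohort500 <- list(
      result = res,
      table = build_cohort_table(res$scorecards, res$metadata),
      profiles = profiles
    )
  }
  .planqm_test_cache$cohort500
}
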