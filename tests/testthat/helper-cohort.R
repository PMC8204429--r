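# Shared synthetic cohorts, simulated once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, builder(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# a reduced cohort for module tests: 2 donors, 2 tissues, shallow libraries
small_config <- function(...) {
  sub <- cohort_config()$subsets
  sub$n_tail <- c(1500L, 600L, 900L, 300L)
  cohort_config(
    donors = tibble::tibble(donor_id = c("D1", "D2"), age = c(35L, 60L)),
    tissues = c("Spl", "LN"),
    depth = 1500L,
    subsets = sub,
    ...
  )
}

small_cohort <- function() {
  fixture("small", function() {
    coh <- simulate_cohort(small_config(), seed = 42)
    coh$clones <- assemble_clones(coh$rearrangements)
    coh
  })
}

# the full default cohort used by the acceptance-level checks
default_cohort <- function() {
  fixture("default", function() {
    coh <- simulate_cohort(cohort_config(), seed = 1)
    coh$clones <- assemble_clones(coh$rearrangements)
    coh
  })
}
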