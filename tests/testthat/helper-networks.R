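# Shared fixtures: toy networks and cached heavy runs.
# All fixtures are built in code; nothing is read from disk.

# single isolated source with exogenous input
single_source <- function() {
  network_model("A",
                forward = data.frame(from = character(0), to = character(0)),
                C = c(A = 1))
}

# two-source feedforward chain A -> B with configurable delay
two_source_chain <- function(delay = 8) {
  network_model(c("A", "B"),
                forward = data.frame(from = "A", to = "B"),
                C = c(A = 1), extrinsic_delay_ms = delay)
}

reduced_grid <- function() simulation_grid()

# cache environment for expensive shared computations (testthat runs all
# files in one process, so acceptance criteria 4/5/6 can share inversions)
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# one older-like + one younger-like reduced cohort with all-model inversions;
# the workhorse behind the model/parameter-recovery acceptance criteria
recovery_run <- function(seed = 1, n_subjects = 15) {
  cached(paste0("recovery_", seed, "_", n_subjects), {
    old <- generate_cohort(cohort_spec("older", n_subjects,
                                       hemispheres = "left", seed = 100 + seed))
    yng <- generate_cohort(cohort_spec("younger", n_subjects,
                                       hemispheres = "left", seed = 200 + seed))
    man <- study_manifest(list(older = old, younger = yng),
                          seed = seed, n_samples = 1e5)
    rep <- run_study(man, progress = FALSE)
    list(old = old, yng = yng, report = rep)
  })
}

# generative-model-only inversions for the delay-contrast criterion
delay_run <- function(seed, n_subjects = 15) {
  cached(paste0("delay_", seed, "_", n_subjects), {
    old <- generate_cohort(cohort_spec("older", n_subjects,
                                       hemispheres = "left", seed = 100 + seed))
    yng <- generate_cohort(cohort_spec("younger", n_subjects,
                                       hemispheres = "left", seed = 200 + seed))
    m2 <- build_model(2, "left"); m3 <- build_model(3, "left")
    po <- invert_cohort(old$data, m2)
    py <- invert_cohort(yng$data, m3)
    list(harvest_old = harvest_parameters(po, m2, group = "older"),
         harvest_yng = harvest_parameters(py, m3, group = "younger"),
         posts_old = po, posts_yng = py, old = old, yng = yng)
  })
}
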