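test_that("cohort specs carry the stated generative defaults", {
  old <- cohort_spec("older")
  expect_equal(old$generative_model_id, 2L)
  expect_equal(old$effects$repetition_fss, c(novel = 1.21, repeated = 0.99))
  expect_equal(old$effects$repetition_fdp, c(novel = 0.81, repeated = 0.67))
  expect_equal(old$effects$forward_delay_ms, 9.18)
  expect_equal(old$effects$rt_base, c(novel = 815.9, repeated = 727.0))

  yng <- cohort_spec("younger")
  expect_equal(yng$generative_model_id, 3L)
  expect_equal(yng$effects$repetition_gain, c(novel = 1.16, repeated = 0.98))
  expect_equal(yng$effects$forward_delay_ms, 7.98)
  expect_equal(yng$effects$frontal_input_mean, 0)

  expect_error(cohort_spec("older", n_subjects = 1))
  expect_error(cohort_spec("older", snr = 0))
})

test_that("subject_sd = 0 collapses every subject onto the group means", {
  sp <- cohort_spec("older", n_subjects = 3, subject_sd = 0,
                    hemispheres = "left", seed = 4)
  means <- cohort_group_means(sp)
  s1 <- sample_subject_parameters(sp, 1, means)
  s2 <- sample_subject_parameters(sp, 2, means)
  expect_equal(s1$theta, s2$theta)
  # generative novel EV->aVT strength is the printed 1.21 / 0.81 pair
  u <- unpack_parameters(means$pack, s1$theta)
  expect_equal(u$novel$Afss["laVT", "lEV"], 1.21)
  expect_equal(u$novel$Afdp["laVT", "lEV"], 0.81)
  # and the repetition drop reproduces the printed repeated means
  net_nov <- microdcm:::.network_with(s1$model, u$novel)
  net_rep <- apply_modulation(net_nov, condition_modulation(s1$b), "repeated")
  expect_equal(net_rep$A_forward$ss["laVT", "lEV"], 0.99)
  expect_equal(net_rep$A_forward$dp["laVT", "lEV"], 0.67)
  # forward delays at the older group mean
  expect_equal(u$novel$D["laVT", "lEV"], 9.18)
})

test_that("younger-like defaults put the repetition effect on aVT gain", {
  sp <- cohort_spec("younger", n_subjects = 3, subject_sd = 0,
                    hemispheres = "left", seed = 4)
  means <- cohort_group_means(sp)
  s <- sample_subject_parameters(sp, 1, means)
  u <- unpack_parameters(means$pack, s$theta)
  expect_equal(unname(u$novel$G["laVT"]), 1.16)
  expect_equal(unname(exp(s$b["G.laVT"])) * 1.16, 0.98)
  expect_equal(u$novel$D["laVT", "lEV"], 7.98)
  expect_true(is.na(s$input_strength))   # no frontal input in model 3
})

test_that("identical spec + seed reproduce byte-identical cohorts", {
  sp <- cohort_spec("older", n_subjects = 3, hemispheres = "left", seed = 9)
  c1 <- generate_cohort(sp)
  c2 <- generate_cohort(sp)
  expect_identical(c1$data, c2$data)
  expect_identical(c1$behavior, c2$behavior)
  # different seed, different data
  c3 <- generate_cohort(cohort_spec("older", n_subjects = 3,
                                    hemispheres = "left", seed = 10))
  expect_false(identical(c1$data[[1]]$novel, c3$data[[1]]$novel))
})

test_that("emitted SNR tracks the requested level", {
  sp <- cohort_spec("older", n_subjects = 8, hemispheres = "left", seed = 31)
  co <- generate_cohort(sp)
  spInf <- sp
  spInf$snr <- Inf
  snrs <- vapply(seq_along(co$subjects), function(i) {
    clean <- simulate_subject(co$subjects[[i]], spInf)
    noisy <- co$data[[i]]
    nz <- c(noisy$novel - clean$novel, noisy$repeated - clean$repeated)
    sqrt(mean(c(clean$novel^2, clean$repeated^2))) / sd(nz)
  }, numeric(1))
  expect_lt(abs(mean(snrs) - sp$snr) / sp$snr, 0.1)
})

test_that("snr = Inf reproduces the deterministic forward simulation", {
  sp <- cohort_spec("older", n_subjects = 3, hemispheres = "left", seed = 12)
  spInf <- sp
  spInf$snr <- Inf
  means <- cohort_group_means(sp)
  s <- sample_subject_parameters(sp, 1, means)
  d1 <- simulate_subject(s, spInf)
  d2 <- simulate_subject(s, spInf)
  expect_identical(d1$novel, d2$novel)
  # conditions differ only where the modulated parameters propagate:
  # identical (near-zero) pre-onset baselines, clear post-onset divergence
  expect_false(isTRUE(all.equal(d1$novel, d1$repeated)))
  diff <- abs(d1$novel - d1$repeated)
  expect_lt(max(diff[, d1$times < 30]), 0.05 * max(diff))
  expect_gt(max(diff), 1e-3)
})

test_that("generative forward delays separate the default cohorts", {
  mean_fwd <- function(group, seed) {
    sp <- cohort_spec(group, n_subjects = 15, hemispheres = "left",
                      seed = seed)
    means <- cohort_group_means(sp)
    pack <- means$pack
    dfwd <- paste0("D.", pack$ix$fwd$label)
    subj <- lapply(seq_len(15), sample_subject_parameters, spec = sp,
                   means = means)
    vapply(subj, function(s) mean(8 * exp(s$theta[dfwd])), numeric(1))
  }
  hits <- vapply(1:10, function(seed) {
    t.test(mean_fwd("older", 400 + seed), mean_fwd("younger", 500 + seed),
           alternative = "greater")$p.value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("behaviour couples reaction time to frontal input as calibrated", {
  # zero-noise, positive slope: exact anticorrelation
  sp0 <- cohort_spec("older", n_subjects = 10, hemispheres = "left", seed = 3,
                     effects = list(rt_beta = 50, rt_subject_sd = 0,
                                    rt_condition_sd = 0))
  co0 <- generate_cohort(sp0)
  r0 <- cor(co0$behavior$input_strength,
            (co0$behavior$rt_novel + co0$behavior$rt_repeated) / 2)
  expect_equal(r0, -1, tolerance = 1e-6)

  # default older-like base RTs give the printed mean priming effect
  expect_equal(priming_effect(815.9, 727.0), 88.9)
  sp <- cohort_spec("older", n_subjects = 200, hemispheres = "left", seed = 17)
  co <- generate_cohort(sp)
  expect_equal(mean(priming_effect(co$behavior$rt_novel,
                                   co$behavior$rt_repeated)),
               88.9, tolerance = 5)

  expect_error(generate_behavior(list(), cohort_spec("older", 3)), ">= 3")
})

test_that("cohorts round-trip through the on-disk layout", {
  sp <- cohort_spec("older", n_subjects = 3, hemispheres = "left", seed = 8)
  co <- generate_cohort(sp)
  dir <- tempfile("cohort")
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  d1 <- read_erp_dataset(file.path(dir, names(co$data)[1]))
  expect_equal(d1$novel, co$data[[1]]$novel, tolerance = 1e-12)
  expect_equal(d1$times, co$data[[1]]$times)
  # run_study accepts the directory form
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  expect_equal(man$generative_model_id, 2)
})
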