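test_that("priming effect is exact arithmetic", {
  expect_equal(priming_effect(815.9, 727.0), 88.9)
  expect_equal(priming_effect(679.1, 608.8), 70.3)
  expect_equal(priming_effect(500, 500), 0)
  expect_error(priming_effect(-1, 5))
})

test_that("harvest emits the right rows per class", {
  run <- recovery_run(1)
  gr <- run$report$groups$older
  m <- run$report$models[[gr$winning_model]]
  h <- gr$harvest
  n_subj <- length(run$old$data)

  # C rows: one per input source per subject
  expect_equal(sum(h$class == "C"), n_subj * length(input_sources(m)))
  # D rows: one per extrinsic edge plus per-source self delay
  pack <- pack_parameters(m)
  n_edges <- length(pack$ix$fwd$label) + length(pack$ix$bwd$label)
  expect_equal(sum(h$class == "D"), n_subj * (n_edges + nrow(m$sources)))
  expect_setequal(unique(h$kind[h$class == "D"]),
                  c("forward", "backward", "self"))
  # B rows are condition-resolved: novel and repeated for every modulated
  # component (2 per forward/backward edge) and per-source gain
  expect_equal(sum(h$class == "B"),
               n_subj * 2 * (2 * n_edges + nrow(m$sources)))
  expect_setequal(unique(h$condition[h$class == "B"]), c("novel", "repeated"))

  # harvest conservation: every free parameter appears exactly once per
  # subject (and per condition for modulated ones)
  per_subj <- table(h$subject, h$parameter, h$condition, useNA = "ifany")
  expect_true(all(per_subj %in% c(0, 1)))

  # model-1 C support is EV only
  m1 <- build_model(1, "left")
  posts1 <- run$report$groups$older$posteriors[["1"]]
  h1 <- harvest_parameters(posts1, m1, classes = "C")
  expect_true(all(grepl("^C\\.lEV$", h1$parameter)))
  expect_error(harvest_parameters(posts1, m1, classes = "Z"), "unknown")
})

test_that("zero modulation yields identical novel and repeated harvest rows", {
  m <- build_model(1, "left")
  pack <- pack_parameters(m)
  post <- structure(list(Ep = pack$theta0, fit = 1, model_id = 1,
                         subject = "s1"),
                    class = "dcm_posterior")
  h <- harvest_parameters(list(post), m, classes = "B")
  wide <- split(h$value, h$condition)
  expect_equal(wide$novel, wide$repeated)
})

test_that("repetition tests match direct arithmetic, with corrections", {
  # build a small synthetic harvest by hand: 6 subjects, 2 parameters
  mk <- function(subj, par, nov, rep) {
    data.frame(subject = subj, group = "g", model_id = 2, class = "B",
               parameter = par, condition = c("novel", "repeated"),
               kind = "forward", value = c(nov, rep))
  }
  set.seed(2)
  h <- do.call(rbind, c(
    lapply(1:6, function(i) mk(paste0("s", i), "p1",
                               1.2 + rnorm(1, 0, 0.05), 1.0)),
    lapply(1:6, function(i) mk(paste0("s", i), "p2", 1.0, 1.0))))
  out <- test_repetition_effects(h, correction = "bonferroni")
  p1 <- out[out$parameter == "p1", ]
  d <- h$value[h$parameter == "p1" & h$condition == "novel"] - 1.0
  tt <- t.test(d)
  expect_equal(p1$t, unname(tt$statistic))
  expect_equal(p1$p_corrected, min(1, 2 * tt$p.value))
  # all-zero contrasts: t = 0, corrected p = 1
  p2 <- out[out$parameter == "p2", ]
  expect_equal(p2$t, 0)
  expect_equal(p2$p_corrected, 1)

  holm <- test_repetition_effects(h, correction = "holm")
  expect_equal(holm$p_corrected, p.adjust(out$p, "holm"))

  expect_error(test_repetition_effects(h[h$subject == "s1", ]), ">= 2")
})

test_that("group delay comparison aggregates per subject then tests", {
  mkD <- function(subj, kind, vals) {
    data.frame(subject = subj, group = "g", model_id = 2, class = "D",
               parameter = paste0("D.", seq_along(vals)),
               condition = NA, kind = kind, value = vals)
  }
  ha <- do.call(rbind, lapply(1:5, function(i)
    rbind(mkD(paste0("a", i), "forward", c(9, 9.4) + i * 0.01),
          mkD(paste0("a", i), "backward", c(8, 8) + i * 0.01))))
  hb <- do.call(rbind, lapply(1:5, function(i)
    rbind(mkD(paste0("b", i), "forward", c(8, 8.2) + i * 0.01),
          mkD(paste0("b", i), "backward", c(8, 8) + i * 0.01))))
  out <- compare_group_delays(ha, hb)
  fwd <- out[out$kind == "forward", ]
  # oracle: direct two-sample t on the per-subject means
  xa <- sapply(1:5, function(i) mean(c(9, 9.4) + i * 0.01))
  xb <- sapply(1:5, function(i) mean(c(8, 8.2) + i * 0.01))
  tt <- t.test(xa, xb)
  expect_equal(fwd$t, unname(tt$statistic))
  expect_equal(fwd$p, tt$p.value)
  # identical groups: t = 0
  expect_equal(compare_group_delays(ha, ha)$t, c(0, 0))

  expect_error(compare_group_delays(ha[ha$kind == "forward", ], hb),
               "missing")
  expect_error(compare_group_delays(ha[ha$subject == "a1", ], hb),
               "singleton")
})

test_that("input-RT correlation matches cor.test and validates input", {
  beh <- data.frame(subject = paste0("s", 1:8),
                    rt_novel = seq(800, 730, length.out = 8),
                    rt_repeated = seq(720, 650, length.out = 8))
  x <- setNames(seq(0.5, 1.5, length.out = 8), beh$subject)
  out <- correlate_input_behavior(x, beh)
  expect_equal(out$r, -1, tolerance = 1e-12)

  # permutation invariance under joint reordering
  perm <- sample(8)
  out2 <- correlate_input_behavior(x[perm], beh)
  expect_equal(out2$r, out$r)

  # matches a direct cor.test oracle on noisy data
  set.seed(5)
  beh$rt_novel <- beh$rt_novel + rnorm(8, 0, 10)
  ct <- cor.test(x, (beh$rt_novel + beh$rt_repeated) / 2)
  out3 <- correlate_input_behavior(x, beh)
  expect_equal(out3$r, unname(ct$estimate))
  expect_equal(out3$p, ct$p.value)

  expect_error(correlate_input_behavior(x[1:2], beh[1:2, ]), ">= 3")
  expect_error(correlate_input_behavior(setNames(rep(1, 8), beh$subject), beh),
               "zero variance")
})

test_that("statistics agree with reference implementations on random tables", {
  set.seed(77)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    x <- rnorm(n); y <- rnorm(n)
    beh <- data.frame(subject = paste0("s", 1:n),
                      rt_novel = 700 + y * 50 + rnorm(n, 0, 1),
                      rt_repeated = 640 + y * 50 - rnorm(n, 0, 1))
    xx <- setNames(exp(x), beh$subject)
    ref <- cor.test(exp(x), (beh$rt_novel + beh$rt_repeated) / 2)
    got <- correlate_input_behavior(xx, beh)
    expect_equal(got$r, unname(ref$estimate), tolerance = 1e-10)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("run_study produces a complete, deterministic report", {
  old <- generate_cohort(cohort_spec("older", 3, hemispheres = "left",
                                     seed = 61))
  yng <- generate_cohort(cohort_spec("younger", 3, hemispheres = "left",
                                     seed = 62))
  man <- study_manifest(list(older = old, younger = yng), seed = 2,
                        n_samples = 1e4)
  rep1 <- run_study(man, progress = FALSE)
  # structural completeness
  for (g in c("older", "younger")) {
    gr <- rep1$groups[[g]]
    expect_s3_class(gr$family_bms, "bms_result")
    expect_true(gr$winning_model %in% c("1", "2", "3"))
    expect_true(all(c("C", "B", "G", "D") %in% gr$harvest$class))
  }
  expect_true(!is.null(rep1$behavior))
  expect_true(!is.null(rep1$delays))
  expect_length(rep1$repetition, 2)

  # determinism: identical manifest + seed -> identical report (modulo the
  # posteriors' environments; compare the numeric content)
  rep2 <- run_study(man, progress = FALSE)
  expect_identical(rep1$behavior, rep2$behavior)
  expect_identical(rep1$delays, rep2$delays)
  expect_identical(lapply(rep1$groups, `[[`, "harvest"),
                   lapply(rep2$groups, `[[`, "harvest"))
  expect_identical(lapply(rep1$groups, function(g) g$family_bms$exceedance_prob),
                   lapply(rep2$groups, function(g) g$family_bms$exceedance_prob))
})

test_that("checkpointed studies resume, and manifests read from JSON", {
  co <- generate_cohort(cohort_spec("older", 3, hemispheres = "left",
                                    seed = 71))
  dir <- tempfile("cohort_old")
  write_cohort(co, dir)
  mpath <- tempfile(fileext = ".json")
  jsonlite::write_json(list(groups = list(older = dir),
                            model_ids = c(2, 3), seed = 5, n_samples = 1e4),
                       mpath, auto_unbox = TRUE)
  man <- read_study_manifest(mpath)
  expect_s3_class(man, "study_manifest")
  expect_equal(man$model_ids, c(2, 3))

  ck <- tempfile("ckpt")
  r1 <- run_study(man, progress = FALSE, checkpoint_dir = ck)
  expect_true(file.exists(file.path(ck, "older_model2.rds")))
  t0 <- Sys.time()
  r2 <- run_study(man, progress = FALSE, checkpoint_dir = ck)
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 10)
  expect_identical(r1$groups$older$harvest, r2$groups$older$harvest)
  expect_equal(r1$groups$older$winning_model, r2$groups$older$winning_model)
})
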