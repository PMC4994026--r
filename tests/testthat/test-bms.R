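# closed-form exceedance oracle for two models: P(r1 > r2) under
# Dirichlet(a1, a2) equals P(r1 > 1/2) = 1 - I_0.5(a1, a2)
beta_exceedance <- function(a1, a2) 1 - pbeta(0.5, a1, a2)

test_that("exceedance sampler matches the K = 2 beta closed form", {
  # spec worked example
  xp <- exceedance_probabilities(c(8, 2), n_samples = 1e6, seed = 11)
  expect_equal(unname(xp[1]), beta_exceedance(8, 2), tolerance = 0.005)
  expect_equal(beta_exceedance(8, 2), 0.9805, tolerance = 1e-4)

  # symmetric cases
  expect_equal(unname(exceedance_probabilities(c(1, 1), seed = 2)[1]), 0.5,
               tolerance = 0.005)
  xp3 <- exceedance_probabilities(c(5, 5, 5), n_samples = 1e6, seed = 3)
  expect_true(all(abs(xp3 - 1 / 3) < 0.01))

  expect_error(exceedance_probabilities(c(1, 1), n_samples = 100),
               "precision floor")
  expect_error(exceedance_probabilities(c(0, 1)))
})

test_that("rfx_bms: symmetry, dominance and permutation equivariance", {
  # identical columns -> uniform everything
  f <- matrix(rnorm(20), 10, 2)
  f[, 2] <- f[, 1]
  r <- rfx_bms(evidence_table(f, model_ids = c("a", "b")),
               n_samples = 1e5, seed = 1)
  expect_equal(unname(r$expected_prob), c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(unname(r$exceedance_prob), c(0.5, 0.5), tolerance = 0.01)
  expect_true(r$uniform_warning)   # exact ties raise the uninformative flag

  # +10 nats for one model in every subject
  f2 <- matrix(0, 10, 2)
  f2[, 1] <- 10
  r2 <- rfx_bms(f2, n_samples = 1e5, seed = 1)
  expect_gt(r2$exceedance_prob[1], 0.99)
  expect_true(all(r2$alpha >= 1))

  # permutation equivariance over 3 models
  f3 <- matrix(rnorm(30, sd = 3), 10, 3)
  perm <- c(3, 1, 2)
  r3 <- rfx_bms(evidence_table(f3, model_ids = c("m1", "m2", "m3")),
                n_samples = 1e5, seed = 5)
  r3p <- rfx_bms(evidence_table(f3[, perm],
                                model_ids = c("m1", "m2", "m3")[perm]),
                 n_samples = 1e5, seed = 5)
  expect_equal(unname(r3p$alpha), unname(r3$alpha[perm]), tolerance = 1e-6)
  expect_equal(unname(r3p$exceedance_prob), unname(r3$exceedance_prob[perm]),
               tolerance = 0.01)
})

test_that("log-evidence scale invariance: adding a constant changes nothing", {
  set.seed(9)
  f <- matrix(rnorm(30, sd = 2), 10, 3)
  r1 <- rfx_bms(f, n_samples = 1e5, seed = 4)
  r2 <- rfx_bms(f + 123.4, n_samples = 1e5, seed = 4)
  expect_equal(r1$alpha, r2$alpha, tolerance = 1e-8)
  expect_equal(r1$exceedance_prob, r2$exceedance_prob)

  # per-subject constants too
  r3 <- rfx_bms(f + rnorm(10) %o% rep(1, 3), n_samples = 1e5, seed = 4)
  expect_equal(r1$alpha, r3$alpha, tolerance = 1e-8)
})

test_that("family_bms is calibrated for unequal family sizes", {
  f <- matrix(0, 15, 3, dimnames = list(NULL, c("1", "2", "3")))
  part <- list(`1` = "1", `2` = c("2", "3"))
  fam <- family_bms(evidence_table(f), part, n_samples = 1e6, seed = 6)
  expect_equal(unname(fam$exceedance_prob), c(0.5, 0.5), tolerance = 0.01)
  expect_equal(unname(fam$expected_prob), c(0.5, 0.5), tolerance = 1e-6)
})

test_that("a dominant family and singleton partitions behave as required", {
  # family 2's models dominate by +10 nats everywhere
  f <- matrix(0, 12, 3, dimnames = list(NULL, c("1", "2", "3")))
  f[, 2] <- 10
  f[, 3] <- 10
  part <- list(`1` = "1", `2` = c("2", "3"))
  fam <- family_bms(evidence_table(f), part, n_samples = 1e6, seed = 7)
  expect_gt(fam$exceedance_prob[["2"]], 0.99)
  # cross-check the two-family margin against the beta oracle
  expect_equal(unname(fam$exceedance_prob[2]),
               beta_exceedance(fam$alpha[[2]], fam$alpha[[1]]),
               tolerance = 0.005)

  # singleton partition reduces exactly to rfx_bms
  set.seed(10)
  f2 <- matrix(rnorm(30, sd = 2), 10, 3, dimnames = list(NULL, c("1", "2", "3")))
  singles <- list(`1` = "1", `2` = "2", `3` = "3")
  fam2 <- family_bms(evidence_table(f2), singles, n_samples = 1e5, seed = 8)
  mod2 <- rfx_bms(evidence_table(f2), n_samples = 1e5, seed = 8)
  expect_equal(unname(fam2$alpha), unname(mod2$alpha), tolerance = 1e-9)
  expect_equal(unname(fam2$exceedance_prob), unname(mod2$exceedance_prob))

  expect_error(family_bms(evidence_table(f2), list(`1` = "1", `2` = "2")),
               "cover")
  expect_error(family_bms(evidence_table(f2),
                          list(`1` = c("1", "2", "3"), `2` = character(0))),
               "empty")
})

test_that("evidence tables validate and round-trip through TSV", {
  expect_error(evidence_table(matrix(c(1, Inf), 1)), "finite")
  expect_error(evidence_table(matrix(1, 3, 1)), ">= 2 models")
  f <- matrix(rnorm(12), 4, 3, dimnames = list(paste0("s", 1:4), c("1", "2", "3")))
  tab <- evidence_table(f, group = "older")
  path <- tempfile(fileext = ".tsv")
  write_evidence_table(tab, path)
  tab2 <- read_evidence_table(path, group = "older")
  expect_equal(tab2$log_evidence, tab$log_evidence)
})

test_that("protected exceedance shrinks to uniform exactly when evidence is flat", {
  f_flat <- matrix(0, 12, 3, dimnames = list(NULL, c("1", "2", "3")))
  r <- rfx_bms(evidence_table(f_flat), n_samples = 1e5, seed = 14,
               protected = TRUE)
  # closed-form oracle at the VB fixed point: flat evidence gives g = 1/3,
  # alpha = (5, 5, 5); F1 = 12 * (psi(5) - psi(15) + log 3)/... reduces to
  # F1 = 12 * sum_k g_k (psi(5) - psi(15) - log g_k) - KL(Dir(5,5,5)||Dir(1))
  f1 <- 12 * (digamma(5) - digamma(15) + log(3)) -
    (lgamma(15) - 3 * lgamma(5) - lgamma(3) + 12 * (digamma(5) - digamma(15)))
  bor_oracle <- 1 / (1 + exp(f1 - 0))
  expect_equal(r$bor, bor_oracle, tolerance = 1e-6)
  expect_gt(r$bor, 0.8)
  expect_true(all(abs(r$protected_exceedance_prob - 1 / 3) < 0.05))

  f_strong <- f_flat
  f_strong[, 2] <- 15
  r2 <- rfx_bms(evidence_table(f_strong), n_samples = 1e5, seed = 14,
                protected = TRUE)
  expect_lt(r2$bor, 0.05)
  expect_equal(unname(r2$protected_exceedance_prob[2]),
               unname(r2$exceedance_prob[2]), tolerance = 0.05)
})

test_that("grouped exceedance sums frequencies before the argmax", {
  # under Dir(1,1,1), P(x1 > x2 + x3) = P(x1 > 1/2) with x1 ~ Beta(1, 2) = 1/4
  xp <- exceedance_probabilities(c(1, 1, 1), n_samples = 1e6, seed = 19,
                                 groups = c("a", "b", "b"))
  expect_equal(unname(xp[["a"]]), 0.25, tolerance = 0.005)
  expect_equal(unname(xp[["b"]]), 0.75, tolerance = 0.005)
})
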