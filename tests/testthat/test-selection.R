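fake_fit <- function(loglik, k, n = 392) {
  structure(list(spec = "x", loglik = loglik, k = k, n_trials = n),
            class = "cm_fit")
}

test_that("BIC log-evidence penalizes free parameters at (k/2) log n", {
  e12 <- log_evidence_bic(fake_fit(-200, 12))
  e7 <- log_evidence_bic(fake_fit(-200, 7))
  expect_equal(e12 - e7, -(5 / 2) * log(392))
  # a longer run at identical per-trial fit punishes the larger model more
  d_long <- log_evidence_bic(fake_fit(-400, 12, 784)) -
    log_evidence_bic(fake_fit(-400, 7, 784))
  expect_lt(d_long, e12 - e7)
})

test_that("bootstrap GLRT produces valid add-one p-values and non-negative statistics", {
  set.seed(30)
  st <- fixed_structure()
  cfg <- task_config(n_blocks = 1)
  gen <- pattern_free("pure_mb")
  sess <- lapply(1:2, function(i)
    simulate_session(gen, "pure_mb", structure = st, config = cfg))
  g <- bootstrap_glrt(sess, "pure_mb", n_boot = 19, n_starts = 2, seed = 31)
  expect_true(all(g$per_subject$statistic >= 0))
  expect_true(all(g$null_subject >= 0))
  expect_true(all(g$per_subject$p > 0 & g$per_subject$p <= 1))
  # p-values recompute from the stored null samples by the add-one rule
  expect_equal(g$per_subject$p,
               vapply(1:2, function(i)
                 (1 + sum(g$null_subject[, i] >= g$per_subject$statistic[i])) /
                   (1 + 19), 1))
  expect_equal(g$group_p,
               (1 + sum(g$null_group >= g$group_statistic)) / (1 + 19))
  expect_error(bootstrap_glrt(sess, "pure_mb", n_boot = 0), "n_boot")
})

test_that("random-effects model selection is exact under full symmetry", {
  E <- matrix(rnorm(20), 20, 1)[, c(1, 1, 1)]  # identical columns
  bm <- bms_random_effects(E, seed = 32)
  expect_equal(unname(bm$expected_prob), rep(1 / 3, 3))
  expect_equal(unname(bm$xp), rep(1 / 3, 3))
  expect_equal(unname(bm$pxp), rep(1 / 3, 3))
  expect_error(bms_random_effects(E[, 1, drop = FALSE]), "2 models")
  expect_error(bms_random_effects(cbind(E, Inf)), "finite")
})

test_that("the protected-exceedance identity holds exactly for arbitrary evidence", {
  set.seed(33)
  for (i in 1:5) {
    E <- matrix(rnorm(60, sd = 3), 20, 3)
    bm <- bms_random_effects(E, seed = i)
    expect_equal(unname(bm$pxp),
                 unname(bm$xp * (1 - bm$bor) + bm$bor / 3))
    expect_equal(sum(bm$expected_prob), 1)
    expect_equal(sum(bm$pxp), 1, tolerance = 1e-12)
  }
})

test_that("two-model selection matches a grid-integration oracle", {
  ## 20 subjects each favoring model 1 by 10 log-evidence units
  E <- cbind(rep(10, 20), 0)
  bm <- bms_random_effects(E, seed = 34)
  ## brute force: uniform prior on the population frequency r of model 1,
  ## marginal likelihood per subject r*E1 + (1-r)*E2 (up to a constant)
  r <- seq(1e-6, 1 - 1e-6, length.out = 20001)
  logpost <- rowSums(vapply(seq_len(20), function(n)
    log(r * exp(10) + (1 - r)) - 10, r))
  w <- exp(logpost - max(logpost))
  er <- sum(r * w) / sum(w)
  expect_equal(unname(bm$expected_prob[1]), er, tolerance = 0.02)
  expect_gt(bm$pxp[1], 0.9)

  ## one subject with a huge gap cannot establish population prevalence
  b1 <- bms_random_effects(cbind(100, 0), seed = 35)
  expect_gt(b1$bor, 0.2)
  expect_lt(b1$pxp[1], b1$xp[1])   # pulled back toward 1/K
})

test_that("Bayesian model averaging weights embedded parameters by model probability", {
  full_p <- empirical_pattern_params()
  sub_p <- apply_constraints("pure_mb", pattern_free("pure_mb"))
  fits <- list(list(full = list(params = full_p),
                    pure_mb = list(params = sub_p)))
  ## equal responsibilities: MFCA weights are halved (averaged with zero)
  bms_eq <- list(g = matrix(0.5, 1, 2))
  ba <- bayesian_average_params(fits, bms_eq)
  expect_equal(unname(ba$params[1, 1:4]), unname(full_p[1:4]) / 2)
  ## degenerate responsibility: recover the single model's parameters
  bms_one <- list(g = matrix(c(1, 0), 1, 2))
  ba1 <- bayesian_average_params(fits, bms_one)
  expect_equal(unname(ba1$params[1, ]), unname(as.numeric(full_p)))
})

test_that("cohort fitting returns an evidence matrix aligned with the fits", {
  set.seed(36)
  sess <- sim_cohort("full", pattern_free("full"), 3,
                     config = task_config(n_blocks = 1))
  fc <- fit_cohort(sess, c("full", "pure_mb"), n_starts = 2, seed = 37)
  expect_equal(dim(fc$evidence), c(3L, 2L))
  expect_equal(unname(fc$evidence[2, "full"]),
               log_evidence_bic(fc$fits[[2]]$full))
  expect_true(all(is.finite(fc$evidence)))
})
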