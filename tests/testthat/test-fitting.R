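test_that("maximum-likelihood fits never fall below the chance point", {
  set.seed(20)
  st <- fixed_structure()
  ses <- generate_session(st, task_config(), zero_params())
  f <- fit_mle(ses, "full", n_starts = 4, seed = 1)
  expect_gte(f$loglik, 392 * log(0.5))
  expect_true(all(f$params[c("f_mf", "f_mb", "f_p")] >= 0 &
                    f$params[c("f_mf", "f_mb", "f_p")] <= 1))
  expect_true(all(abs(f$params[c(1:8, 11)]) <= 3))
  expect_equal(f$k, 12)
  expect_equal(f$n_trials, 392)
})

test_that("the compiled optimizer agrees with L-BFGS-B on shared starts", {
  set.seed(21)
  st <- fixed_structure()
  ses <- generate_session(st, task_config(n_blocks = 2),
                          empirical_pattern_params())
  spec <- creditmap:::as_model_spec("pure_mf")
  obj <- creditmap:::make_objective(ses, spec)
  b <- creditmap:::opt_bounds(spec)
  starts <- creditmap:::make_starts(spec, 4)
  ref <- min(vapply(seq_len(4), function(i)
    optim(starts[i, ], obj$fn, obj$gr, method = "L-BFGS-B", lower = b$lower,
          upper = b$upper, control = list(maxit = 500))$value, 1))
  f <- fit_mle(ses, spec, n_starts = 0,
               extra_starts = t(apply(starts, 1, function(v)
                 creditmap:::opt_to_natural(spec, v))))
  expect_lte(-f$loglik, ref + 1e-3)   # at least as good as the reference
})

test_that("fit_mle with zero LHS starts still includes the supplied starts only", {
  set.seed(27)
  ses <- generate_session(fixed_structure(), task_config(n_blocks = 1),
                          zero_params())
  f <- fit_mle(ses, "pure_mf", n_starts = 1)   # chance start only
  expect_gte(f$loglik, 56 * log(0.5))
})

test_that("best log-likelihood is non-decreasing in the number of starts", {
  set.seed(22)
  st <- fixed_structure()
  ses <- generate_session(st, task_config(n_blocks = 2),
                          empirical_pattern_params())
  lls <- vapply(c(1, 3, 6, 10), function(ns)
    fit_mle(ses, "full", n_starts = ns, seed = 99)$loglik, 1)
  expect_true(all(diff(lls) >= -1e-9))
})

test_that("seeded submodel refits enforce non-negative likelihood-ratio statistics", {
  set.seed(23)
  st <- fixed_structure()
  for (i in 1:4) {
    ses <- generate_session(st, task_config(n_blocks = 2), random_full_params())
    pair <- fit_submodel_seeded(ses, "pure_mb", n_starts = 3)
    expect_gte(pair$statistic, 0)
    expect_gte(pair$full$loglik, pair$sub$loglik)
  }
  # degenerate comparison of a spec against itself
  ses <- generate_session(st, task_config(n_blocks = 2), random_full_params())
  self <- fit_submodel_seeded(ses, "full", "full", n_starts = 2)
  expect_equal(self$statistic, 0)
})

test_that("parameter recovery reports are well formed and flag degenerate cohorts", {
  set.seed(24)
  pars <- sample_cohort_params(8, "pure_mb")
  rec <- recover_parameters("pure_mb", pars, n_starts = 5, seed = 25)
  expect_equal(nrow(rec$report), 7)             # one row per free parameter
  expect_true(all(rec$report$correlation >= -1 & rec$report$correlation <= 1,
                  na.rm = TRUE))
  expect_gt(mean(rec$report$correlation[1:4]), 0)  # CA weights recover

  flat <- matrix(rep(creditmap:::project_params("pure_mb",
                                                empirical_pattern_params()),
                     each = 4), nrow = 4)
  rec2 <- recover_parameters("pure_mb", flat, n_starts = 3, seed = 26)
  expect_true(all(rec2$report$degenerate))      # zero generating spread
})
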