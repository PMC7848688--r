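test_that("accuracy and sensitivity behave at the policy extremes", {
  set.seed(40)
  st <- fixed_structure()
  orc <- generate_session(st, task_config(), "oracle")
  expect_equal(accuracy(orc)$accuracy, 1)
  cs_o <- choice_sensitivity(orc)
  expect_true(cs_o$separation)
  expect_equal(cs_o$slope, 10)              # capped under separation

  rnd <- generate_session(st, task_config(), "random")
  expect_lt(abs(choice_sensitivity(rnd)$slope), 3)
  expect_gt(accuracy(rnd)$n_scored, 380)

  ## sensitivity tracks accuracy across skill levels
  skills <- seq(0, 2.5, length.out = 12)
  res <- t(vapply(skills, function(s) {
    ses <- generate_session(st, task_config(),
                            model_params(c_mb = rep(s / 4, 4), f_mb = 0.2))
    c(accuracy(ses)$accuracy, choice_sensitivity(ses)$slope)
  }, numeric(2)))
  expect_gt(cor(res[, 1], res[, 2]), 0.8)
})

test_that("difficulty matches the analytic block-initial expectation", {
  st <- fixed_structure()
  ## constant equal walks: difficulty 0
  flat <- generate_session(st, task_config(), "random", seed = 41)
  flat$trials[, paste0("p", 1:4)] <- 0.5
  expect_equal(mean_difficulty(flat), 0)

  d <- estimate_difficulty(150, seed = 42)
  expect_lt(abs(d$block_initial_mean - 1 / 6), 0.008)
  expect_equal(length(d$per_session), 150)
  ## whole-session difficulty is below the block-initial spread (the walks
  ## mix toward their stationary distribution)
  expect_lt(d$mean, d$block_initial_mean)
})

test_that("the grid filter matches closed-form posterior updates", {
  kern <- make_transition_kernel(121, 0.03, 0.2, 0.8)
  expect_equal(colSums(kern$K), rep(1, 121))
  expect_true(all(kern$K >= 0))
  expect_error(make_transition_kernel(5), "grid_size")

  ## uniform prior, one sold observation, no drift:
  ## posterior mean = E[p^2]/E[p] = 0.28/0.5 = 0.56 on [0.2, 0.8]
  B <- matrix(1 / 121, 121, 1)
  B1 <- observer_update(B, kern$grid, 1)
  expect_lt(abs(sum(B1 * kern$grid) - 0.56), 2e-3)
  ## and an unsold observation: E[p(1-p)]/E[1-p] = 0.22/0.5 = 0.44
  B0 <- observer_update(B, kern$grid, 0)
  expect_lt(abs(sum(B0 * kern$grid) - 0.44), 2e-3)
  ## repeated sold observations concentrate on the upper bound
  for (i in 1:60) B1 <- observer_update(B1, kern$grid, 1)
  expect_gt(sum(B1 * kern$grid), 0.78)
})

test_that("regression tables restrict and code transitions correctly", {
  set.seed(43)
  st <- fixed_structure()
  sessions <- lapply(1:2, function(i)
    generate_session(st, task_config(), empirical_pattern_params()))
  tab <- build_repetition_table(sessions)
  side <- build_sidechoice_table(sessions)

  codes <- as.matrix(tab[, c("common", "unique", "absent", "other",
                             "importance")])
  expect_true(all(codes %in% c(-0.5, 0.5)))
  expect_true(all(as.matrix(side[, c("r1", "r2", "importance")]) %in%
                    c(-0.5, 0.5)))
  ## all within-block transitions appear in the side table; about half are
  ## repeat-eligible
  expect_equal(nrow(side), 2 * (392 - 7))
  expect_equal(nrow(tab) / nrow(side), 0.5, tolerance = 0.05)

  ## dual route: every repetition row must agree with classify_transition
  tr <- sessions[[1]]$trials
  k <- 0
  mismatches <- 0
  for (i in which(diff(tr$block) == 0)) {
    t1 <- list(left = tr$left[i], right = tr$right[i], chosen = tr$chosen[i],
               sold = setNames(as.numeric(tr[i, paste0("s", 1:4)]),
                               st$vegetables))
    t2 <- list(left = tr$left[i + 1], right = tr$right[i + 1],
               chosen = tr$chosen[i + 1])
    rec <- classify_transition(st, t1, t2)
    if (!rec$repeat_available) next
    k <- k + 1
    row <- tab[tab$subject == 1, ][k, ]
    expected <- c(
      common = unname(t1$sold[names(which(rec$roles_next == "Common"))]) - 0.5,
      unique = unname(t1$sold[names(which(rec$roles_next == "Unique"))]) - 0.5,
      absent = unname(t1$sold[names(which(rec$roles_next == "Absent"))]) - 0.5,
      other = unname(t1$sold[names(which(rec$roles_next == "Other"))]) - 0.5,
      importance = rec$importance_prev - 0.5,
      repeat_ = as.numeric(rec$repeat_))
    got <- unlist(row[names(expected)])
    mismatches <- mismatches + !isTRUE(all.equal(unname(got),
                                                 unname(expected)))
  }
  expect_gt(k, 100)
  expect_equal(mismatches, 0)
})

test_that("a pure-perseveration cohort shows repetition but no reward effects", {
  set.seed(44)
  sessions <- sim_cohort("full",
                         as.numeric(model_params(pr = 0.6, f_p = 0.4)), 20)
  fit <- fit_repetition_model(build_repetition_table(sessions))
  expect_gt(fit$estimate[fit$term == "(Intercept)"], 0.3)
  rewards <- fit[fit$term %in% c("common", "unique", "absent", "other"), ]
  expect_true(all(abs(rewards$estimate) < 0.2))
  expect_true(all(rewards$p > 0.01))
})

test_that("side-choice effects mirror under left-right relabeling", {
  set.seed(45)
  sessions <- sim_cohort("full", pattern_free("full"), 10)
  side <- build_sidechoice_table(sessions)
  fit <- fit_sidechoice_model(side)
  mirrored <- side
  mirrored$choose_right <- 1 - side$choose_right
  mirrored$r1 <- side$r2
  mirrored$r2 <- side$r1
  fit_m <- fit_sidechoice_model(mirrored)
  expect_equal(fit_m$estimate[fit_m$term == "r1"],
               -fit$estimate[fit$term == "r2"], tolerance = 1e-6)
  expect_equal(fit_m$estimate[fit_m$term == "r1:importance"],
               -fit$estimate[fit$term == "r2:importance"], tolerance = 1e-6)
})

test_that("credit-assignment parameter regressions recover the built-in contrasts", {
  set.seed(46)
  n <- 40
  ## MF pattern: related positive, unrelated mildly negative
  ca_mf <- cbind(rnorm(n, 0.6, 0.2), rnorm(n, 0.6, 0.2),
                 rnorm(n, -0.15, 0.2), rnorm(n, -0.15, 0.2))
  eff <- ca_param_effects(ca_mf, "MF")
  expect_gt(eff$effects$estimate[eff$effects$term == "R"], 0.5)
  expect_lt(eff$effects$p[eff$effects$term == "R"], 0.001)
  expect_lt(eff$simple$estimate[eff$simple$term == "unrelated"], 0)
  expect_lt(eff$simple$p[eff$simple$term == "unrelated"], 0.05)

  ## MB pattern: important > unimportant > 0
  ca_mb <- cbind(rnorm(n, 0.15, 0.1), rnorm(n, 0.28, 0.1),
                 rnorm(n, 0.28, 0.1), rnorm(n, 0.15, 0.1))
  eff2 <- ca_param_effects(ca_mb, "MB")
  expect_gt(eff2$effects$estimate[eff2$effects$term == "I"], 0.05)
  expect_lt(eff2$effects$p[eff2$effects$term == "I"], 0.05)
  expect_true(all(eff2$simple$estimate > 0))

  ## (near-)equal parameters: every contrast collapses to zero
  eff0 <- ca_param_effects(matrix(0.4, 10, 4) + rnorm(40, sd = 1e-4), "MF")
  expect_equal(max(abs(eff0$effects$estimate[-1])), 0, tolerance = 1e-3)
})
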