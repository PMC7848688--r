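test_that("model-based person values sum the two grown vegetables", {
  st <- fixed_structure()
  state <- agent_state_init(st)
  expect_true(all(vapply(st$persons, function(p)
    mb_person_value(state, st, p), 1) == 0))
  state$q_mb[st$grows[["P1"]]] <- c(0.3, 0.2)
  expect_equal(mb_person_value(state, st, "P1"), 0.5)
  expect_error(mb_person_value(state, st, "P9"), "unknown")

  # the shared vegetable cancels from the offered-pair value contrast
  pp <- st$valid_pairs[1, ]
  shared <- intersect(st$grows[[pp[1]]], st$grows[[pp[2]]])
  d0 <- mb_person_value(state, st, pp[1]) - mb_person_value(state, st, pp[2])
  state$q_mb[shared] <- state$q_mb[shared] + 5
  d1 <- mb_person_value(state, st, pp[1]) - mb_person_value(state, st, pp[2])
  expect_equal(d0, d1)
})

test_that("choice probabilities are a softmax of net values", {
  st <- fixed_structure()
  p <- zero_params()
  state <- agent_state_init(st)
  pp <- st$valid_pairs[1, ]
  cp <- choice_probability(state, st, p, pp)
  expect_equal(unname(cp$prob), c(0.5, 0.5))
  state$q_mf[pp[1]] <- 1
  cp1 <- choice_probability(state, st, p, pp)
  expect_equal(unname(cp1$prob[pp[1]]), 1 / (1 + exp(-1)))
  expect_equal(sum(cp1$prob), 1)
  # shift invariance
  state$q_mf[pp] <- state$q_mf[pp] + 3
  cp2 <- choice_probability(state, st, p, pp)
  expect_equal(cp1$prob, cp2$prob)
})

test_that("feedback updates follow the credit-assignment equations", {
  st <- fixed_structure()
  pp <- st$valid_pairs[1, ]
  cls <- classify_outcomes(st, pp, pp[1])
  # rewards +1,+1,-1,-1 for Common, Exclusive, Counterfactual, Absent
  sold <- setNames(integer(4), st$vegetables)
  sold[names(which(cls$role == "Common"))] <- 1L
  sold[names(which(cls$role == "Exclusive"))] <- 1L

  p <- model_params(c_mf = rep(0.5, 4))
  s1 <- update_after_feedback(agent_state_init(st), st, p, pp, pp[1], sold)
  expect_equal(unname(s1$q_mf[pp[1]]), 0)  # 0.5*(1+1-1-1)

  # pure forgetting halves a cached value
  p2 <- model_params(f_mf = 0.5)
  s0 <- agent_state_init(st)
  s0$q_mf[pp[1]] <- 1
  s2 <- update_after_feedback(s0, st, p2, pp, pp[2], sold)
  expect_equal(unname(s2$q_mf[pp[1]]), 0.5)

  # perseveration: chosen gains pr; others decay by (1 - f_p)
  p3 <- model_params(pr = 0.2, f_p = 0.5)
  s0 <- agent_state_init(st)
  s0$pers[pp[2]] <- 0.4
  s3 <- update_after_feedback(s0, st, p3, pp, pp[1], sold)
  expect_equal(unname(s3$pers[pp[1]]), 0.2)
  expect_equal(unname(s3$pers[pp[2]]), 0.2)

  # MB updates are per-vegetable with role-specific weights
  p4 <- model_params(c_mb = c(0.1, 0.2, 0.3, 0.4), f_mb = 0.5)
  s4 <- update_after_feedback(agent_state_init(st), st, p4, pp, pp[1], sold)
  expect_equal(unname(s4$q_mb[names(which(cls$role == "Common"))]), 0.1)
  expect_equal(unname(s4$q_mb[names(which(cls$role == "Exclusive"))]), 0.2)
  expect_equal(unname(s4$q_mb[names(which(cls$role == "Counterfactual"))]), -0.3)
  expect_equal(unname(s4$q_mb[names(which(cls$role == "Absent"))]), -0.4)
})

test_that("the compiled likelihood equals the naive replay oracle", {
  set.seed(15)
  st <- fixed_structure()
  for (i in 1:5) {
    ses <- generate_session(st, task_config(n_blocks = 2), random_full_params())
    p <- random_full_params()
    expect_equal(session_loglik(p, ses), session_loglik_replay(p, ses),
                 tolerance = 1e-12)
  }
})

test_that("likelihood identities hold: chance point, nesting, block permutation", {
  set.seed(16)
  ses <- generate_session(fixed_structure(), task_config(), "random")
  expect_equal(session_loglik(zero_params(), ses), 392 * log(0.5))
  p <- random_full_params()
  ll <- session_loglik(p, ses)
  expect_true(is.finite(ll) && ll <= 0)

  # every submodel's likelihood equals the full model's at the embedded point
  for (nm in c("pure_mb", "pure_mf", "no_cm_mf", "no_unrelated_mfca",
               "egalitarian_mb")) {
    sp <- model_spec(nm)
    free <- runif(sp$k, -0.5, 0.5)
    free[sp$forgetting] <- runif(sum(sp$forgetting), 0.1, 0.9)
    expect_identical(session_loglik(free, ses, spec = nm),
                     session_loglik(apply_constraints(nm, free), ses))
  }

  # permuting block order permutes per-block contributions unchanged
  tr <- ses$trials
  perm <- c(4, 1, 7, 3, 6, 2, 5)
  tr2 <- do.call(rbind, lapply(seq_along(perm),
                               function(i) tr[tr$block == perm[i], ]))
  tr2$block <- rep(1:7, each = 56)
  ses2 <- ses
  ses2$trials <- tr2
  expect_equal(session_loglik(p, ses2), ll, tolerance = 1e-12)
})

test_that("cached values respect the geometric fixed-point bounds over long histories", {
  set.seed(17)
  st <- fixed_structure()
  cfg <- task_config(n_blocks = 1, trials_per_block = 10000)
  p <- model_params(c_mf = runif(4, -2, 2), c_mb = runif(4, -2, 2),
                    f_mf = runif(1, 0.05, 0.9), f_mb = runif(1, 0.05, 0.9),
                    pr = runif(1, -2, 2), f_p = runif(1, 0.05, 0.9))
  ses <- generate_session(st, cfg, p)
  tr <- ses$trials
  state <- agent_state_init(st)
  max_mf <- max_mb <- max_p <- 0
  for (i in seq_len(nrow(tr))) {
    sold <- setNames(as.numeric(tr[i, paste0("s", 1:4)]), st$vegetables)
    state <- update_after_feedback(state, st, p, c(tr$left[i], tr$right[i]),
                                   tr$chosen[i], sold)
    max_mf <- max(max_mf, abs(state$q_mf))
    max_mb <- max(max_mb, abs(state$q_mb))
    max_p <- max(max_p, abs(state$pers))
  }
  expect_lte(max_mf, sum(abs(p[1:4])) / p[["f_mf"]])
  expect_lte(max_mb, max(abs(p[5:8])) / p[["f_mb"]])
  expect_lte(max_p, abs(p[["pr"]]) / p[["f_p"]])
})

test_that("constraint embeddings have the documented free-parameter counts", {
  expect_equal(model_spec("full")$k, 12)
  expect_equal(model_spec("pure_mb")$k, 7)
  expect_equal(model_spec("pure_mf")$k, 7)
  expect_equal(model_spec("no_cm_mf")$k, 9)
  expect_equal(model_spec("no_unrelated_mfca")$k, 10)
  expect_equal(model_spec("egalitarian_mb")$k, 9)

  pm <- apply_constraints("pure_mb", c(1:4 / 10, 0.5, 0.3, 0.2))
  expect_equal(unname(pm[1:4]), rep(0, 4))        # MFCA knocked out
  expect_equal(unname(pm[5:8]), 1:4 / 10)
  nc <- apply_constraints("no_cm_mf", c(0.7, 0.5, 1:4 / 10, 0.3, 0.2, 0.1))
  expect_equal(unname(nc[1:4]), rep(0.7, 4))      # shared MFCA weight
  expect_error(apply_constraints("pure_mb", 1:5), "expected 7")
})

test_that("simulated choices follow the generating policy", {
  set.seed(18)
  st <- fixed_structure()
  # all-zero parameters: both sides chosen equally often
  side_rate <- mean(replicate(5, {
    ses <- generate_session(st, task_config(), zero_params())
    mean(ses$trials$chosen == ses$trials$right)
  }))
  expect_lt(abs(side_rate - 0.5), 0.04)
  # strong non-decaying perseveration: previous choice repeated when re-offered
  pers <- model_params(pr = 5, f_p = 0)
  ses2 <- generate_session(st, task_config(), pers)
  tr <- ses2$trials
  i <- which(diff(tr$block) == 0)
  avail <- tr$chosen[i] == tr$left[i + 1] | tr$chosen[i] == tr$right[i + 1]
  expect_gt(mean(tr$chosen[i + 1][avail] == tr$chosen[i][avail]), 0.85)
  # fitting the generating model beats the chance point on its own data
  set.seed(19)
  ll_gen <- mean(replicate(10, {
    s <- generate_session(st, task_config(), empirical_pattern_params())
    session_loglik(empirical_pattern_params(), s) -
      session_loglik(zero_params(), s)
  }))
  expect_gt(ll_gen, 0)
})
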