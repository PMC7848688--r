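test_that("random structures always satisfy the bipartite 4-cycle invariants", {
  for (seed in 1:25) {
    st <- make_structure(seed)
    grown_by <- table(unlist(st$grows))
    expect_true(all(lengths(st$grows) == 2))          # each person grows 2
    expect_true(all(grown_by == 2))                   # each veg grown by 2
    expect_equal(length(unique(vapply(st$grows, function(v)
      paste(sort(v), collapse = ""), ""))), 4)        # all pairs distinct
    expect_equal(nrow(st$valid_pairs), 4)             # exactly 4 valid pairs

    cmb <- combn(st$persons, 2)
    shared <- apply(cmb, 2, function(pp)
      length(intersect(st$grows[[pp[1]]], st$grows[[pp[2]]])))
    expect_equal(sort(shared), c(0, 0, 1, 1, 1, 1))   # 4 share one, 2 share none

    for (k in 1:4) {
      pp <- st$valid_pairs[k, ]
      vegs <- c(st$grows[[pp[1]]], st$grows[[pp[2]]])
      expect_equal(sum(duplicated(vegs)), 1)          # 1 shared, 2 distinctive
      expect_equal(length(setdiff(st$vegetables, vegs)), 1)  # 1 absent
    }
  }
})

test_that("outcome classification assigns the four roles correctly", {
  st <- fixed_structure()
  pp <- st$valid_pairs[1, ]
  shared <- intersect(st$grows[[pp[1]]], st$grows[[pp[2]]])
  cls <- classify_outcomes(st, pp, chosen = pp[1])
  expect_equal(sort(unname(cls$role)),
               sort(c("Common", "Exclusive", "Counterfactual", "Absent")))
  expect_equal(unname(cls$role[shared]), "Common")
  expect_equal(unname(cls$role[setdiff(st$grows[[pp[1]]], shared)]), "Exclusive")
  expect_equal(unname(cls$role[setdiff(st$grows[[pp[2]]], shared)]),
               "Counterfactual")
  # related = chosen person's vegetables; important = the distinctive pair
  expect_setequal(cls$related, st$grows[[pp[1]]])
  expect_setequal(cls$important,
                  c(setdiff(st$grows[[pp[1]]], shared),
                    setdiff(st$grows[[pp[2]]], shared)))

  # swapping the chosen person swaps Exclusive and Counterfactual only
  cls2 <- classify_outcomes(st, pp, chosen = pp[2])
  expect_equal(names(which(cls$role == "Exclusive")),
               names(which(cls2$role == "Counterfactual")))
  expect_equal(names(which(cls$role == "Common")),
               names(which(cls2$role == "Common")))
  expect_equal(names(which(cls$role == "Absent")),
               names(which(cls2$role == "Absent")))

  expect_error(classify_outcomes(st, pp, chosen = setdiff(st$persons, pp)[1]),
               "chosen")
  # the pair sharing no vegetable is rejected
  other <- st$persons[!vapply(st$persons, function(p)
    is_valid_pair(st, st$persons[1], p) || p == st$persons[1], TRUE)]
  expect_error(classify_outcomes(st, c(st$persons[1], other), st$persons[1]),
               "share")
})

test_that("transition classification satisfies the importance-coherence invariants", {
  set.seed(4)
  st <- fixed_structure()
  n_checked <- 0L
  violations <- 0L
  for (s in 1:26) {
    ses <- generate_session(st, task_config(), policy = "random")
    tr <- ses$trials
    for (i in which(diff(tr$block) == 0)) {
      t1 <- list(left = tr$left[i], right = tr$right[i], chosen = tr$chosen[i],
                 sold = setNames(as.numeric(tr[i, paste0("s", 1:4)]),
                                 st$vegetables))
      t2 <- list(left = tr$left[i + 1], right = tr$right[i + 1],
                 chosen = tr$chosen[i + 1])
      rec <- classify_transition(st, t1, t2)
      imp_n <- classify_outcomes(st, c(t1$left, t1$right), t1$chosen)$important
      ok <- rec$distinctive_left$veg %in% imp_n ==
        rec$distinctive_right$veg %in% imp_n
      if (rec$repeat_available) {
        uniq <- names(which(rec$roles_next == "Unique"))
        oth <- names(which(rec$roles_next == "Other"))
        common <- names(which(rec$roles_next == "Common"))
        absent <- names(which(rec$roles_next == "Absent"))
        related <- st$grows[[t1$chosen]]
        ok <- ok &&
          all(c(common, uniq) %in% related) &&          # related on trial n
          !any(c(oth, absent) %in% related) &&          # unrelated on trial n
          (uniq %in% imp_n) == (oth %in% imp_n) &&      # shared importance
          rec$importance_prev == (uniq %in% imp_n)
      }
      violations <- violations + !ok
      n_checked <- n_checked + 1L
    }
    if (n_checked >= 10000L) break
  }
  expect_gte(n_checked, 10000L)
  expect_identical(violations, 0L)
})
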