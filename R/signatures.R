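## per-trial expected value of each offered person (mean of its two
## vegetables' generating probabilities) for one cm_session
session_offer_values <- function(session) {
  st <- session$structure
  tr <- session$trials
  gi <- st$grows_idx
  probs <- as.matrix(tr[, paste0("p", 1:4)])
  pv <- function(person) {
    i <- person_index(st, person)
    (probs[cbind(seq_along(i), gi[i, 1])] +
     probs[cbind(seq_along(i), gi[i, 2])]) / 2
  }
  cbind(left = pv(tr$left), right = pv(tr$right))
}

#' Choice accuracy of a session
#'
#' Proportion of trials on which the offered person with the higher expected
#' generating reward probability (mean over its two vegetables) was chosen.
#' Trials where the two persons' expected values tie are excluded from the
#' denominator.
#'
#' @param session a `cm_session`.
#' @return a list with `accuracy`, `n_scored` and `n_ties`; `accuracy` is
#'   `NA` (flagged) if every trial ties.
#' @export
accuracy <- function(session) {
  v <- session_offer_values(session)
  tie <- v[, 1] == v[, 2]
  chose_left <- session$trials$chosen == session$trials$left
  correct <- ifelse(v[, 1] > v[, 2], chose_left, !chose_left)
  n <- sum(!tie)
  list(accuracy = if (n == 0) NA_real_ else mean(correct[!tie]),
       n_scored = n, n_ties = sum(tie))
}

#' Choice sensitivity of a session
#'
#' Slope of a logistic regression of the chosen display side (right = 1) on
#' the right-minus-left contrast in the offered persons' expected generating
#' reward probabilities. Under (quasi-)separation the slope is capped at
#' +/- 10 and flagged.
#'
#' @param session a `cm_session`.
#' @param cap magnitude cap applied under separation.
#' @return list with `slope` and `separation` flag.
#' @export
choice_sensitivity <- function(session, cap = 10) {
  v <- session_offer_values(session)
  y <- as.integer(session$trials$chosen == session$trials$right)
  x <- v[, 2] - v[, 1]
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ x, family = binomial()),
    warning = function(w) {
      sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || abs(slope) > cap) {
    sep <- TRUE
    slope <- sign(slope) * cap
  }
  list(slope = slope, separation = sep)
}

#' Mean difficulty of a session
#'
#' Across-trials average absolute difference between the offered persons'
#' expected generating reward probabilities.
#'
#' @param session a `cm_session`.
#' @export
mean_difficulty <- function(session) {
  v <- session_offer_values(session)
  mean(abs(v[, 1] - v[, 2]))
}

#' Estimate task difficulty by simulation
#'
#' Simulates sessions from the generative task process (choices are
#' irrelevant to difficulty) and returns the across-sessions mean of
#' [mean_difficulty()], together with the block-initial-trial mean, whose
#' analytic expectation is 1/6 under the default initial values.
#'
#' @param n_sessions number of simulated sessions.
#' @param config a [task_config()].
#' @param seed optional seed.
#' @return list with `mean`, `per_session`, `block_initial_mean`.
#' @export
estimate_difficulty <- function(n_sessions = 500, config = task_config(),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  st <- make_structure()
  batch <- gen_batch(st, config, n_sessions)
  v <- offered_values(st, batch)
  d <- abs(v[, 1] - v[, 2])
  per_session <- as.numeric(rowsum(d, batch$session)) /
    (config$n_blocks * config$trials_per_block)
  list(mean = mean(per_session), per_session = per_session,
       block_initial_mean = mean(d[batch$reset]))
}

## ---------------------------------------------------------------------------
## Ideal Bayesian observer

#' Reflected-Gaussian transition kernel on a probability grid
#'
#' Column j gives the distribution of the next-trial probability given the
#' current value at grid point j, under a Gaussian increment of SD `sd`
#' folded back into `[lo, hi]` by mirror reflection. Cell masses integrate
#' the (single-image) reflected normal density over the grid cells and are
#' renormalized.
#'
#' @param grid_size number of grid points (>= 11).
#' @param sd increment SD.
#' @param lo,hi reflecting bounds.
#' @return list with `grid` (points) and `K` (grid_size x grid_size kernel).
#' @export
make_transition_kernel <- function(grid_size = 121, sd = 0.03,
                                   lo = 0.2, hi = 0.8) {
  if (grid_size < 11) stop("grid_size must be >= 11")
  grid <- seq(lo, hi, length.out = grid_size)
  edges <- c(lo, (grid[-1] + grid[-grid_size]) / 2, hi)
  K <- matrix(0, grid_size, grid_size)
  for (j in seq_len(grid_size)) {
    p <- grid[j]
    direct <- pnorm(edges[-1], p, sd) - pnorm(edges[-length(edges)], p, sd)
    refl_lo <- pnorm(2 * lo - edges[-length(edges)], p, sd) -
               pnorm(2 * lo - edges[-1], p, sd)
    refl_hi <- pnorm(2 * hi - edges[-length(edges)], p, sd) -
               pnorm(2 * hi - edges[-1], p, sd)
    K[, j] <- direct + refl_lo + refl_hi
  }
  list(grid = grid, K = sweep(K, 2, colSums(K), `/`))
}

#' Bayes update of a grid belief on one Bernoulli observation
#'
#' @param belief numeric grid belief (sums to 1) or a matrix of column
#'   beliefs.
#' @param grid the grid points (success probabilities).
#' @param sold 1/TRUE for a sale, 0/FALSE otherwise; vectorized over belief
#'   columns.
#' @return updated belief(s), column-normalized.
#' @export
observer_update <- function(belief, grid, sold) {
  B <- as.matrix(belief)
  lik <- outer(grid, rep(1, ncol(B)))
  lik[, !as.logical(sold)] <- 1 - lik[, !as.logical(sold)]
  B <- B * lik
  sweep(B, 2, colSums(B), `/`)
}

#' Accuracy of the ideal Bayesian observer
#'
#' Runs, per vegetable, an exact discretized Bayes filter over the sale
#' probability (uniform prior on `[lo, hi]` at every block start,
#' reflected-Gaussian drift between trials, Bernoulli observations of all
#' four vegetables each trial), chooses the offered person with the higher
#' posterior-mean value sum, and scores accuracy against the generating
#' probabilities (true ties excluded; observer ties broken at random).
#'
#' @param config a [task_config()].
#' @param n_sessions number of simulated sessions.
#' @param grid_size filter grid resolution (>= 11).
#' @param seed optional seed.
#' @return list with `accuracy` (mean of per-session accuracies),
#'   `per_session`, `n_sessions`, `grid_size`.
#' @export
ideal_observer_accuracy <- function(config = task_config(), n_sessions = 200,
                                    grid_size = 121, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  st <- make_structure()
  batch <- gen_batch(st, config, n_sessions)
  kern <- make_transition_kernel(grid_size, config$walk_sd,
                                 config$walk_lo, config$walk_hi)
  G <- grid_size; S <- n_sessions
  TT <- config$n_blocks * config$trials_per_block
  gi <- st$grows_idx
  B <- matrix(1 / G, G, 4L * S)          # beliefs, one column per (session, veg)
  col_of <- function(s, v) (s - 1L) * 4L + v
  correct <- numeric(S); scored <- numeric(S)
  sess_off <- (seq_len(S) - 1L) * TT

  for (t in seq_len(TT)) {
    idx <- sess_off + t
    if (batch$reset[t]) B[] <- 1 / G
    m <- matrix(colSums(B * kern$grid), nrow = 4L)   # posterior means, 4 x S
    vl <- (m[cbind(gi[batch$left[idx], 1], seq_len(S))] +
           m[cbind(gi[batch$left[idx], 2], seq_len(S))]) / 2
    vr <- (m[cbind(gi[batch$right[idx], 1], seq_len(S))] +
           m[cbind(gi[batch$right[idx], 2], seq_len(S))]) / 2
    pick_left <- vl > vr | (vl == vr & runif(S) < 0.5)
    pv <- function(person) (batch$probs[cbind(idx, gi[person, 1])] +
                            batch$probs[cbind(idx, gi[person, 2])]) / 2
    tvl <- pv(batch$left[idx]); tvr <- pv(batch$right[idx])
    tie <- tvl == tvr
    ok <- ifelse(tvl > tvr, pick_left, !pick_left)
    correct <- correct + ifelse(tie, 0, ok)
    scored <- scored + !tie
    ## observe all four outcomes, then drift towards the next trial
    sold <- as.vector(t(batch$sold[idx, , drop = FALSE]))  # veg fastest
    B <- observer_update(B, kern$grid, sold)
    if (t < TT && !batch$reset[t + 1L]) B <- kern$K %*% B
  }
  per_session <- correct / pmax(scored, 1)
  list(accuracy = mean(per_session), per_session = per_session,
       n_sessions = S, grid_size = G)
}

## ---------------------------------------------------------------------------
## Transition regression tables

## per-trial lookups for one session: pair id, shared veg, distinctive veg of
## the left and right persons, importance class
session_trial_geometry <- function(session) {
  st <- session$structure
  tr <- session$trials
  pt <- pair_table(st)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  pair_id <- match(key(tr$left, tr$right), key(pt$pairs[, 1], pt$pairs[, 2]))
  shared <- integer(4); dist1 <- integer(4); dist2 <- integer(4)
  for (k in seq_len(4)) {
    i <- person_index(st, pt$pairs[k, ])
    shared[k] <- intersect(st$grows_idx[i[1], ], st$grows_idx[i[2], ])
    dist1[k] <- setdiff(st$grows_idx[i[1], ], shared[k])
    dist2[k] <- setdiff(st$grows_idx[i[2], ], shared[k])
  }
  left_is_first <- tr$left == pt$pairs[pair_id, 1]
  list(pair_id = pair_id,
       class = pt$class[pair_id],
       shared = shared[pair_id],
       dist_left = ifelse(left_is_first, dist1[pair_id], dist2[pair_id]),
       dist_right = ifelse(left_is_first, dist2[pair_id], dist1[pair_id]))
}

#' Build the choice-repetition regression table
#'
#' One row per eligible transition: consecutive trials of one block whose
#' second trial offers the first trial's chosen person. Regressors are the
#' trial-n reward codes (+0.5 sold / -0.5 unsold) of the vegetables in their
#' trial-n+1 roles (Common, Unique, Absent, Other), and the +/-0.5
#' IMPORTANCE code of whether the Unique and Other vegetables were important
#' on trial n. The regressand REPEAT indicates choice repetition.
#'
#' @param sessions a `cm_session` or list of them (one per subject).
#' @return a data.frame with columns `subject`, `repeat_`, `common`,
#'   `unique`, `absent`, `other`, `importance`.
#' @export
build_repetition_table <- function(sessions) {
  if (inherits(sessions, "cm_session")) sessions <- list(sessions)
  out <- lapply(seq_along(sessions), function(si) {
    ses <- sessions[[si]]
    tr <- ses$trials
    st <- ses$structure
    g <- session_trial_geometry(ses)
    n <- nrow(tr)
    i <- which(diff(tr$block) == 0)           # transition n -> n+1 within block
    j <- i + 1L
    chosen_n <- tr$chosen[i]
    avail <- chosen_n == tr$left[j] | chosen_n == tr$right[j]
    i <- i[avail]; j <- j[avail]
    if (!length(i)) return(NULL)
    chosen_is_left <- tr$chosen[i] == tr$left[j]
    uniq <- ifelse(chosen_is_left, g$dist_left[j], g$dist_right[j])
    oth <- ifelse(chosen_is_left, g$dist_right[j], g$dist_left[j])
    sold <- as.matrix(tr[, paste0("s", 1:4)])
    code <- function(v) sold[cbind(i, v)] - 0.5
    data.frame(subject = si,
               repeat_ = as.integer(tr$chosen[j] == tr$chosen[i]),
               common = code(g$shared[j]),
               unique = code(uniq),
               absent = code(10L - g$shared[j] - g$dist_left[j] - g$dist_right[j]),
               other = code(oth),
               importance = (g$class[i] == g$class[j]) - 0.5)
  })
  do.call(rbind, out)
}

#' Build the side-choice regression table
#'
#' One row per within-block transition (no repetition restriction). R1 and R2
#' are the +/-0.5 trial-n reward codes of the vegetables distinctive to the
#' trial-n+1 right and left persons; IMPORTANCE codes whether those two
#' vegetables were important on trial n; the regressand is whether the
#' right-side person was chosen on trial n+1.
#'
#' @inheritParams build_repetition_table
#' @return data.frame with `subject`, `choose_right`, `r1`, `r2`,
#'   `importance`.
#' @export
build_sidechoice_table <- function(sessions) {
  if (inherits(sessions, "cm_session")) sessions <- list(sessions)
  out <- lapply(seq_along(sessions), function(si) {
    ses <- sessions[[si]]
    tr <- ses$trials
    g <- session_trial_geometry(ses)
    i <- which(diff(tr$block) == 0)
    j <- i + 1L
    if (!length(i)) return(NULL)
    sold <- as.matrix(tr[, paste0("s", 1:4)])
    data.frame(subject = si,
               choose_right = as.integer(tr$chosen[j] == tr$right[j]),
               r1 = sold[cbind(i, g$dist_right[j])] - 0.5,
               r2 = sold[cbind(i, g$dist_left[j])] - 0.5,
               importance = (g$class[i] == g$class[j]) - 0.5)
  })
  do.call(rbind, out)
}

## two-stage estimator: per-subject ML logistic fits, then one-sample t-tests
## on the coefficient (or contrast) across subjects
two_stage_logistic <- function(table, formula, terms, contrasts, cap = 10) {
  subjects <- unique(table$subject)
  coefs <- t(vapply(subjects, function(s) {
    d <- table[table$subject == s, ]
    fit <- suppressWarnings(glm(formula, family = binomial(), data = d))
    b <- coef(fit)[terms]
    b[!is.finite(b)] <- 0
    pmin(pmax(b, -cap), cap)
  }, numeric(length(terms))))
  colnames(coefs) <- terms
  capped <- any(abs(coefs) >= cap)
  all_effects <- coefs
  if (length(contrasts)) {
    cm <- vapply(contrasts, function(ct) coefs[, ct[1]] - coefs[, ct[2]],
                 numeric(length(subjects)))
    all_effects <- cbind(coefs, cm)
  }
  est <- colMeans(all_effects)
  se <- apply(all_effects, 2, sd) / sqrt(length(subjects))
  tval <- est / se
  df <- length(subjects) - 1
  res <- data.frame(term = colnames(all_effects), estimate = est, se = se,
                    t = tval, df = df,
                    p = 2 * pt(-abs(tval), df), row.names = NULL)
  attr(res, "coefs") <- all_effects
  attr(res, "capped") <- capped
  res
}

#' Fit the choice-repetition model
#'
#' Two-stage hierarchical logistic estimate of
#' `REPEAT ~ IMPORTANCE * (COMMON + UNIQUE + ABSENT + OTHER)`: per-subject ML
#' logistic fits (coefficients capped at +/-10 under separation) followed by
#' across-subject one-sample t-tests on each coefficient and on the
#' contrasts (Unique - Common), (Absent - Other) and (Common - Absent).
#'
#' @param table output of [build_repetition_table()] (needs >= 2 subjects).
#' @return data.frame of effect estimates with `term`, `estimate`, `se`,
#'   `t`, `df`, `p`; per-subject coefficients in `attr(, "coefs")`.
#' @export
fit_repetition_model <- function(table) {
  if (length(unique(table$subject)) < 2) stop("need >= 2 subjects")
  terms <- c("(Intercept)", "common", "unique", "absent", "other",
             "importance", "common:importance", "unique:importance",
             "absent:importance", "other:importance")
  contrasts <- list(unique_minus_common = c("unique", "common"),
                    absent_minus_other = c("absent", "other"),
                    common_minus_absent = c("common", "absent"))
  two_stage_logistic(table,
    repeat_ ~ (common + unique + absent + other) * importance,
    terms, contrasts)
}

#' Fit the side-choice model
#'
#' Two-stage estimate of `CHOOSE_RIGHT ~ IMPORTANCE * (R1 + R2)` across all
#' transitions.
#'
#' @param table output of [build_sidechoice_table()].
#' @return as [fit_repetition_model()].
#' @export
fit_sidechoice_model <- function(table) {
  if (length(unique(table$subject)) < 2) stop("need >= 2 subjects")
  terms <- c("(Intercept)", "r1", "r2", "importance",
             "r1:importance", "r2:importance")
  two_stage_logistic(table, choose_right ~ (r1 + r2) * importance,
                     terms, list())
}

#' Mixed-effects analysis of fitted credit-assignment parameters
#'
#' Regresses per-subject CA parameters (4 per subject, one per outcome role)
#' on +/-0.5-coded indicators of choice-relatedness (R: Common, Exclusive)
#' and importance (I: Exclusive, Counterfactual) with a subject random
#' intercept, plus simple-effect t-tests of the role-group means.
#'
#' @param ca subjects x 4 matrix of CA weights, columns in role order
#'   (Common, Exclusive, Counterfactual, Absent).
#' @param system `"MF"` or `"MB"` (selects which simple effects to report).
#' @return list with `effects` (fixed-effect estimates for R, I, R:I) and
#'   `simple` (group-mean t-tests).
#' @export
ca_param_effects <- function(ca, system = c("MF", "MB")) {
  system <- match.arg(system)
  ca <- as.matrix(ca)
  stopifnot(ncol(ca) == 4)
  n <- nrow(ca)
  long <- data.frame(
    value = as.vector(t(ca)),
    R = rep(c(0.5, 0.5, -0.5, -0.5), n),
    I = rep(c(-0.5, 0.5, 0.5, -0.5), n),
    subject = factor(rep(seq_len(n), each = 4)))
  fit <- suppressMessages(
    lmerTest::lmer(value ~ R * I + (1 | subject), data = long))
  sm <- summary(fit)$coefficients
  effects <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                        se = sm[, "Std. Error"], t = sm[, "t value"],
                        p = sm[, "Pr(>|t|)"], row.names = NULL)
  groups <- if (system == "MF")
    list(related = c(1, 2), unrelated = c(3, 4))
  else
    list(important = c(2, 3), unimportant = c(1, 4))
  simple <- do.call(rbind, lapply(names(groups), function(g) {
    m <- rowMeans(ca[, groups[[g]], drop = FALSE])
    tt <- t.test(m)
    data.frame(term = g, estimate = mean(m), t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value)
  }))
  list(effects = effects, simple = simple)
}

## the six directional signatures of cognitive-map-guided credit assignment,
## plus the two side-choice importance interactions
SIGNATURE_DEFS <- list(
  common_positive = list(model = "rep", term = "common", dir = +1),
  unique_minus_common_positive = list(model = "rep", term = "unique_minus_common", dir = +1),
  absent_minus_other_positive = list(model = "rep", term = "absent_minus_other", dir = +1),
  common_minus_absent_positive = list(model = "rep", term = "common_minus_absent", dir = +1),
  unique_x_importance_positive = list(model = "rep", term = "unique:importance", dir = +1),
  other_x_importance_negative = list(model = "rep", term = "other:importance", dir = -1),
  r1_x_importance_positive = list(model = "side", term = "r1:importance", dir = +1),
  r2_x_importance_negative = list(model = "side", term = "r2:importance", dir = -1))

#' Assemble the signature report from fitted regression models
#'
#' For each directional signature, reports the group estimate, the one-sided
#' p-value in the predicted direction, and whether the signature holds
#' (predicted sign, one-sided p < alpha).
#'
#' @param rep_fit output of [fit_repetition_model()].
#' @param side_fit output of [fit_sidechoice_model()].
#' @param alpha significance level for the `holds` flag.
#' @return data.frame with one row per signature.
#' @export
signature_report <- function(rep_fit, side_fit, alpha = 0.05) {
  rows <- lapply(names(SIGNATURE_DEFS), function(nm) {
    def <- SIGNATURE_DEFS[[nm]]
    fit <- if (def$model == "rep") rep_fit else side_fit
    r <- fit[fit$term == def$term, ]
    p_onesided <- pt(-def$dir * r$t, r$df)
    data.frame(signature = nm, term = r$term, direction = def$dir,
               estimate = r$estimate, t = r$t, p_one_sided = p_onesided,
               holds = sign(r$estimate) == def$dir & p_onesided < alpha)
  })
  do.call(rbind, rows)
}

#' Predicted signatures of a model spec
#'
#' Simulates a synthetic cohort from the spec at the given generating
#' parameters, runs both model-agnostic regressions, and reports which
#' directional signatures the spec predicts. Used to verify each submodel's
#' characteristic failures.
#'
#' @param spec a [model_spec()] or name.
#' @param cohort_params `n_subjects x k` matrix of generating free vectors,
#'   or a single free/parameter vector recycled across subjects.
#' @param n_subjects cohort size (used when `cohort_params` is a single
#'   vector).
#' @param config a [task_config()].
#' @param seed optional seed.
#' @return list with `report` (the [signature_report()] data.frame),
#'   `rep_fit`, `side_fit`.
#' @export
predict_signatures <- function(spec, cohort_params, n_subjects = 42,
                               config = task_config(), seed = NULL) {
  spec <- as_model_spec(spec)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(dim(cohort_params)))
    cohort_params <- matrix(rep(as.numeric(cohort_params), each = n_subjects),
                            n_subjects)
  sessions <- lapply(seq_len(nrow(cohort_params)), function(i)
    simulate_session(cohort_params[i, ], spec, structure = make_structure(),
                     config = config))
  rep_fit <- fit_repetition_model(build_repetition_table(sessions))
  side_fit <- fit_sidechoice_model(build_sidechoice_table(sessions))
  list(report = signature_report(rep_fit, side_fit),
       rep_fit = rep_fit, side_fit = side_fit)
}
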