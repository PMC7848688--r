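#' BIC log-evidence of a fit
#'
#' Approximates the per-subject log model evidence as
#' `loglik - (k / 2) * log(n_trials)` (i.e. -BIC/2). Only parameters that
#' move the likelihood count towards `k`.
#'
#' @param fit a `cm_fit`.
#' @return numeric log-evidence.
#' @export
log_evidence_bic <- function(fit) {
  fit$loglik - fit$k / 2 * log(fit$n_trials)
}

#' Fit several model specs to a cohort of sessions
#'
#' @param sessions list of `cm_session`.
#' @param specs character vector of spec names.
#' @param n_starts optimizer starts per fit.
#' @param seed optional seed.
#' @return list with `fits` (subjects x specs nested list) and `evidence`
#'   (subjects x specs matrix of BIC log-evidences).
#' @export
fit_cohort <- function(sessions, specs = MODEL_NAMES, n_starts = 5,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fits <- lapply(sessions, function(s) {
    fs <- lapply(specs, function(sp) fit_mle(s, sp, n_starts = n_starts))
    names(fs) <- specs
    fs
  })
  E <- t(vapply(fits, function(fs) vapply(fs, log_evidence_bic, numeric(1)),
                numeric(length(specs))))
  colnames(E) <- specs
  list(fits = fits, evidence = E)
}

#' Bootstrap generalized-likelihood-ratio test of a nested submodel
#'
#' The submodel plays the null hypothesis. Each subject's session is fitted
#' under both models (full refit seeded from the embedded submodel optimum,
#' so all statistics are non-negative). The null distribution is built by
#' simulating, per bootstrap replicate, each subject's session from that
#' subject's fitted submodel parameters and refitting both models. P-values
#' use the add-one rule `(1 + #(null >= observed)) / (1 + n_boot)`, at the
#' individual and group (summed statistic) levels.
#'
#' @param sessions list of `cm_session` (one per subject).
#' @param sub_spec the null submodel spec or name.
#' @param full_spec the alternative (default `"full"`).
#' @param n_boot number of bootstrap replicates (>= 1).
#' @param n_starts size of the submodel start set. One fixed start set
#'   (chance point plus Latin-hypercube draws) is shared by the observed-data
#'   fits and every bootstrap refit, and the full-model fits always add the
#'   embedded submodel optimum, so the observed and null statistics are
#'   computed by exactly the same procedure.
#' @param n_starts_full size of the full-model start set (in addition to the
#'   embedded submodel optimum).
#' @param seed optional seed.
#' @return a list of class `cm_glrt` with per-subject statistics and
#'   p-values, the group statistic and p-value, and the null samples.
#' @export
bootstrap_glrt <- function(sessions, sub_spec, full_spec = "full",
                           n_boot = 1000, n_starts = 5, n_starts_full = 2,
                           seed = NULL) {
  if (n_boot < 1) stop("n_boot must be >= 1")
  sub_spec <- as_model_spec(sub_spec)
  full_spec <- as_model_spec(full_spec)
  if (!is.null(seed)) set.seed(seed)
  n <- length(sessions)
  bs <- opt_bounds(sub_spec); bf <- opt_bounds(full_spec)
  starts_sub <- make_starts(sub_spec, n_starts)
  starts_full <- make_starts(full_spec, n_starts_full)
  isl_sub <- as.integer(sub_spec$forgetting)
  isl_full <- as.integer(full_spec$forgetting)

  obs_stat <- numeric(n)
  sub_free_opt <- matrix(NA_real_, n, sub_spec$k)
  obs <- vector("list", n)
  for (i in seq_len(n)) {
    a <- session_arrays(sessions[[i]])
    r <- cpp_glrt_observed(sub_spec$M, isl_sub, bs$lower, bs$upper, starts_sub,
                           full_spec$M, isl_full, bf$lower, bf$upper,
                           starts_full, sessions[[i]]$structure$grows_idx - 1L,
                           a$left, a$right, a$chosen, a$rewards,
                           as.integer(a$reset))
    obs_stat[i] <- r$statistic
    sub_free_opt[i, ] <- r$sub_free
    obs[[i]] <- list(statistic = r$statistic,
                     sub_free = setNames(opt_to_natural(sub_spec, r$sub_free),
                                         sub_spec$free_names))
  }

  null_stat <- matrix(NA_real_, n_boot, n)
  for (i in seq_len(n)) {
    st <- sessions[[i]]$structure
    cfg <- sessions[[i]]$config
    batch <- gen_batch(st, cfg, n_boot)
    TT <- cfg$n_blocks * cfg$trials_per_block
    null_stat[, i] <- cpp_glrt_stats(
      sub_free_opt[i, , drop = FALSE], sub_spec$M, isl_sub, bs$lower, bs$upper,
      starts_sub, full_spec$M, isl_full, bf$lower, bf$upper, starts_full,
      st$grows_idx - 1L,
      subject = integer(n_boot), offsets = as.integer(seq(0, n_boot * TT, TT)),
      left = batch$left - 1L, right = batch$right - 1L,
      rewards = 2L * batch$sold - 1L, reset = as.integer(batch$reset),
      u = runif(n_boot * TT))
  }
  null_group <- rowSums(null_stat)
  group_stat <- sum(obs_stat)
  p_subject <- vapply(seq_len(n), function(i)
    (1 + sum(null_stat[, i] >= obs_stat[i])) / (1 + n_boot), numeric(1))
  structure(list(
    per_subject = data.frame(subject = seq_len(n), statistic = obs_stat,
                             p = p_subject),
    group_statistic = group_stat,
    group_p = (1 + sum(null_group >= group_stat)) / (1 + n_boot),
    n_boot = n_boot, null_subject = null_stat, null_group = null_group,
    fits = obs, sub_spec = sub_spec$name, full_spec = full_spec$name),
    class = "cm_glrt")
}

#' @export
print.cm_glrt <- function(x, ...) {
  cat("<cm_glrt> ", x$sub_spec, " vs ", x$full_spec,
      ": group 2*dLL = ", round(x$group_statistic, 2),
      ", p = ", signif(x$group_p, 3), " (n_boot = ", x$n_boot, ")\n", sep = "")
  invisible(x)
}

#' Random-effects Bayesian model selection
#'
#' Variational treatment of models as random effects in the population: the
#' population model frequencies get a Dirichlet posterior whose
#' concentrations are updated against the per-subject log-evidences.
#' Exceedance probabilities (probability that a model is the most frequent)
#' are estimated by Monte-Carlo sampling of the posterior Dirichlet (with an
#' exact 1/K shortcut in the fully symmetric case); the Bayes omnibus risk
#' (BOR) compares the random-effects model against the null of equal
#' frequencies, and protected exceedance probabilities are
#' `pxp = xp * (1 - bor) + bor / K`.
#'
#' @param E subjects x models matrix of log-evidences (finite).
#' @param alpha0 Dirichlet prior concentration per model.
#' @param n_samp Monte-Carlo draws for the exceedance probabilities.
#' @param tol,max_iter convergence controls for the variational iteration.
#' @param seed optional seed for the Monte-Carlo step.
#' @return a list of class `cm_bms`: `alpha`, `expected_prob`, `xp`, `bor`,
#'   `pxp`, `g` (per-subject posterior model probabilities), `F1`, `F0`.
#' @export
bms_random_effects <- function(E, alpha0 = 1, n_samp = 1e5, tol = 1e-8,
                               max_iter = 1000, seed = NULL) {
  E <- as.matrix(E)
  if (!all(is.finite(E))) stop("log-evidence matrix must be finite")
  n <- nrow(E); K <- ncol(E)
  if (K < 2) stop("need at least 2 models")
  if (!is.null(seed)) set.seed(seed)
  a0 <- rep(alpha0, K)
  alpha <- a0 + n / K
  for (it in seq_len(max_iter)) {
    w <- sweep(E, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    w <- w - apply(w, 1, max)
    g <- exp(w) / rowSums(exp(w))
    alpha_new <- a0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol) { alpha <- alpha_new; break }
    alpha <- alpha_new
  }
  expected_prob <- alpha / sum(alpha)

  ## exceedance probabilities
  if (max(alpha) - min(alpha) < 1e-10) {
    xp <- rep(1 / K, K)
  } else {
    draws <- matrix(rgamma(n_samp * K, shape = rep(alpha, each = n_samp)),
                    n_samp, K)
    xp <- tabulate(max.col(draws), nbins = K) / n_samp
  }

  ## free energies of the random-effects model and the equal-frequency null
  elog <- digamma(alpha) - digamma(sum(alpha))
  lnB <- function(a) sum(lgamma(a)) - lgamma(sum(a))
  F1 <- sum(g * sweep(E, 2, elog, `+`)) - sum(g * log(pmax(g, 1e-300))) +
    sum((a0 - alpha) * elog) + lnB(alpha) - lnB(a0)
  F0 <- sum(apply(E - log(K), 1, function(r) {
    m <- max(r); m + log(sum(exp(r - m)))
  }))
  bor <- 1 / (1 + exp(F1 - F0))
  pxp <- xp * (1 - bor) + bor / K

  structure(list(alpha = setNames(alpha, colnames(E)),
                 expected_prob = setNames(expected_prob, colnames(E)),
                 xp = setNames(xp, colnames(E)), bor = bor,
                 pxp = setNames(pxp, colnames(E)),
                 g = g, F1 = F1, F0 = F0, iterations = it),
            class = "cm_bms")
}

#' @export
print.cm_bms <- function(x, ...) {
  cat("<cm_bms> expected_prob:",
      paste(names(x$expected_prob),
            sprintf("%.3f", x$expected_prob), collapse = ", "),
      "\n  pxp:", paste(sprintf("%.3f", x$pxp), collapse = ", "),
      " bor:", sprintf("%.3f", x$bor), "\n")
  invisible(x)
}

#' Bayesian model averaging of parameters
#'
#' Averages each subject's embedded full-space parameter vector across model
#' specs, weighting by the subject's posterior model probabilities from the
#' random-effects model selection (constrained coordinates enter as their
#' constrained values, e.g. 0 for knocked-out weights).
#'
#' @param fits subjects x specs nested list of `cm_fit` (as returned in
#'   `fit_cohort()$fits`), spec order matching the BMS evidence columns.
#' @param bms a `cm_bms` from [bms_random_effects()].
#' @return list with `params` (subjects x 12 matrix of model-averaged
#'   parameters) and `model_prob` (subjects x specs).
#' @export
bayesian_average_params <- function(fits, bms) {
  n <- length(fits)
  stopifnot(nrow(bms$g) == n)
  P <- t(vapply(seq_len(n), function(i) {
    mats <- vapply(fits[[i]], function(f) as.numeric(f$params), numeric(12))
    drop(mats %*% bms$g[i, ])
  }, numeric(12)))
  colnames(P) <- PARAM_NAMES
  list(params = P, model_prob = bms$g)
}
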