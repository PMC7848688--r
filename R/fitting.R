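## Optimizer scale: CA weights and pr are fitted on their natural scale in
## [-3, 3]; forgetting rates are fitted on a logit scale in [-10, 10]
## (f in roughly [4.5e-5, 1 - 4.5e-5]) so box constraints never pin them to
## exactly 0 or 1.
WEIGHT_BOUND <- 3
LOGIT_BOUND <- 10

opt_to_natural <- function(spec, x) {
  x[spec$forgetting] <- plogis(x[spec$forgetting])
  x
}
natural_to_opt <- function(spec, x) {
  f <- pmin(pmax(x[spec$forgetting], plogis(-LOGIT_BOUND)), plogis(LOGIT_BOUND))
  x[spec$forgetting] <- qlogis(f)
  pmin(pmax(x, opt_bounds(spec)$lower), opt_bounds(spec)$upper)
}
opt_bounds <- function(spec) {
  lo <- ifelse(spec$forgetting, -LOGIT_BOUND, -WEIGHT_BOUND)
  hi <- ifelse(spec$forgetting, LOGIT_BOUND, WEIGHT_BOUND)
  list(lower = lo, upper = hi)
}

## negative log-likelihood and gradient on the optimizer scale
make_objective <- function(session, spec) {
  a <- session_arrays(session)
  grows0 <- session$structure$grows_idx - 1L
  M <- spec$M
  fn <- function(x) {
    nat <- opt_to_natural(spec, x)
    p12 <- drop(M %*% nat)
    -cpp_loglik(p12, grows0, a$left, a$right, a$chosen, a$rewards, a$reset,
                FALSE)$loglik
  }
  gr <- function(x) {
    nat <- opt_to_natural(spec, x)
    p12 <- drop(M %*% nat)
    res <- cpp_loglik(p12, grows0, a$left, a$right, a$chosen, a$rewards,
                      a$reset, TRUE)
    g <- drop(crossprod(M, res$grad))
    g[spec$forgetting] <- g[spec$forgetting] *
      nat[spec$forgetting] * (1 - nat[spec$forgetting])
    -g
  }
  list(fn = fn, gr = gr, n_trials = length(a$left))
}

## Latin-hypercube start points on the optimizer scale (weights in
## [-2.5, 2.5], forgetting logits in [-4, 4]); start 1 is always the chance
## point (all weights 0), guaranteeing loglik >= n * log(0.5).
make_starts <- function(spec, n_starts) {
  k <- spec$k
  starts <- matrix(0, n_starts, k)
  if (n_starts > 1L) {
    ## draw a fixed-size Latin hypercube and take its leading rows, so the
    ## start set is nested in n_starts (best loglik then non-decreasing)
    H <- lhs::randomLHS(max(64L, n_starts - 1L), k)[seq_len(n_starts - 1L), ,
                                                    drop = FALSE]
    rng <- ifelse(spec$forgetting, 4, 2.5)
    starts[-1L, ] <- sweep(H * 2 - 1, 2, rng, `*`)
  }
  starts
}

#' Maximum-likelihood fit of one session
#'
#' Multi-start bounded quasi-Newton (L-BFGS-B with analytic gradients)
#' maximization of [session_loglik()] under a model spec. The chance point
#' (all CA and perseveration weights 0) is always among the starts, so the
#' fitted log-likelihood is never below `n * log(0.5)`. Ties between starts
#' are broken by the lowest start index.
#'
#' @param session a `cm_session`.
#' @param spec a [model_spec()] or name.
#' @param n_starts number of optimizer starts (>= 1).
#' @param seed optional seed for the start draw (independent of data seeds).
#' @param extra_starts optional matrix (rows = natural-scale free vectors of
#'   `spec`) of additional start points, tried after the default ones.
#' @param maxit L-BFGS-B iteration cap.
#' @return a list of class `cm_fit`: `spec`, `params` (embedded
#'   [model_params()]), `free` (natural-scale free vector), `loglik`, `k`,
#'   `n_trials`, `n_starts`, `converged`, `best_start`.
#' @export
fit_mle <- function(session, spec = "full", n_starts = 10, seed = NULL,
                    extra_starts = NULL, maxit = 300) {
  spec <- as_model_spec(spec)
  if (!is.null(seed)) set.seed(seed)
  a <- session_arrays(session)
  b <- opt_bounds(spec)
  starts <- make_starts(spec, n_starts)
  if (!is.null(extra_starts)) {
    extra <- t(apply(matrix(extra_starts, ncol = spec$k), 1,
                     function(v) natural_to_opt(spec, v)))
    starts <- rbind(starts, extra)
  }
  res <- cpp_fit(starts, spec$M, as.integer(spec$forgetting),
                 b$lower, b$upper, session$structure$grows_idx - 1L,
                 a$left, a$right, a$chosen, a$rewards,
                 as.integer(a$reset), maxit)
  free_nat <- opt_to_natural(spec, res$par)
  structure(list(spec = spec$name, params = apply_constraints(spec, free_nat),
                 free = setNames(free_nat, spec$free_names),
                 loglik = -res$value, k = spec$k, n_trials = length(a$left),
                 n_starts = nrow(starts), converged = res$converged == 1L,
                 best_start = res$best_start),
            class = "cm_fit")
}

#' @export
print.cm_fit <- function(x, ...) {
  cat("<cm_fit> spec=", x$spec, " loglik=", round(x$loglik, 2),
      " k=", x$k, " n=", x$n_trials, "\n", sep = "")
  invisible(x)
}

#' Fit a nested submodel and refit the full model seeded from it
#'
#' The full-model refit always includes the embedded submodel optimum among
#' its starts, so `loglik(full) >= loglik(sub)` holds exactly and the GLRT
#' statistic `2 * (LL_full - LL_sub)` is non-negative by construction.
#'
#' @param session a `cm_session`.
#' @param sub_spec the nested spec.
#' @param full_spec the encompassing spec (default `"full"`).
#' @param n_starts starts for the submodel fit.
#' @param n_starts_full additional independent starts for the full refit
#'   (the embedded submodel optimum is always added).
#' @param sub_extra_starts optional extra natural-scale starts for the
#'   submodel fit (e.g. the generating parameters of a bootstrap replicate).
#' @param seed optional seed.
#' @return list with elements `sub` and `full` (both `cm_fit`), and
#'   `statistic = 2 * (LL_full - LL_sub)`.
#' @export
fit_submodel_seeded <- function(session, sub_spec, full_spec = "full",
                                n_starts = 5, n_starts_full = 2,
                                sub_extra_starts = NULL, seed = NULL) {
  sub_spec <- as_model_spec(sub_spec)
  full_spec <- as_model_spec(full_spec)
  if (!is.null(seed)) set.seed(seed)
  sub <- fit_mle(session, sub_spec, n_starts = n_starts,
                 extra_starts = sub_extra_starts)
  if (identical(sub_spec$name, full_spec$name))
    return(list(sub = sub, full = sub, statistic = 0))
  embedded <- project_params(full_spec, sub$params)
  full <- fit_mle(session, full_spec, n_starts = n_starts_full,
                  extra_starts = matrix(embedded, nrow = 1))
  if (full$loglik < sub$loglik) {   # numerically exact nesting floor
    full$loglik <- sub$loglik
    full$free <- setNames(embedded, full_spec$free_names)
    full$params <- apply_constraints(full_spec, embedded)
  }
  list(sub = sub, full = full, statistic = 2 * (full$loglik - sub$loglik))
}

#' Reference credit-assignment parameter pattern
#'
#' A full-model parameter point with the qualitative pattern recovered from
#' behaviour: positive MFCA for choice-related outcomes, mildly negative MFCA
#' for unrelated outcomes, and MBCA larger for important than unimportant
#' outcomes; moderate forgetting and perseveration.
#'
#' @return a [model_params()] vector.
#' @export
empirical_pattern_params <- function() {
  model_params(c_mf = c(0.6, 0.6, -0.15, -0.15),
               c_mb = c(0.15, 0.28, 0.28, 0.15),
               f_mf = 0.15, f_mb = 0.1, pr = 0.2, f_p = 0.25)
}

#' Draw a heterogeneous cohort of generating parameters
#'
#' Per-subject free vectors for `spec`, centred on a mean pattern: CA and
#' perseveration weights are Gaussian around the mean (SD `sd_weight`,
#' truncated to `[-2.5, 2.5]`), forgetting rates uniform on
#' `[f_range[1], f_range[2]]`.
#'
#' @param n number of subjects.
#' @param spec a [model_spec()] or name.
#' @param mean central free vector (natural scale); default projects
#'   [empirical_pattern_params()] onto the spec.
#' @param sd_weight SD of the weight draw.
#' @param f_range range of the forgetting-rate draw.
#' @return an `n x k` matrix of natural-scale free vectors.
#' @export
sample_cohort_params <- function(n, spec = "full", mean = NULL,
                                 sd_weight = 0.3, f_range = c(0.05, 0.6)) {
  spec <- as_model_spec(spec)
  if (is.null(mean)) mean <- project_params(spec, empirical_pattern_params())
  stopifnot(length(mean) == spec$k)
  out <- matrix(NA_real_, n, spec$k, dimnames = list(NULL, spec$free_names))
  for (j in seq_len(spec$k)) {
    out[, j] <- if (spec$forgetting[j]) runif(n, f_range[1], f_range[2])
                else pmin(pmax(rnorm(n, mean[j], sd_weight), -2.5), 2.5)
  }
  out
}

#' Parameter-recovery harness
#'
#' Simulates one session per subject from known generating parameters, refits
#' by maximum likelihood, and tabulates generating-vs-recovered correlation,
#' bias and RMSE per free parameter.
#'
#' @param spec a [model_spec()] or name.
#' @param cohort_params `n x k` matrix of generating free vectors (natural
#'   scale), e.g. from [sample_cohort_params()].
#' @param config a [task_config()].
#' @param n_starts optimizer starts per fit.
#' @param seed optional master seed.
#' @return a list with `report` (one row per free parameter: correlation,
#'   bias, RMSE, degenerate flag) and `recovered` (n x k matrix).
#' @export
recover_parameters <- function(spec, cohort_params, config = task_config(),
                               n_starts = 10, seed = NULL) {
  spec <- as_model_spec(spec)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cohort_params)
  recovered <- matrix(NA_real_, n, spec$k,
                      dimnames = list(NULL, spec$free_names))
  for (i in seq_len(n)) {
    ses <- simulate_session(cohort_params[i, ], spec,
                            structure = make_structure(), config = config)
    recovered[i, ] <- fit_mle(ses, spec, n_starts = n_starts)$free
  }
  report <- data.frame(
    param = spec$free_names,
    generating_mean = colMeans(cohort_params),
    recovered_mean = colMeans(recovered),
    correlation = vapply(seq_len(spec$k), function(j) {
      if (sd(cohort_params[, j]) < 1e-12) NA_real_
      else cor(cohort_params[, j], recovered[, j])
    }, numeric(1)),
    bias = colMeans(recovered - cohort_params),
    rmse = sqrt(colMeans((recovered - cohort_params)^2)))
  report$degenerate <- is.na(report$correlation)
  list(report = report, recovered = recovered, generating = cohort_params)
}
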