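## person expected-earnings value on a trial = sum (not mean) of its two
## vegetables' generating probabilities (a notional GBP 1 per sale)
offered_earnings <- function(structure, batch) {
  gi <- structure$grows_idx
  ev <- function(person) {
    batch$probs[cbind(seq_along(person), gi[person, 1])] +
      batch$probs[cbind(seq_along(person), gi[person, 2])]
  }
  cbind(left = ev(batch$left), right = ev(batch$right))
}

#' Standardized earnings of an agent on the task
#'
#' Simulates sessions and scores, per trial, the expected earnings of the
#' policy against a random baseline (mean of both offered persons' expected
#' values) and an omniscient oracle (their max). The per-session score is
#' `(agent - random) / (oracle - random)`; the oracle scores exactly 1 and a
#' coin-flip policy exactly 0 by construction. For hybrid-agent policies the
#' per-trial integrand is the expectation over the agent's choice
#' probability (choices are still sampled to drive learning), a pure
#' variance-reduction step with unchanged expectation.
#'
#' @param params a [model_params()] vector, a free vector of `spec`,
#'   `"oracle"` or `"random"`.
#' @param spec a [model_spec()] or name (for free vectors).
#' @param config a [task_config()].
#' @param n_sims number of simulated sessions (>= 1).
#' @param structure optional fixed `cm_structure` (default: one random draw;
#'   earnings are invariant to relabeling).
#' @param seed optional seed.
#' @return list with `value` (mean standardized earnings), `se`
#'   (Monte-Carlo SE across sessions) and `per_session`.
#' @export
standardized_earnings <- function(params, spec = "full",
                                  config = task_config(), n_sims = 2000,
                                  structure = NULL, seed = NULL) {
  if (n_sims < 1) stop("n_sims must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(structure)) structure <- make_structure()
  batch <- gen_batch(structure, config, n_sims)
  ev <- offered_earnings(structure, batch)
  oracle <- pmax(ev[, 1], ev[, 2])
  random <- (ev[, 1] + ev[, 2]) / 2
  denom <- as.numeric(rowsum(oracle - random, batch$session))
  if (all(denom == 0)) stop("degenerate task: oracle equals random on every trial")

  if (is.character(params) && length(params) == 1L) {
    agent <- switch(params,
      oracle = oracle,
      random = random,
      stop("unknown policy: ", params))
  } else {
    spec <- as_model_spec(spec)
    if (length(params) == spec$k && spec$k != 12L)
      params <- apply_constraints(spec, params)
    res <- cpp_simulate_full(as.numeric(as_model_params(params)),
                             structure$grows_idx - 1L,
                             batch$left - 1L, batch$right - 1L,
                             2L * batch$sold - 1L, batch$reset,
                             runif(length(batch$left)))
    agent <- res$p_left * ev[, 1] + (1 - res$p_left) * ev[, 2]
  }
  num <- as.numeric(rowsum(agent - random, batch$session))
  z <- num / denom
  list(value = mean(z), se = sd(z) / sqrt(n_sims), per_session = z)
}

#' Credit-assignment regime specifications for earnings sweeps
#'
#' Maps grid coordinates to full-model parameters for the five sweep
#' families: `mf_ratio` (pure-MF; abscissa = related MFCA weight R, ordinate
#' = unrelated/related ratio), `mf_split` (pure-MF; total MFCA vs proportion
#' unrelated, unrelated weights negative), `mb_split` (pure-MB; total MBCA vs
#' proportion unimportant), `mb_split_autocorr` (as `mb_split` on the
#' importance-autocorrelated task) and `hybrid_split` (total CA vs proportion
#' MF; the MF arm uses the map-guided pattern related = +, unrelated = -,
#' equal magnitude; the MB arm is egalitarian). Nuisance parameters are fixed
#' at moderate defaults: forgetting 0.2 for active systems, no
#' perseveration.
#'
#' @param family regime family name.
#' @param x,y grid coordinate values.
#' @param forgetting forgetting rate applied to the active system(s).
#' @return a [model_params()] vector for the cell.
#' @export
regime_params <- function(family = c("mf_ratio", "mf_split", "mb_split",
                                     "mb_split_autocorr", "hybrid_split"),
                          x, y, forgetting = 0.2) {
  family <- match.arg(family)
  f <- forgetting
  switch(family,
    mf_ratio = model_params(c_mf = c(x, x, y * x, y * x), f_mf = f),
    mf_split = model_params(c_mf = c((1 - y) * x, (1 - y) * x,
                                     -y * x, -y * x), f_mf = f),
    mb_split = ,
    mb_split_autocorr = model_params(
      c_mb = c(y * x, (1 - y) * x, (1 - y) * x, y * x), f_mb = f),
    hybrid_split = model_params(
      c_mf = c(y * x, y * x, -y * x, -y * x),
      c_mb = rep((1 - y) * x, 4),
      f_mf = f, f_mb = f))
}

default_grid <- function(family) {
  switch(family,
    mf_ratio = list(x = seq(0.4, 2.8, length.out = 7),
                    y = seq(1, -1, length.out = 7)),
    mf_split = list(x = seq(0.5, 3.5, length.out = 7),
                    y = seq(0, 1, length.out = 7)),
    mb_split = ,
    mb_split_autocorr = list(x = seq(0.5, 3.5, length.out = 7),
                             y = seq(0, 1, length.out = 7)),
    hybrid_split = list(x = seq(0.5, 3.5, length.out = 7),
                        y = seq(0, 1, length.out = 7)))
}

#' Sweep standardized earnings over a credit-assignment regime grid
#'
#' Evaluates [standardized_earnings()] on every grid cell of a
#' [regime_params()] family and marks, per column (abscissa value), the
#' maximizing ordinate cell, flagging columns whose maximum is not
#' significantly above the central-row cell (two-SE criterion), in which
#' case the central row is co-optimal.
#'
#' @param family regime family (see [regime_params()]).
#' @param config a [task_config()]; for `mb_split_autocorr` its
#'   `pair_persistence` is set to `pair_persistence` if still 0.
#' @param n_sims simulated sessions per cell.
#' @param grid optional list with `x`, `y` vectors overriding the default
#'   7 x 7 grid.
#' @param pair_persistence stay probability for the autocorrelated family.
#' @param forgetting nuisance forgetting rate.
#' @param seed optional seed.
#' @return a list of class `cm_earnings_grid`: `cells` (data.frame with x,
#'   y, earnings, se), `argmax` (per-column data.frame), `family`.
#' @export
sweep_regime <- function(family, config = task_config(), n_sims = 2000,
                         grid = NULL, pair_persistence = 0.9,
                         forgetting = 0.2, seed = NULL) {
  family <- match.arg(family, c("mf_ratio", "mf_split", "mb_split",
                                "mb_split_autocorr", "hybrid_split"))
  if (!is.null(seed)) set.seed(seed)
  if (family == "mb_split_autocorr" && config$pair_persistence == 0) {
    if (pair_persistence <= 0.5)
      stop("autocorrelated regime needs pair_persistence > 0.5")
    config <- task_config(config$n_blocks, config$trials_per_block,
                          config$walk_sd, config$walk_lo, config$walk_hi,
                          config$init_values, pair_persistence)
  }
  grid <- grid %||% default_grid(family)
  structure <- make_structure()
  cells <- expand.grid(y = grid$y, x = grid$x)[, c("x", "y")]
  res <- lapply(seq_len(nrow(cells)), function(i) {
    p <- regime_params(family, cells$x[i], cells$y[i], forgetting)
    standardized_earnings(p, config = config, n_sims = n_sims,
                          structure = structure)
  })
  cells$earnings <- vapply(res, `[[`, numeric(1), "value")
  cells$se <- vapply(res, `[[`, numeric(1), "se")

  central <- grid$y[ceiling(length(grid$y) / 2)]
  argmax <- do.call(rbind, lapply(grid$x, function(xv) {
    cc <- cells[cells$x == xv, ]
    best <- which.max(cc$earnings)
    ce <- cc[cc$y == central, ]
    sig <- (cc$earnings[best] - ce$earnings) >
      2 * sqrt(cc$se[best]^2 + ce$se^2)
    data.frame(x = xv, y_max = cc$y[best], earnings_max = cc$earnings[best],
               central_co_optimal = !sig)
  }))
  structure(list(cells = cells, argmax = argmax, family = family,
                 n_sims = n_sims, central_row = central),
            class = "cm_earnings_grid")
}

#' @rdname sweep_regime
#' @param ... passed on to [sweep_regime()].
#' @export
sweep_autocorrelated <- function(pair_persistence = 0.9, ...) {
  sweep_regime("mb_split_autocorr", pair_persistence = pair_persistence, ...)
}

#' @export
print.cm_earnings_grid <- function(x, ...) {
  cat("<cm_earnings_grid> family=", x$family, ", ", nrow(x$cells),
      " cells x ", x$n_sims, " sims\n", sep = "")
  print(x$argmax)
  invisible(x)
}
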