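## Canonical parameter layout shared with the C++ core.
PARAM_NAMES <- c("cmf_common", "cmf_exclusive", "cmf_counter", "cmf_absent",
                 "cmb_common", "cmb_exclusive", "cmb_counter", "cmb_absent",
                 "f_mf", "f_mb", "pr", "f_p")

#' Hybrid-agent parameter vector
#'
#' The agent has 12 free parameters: four model-free credit-assignment (MFCA)
#' weights and four model-based (MBCA) weights, one per outcome role (Common,
#' Exclusive, Counterfactual, Absent); forgetting rates for the MF and MB
#' value stores; and a progressive-perseveration weight with its own
#' forgetting rate. Rewards enter updates coded +1 (sold) / -1 (unsold). There
#' is no separate softmax inverse temperature: the CA weights carry the choice
#' scale, so fitted weights are effective (learning rate x temperature)
#' quantities.
#'
#' @param c_mf,c_mb numeric(4) CA weights in role order Common, Exclusive,
#'   Counterfactual, Absent.
#' @param f_mf,f_mb,f_p forgetting rates in `[0, 1]`.
#' @param pr perseveration weight.
#' @return a named numeric vector of class `cm_params`.
#' @export
model_params <- function(c_mf = c(0, 0, 0, 0), c_mb = c(0, 0, 0, 0),
                         f_mf = 0, f_mb = 0, pr = 0, f_p = 0) {
  stopifnot(length(c_mf) == 4, length(c_mb) == 4,
            f_mf >= 0, f_mf <= 1, f_mb >= 0, f_mb <= 1, f_p >= 0, f_p <= 1,
            all(is.finite(c(c_mf, c_mb, pr))))
  structure(setNames(c(c_mf, c_mb, f_mf, f_mb, pr, f_p), PARAM_NAMES),
            class = "cm_params")
}

#' @rdname model_params
#' @param x a numeric vector of length 12 in canonical order.
#' @export
as_model_params <- function(x) {
  if (inherits(x, "cm_params")) return(x)
  stopifnot(is.numeric(x), length(x) == 12L)
  model_params(x[1:4], x[5:8], x[9], x[10], x[11], x[12])
}

#' @rdname model_params
#' @export
zero_params <- function() model_params()

MODEL_NAMES <- c("full", "pure_mb", "pure_mf", "no_cm_mf",
                 "no_unrelated_mfca", "egalitarian_mb")

#' Model specifications (full model and its five nested submodels)
#'
#' Each spec constrains the 12-parameter space linearly: `pure_mb` sets all
#' four MFCA weights to 0 (and drops the then non-identifiable `f_mf`);
#' `pure_mf` sets all MBCA weights to 0 (drops `f_mb`); `no_cm_mf` forces the
#' four MFCA weights to share one value; `no_unrelated_mfca` zeroes the MFCA
#' weights of the choice-unrelated (Counterfactual and Absent) outcomes;
#' `egalitarian_mb` forces the four MBCA weights to share one value. Free
#' parameter counts `k` cover only parameters that move the likelihood.
#'
#' @param name one of `"full"`, `"pure_mb"`, `"pure_mf"`, `"no_cm_mf"`,
#'   `"no_unrelated_mfca"`, `"egalitarian_mb"`.
#' @return a list of class `cm_spec` with the embedding matrix `M` (12 x k)
#'   such that `params12 = M %*% free`, free-parameter names, `k`, and which
#'   free coordinates are forgetting rates.
#' @export
model_spec <- function(name = MODEL_NAMES) {
  name <- match.arg(name)
  free <- switch(name,
    full = PARAM_NAMES,
    pure_mb = c("cmb_common", "cmb_exclusive", "cmb_counter", "cmb_absent",
                "f_mb", "pr", "f_p"),
    pure_mf = c("cmf_common", "cmf_exclusive", "cmf_counter", "cmf_absent",
                "f_mf", "pr", "f_p"),
    no_cm_mf = c("cmf_shared", "f_mf",
                 "cmb_common", "cmb_exclusive", "cmb_counter", "cmb_absent",
                 "f_mb", "pr", "f_p"),
    no_unrelated_mfca = c("cmf_common", "cmf_exclusive", "f_mf",
                          "cmb_common", "cmb_exclusive", "cmb_counter",
                          "cmb_absent", "f_mb", "pr", "f_p"),
    egalitarian_mb = c("cmf_common", "cmf_exclusive", "cmf_counter",
                       "cmf_absent", "f_mf", "cmb_shared", "f_mb", "pr", "f_p"))
  k <- length(free)
  M <- matrix(0, 12L, k, dimnames = list(PARAM_NAMES, free))
  for (j in seq_len(k)) {
    targets <- switch(free[j],
      cmf_shared = paste0("cmf_", c("common", "exclusive", "counter", "absent")),
      cmb_shared = paste0("cmb_", c("common", "exclusive", "counter", "absent")),
      free[j])
    M[targets, j] <- 1
  }
  structure(list(name = name, free_names = free, k = k, M = M,
                 forgetting = grepl("^f_", free)),
            class = "cm_spec")
}

as_model_spec <- function(spec) {
  if (inherits(spec, "cm_spec")) spec else model_spec(spec)
}

#' Embed a submodel's free parameters into the full 12-parameter space
#'
#' @param spec a [model_spec()] or its name.
#' @param free numeric vector of length `spec$k` (natural scale; forgetting
#'   rates in `[0, 1]`).
#' @return a [model_params()] vector.
#' @export
apply_constraints <- function(spec, free) {
  spec <- as_model_spec(spec)
  if (length(free) != spec$k)
    stop("expected ", spec$k, " free values for spec '", spec$name, "'")
  as_model_params(drop(spec$M %*% as.numeric(free)))
}

## project full-model params onto a spec's free coordinates (left inverse of
## the embedding; shared coordinates take the mean of their group)
project_params <- function(spec, params) {
  spec <- as_model_spec(spec)
  M <- spec$M
  drop(solve(crossprod(M), crossprod(M, as.numeric(params))))
}

#' Fresh agent state (all values zero, as at a block start)
#' @param structure a `cm_structure`.
#' @export
agent_state_init <- function(structure) {
  list(q_mf = setNames(numeric(4), structure$persons),
       q_mb = setNames(numeric(4), structure$vegetables),
       pers = setNames(numeric(4), structure$persons))
}

#' Model-based value of a person
#'
#' The on-demand MB value is the sum of the MB values of the person's two
#' vegetables.
#'
#' @param state an agent state from [agent_state_init()].
#' @param structure a `cm_structure`.
#' @param person person label.
#' @export
mb_person_value <- function(state, structure, person) {
  i <- person_index(structure, person)
  sum(state$q_mb[structure$grows_idx[i, ]])
}

#' Choice probabilities for an offered pair
#'
#' Net values are `Q_MB + Q_MF + PERS` per offered person; the probability of
#' choosing a person is the softmax (logistic in the net-value difference).
#' There is no inverse-temperature parameter.
#'
#' @inheritParams mb_person_value
#' @param params a [model_params()] vector (unused here beyond validation;
#'   values live in `state`).
#' @param offered character(2) offered person labels.
#' @return a list with named `q_net` and `prob` over the offered pair.
#' @export
choice_probability <- function(state, structure, params, offered) {
  stopifnot(length(offered) == 2L)
  q_net <- vapply(offered, function(p)
    state$q_mf[[p]] + mb_person_value(state, structure, p) + state$pers[[p]],
    numeric(1))
  pr1 <- plogis(q_net[1] - q_net[2])
  list(q_net = q_net, prob = setNames(c(pr1, 1 - pr1), offered))
}

#' Update agent values after reward feedback
#'
#' Applies the MFCA update to the chosen person (forgetting plus the sum of
#' role-weighted coded rewards), forgetting to the other persons' MF values,
#' the MBCA update to every vegetable under its role weight, and the
#' perseveration update (decay everywhere, bonus to the chosen person).
#' Rewards are coded +1 for sold, -1 for unsold.
#'
#' @inheritParams choice_probability
#' @param chosen chosen person label.
#' @param sold named (by vegetable) 0/1 or logical vector of sale outcomes.
#' @return the updated state.
#' @export
update_after_feedback <- function(state, structure, params, offered, chosen, sold) {
  params <- as_model_params(params)
  cls <- classify_outcomes(structure, offered, chosen)
  r <- 2 * as.numeric(sold[structure$vegetables]) - 1
  names(r) <- structure$vegetables
  role <- cls$role
  f_mf <- params[["f_mf"]]; f_mb <- params[["f_mb"]]; f_p <- params[["f_p"]]

  gain <- sum(vapply(structure$vegetables, function(v) {
    w <- switch(role[[v]], Common = params[["cmf_common"]],
                Exclusive = params[["cmf_exclusive"]],
                Counterfactual = params[["cmf_counter"]],
                Absent = params[["cmf_absent"]])
    w * r[[v]]
  }, numeric(1)))
  state$q_mf <- (1 - f_mf) * state$q_mf
  state$q_mf[[chosen]] <- state$q_mf[[chosen]] + gain

  for (v in structure$vegetables) {
    w <- switch(role[[v]], Common = params[["cmb_common"]],
                Exclusive = params[["cmb_exclusive"]],
                Counterfactual = params[["cmb_counter"]],
                Absent = params[["cmb_absent"]])
    state$q_mb[[v]] <- (1 - f_mb) * state$q_mb[[v]] + w * r[[v]]
  }

  state$pers <- (1 - f_p) * state$pers
  state$pers[[chosen]] <- state$pers[[chosen]] + params[["pr"]]
  state
}

#' Session log-likelihood of the hybrid agent
#'
#' Sums the log choice probabilities over all trials, resetting all value
#' stores at every block boundary. Evaluated by the compiled core; see
#' [session_loglik_replay()] for the independent trial-by-trial replay used in
#' verification.
#'
#' @param params a [model_params()] vector, or a free vector of `spec`.
#' @param session a `cm_session`.
#' @param spec a model spec or name (used to embed free vectors).
#' @param gradient if `TRUE`, attach the 12-parameter gradient as an
#'   attribute `"gradient"`.
#' @return the log-likelihood (numeric scalar, always finite and <= 0).
#' @export
session_loglik <- function(params, session, spec = "full", gradient = FALSE) {
  spec <- as_model_spec(spec)
  if (!inherits(params, "cm_params")) {
    if (length(params) == spec$k && spec$k != 12L)
      params <- apply_constraints(spec, params)
    else params <- as_model_params(params)
  }
  if (!all(is.finite(params))) stop("non-finite parameter")
  a <- session_arrays(session)
  res <- cpp_loglik(as.numeric(params), session$structure$grows_idx - 1L,
                    a$left, a$right, a$chosen, a$rewards, a$reset, gradient)
  ll <- res$loglik
  if (gradient) attr(ll, "gradient") <- setNames(res$grad, PARAM_NAMES)
  ll
}

#' Replay-oracle session log-likelihood
#'
#' A deliberately naive trial-by-trial replay of the update and choice
#' equations built on [choice_probability()] and [update_after_feedback()],
#' kept independent of the compiled path so the two can be cross-checked.
#'
#' @inheritParams session_loglik
#' @export
session_loglik_replay <- function(params, session) {
  params <- as_model_params(params)
  st <- session$structure
  tr <- session$trials
  state <- agent_state_init(st)
  ll <- 0
  for (i in seq_len(nrow(tr))) {
    if (i == 1L || tr$block[i] != tr$block[i - 1L]) state <- agent_state_init(st)
    offered <- c(tr$left[i], tr$right[i])
    cp <- choice_probability(state, st, params, offered)
    ll <- ll + log(cp$prob[[tr$chosen[i]]])
    sold <- setNames(as.numeric(tr[i, paste0("s", 1:4)]), st$vegetables)
    state <- update_after_feedback(state, st, params, offered, tr$chosen[i], sold)
  }
  ll
}
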