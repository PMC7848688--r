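## Internal batch generator: draws walks, offer schedules and reward outcomes
## for `n_sessions` sessions at once (vectorized across blocks), before any
## agent is involved. Choices are filled in by the caller.
gen_batch <- function(structure, config, n_sessions) {
  nb <- config$n_blocks; nt <- config$trials_per_block
  B <- n_sessions * nb                  # total blocks
  N <- B * nt                           # total trials

  ## block-initial values: a random permutation of init_values per block
  ord <- apply(matrix(runif(4L * B), 4L, B), 2, order)
  p0 <- matrix(config$init_values[ord], 4L, B)
  walks <- walk_chain(p0, nt, config$walk_sd, config$walk_lo, config$walk_hi)
  probs <- matrix(aperm(walks, c(1, 3, 2)), nrow = N, ncol = 4L)

  ## offer schedule per block
  if (config$pair_persistence == 0) {
    base <- rep(seq_len(4L), each = nt %/% 4L)
    pair_idx <- as.vector(vapply(seq_len(B), function(b) sample(base), integer(nt)))
  } else {
    pt_cls <- pair_table(structure)$class
    pair_idx <- as.vector(vapply(seq_len(B), function(b) {
      stay <- runif(nt) < config$pair_persistence
      cls <- cumsum(c(sample(0:1, 1), !stay[-1])) %% 2L + 1L
      idx <- integer(nt)
      for (k in 1:2) {
        members <- which(pt_cls == k)
        idx[cls == k] <- sample(members, sum(cls == k), replace = TRUE)
      }
      idx
    }, integer(nt)))
  }
  vp_idx <- cbind(person_index(structure, structure$valid_pairs[, 1]),
                  person_index(structure, structure$valid_pairs[, 2]))
  flip <- runif(N) < 0.5
  left <- ifelse(flip, vp_idx[pair_idx, 2], vp_idx[pair_idx, 1])
  right <- ifelse(flip, vp_idx[pair_idx, 1], vp_idx[pair_idx, 2])

  sold <- matrix(as.integer(runif(N * 4L) < probs), N, 4L)

  list(n_sessions = n_sessions,
       session = rep(seq_len(n_sessions), each = nb * nt),
       block = rep(rep(seq_len(nb), each = nt), times = n_sessions),
       trial = rep(seq_len(nb * nt), times = n_sessions),
       reset = rep(rep(c(TRUE, rep(FALSE, nt - 1L)), nb), n_sessions),
       left = left, right = right, pair = pair_idx,
       probs = probs, sold = sold)
}

## person expected values (mean of the two grown vegetables' probabilities)
## for a batch; returns an N x 2 matrix for the left/right offered persons
offered_values <- function(structure, batch) {
  gi <- structure$grows_idx
  pv <- function(person) {
    (batch$probs[cbind(seq_along(person), gi[person, 1])] +
     batch$probs[cbind(seq_along(person), gi[person, 2])]) / 2
  }
  cbind(left = pv(batch$left), right = pv(batch$right))
}

## choices for a batch under a policy: a cm_params vector (hybrid agent, fast
## C++ path), "random", or "oracle" (argmax of true expected values, random
## tie-break). Returns 1-based chosen person indices.
batch_choices <- function(structure, batch, policy) {
  N <- length(batch$left)
  if (inherits(policy, "cm_params") || (is.numeric(policy) && length(policy) == 12L)) {
    res <- cpp_simulate_full(as.numeric(policy), structure$grows_idx - 1L,
                             batch$left - 1L, batch$right - 1L,
                             2L * batch$sold - 1L, batch$reset, runif(N))
    return(res$chosen + 1L)
  }
  if (identical(policy, "random"))
    return(ifelse(runif(N) < 0.5, batch$left, batch$right))
  if (identical(policy, "oracle")) {
    v <- offered_values(structure, batch)
    pick_left <- v[, 1] > v[, 2] | (v[, 1] == v[, 2] & runif(N) < 0.5)
    return(ifelse(pick_left, batch$left, batch$right))
  }
  if (is.function(policy)) {
    ch <- integer(N)
    for (i in seq_len(N)) {
      pl <- policy(structure$persons[batch$left[i]],
                   structure$persons[batch$right[i]], batch$probs[i, ])
      ch[i] <- if (runif(1) < pl) batch$left[i] else batch$right[i]
    }
    return(ch)
  }
  stop("unknown policy")
}

batch_to_session <- function(structure, config, batch, chosen, seed = NULL, id = 1L) {
  keep <- batch$session == id
  gi <- structure$grows_idx
  ch <- chosen[keep]
  sold <- batch$sold[keep, , drop = FALSE]
  earned <- sold[cbind(seq_along(ch), gi[ch, 1])] +
            sold[cbind(seq_along(ch), gi[ch, 2])]
  trials <- data.frame(
    block = batch$block[keep], trial = batch$trial[keep],
    left = structure$persons[batch$left[keep]],
    right = structure$persons[batch$right[keep]],
    chosen = structure$persons[ch],
    stringsAsFactors = FALSE)
  probs <- batch$probs[keep, , drop = FALSE]
  colnames(probs) <- paste0("p", 1:4)
  colnames(sold) <- paste0("s", 1:4)
  trials <- cbind(trials, probs, sold, earned = earned)
  structure(list(structure = structure, config = config, trials = trials,
                 seed = seed), class = "cm_session")
}

#' Simulate one full task session
#'
#' Draws fresh random walks and a fresh offer schedule per block, samples all
#' four reward outcomes each trial (full feedback), and samples choices from
#' the given policy.
#'
#' @param structure a `cm_structure` (default: a fresh random one).
#' @param config a [task_config()].
#' @param policy a [model_params()] vector (hybrid agent), `"random"`,
#'   `"oracle"` (picks the person with the higher true expected value), or a
#'   function `(left, right, probs) -> P(choose left)`.
#' @param seed optional integer seed; a fixed seed makes the session
#'   byte-identical on regeneration.
#' @return an object of class `cm_session` with elements `structure`,
#'   `config`, `trials` (one row per trial) and `seed`.
#' @export
generate_session <- function(structure = make_structure(),
                             config = task_config(),
                             policy = "random", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  batch <- gen_batch(structure, config, 1L)
  chosen <- batch_choices(structure, batch, policy)
  batch_to_session(structure, config, batch, chosen, seed = seed)
}

#' Simulate a session from the hybrid agent
#'
#' Convenience wrapper around [generate_session()] with an agent policy given
#' by model parameters (optionally as a submodel's free-parameter vector).
#'
#' @param params a [model_params()] vector, or a free-parameter vector of
#'   `spec`.
#' @param spec a model spec name or [model_spec()] (used to embed `params`
#'   when it is a free vector).
#' @inheritParams generate_session
#' @export
simulate_session <- function(params, spec = "full",
                             structure = make_structure(),
                             config = task_config(), seed = NULL) {
  spec <- as_model_spec(spec)
  if (length(params) == 12L) params <- as_model_params(params)
  else if (length(params) == spec$k) params <- apply_constraints(spec, params)
  else stop("params must have length 12 or spec$k = ", spec$k)
  generate_session(structure, config, policy = params, seed = seed)
}

#' Write / read a session as tidy CSV plus a JSON sidecar
#'
#' The CSV holds one row per trial; the sidecar (same path with extension
#' `.json`) records the structure map, configuration and seed so that the
#' round trip is lossless.
#'
#' @param session a `cm_session`.
#' @param path CSV file path.
#' @return `write_session` returns `path` invisibly; `read_session` returns
#'   the restored `cm_session`.
#' @export
write_session <- function(session, path) {
  write.csv(session$trials, path, row.names = FALSE)
  side <- list(
    persons = session$structure$persons,
    vegetables = session$structure$vegetables,
    grows = session$structure$grows,
    config = unclass(session$config),
    seed = session$seed)
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' @rdname write_session
#' @export
read_session <- function(path) {
  trials <- read.csv(path, stringsAsFactors = FALSE)
  side <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  persons <- side$persons
  grows_idx <- t(vapply(persons,
                        function(p) match(unlist(side$grows[[p]]), side$vegetables),
                        integer(2)))
  rownames(grows_idx) <- persons
  st <- structure(list(persons = persons, vegetables = side$vegetables,
                       grows = lapply(side$grows, unlist),
                       grows_idx = grows_idx, valid_pairs = NULL),
                  class = "cm_structure")
  cmb <- utils::combn(4, 2)
  shared <- apply(cmb, 2, function(ij)
    length(intersect(grows_idx[ij[1], ], grows_idx[ij[2], ])))
  valid <- cmb[, shared == 1, drop = FALSE]
  st$valid_pairs <- cbind(persons[valid[1, ]], persons[valid[2, ]])
  cfg <- side$config
  config <- task_config(cfg$n_blocks, cfg$trials_per_block, cfg$walk_sd,
                        cfg$walk_lo, cfg$walk_hi, unlist(cfg$init_values),
                        cfg$pair_persistence)
  structure(list(structure = st, config = config, trials = trials,
                 seed = side$seed), class = "cm_session")
}

## convert a cm_session's trials into the 0-based arrays the C++ core expects
session_arrays <- function(session) {
  tr <- session$trials
  st <- session$structure
  list(left = person_index(st, tr$left) - 1L,
       right = person_index(st, tr$right) - 1L,
       chosen = person_index(st, tr$chosen) - 1L,
       rewards = 2L * as.matrix(tr[, paste0("s", 1:4)]) - 1L,
       reset = c(TRUE, diff(tr$block) != 0))
}

#' @export
print.cm_session <- function(x, ...) {
  cat("<cm_session> ", nrow(x$trials), " trials, ",
      x$config$n_blocks, " blocks\n", sep = "")
  invisible(x)
}
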