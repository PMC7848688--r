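#' Task configuration
#'
#' Defaults reproduce the study conditions: 7 blocks of 56 trials, sale
#' probabilities following independent Gaussian-increment random walks with
#' per-trial SD 0.03 and reflecting boundaries 0.2/0.8, block-initial values a
#' random permutation of (0.2, 0.4, 0.6, 0.8), and a balanced offer schedule
#' (each of the 4 valid pairs on 14 trials per block, shuffled).
#' `pair_persistence > 0` switches to the importance-autocorrelated variant, a
#' symmetric two-state Markov chain over the two importance classes of offer
#' pairs with the given stay probability.
#'
#' @param n_blocks,trials_per_block session layout.
#' @param walk_sd per-trial SD of the Gaussian increments.
#' @param walk_lo,walk_hi reflecting boundaries.
#' @param init_values block-initial probabilities (permuted at random).
#' @param pair_persistence 0 for the balanced design, else the stay
#'   probability of the importance class in (0, 1].
#' @return a list of class `cm_config`.
#' @export
task_config <- function(n_blocks = 7L, trials_per_block = 56L, walk_sd = 0.03,
                        walk_lo = 0.2, walk_hi = 0.8,
                        init_values = c(0.2, 0.4, 0.6, 0.8),
                        pair_persistence = 0) {
  stopifnot(walk_lo >= 0, walk_lo < walk_hi, walk_hi <= 1, walk_sd > 0,
            n_blocks >= 1, trials_per_block >= 1,
            length(init_values) == 4, all(init_values >= walk_lo),
            all(init_values <= walk_hi),
            pair_persistence >= 0, pair_persistence <= 1)
  if (pair_persistence == 0 && trials_per_block %% 4L != 0L)
    stop("trials_per_block must be divisible by 4 for the balanced design")
  structure(list(n_blocks = as.integer(n_blocks),
                 trials_per_block = as.integer(trials_per_block),
                 walk_sd = walk_sd, walk_lo = walk_lo, walk_hi = walk_hi,
                 init_values = init_values,
                 pair_persistence = pair_persistence),
            class = "cm_config")
}

## fold x back into [lo, hi] by mirror reflection, repeated until inside
reflect_into <- function(x, lo, hi) {
  while (any(bad <- x < lo | x > hi)) {
    x[bad & x > hi] <- 2 * hi - x[bad & x > hi]
    x[bad & x < lo] <- 2 * lo - x[bad & x < lo]
  }
  x
}

#' One reflected random-walk step
#'
#' Adds a Gaussian(0, sd) increment and folds the result back into
#' `[lo, hi]` by mirror reflection (repeated until inside; a single
#' reflection suffices for small sd). Vectorized over `p`.
#'
#' @param p current probability value(s), inside `[lo, hi]`.
#' @param sd increment SD (> 0).
#' @param lo,hi reflecting bounds.
#' @param increment optional fixed increment(s) instead of a random draw.
#' @export
step_walk <- function(p, sd = 0.03, lo = 0.2, hi = 0.8, increment = NULL) {
  if (sd <= 0) stop("sd must be > 0")
  stopifnot(all(p >= lo & p <= hi))
  eps <- increment %||% rnorm(length(p), 0, sd)
  reflect_into(p + eps, lo, hi)
}

## Iterate the reflected walk for many chains at once.
## p0: 4 x B matrix of initial values; returns (n_trials x 4 x B) array.
walk_chain <- function(p0, n_trials, sd, lo, hi) {
  B <- ncol(p0)
  out <- array(NA_real_, dim = c(n_trials, 4L, B))
  p <- p0
  out[1L, , ] <- p
  if (n_trials > 1L) for (t in 2:n_trials) {
    p <- reflect_into(p + rnorm(4L * B, 0, sd), lo, hi)
    out[t, , ] <- p
  }
  out
}

#' Generate one block of market random walks
#'
#' The first trial's probabilities are a uniformly random permutation of
#' `config$init_values`; each later trial applies [step_walk()] independently
#' per vegetable. A fresh walk is drawn for every block.
#'
#' @param config a [task_config()].
#' @return a `trials_per_block x 4` matrix of sale probabilities.
#' @export
generate_walks <- function(config = task_config()) {
  p0 <- matrix(sample(config$init_values), ncol = 1)
  walk_chain(p0, config$trials_per_block, config$walk_sd,
             config$walk_lo, config$walk_hi)[, , 1]
}

## The 4 valid pairs of a structure, with their distinctive-vegetable
## ("importance") class: pairs fall into two classes of two pairs each.
pair_table <- function(structure) {
  vp <- structure$valid_pairs
  dist <- t(apply(vp, 1, function(pr) sort(distinctive_vegs(structure, pr))))
  cls <- match(paste(dist[, 1], dist[, 2]), unique(paste(dist[, 1], dist[, 2])))
  list(pairs = vp, class = cls)
}

#' Generate one block's balanced offer sequence
#'
#' Each valid pair appears `trials_per_block / 4` times in uniformly shuffled
#' order; display sides are assigned at random per trial.
#'
#' @param structure a `cm_structure`.
#' @param config a [task_config()] with `pair_persistence = 0`.
#' @return a data.frame with columns `left`, `right` (person labels) and
#'   `pair` (index into the structure's valid pairs).
#' @export
make_trial_sequence <- function(structure, config = task_config()) {
  if (config$pair_persistence != 0)
    stop("balanced sequence requires pair_persistence = 0; see make_autocorrelated_sequence")
  n <- config$trials_per_block
  if (n %% 4L != 0L) stop("trials_per_block must be divisible by 4")
  idx <- sample(rep(seq_len(4L), each = n %/% 4L))
  assemble_sequence(structure, idx)
}

#' Generate one block's importance-autocorrelated offer sequence
#'
#' The importance class of the offered pair follows a symmetric two-state
#' Markov chain with stay probability `config$pair_persistence`; the pair
#' within the class is drawn uniformly, as is the display side.
#'
#' @inheritParams make_trial_sequence
#' @export
make_autocorrelated_sequence <- function(structure, config) {
  q <- config$pair_persistence
  if (q <= 0 || q > 1) stop("pair_persistence must be in (0, 1]")
  n <- config$trials_per_block
  stay <- runif(n) < q
  cls <- cumsum(c(sample(0:1, 1), !stay[-1])) %% 2L + 1L
  pt <- pair_table(structure)
  idx <- integer(n)
  for (k in 1:2) {
    members <- which(pt$class == k)
    idx[cls == k] <- sample(members, sum(cls == k), replace = TRUE)
  }
  assemble_sequence(structure, idx)
}

assemble_sequence <- function(structure, pair_idx) {
  vp <- structure$valid_pairs
  flip <- runif(length(pair_idx)) < 0.5
  left <- ifelse(flip, vp[pair_idx, 2], vp[pair_idx, 1])
  right <- ifelse(flip, vp[pair_idx, 1], vp[pair_idx, 2])
  data.frame(left = left, right = right, pair = pair_idx,
             stringsAsFactors = FALSE)
}

#' Sample reward (sale) outcomes for one trial
#'
#' Independent Bernoulli draws, one per vegetable; all four outcomes are
#' revealed every trial (full feedback).
#'
#' @param probs numeric(4) sale probabilities in `[0, 1]`.
#' @return integer(4) of 0/1 sold flags.
#' @export
sample_rewards <- function(probs) {
  stopifnot(length(probs) == 4, all(probs >= 0 & probs <= 1))
  as.integer(runif(4) < probs)
}
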