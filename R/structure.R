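#' Build a random person-vegetable transition structure
#'
#' Four persons each grow a unique unordered pair out of four vegetables, with
#' every vegetable grown by exactly two persons. Up to relabeling this forces a
#' 4-cycle topology on the person-vegetable bipartite graph, so exactly 4 of
#' the 6 unordered person pairs share exactly one vegetable; these are the
#' valid offer pairs. The assignment of vegetables to persons is randomized.
#'
#' @param seed optional integer seed for the assignment.
#' @return an object of class `cm_structure`: a list with `persons`,
#'   `vegetables`, `grows` (named list person -> character(2)), `grows_idx`
#'   (4 x 2 integer matrix of vegetable indices), and `valid_pairs`
#'   (4 x 2 character matrix of person labels).
#' @export
#' @examples
#' s <- make_structure(seed = 1)
#' s$grows
make_structure <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  persons <- paste0("P", 1:4)
  vegetables <- paste0("V", 1:4)
  ## canonical 4-cycle on vegetable slots (1,2),(1,3),(2,4),(3,4), with the
  ## slots filled by a random permutation and the rows dealt to persons in
  ## random order
  perm <- sample.int(4)
  rows <- matrix(c(1, 2, 1, 3, 2, 4, 3, 4), ncol = 2, byrow = TRUE)
  rows[] <- perm[rows]
  rows <- rows[sample.int(4), , drop = FALSE]
  grows_idx <- rows
  rownames(grows_idx) <- persons
  grows <- lapply(seq_len(4), function(i) vegetables[grows_idx[i, ]])
  names(grows) <- persons

  cmb <- utils::combn(4, 2)
  shared <- apply(cmb, 2, function(ij) {
    length(intersect(grows_idx[ij[1], ], grows_idx[ij[2], ]))
  })
  valid <- cmb[, shared == 1, drop = FALSE]
  valid_pairs <- cbind(persons[valid[1, ]], persons[valid[2, ]])

  structure(
    list(persons = persons, vegetables = vegetables, grows = grows,
         grows_idx = grows_idx, valid_pairs = valid_pairs),
    class = "cm_structure")
}

person_index <- function(structure, person) {
  i <- match(person, structure$persons)
  if (anyNA(i)) stop("unknown person: ", paste(person[is.na(i)], collapse = ", "))
  i
}

#' Test whether two persons form a valid offer pair
#' @param structure a `cm_structure`.
#' @param a,b person labels.
#' @return logical.
#' @export
is_valid_pair <- function(structure, a, b) {
  i <- person_index(structure, a); j <- person_index(structure, b)
  length(intersect(structure$grows_idx[i, ], structure$grows_idx[j, ])) == 1L
}

#' Classify the four outcomes of a choice trial
#'
#' Given a valid offered pair and the chosen person, each vegetable takes
#' exactly one role: Common (grown by both offered persons), Exclusive (chosen
#' person only), Counterfactual (unchosen person only) or Absent (neither).
#' Choice-related outcomes are Common and Exclusive; important outcomes (those
#' entering the model-based value contrast between the offered persons) are
#' Exclusive and Counterfactual.
#'
#' @param structure a `cm_structure`.
#' @param offered character(2) of offered person labels.
#' @param chosen the chosen person label (must be one of `offered`).
#' @return a list with `role` (named character: vegetable -> role),
#'   `related` and `important` (character(2) vegetable sets).
#' @export
classify_outcomes <- function(structure, offered, chosen) {
  stopifnot(length(offered) == 2L)
  if (!chosen %in% offered) stop("chosen person must be one of the offered pair")
  if (!is_valid_pair(structure, offered[1], offered[2]))
    stop("offered persons do not share exactly one vegetable")
  ch <- person_index(structure, chosen)
  un <- person_index(structure, setdiff(offered, chosen))
  gi <- structure$grows_idx
  veg_ch <- gi[ch, ]; veg_un <- gi[un, ]
  common <- intersect(veg_ch, veg_un)
  exclusive <- setdiff(veg_ch, common)
  counter <- setdiff(veg_un, common)
  absent <- setdiff(1:4, c(common, exclusive, counter))
  role <- character(4)
  role[c(common, exclusive, counter, absent)] <-
    c("Common", "Exclusive", "Counterfactual", "Absent")
  names(role) <- structure$vegetables
  list(role = role,
       related = structure$vegetables[c(common, exclusive)],
       important = structure$vegetables[c(exclusive, counter)])
}

## distinctive vegetables of an offered pair (one per person, order matches
## `offered`); these are the important outcomes of the trial
distinctive_vegs <- function(structure, offered) {
  i <- person_index(structure, offered)
  gi <- structure$grows_idx
  common <- intersect(gi[i[1], ], gi[i[2], ])
  c(setdiff(gi[i[1], ], common), setdiff(gi[i[2], ], common))
}

#' Classify a trial-to-trial transition
#'
#' Relative to the trial n+1 offer, vegetables are labeled Common (shared by
#' the n+1 pair), Unique (distinctive to the repeated person, i.e. the trial-n
#' chosen person, when re-offered), Other (distinctive to the alternative
#' person) and Absent. `repeat_available` indicates that the trial-n chosen
#' person is on offer at n+1; only then are Unique/Other defined relative to a
#' repetition. `importance_prev` flags whether the Unique and Other vegetables
#' were important on trial n (they always share importance status, a
#' structural property of the 4-cycle map).
#'
#' @param structure a `cm_structure`.
#' @param trial_n,trial_n1 lists (or single data.frame rows) with elements
#'   `left`, `right`, `chosen` and `sold` (named logical/0-1 vector over
#'   vegetables) for consecutive trials of one block.
#' @return a list mirroring the transition record described above.
#' @export
classify_transition <- function(structure, trial_n, trial_n1) {
  off_n <- c(trial_n$left, trial_n$right)
  off_n1 <- c(trial_n1$left, trial_n1$right)
  sold_n <- trial_n$sold
  imp_n <- structure$vegetables[distinctive_vegs(structure, off_n)]
  dist_n1 <- structure$vegetables[distinctive_vegs(structure, off_n1)]
  i1 <- person_index(structure, off_n1)
  common_n1 <- structure$vegetables[
    intersect(structure$grows_idx[i1[1], ], structure$grows_idx[i1[2], ])]
  absent_n1 <- setdiff(structure$vegetables, c(common_n1, dist_n1))

  repeat_available <- trial_n$chosen %in% off_n1
  roles_next <- setNames(rep("Absent", 4), structure$vegetables)
  roles_next[common_n1] <- "Common"
  if (repeat_available) {
    unique_veg <- dist_n1[match(trial_n$chosen, off_n1)]
    other_veg <- setdiff(dist_n1, unique_veg)
    roles_next[unique_veg] <- "Unique"
    roles_next[other_veg] <- "Other"
  } else {
    unique_veg <- other_veg <- NA_character_
    roles_next[dist_n1] <- "Distinctive"
  }
  list(
    repeat_available = repeat_available,
    repeat_ = if (repeat_available) identical(trial_n1$chosen, trial_n$chosen) else NA,
    roles_next = roles_next,
    rewards_prev = sold_n,
    importance_prev = if (repeat_available) unique_veg %in% imp_n
                      else all(dist_n1 %in% imp_n),
    distinctive_right = list(veg = dist_n1[2], reward_prev = unname(sold_n[dist_n1[2]])),
    distinctive_left = list(veg = dist_n1[1], reward_prev = unname(sold_n[dist_n1[1]])),
    chosen_side_next = if (!is.null(trial_n1$chosen)) trial_n1$chosen == trial_n1$right else NA
  )
}
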