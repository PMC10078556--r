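#' Design specification for a rating experiment
#'
#' Describes the factorial structure of the 2x2 rating studies: a
#' between-subject numeral-exposure factor, a within-subject knowledgeability
#' factor balanced over the target trials, and pseudo-randomized trial orders
#' with two hard constraints: the first trial is an exposure trial, and no
#' two target trials are adjacent.
#'
#' @param n_participants Number of participants (default 240).
#' @param n_target Target trials per participant (default 8; must be even so
#'   knowledgeability splits evenly).
#' @param n_exposure Exposure (filler) trials per participant (default 24,
#'   giving 32 trials in total).
#' @param first_trial_exposure Enforce that position 1 is an exposure trial.
#' @param no_adjacent_targets Enforce that no two target trials are adjacent.
#' @return A list of class `design_spec`.
#' @examples
#' design_spec()
#' @export
design_spec <- function(n_participants = 240, n_target = 8, n_exposure = 24,
                        first_trial_exposure = TRUE, no_adjacent_targets = TRUE) {
  n_participants <- assert_count(n_participants, "n_participants", min = 1L)
  n_target <- assert_count(n_target, "n_target", min = 2L)
  n_exposure <- assert_count(n_exposure, "n_exposure", min = 0L)
  if (n_target %% 2L != 0L) {
    abort("`n_target` must be even (targets split equally across knowledgeability).",
          class = "altrsa_validation_error")
  }
  structure(
    list(n_participants = n_participants, n_target = n_target,
         n_exposure = n_exposure,
         first_trial_exposure = isTRUE(first_trial_exposure),
         no_adjacent_targets = isTRUE(no_adjacent_targets)),
    class = "design_spec"
  )
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf("<design_spec> %d participants, %d target + %d exposure trials (%d total)\n",
              x$n_participants, x$n_target, x$n_exposure, x$n_target + x$n_exposure))
  invisible(x)
}

# sample k pairwise non-adjacent positions uniformly from lo..hi
# (classic bijection: non-adjacent k-subsets of m slots <-> k-subsets of m-k+1)
sample_nonadjacent <- function(lo, hi, k) {
  m <- hi - lo + 1L
  base <- sort(sample.int(m - k + 1L, k))
  base + 0:(k - 1L) + (lo - 1L)
}

# trial layout for a single participant; assumes set.seed() already applied
participant_design <- function(spec) {
  total <- spec$n_target + spec$n_exposure
  k <- spec$n_target
  lo <- if (spec$first_trial_exposure) 2L else 1L
  if (spec$no_adjacent_targets) {
    target_pos <- sample_nonadjacent(lo, total, k)
  } else {
    target_pos <- sort(sample(lo:total, k))
  }
  trial_type <- rep("exposure", total)
  trial_type[target_pos] <- "target"
  know <- character(total)
  know[target_pos] <- sample(rep(c("partial", "full"), k / 2L))
  n_exp <- spec$n_exposure
  exp_know <- sample(rep(c("partial", "full"), length.out = n_exp))
  know[trial_type == "exposure"] <- exp_know
  item <- character(total)
  item[target_pos] <- sample(paste0("T", seq_len(k)))
  item[trial_type == "exposure"] <- sample(paste0("E", seq_len(n_exp)))
  list(trial_type = trial_type, knowledgeability = know, item = item)
}

check_design_satisfiable <- function(spec) {
  total <- spec$n_target + spec$n_exposure
  lo <- if (spec$first_trial_exposure) 2L else 1L
  m <- total - lo + 1L
  if (spec$first_trial_exposure && spec$n_exposure < 1L) {
    abort("unsatisfiable design: the first trial must be an exposure trial but there are no exposure trials.",
          class = "altrsa_design_error")
  }
  if (spec$no_adjacent_targets && m - spec$n_target + 1L < spec$n_target) {
    abort(sprintf("unsatisfiable design: cannot place %d pairwise non-adjacent target trials in positions %d..%d.",
                  spec$n_target, lo, total),
          class = "altrsa_design_error")
  }
  if (!spec$no_adjacent_targets && m < spec$n_target) {
    abort("unsatisfiable design: more target trials than available positions.",
          class = "altrsa_design_error")
  }
  invisible(TRUE)
}

#' Build pseudo-randomized trial orders
#'
#' Generates one trial sequence per participant satisfying the ordering
#' constraints in the [design_spec()]: the first trial is an exposure trial
#' and no two target trials follow each other. Knowledgeability levels are
#' balanced over target trials and assigned to target items independently
#' per participant (item counterbalancing); exposure trials are split
#' half-partial / half-full. The result is deterministic given `seed`.
#'
#' @param spec A [design_spec()].
#' @param seed Integer master seed; per-participant streams are derived from
#'   it, so participant `i`'s sequence does not depend on how many
#'   participants are generated.
#' @return A tibble with columns `participant`, `position`, `trial_type`,
#'   `item`, `knowledgeability`.
#' @examples
#' build_design(design_spec(n_participants = 2), seed = 1)
#' @export
build_design <- function(spec, seed) {
  stopifnot(inherits(spec, "design_spec"))
  seed <- assert_count(seed, "seed", min = 0L)
  check_design_satisfiable(spec)
  n <- spec$n_participants
  total <- spec$n_target + spec$n_exposure
  streams <- derive_streams(seed, n)
  withr::local_preserve_seed()
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(streams$design[i])
    d <- participant_design(spec)
    rows[[i]] <- d
  }
  tibble(
    participant = rep(seq_len(n), each = total),
    position = rep(seq_len(total), times = n),
    trial_type = unlist(lapply(rows, `[[`, "trial_type")),
    item = unlist(lapply(rows, `[[`, "item")),
    knowledgeability = unlist(lapply(rows, `[[`, "knowledgeability"))
  )
}
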