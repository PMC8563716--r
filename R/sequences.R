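#' Per-block role compositions for the two learning conditions
#'
#' Both conditions present 144 learning trials in three 48-trial blocks
#' with role totals 72 prototype : 36 rule-follower : 36 exception (the
#' 2:1:1 ratio).  In the early condition every block mixes all three roles
#' (24 P, 12 R, 12 E); in the delayed condition exceptions are withheld
#' from block 1 (32 P, 16 R, preserving 2:1) and first appear at trial 49,
#' with blocks 2-3 at 20 P, 10 R, 18 E each so that role totals match the
#' early condition exactly.
#'
#' @param condition `"early"` or `"delayed"`.
#' @return A 3 x 3 integer matrix (blocks x roles).
#' @export
block_composition <- function(condition = c("early", "delayed")) {
  condition <- match.arg(condition)
  comp <- if (condition == "early") {
    rbind(c(24L, 12L, 12L), c(24L, 12L, 12L), c(24L, 12L, 12L))
  } else {
    rbind(c(32L, 16L, 0L), c(20L, 10L, 18L), c(20L, 10L, 18L))
  }
  dimnames(comp) <- list(block = 1:3,
                         role = c("prototype", "rule_follower", "exception"))
  comp
}

# allocate n trials over the member ids of one role, balanced to +/-1,
# rotating which members get the extra trial by block so totals even out
balanced_members <- function(ids, n, offset = 0L) {
  m <- length(ids)
  base <- n %/% m
  extra <- n %% m
  counts <- rep(base, m)
  if (extra > 0L) {
    take <- ((offset + seq_len(extra) - 1L) %% m) + 1L
    counts[take] <- counts[take] + 1L
  }
  rep(ids, counts)
}

#' Generate a learning sequence for one condition
#'
#' Builds the ordered 144-trial learning sequence: per-block role counts
#' from [block_composition()], members within a role balanced to within one
#' appearance of each other (prototype trials alternate between the two
#' nondiagnostic variants of each category), a prototype-only prefix of
#' `prefix_len` trials opening block 1, and a seeded random permutation
#' within each block otherwise.
#'
#' @param stimuli A [stimulus_set()].
#' @param condition `"early"` or `"delayed"`.
#' @param seed Integer RNG seed; the same seed reproduces the sequence.
#' @param composition Optional 3 x 3 blocks-by-role count matrix overriding
#'   [block_composition()].  Rows must sum to 48.
#' @param prefix_len Length of the prototype-only prefix of block 1
#'   (default 8).
#' @return A tibble of class `trial_sequence`: `trial` (1..144), `block`,
#'   `phase` (`"learning"`), `stimulus_id`, `role`, `category`, `encoding`,
#'   with the condition and seed stored as attributes.
#' @export
generate_learning_sequence <- function(stimuli, condition = c("early", "delayed"),
                                       seed = 1L, composition = NULL,
                                       prefix_len = 8L) {
  condition <- match.arg(condition)
  comp <- if (is.null(composition)) block_composition(condition) else composition
  if (!all(rowSums(comp) == 48L))
    stop("sequence construction: each block must contain 48 trials", call. = FALSE)
  if (any(comp < 0L))
    stop("sequence construction: negative role counts", call. = FALSE)
  if (prefix_len > comp[1L, "prototype"])
    stop("sequence construction: prototype-only prefix longer than block 1 prototype count",
         call. = FALSE)
  roles <- colnames(comp)
  members <- lapply(roles, function(r) stimuli$id[stimuli$role == r])
  names(members) <- roles

  rng <- local_seed_state(seed)
  trials <- character(0)
  for (b in 1:3) {
    pool <- unlist(lapply(roles, function(r) {
      balanced_members(members[[r]], comp[b, r], offset = (b - 1L) * (comp[b, r] %% length(members[[r]])))
    }))
    if (b == 1L && prefix_len > 0L) {
      protos <- balanced_members(members[["prototype"]], prefix_len, offset = 0L)
      prefix <- sample(protos)
      # remove the prefix stimuli from the block pool, one occurrence each
      for (p in prefix) pool <- pool[-match(p, pool)]
      block_trials <- c(prefix, sample(pool))
    } else {
      block_trials <- sample(pool)
    }
    trials <- c(trials, block_trials)
  }
  restore_seed_state(rng)

  seq_tbl <- tibble::tibble(
    trial = seq_along(trials),
    block = rep(1:3, each = 48L),
    phase = "learning",
    stimulus_id = trials
  ) |>
    dplyr::left_join(stimuli[, c("id", "role", "category", "encoding")],
                     by = c("stimulus_id" = "id"))
  attr(seq_tbl, "condition") <- condition
  attr(seq_tbl, "seed") <- seed
  class(seq_tbl) <- c("trial_sequence", class(seq_tbl))
  seq_tbl
}

#' Generate the common test sequence
#'
#' 48 trials with 16 per role (prototypes and rule-followers: 4 appearances
#' of each member; exceptions: 8 each), in seeded random order.  The test
#' composition is identical across conditions.
#'
#' @inheritParams generate_learning_sequence
#' @return A `trial_sequence` tibble with `phase = "test"` and
#'   `block = "test"`.
#' @export
generate_test_sequence <- function(stimuli, seed = 1L) {
  roles <- c("prototype", "rule_follower", "exception")
  pool <- unlist(lapply(roles, function(r)
    balanced_members(stimuli$id[stimuli$role == r], 16L)))
  rng <- local_seed_state(seed)
  trials <- sample(pool)
  restore_seed_state(rng)
  seq_tbl <- tibble::tibble(
    trial = seq_along(trials),
    block = "test",
    phase = "test",
    stimulus_id = trials
  ) |>
    dplyr::left_join(stimuli[, c("id", "role", "category", "encoding")],
                     by = c("stimulus_id" = "id"))
  attr(seq_tbl, "seed") <- seed
  class(seq_tbl) <- c("trial_sequence", class(seq_tbl))
  seq_tbl
}

#' Checkpoint schedules for representational testing
#'
#' Trial indices after which the network is probed with all 10 stimuli
#' (weights frozen).  The delayed schedule samples densely around trial 48
#' to capture the introduction of exceptions.
#'
#' @param condition `"early"` or `"delayed"`.
#' @return Integer vector of trial indices, ending at 144.
#' @export
checkpoint_schedule <- function(condition = c("early", "delayed")) {
  condition <- match.arg(condition)
  if (condition == "early") c(12L, 36L, 48L, 72L, 96L, 120L, 144L)
  else c(24L, 48L, 60L, 72L, 84L, 96L, 120L, 144L)
}

#' Write a trial sequence to CSV
#'
#' Columns: trial, block, phase, stimulus_id, role, category, encoding.
#'
#' @param sequence A `trial_sequence`.
#' @param path File path.
#' @export
write_sequence_csv <- function(sequence, path) {
  readr::write_csv(as.data.frame(sequence), path)
  invisible(path)
}

# run code under a private RNG stream without disturbing the caller's seed
local_seed_state <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  old
}

restore_seed_state <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
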