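#' Configuration for the synthetic behavioural generator
#'
#' Ground-truth logit structure for simulated trial-level accuracy:
#' per role-by-condition intercepts and repetition slopes (log-odds per
#' repetition), a participant random-intercept SD, and a truncated
#' log-normal reaction-time model.  Defaults qualitatively mimic the
#' observed pattern (prototype > rule-follower > exception; steeper
#' learning for delayed exceptions) and are illustrative, not fitted
#' values.
#'
#' @param n_participants Participants per condition.
#' @param intercepts Named list `early` / `delayed`, each a named numeric
#'   vector over roles, giving the cell intercept in log-odds.
#' @param slopes Same shape as `intercepts`; log-odds change per
#'   repetition.
#' @param participant_sd SD of the participant random intercept.
#' @param rt_meanlog,rt_sdlog Log-normal reaction-time parameters.
#' @param rt_bounds Truncation bounds for generated reaction times (s).
#' @param logit_cap Absolute cap on the linear predictor.
#' @param seed RNG seed.
#' @return A list of class `behavior_gen_config`.
#' @export
behavior_gen_config <- function(
    n_participants = 40L,
    intercepts = list(
      early   = c(prototype = 1.0, rule_follower = 0.5, exception = 0.0),
      delayed = c(prototype = 1.0, rule_follower = 0.5, exception = 0.1)),
    slopes = list(
      early   = c(prototype = 0.017, rule_follower = -0.010, exception = 0.006),
      delayed = c(prototype = 0.037, rule_follower = 0.019, exception = 0.038)),
    participant_sd = 0.5,
    rt_meanlog = log(0.65), rt_sdlog = 0.25,
    rt_bounds = c(0.15, 2),
    logit_cap = 10,
    seed = 1L) {
  stopifnot(n_participants >= 1L, participant_sd >= 0, rt_sdlog >= 0)
  roles <- c("prototype", "rule_follower", "exception")
  for (cond in c("early", "delayed")) {
    if (!all(roles %in% names(intercepts[[cond]])) ||
        !all(roles %in% names(slopes[[cond]])))
      stop("intercepts and slopes must name all three roles for both conditions",
           call. = FALSE)
  }
  structure(list(n_participants = as.integer(n_participants),
                 intercepts = intercepts, slopes = slopes,
                 participant_sd = participant_sd,
                 rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog,
                 rt_bounds = rt_bounds, logit_cap = logit_cap,
                 seed = as.integer(seed)),
            class = "behavior_gen_config")
}

rtrunc_lnorm <- function(n, meanlog, sdlog, bounds) {
  plo <- stats::plnorm(bounds[1], meanlog, sdlog)
  phi <- stats::plnorm(bounds[2], meanlog, sdlog)
  stats::qlnorm(plo + stats::runif(n) * (phi - plo), meanlog, sdlog)
}

#' Generate a synthetic behavioural dataset
#'
#' Simulates trial-level accuracy and reaction times in the layout of the
#' behavioural experiment: each participant works through their
#' condition's 144-trial learning sequence plus the 48-trial test block;
#' `correct ~ Bernoulli(logistic(intercept(role, condition) +
#' slope(role, condition) * repetition + participant intercept))`, with
#' repetition the 0-based count of prior appearances of the trial's
#' stimulus type.  Reaction times are truncated log-normal and exist only
#' to exercise the exclusion rules.
#'
#' @param stimuli A [stimulus_set()].
#' @param sequences Named list `early` / `delayed` of learning
#'   `trial_sequence`s (built by [generate_learning_sequence()]).
#' @param config A [behavior_gen_config()].
#' @param test_sequences Optional named list of test sequences; generated
#'   from `config$seed` when omitted.
#' @return A list of class `hc_behavior_dataset`: `data` (the trial
#'   tibble), `ground_truth` (the generating parameters), `latent`
#'   (per-participant intercepts), `planted` (exclusion pathologies, empty
#'   until [inject_exclusion_cases()]).
#' @export
generate_participants <- function(stimuli, sequences, config = behavior_gen_config(),
                                  test_sequences = NULL) {
  stopifnot(all(c("early", "delayed") %in% names(sequences)))
  if (is.null(test_sequences)) {
    test_sequences <- list(early = generate_test_sequence(stimuli, seed = config$seed),
                           delayed = generate_test_sequence(stimuli, seed = config$seed + 1L))
  }
  rng <- local_seed_state(config$seed)
  rows <- list()
  latents <- list()
  pid <- 0L
  for (cond in c("early", "delayed")) {
    learn <- sequences[[cond]]
    test <- test_sequences[[cond]]
    full <- dplyr::bind_rows(
      tibble::tibble(block = as.character(learn$block), trial_index = learn$trial,
                     stimulus_id = learn$stimulus_id, role = learn$role,
                     category = learn$category),
      tibble::tibble(block = "test", trial_index = max(learn$trial) + test$trial,
                     stimulus_id = test$stimulus_id, role = test$role,
                     category = test$category)
    )
    # 0-based count of prior appearances of the trial's stimulus type
    full <- full |>
      dplyr::group_by(.data$role) |>
      dplyr::mutate(repetition = dplyr::row_number() - 1L) |>
      dplyr::ungroup()
    for (i in seq_len(config$n_participants)) {
      pid <- pid + 1L
      b_i <- stats::rnorm(1L, 0, config$participant_sd)
      eta <- config$intercepts[[cond]][full$role] +
        config$slopes[[cond]][full$role] * full$repetition + b_i
      eta <- pmin(pmax(eta, -config$logit_cap), config$logit_cap)
      rows[[pid]] <- tibble::tibble(
        participant_id = sprintf("P%03d", pid),
        condition = cond,
        full[, c("block", "trial_index", "stimulus_id", "role", "category",
                 "repetition")],
        correct = stats::rbinom(nrow(full), 1L, stats::plogis(eta)),
        rt = rtrunc_lnorm(nrow(full), config$rt_meanlog, config$rt_sdlog,
                          config$rt_bounds)
      )
      latents[[pid]] <- tibble::tibble(participant_id = sprintf("P%03d", pid),
                                       condition = cond, intercept = b_i)
    }
  }
  restore_seed_state(rng)
  structure(list(data = dplyr::bind_rows(rows),
                 ground_truth = list(intercepts = config$intercepts,
                                     slopes = config$slopes,
                                     participant_sd = config$participant_sd),
                 latent = dplyr::bind_rows(latents),
                 config = config,
                 planted = list()),
            class = "hc_behavior_dataset")
}

#' Plant exclusion-rule violations in a synthetic dataset
#'
#' Deterministically modifies chosen participants so the preprocessing
#' rules fire on exactly known cases: `rt_rule` participants get 25% of
#' their reaction times set to 2.5 s (violating the 20% out-of-range
#' rule); `accuracy_rule` participants get every block-1 response set to
#' incorrect (so no stimulus type passes 0.75 in that block);
#' `out_of_range_trials` rows (participant_id, trial_index) get `rt`
#' set to 0.05 s.  All plants are recorded in `$planted`.
#'
#' @param dataset An [generate_participants()] dataset.
#' @param rt_rule Character vector of participant ids.
#' @param accuracy_rule Character vector of participant ids.
#' @param out_of_range_trials Tibble with `participant_id`, `trial_index`.
#' @return The modified `hc_behavior_dataset`.
#' @export
inject_exclusion_cases <- function(dataset, rt_rule = character(0),
                                   accuracy_rule = character(0),
                                   out_of_range_trials = NULL) {
  d <- dataset$data
  for (p in rt_rule) {
    idx <- which(d$participant_id == p)
    if (length(idx) == 0L) stop("unknown participant ", p, call. = FALSE)
    hit <- idx[seq_along(idx) %% 4L == 1L]  # every 4th trial -> 25%
    d$rt[hit] <- 2.5
  }
  for (p in accuracy_rule) {
    idx <- which(d$participant_id == p & d$block == "1")
    if (length(idx) == 0L) stop("participant ", p, " has no block-1 trials",
                                call. = FALSE)
    d$correct[idx] <- 0L
  }
  if (!is.null(out_of_range_trials)) {
    for (i in seq_len(nrow(out_of_range_trials))) {
      j <- which(d$participant_id == out_of_range_trials$participant_id[i] &
                 d$trial_index == out_of_range_trials$trial_index[i])
      if (length(j) != 1L) stop("trial not found for out-of-range plant", call. = FALSE)
      d$rt[j] <- 0.05
    }
  }
  dataset$data <- d
  dataset$planted <- list(rt_rule = rt_rule, accuracy_rule = accuracy_rule,
                          out_of_range_trials = out_of_range_trials)
  dataset
}

#' Write a synthetic behavioural dataset to CSV (+ ground-truth JSON)
#'
#' @param dataset An `hc_behavior_dataset`.
#' @param path CSV path; the ground truth is written next to it with a
#'   `.truth.json` suffix.
#' @export
write_behavior_csv <- function(dataset, path) {
  readr::write_csv(dataset$data, path)
  jsonlite::write_json(dataset$ground_truth,
                       paste0(sub("\\.csv$", "", path), ".truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
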