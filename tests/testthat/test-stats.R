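make_behavior <- function(n = 6L, seed = 1L, ...) {
  stim <- fixture_stimuli()
  seqs <- list(early = generate_learning_sequence(stim, "early", seed = seed),
               delayed = generate_learning_sequence(stim, "delayed", seed = seed + 1L))
  cfg <- behavior_gen_config(n_participants = n, seed = seed, ...)
  generate_participants(stim, seqs, cfg)
}

test_that("preprocessing applies both participant rules and both trial filters", {
  ds <- make_behavior(n = 6L, seed = 2L,
                      intercepts = list(
                        early = c(prototype = 3, rule_follower = 3, exception = 3),
                        delayed = c(prototype = 3, rule_follower = 3, exception = 3)))
  ds <- inject_exclusion_cases(ds, rt_rule = "P002", accuracy_rule = "P003",
                               out_of_range_trials = tibble::tibble(
                                 participant_id = "P004", trial_index = 10L))
  pp <- preprocess_behavior(ds$data)
  excl <- pp$report$excluded_participants
  expect_setequal(excl$participant_id, c("P002", "P003"))
  expect_equal(excl$reason[excl$participant_id == "P002"], "rt_outlier_proportion")
  expect_equal(excl$reason[excl$participant_id == "P003"], "block_accuracy")
  # the planted out-of-range trial is exactly the trial dropped
  expect_equal(pp$report$dropped_trials$participant_id, "P004")
  expect_equal(pp$report$dropped_trials$trial_index, 10L)
  # a clean high-accuracy participant is fully retained
  expect_true("P001" %in% pp$data$participant_id)
  # learning analyses keep only the first 36 repetitions per type
  expect_lt(max(pp$data$repetition[pp$data$learning_kept]), 36L)
  expect_equal(sum(pp$data$participant_id == "P001" & pp$data$learning_kept &
                   pp$data$role == "prototype"), 36L)
})

test_that("preprocessing is idempotent and rejects schema violations", {
  ds <- make_behavior(n = 4L, seed = 3L,
                      intercepts = list(
                        early = c(prototype = 3, rule_follower = 2.5, exception = 2),
                        delayed = c(prototype = 3, rule_follower = 2.5, exception = 2)))
  pp1 <- preprocess_behavior(ds$data)
  pp2 <- preprocess_behavior(pp1$data)
  expect_equal(pp2$data, pp1$data)
  expect_equal(nrow(pp2$report$excluded_participants), 0L)
  bad <- ds$data
  bad$correct[5] <- 2
  expect_error(preprocess_behavior(bad), "schema violation")
  expect_error(preprocess_behavior(ds$data[, -1]), "missing columns")
})

test_that("the behavioural mixed model recovers its structure and flags separation", {
  ds <- make_behavior(n = 30L, seed = 4L)
  pp <- preprocess_behavior(ds$data)
  fit <- fit_behavioral_glme(pp, "base", scope = "learning", nagq = 0L)
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "p_value", "conf_low", "conf_high") %in%
                  names(td)))
  expect_true(all(td$conf_low <= td$estimate & td$estimate <= td$conf_high))
  gl <- glance(fit)
  expect_true(is.finite(gl$BIC))
  expect_equal(gl$family, "binomial")
  # contrast table exposes condition effects within each stimulus type
  expect_true(any(grepl("condition_delayed_vs_early\\|exception", fit$contrasts$term)))

  # the repetition model fits the learning curves better than the base model
  fit_rep <- fit_behavioral_glme(pp, "with_repetition", scope = "learning", nagq = 0L)
  expect_lt(glance(fit_rep)$BIC, gl$BIC)

  # complete separation in a cell is flagged, not silently absorbed
  sep <- pp$data
  sep$correct[sep$role == "prototype"] <- 1L
  expect_warning(fit_behavioral_glme(sep, "base", scope = "learning", nagq = 0L),
                 "separation")
})

test_that("within-fit type contrasts are additive", {
  ds <- make_behavior(n = 10L, seed = 5L)
  fit <- fit_behavioral_glme(preprocess_behavior(ds$data), "base",
                             scope = "learning", nagq = 0L)
  ct <- fit$contrasts
  pick <- function(pat) ct$estimate[grepl(pat, ct$term, fixed = TRUE)][1]
  er <- pick("exception - rule_follower|early")
  rp <- pick("rule_follower - prototype|early")
  ep <- pick("exception - prototype|early")
  expect_equal(er + rp, ep, tolerance = 1e-8)
})

test_that("the model-accuracy mixed model recovers injected condition effects", {
  # synthetic accuracy table with a known +0.05 delayed shift for
  # exceptions only
  set.seed(50)
  stim <- fixture_stimuli()
  grid <- tidyr::expand_grid(batch = 1:500, condition = c("early", "delayed"),
                             stimulus_id = stim$id)
  grid <- dplyr::left_join(grid, stim[, c("id", "role", "category")],
                           by = c("stimulus_id" = "id"))
  base <- c(prototype = 0.85, rule_follower = 0.75, exception = 0.6)
  b_batch <- stats::rnorm(500, 0, 0.03)
  grid$checkpoint <- 144L
  grid$accuracy <- base[grid$role] +
    0.05 * (grid$role == "exception" & grid$condition == "delayed") +
    b_batch[grid$batch] + stats::rnorm(nrow(grid), 0, 0.05)
  fit <- fit_model_accuracy_lmm(grid, "roles")
  eff <- fit$contrasts
  e_exc <- eff$estimate[eff$term == "condition_delayed_vs_early|exception"]
  expect_lt(abs(e_exc - 0.05), 0.01)
  e_pro <- eff$estimate[eff$term == "condition_delayed_vs_early|prototype"]
  expect_lt(abs(e_pro), 0.01)

  # degenerate: constant accuracy gives zero effects
  grid$accuracy <- 0.5
  fit0 <- fit_model_accuracy_lmm(grid, "roles")
  td0 <- tidy(fit0)
  expect_true(all(abs(td0$estimate[td0$term != "(Intercept)"]) < 1e-10))

  # duplicate records are rejected
  dup <- dplyr::bind_rows(grid, grid[1, ])
  expect_error(fit_model_accuracy_lmm(dup, "roles"), "duplicate")
})

test_that("the exceptions-by-category model exposes per-exception condition effects", {
  set.seed(51)
  grid <- tidyr::expand_grid(batch = 1:300, condition = c("early", "delayed"),
                             stimulus_id = c("EA", "EB"))
  grid$role <- "exception"
  grid$category <- ifelse(grid$stimulus_id == "EA", "A", "B")
  grid$checkpoint <- 144L
  grid$accuracy <- 0.55 +
    0.18 * (grid$category == "B" & grid$condition == "delayed") -
    0.08 * (grid$category == "A" & grid$condition == "delayed") +
    stats::rnorm(nrow(grid), 0, 0.08)
  fit <- fit_model_accuracy_lmm(grid, "exceptions")
  eff <- fit$contrasts
  eb <- eff$estimate[eff$term == "condition_delayed_vs_early|EB"]
  ea <- eff$estimate[eff$term == "condition_delayed_vs_early|EA"]
  inter <- eff$estimate[grepl("interaction", eff$term)]
  expect_lt(abs(eb - 0.18), 0.02)
  expect_lt(abs(ea + 0.08), 0.02)
  expect_equal(inter, eb - ea, tolerance = 1e-8)
})
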