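#' Preprocess a behavioural trial table
#'
#' Applies the participant- and trial-level exclusion rules used for the
#' behavioural analyses:
#' \enumerate{
#'   \item a participant is excluded if, in at least one of the learning
#'     or test blocks, no stimulus type reaches an accuracy above 0.75;
#'   \item a participant is excluded if more than 20% of their reaction
#'     times fall outside \[0.15 s, 2 s\];
#'   \item remaining trials with `rt` outside \[0.15 s, 2 s\] are dropped;
#'   \item learning-phase trials beyond the first `repetition_cap`
#'     repetitions of a stimulus type (repetition is the 0-based count of
#'     prior appearances of that type) are flagged out of the learning
#'     analyses via the `learning_kept` column, equating exposure across
#'     types.  Flagging rather than dropping keeps the preprocessing
#'     idempotent.
#' }
#'
#' @param raw Behavioural trial tibble with columns `participant_id`,
#'   `condition`, `block`, `trial_index`, `stimulus_id`, `role`,
#'   `category`, `repetition`, `correct`, `rt`.
#' @param accuracy_threshold Per-block accuracy criterion (default 0.75).
#' @param rt_range Valid reaction-time range in seconds.
#' @param rt_outlier_prop Maximum tolerated proportion of out-of-range
#'   reaction times per participant.
#' @param repetition_cap Learning-phase repetition cap (default 36).
#' @return A list of class `hc_preprocess`: `data` (the filtered tibble)
#'   and `report` (tibbles `excluded_participants` with reasons and
#'   `dropped_trials`, plus counts).
#' @export
preprocess_behavior <- function(raw, accuracy_threshold = 0.75,
                                rt_range = c(0.15, 2),
                                rt_outlier_prop = 0.2,
                                repetition_cap = 36L) {
  required <- c("participant_id", "condition", "block", "trial_index",
                "stimulus_id", "role", "category", "repetition", "correct", "rt")
  miss <- setdiff(required, names(raw))
  if (length(miss) > 0L)
    stop("behavioural table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad_rows <- which(!(raw$correct %in% c(0, 1)) | raw$repetition < 0 | !is.finite(raw$rt))
  if (length(bad_rows) > 0L)
    stop("schema violation in rows: ", paste(utils::head(bad_rows, 10L), collapse = ", "),
         call. = FALSE)

  # rule 1: some block in which every stimulus type is at or below threshold
  block_acc <- raw |>
    dplyr::group_by(.data$participant_id, .data$block, .data$role) |>
    dplyr::summarise(acc = mean(.data$correct), .groups = "drop_last") |>
    dplyr::summarise(best = max(.data$acc), .groups = "drop_last") |>
    dplyr::summarise(failed = any(.data$best <= accuracy_threshold), .groups = "drop")
  acc_excluded <- block_acc$participant_id[block_acc$failed]

  # rule 2: too many out-of-range reaction times
  rt_prop <- raw |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(prop_out = mean(.data$rt < rt_range[1] | .data$rt > rt_range[2]),
                     .groups = "drop")
  rt_excluded <- rt_prop$participant_id[rt_prop$prop_out > rt_outlier_prop]

  excluded <- dplyr::bind_rows(
    tibble::tibble(participant_id = acc_excluded, reason = "block_accuracy"),
    tibble::tibble(participant_id = rt_excluded, reason = "rt_outlier_proportion")
  )
  kept <- raw[!(raw$participant_id %in% excluded$participant_id), ]

  out_of_range <- kept$rt < rt_range[1] | kept$rt > rt_range[2]
  dropped_trials <- kept[out_of_range, c("participant_id", "block", "trial_index", "rt")]
  kept <- kept[!out_of_range, ]

  kept$learning_kept <- kept$block != "test" & kept$repetition < repetition_cap

  structure(list(
    data = tibble::as_tibble(kept),
    report = list(
      excluded_participants = excluded,
      dropped_trials = tibble::as_tibble(dropped_trials),
      n_participants_in = dplyr::n_distinct(raw$participant_id),
      n_participants_kept = dplyr::n_distinct(kept$participant_id),
      n_trials_dropped_rt = sum(out_of_range),
      n_trials_capped_repetition = sum(!kept$learning_kept & kept$block != "test")
    )
  ), class = "hc_preprocess")
}

#' Fit the behavioural mixed-effects model
#'
#' Binomial generalized linear mixed model (logit link) for trial-level
#' accuracy with a participant random intercept.  Variants:
#' \describe{
#'   \item{`base`}{`correct ~ role * condition + (1 | participant_id)`}
#'   \item{`with_repetition`}{adds `repetition` and all interactions}
#'   \item{`cell_means`}{one intercept and one repetition slope per
#'     role-by-condition cell (no marginal terms), the parameterization
#'     matched by the synthetic generator's ground truth}
#'   \item{`exceptions_by_category`}{exception trials only, fixed effects
#'     exception category x condition (the per-exception analysis, exposing
#'     the category-by-condition crossover)}
#' }
#' Contrasts exposing the standard comparisons (type differences within
#' condition, condition effects within type, and their interactions) are
#' computed with `emmeans` and attached.
#'
#' @param table A preprocessed behavioural tibble (the `data` element of
#'   [preprocess_behavior()]), or an `hc_preprocess` object.
#' @param formula_variant One of `"base"`, `"with_repetition"`,
#'   `"cell_means"`.
#' @param scope Fit the `"learning"` blocks or the `"test"` block.
#' @param nagq `nAGQ` passed to [lme4::glmer()] (0 is fast and adequate
#'   for the recovery harness).
#' @return An object of class `hc_fit`; see [tidy.hc_fit()] /
#'   [glance.hc_fit()].
#' @export
fit_behavioral_glme <- function(table,
                                formula_variant = c("base", "with_repetition", "cell_means",
                                                    "exceptions_by_category"),
                                scope = c("learning", "test"),
                                nagq = 1L) {
  formula_variant <- match.arg(formula_variant)
  scope <- match.arg(scope)
  if (inherits(table, "hc_preprocess")) table <- table$data
  tbl <- if (scope == "test") {
    table[table$block == "test", ]
  } else if ("learning_kept" %in% names(table)) {
    table[table$learning_kept, ]
  } else {
    table[table$block != "test", ]
  }
  if (formula_variant == "exceptions_by_category") {
    tbl <- tbl[tbl$role == "exception", ]
    tbl$category <- factor(tbl$category, levels = c("A", "B"))
  }
  if (nrow(tbl) == 0L) stop("no trials in scope '", scope, "'", call. = FALSE)
  tbl$role <- factor(tbl$role, levels = c("exception", "rule_follower", "prototype"))
  tbl$condition <- factor(tbl$condition, levels = c("early", "delayed"))

  # flag complete separation: a fully correct or fully incorrect cell
  cells <- tbl |>
    dplyr::group_by(.data$role, .data$condition) |>
    dplyr::summarise(m = mean(.data$correct), .groups = "drop")
  if (any(cells$m %in% c(0, 1)))
    warning("complete separation: at least one role x condition cell is all-correct or all-incorrect",
            call. = FALSE)

  form <- switch(formula_variant,
    base = correct ~ role * condition + (1 | participant_id),
    with_repetition = correct ~ role * condition * repetition + (1 | participant_id),
    cell_means = correct ~ 0 + role:condition + role:condition:repetition + (1 | participant_id),
    exceptions_by_category = correct ~ category * condition + (1 | participant_id)
  )
  fit <- withCallingHandlers(
    lme4::glmer(form, data = tbl, family = stats::binomial(), nAGQ = nagq),
    message = function(m) invokeRestart("muffleMessage")
  )
  check_convergence(fit)
  contrasts <- switch(formula_variant,
    cell_means = NULL,
    exceptions_by_category = glme_category_contrasts(fit),
    glme_contrasts(fit))
  new_hc_fit(fit, family = "binomial", variant = formula_variant,
             scope = scope, contrasts = contrasts)
}

#' Fit the model-accuracy mixed model
#'
#' Linear mixed model on the continuous Luce-choice accuracies at end of
#' learning, with simulation batch as random intercept.  The response is
#' modelled on the accuracy scale (identity link): the quantities of
#' interest are accuracy differences, and a logit-scale sensitivity fit is
#' available via `logit = TRUE`.
#'
#' @param table An `hc_ensemble`, a list of ensembles, or an accuracy
#'   tibble covering both conditions.
#' @param contrast_set `"roles"` (all 10 stimuli; fixed effects
#'   role x condition) or `"exceptions"` (EA/EB only; fixed effects
#'   category x condition).
#' @param checkpoint Accuracy checkpoint to analyse (default 144).
#' @param logit Fit on the empirical-logit scale instead of raw accuracy.
#' @return An `hc_fit`.  Its `contrasts` tibble contains the
#'   delayed-minus-early condition effect within each role (or exception
#'   category) and the interaction contrasts.
#' @export
fit_model_accuracy_lmm <- function(table, contrast_set = c("roles", "exceptions"),
                                   checkpoint = 144L, logit = FALSE) {
  contrast_set <- match.arg(contrast_set)
  tbl <- accuracy_table(table)
  tbl <- tbl[tbl$checkpoint == checkpoint, ]
  if (nrow(tbl) == 0L) stop("no accuracy records at checkpoint ", checkpoint,
                            call. = FALSE)
  dup <- tbl |>
    dplyr::count(.data$batch, .data$condition, .data$stimulus_id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L)
    stop("duplicate (batch, condition, stimulus) accuracy records", call. = FALSE)
  tbl$condition <- factor(tbl$condition, levels = c("early", "delayed"))
  tbl$batch_id <- interaction(tbl$condition, tbl$batch, drop = TRUE)
  resp <- if (logit) stats::qlogis(pmin(pmax(tbl$accuracy, 1e-6), 1 - 1e-6)) else tbl$accuracy
  tbl$resp <- resp

  if (contrast_set == "roles") {
    tbl$role <- factor(tbl$role, levels = c("exception", "rule_follower", "prototype"))
    fit <- lme4::lmer(resp ~ role * condition + (1 | batch_id), data = tbl,
                      REML = TRUE)
    contrasts <- tryCatch({
    grid <- emmeans::emmeans(fit, ~ condition | role, lmer.df = "asymptotic")
    cond_eff <- summary(emmeans::contrast(grid, "revpairwise"), infer = TRUE)
    tibble::tibble(
      term = paste0("condition_delayed_vs_early|", cond_eff$role),
      estimate = cond_eff$estimate, std_error = cond_eff$SE,
      conf_low = cond_eff$asymp.LCL %||% cond_eff$lower.CL,
      conf_high = cond_eff$asymp.UCL %||% cond_eff$upper.CL,
      p_value = cond_eff$p.value
    )
    }, error = function(e) {
      message("contrast computation unavailable for a degenerate fit: ",
              conditionMessage(e))
      NULL
    })
  } else {
    tbl <- tbl[tbl$role == "exception", ]
    tbl$category <- factor(tbl$category, levels = c("A", "B"))
    fit <- lme4::lmer(resp ~ category * condition + (1 | batch_id), data = tbl,
                      REML = TRUE)
    contrasts <- tryCatch({
    grid <- emmeans::emmeans(fit, ~ condition | category, lmer.df = "asymptotic")
    cond_eff <- summary(emmeans::contrast(grid, "revpairwise"), infer = TRUE)
    inter <- summary(emmeans::contrast(
      emmeans::emmeans(fit, ~ condition * category, lmer.df = "asymptotic"),
      interaction = "revpairwise"), infer = TRUE)
    dplyr::bind_rows(
      tibble::tibble(
        term = paste0("condition_delayed_vs_early|E", cond_eff$category),
        estimate = cond_eff$estimate, std_error = cond_eff$SE,
        conf_low = cond_eff$asymp.LCL %||% cond_eff$lower.CL,
        conf_high = cond_eff$asymp.UCL %||% cond_eff$upper.CL,
        p_value = cond_eff$p.value
      ),
      tibble::tibble(
        term = "interaction_(delayed-early)_EB_vs_EA",
        estimate = inter$estimate, std_error = inter$SE,
        conf_low = inter$asymp.LCL %||% inter$lower.CL,
        conf_high = inter$asymp.UCL %||% inter$upper.CL,
        p_value = inter$p.value
      )
    )
    }, error = function(e) {
      message("contrast computation unavailable for a degenerate fit: ",
              conditionMessage(e))
      NULL
    })
  }
  new_hc_fit(fit, family = if (logit) "gaussian(logit-response)" else "gaussian",
             variant = contrast_set, scope = "model_accuracy",
             contrasts = contrasts)
}

accuracy_table <- function(x) {
  if (inherits(x, "hc_ensemble")) return(x$accuracy)
  if (is.list(x) && !is.data.frame(x) && all(purrr::map_lgl(x, inherits, "hc_ensemble")))
    return(dplyr::bind_rows(purrr::map(x, "accuracy")))
  tibble::as_tibble(x)
}

# condition effects within role and role contrasts within condition
glme_contrasts <- function(fit) {
  grid <- emmeans::emmeans(fit, ~ condition | role)
  cond_eff <- summary(emmeans::contrast(grid, "revpairwise"), infer = TRUE)
  grid2 <- emmeans::emmeans(fit, ~ role | condition)
  role_eff <- summary(emmeans::contrast(grid2, "pairwise"), infer = TRUE)
  inter <- summary(emmeans::contrast(emmeans::emmeans(fit, ~ condition * role),
                                     interaction = "revpairwise"), infer = TRUE)
  dplyr::bind_rows(
    tibble::tibble(term = paste0("condition_delayed_vs_early|", cond_eff$role),
                   estimate = cond_eff$estimate, std_error = cond_eff$SE,
                   conf_low = cond_eff$asymp.LCL %||% cond_eff$lower.CL,
                   conf_high = cond_eff$asymp.UCL %||% cond_eff$upper.CL,
                   p_value = cond_eff$p.value),
    tibble::tibble(term = paste0(role_eff$contrast, "|", role_eff$condition),
                   estimate = role_eff$estimate, std_error = role_eff$SE,
                   conf_low = role_eff$asymp.LCL %||% role_eff$lower.CL,
                   conf_high = role_eff$asymp.UCL %||% role_eff$upper.CL,
                   p_value = role_eff$p.value),
    tibble::tibble(term = paste0("interaction_", inter$condition_revpairwise, ":",
                                 inter$role_revpairwise),
                   estimate = inter$estimate, std_error = inter$SE,
                   conf_low = inter$asymp.LCL %||% inter$lower.CL,
                   conf_high = inter$asymp.UCL %||% inter$upper.CL,
                   p_value = inter$p.value)
  )
}

# condition effect within exception category plus the crossover interaction
glme_category_contrasts <- function(fit) {
  grid <- emmeans::emmeans(fit, ~ condition | category)
  cond_eff <- summary(emmeans::contrast(grid, "revpairwise"), infer = TRUE)
  inter <- summary(emmeans::contrast(emmeans::emmeans(fit, ~ condition * category),
                                     interaction = "revpairwise"), infer = TRUE)
  dplyr::bind_rows(
    tibble::tibble(term = paste0("condition_delayed_vs_early|E", cond_eff$category),
                   estimate = cond_eff$estimate, std_error = cond_eff$SE,
                   conf_low = cond_eff$asymp.LCL %||% cond_eff$lower.CL,
                   conf_high = cond_eff$asymp.UCL %||% cond_eff$upper.CL,
                   p_value = cond_eff$p.value),
    tibble::tibble(term = "interaction_(delayed-early)_EB_vs_EA",
                   estimate = inter$estimate, std_error = inter$SE,
                   conf_low = inter$asymp.LCL %||% inter$lower.CL,
                   conf_high = inter$asymp.UCL %||% inter$upper.CL,
                   p_value = inter$p.value)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_convergence <- function(fit) {
  msgs <- fit@optinfo$conv$lme4$messages
  if (!is.null(msgs))
    warning("mixed-model convergence diagnostics: ",
            paste(msgs, collapse = "; "),
            "; max abs gradient = ",
            format(max(abs(fit@optinfo$derivs$gradient %||% NA_real_))),
            call. = FALSE)
  invisible(fit)
}

new_hc_fit <- function(fit, family, variant, scope, contrasts = NULL) {
  structure(list(fit = fit, family = family, variant = variant,
                 scope = scope, contrasts = contrasts),
            class = "hc_fit")
}

#' Tidy the fixed effects of a mixed-model fit
#'
#' Broom-style one-row-per-term summary of the fixed effects with Wald
#' standard errors, 95% confidence intervals and p-values (normal
#' approximation).
#'
#' @param x An `hc_fit`.
#' @param ... Unused.
#' @return Tibble: `term`, `estimate`, `std_error`, `statistic`,
#'   `p_value`, `conf_low`, `conf_high`.
#' @export
tidy.hc_fit <- function(x, ...) {
  est <- lme4::fixef(x$fit)
  se <- tryCatch(sqrt(diag(as.matrix(stats::vcov(x$fit)))),
                 error = function(e) rep(NA_real_, length(est)))
  z <- est / se
  tibble::tibble(
    term = names(est), estimate = unname(est), std_error = unname(se),
    statistic = unname(z),
    p_value = 2 * stats::pnorm(-abs(unname(z))),
    conf_low = unname(est - stats::qnorm(0.975) * se),
    conf_high = unname(est + stats::qnorm(0.975) * se)
  )
}

#' One-row model summary of a mixed-model fit
#'
#' @param x An `hc_fit`.
#' @param ... Unused.
#' @return Tibble with `family`, `variant`, `scope`, `nobs`, `logLik`,
#'   `AIC`, `BIC`.
#' @export
glance.hc_fit <- function(x, ...) {
  ll <- stats::logLik(x$fit)
  tibble::tibble(family = x$family, variant = x$variant, scope = x$scope,
                 nobs = stats::nobs(x$fit),
                 logLik = as.numeric(ll), AIC = stats::AIC(x$fit),
                 BIC = stats::BIC(x$fit))
}

#' @export
print.hc_fit <- function(x, ...) {
  cat("<hc_fit>", x$family, "|", x$variant, "|", x$scope, "\n")
  print(tidy.hc_fit(x), n = 20)
  if (!is.null(x$contrasts)) {
    cat("\ncontrasts:\n")
    print(x$contrasts, n = 30)
  }
  invisible(x)
}

#' Serialize a fit to JSON
#'
#' Writes the tidied fixed effects, contrasts and model summary.
#'
#' @param x An `hc_fit`.
#' @param path File path.
#' @export
write_fit_json <- function(x, path) {
  jsonlite::write_json(list(fixed_effects = tidy.hc_fit(x),
                            contrasts = x$contrasts,
                            summary = glance.hc_fit(x)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
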