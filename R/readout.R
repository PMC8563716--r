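#' Luce-choice accuracy from the category readout
#'
#' Accuracy of a settled output pattern is the Luce-choice ratio of cosine
#' similarities between the two category units of EC_out (`x_D5`) and the
#' one-hot target versus nontarget codes:
#' `cos(x, target) / (cos(x, target) + cos(x, nontarget))`.
#' For nonnegative 2-vectors against complementary one-hots this reduces
#' to `x_t / (x_t + x_nt)`; the cosine form is computed explicitly.
#'
#' @param x_d5 Numeric 2-vector of EC_out activations on the category
#'   units, entries in \[0,1\].
#' @param target One-hot target, `c(1,0)` or `c(0,1)` (or the strings
#'   `"10"` / `"01"`).
#' @param zero_readout How to treat an all-zero `x_d5`: `"error"`
#'   (default) or `"half"` (return 0.5).  Silent defaults would mask an
#'   untrained-network pathology, so the opt-in is explicit.
#' @return Accuracy in \[0,1\].
#' @export
luce_accuracy <- function(x_d5, target, zero_readout = c("error", "half")) {
  zero_readout <- match.arg(zero_readout)
  if (is.character(target))
    target <- as.numeric(strsplit(target, "")[[1]])
  stopifnot(length(x_d5) == 2L, length(target) == 2L,
            all(target %in% c(0, 1)), sum(target) == 1)
  if (any(!is.finite(x_d5)) || any(x_d5 < 0))
    stop("undefined readout: x_d5 must be finite and nonnegative", call. = FALSE)
  nrm <- sqrt(sum(x_d5^2))
  if (nrm == 0) {
    if (zero_readout == "half") return(0.5)
    stop("undefined readout: both category units are zero", call. = FALSE)
  }
  nontarget <- 1 - target
  cos_t <- sum(x_d5 * target) / (nrm * sqrt(sum(target^2)))
  cos_nt <- sum(x_d5 * nontarget) / (nrm * sqrt(sum(nontarget^2)))
  cos_t / (cos_t + cos_nt)
}

# Eq.-1 accuracy for every stimulus in a snapshot; the target one-hot is
# the stimulus's own category pair code (A = "10", B = "01")
snapshot_accuracy <- function(snap, stimuli, zero_readout = "half") {
  vapply(seq_len(nrow(stimuli)), function(i) {
    x <- snap$ec_out[stimuli$id[i], 9:10]
    target <- if (stimuli$category[i] == "A") c(1, 0) else c(0, 1)
    luce_accuracy(x, target, zero_readout = zero_readout)
  }, numeric(1)) |>
    stats::setNames(stimuli$id)
}

#' Aggregate accuracy records with bootstrap confidence intervals
#'
#' Groups accuracy records, computes the per-batch mean within each group,
#' then reports the median of bootstrapped means and a percentile 95%
#' confidence interval across batches.
#'
#' @param records Tibble of accuracy records (the `accuracy` element of an
#'   [run_batches()] ensemble, or any tibble with `batch` and `accuracy`).
#' @param ... Grouping columns (tidy-select), e.g. `role, condition`.
#' @param n_boot Number of bootstrap resamples (default 10000).
#' @param seed RNG seed for the bootstrap.
#' @return Tibble with one row per group: `n_batches`, `mean_accuracy`,
#'   `boot_median`, `ci_lo`, `ci_hi`.
#' @export
aggregate_accuracy <- function(records, ..., n_boot = 10000L, seed = 1L) {
  if (nrow(records) == 0L) stop("no accuracy records", call. = FALSE)
  per_batch <- records |>
    dplyr::group_by(..., .data$batch) |>
    dplyr::summarise(batch_mean = mean(.data$accuracy), .groups = "drop_last")
  rng <- local_seed_state(seed)
  out <- per_batch |>
    dplyr::summarise(
      n_batches = dplyr::n(),
      mean_accuracy = mean(.data$batch_mean),
      boot = list(boot_mean_quantiles(.data$batch_mean, n_boot)),
      .groups = "drop"
    ) |>
    tidyr::unnest_wider("boot")
  restore_seed_state(rng)
  out
}

boot_mean_quantiles <- function(x, n_boot) {
  n <- length(x)
  means <- vapply(seq_len(n_boot),
                  function(i) mean(x[sample.int(n, n, replace = TRUE)]),
                  numeric(1))
  list(boot_median = stats::median(means),
       ci_lo = unname(stats::quantile(means, 0.025)),
       ci_hi = unname(stats::quantile(means, 0.975)))
}

#' Write an ensemble's accuracy table to CSV
#'
#' Columns: batch, condition, checkpoint, stimulus_id, role, category,
#' accuracy.
#'
#' @param ensemble An `hc_ensemble` (or its `accuracy` tibble).
#' @param path File path.
#' @export
write_accuracy_csv <- function(ensemble, path) {
  tbl <- if (inherits(ensemble, "hc_ensemble")) ensemble$accuracy else ensemble
  readr::write_csv(tbl, path)
  invisible(path)
}
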