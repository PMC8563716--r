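# Shared simulation fixtures, built once per test run and memoized.
# The reference ensemble uses the default network on both 144-trial
# conditions; directional checks use its first 50 batches, the reference-
# value checks the full set.

.hc_cache <- new.env(parent = emptyenv())

fixture_stimuli <- function() {
  if (is.null(.hc_cache$stim)) .hc_cache$stim <- stimulus_set()
  .hc_cache$stim
}

# full-scale ensembles (500 batches/condition) for the reference checks
fixture_ensembles <- function(n_batches = 500L) {
  key <- paste0("ens", n_batches)
  if (is.null(.hc_cache[[key]])) {
    stim <- fixture_stimuli()
    .hc_cache[[key]] <- list(
      early = run_batches(stim, "early", n_batches = n_batches, base_seed = 0L),
      delayed = run_batches(stim, "delayed", n_batches = n_batches,
                            base_seed = n_batches)
    )
  }
  .hc_cache[[key]]
}

# a smaller slice for directional checks (independent seeded batches, so a
# leading subset of the big ensemble is itself a valid smaller ensemble)
fixture_ensembles_50 <- function() {
  ens <- fixture_ensembles()
  lapply(ens, subset_ensemble, batches = 1:50)
}

subset_ensemble <- function(ensemble, batches) {
  out <- ensemble
  for (nm in c("accuracy", "rsa", "sparsity", "ec_out"))
    out[[nm]] <- ensemble[[nm]][ensemble[[nm]]$batch %in% batches, ]
  out$n_batches <- length(batches)
  out
}

fixture_tiny_ensemble <- function() {
  if (is.null(.hc_cache$tiny)) {
    stim <- fixture_stimuli()
    .hc_cache$tiny <- run_batches(stim, "delayed", n_batches = 5L,
                                  base_seed = 9000L)
  }
  .hc_cache$tiny
}
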