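#' Network parameters for the hippocampal autoencoder
#'
#' Assembles and validates the full parameter set of the rate-coded
#' hippocampal circuit.  The architecture is fixed to the 8-projection
#' graph EC_in->DG, EC_in->CA3, DG->CA3, CA3->CA1 (trisynaptic pathway),
#' EC_in->CA1, EC_out->CA1 (monosynaptic pathway), CA1->EC_out (output),
#' and EC_out->EC_in (big-loop recurrence, a fixed one-to-one feedback).
#'
#' Layer sparsity is enforced by k-winners-take-all inhibition; the
#' active-fraction ordering DG < CA3 < CA1 (sparsest to densest) is
#' validated here.  Trisynaptic-pathway learning rates must strictly
#' exceed every monosynaptic-pathway rate, mirroring the fast/slow
#' division of labour between pattern separation and generalization.
#'
#' @param n_dg,n_ca3,n_ca1 Hidden layer sizes (units).
#' @param k_dg,k_ca3,k_ca1,k_out Target winner counts for k-WTA inhibition.
#' @param gain Logistic activation gain of the sparse hidden layers
#'   (DG, CA3).
#' @param gain_ca1 Activation gain of CA1.
#' @param gain_ec Activation gain of the EC layers (softer, so the output
#'   readout stays graded).
#' @param dt Rate-dynamics step size per cycle (0,1].
#' @param lr_tsp Learning rate shared by the four trisynaptic projections.
#' @param lr_msp Learning rate for EC_in->CA1 and EC_out->CA1.
#' @param lr_out Learning rate for CA1->EC_out.
#' @param lr_bigloop Learning rate for EC_out->EC_in (0 = fixed feedback).
#' @param hebb Hebbian mixing coefficient added to the contrastive update.
#' @param scale_ca3_ca1,scale_in_ca1 Connectivity strength multipliers in
#'   \[0,1\] for the CA3->CA1 and EC_in->CA1 projections (1 = intact).
#' @param scale_out_ca1 Strength multiplier for the EC_out->CA1 feedback.
#' @param n_cycles Settling cycles per trial (default 80).
#' @param n_expect Cycles of the expectation phase; the remaining
#'   `n_cycles - n_expect` form the outcome phase.
#' @param test_category_free At test, leave the two category units of
#'   EC_in free (driven by big-loop feedback) rather than clamped to zero.
#'   The cue itself always has both category units at zero.
#' @param w_min,w_max Uniform weight-initialization bounds.
#' @return A named list of class `hc_params`.
#' @export
hc_params <- function(n_dg = 400L, n_ca3 = 80L, n_ca1 = 100L,
                      k_dg = 4L, k_ca3 = 6L, k_ca1 = 25L, k_out = 5L,
                      gain = 100, gain_ca1 = 100, gain_ec = 8, dt = 0.4,
                      lr_tsp = 0.08, lr_msp = 0.03, lr_out = 0.02,
                      lr_bigloop = 0, hebb = 0.05,
                      scale_ca3_ca1 = 1, scale_in_ca1 = 1, scale_out_ca1 = 1,
                      n_cycles = 80L, n_expect = 60L,
                      test_category_free = FALSE,
                      w_min = 0.25, w_max = 0.75) {
  p <- list(
    n_dg = as.integer(n_dg), n_ca3 = as.integer(n_ca3), n_ca1 = as.integer(n_ca1),
    k_dg = as.integer(k_dg), k_ca3 = as.integer(k_ca3), k_ca1 = as.integer(k_ca1),
    k_out = as.integer(k_out),
    gain = gain, gain_ca1 = gain_ca1, gain_ec = gain_ec, dt = dt,
    lr_in_dg = lr_tsp, lr_in_ca3 = lr_tsp, lr_dg_ca3 = lr_tsp,
    lr_ca3_ca1 = lr_tsp,
    lr_in_ca1 = lr_msp, lr_out_ca1 = lr_msp, lr_ca1_out = lr_out,
    lr_out_in = lr_bigloop,
    hebb = hebb,
    scale_ca3_ca1 = scale_ca3_ca1, scale_in_ca1 = scale_in_ca1,
    scale_out_ca1 = scale_out_ca1,
    n_cycles = as.integer(n_cycles), n_expect = as.integer(n_expect),
    test_category_free = isTRUE(test_category_free),
    exp_in = 5, w_min = w_min, w_max = w_max
  )
  validate_hc_params(p)
  class(p) <- "hc_params"
  p
}

validate_hc_params <- function(p) {
  frac <- c(dg = p$k_dg / p$n_dg, ca3 = p$k_ca3 / p$n_ca3, ca1 = p$k_ca1 / p$n_ca1)
  if (!(frac["dg"] < frac["ca3"] && frac["ca3"] < frac["ca1"]))
    stop("invalid layer specs: sparsity must be ordered DG < CA3 < CA1",
         call. = FALSE)
  tsp <- c(p$lr_in_dg, p$lr_in_ca3, p$lr_dg_ca3, p$lr_ca3_ca1)
  msp <- c(p$lr_in_ca1, p$lr_out_ca1)
  # an all-zero schedule (diagnostic null-learning runs) is permitted
  if (any(c(tsp, msp) > 0) && min(tsp) <= max(msp))
    stop("invalid projection specs: every TSP learning rate must exceed every MSP rate",
         call. = FALSE)
  if (p$n_cycles < 1L || p$n_expect < 1L || p$n_expect >= p$n_cycles)
    stop("phase schedule must partition n_cycles >= 2 into expectation and outcome phases",
         call. = FALSE)
  if (any(c(p$k_dg >= p$n_dg, p$k_ca3 >= p$n_ca3, p$k_ca1 >= p$n_ca1, p$k_out >= 10L)))
    stop("k_active must be smaller than the layer size", call. = FALSE)
  invisible(p)
}

#' Read network parameters from a YAML file
#'
#' The YAML document holds any subset of the [hc_params()] arguments;
#' unspecified fields take their defaults.
#'
#' @param path YAML file path.
#' @return An `hc_params` object.
#' @export
read_hc_params <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read parameter files", call. = FALSE)
  do.call(hc_params, yaml::read_yaml(path))
}

#' Initialize a network state
#'
#' Draws every learnable weight matrix i.i.d. uniform on
#' \[`w_min`, `w_max`\] under the given seed; the big-loop feedback
#' EC_out->EC_in is a fixed identity map (the deep-layer output re-enters
#' the superficial-layer code one-to-one).
#'
#' @param params An [hc_params()] object.
#' @param seed Integer RNG seed.
#' @return A list of class `hc_state`: `weights` (8 named matrices),
#'   `params`, `trial_count`.
#' @export
init_network <- function(params = hc_params(), seed = 1L) {
  rng <- local_seed_state(seed)
  ru <- function(nr, nc) matrix(stats::runif(nr * nc, params$w_min, params$w_max), nr, nc)
  weights <- list(
    in_dg   = ru(10L, params$n_dg),
    in_ca3  = ru(10L, params$n_ca3),
    dg_ca3  = ru(params$n_dg, params$n_ca3),
    ca3_ca1 = ru(params$n_ca3, params$n_ca1),
    in_ca1  = ru(10L, params$n_ca1),
    out_ca1 = ru(10L, params$n_ca1),
    ca1_out = ru(params$n_ca1, 10L),
    out_in  = diag(10)
  )
  restore_seed_state(rng)
  structure(list(weights = weights, params = params, trial_count = 0L),
            class = "hc_state")
}

#' Settle the network on an input pattern
#'
#' Iterates the rate dynamics (per-projection net input, logistic
#' activation, k-WTA inhibition in the hidden layers) for `n_cycles`
#' without touching the weights.
#'
#' @param state An `hc_state`.
#' @param input Length-10 input vector in \[0,1\] for EC_in.
#' @param free_in Integer indices (1-based) of EC_in units left free
#'   (driven by big-loop feedback); all others are clamped to `input`.
#' @param clamp_out Optional length-10 pattern to clamp EC_out to.
#' @param n_cycles Number of settling cycles (default `params$n_cycles`).
#' @param init Optional activation list to continue settling from.
#' @return Named list of settled activation vectors
#'   (`ec_in`, `dg`, `ca3`, `ca1`, `ec_out`).
#' @export
settle <- function(state, input, free_in = integer(0), clamp_out = NULL,
                   n_cycles = NULL, init = NULL) {
  stopifnot(length(input) == 10L, all(input >= 0), all(input <= 1))
  p <- state$params
  n_cycles <- if (is.null(n_cycles)) p$n_cycles else as.integer(n_cycles)
  out_pat <- if (is.null(clamp_out)) numeric(10L) else clamp_out
  hc_settle_cpp(state$weights, unclass(p), as.numeric(input),
                as.integer(free_in) - 1L, !is.null(clamp_out),
                as.numeric(out_pat), n_cycles, init)
}

#' Train the network on a single stimulus presentation
#'
#' Runs the expectation phase (EC_in clamped to the full pattern, EC_out
#' free to predict) followed by the outcome phase (EC_out also clamped),
#' then applies the contrastive weight update (outcome coproduct minus
#' expectation coproduct) plus the Hebbian term to every learnable
#' projection, clipping weights to \[0,1\].
#'
#' @param state An `hc_state`.
#' @param pattern Full length-10 stimulus encoding.
#' @return The updated `hc_state` (trial_count incremented).
#' @export
train_trial <- function(state, pattern) {
  stopifnot(length(pattern) == 10L)
  state$weights <- hc_train_trial_cpp(state$weights, unclass(state$params),
                                      as.numeric(pattern))
  state$trial_count <- state$trial_count + 1L
  state
}

#' Probe the network with all 10 stimuli
#'
#' Presents each stimulus as a cue with both category units at zero, so
#' the network must pattern-complete the category, settles for the full
#' cycle count, and records the settled DG, CA3, CA1 and EC_out
#' activations.  Weights are never updated.
#'
#' @param state An `hc_state`.
#' @param stimuli A [stimulus_set()].
#' @return A list of class `hc_snapshot`: matrices `dg`, `ca3`, `ca1`,
#'   `ec_out` (stimuli x units, rownames = stimulus ids), plus
#'   `stimulus_id` and `checkpoint` (the state's trial count).
#' @export
test_items <- function(state, stimuli) {
  enc <- encode_stimuli(stimuli)
  snap <- hc_test_items_cpp(state$weights, unclass(state$params),
                            enc * 1.0)
  for (nm in c("dg", "ca3", "ca1", "ec_out", "ec_in"))
    rownames(snap[[nm]]) <- stimuli$id
  snap$stimulus_id <- stimuli$id
  snap$checkpoint <- state$trial_count
  class(snap) <- "hc_snapshot"
  snap
}

#' Train on a full trial sequence with checkpointed testing
#'
#' Trains trial-by-trial through `sequence`; after each trial index listed
#' in `checkpoints` the network is probed with [test_items()] (no weight
#' updates during the probe) and the snapshot stored.
#'
#' @param state An `hc_state`.
#' @param sequence A learning `trial_sequence`.
#' @param stimuli The [stimulus_set()] the sequence references.
#' @param checkpoints Integer trial indices in `1:nrow(sequence)`.
#' @return List with `snapshots` (one `hc_snapshot` per checkpoint) and
#'   `state` (the trained `hc_state`).
#' @export
train_sequence <- function(state, sequence, stimuli,
                           checkpoints = checkpoint_schedule(attr(sequence, "condition"))) {
  checkpoints <- sort(as.integer(checkpoints))
  if (any(checkpoints < 1L) || any(checkpoints > nrow(sequence)))
    stop("checkpoints must lie within the sequence", call. = FALSE)
  enc <- encode_stimuli(stimuli)
  seq_enc <- enc[sequence$stimulus_id, , drop = FALSE]
  res <- hc_run_sequence_cpp(state$weights, unclass(state$params),
                             seq_enc * 1.0, enc * 1.0, checkpoints)
  snaps <- purrr::map2(res$snapshots, checkpoints, function(s, cp) {
    for (nm in c("dg", "ca3", "ca1", "ec_out", "ec_in"))
      rownames(s[[nm]]) <- stimuli$id
    s$stimulus_id <- stimuli$id
    s$checkpoint <- cp
    class(s) <- "hc_snapshot"
    s
  })
  state$weights <- res$weights
  state$trial_count <- state$trial_count + nrow(sequence)
  list(snapshots = snaps, state = state)
}

# fraction of units above half-maximum activation, per layer
snapshot_active_fraction <- function(snap) {
  vapply(c("dg", "ca3", "ca1"), function(l) {
    m <- snap[[l]]
    mean(m > 0.5 * max(m, 1e-12))
  }, numeric(1))
}

#' Run an ensemble of independently initialized simulations
#'
#' Batch `b` uses seed `base_seed + b` for both the weight initialization
#' and the sequence shuffle, trains through the condition's 144-trial
#' sequence, and probes all 10 stimuli at every checkpoint.  Per batch the
#' function stores the Luce-choice accuracy of every stimulus, the
#' per-subfield 10 x 10 Pearson similarity matrices, the settled EC_out
#' patterns, and per-layer active-unit fractions.
#'
#' @param stimuli A [stimulus_set()].
#' @param condition `"early"` or `"delayed"`.
#' @param n_batches Number of batches (the reference scale is 500).
#' @param base_seed Base RNG seed; batches use `base_seed + 1:n_batches`.
#' @param params An [hc_params()] object.
#' @param checkpoints Checkpoint schedule (defaults to the condition's).
#' @return A list of class `hc_ensemble`: tibbles `accuracy`
#'   (batch, condition, checkpoint, stimulus_id, role, category, accuracy),
#'   `rsa` (batch, condition, checkpoint, subfield, matrix list-column),
#'   `sparsity`, and `ec_out` (list-column of 10 x 10 settled outputs).
#' @export
run_batches <- function(stimuli, condition = c("early", "delayed"),
                        n_batches = 500L, base_seed = 0L,
                        params = hc_params(),
                        checkpoints = checkpoint_schedule(condition)) {
  condition <- match.arg(condition)
  stopifnot(n_batches >= 1L)
  role_map <- stats::setNames(stimuli$role, stimuli$id)
  cat_map <- stats::setNames(stimuli$category, stimuli$id)
  batches <- purrr::map(seq_len(n_batches), function(b) {
    seed_b <- base_seed + b
    seqs <- generate_learning_sequence(stimuli, condition, seed = seed_b)
    st <- init_network(params, seed = seed_b)
    run <- train_sequence(st, seqs, stimuli, checkpoints)
    per_cp <- purrr::map(run$snapshots, function(snap) {
      acc <- snapshot_accuracy(snap, stimuli)
      rsa <- purrr::map(c(dg = "dg", ca3 = "ca3", ca1 = "ca1"),
                        function(l) rsa_matrix(snap[[l]]))
      list(checkpoint = snap$checkpoint, acc = acc, rsa = rsa,
           ec_out = snap$ec_out,
           act_frac = snapshot_active_fraction(snap))
    })
    list(batch = b, per_cp = per_cp)
  })

  acc_tbl <- purrr::map_dfr(batches, function(bt) {
    purrr::map_dfr(bt$per_cp, function(cp) {
      tibble::tibble(batch = bt$batch, condition = condition,
                     checkpoint = cp$checkpoint,
                     stimulus_id = names(cp$acc), accuracy = unname(cp$acc))
    })
  })
  acc_tbl$role <- unname(role_map[acc_tbl$stimulus_id])
  acc_tbl$category <- unname(cat_map[acc_tbl$stimulus_id])

  rsa_tbl <- purrr::map_dfr(batches, function(bt) {
    purrr::map_dfr(bt$per_cp, function(cp) {
      tibble::tibble(batch = bt$batch, condition = condition,
                     checkpoint = cp$checkpoint,
                     subfield = c("DG", "CA3", "CA1"),
                     matrix = list(cp$rsa$dg, cp$rsa$ca3, cp$rsa$ca1))
    })
  })
  sparsity_tbl <- purrr::map_dfr(batches, function(bt) {
    purrr::map_dfr(bt$per_cp, function(cp) {
      tibble::tibble(batch = bt$batch, condition = condition,
                     checkpoint = cp$checkpoint,
                     subfield = c("DG", "CA3", "CA1"),
                     active_fraction = unname(cp$act_frac))
    })
  })
  ec_out_tbl <- purrr::map_dfr(batches, function(bt) {
    purrr::map_dfr(bt$per_cp, function(cp) {
      tibble::tibble(batch = bt$batch, condition = condition,
                     checkpoint = cp$checkpoint, ec_out = list(cp$ec_out))
    })
  })
  structure(list(accuracy = acc_tbl, rsa = rsa_tbl, sparsity = sparsity_tbl,
                 ec_out = ec_out_tbl, condition = condition,
                 n_batches = n_batches, base_seed = base_seed,
                 params = params, checkpoints = checkpoints,
                 stimuli = stimuli),
            class = "hc_ensemble")
}

#' @export
print.hc_ensemble <- function(x, ...) {
  cat("<hc_ensemble> condition:", x$condition,
      "| batches:", x$n_batches,
      "| checkpoints:", paste(x$checkpoints, collapse = ", "), "\n")
  invisible(x)
}
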