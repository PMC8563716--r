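#' Convert a similarity matrix to a dissimilarity matrix
#'
#' Default transform `d = 1 - r` (bounded, monotone-decreasing, the
#' standard choice for correlation-based representational analysis); the
#' diagonal is forced to zero and the transform recorded as an attribute.
#'
#' @param matrix 10 x 10 Pearson similarity matrix.
#' @return Nonnegative symmetric dissimilarity matrix with zero diagonal
#'   and attribute `transform = "1 - r"`.
#' @export
to_dissimilarity <- function(matrix) {
  d <- 1 - matrix
  d <- (d + t(d)) / 2
  diag(d) <- 0
  attr(d, "transform") <- "1 - r"
  d
}

#' Sammon mapping into two dimensions
#'
#' Minimizes Sammon stress
#' `E = (1 / sum(delta)) * sum((delta - d)^2 / delta)` over 2-D point
#' configurations, where `delta` are the input dissimilarities and `d` the
#' embedded Euclidean distances.  The fit starts from the classical metric
#' scaling (principal coordinates) solution and is refined by iterative
#' descent, making the map deterministic for a given input; `seed` is used
#' only when zero off-diagonal dissimilarities must be jittered.
#'
#' @param d Symmetric dissimilarity matrix with zero diagonal.
#' @param seed RNG seed for the jitter fallback.
#' @param max_iter Maximum descent iterations.
#' @param tol Convergence tolerance on the stress.
#' @param zero_action `"jitter"` replaces zero off-diagonal entries with a
#'   small positive value; `"fail"` raises an error.
#' @return A list of class `sammon_config`: `points` (10 x 2 matrix,
#'   rownames preserved), `stress`, `n_points`.
#' @export
sammon_map <- function(d, seed = 1L, max_iter = 200L, tol = 1e-9,
                       zero_action = c("jitter", "fail")) {
  zero_action <- match.arg(zero_action)
  d <- as.matrix(d)
  stopifnot(nrow(d) == ncol(d), all(abs(d - t(d)) < 1e-12))
  off <- d[upper.tri(d)]
  if (any(off == 0)) {
    if (zero_action == "fail")
      stop("zero off-diagonal dissimilarity: Sammon stress undefined", call. = FALSE)
    eps <- max(1e-6, min(off[off > 0], na.rm = TRUE) * 1e-3)
    rng <- local_seed_state(seed)
    d[d == 0] <- eps * stats::runif(sum(d == 0), 0.5, 1.5)
    restore_seed_state(rng)
    d <- (d + t(d)) / 2
    diag(d) <- 0
  }
  init <- stats::cmdscale(d, k = 2L)
  if (ncol(init) < 2L) init <- cbind(init, 0)
  # cmdscale can return duplicate rows for symmetric inputs; sammon requires
  # distinct starting points
  if (anyDuplicated(round(init, 10))) {
    rng <- local_seed_state(seed)
    init <- init + matrix(stats::rnorm(length(init), 0, 1e-4 + stats::sd(init)), nrow(init))
    restore_seed_state(rng)
  }
  fit <- MASS::sammon(stats::as.dist(d), y = init, k = 2L,
                      niter = max_iter, tol = tol, trace = FALSE)
  structure(list(points = fit$points, stress = fit$stress,
                 n_points = nrow(d)),
            class = "sammon_config")
}

#' Sammon stress of a given 2-D configuration
#'
#' @param points n x 2 coordinate matrix.
#' @param d n x n dissimilarity matrix.
#' @return The Sammon stress value.
#' @export
sammon_stress <- function(points, d) {
  dd <- as.matrix(stats::dist(points))
  ut <- upper.tri(d)
  delta <- d[ut]
  sum((delta - dd[ut])^2 / delta) / sum(delta)
}

#' Procrustes alignment of one configuration to a reference
#'
#' Least-squares superimposition allowing translation, isotropic scaling,
#' rotation and reflection (reflections are permitted: the goal is visual
#' comparability of configurations).  The disparity is the symmetric
#' normalized sum of squared residuals (both configurations centred and
#' scaled to unit norm), so it is invariant to the scale of either input.
#'
#' @param config A `sammon_config` or an n x 2 coordinate matrix.
#' @param reference The reference configuration (same point count/order).
#' @return A list of class `procrustes_config`: `points` (aligned
#'   coordinates in the reference frame), `disparity`, `rotation`,
#'   `scale`, `translation`.
#' @export
procrustes_align <- function(config, reference) {
  X <- if (inherits(reference, "sammon_config")) reference$points else as.matrix(reference)
  Y <- if (inherits(config, "sammon_config")) config$points else as.matrix(config)
  stopifnot(nrow(X) == nrow(Y), ncol(X) == ncol(Y))
  if (all(apply(X, 2L, stats::sd) == 0))
    stop("degenerate reference: all points coincident", call. = FALSE)
  fit <- vegan::procrustes(X, Y, scale = TRUE, symmetric = FALSE)
  sym <- vegan::procrustes(X, Y, scale = TRUE, symmetric = TRUE)
  pts <- fit$Yrot
  # place the aligned centroid on the reference centroid (the optimal
  # translation)
  pts <- sweep(pts, 2L, colMeans(X) - colMeans(pts), "+")
  dimnames(pts) <- dimnames(Y)
  structure(list(points = pts, disparity = sym$ss,
                 rotation = fit$rotation, scale = fit$scale,
                 translation = fit$translation),
            class = "procrustes_config")
}

#' Procrustes-aligned Sammon trajectory across checkpoints
#'
#' For one subfield and condition, takes the ensemble-mean similarity
#' matrix at every checkpoint, Sammon-maps each into 2-D, and aligns every
#' configuration to the end-of-learning (trial 144) configuration so that
#' representational change over learning can be read as point
#' displacement.
#'
#' @param ensemble An [run_batches()] ensemble.
#' @param subfield `"DG"`, `"CA3"` or `"CA1"`.
#' @param checkpoints Checkpoint schedule (defaults to the ensemble's).
#' @param seed Seed passed to [sammon_map()].
#' @return A tibble of class `hc_trajectory`: `checkpoint`, `stimulus_id`,
#'   `x`, `y`, `stress`, `disparity` (alignment residual to the final
#'   configuration).
#' @export
trajectory <- function(ensemble, subfield = "CA1",
                       checkpoints = ensemble$checkpoints, seed = 1L) {
  avail <- sort(unique(ensemble$rsa$checkpoint))
  missing_cp <- setdiff(checkpoints, avail)
  if (length(missing_cp) > 0L) {
    message("missing checkpoints dropped from trajectory: ",
            paste(missing_cp, collapse = ", "))
    checkpoints <- intersect(checkpoints, avail)
  }
  checkpoints <- sort(checkpoints)
  configs <- purrr::map(checkpoints, function(cp) {
    m <- mean_rsa_matrix(ensemble, subfield, cp)
    sammon_map(to_dissimilarity(m), seed = seed)
  })
  names(configs) <- checkpoints
  ref <- configs[[length(configs)]]
  out <- purrr::map2_dfr(configs, checkpoints, function(cf, cp) {
    al <- procrustes_align(cf, ref)
    tibble::tibble(checkpoint = cp,
                   stimulus_id = rownames(cf$points),
                   x = al$points[, 1L], y = al$points[, 2L],
                   stress = cf$stress, disparity = al$disparity)
  })
  attr(out, "subfield") <- subfield
  attr(out, "condition") <- ensemble$condition
  class(out) <- c("hc_trajectory", class(out))
  out
}

#' Displacement of each stimulus along a trajectory
#'
#' Euclidean distance between a stimulus's aligned position at
#' `from_checkpoint` and at the final checkpoint.
#'
#' @param traj An [trajectory()] tibble.
#' @param from_checkpoint Starting checkpoint (default the first).
#' @return Tibble: `stimulus_id`, `displacement`.
#' @export
trajectory_displacement <- function(traj, from_checkpoint = min(traj$checkpoint)) {
  last_cp <- max(traj$checkpoint)
  a <- dplyr::filter(traj, .data$checkpoint == from_checkpoint)
  b <- dplyr::filter(traj, .data$checkpoint == last_cp)
  m <- dplyr::inner_join(a, b, by = "stimulus_id", suffix = c("_a", "_b"))
  tibble::tibble(stimulus_id = m$stimulus_id,
                 displacement = sqrt((m$x_a - m$x_b)^2 + (m$y_a - m$y_b)^2))
}

#' Write a trajectory (or single configuration) to CSV
#'
#' Columns: stimulus_id, x, y, checkpoint, stress.
#'
#' @param traj An `hc_trajectory` tibble.
#' @param path File path.
#' @export
write_trajectory_csv <- function(traj, path) {
  readr::write_csv(as.data.frame(traj), path)
  invisible(path)
}
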