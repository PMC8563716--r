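test_that("the correlation-to-dissimilarity transform is the monotone 1 - r map", {
  r <- matrix(c(1, 0.5, -1, 0.5, 1, 0, -1, 0, 1), 3)
  d <- to_dissimilarity(r)
  expect_equal(diag(d), rep(0, 3))
  expect_equal(d[1, 3], 2)
  expect_equal(d[1, 2], 0.5)
  rs <- seq(-1, 1, by = 0.1)
  expect_true(all(diff(1 - rs) < 0))
  expect_equal(attr(d, "transform"), "1 - r")
})

test_that("exactly embeddable dissimilarities reach near-zero stress", {
  # planar square
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  d <- as.matrix(stats::dist(sq))
  fit <- sammon_map(d)
  expect_lt(fit$stress, 1e-6)
  # three equidistant points form an equilateral triangle
  d3 <- matrix(1, 3, 3); diag(d3) <- 0
  expect_lt(sammon_map(d3)$stress, 1e-6)
})

test_that("planar recovery is seed-independent", {
  set.seed(40)
  pts <- matrix(stats::rnorm(20), 10, 2)
  d <- as.matrix(stats::dist(pts))
  for (s in 1:10) expect_lt(sammon_map(d, seed = s)$stress, 1e-6)
})

test_that("tetrahedron stress matches a multi-restart brute-force optimizer", {
  d4 <- matrix(1, 4, 4); diag(d4) <- 0  # regular tetrahedron, not planar
  fit <- sammon_map(d4)
  # oracle: direct numerical minimization of the Sammon stress from many
  # random starts
  set.seed(41)
  best <- Inf
  for (i in 1:40) {
    obj <- function(v) sammon_stress(matrix(v, 4, 2), d4)
    o <- stats::optim(stats::rnorm(8), obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
    best <- min(best, o$value)
  }
  expect_equal(fit$stress, best, tolerance = 1e-3)
  expect_equal(sammon_stress(fit$points, d4), fit$stress, tolerance = 1e-6)
})

test_that("Sammon stress is invariant to rigid motion and global scale", {
  set.seed(42)
  pts <- matrix(stats::rnorm(20), 10, 2)
  d <- as.matrix(stats::dist(matrix(stats::rnorm(30), 10, 3)))
  s0 <- sammon_stress(pts, d)
  th <- 0.7; rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(sammon_stress(pts %*% rot, d), s0)
  expect_equal(sammon_stress(sweep(pts, 2, c(3, -2), "+"), d), s0)
  # global scaling of the dissimilarities leaves the optimal stress of the
  # rescaled configuration unchanged
  expect_equal(sammon_stress(pts * 2, d * 2), s0)
})

test_that("zero off-diagonal dissimilarities are jittered or rejected", {
  d <- matrix(1, 4, 4); diag(d) <- 0; d[1, 2] <- d[2, 1] <- 0
  expect_error(sammon_map(d, zero_action = "fail"), "zero off-diagonal")
  fit <- sammon_map(d, zero_action = "jitter", seed = 1L)
  expect_true(is.finite(fit$stress))
})

test_that("Procrustes alignment recovers similarity transforms exactly", {
  set.seed(43)
  ref <- matrix(stats::rnorm(20), 10, 2)
  th <- 1.1; rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- 1.7 * ref %*% rot + matrix(rep(c(5, -3), each = 10), 10, 2)
  al <- procrustes_align(moved, ref)
  expect_lt(al$disparity, 1e-10)
  expect_equal(al$points, ref, tolerance = 1e-8, ignore_attr = TRUE)
  # reflections are allowed
  refl <- ref %*% diag(c(-1, 1))
  expect_lt(procrustes_align(refl, ref)$disparity, 1e-10)
  expect_error(procrustes_align(ref, matrix(1, 10, 2)), "degenerate")
})

test_that("Procrustes disparity equals the closed-form optimum from the SVD", {
  set.seed(44)
  X <- matrix(stats::rnorm(20), 10, 2)
  Y <- matrix(stats::rnorm(20), 10, 2)
  al <- procrustes_align(Y, X)
  # independent closed form: standardize both configurations, then the
  # minimized residual is 1 - (sum of cross-covariance singular values)^2
  std <- function(m) {
    m <- scale(m, scale = FALSE)
    m / sqrt(sum(m^2))
  }
  sv <- svd(crossprod(std(X), std(Y)))$d
  expect_equal(al$disparity, 1 - sum(sv)^2, tolerance = 1e-10)
})

test_that("alignment does not change the Sammon stress of a configuration", {
  set.seed(45)
  d <- as.matrix(stats::dist(matrix(stats::rnorm(30), 10, 3)))
  fit <- sammon_map(d)
  ref <- matrix(stats::rnorm(20), 10, 2)
  al <- procrustes_align(fit, ref)
  # stress is computed on the aligned points relative to their own scale:
  # rescale by the fitted global factor before comparing
  centered <- scale(al$points, scale = FALSE)
  orig <- scale(fit$points, scale = FALSE)
  ratio <- sqrt(sum(centered^2) / sum(orig^2))
  expect_equal(sammon_stress(al$points / ratio, d), fit$stress,
               tolerance = 1e-8)
})

test_that("trajectories align every checkpoint to end of learning", {
  ens <- fixture_tiny_ensemble()
  tr <- trajectory(ens, "CA1")
  expect_equal(sort(unique(tr$checkpoint)), checkpoint_schedule("delayed"))
  expect_equal(nrow(tr), 8L * 10L)
  last <- tr[tr$checkpoint == 144L, ]
  expect_lt(max(last$disparity), 1e-10)
  disp <- trajectory_displacement(tr, from_checkpoint = 48L)
  expect_equal(nrow(disp), 10L)
  expect_true(all(disp$displacement >= 0))
  expect_message(trajectory(ens, "CA1", checkpoints = c(48L, 999L, 144L)),
                 "missing checkpoints")
})
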