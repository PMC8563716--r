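canon <- c("PA1", "PA2", "RA1", "RA2", "EA", "PB1", "PB2", "RB1", "RB2", "EB")

named_matrix <- function(m) {
  rownames(m) <- colnames(m) <- canon
  m
}

test_that("similarity matrices are Pearson correlations of activation rows", {
  set.seed(30)
  acts <- matrix(stats::runif(10 * 6), 10, 6, dimnames = list(canon, NULL))
  acts[2, ] <- acts[1, ]
  m <- rsa_matrix(acts)
  expect_equal(m[1, 2], 1)
  expect_true(isSymmetric(unname(m)))
  expect_true(all(diag(m) == 1))
  # orthogonal mean-centered rows correlate at zero
  acts2 <- rbind(c(1, -1, 1, -1), c(1, 1, -1, -1))
  expect_equal(stats::cor(acts2[1, ], acts2[2, ]), rsa_matrix(acts2)[1, 2])
  expect_equal(rsa_matrix(acts2)[1, 2], 0)
  # 3-unit toy vectors: hand-computed Pearson of (1,0,0) vs (0,1,0)
  toy <- rbind(c(1, 0, 0), c(0, 1, 0))
  expect_equal(rsa_matrix(toy)[1, 2], -0.5)
})

test_that("constant activation rows are flagged as missing with a warning", {
  acts <- matrix(stats::runif(30), 10, 3, dimnames = list(canon, NULL))
  acts[4, ] <- 0.7
  expect_warning(m <- rsa_matrix(acts), "constant")
  expect_true(all(is.na(m[4, ])))
  expect_false(anyNA(m[-4, -4]))
})

test_that("condition differences subtract elementwise and reject order mismatches", {
  set.seed(31)
  a <- named_matrix(matrix(stats::runif(100), 10))
  b <- named_matrix(matrix(stats::runif(100), 10))
  expect_equal(condition_difference(a, a), a - a)
  expect_equal(condition_difference(a, b), -condition_difference(b, a))
  b2 <- b[rev(canon), rev(canon)]
  expect_error(condition_difference(a, b2), "order mismatch")
})

test_that("intercategory similarity averages exactly the 25 cross-category cells", {
  m <- named_matrix(matrix(0, 10, 10))
  m[1:5, 6:10] <- 0.5; m[6:10, 1:5] <- 0.5; diag(m) <- 1
  expect_equal(intercategory_similarity(m), 0.5)
  blockdiag <- named_matrix(rbind(cbind(matrix(0.8, 5, 5), matrix(0, 5, 5)),
                                  cbind(matrix(0, 5, 5), matrix(0.8, 5, 5))))
  expect_equal(intercategory_similarity(blockdiag), 0)
  # independent oracle: explicit enumeration over (A, B) pairs
  set.seed(32)
  r <- matrix(stats::runif(100, -1, 1), 10); r <- (r + t(r)) / 2; diag(r) <- 1
  r <- named_matrix(r)
  pairs <- expand.grid(a = canon[1:5], b = canon[6:10],
                       stringsAsFactors = FALSE)
  manual <- mean(mapply(function(a, b) r[a, b], pairs$a, pairs$b))
  expect_equal(intercategory_similarity(r), manual)
  manual_intra <- mean(c(r[1:5, 1:5][upper.tri(diag(5))],
                         r[6:10, 6:10][upper.tri(diag(5))]))
  expect_equal(intracategory_similarity(r), manual_intra)
})

test_that("CRD follows its normalized-difference definition", {
  expect_equal(crd_value(0.5, 0.5), 0)
  expect_equal(crd_value(0.5, 0), 0.2)  # (1.5 - 1) / (1.5 + 1)
  expect_equal(crd_value(1, -1), 1)
  expect_error(crd_value(-1, -1), "degenerate")
  # monotone increasing in rho_intra, decreasing in rho_inter
  g <- seq(-0.99, 0.99, length.out = 100)
  for (fixed in c(-0.5, 0, 0.5)) {
    expect_true(all(diff(crd_value(g, fixed)) > 0))
    expect_true(all(diff(crd_value(fixed, g)) < 0))
    expect_equal(sign(crd_value(g, fixed)), sign(g - fixed))
  }
})

test_that("per-exception CRD uses self-excluded intra and full inter means", {
  set.seed(33)
  r <- matrix(stats::runif(100, -1, 1), 10); r <- (r + t(r)) / 2; diag(r) <- 1
  r <- named_matrix(r)
  rec <- crd(r, "EA")
  expect_equal(rec$rho_intra, mean(r["EA", c("PA1", "PA2", "RA1", "RA2")]))
  expect_equal(rec$rho_inter, mean(r["EA", canon[6:10]]))
  expect_equal(rec$crd, crd_value(rec$rho_intra, rec$rho_inter))
  rec_b <- crd(r, "EB")
  expect_equal(rec_b$rho_intra, mean(r["EB", c("PB1", "PB2", "RB1", "RB2")]))
})

test_that("rank-sum comparisons use the two-sample W convention", {
  same <- ranksum_compare(c(1, 2, 3), c(1, 2, 3))
  expect_gte(same$p_value, 0.99)
  # (1,2,3) vs (4,5,6): W counts pairs where x > y, so the most extreme
  # attainable value for n = 3,3 is 0; enumeration over all 20 rank splits
  # confirms 0 and 9 are the extremes
  splits <- utils::combn(6, 3)
  ws <- apply(splits, 2, function(ix) {
    x <- (1:6)[ix]; y <- (1:6)[-ix]
    sum(outer(x, y, ">"))
  })
  expect_equal(range(ws), c(0, 9))
  res <- ranksum_compare(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic_W, 0)
  expect_equal(res$n_early, 3L)
  expect_equal(res$median_delayed, 5)
  expect_warning(tied <- ranksum_compare(rep(1, 5), rep(1, 5)), "tied")
  expect_equal(tied$p_value, 1)
})

test_that("rank-sum detects a one-SD shift at the ensemble scale", {
  set.seed(34)
  for (i in 1:3) {
    x <- stats::rnorm(500)
    y <- stats::rnorm(500, mean = 1)
    expect_lt(ranksum_compare(x, y)$p_value, 0.001)
  }
})

test_that("ensemble CRD tables and mean matrices are well formed", {
  ens <- fixture_tiny_ensemble()
  tbl <- crd_table(ens)
  expect_equal(nrow(tbl), 5L * 3L * 2L)  # batches x subfields x exceptions
  expect_true(all(tbl$crd > -1 & tbl$crd < 1))
  m <- mean_rsa_matrix(ens, "CA1", 144L)
  expect_equal(dim(m), c(10L, 10L))
  expect_true(isSymmetric(unname(m), tol = 1e-12))
  expect_error(mean_rsa_matrix(ens, "CA1", 999L), "no matrices")
})
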