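snapshot_acc_one <- function(state, stim, id) {
  snap <- test_items(state, stim)
  hipporpe:::snapshot_accuracy(snap, stim)[[id]]
}

test_that("weight initialization is seed-deterministic with the full projection graph", {
  p <- hc_params()
  a <- init_network(p, seed = 1L)
  b <- init_network(p, seed = 1L)
  cc <- init_network(p, seed = 2L)
  expect_identical(a$weights, b$weights)
  expect_false(identical(a$weights, cc$weights))
  expect_setequal(names(a$weights),
                  c("in_dg", "in_ca3", "dg_ca3", "ca3_ca1", "in_ca1",
                    "out_ca1", "ca1_out", "out_in"))
  expect_equal(dim(a$weights$dg_ca3), c(p$n_dg, p$n_ca3))
  expect_true(all(vapply(a$weights, function(w) all(w >= 0 & w <= 1), logical(1))))
})

test_that("parameter validation enforces sparsity ordering and pathway rate ordering", {
  expect_error(hc_params(k_dg = 40L, n_dg = 100L), "sparsity")
  expect_error(hc_params(lr_tsp = 0.01, lr_msp = 0.02), "TSP")
  expect_error(hc_params(n_expect = 80L, n_cycles = 80L), "phase")
  # an all-zero learning schedule is allowed for diagnostics
  expect_s3_class(hc_params(lr_tsp = 0, lr_msp = 0, lr_out = 0), "hc_params")
})

test_that("settling with no drive leaves all free units silent", {
  st <- init_network(hc_params(), seed = 1L)
  st$weights <- lapply(st$weights, function(w) w * 0)
  acts <- settle(st, rep(0, 10))
  expect_true(all(unlist(acts) == 0))
})

test_that("k-WTA keeps the realized active fractions ordered DG < CA3 < CA1", {
  p <- hc_params()
  st <- init_network(p, seed = 4L)
  sizes <- c(dg = p$n_dg, ca3 = p$n_ca3, ca1 = p$n_ca1)
  set.seed(21)
  for (i in 1:100) {
    acts <- settle(st, stats::runif(10), n_cycles = 40L)
    frac <- vapply(names(sizes), function(l)
      sum(acts[[l]] > 0.5 * max(acts[[l]], 1e-12)) / sizes[[l]], numeric(1))
    expect_true(frac[["dg"]] < frac[["ca3"]])
    expect_true(frac[["ca3"]] < frac[["ca1"]])
  }
  # on the operating regime (stimulus cues), realized winner counts also
  # stay within ~10% of each layer's k (small-k layers get one tie's slack)
  enc <- encode_stimuli(fixture_stimuli())
  for (i in 1:10) {
    acts <- settle(st, as.numeric(enc[i, ]))
    for (l in names(sizes)) {
      k <- c(dg = p$k_dg, ca3 = p$k_ca3, ca1 = p$k_ca1)[[l]]
      expect_lte(sum(acts[[l]] > 0.5 * max(acts[[l]])), ceiling(1.1 * k) + 1L)
    }
  }
})

test_that("settling reaches a fixed point within the convergence tolerance", {
  stim <- fixture_stimuli()
  st <- init_network(hc_params(), seed = 2L)
  pat <- as.numeric(encode_stimuli(stim)["EA", ])
  a1 <- settle(st, pat)
  a2 <- settle(st, pat, init = a1)
  expect_lt(max(abs(unlist(a2) - unlist(a1))), 1e-4)
})

test_that("a null learning schedule leaves weights untouched", {
  p0 <- hc_params(lr_tsp = 0, lr_msp = 0, lr_out = 0, hebb = 0)
  st <- init_network(p0, seed = 3L)
  pat <- as.numeric(encode_stimuli(fixture_stimuli())["PA1", ])
  st2 <- train_trial(st, pat)
  expect_identical(st$weights, st2$weights)
  expect_equal(st2$trial_count, 1L)
})

test_that("repeated training of one pattern raises its readout accuracy", {
  stim <- fixture_stimuli()
  st <- init_network(hc_params(), seed = 5L)
  acc_before <- snapshot_acc_one(st, stim, "PB1")
  for (i in 1:20) st <- train_trial(st, as.numeric(encode_stimuli(stim)["PB1", ]))
  acc_after <- snapshot_acc_one(st, stim, "PB1")
  expect_gt(acc_after, acc_before)
  expect_true(all(vapply(st$weights, function(w) all(w >= 0 & w <= 1), logical(1))))
})

test_that("training is fully deterministic given seed and sequence", {
  stim <- fixture_stimuli()
  sq <- generate_learning_sequence(stim, "early", seed = 6L)
  r1 <- train_sequence(init_network(hc_params(), seed = 6L), sq, stim,
                       checkpoints = 144L)
  r2 <- train_sequence(init_network(hc_params(), seed = 6L), sq, stim,
                       checkpoints = 144L)
  expect_identical(r1$state$weights, r2$state$weights)
  expect_identical(r1$snapshots[[1]]$ec_out, r2$snapshots[[1]]$ec_out)
})

test_that("checkpoint probes are read-only and follow the schedules", {
  stim <- fixture_stimuli()
  sq_e <- generate_learning_sequence(stim, "early", seed = 8L)
  sq_d <- generate_learning_sequence(stim, "delayed", seed = 8L)
  run_e <- train_sequence(init_network(hc_params(), seed = 8L), sq_e, stim)
  run_d <- train_sequence(init_network(hc_params(), seed = 8L), sq_d, stim)
  expect_length(run_e$snapshots, 7L)
  expect_length(run_d$snapshots, 8L)
  # probing twice from the same state gives identical snapshots and no
  # weight change
  st <- run_e$state
  w_before <- st$weights
  s1 <- test_items(st, stim)
  s2 <- test_items(st, stim)
  expect_identical(st$weights, w_before)
  expect_identical(s1$ec_out, s2$ec_out)
  expect_equal(dim(s1$dg), c(10L, st$params$n_dg))
  # training with a mid-sequence checkpoint ends at the same weights as
  # training without one
  r_cp <- train_sequence(init_network(hc_params(), seed = 9L), sq_e, stim,
                         checkpoints = c(72L, 144L))
  r_no <- train_sequence(init_network(hc_params(), seed = 9L), sq_e, stim,
                         checkpoints = 144L)
  expect_identical(r_cp$state$weights, r_no$state$weights)
})

test_that("untrained networks read out at chance on average", {
  stim <- fixture_stimuli()
  accs <- vapply(1:50, function(s) {
    st <- init_network(hc_params(), seed = 4000L + s)
    mean(hipporpe:::snapshot_accuracy(test_items(st, stim), stim))
  }, numeric(1))
  expect_gt(mean(accs), 0.4)
  expect_lt(mean(accs), 0.6)
})
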