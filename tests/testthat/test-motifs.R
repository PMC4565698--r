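test_that("strict next-rank hierarchies give W(n) = n exactly", {
  m <- linear_matrix(7, wins = 3L)
  ord <- identity_order(m)
  for (n in 1:5) {
    w <- weighted_rank_difference(m, ord, n)
    expect_equal(w$W, n)
    expect_equal(w$chains, 7 - n)
  }
})

test_that("equal aggression toward everyone gives T(n) = 0", {
  m <- matrix(4, 6, 6, dimnames = list(paste0("I", 1:6), paste0("I", 1:6)))
  diag(m) <- 0
  for (n in 2:4) {
    expect_equal(fractional_transitivity(m, n)$T, 0, tolerance = 1e-12)
    expect_equal(fractional_transitivity(m, n, baseline = "first")$T, 0,
                 tolerance = 1e-12)
  }
})

test_that("an origin that never attacks chain terminals gives T(2) = -1", {
  ids <- c("A", "B", "C", "D")
  m <- matrix(0L, 4, 4, dimnames = list(ids, ids))
  m["A", "B"] <- 2L  # A's only 2-chain runs A -> B -> C
  m["B", "C"] <- 3L
  m["A", "D"] <- 5L  # A attacks elsewhere, so its baseline is positive
  expect_equal(fractional_transitivity(m, 2)$T, -1)
})

test_that("optimized enumeration equals the all-tuples reference", {
  set.seed(67)
  for (rep in 1:12) {
    n_ind <- sample(4:7, 1)
    n <- sample(1:min(5, n_ind - 1), 1)
    m <- random_matrix(n_ind)
    ord <- setNames(sample(n_ind), rownames(m))
    for (bl in c("interior", "first")) {
      fast_w <- weighted_rank_difference(m, ord, n)
      ref <- chain_stats_naive(m, ord, n, baseline = bl)
      expect_equal(fast_w$W, ref$W, tolerance = 1e-12)
      expect_equal(fast_w$total_weight, ref$total_weight, tolerance = 1e-12)
      if (n >= 2) {
        fast_t <- fractional_transitivity(m, n, baseline = bl)
        expect_equal(fast_t$T, ref$T, tolerance = 1e-12)
        expect_equal(fast_t$chains_excluded, ref$chains_excluded)
      }
    }
  }
})

test_that("W and T are invariant to integer rescaling of the matrix", {
  set.seed(71)
  m <- random_matrix(6, 1.5)
  ord <- identity_order(m)
  for (n in 2:4) {
    expect_equal(weighted_rank_difference(m * 3L, ord, n)$W,
                 weighted_rank_difference(m, ord, n)$W, tolerance = 1e-12)
    expect_equal(fractional_transitivity(m * 3L, n)$T,
                 fractional_transitivity(m, n)$T, tolerance = 1e-12)
  }
})

test_that("chains with repeated individuals are excluded", {
  # pure 2-cycle: the only walks of length 2 revisit the origin
  ids <- c("A", "B")
  m <- matrix(c(0L, 5L, 4L, 0L), 2, 2, byrow = TRUE,
              dimnames = list(ids, ids))
  # length-2 chains need 3 distinct individuals
  expect_error(weighted_rank_difference(m, setNames(1:2, ids), 2),
               "distinct individuals")
  m3 <- rbind(cbind(m, C = c(0L, 0L)), C = c(0L, 0L, 0L))
  colnames(m3) <- rownames(m3) <- c("A", "B", "C")
  w <- weighted_rank_difference(m3, setNames(1:3, colnames(m3)), 2)
  expect_false(w$defined)
  expect_equal(w$chains, 0)
})

test_that("the enumeration cap aborts with a clear error", {
  set.seed(73)
  m <- random_matrix(10, 3)
  expect_error(weighted_rank_difference(m, identity_order(m), 5,
                                        max_visits = 100),
               "max_visits")
})

test_that("the chain suite reports null bands and directions", {
  sim <- simulate_events(generator_config(N = 10, total_events = 600,
                                          phase_change_day = 0, seed = 79))
  m <- build_matrix(sim$log)
  ec <- ec_power(normalize_aggression(m))
  ord <- rank_order(ec)
  k <- fit_null_kernel(ec)
  ens <- sample_null_ensemble(k, rowSums(m), B = 30, seed = 81)
  cs <- chain_statistics_suite(m, ord, ens, max_n = 3)
  expect_equal(cs$n, 1:3)
  expect_true(is.na(cs$T[1]))
  expect_true(all(is.finite(cs$W)))
  expect_true(all(is.finite(cs$T[2:3])))
  expect_true(all(cs$W_p > 0 & cs$W_p <= 1))
  expect_true(all(cs$W_dir %in% c("greater", "less")))
  expect_equal(attr(cs, "B"), 30)
})
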