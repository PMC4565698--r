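test_that("normalization yields row-stochastic matrices with zero diagonal", {
  m <- matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("A", "B")))
  t0 <- normalize_aggression(m, epsilon = 0)
  expect_equal(t0["A", "B"], 1)
  expect_equal(t0["B", "A"], 1)

  z <- matrix(0, 4, 4, dimnames = list(paste0("I", 1:4), paste0("I", 1:4)))
  tz <- normalize_aggression(z, epsilon = 0.5)
  expect_true(all(abs(tz[row(tz) != col(tz)] - 1 / 3) < 1e-12))
  expect_error(normalize_aggression(z, epsilon = 0), "epsilon > 0")

  set.seed(5)
  t3 <- normalize_aggression(random_matrix(3), epsilon = 0.01)
  expect_equal(rowSums(t3), c(I1 = 1, I2 = 1, I3 = 1))
  expect_true(all(diag(t3) == 0))
})

test_that("EC power is the stationary distribution of the aggression chain", {
  # symmetric uniform aggression -> uniform scores
  u <- matrix(2, 5, 5, dimnames = list(paste0("I", 1:5), paste0("I", 1:5)))
  diag(u) <- 0
  v <- ec_power(normalize_aggression(u, 0.01))
  expect_equal(unname(v$score), rep(0.2, 5), tolerance = 1e-12)

  # two individuals always split evenly
  m2 <- matrix(c(0, 7, 2, 0), 2, 2, byrow = TRUE,
               dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(unname(ec_power(normalize_aggression(m2, 0.01))$score),
               c(0.5, 0.5), tolerance = 1e-12)

  # matches the dense linear-solve oracle on random matrices
  set.seed(13)
  for (rep in 1:5) {
    t_mat <- normalize_aggression(random_matrix(4, 2), 0.01)
    v <- ec_power(t_mat)
    expect_equal(unname(v$score), unname(stationary_oracle(t_mat)),
                 tolerance = 1e-10)
    expect_equal(sum(v$score), 1, tolerance = 1e-12)
  }
})

test_that("EC power is permutation-equivariant", {
  set.seed(17)
  m <- random_matrix(6, 2)
  v <- ec_power(normalize_aggression(m, 0.01))$score
  perm <- sample(6)
  mp <- m[perm, perm]
  vp <- ec_power(normalize_aggression(mp, 0.01))$score
  expect_equal(vp[names(v)], v, tolerance = 1e-12)
})

test_that("regularized EC converges to the unregularized limit", {
  set.seed(19)
  m <- random_matrix(5, 3) + 1  # strictly positive: irreducible at eps = 0
  diag(m) <- 0
  v0 <- ec_power(normalize_aggression(m, 0))$score
  errs <- vapply(c(1e-2, 1e-4, 1e-6), function(eps) {
    max(abs(ec_power(normalize_aggression(m, eps))$score - v0))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-6)
})

test_that("WSC multiplies incoming aggression by distinct aggressors", {
  ids <- paste0("I", 1:4)
  m <- matrix(0L, 4, 4, dimnames = list(ids, ids))
  m["I1", "I3"] <- 3; m["I2", "I3"] <- 2   # I3: 5 events from 2 aggressors
  w <- wsc_power(m)
  expect_equal(w$score[["I3"]], 10)
  expect_equal(w$score[["I4"]], 0)

  # matches an exhaustive per-individual computation on random matrices
  set.seed(23)
  mm <- random_matrix(4)
  ws <- wsc_power(mm)$score
  for (j in 1:4) {
    expect_equal(ws[[j]], sum(mm[, j]) * sum(mm[, j] > 0))
  }
})

test_that("David's Score matches its defining win-proportion sums", {
  # perfectly symmetric aggression -> all scores zero
  s <- matrix(3, 4, 4, dimnames = list(paste0("I", 1:4), paste0("I", 1:4)))
  diag(s) <- 0
  expect_equal(unname(davids_score(s)$score), rep(0, 4))

  # dyad: A beats B 3-1 gives DS_A = 1/2 = -DS_B
  d2 <- matrix(c(0, 3, 1, 0), 2, 2, byrow = TRUE,
               dimnames = list(c("A", "B"), c("A", "B")))
  ds2 <- davids_score(d2)$score
  expect_equal(ds2[["A"]], 0.5)
  expect_equal(ds2[["B"]], -0.5)

  # loop-based oracle on a random 4-individual group
  set.seed(29)
  m <- random_matrix(4, 2)
  ds <- davids_score(m)$score
  n <- 4
  p <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    tot <- m[i, j] + m[j, i]
    if (i != j && tot > 0) p[i, j] <- m[i, j] / tot
  }
  for (i in 1:n) {
    w <- sum(p[i, ]); l <- sum(p[, i])
    w2 <- sum(p[i, ] * rowSums(p)); l2 <- sum(p[, i] * colSums(p))
    expect_equal(ds[[i]], w + w2 - l - l2)
  }
})

test_that("rank order puts the most dominant individual first", {
  ids <- c("A", "B", "C")
  ec <- aggrank:::new_power_scores(setNames(c(0.5, 0.2, 0.3), ids), "ec",
                                   TRUE)
  expect_equal(rank_order(ec), setNames(c(3L, 1L, 2L), ids),
               ignore_attr = TRUE)
  ds <- aggrank:::new_power_scores(setNames(c(5, -1, 2), ids), "ds", FALSE)
  expect_equal(rank_order(ds), setNames(c(1L, 3L, 2L), ids),
               ignore_attr = TRUE)
  # ties break by stable roster order
  tie <- aggrank:::new_power_scores(setNames(c(1, 1, 0), ids), "wsc", TRUE)
  expect_equal(rank_order(tie), setNames(c(2L, 3L, 1L), ids),
               ignore_attr = TRUE)
})

test_that("rank agreement reports signed r-squared in both directions", {
  ids <- paste0("I", 1:6)
  a <- aggrank:::new_power_scores(setNames(1:6 / 21, ids), "ec", TRUE)
  same <- rank_agreement(a, a)
  expect_equal(same$pearson_r, 1)
  expect_equal(same$signed_r2, 1)
  b <- aggrank:::new_power_scores(setNames(rev(1:6 / 21), ids), "wsc", TRUE)
  opp <- rank_agreement(a, b)
  expect_equal(opp$pearson_r, -1)
  expect_equal(opp$signed_r2, -1)
  expect_equal(opp$signed_rho2, -1)
  # constant scoring flagged, not an error
  cst <- aggrank:::new_power_scores(setNames(rep(1, 6), ids), "wsc", TRUE)
  expect_true(rank_agreement(a, cst)$degenerate)
})

test_that("EC and WSC agree strongly on a structured synthetic group", {
  sim <- simulate_events(generator_config(N = 20, total_events = 1200,
                                          phase_change_day = 0, seed = 31))
  m <- build_matrix(sim$log)
  agr <- rank_agreement(ec_power(normalize_aggression(m)), wsc_power(m))
  expect_gt(agr$signed_r2, 0.5)
})

test_that("bootstrap is deterministic and degenerates correctly", {
  # a single repeated dyadic event: resampling cannot change the matrix
  mono <- aggression_log(ev_df(1:10, rep("A", 10), rep("B", 10)),
                         t_obs_min = 10)
  bp <- bootstrap_power(mono, B = 20, seed = 4)
  expect_equal(bp$boot_sd, c(0, 0))
  expect_equal(bp$rank_sd, c(0, 0))

  sim <- simulate_events(generator_config(N = 10, total_events = 400,
                                          phase_change_day = 0, seed = 37))
  b1 <- bootstrap_power(sim$log, B = 30, seed = 99)
  b2 <- bootstrap_power(sim$log, B = 30, seed = 99)
  expect_identical(b1, b2)

  # strong hierarchy: the top-ranked individual's modal bootstrap rank is 1
  top <- b1$id[b1$rank == 1]
  expect_equal(b1$rank_modal[b1$id == top], 1L)

  empty <- aggression_log(ev_df(numeric(0), character(0), character(0)),
                          roster = c("A", "B"), t_obs_min = 5)
  expect_error(bootstrap_power(empty, B = 10), "empty")
})
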