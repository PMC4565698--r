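test_that("CSV event logs parse, validate and sort", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,actor,target", "30,A,B", "10,B,C", "20,A,C"), path)
  log <- read_event_log(path)
  expect_s3_class(log, "aggression_log")
  expect_equal(nrow(log$events), 3)
  expect_equal(log$roster, c("A", "B", "C"))
  expect_equal(log$events$time, c(10, 20, 30))

  writeLines(c("time,actor,target", "10,A,B", "20,B,B"), path)
  expect_error(read_event_log(path), "row\\(s\\): 2")

  writeLines(c("time,actor", "10,A"), path)
  expect_error(read_event_log(path), "missing column")

  writeLines(c("time,actor,target", "10,A,B", "20,Z,A"), path)
  expect_error(read_event_log(path, roster = c("A", "B")), "not in roster")
})

test_that("ISO-8601 timestamps become seconds since observation start", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,actor,target",
               "2024-05-01T06:00:00,A,B",
               "2024-05-01T06:01:30,B,A"), path)
  log <- read_event_log(path)
  expect_equal(log$events$time, c(0, 90))
})

test_that("win cooldown collapses barrages and respects ordered pairs", {
  # a string of 6 sub-attacks within 10 s scores a single win
  barrage <- aggression_log(
    ev_df(seq(0, 10, by = 2), rep("A", 6), rep("B", 6)),
    roster = c("A", "B"), t_obs_min = 10
  )
  expect_equal(nrow(apply_win_cooldown(barrage, 60)$events), 1)

  # a cessation of >= 60 s re-arms the win
  gap <- aggression_log(ev_df(c(0, 61), c("A", "A"), c("B", "B")),
                        t_obs_min = 10)
  expect_equal(nrow(apply_win_cooldown(gap, 60)$events), 2)

  # distinct ordered pairs have independent clocks
  pairs <- aggression_log(
    ev_df(c(5, 5, 6), c("A", "A", "B"), c("B", "C", "A")),
    t_obs_min = 10
  )
  expect_equal(nrow(apply_win_cooldown(pairs, 60)$events), 3)
})

test_that("cooldown is conservative and idempotent", {
  set.seed(7)
  n <- 200
  ev <- ev_df(sort(runif(n, 0, 3600)),
              sample(LETTERS[1:4], n, TRUE), sample(LETTERS[5:8], n, TRUE))
  log <- aggression_log(ev, t_obs_min = 60)
  once <- apply_win_cooldown(log, 60)
  expect_equal(nrow(once$events) + attr(once, "n_removed"), n)
  twice <- apply_win_cooldown(once, 60)
  expect_equal(twice$events, once$events)
})

test_that("window splitting produces half-open study quarters", {
  set.seed(11)
  n <- 120
  ev <- ev_df(sort(runif(n, 0, 24 * 86400)),
              sample(c("A", "B", "C"), n, TRUE),
              sample(c("D", "E", "F"), n, TRUE))
  log <- aggression_log(ev, t_obs_min = 24 * 1440)
  quarters <- split_windows(log, 6)
  expect_length(quarters, 4)
  expect_named(quarters, c("Q1", "Q2", "Q3", "Q4"))
  expect_equal(sum(vapply(quarters, function(w) nrow(w$events), numeric(1))),
               n)
  # per-window observation time proportional to window length
  expect_true(all(vapply(quarters, function(w) w$t_obs_min, numeric(1)) ==
                    6 * 1440))
  # window matrices sum to the whole-log matrix
  whole <- build_matrix(log)
  parts <- Reduce(`+`, lapply(quarters, build_matrix))
  expect_equal(unclass(parts), unclass(whole), ignore_attr = TRUE)

  # whole-study window is the identity
  one <- split_windows(log, 24)
  expect_length(one, 1)
  expect_equal(one[[1]]$events, log$events)

  expect_error(split_windows(log, 7), "not a multiple")
  expect_length(split_windows(log, 7, force = TRUE), 4)
})

test_that("boundary events belong to the later window", {
  log <- aggression_log(ev_df(c(0, 6 * 86400), c("A", "A"), c("B", "B")),
                        t_obs_min = 12 * 1440)
  wins <- split_windows(log, 6)
  expect_equal(nrow(wins$Q1$events), 1)
  expect_equal(nrow(wins$Q2$events), 1)
  expect_equal(wins$Q2$events$time, 0)  # re-based to window start
})

test_that("excluding individuals drops their events but not observation time", {
  ids <- paste0("P", 1:19)
  set.seed(3)
  n <- 100
  ab <- t(replicate(n, sample(ids, 2)))
  log <- aggression_log(ev_df(sort(runif(n, 0, 1000)), ab[, 1], ab[, 2]),
                        roster = ids, t_obs_min = 100)
  out <- exclude_individuals(log, "P7")
  expect_length(out$roster, 18)
  expect_false(any(c(out$events$actor, out$events$target) == "P7"))
  expect_equal(out$t_obs_min, log$t_obs_min)
  expect_equal(exclude_individuals(log, character(0)), log)
  expect_error(exclude_individuals(log, "ZZ"), "not in roster")
})

test_that("win matrices tally events with a zero diagonal", {
  log <- toy_log3()
  m <- build_matrix(log)
  expect_equal(m["A", "B"], 2L, ignore_attr = TRUE)
  expect_equal(m["B", "A"], 1L, ignore_attr = TRUE)
  expect_equal(sum(m), nrow(log$events))
  expect_true(all(diag(m) == 0))

  empty <- aggression_log(ev_df(numeric(0), character(0), character(0)),
                          roster = c("A", "B"), t_obs_min = 10)
  expect_true(all(build_matrix(empty) == 0))

  # invariant to permutations of equal-time events
  ev <- ev_df(rep(5, 4), c("A", "B", "A", "C"), c("B", "A", "C", "A"))
  m1 <- build_matrix(aggression_log(ev, t_obs_min = 1))
  m2 <- build_matrix(aggression_log(ev[c(3, 1, 4, 2), ], t_obs_min = 1))
  expect_identical(m1, m2)
})

test_that("directed density counts ordered pairs with any aggression", {
  full <- matrix(1, 3, 3); diag(full) <- 0
  expect_equal(network_density(full), 1)
  expect_equal(network_density(matrix(0, 4, 4)), 0)
  # exactly 3 of the 6 ordered pairs nonzero
  half <- matrix(0, 3, 3)
  half[1, 2] <- 2; half[2, 1] <- 1; half[3, 1] <- 4
  expect_equal(network_density(half), 0.5)
  expect_error(network_density(matrix(0, 1, 1)), "at least 2")
})
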