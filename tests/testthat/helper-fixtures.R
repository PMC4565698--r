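# Small in-code fixtures shared across tests.

# Event table helper
ev_df <- function(time, actor, target) {
  data.frame(time = time, actor = actor, target = target,
             stringsAsFactors = FALSE)
}

# A 3-individual log: A beats B twice, B beats A once, spread over a day
toy_log3 <- function() {
  aggression_log(
    ev_df(c(100, 200, 5000), c("A", "B", "A"), c("B", "A", "B")),
    roster = c("A", "B", "C"), t_obs_min = 1440
  )
}

# Random win-count matrix with roster dimnames
random_matrix <- function(n, lambda = 1.2) {
  m <- matrix(rpois(n * n, lambda), n, n)
  diag(m) <- 0
  dimnames(m) <- list(paste0("I", seq_len(n)), paste0("I", seq_len(n)))
  m
}

# Strict next-rank-only hierarchy: rank r attacks only rank r + 1
linear_matrix <- function(n, wins = 1L) {
  ids <- paste0("I", seq_len(n))
  m <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (r in seq_len(n - 1)) m[r, r + 1] <- wins
  m
}

identity_order <- function(m) {
  setNames(seq_len(nrow(m)), rownames(m))
}

# Independent stationary-distribution oracle: solve the linear system
# v' (T - I) = 0 with the sum-to-one constraint replacing one equation.
stationary_oracle <- function(t_mat) {
  n <- nrow(t_mat)
  a <- t(t_mat) - diag(n)
  a[n, ] <- 1
  b <- c(rep(0, n - 1), 1)
  solve(a, b)
}
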