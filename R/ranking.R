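#' Row-normalize a win-count matrix with regularization
#'
#' Converts win counts into transition weights
#' \eqn{t_{ij} = (d_{ij} + \epsilon) / \sum_{k \ne i}(d_{ik} + \epsilon)}
#' with a zero diagonal, so each row is a probability distribution over
#' targets. The regularizer \eqn{\epsilon > 0} guarantees irreducibility of
#' the induced chain (every individual reaches every other), which the
#' power-score computation requires; it should stay well below typical row
#' totals. The regularizer is added only to off-diagonal entries.
#'
#' @param m win-count matrix.
#' @param epsilon regularizer (default 0.01). `epsilon = 0` is allowed only
#'   when every individual has at least one win.
#' @return Row-stochastic matrix with attribute `"epsilon"`.
#' @export
normalize_aggression <- function(m, epsilon = 0.01) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m), nrow(m) >= 2,
            all(m >= 0), epsilon >= 0)
  n <- nrow(m)
  t_mat <- m + epsilon
  diag(t_mat) <- 0
  rs <- rowSums(t_mat)
  if (any(rs == 0)) {
    stop("row(s) with no aggression and epsilon = 0: ",
         paste(rownames(m)[rs == 0], collapse = ", "),
         "; use epsilon > 0")
  }
  t_mat <- t_mat / rs
  attr(t_mat, "epsilon") <- epsilon
  t_mat
}

# Stationary distribution of a row-stochastic matrix: dense eigen
# decomposition of the transpose for small systems, power iteration above.
stationary_distribution <- function(t_mat, tol = 1e-12, max_iter = 1e5) {
  n <- nrow(t_mat)
  if (n <= 64L) {
    e <- eigen(t(t_mat))
    i <- which.min(abs(e$values - 1))
    if (abs(e$values[i] - 1) > 1e-8) {
      stop("no unit eigenvalue: matrix is not row-stochastic?")
    }
    v <- Re(e$vectors[, i])
    v <- v / sum(v)
    if (any(v < -1e-10)) {
      stop("stationary distribution not unique (reducible chain); ",
           "regularize with epsilon > 0")
    }
    v[v < 0] <- 0
    v / sum(v)
  } else {
    v <- rep(1 / n, n)
    for (it in seq_len(max_iter)) {
      v_new <- as.vector(v %*% t_mat)
      v_new <- v_new / sum(v_new)
      if (max(abs(v_new - v)) < tol) return(v_new)
      v <- v_new
    }
    stop("power iteration did not converge in ", max_iter, " iterations")
  }
}

new_power_scores <- function(score, method, higher_is_lower_rank,
                             epsilon = NA_real_) {
  structure(
    list(score = score, method = method,
         higher_is_lower_rank = higher_is_lower_rank, epsilon = epsilon),
    class = "power_scores"
  )
}

#' @export
print.power_scores <- function(x, ...) {
  cat("power_scores (", toupper(x$method), "), ", length(x$score),
      " individuals; higher score = ",
      if (x$higher_is_lower_rank) "lower" else "higher", " rank\n", sep = "")
  print(round(x$score, 4))
  invisible(x)
}

#' Eigenvector-centrality power scores
#'
#' Power is scored as the stationary distribution of the row-normalized
#' aggression chain: the unique probability vector `v` with
#' \eqn{v_i = \sum_j v_j t_{ji}}. Centrality accrues through *incoming*
#' aggression, recursively: an individual has low power if it receives much
#' aggression from individuals who themselves have low power. High score
#' therefore equates to low power (rank 1, the most dominant individual,
#' has the smallest score). Note the fixed-point condition is the stationary
#' equation of the chain, not the row-wise average
#' \eqn{v_i = \sum_j t_{ij} v_j}, which is degenerate for a row-stochastic
#' matrix (its only solution is uniform) and cannot express the recursive
#' incoming-aggression semantics.
#'
#' @param t_mat row-stochastic matrix from [normalize_aggression()]. With
#'   `epsilon = 0` the chain can be reducible, in which case an error
#'   advises regularizing.
#' @return A `power_scores` object with method `"ec"`; scores sum to 1.
#' @export
ec_power <- function(t_mat) {
  stopifnot(is.matrix(t_mat), nrow(t_mat) == ncol(t_mat))
  if (max(abs(rowSums(t_mat) - 1)) > 1e-8) {
    stop("matrix is not row-stochastic; use normalize_aggression() first")
  }
  eps <- attr(t_mat, "epsilon")
  if (is.null(eps)) eps <- NA_real_
  v <- stationary_distribution(t_mat)
  names(v) <- rownames(t_mat)
  new_power_scores(v, "ec", higher_is_lower_rank = TRUE, epsilon = eps)
}

#' Weighted Simple Consensus power scores
#'
#' A breadth measure: the product of the total incoming aggression an
#' individual receives and the number of distinct individuals who directed
#' it. Higher WSC equates to lower rank. Unlike depth measures it ignores
#' who the aggressors are, making it a candidate cognitively-accessible
#' signal of rank.
#'
#' @param m win-count matrix.
#' @return A `power_scores` object with method `"wsc"`.
#' @export
wsc_power <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  incoming <- colSums(m)
  n_aggressors <- colSums(m > 0)
  score <- incoming * n_aggressors
  names(score) <- colnames(m)
  new_power_scores(score, "wsc", higher_is_lower_rank = TRUE)
}

#' David's Score
#'
#' The standard depth-two dominance score based on dyadic win proportions
#' \eqn{P_{ij} = d_{ij} / (d_{ij} + d_{ji})} (dyads with no interaction
#' contribute nothing): \eqn{DS_i = w_i + w2_i - l_i - l2_i} with
#' \eqn{w_i = \sum_j P_{ij}}, \eqn{w2_i = \sum_j P_{ij} w_j},
#' \eqn{l_i = \sum_j P_{ji}} and \eqn{l2_i = \sum_j P_{ji} l_j}. It reaches
#' two steps into the network (my targets' targets; my aggressors'
#' aggressors). Higher DS = higher rank, the opposite orientation to the
#' centrality and consensus scores.
#'
#' @param m win-count matrix.
#' @return A `power_scores` object with method `"ds"`.
#' @export
davids_score <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  n_mat <- m + t(m)
  p <- ifelse(n_mat > 0, m / ifelse(n_mat > 0, n_mat, 1), 0)
  diag(p) <- 0
  w <- rowSums(p)
  l <- colSums(p)
  w2 <- as.vector(p %*% w)
  l2 <- as.vector(t(p) %*% l)
  score <- w + w2 - l - l2
  names(score) <- rownames(m)
  new_power_scores(score, "ds", higher_is_lower_rank = FALSE)
}

#' Ordinal ranks from power scores
#'
#' Rank 1 is the most dominant individual: the lowest score for EC and WSC
#' (where high score = low power) and the highest score for David's Score.
#' Ties are broken by stable roster order and the policy is recorded in the
#' `"tie_policy"` attribute.
#'
#' @param ps a `power_scores` object.
#' @return Named integer vector of ranks `1..N` (a permutation).
#' @export
rank_order <- function(ps) {
  stopifnot(inherits(ps, "power_scores"))
  s <- ps$score
  ord <- order(if (ps$higher_is_lower_rank) s else -s)
  rk <- integer(length(s))
  rk[ord] <- seq_along(s)
  names(rk) <- names(s)
  attr(rk, "tie_policy") <- "stable roster order"
  rk
}

#' Agreement between two power scorings
#'
#' Pearson and Spearman correlations between two scorings of the same
#' roster, each also reported as a signed coefficient of determination
#' \eqn{sign(r) \cdot r^2} (so perfect anticorrelation gives -1). By
#' default scores are first aligned to a common orientation (higher score =
#' lower rank), so that two methods that induce the same ordering correlate
#' positively regardless of their native orientation.
#'
#' @param a,b `power_scores` objects on the same roster.
#' @param align flip scores to a common orientation first (default TRUE).
#' @return List with `pearson_r`, `spearman_rho`, `signed_r2`,
#'   `signed_rho2`, `n` and a `degenerate` flag set when either scoring is
#'   constant (correlation undefined).
#' @export
rank_agreement <- function(a, b, align = TRUE) {
  stopifnot(inherits(a, "power_scores"), inherits(b, "power_scores"))
  if (!identical(sort(names(a$score)), sort(names(b$score)))) {
    stop("scorings are on different rosters")
  }
  x <- a$score
  y <- b$score[names(x)]
  if (align) {
    if (!a$higher_is_lower_rank) x <- -x
    if (!b$higher_is_lower_rank) y <- -y
  }
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(pearson_r = NA_real_, spearman_rho = NA_real_,
                signed_r2 = NA_real_, signed_rho2 = NA_real_,
                n = length(x), degenerate = TRUE))
  }
  r <- cor(x, y)
  rho <- cor(x, y, method = "spearman")
  list(pearson_r = r, spearman_rho = rho,
       signed_r2 = sign(r) * r^2, signed_rho2 = sign(rho) * rho^2,
       n = length(x), degenerate = FALSE)
}

#' Bootstrap uncertainty for power scores and ranks
#'
#' Resamples the event list with replacement (keeping the event count),
#' re-scores each replicate end-to-end, and summarizes per-individual score
#' and rank variability. The 1-sigma score range is `mean ± sd` over
#' replicates.
#'
#' @param log an [aggression_log()].
#' @param B number of bootstrap replicates (at least 2).
#' @param method `"ec"`, `"wsc"` or `"ds"`.
#' @param epsilon regularizer for `method = "ec"`.
#' @param seed RNG seed.
#' @return data.frame with one row per individual: bootstrap mean, sd, and
#'   1-sigma bounds of the score, modal rank, rank sd, and the observed
#'   score and rank. Attribute `"B"` records the replicate count.
#' @export
bootstrap_power <- function(log, B = 500, method = c("ec", "wsc", "ds"),
                            epsilon = 0.01, seed = 1) {
  stopifnot(inherits(log, "aggression_log"), B >= 2)
  method <- match.arg(method)
  if (nrow(log$events) == 0L) stop("cannot bootstrap an empty log")
  score_fn <- switch(method,
    ec = function(m) ec_power(normalize_aggression(m, epsilon)),
    wsc = wsc_power,
    ds = davids_score
  )
  m_obs <- build_matrix(log)
  ps_obs <- score_fn(m_obs)
  rk_obs <- rank_order(ps_obs)
  n <- length(log$roster)
  scores <- matrix(NA_real_, B, n, dimnames = list(NULL, log$roster))
  ranks <- matrix(NA_integer_, B, n, dimnames = list(NULL, log$roster))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ev <- log$events
  for (b in seq_len(B)) {
    idx <- sample.int(nrow(ev), nrow(ev), replace = TRUE)
    lb <- aggression_log(ev[idx, , drop = FALSE], roster = log$roster,
                         t_obs_min = log$t_obs_min)
    ps <- score_fn(build_matrix(lb))
    scores[b, ] <- ps$score
    ranks[b, ] <- rank_order(ps)
  }
  modal_rank <- apply(ranks, 2, function(x) {
    tb <- table(x)
    as.integer(names(tb)[which.max(tb)])
  })
  out <- data.frame(
    id = log$roster,
    method = method,
    score = unname(ps_obs$score),
    rank = unname(rk_obs),
    boot_mean = colMeans(scores),
    boot_sd = apply(scores, 2, sd),
    rank_modal = modal_rank,
    rank_sd = apply(ranks, 2, sd),
    stringsAsFactors = FALSE
  )
  out$boot_lo <- out$boot_mean - out$boot_sd
  out$boot_hi <- out$boot_mean + out$boot_sd
  rownames(out) <- NULL
  attr(out, "B") <- B
  attr(out, "seed") <- seed
  out
}

# Save/restore the global RNG state so seeded helpers do not perturb the
# caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
}
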