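as_rank_vector <- function(order, ids) {
  if (!setequal(names(order), ids)) stop("rank order does not cover roster")
  as.integer(order[ids])
}

#' Weighted rank difference over aggression chains, W(n)
#'
#' An aggression chain of length `n` is a directed path
#' \eqn{i \to j \to \dots} of `n` nonzero aggression edges whose `n + 1`
#' individuals are pairwise distinct. `W(n)` is the mean rank difference
#' between a chain's originator and its terminal individual, weighted by
#' the product of the win counts along the chain; for `n = 2`,
#' \eqn{W(2) = \sum_{ijk} d_{ij} d_{jk} \Delta(i,k) / \sum_{ijk} d_{ij} d_{jk}}
#' over distinct triples. Rank differences are
#' `rank(terminal) - rank(origin)`, positive when the terminal individual
#' sits below the originator in the hierarchy. `n = 1` reduces to the
#' dyadic weighted mean rank difference of aggression. `W(n)` measures how
#' much information the mere observation of a chain carries about relative
#' rank.
#'
#' @param m win-count matrix.
#' @param order named rank vector from [rank_order()].
#' @param n chain length in edges (`1 <= n <= N - 1`).
#' @param max_visits safety cap on enumeration steps; the cost grows as
#'   `N!/(N-n-1)!`, so long chains in large dense groups are expensive.
#' @return List with `W` (NA with `defined = FALSE` if no chain has
#'   positive weight), `total_weight`, `chains`, `n`.
#' @export
weighted_rank_difference <- function(m, order, n, max_visits = 5e9) {
  stopifnot(is.matrix(m), n >= 1)
  rk <- as_rank_vector(order, rownames(m))
  res <- chain_stats_cpp(m * 1.0, rk, as.integer(n),
                         max_visits = max_visits)
  defined <- res$w_den > 0
  list(W = if (defined) res$w_num / res$w_den else NA_real_,
       total_weight = res$w_den, chains = res$chains, n = n,
       defined = defined)
}

#' Fractional transitivity over aggression chains, T(n)
#'
#' For each chain, compare the originator's aggression toward the chain's
#' terminal individual with the originator's baseline aggression
#' \eqn{\bar d}: the chain-weighted mean of
#' \eqn{(d_{origin,terminal} - \bar d) / \bar d}. For `n = 2` the baseline
#' is the originator's mean aggression toward all individuals other than
#' the intermediate `j`. For longer chains two generalizations are
#' available: `baseline = "interior"` (default) excludes all interior chain
#' members from the baseline; `baseline = "first"` excludes only the first
#' intermediate, the literal reading of the 2-chain rule. Both coincide at
#' `n = 2`. Positive `T(n)` means individuals direct above-baseline
#' aggression at chain-terminal individuals; negative values mean they
#' avoid them. Chains whose baseline is zero are excluded from the sums and
#' counted, unless `baseline_epsilon > 0` regularizes the denominator.
#'
#' @param m win-count matrix.
#' @param n chain length in edges (`n >= 2`).
#' @param baseline `"interior"` or `"first"`.
#' @param baseline_epsilon optional additive regularizer for the baseline.
#' @param max_visits safety cap on enumeration steps.
#' @return List with `T` (NA with `defined = FALSE` when every chain is
#'   excluded), `total_weight`, `chains`, `chains_excluded`, `n`,
#'   `baseline`.
#' @export
fractional_transitivity <- function(m, n, baseline = c("interior", "first"),
                                    baseline_epsilon = 0,
                                    max_visits = 5e9) {
  stopifnot(is.matrix(m), n >= 2)
  baseline <- match.arg(baseline)
  rk <- seq_len(nrow(m))  # ranks are irrelevant to T
  res <- chain_stats_cpp(m * 1.0, as.integer(rk), as.integer(n),
                         baseline_mode = match(baseline,
                                               c("interior", "first")) - 1L,
                         baseline_eps = baseline_epsilon,
                         max_visits = max_visits)
  defined <- res$t_den > 0
  list(T = if (defined) res$t_num / res$t_den else NA_real_,
       total_weight = res$t_den, chains = res$chains,
       chains_excluded = res$zero_baseline, n = n, baseline = baseline,
       defined = defined)
}

#' Chain statistics with null comparison, for a range of chain lengths
#'
#' Computes `W(n)` for `n = 1..max_n` and `T(n)` for `n = 2..max_n` on the
#' observed matrix, together with the null-ensemble mean, 1-sigma band and
#' a one-sided empirical p-value per statistic. The test direction is the
#' side of the null mean on which the observed value falls, and is
#' reported. Ranks are held at the observed ordering for null samples
#' (the null preserves power scores by construction).
#'
#' @param m observed win-count matrix.
#' @param order observed rank order.
#' @param ensemble a [sample_null_ensemble()] result on the same roster.
#' @param max_n largest chain length (default 6; enumeration cost grows
#'   factorially, and null samples are typically denser than the observed
#'   matrix).
#' @param baseline baseline rule for [fractional_transitivity()].
#' @param max_visits safety cap per enumeration.
#' @return data.frame with one row per `n`: observed `W` and `T`, null
#'   means/sds, p-values and test directions, `total_weight`, `chains`.
#' @export
chain_statistics_suite <- function(m, order, ensemble, max_n = 6,
                                   baseline = c("interior", "first"),
                                   max_visits = 5e9) {
  stopifnot(inherits(ensemble, "null_ensemble"), max_n >= 1)
  baseline <- match.arg(baseline)
  B <- length(ensemble$samples)
  rows <- vector("list", max_n)
  for (n in seq_len(max_n)) {
    obs_w <- weighted_rank_difference(m, order, n, max_visits)
    obs_t <- if (n >= 2) {
      fractional_transitivity(m, n, baseline, max_visits = max_visits)
    } else NULL
    w_null <- vapply(ensemble$samples, function(s) {
      weighted_rank_difference(s, order, n, max_visits)$W
    }, numeric(1))
    t_null <- if (n >= 2) {
      vapply(ensemble$samples, function(s) {
        fractional_transitivity(s, n, baseline, max_visits = max_visits)$T
      }, numeric(1))
    } else rep(NA_real_, B)
    emp <- function(obs, nulls) {
      ok <- nulls[!is.na(nulls)]
      if (length(ok) == 0L || is.na(obs)) {
        return(list(mean = NA_real_, sd = NA_real_, p = NA_real_,
                    dir = NA_character_))
      }
      mu <- mean(ok)
      dir <- if (obs >= mu) "greater" else "less"
      hits <- if (dir == "greater") sum(ok >= obs) else sum(ok <= obs)
      list(mean = mu, sd = if (length(ok) > 1) sd(ok) else 0,
           p = (1 + hits) / (length(ok) + 1), dir = dir)
    }
    ew <- emp(obs_w$W, w_null)
    et <- if (n >= 2) emp(obs_t$T, t_null) else
      list(mean = NA_real_, sd = NA_real_, p = NA_real_, dir = NA_character_)
    rows[[n]] <- data.frame(
      n = n,
      W = obs_w$W, W_null_mean = ew$mean, W_null_sd = ew$sd,
      W_p = ew$p, W_dir = ew$dir,
      T = if (n >= 2) obs_t$T else NA_real_,
      T_null_mean = et$mean, T_null_sd = et$sd, T_p = et$p, T_dir = et$dir,
      total_weight = obs_w$total_weight, chains = obs_w$chains,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "baseline") <- baseline
  attr(out, "B") <- B
  out
}

#' Reference all-tuples chain enumerator
#'
#' A deliberately naive implementation of `W(n)` and `T(n)`: enumerate
#' every ordered tuple of `n + 1` distinct individuals, multiply the win
#' counts along the implied path, and accumulate the weighted sums
#' directly from the definitions. It shares no code with the optimized
#' depth-first enumerator and exists as an independent cross-check; it is
#' only practical for small groups (roughly `N <= 8`, `n <= 5`).
#'
#' @param m win-count matrix.
#' @param order named rank vector.
#' @param n chain length in edges.
#' @param baseline baseline rule, as in [fractional_transitivity()].
#' @return List with `W`, `T`, `total_weight`, `t_weight`, `chains`,
#'   `chains_excluded`.
#' @export
chain_stats_naive <- function(m, order, n,
                              baseline = c("interior", "first")) {
  stopifnot(is.matrix(m), n >= 1, n <= nrow(m) - 1)
  baseline <- match.arg(baseline)
  ids <- rownames(m)
  rk <- as_rank_vector(order, ids)
  N <- nrow(m)
  w_num <- w_den <- t_num <- t_den <- 0
  chains <- excluded <- 0
  tuples <- list(integer(0))
  for (pos in seq_len(n + 1)) {
    tuples <- unlist(lapply(tuples, function(tp) {
      lapply(setdiff(seq_len(N), tp), function(x) c(tp, x))
    }), recursive = FALSE)
  }
  for (tp in tuples) {
    w <- 1
    for (e in seq_len(n)) w <- w * m[tp[e], tp[e + 1]]
    if (w == 0) next
    chains <- chains + 1
    origin <- tp[1]; terminal <- tp[n + 1]
    w_num <- w_num + w * (rk[terminal] - rk[origin])
    w_den <- w_den + w
    if (n >= 2) {
      excl <- if (baseline == "interior") tp[2:n] else tp[2]
      others <- setdiff(seq_len(N), c(origin, excl))
      dbar <- mean(m[origin, others])
      if (dbar > 0) {
        t_num <- t_num + w * (m[origin, terminal] - dbar) / dbar
        t_den <- t_den + w
      } else {
        excluded <- excluded + 1
      }
    }
  }
  list(W = if (w_den > 0) w_num / w_den else NA_real_,
       T = if (t_den > 0) t_num / t_den else NA_real_,
       total_weight = w_den, t_weight = t_den,
       chains = chains, chains_excluded = excluded)
}
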