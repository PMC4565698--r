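#' Fit a hierarchy-constrained null kernel
#'
#' Constructs a zero-diagonal row-stochastic matrix whose stationary
#' distribution matches a target power-score vector `v`. Together with
#' [sample_null_ensemble()] this realizes the hierarchy-constrained null
#' model: random aggression networks that reproduce the observed power
#' scores on average but are otherwise unstructured. The construction is an
#' independence kernel with iterative column rescaling: initialize
#' \eqn{t_{ij} \propto v_j} (for \eqn{j \ne i}), then repeat { compute the
#' stationary distribution `w`; rescale column `j` by \eqn{v_j / w_j}; zero
#' the diagonal; renormalize rows } until `max |w - v| < tol`. Rows of the
#' fitted kernel carry no structure beyond the stationary constraint.
#'
#' @param v a `power_scores` object (method `"ec"`) or a positive
#'   probability vector.
#' @param tol convergence tolerance on the stationary residual
#'   (default 1e-8).
#' @param max_iter iteration cap; extreme `v` (e.g. forced two-individual
#'   chains) can be infeasible, in which case the error reports the
#'   achieved residual.
#' @return An object of class `null_kernel`: list with `t_null`,
#'   `target_v`, `residual`, `iterations`.
#' @export
fit_null_kernel <- function(v, tol = 1e-8, max_iter = 10000) {
  if (inherits(v, "power_scores")) v <- v$score
  stopifnot(is.numeric(v), all(v > 0))
  v <- v / sum(v)
  n <- length(v)
  if (n < 2L) stop("need at least 2 individuals")
  ids <- names(v)
  t_null <- matrix(rep(v, each = n), n, n)
  diag(t_null) <- 0
  t_null <- t_null / rowSums(t_null)
  w <- stationary_distribution(t_null)
  res <- max(abs(w - v))
  iter <- 1L
  while (res >= tol && iter < max_iter) {
    t_null <- sweep(t_null, 2, v / w, `*`)
    diag(t_null) <- 0
    t_null <- t_null / rowSums(t_null)
    w <- stationary_distribution(t_null)
    res <- max(abs(w - v))
    iter <- iter + 1L
  }
  if (res >= tol) {
    stop("null kernel did not converge in ", max_iter,
         " iterations; achieved stationary residual ",
         format(res, digits = 4))
  }
  dimnames(t_null) <- list(ids, ids)
  structure(
    list(t_null = t_null, target_v = v, residual = res, iterations = iter),
    class = "null_kernel"
  )
}

#' @export
print.null_kernel <- function(x, ...) {
  cat("null_kernel: N =", nrow(x$t_null), "| stationary residual",
      format(x$residual, digits = 4), "after", x$iterations, "iterations\n")
  invisible(x)
}

#' Sample a null ensemble of aggression matrices
#'
#' Draws `B` integer aggression matrices from the fitted kernel: each
#' individual's observed total outgoing aggression is redistributed across
#' targets by independent categorical draws with that individual's kernel
#' row. Every sample's row totals therefore equal the observed totals
#' exactly, while power scores are reproduced on average over the ensemble
#' (individual samples fluctuate with multinomial noise).
#'
#' @param kernel a [fit_null_kernel()] result.
#' @param row_totals named non-negative integer vector of per-individual
#'   outgoing totals, e.g. `rowSums(build_matrix(log))`.
#' @param B number of samples.
#' @param seed RNG seed.
#' @return An object of class `null_ensemble`: list with `samples` (list of
#'   integer matrices), `kernel`, `row_totals`, `seed`.
#' @export
sample_null_ensemble <- function(kernel, row_totals, B, seed = 1) {
  stopifnot(inherits(kernel, "null_kernel"), B >= 1,
            all(row_totals >= 0))
  n <- nrow(kernel$t_null)
  stopifnot(length(row_totals) == n)
  ids <- rownames(kernel$t_null)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  samples <- vector("list", B)
  for (b in seq_len(B)) {
    m <- matrix(0L, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n)) {
      if (row_totals[i] > 0) {
        m[i, ] <- as.integer(rmultinom(1, row_totals[i], kernel$t_null[i, ]))
      }
    }
    samples[[b]] <- m
  }
  structure(
    list(samples = samples, kernel = kernel,
         row_totals = as.integer(row_totals), seed = seed),
    class = "null_ensemble"
  )
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat("null_ensemble:", length(x$samples), "samples, N =",
      nrow(x$kernel$t_null), "| seed", x$seed, "\n")
  invisible(x)
}

#' Null distribution summary and empirical p for a statistic
#'
#' Evaluates a scalar statistic on every ensemble sample and returns its
#' null mean and 1-sigma band. If an observed value is supplied, the
#' one-sided empirical p-value is the fraction of null samples at least as
#' extreme in the given direction, with the standard +1 correction:
#' \eqn{p = (1 + \#\{null \ge obs\}) / (B + 1)} for direction `"greater"`.
#' Samples on which the statistic is undefined (`NA`) are dropped and
#' counted.
#'
#' @param statistic function of a single aggression matrix returning a
#'   scalar (or `NA` when undefined).
#' @param ensemble a [sample_null_ensemble()] result.
#' @param observed optional observed value of the statistic.
#' @param direction `"greater"` or `"less"`: the tail in which the observed
#'   value is tested.
#' @return List with `mean`, `sd`, `n_used`, `n_dropped`, `values`, and
#'   (when `observed` is given) `p`.
#' @export
null_band <- function(statistic, ensemble, observed = NULL,
                      direction = c("greater", "less")) {
  stopifnot(inherits(ensemble, "null_ensemble"), is.function(statistic))
  direction <- match.arg(direction)
  vals <- vapply(ensemble$samples, function(s) {
    out <- statistic(s)
    if (length(out) != 1L) stop("statistic must return a scalar")
    as.numeric(out)
  }, numeric(1))
  dropped <- sum(is.na(vals))
  use <- vals[!is.na(vals)]
  out <- list(
    mean = mean(use), sd = if (length(use) > 1L) sd(use) else 0,
    n_used = length(use), n_dropped = dropped, values = vals
  )
  if (!is.null(observed)) {
    hits <- if (direction == "greater") sum(use >= observed)
            else sum(use <= observed)
    out$p <- (1 + hits) / (length(use) + 1)
    out$observed <- observed
    out$direction <- direction
  }
  out
}
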