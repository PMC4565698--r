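#' Does body size predict rank?
#'
#' Correlates each morphometric trait with ordinal dominance rank and
#' reports the signed coefficient of determination
#' \eqn{sign(r) \cdot r^2} with its two-sided p-value, for both Pearson and
#' Spearman correlations. A strong |signed r^2| would mean individuals
#' could read rank off body size alone, without social observation.
#'
#' @param morpho data.frame with an `id` column and one numeric column per
#'   trait (e.g. `wing_chord`, `culmen_depth`, `culmen_width`, `mass`).
#' @param order named rank vector from [rank_order()]; ids must cover the
#'   morphometric table.
#' @return data.frame with one row per trait: `signal`, `signed_r2`, `p`,
#'   `signed_rho2`, `p_spearman`, `n`, `degenerate`.
#' @export
morphometric_rank_signal <- function(morpho, order) {
  stopifnot(is.data.frame(morpho), "id" %in% names(morpho))
  ids <- as.character(morpho$id)
  unknown <- setdiff(ids, names(order))
  if (length(unknown) > 0L) {
    stop("morphometric id(s) without a rank: ", paste(unknown, collapse = ", "))
  }
  traits <- setdiff(names(morpho), "id")
  traits <- traits[vapply(morpho[traits], is.numeric, logical(1))]
  if (length(traits) == 0L) stop("no numeric trait columns")
  rk <- as.numeric(order[ids])
  rows <- lapply(traits, function(tr) {
    x <- morpho[[tr]]
    ok <- is.finite(x) & is.finite(rk)
    if (sum(ok) < 3L) stop("need at least 3 complete rows for trait ", tr)
    if (sd(x[ok]) == 0) {
      return(data.frame(signal = tr, signed_r2 = NA_real_, p = NA_real_,
                        signed_rho2 = NA_real_, p_spearman = NA_real_,
                        n = sum(ok), degenerate = TRUE))
    }
    ct <- cor.test(x[ok], rk[ok])
    cs <- suppressWarnings(cor.test(x[ok], rk[ok], method = "spearman"))
    data.frame(signal = tr,
               signed_r2 = sign(ct$estimate) * ct$estimate^2,
               p = ct$p.value,
               signed_rho2 = sign(cs$estimate) * cs$estimate^2,
               p_spearman = cs$p.value,
               n = sum(ok), degenerate = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Does spatial proximity predict rank difference?
#'
#' Builds the dyadic table of how many times individual `i` was observed as
#' individual `j`'s nearest neighbour (ordered pairs, every ordered pair in
#' the roster appears with a count, possibly zero) and correlates the count
#' with the absolute rank difference `|rank(i) - rank(j)|`. A strongly
#' negative signed r^2 means rank neighbours are also spatial neighbours,
#' so proximity could serve as a cue to rank.
#'
#' @param scans data.frame with columns `scan_id`, `focal`, `neighbor`.
#' @param order named rank vector covering all ids in the scans.
#' @param directed count ordered pairs (default); `FALSE` pools the two
#'   directions of each dyad.
#' @return List with `signed_r2`, `p`, `signed_rho2`, `p_spearman`, `n_pairs`,
#'   `n_scans`, `dyads` (the dyadic table) and flags `degenerate` /
#'   `low_power` (fewer than 10 scans).
#' @export
neighbor_rank_signal <- function(scans, order, directed = TRUE) {
  stopifnot(is.data.frame(scans),
            all(c("scan_id", "focal", "neighbor") %in% names(scans)))
  if (nrow(scans) == 0L) stop("no scans")
  focal <- as.character(scans$focal)
  nb <- as.character(scans$neighbor)
  if (any(focal == nb)) stop("focal equals neighbor in scan row(s): ",
                             paste(which(focal == nb), collapse = ", "))
  ids <- names(order)
  unknown <- setdiff(c(focal, nb), ids)
  if (length(unknown) > 0L) {
    stop("scan id(s) without a rank: ", paste(unknown, collapse = ", "))
  }
  pairs <- expand.grid(i = ids, j = ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$i != pairs$j, ]
  # count: times i was observed as j's nearest neighbour
  key <- paste(nb, focal, sep = "\r")
  tab <- table(key)
  pk <- paste(pairs$i, pairs$j, sep = "\r")
  pairs$count <- as.integer(ifelse(pk %in% names(tab), tab[pk], 0L))
  pairs$abs_delta <- abs(as.integer(order[pairs$i]) -
                           as.integer(order[pairs$j]))
  if (!directed) {
    und_key <- ifelse(pairs$i < pairs$j,
                      paste(pairs$i, pairs$j), paste(pairs$j, pairs$i))
    cnt <- tapply(pairs$count, und_key, sum)
    dl <- tapply(pairs$abs_delta, und_key, `[`, 1)
    pairs <- data.frame(dyad = names(cnt), count = as.integer(cnt),
                        abs_delta = as.integer(dl), stringsAsFactors = FALSE)
  }
  degenerate <- sd(pairs$count) == 0
  if (degenerate) {
    return(list(signed_r2 = NA_real_, p = NA_real_, signed_rho2 = NA_real_,
                p_spearman = NA_real_, n_pairs = nrow(pairs),
                n_scans = nrow(scans), dyads = pairs,
                degenerate = TRUE, low_power = nrow(scans) < 10))
  }
  ct <- cor.test(pairs$count, pairs$abs_delta)
  cs <- suppressWarnings(
    cor.test(pairs$count, pairs$abs_delta, method = "spearman"))
  list(signed_r2 = unname(sign(ct$estimate) * ct$estimate^2),
       p = ct$p.value,
       signed_rho2 = unname(sign(cs$estimate) * cs$estimate^2),
       p_spearman = cs$p.value,
       n_pairs = nrow(pairs), n_scans = nrow(scans), dyads = pairs,
       degenerate = FALSE, low_power = nrow(scans) < 10)
}
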