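#' Construct an aggression event log
#'
#' An event log couples an ordered table of directed win events with the
#' fixed roster of individuals and the total observation time. The roster
#' order is stable for the lifetime of an analysis: matrices, scores and
#' ranks all index it.
#'
#' @param events data.frame with columns `time` (seconds since observation
#'   start, non-negative), `actor`, `target` (ids). Rows are sorted by time.
#' @param roster character vector of unique individual ids. Defaults to the
#'   sorted set of ids appearing in `events`.
#' @param t_obs_min total observation time in minutes; must cover the last
#'   event. Defaults to the last event time rounded up to a whole minute.
#' @return An object of class `aggression_log`: a list with elements
#'   `events`, `roster` and `t_obs_min`.
#' @export
aggression_log <- function(events, roster = NULL, t_obs_min = NULL) {
  stopifnot(is.data.frame(events))
  need <- c("time", "actor", "target")
  miss <- setdiff(need, names(events))
  if (length(miss) > 0L) {
    stop("event table is missing column(s): ", paste(miss, collapse = ", "))
  }
  events <- events[need]
  events$actor <- as.character(events$actor)
  events$target <- as.character(events$target)
  events$time <- as.numeric(events$time)

  bad <- which(!is.finite(events$time) | events$time < 0 |
                 is.na(events$actor) | is.na(events$target) |
                 events$actor == "" | events$target == "")
  if (length(bad) > 0L) {
    stop("malformed event row(s): ", paste(bad, collapse = ", "))
  }
  self <- which(events$actor == events$target)
  if (length(self) > 0L) {
    stop("actor equals target in row(s): ", paste(self, collapse = ", "))
  }

  seen <- sort(unique(c(events$actor, events$target)))
  if (is.null(roster)) {
    roster <- seen
  } else {
    roster <- as.character(roster)
    if (anyDuplicated(roster)) stop("roster ids must be unique")
    unknown <- setdiff(seen, roster)
    if (length(unknown) > 0L) {
      stop("event ids not in roster: ", paste(unknown, collapse = ", "))
    }
  }

  events <- events[order(events$time), , drop = FALSE]
  rownames(events) <- NULL

  max_min <- if (nrow(events) > 0L) max(events$time) / 60 else 0
  if (is.null(t_obs_min)) t_obs_min <- max(ceiling(max_min), 1)
  t_obs_min <- as.numeric(t_obs_min)
  if (!is.finite(t_obs_min) || t_obs_min <= 0) {
    stop("t_obs_min must be a positive number of minutes")
  }
  if (t_obs_min < max_min - 1e-9) {
    stop("t_obs_min (", t_obs_min, " min) is shorter than the last event")
  }

  structure(
    list(events = events, roster = roster, t_obs_min = t_obs_min),
    class = "aggression_log"
  )
}

#' @export
print.aggression_log <- function(x, ...) {
  cat("aggression_log:", nrow(x$events), "events,",
      length(x$roster), "individuals,",
      format(x$t_obs_min, digits = 6), "min observed\n")
  invisible(x)
}

#' Read a dyadic aggression event log from CSV
#'
#' Expects a header with columns `time,actor,target`. Times are either
#' numeric seconds since observation start or ISO-8601 timestamps, which are
#' converted to seconds relative to the earliest event. Malformed rows
#' (missing fields, non-finite time, actor equal to target) abort with the
#' offending row numbers rather than being silently dropped.
#'
#' @param path CSV file path.
#' @param roster optional roster; ids in the file must be a subset.
#' @param t_obs_min optional total observation time in minutes.
#' @return An [aggression_log()].
#' @export
read_event_log <- function(path, roster = NULL, t_obs_min = NULL) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", "actor", "target")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0L) {
    stop("'", path, "' is missing column(s): ", paste(miss, collapse = ", "))
  }
  tm <- raw$time
  if (!is.numeric(tm)) {
    num <- suppressWarnings(as.numeric(tm))
    if (all(is.finite(num))) {
      tm <- num
    } else {
      ts <- as.POSIXct(as.character(tm), tz = "UTC",
                       tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                      "%Y-%m-%d %H:%M:%OS",
                                      "%Y-%m-%d"))
      if (anyNA(ts)) {
        stop("unparseable time value in row(s): ",
             paste(which(is.na(ts)), collapse = ", "))
      }
      tm <- as.numeric(ts) - as.numeric(min(ts))
    }
  }
  raw$time <- tm
  aggression_log(raw, roster = roster, t_obs_min = t_obs_min)
}

#' Collapse sub-attack barrages into single wins
#'
#' Field protocols score a win only after a cessation of aggression from the
#' actor toward that target of at least `cooldown` seconds, so a string of
#' rapid sub-attacks (e.g. 6 attacks in 10 s) counts as one win. For each
#' ordered actor-target pair, an event is retained only if at least
#' `cooldown` seconds have elapsed since the previously *retained* event of
#' that pair; the first event of each pair is always retained. Resetting the
#' clock from retained events means a continuous barrage yields one win per
#' cooldown period rather than a single win forever.
#'
#' @param log an [aggression_log()].
#' @param cooldown cooldown in seconds (default 60).
#' @return Filtered `aggression_log`; the number of removed events is
#'   available as `attr(x, "n_removed")`.
#' @export
apply_win_cooldown <- function(log, cooldown = 60) {
  stopifnot(inherits(log, "aggression_log"), cooldown > 0)
  ev <- log$events
  if (nrow(ev) == 0L) {
    out <- log
    attr(out, "n_removed") <- 0L
    return(out)
  }
  key <- paste(ev$actor, ev$target, sep = "\r")
  keep <- logical(nrow(ev))
  last <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(ev))) {
    k <- key[r]
    prev <- get0(k, envir = last, ifnotfound = NULL)
    if (is.null(prev) || ev$time[r] - prev >= cooldown) {
      keep[r] <- TRUE
      assign(k, ev$time[r], envir = last)
    }
  }
  out <- aggression_log(ev[keep, , drop = FALSE], roster = log$roster,
                        t_obs_min = log$t_obs_min)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Partition a log into equal observation windows
#'
#' Splits the study period into consecutive half-open windows
#' `[start, end)` of `window_days` days each (events at a boundary belong to
#' the later window). The study duration must be an exact multiple of the
#' window length unless `force = TRUE`. Each window's event times are
#' re-expressed relative to the window start and its observation time is the
#' window length.
#'
#' @param log an [aggression_log()].
#' @param window_days window length in days (default 6, i.e. study quarters
#'   for a 24-day study).
#' @param force allow a ragged final window.
#' @return List of `aggression_log` windows, named `Q1`, `Q2`, ...
#' @export
split_windows <- function(log, window_days = 6, force = FALSE) {
  stopifnot(inherits(log, "aggression_log"), window_days > 0)
  day_min <- 24 * 60
  duration_days <- log$t_obs_min / day_min
  n_win <- duration_days / window_days
  if (abs(n_win - round(n_win)) > 1e-9) {
    if (!force) {
      stop("study duration (", duration_days, " d) is not a multiple of ",
           window_days, " d; use force = TRUE for a ragged final window")
    }
    n_win <- ceiling(n_win)
  } else {
    n_win <- round(n_win)
  }
  win_sec <- window_days * 86400
  out <- vector("list", n_win)
  for (w in seq_len(n_win)) {
    lo <- (w - 1) * win_sec
    hi <- w * win_sec
    ev <- log$events[log$events$time >= lo & log$events$time < hi, ,
                     drop = FALSE]
    ev$time <- ev$time - lo
    len_min <- min(window_days * day_min, log$t_obs_min - lo / 60)
    out[[w]] <- aggression_log(ev, roster = log$roster, t_obs_min = len_min)
  }
  names(out) <- paste0("Q", seq_len(n_win))
  out
}

#' Remove individuals from a log
#'
#' Drops every event in which an excluded id appears as actor or target and
#' shrinks the roster; observation time is unchanged. Used for anomalous
#' individuals whose incoming aggression is reactive rather than strategic.
#'
#' @param log an [aggression_log()].
#' @param ids character vector of roster ids to exclude (may be empty).
#' @return Filtered `aggression_log` with a smaller roster.
#' @export
exclude_individuals <- function(log, ids) {
  stopifnot(inherits(log, "aggression_log"))
  ids <- as.character(ids)
  if (length(ids) == 0L) return(log)
  unknown <- setdiff(ids, log$roster)
  if (length(unknown) > 0L) {
    stop("id(s) not in roster: ", paste(unknown, collapse = ", "))
  }
  ev <- log$events
  ev <- ev[!(ev$actor %in% ids) & !(ev$target %in% ids), , drop = FALSE]
  aggression_log(ev, roster = setdiff(log$roster, ids),
                 t_obs_min = log$t_obs_min)
}

#' Tally a log into a directed win-count matrix
#'
#' Entry `d[i, j]` is the number of events in which `i` was the actor and
#' `j` the target; the diagonal is zero and the matrix total equals the
#' number of events. Rows and columns follow the roster order.
#'
#' @param log an [aggression_log()].
#' @param window_label label attached as the `"window"` attribute.
#' @return Integer matrix with roster dimnames.
#' @export
build_matrix <- function(log, window_label = "all") {
  stopifnot(inherits(log, "aggression_log"))
  ids <- log$roster
  if (length(ids) == 0L) stop("empty roster")
  n <- length(ids)
  d <- matrix(0L, n, n, dimnames = list(ids, ids))
  if (nrow(log$events) > 0L) {
    tab <- table(factor(log$events$actor, levels = ids),
                 factor(log$events$target, levels = ids))
    d[] <- as.integer(tab)
  }
  attr(d, "window") <- window_label
  d
}

#' Directed network density
#'
#' Fraction of ordered off-diagonal pairs with at least one win. The
#' directed convention is used because the aggression network is directed;
#' `dyadic = TRUE` instead counts unordered pairs with aggression in either
#' direction.
#'
#' @param m win-count matrix from [build_matrix()].
#' @param dyadic count unordered dyads instead of ordered pairs.
#' @return Proportion in `[0, 1]`.
#' @export
network_density <- function(m, dyadic = FALSE) {
  stopifnot(is.matrix(m))
  n <- nrow(m)
  if (n < 2L) stop("density needs at least 2 individuals")
  off <- row(m) != col(m)
  if (dyadic) {
    any_dir <- (m + t(m)) > 0
    sum(any_dir[upper.tri(any_dir)]) / (n * (n - 1) / 2)
  } else {
    sum(m[off] > 0) / (n * (n - 1))
  }
}
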