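#' Daily rating and rank snapshots
#'
#' `elo_snapshot()` returns every individual's Elo-rating and ordinal rank
#' on a given date: the rating after the last interaction at or before the
#' end of that day (with `include_same_day = FALSE`, strictly before that
#' day), or the starting rating if the individual has not yet interacted.
#' Ordinal ranks use competition ranking — tied ratings share the smaller
#' rank and the following rank is skipped (1, 2, 2, 4) — so individuals
#' with identical ratings are not ordered arbitrarily.
#'
#' @param object An `elo_seq` fit or an `elo_traj` from
#'   [read_trajectory()].
#' @param date A `Date` (or `YYYY-MM-DD` string).
#' @param include_same_day Logical; include interactions occurring on
#'   `date` itself (default `TRUE`, i.e. end-of-day ratings).
#' @return A data frame with columns `id`, `rating`, `rank`, ordered by
#'   rank; the date is attached as attribute `"date"`.
#' @examples
#' fit <- elo_seq(system.file("extdata", "example_interactions.csv",
#'                            package = "elohist"))
#' elo_snapshot(fit, "2003-10-20")
#' @export
elo_snapshot <- function(object, date, include_same_day = TRUE) {
  tr <- as_traj(object)
  date <- as_date_scalar(date)
  cutoff <- if (include_same_day) date else date - 1L
  r <- ratings_at(tr, cutoff)
  out <- data.frame(id = names(r), rating = unname(r),
                    rank = unname(competition_rank(r)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$rank, out$id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "date") <- date
  out
}

#' Join daily ratings and ranks onto dated events
#'
#' For downstream analyses that need an individual's hierarchy position on
#' particular days (e.g. days on which it mated or called), joins the
#' snapshot rating and ordinal rank onto a list of `(date, id)` events,
#' preserving the input order.
#'
#' @inheritParams elo_snapshot
#' @param events Data frame with columns `date` and `id` (extra columns
#'   are carried through).
#' @return `events` with `rating` and `rank` columns appended.
#' @export
ranks_on_dates <- function(object, events, include_same_day = TRUE) {
  tr <- as_traj(object)
  stopifnot(is.data.frame(events))
  nm <- tolower(names(events))
  di <- match("date", nm); ii <- match("id", nm)
  if (is.na(di) || is.na(ii)) {
    stop("'events' needs columns 'date' and 'id'", call. = FALSE)
  }
  events <- as.data.frame(events)
  ids <- as.character(events[[ii]])
  bad <- setdiff(ids, tr$roster)
  if (length(bad)) stop("id '", bad[1], "' is not in the roster",
                        call. = FALSE)
  dates <- as.Date(events[[di]])
  if (anyNA(dates) && nrow(events)) {
    stop("unparseable date in 'events'", call. = FALSE)
  }
  events$rating <- rep(NA_real_, nrow(events))
  events$rank <- rep(NA_integer_, nrow(events))
  for (d in unique(dates)) {
    sel <- which(dates == d)
    snap <- elo_snapshot(object, as.Date(d, origin = "1970-01-01"),
                         include_same_day = include_same_day)
    m <- match(ids[sel], snap$id)
    events$rating[sel] <- snap$rating[m]
    events$rank[sel] <- snap$rank[m]
  }
  events
}

#' Detect the end of the burn-in period
#'
#' When all individuals start from a common rating, early ratings and
#' ranks do not yet reflect real relative positions (the burn-in period)
#' and should be discarded. A workable signal that burn-in has ended is a
#' stable trajectory for the top-rated (alpha) individual: this function
#' returns the earliest date `d` such that over the window
#' `[d, d + window_days]` (which must lie within the span of the record)
#' a single individual holds the uniquely highest rating on every day and
#' that individual's largest absolute day-over-day rating change does not
#' exceed `tolerance`. Days on which the top rating is shared (as at an
#' equal start) are never stable, since the alpha identity is unresolved.
#'
#' The defaults — a 30-day window and a 25-point tolerance, one eighth of
#' the default K — are pragmatic: they ask that for a month no single
#' interaction moved the alpha by more than a small fraction of the
#' nominal per-event change. They are starting points to be tuned to the
#' interaction rate of the study system, not calibrated constants.
#'
#' @inheritParams elo_snapshot
#' @param window_days Length of the stability window, in days (>= 1).
#' @param tolerance Maximum tolerated day-over-day rating change for the
#'   top individual, in Elo points (>= 0).
#' @return The earliest stable `Date`, or `NA` if no window qualifies.
#' @examples
#' fit <- elo_seq(system.file("extdata", "example_interactions.csv",
#'                            package = "elohist"))
#' detect_burn_in(fit, window_days = 2, tolerance = 50)
#' @export
detect_burn_in <- function(object, window_days = 30, tolerance = 25,
                           include_same_day = TRUE) {
  tr <- as_traj(object)
  if (tr$n_processed == 0) {
    stop("cannot assess burn-in on an empty sequence", call. = FALSE)
  }
  stopifnot(window_days >= 1, tolerance >= 0)
  first <- min(tr$trajectory$date)
  last <- max(tr$trajectory$date)
  dates <- seq(first, last, by = "day")
  if (!include_same_day) dates <- dates - 1L
  mat <- daily_rating_matrix(object, dates)
  top_val <- apply(mat, 1L, max)
  n_top <- rowSums(mat == top_val)
  top_id <- max.col(mat, ties.method = "first")
  stable_day <- n_top == 1L
  # day-over-day change of the day's top individual, looking back one day
  n_days <- length(dates)
  if (n_days == 1L) {
    ok_change <- TRUE
  } else {
    prev <- mat[cbind(pmax(seq_len(n_days) - 1L, 1L), top_id)]
    ok_change <- c(TRUE, abs(top_val[-1L] - prev[-1L]) <= tolerance)
  }
  w <- as.integer(window_days)
  for (s in seq_len(n_days - w)) {
    win <- s:(s + w)
    if (all(stable_day[win]) &&
        length(unique(top_id[win])) == 1L &&
        all(ok_change[win[-1L]])) {
      return(dates[s] + if (!include_same_day) 1L else 0L)
    }
  }
  as.Date(NA)
}

# ratings for every roster id after the last event dated <= cutoff
ratings_at <- function(tr, cutoff) {
  r <- tr$start[tr$roster]
  t2 <- tr$trajectory[tr$trajectory$date <= cutoff, , drop = FALSE]
  if (nrow(t2)) {
    last <- t2[!duplicated(t2$id, fromLast = TRUE), , drop = FALSE]
    r[last$id] <- last$rating_after
  }
  r
}

# dates x ids matrix of end-of-day ratings (piecewise constant)
daily_rating_matrix <- function(object, dates) {
  tr <- as_traj(object)
  ids <- tr$roster
  mat <- matrix(rep(tr$start[ids], each = length(dates)),
                nrow = length(dates), ncol = length(ids),
                dimnames = list(format(dates), ids))
  traj <- tr$trajectory
  for (j in seq_along(ids)) {
    rows <- traj[traj$id == ids[j], , drop = FALSE]
    if (!nrow(rows)) next
    # last event per day, in event order
    day_last <- rows[!duplicated(rows$date, fromLast = TRUE), , drop = FALSE]
    pos <- findInterval(as.integer(dates), as.integer(day_last$date))
    has <- pos > 0L
    mat[has, j] <- day_last$rating_after[pos[has]]
  }
  mat
}

as_date_scalar <- function(date) {
  d <- tryCatch(as.Date(date), error = function(e) as.Date(NA))
  if (length(d) != 1L || is.na(d)) {
    stop("invalid date: ", paste(format(date), collapse = ", "),
         call. = FALSE)
  }
  d
}
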