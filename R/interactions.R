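#' Read a dyadic interaction record
#'
#' Reads (or validates) an event log of dated agonistic interactions, the
#' input to [elo_seq()]. The expected layout is a CSV file with header
#' `Date, Time, Winner, Loser, K, Outcome`:
#'
#' * `Date` — ISO dates (`YYYY-MM-DD`).
#' * `Time` — optional time of day (`HH:MM` or `HH:MM:SS`); rows without a
#'   time sort after timed rows on the same date.
#' * `Winner`, `Loser` — case-sensitive individual identifiers.
#' * `K` — per-interaction K value (positive). Blank cells receive
#'   `default_k`, so a file with an entirely blank K column reproduces the
#'   constant-K analysis.
#' * `Outcome` — `1` for a decided interaction, `0` for a draw.
#'
#' Rows are stably sorted by date then time, so events sharing a timestamp
#' (or lacking one) are processed in file order.
#'
#' @param x Path to a CSV file, or a data frame with the columns above
#'   (column names matched case-insensitively).
#' @param default_k Positive number substituted for blank K cells.
#' @return A data frame of class `elo_interactions` with columns
#'   `date` (Date), `time` (character, `NA` if absent), `winner`, `loser`,
#'   `k`, and `outcome` (`"decided"` or `"draw"`), in chronological order.
#' @examples
#' path <- system.file("extdata", "example_interactions.csv",
#'                     package = "elohist")
#' ints <- read_interactions(path)
#' head(ints)
#' @export
read_interactions <- function(x, default_k = 200) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("interaction file not found: ", x, call. = FALSE)
    x <- utils::read.csv(x, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  }
  if (!is.data.frame(x)) {
    stop("'x' must be a file path or a data frame", call. = FALSE)
  }
  as_interactions(x, default_k = default_k)
}

#' @rdname read_interactions
#' @export
as_interactions <- function(x, default_k = 200) {
  if (inherits(x, "elo_interactions")) {
    # already validated; re-establish chronological order in case the
    # caller reordered rows
    key_time <- ifelse(is.na(x$time), "~", x$time)
    x <- x[order(x$date, key_time, method = "radix"), , drop = FALSE]
    rownames(x) <- NULL
    return(x)
  }
  stopifnot(is.data.frame(x))
  if (!is.numeric(default_k) || length(default_k) != 1L ||
      is.na(default_k) || default_k <= 0) {
    stop("'default_k' must be a single positive number", call. = FALSE)
  }
  nm <- tolower(names(x))
  need <- c("date", "winner", "loser", "outcome")
  missing_cols <- setdiff(need, nm)
  if (length(missing_cols)) {
    stop("missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  col <- function(name) {
    i <- match(name, nm)
    if (is.na(i)) rep(NA_character_, nrow(x)) else as.character(x[[i]])
  }

  date_raw <- trimws(col("date"))
  date <- as.Date(date_raw, format = "%Y-%m-%d")
  bad <- which(is.na(date))
  if (length(bad)) {
    stop("unparseable Date '", date_raw[bad[1]], "' at data row ", bad[1],
         " (expected YYYY-MM-DD)", call. = FALSE)
  }

  time <- normalize_time(trimws(col("time")))

  winner <- trimws(col("winner"))
  loser  <- trimws(col("loser"))
  if (any(winner == "" | is.na(winner) | loser == "" | is.na(loser))) {
    stop("Winner and Loser must be non-empty in every row", call. = FALSE)
  }
  same <- which(winner == loser)
  if (length(same)) {
    stop("winner equals loser ('", winner[same[1]], "') at data row ",
         same[1], call. = FALSE)
  }

  k_raw <- trimws(col("k"))
  k <- suppressWarnings(as.numeric(k_raw))
  k[is.na(k_raw) | k_raw == ""] <- default_k
  bad <- which(is.na(k) | k <= 0)
  if (length(bad)) {
    stop("K must be blank or a positive number; offending value '",
         k_raw[bad[1]], "' at data row ", bad[1], call. = FALSE)
  }

  out_raw <- trimws(col("outcome"))
  if (!all(out_raw %in% c("0", "1"))) {
    bad <- which(!out_raw %in% c("0", "1"))[1]
    stop("Outcome must be 1 (decided) or 0 (draw); offending value '",
         out_raw[bad], "' at data row ", bad, call. = FALSE)
  }
  outcome <- ifelse(out_raw == "1", "decided", "draw")

  out <- data.frame(date = date, time = time, winner = winner,
                    loser = loser, k = k, outcome = outcome,
                    stringsAsFactors = FALSE)
  # stable chronological sort; untimed rows sort to end of day
  key_time <- ifelse(is.na(out$time), "~", out$time)
  out <- out[order(out$date, key_time, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("elo_interactions", "data.frame")
  out
}

# "8:56" -> "08:56"; "" -> NA; anything not HH:MM[:SS] is an error
normalize_time <- function(time) {
  time[is.na(time) | time == ""] <- NA_character_
  idx <- which(!is.na(time))
  if (!length(idx)) return(time)
  ok <- grepl("^[0-9]{1,2}:[0-9]{2}(:[0-9]{2})?$", time[idx])
  if (!all(ok)) {
    stop("unparseable Time '", time[idx][!ok][1], "' at data row ",
         idx[!ok][1], " (expected HH:MM)", call. = FALSE)
  }
  time[idx] <- sub("^([0-9]):", "0\\1:", time[idx])
  time
}

#' Write an interaction record to CSV
#'
#' Serializes interactions back to the `Date,Time,Winner,Loser,K,Outcome`
#' dialect read by [read_interactions()].
#'
#' @param interactions An `elo_interactions` object (or coercible data frame).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(interactions, path) {
  interactions <- as_interactions(interactions)
  out <- data.frame(Date = format(interactions$date, "%Y-%m-%d"),
                    Time = ifelse(is.na(interactions$time), "",
                                  interactions$time),
                    Winner = interactions$winner,
                    Loser = interactions$loser,
                    K = interactions$k,
                    Outcome = ifelse(interactions$outcome == "decided", 1L, 0L))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
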