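#' Write and re-read a rating trajectory
#'
#' `write_trajectory()` exports the per-interaction rating log of a fitted
#' [elo_seq()] model as a long-format CSV with columns
#' `date, time, event_index, id, rating_before, rating_after` — one row per
#' participant per event, ordered by event index with the winner's row
#' before the loser's. A header block of comment lines (prefixed `#`)
#' records the starting ratings so that the file is self-contained.
#'
#' `read_trajectory()` reads such a file back into a lightweight
#' `elo_traj` object accepted by [elo_snapshot()], [detect_burn_in()],
#' [ranks_on_dates()] and [consistency_report()], so that extraction and
#' validation can run from a stored file without refitting.
#'
#' @param object An `elo_seq` fit.
#' @param path File path.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns an `elo_traj` object.
#' @examples
#' fit <- elo_seq(system.file("extdata", "example_interactions.csv",
#'                            package = "elohist"))
#' f <- tempfile(fileext = ".csv")
#' write_trajectory(fit, f)
#' tr <- read_trajectory(f)
#' @export
write_trajectory <- function(object, path) {
  stopifnot(inherits(object, "elo_seq"))
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open '", path, "' for writing: ", conditionMessage(e),
         call. = FALSE)
  })
  on.exit(close(con))
  writeLines(sprintf("# start %s %s", names(object$start),
                     fmt17(object$start)), con)
  tr <- object$trajectory
  out <- data.frame(date = format(tr$date, "%Y-%m-%d"),
                    time = ifelse(is.na(tr$time), "", tr$time),
                    event_index = tr$event,
                    id = tr$id,
                    rating_before = fmt17(tr$rating_before),
                    rating_after = fmt17(tr$rating_after))
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("trajectory file not found: ", path,
                               call. = FALSE)
  lines <- readLines(path)
  hdr <- grep("^# start ", lines, value = TRUE)
  start <- numeric(0)
  if (length(hdr)) {
    parts <- strsplit(sub("^# start ", "", hdr), " ", fixed = TRUE)
    start <- stats::setNames(as.numeric(vapply(parts, `[`, "", 2L)),
                             vapply(parts, `[`, "", 1L))
  }
  tab <- utils::read.csv(text = lines[!startsWith(lines, "#")],
                         stringsAsFactors = FALSE,
                         colClasses = c(date = "character",
                                        time = "character", id = "character"))
  need <- c("date", "time", "event_index", "id", "rating_before",
            "rating_after")
  if (!all(need %in% names(tab))) {
    stop("not a trajectory file: expected columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  traj <- data.frame(event = tab$event_index,
                     date = as.Date(tab$date),
                     time = ifelse(is.na(tab$time) | tab$time == "",
                                   NA_character_, tab$time),
                     id = tab$id,
                     rating_before = tab$rating_before,
                     rating_after = tab$rating_after,
                     stringsAsFactors = FALSE)
  if (!length(start)) {
    first <- traj[!duplicated(traj$id), , drop = FALSE]
    start <- stats::setNames(first$rating_before, first$id)
  }
  structure(list(trajectory = traj, start = start,
                 roster = names(start),
                 n_processed = if (nrow(traj)) max(traj$event) else 0L),
            class = "elo_traj")
}

#' @export
print.elo_traj <- function(x, ...) {
  cat("Elo-rating trajectory: ", length(x$roster), " individuals, ",
      x$n_processed, " events\n", sep = "")
  invisible(x)
}

# 17 significant digits: enough for doubles to round-trip through text
fmt17 <- function(x) sprintf("%.17g", x)

# Normalize an elo_seq / elo_traj to the pieces extraction needs.
as_traj <- function(object) {
  if (inherits(object, "elo_seq")) {
    list(trajectory = object$trajectory, start = object$start,
         roster = object$roster, n_processed = object$n_processed)
  } else if (inherits(object, "elo_traj")) {
    unclass(object)
  } else {
    stop("expected an 'elo_seq' fit or an 'elo_traj' object", call. = FALSE)
  }
}
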