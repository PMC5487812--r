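#' Read a directional subordination-signal record
#'
#' Reads a CSV of directed subordination signals — e.g. chimpanzee
#' pant-grunts, in which the signaller acknowledges the recipient as
#' dominant — with header `Date, Time, Signaller, Recipient`. Records are
#' returned in chronological order (stable within ties; untimed rows sort
#' to the end of their day).
#'
#' @param x Path to a CSV file, or a data frame with those columns
#'   (matched case-insensitively).
#' @return A data frame of class `elo_signals` with columns `date`
#'   (Date), `time` (character or `NA`), `signaller`, `recipient`.
#' @export
read_signals <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("signal file not found: ", x, call. = FALSE)
    x <- utils::read.csv(x, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  }
  if (inherits(x, "elo_signals")) {
    key_time <- ifelse(is.na(x$time), "~", x$time)
    x <- x[order(x$date, key_time, method = "radix"), , drop = FALSE]
    rownames(x) <- NULL
    return(x)
  }
  stopifnot(is.data.frame(x))
  nm <- tolower(names(x))
  need <- c("date", "signaller", "recipient")
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
         call. = FALSE)
  }
  signaller <- trimws(col("signaller"))
  recipient <- trimws(col("recipient"))
  same <- which(signaller == recipient)
  if (length(same)) {
    stop("signaller equals recipient ('", signaller[same[1]],
         "') at data row ", same[1], call. = FALSE)
  }
  out <- data.frame(date = date, time = normalize_time(trimws(col("time"))),
                    signaller = signaller, recipient = recipient,
                    stringsAsFactors = FALSE)
  key_time <- ifelse(is.na(out$time), "~", out$time)
  out <- out[order(out$date, key_time, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("elo_signals", "data.frame")
  out
}

#' Write a signal record to CSV
#'
#' @param signals An `elo_signals` object (or coercible data frame).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_signals <- function(signals, path) {
  signals <- read_signals(signals)
  out <- data.frame(Date = format(signals$date, "%Y-%m-%d"),
                    Time = ifelse(is.na(signals$time), "", signals$time),
                    Signaller = signals$signaller,
                    Recipient = signals$recipient)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Check a modeled hierarchy against directional subordination signals
#'
#' A subordination signal directed from a higher-rated to a lower-rated
#' individual contradicts the modeled hierarchy: the model claims the
#' signaller is dominant while the signal says the opposite. This function
#' counts such inconsistencies, the distinct dyads involved, and the mean
#' and standard deviation of the offending rating differences, giving a
#' minimum standard against which hierarchies built under different
#' assumptions can be compared.
#'
#' Each signal is evaluated against the ratings on its own date (snapshot
#' semantics as in [elo_snapshot()]). A signal counts as inconsistent when
#' the signaller's rating exceeds the recipient's by more than
#' `class_interval`. The default interval of 0 counts every
#' reversed-direction signal, however small the difference; the
#' traditional chess class interval of 200 points can be supplied to
#' exempt signals within one rating "class", i.e. between individuals
#' whose dominance relationship the model deems undecided. Signals between
#' equally rated individuals are never inconsistent.
#'
#' @inheritParams elo_snapshot
#' @param signals An `elo_signals` record from [read_signals()] (or
#'   coercible data frame / path).
#' @param class_interval Rating band (>= 0) within which a dyad counts as
#'   the same class and a reversed signal is exempt. Default 0.
#' @return An object of class `elo_consistency`: a list with
#'   `n_signals`, `n_inconsistencies`, `n_inconsistent_dyads` (unordered
#'   pairs), `diff_mean`, `diff_sd` (over the inconsistent signals' rating
#'   differences; `NA` when undefined), `class_interval`, and `details`, a
#'   data frame with one row per inconsistent signal
#'   (`date, signaller, recipient, signaller_rating, recipient_rating,
#'   difference`).
#' @export
consistency_report <- function(object, signals, class_interval = 0,
                               include_same_day = TRUE) {
  tr <- as_traj(object)
  signals <- read_signals(signals)
  if (!is.numeric(class_interval) || length(class_interval) != 1L ||
      is.na(class_interval) || class_interval < 0) {
    stop("'class_interval' must be a single number >= 0", call. = FALSE)
  }
  bad <- setdiff(unique(c(signals$signaller, signals$recipient)), tr$roster)
  if (length(bad)) stop("signal id '", bad[1], "' is not in the roster",
                        call. = FALSE)

  n <- nrow(signals)
  s_rating <- r_rating <- numeric(n)
  for (d in unique(signals$date)) {
    sel <- which(signals$date == d)
    r <- ratings_at(tr, if (include_same_day)
      as.Date(d, origin = "1970-01-01") else
        as.Date(d, origin = "1970-01-01") - 1L)
    s_rating[sel] <- r[signals$signaller[sel]]
    r_rating[sel] <- r[signals$recipient[sel]]
  }
  diff <- s_rating - r_rating
  inc <- diff > class_interval
  details <- data.frame(date = signals$date[inc],
                        signaller = signals$signaller[inc],
                        recipient = signals$recipient[inc],
                        signaller_rating = s_rating[inc],
                        recipient_rating = r_rating[inc],
                        difference = diff[inc],
                        stringsAsFactors = FALSE)
  dyads <- unique(paste(pmin(details$signaller, details$recipient),
                        pmax(details$signaller, details$recipient)))
  structure(list(n_signals = n,
                 n_inconsistencies = sum(inc),
                 n_inconsistent_dyads = length(dyads),
                 diff_mean = if (sum(inc) >= 1L) mean(diff[inc]) else NA_real_,
                 diff_sd = if (sum(inc) >= 2L) stats::sd(diff[inc])
                           else NA_real_,
                 class_interval = class_interval,
                 details = details),
            class = "elo_consistency")
}

#' @export
print.elo_consistency <- function(x, ...) {
  cat("Hierarchy vs. subordination-signal consistency\n")
  cat("  signals:", x$n_signals,
      " class interval:", x$class_interval, "\n")
  cat("  ", format_consistency(x), "\n", sep = "")
  invisible(x)
}

# "N (D) mean +/- sd" one-liner, inconsistency count (dyads) and the
# mean +/- SD rating difference among inconsistent signals
format_consistency <- function(x) {
  if (x$n_inconsistencies == 0L) return("0 (0)")
  msd <- if (is.na(x$diff_sd)) sprintf("%.2f", x$diff_mean) else
    sprintf("%.2f ± %.2f", x$diff_mean, x$diff_sd)
  sprintf("%d (%d) %s", x$n_inconsistencies, x$n_inconsistent_dyads, msd)
}
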