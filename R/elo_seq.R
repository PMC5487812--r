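#' Fit a sequential Elo-rating model to an interaction record
#'
#' Processes a chronological record of dyadic win/loss interactions,
#' updating both participants' Elo-ratings after every event. The rating
#' change for one event is `delta = (1 - p) * k`, added to the winner and
#' subtracted from the loser, where `p` is the winner's expected win
#' probability given the pre-interaction rating difference
#' (see [elo_expected()]) and `k` is that interaction's K value. Upsets —
#' wins by the lower-rated individual — therefore move ratings more than
#' expected wins, and high-intensity interactions (larger K) more than
#' low-intensity ones. Draws move each participant by
#' `k * (0.5 - p_self)`. Every update is zero-sum, so the rating total is
#' conserved across the whole sequence.
#'
#' Starting ratings come from [starting_ratings()]: with no prior history
#' every individual starts at `priors$starting_value` and the model is the
#' standard equal-start formulation; with prior Elo-ratings, ordinal ranks,
#' or rank categories supplied, individuals start from positions that
#' already encode the known hierarchy, which shortens or removes the
#' burn-in period.
#'
#' Events are processed in chronological order (ties in timestamp in input
#' order). Individuals named only in the priors but never interacting keep
#' their starting rating and appear in all outputs.
#'
#' @param interactions An `elo_interactions` object from
#'   [read_interactions()], or a data frame / CSV path coercible to one.
#' @param priors An [elo_priors()] object (default: no prior history,
#'   baseline 1000, K 200).
#' @param model Expectation model, `"normal"` (default) or `"logistic"`;
#'   see [elo_expected()].
#' @param roster Optional character vector fixing the set of individuals.
#'   By default the roster is the union of ids appearing in the
#'   interactions and in the priors. If given, every interacting id must be
#'   in it.
#' @param default_k Default K used when `interactions` is a path or plain
#'   data frame with blank K cells; ignored for ready-made
#'   `elo_interactions` input.
#' @return An object of class `elo_seq`: a list with elements
#'   `ratings` (final ratings, named), `start` (starting ratings),
#'   `trajectory` (data frame: `event`, `date`, `time`, `id`,
#'   `rating_before`, `rating_after`; winner row before loser row within an
#'   event), `interactions`, `roster`, `model`, `priors`, `n_processed`.
#' @examples
#' path <- system.file("extdata", "example_interactions.csv",
#'                     package = "elohist")
#' fit <- elo_seq(path)
#' fit
#' coef(fit)
#' @seealso [elo_snapshot()], [detect_burn_in()], [consistency_report()]
#' @export
elo_seq <- function(interactions, priors = elo_priors(),
                    model = c("normal", "logistic"), roster = NULL,
                    default_k = priors$k) {
  model <- match.arg(model)
  stopifnot(inherits(priors, "elo_priors"))
  interactions <- read_interactions(interactions, default_k = default_k)

  prior_ids <- unique(c(names(priors$prior_elo), names(priors$prior_ranks),
                        names(priors$prior_categories)))
  active <- unique(c(interactions$winner, interactions$loser))
  if (is.null(roster)) {
    roster <- unique(c(active, prior_ids))
  } else {
    roster <- as.character(roster)
    outside <- setdiff(active, roster)
    if (length(outside)) {
      stop("interaction references id '", outside[1],
           "' outside the supplied roster", call. = FALSE)
    }
  }
  if (!length(roster)) {
    stop("no individuals: empty interaction record and no priors",
         call. = FALSE)
  }

  start <- starting_ratings(priors, roster)
  r <- start
  n <- nrow(interactions)
  wi <- match(interactions$winner, roster)
  li <- match(interactions$loser, roster)

  before_w <- before_l <- after_w <- after_l <- numeric(n)
  for (i in seq_len(n)) {
    p <- elo_expected(r[[wi[i]]] - r[[li[i]]], model)
    d <- elo_delta(p, interactions$k[i], interactions$outcome[i])
    before_w[i] <- r[[wi[i]]]; before_l[i] <- r[[li[i]]]
    r[[wi[i]]] <- r[[wi[i]]] + d
    r[[li[i]]] <- r[[li[i]]] - d
    after_w[i] <- r[[wi[i]]]; after_l[i] <- r[[li[i]]]
  }

  traj <- data.frame(
    event = rep(seq_len(n), each = 2L),
    date = rep(interactions$date, each = 2L),
    time = rep(interactions$time, each = 2L),
    id = as.vector(rbind(interactions$winner, interactions$loser)),
    rating_before = as.vector(rbind(before_w, before_l)),
    rating_after = as.vector(rbind(after_w, after_l)),
    stringsAsFactors = FALSE
  )

  structure(list(ratings = r, start = start, trajectory = traj,
                 interactions = interactions, roster = roster,
                 model = model, priors = priors, n_processed = n,
                 call = match.call()),
            class = "elo_seq")
}

#' @export
print.elo_seq <- function(x, ...) {
  cat("Sequential Elo-rating model (", x$model, " expectation)\n", sep = "")
  cat("  ", length(x$roster), " individuals, ", x$n_processed,
      " interactions", sep = "")
  if (x$n_processed > 0) {
    cat(" (", format(min(x$interactions$date)), " to ",
        format(max(x$interactions$date)), ")", sep = "")
  }
  cat("\n")
  top <- sort(x$ratings, decreasing = TRUE)
  k <- min(5L, length(top))
  cat("  final ratings (top ", k, "): ",
      paste(sprintf("%s=%.0f", names(top)[1:k], top[1:k]), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.elo_seq <- function(object, ...) {
  tab <- data.frame(id = object$roster,
                    start = unname(object$start[object$roster]),
                    final = unname(object$ratings[object$roster]),
                    stringsAsFactors = FALSE)
  tab$change <- tab$final - tab$start
  tab$rank <- competition_rank(object$ratings)[tab$id]
  tab <- tab[order(tab$rank, -tab$final), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, model = object$model,
                 n_processed = object$n_processed,
                 priors = object$priors,
                 dates = if (object$n_processed > 0)
                   range(object$interactions$date) else NULL),
            class = "summary.elo_seq")
}

#' @export
print.summary.elo_seq <- function(x, digits = 1, ...) {
  cat("Sequential Elo-rating model (", x$model, " expectation)\n", sep = "")
  if (!is.null(x$dates)) {
    cat(x$n_processed, " interactions, ", format(x$dates[1]), " to ",
        format(x$dates[2]), "\n", sep = "")
  } else {
    cat("no interactions processed\n")
  }
  print(x$priors)
  cat("\nFinal ratings:\n")
  tab <- x$table
  tab$start <- round(tab$start, digits)
  tab$final <- round(tab$final, digits)
  tab$change <- round(tab$change, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.elo_seq <- function(object, ...) object$ratings

#' Expected win probabilities from a fitted Elo sequence
#'
#' Returns the probability that `focal` beats `opponent` given their
#' ratings on `date` (by default, the final ratings), under the fitted
#' expectation model.
#'
#' @param object An `elo_seq` fit.
#' @param focal,opponent Character vectors of ids (recycled to a common
#'   length).
#' @param date Optional date at which to take the ratings; default final.
#' @param ... Unused.
#' @return Numeric vector of win probabilities.
#' @export
predict.elo_seq <- function(object, focal, opponent, date = NULL, ...) {
  n <- max(length(focal), length(opponent))
  focal <- rep_len(as.character(focal), n)
  opponent <- rep_len(as.character(opponent), n)
  bad <- setdiff(c(focal, opponent), object$roster)
  if (length(bad)) stop("unknown id '", bad[1], "'", call. = FALSE)
  r <- if (is.null(date)) object$ratings else {
    snap <- elo_snapshot(object, date)
    stats::setNames(snap$rating, snap$id)
  }
  elo_expected(r[focal] - r[opponent], object$model) |> unname()
}

#' Outcome residuals of a fitted Elo sequence
#'
#' For each interaction, the winner's observed score (1 for a decided
#' interaction, 0.5 for a draw) minus the winner's expected win probability
#' before the interaction. Positive residuals are upsets or wins by
#' closely matched individuals; a long run of large residuals early in the
#' record is the signature of a burn-in period, where pre-interaction
#' ratings do not yet predict outcomes.
#'
#' @param object An `elo_seq` fit.
#' @param ... Unused.
#' @return Numeric vector, one residual per interaction.
#' @export
residuals.elo_seq <- function(object, ...) {
  tr <- object$trajectory
  wrows <- tr[seq(1L, by = 2L, length.out = object$n_processed), ,
              drop = FALSE]
  ints <- object$interactions
  lrows <- tr[seq(2L, by = 2L, length.out = object$n_processed), ,
              drop = FALSE]
  p <- elo_expected(wrows$rating_before - lrows$rating_before, object$model)
  score <- ifelse(ints$outcome == "decided", 1, 0.5)
  score - p
}

#' Plot rating trajectories
#'
#' Draws each individual's Elo-rating trajectory over the span of the
#' interaction record as a step function (ratings are piecewise constant
#' between interactions).
#'
#' @param x An `elo_seq` fit.
#' @param ids Ids to draw (default: whole roster).
#' @param col Line colours, recycled over ids.
#' @param legend Logical; draw a legend (default `TRUE`).
#' @param ... Passed to [graphics::matplot()]-style base plotting.
#' @return `x`, invisibly.
#' @export
plot.elo_seq <- function(x, ids = x$roster, col = NULL, legend = TRUE, ...) {
  if (x$n_processed == 0) stop("nothing to plot: no interactions",
                               call. = FALSE)
  dates <- seq(min(x$interactions$date), max(x$interactions$date), by = "day")
  mat <- daily_rating_matrix(x, dates)[, ids, drop = FALSE]
  if (is.null(col)) col <- grDevices::hcl.colors(length(ids), "Dark 3")
  col <- rep_len(col, length(ids))
  graphics::matplot(dates, mat, type = "s", lty = 1, col = col,
                    xlab = "date", ylab = "Elo-rating",
                    main = "Elo-rating trajectories", xaxt = "n", ...)
  graphics::axis.Date(1, x = dates)
  if (legend) {
    graphics::legend("topleft", legend = ids, col = col, lty = 1,
                     cex = 0.8, bty = "n")
  }
  invisible(x)
}

#' Simulate replicate interaction records from a fitted model
#'
#' Keeps the observed schedule (dates, times, dyads and K values) and
#' redraws every outcome from the fitted final ratings under the fitted
#' expectation model. Useful as a parametric-bootstrap check of trajectory
#' variability under the model.
#'
#' @param object An `elo_seq` fit.
#' @param nsim Number of replicate records.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @param ... Unused.
#' @return A list of `nsim` `elo_interactions` data frames.
#' @export
simulate.elo_seq <- function(object, nsim = 1, seed = NULL, ...) {
  if (object$n_processed == 0) stop("no interactions to resample",
                                    call. = FALSE)
  with_seed(seed, {
    ints <- object$interactions
    p1 <- elo_expected(object$ratings[ints$winner] -
                         object$ratings[ints$loser], object$model)
    lapply(seq_len(nsim), function(s) {
      win1 <- stats::runif(nrow(ints)) < p1
      out <- ints
      out$winner <- ifelse(win1, ints$winner, ints$loser)
      out$loser <- ifelse(win1, ints$loser, ints$winner)
      class(out) <- c("elo_interactions", "data.frame")
      out
    })
  })
}

# competition ranking: tied ratings share the smaller rank, next rank skipped
competition_rank <- function(ratings) {
  vapply(ratings, function(v) 1L + sum(ratings > v), integer(1L)) |>
    stats::setNames(names(ratings))
}

# evaluate expr with a temporary seed, restoring the RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
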