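#' Intensity categories and K values of male chimpanzee aggression
#'
#' The per-interaction K ladder used for male chimpanzee agonistic
#' behaviour, anchoring the customary K of 200 at the most commonly
#' observed form (the directed charging display) and scaling up and down
#' in multiples of 25 with the intensity of aggression: static threats 50,
#' approach threats 100, undirected charging displays 150 or 175, directed
#' charging displays 200, chases 225, and attacks 250-375 by severity.
#' The mixture weights are proportional to the observed frequency of each
#' intensity among 405 decided interactions (38, 53, 5, 22, 125, 97, 26,
#' 35, 4), so the default simulator draws K values with realistic
#' frequencies.
#'
#' @return A list with `k_values` (numeric, ascending), `weights`
#'   (probabilities summing to 1), and `counts` (the observed tallies).
#' @examples
#' default_intensity_mixture()
#' @seealso [simulate_hierarchy()]
#' @export
default_intensity_mixture <- function() {
  counts <- c(`threat/static` = 38, `threat/approach` = 53,
              `charge/no target` = 5, `charge/through party` = 22,
              `charge/targeted` = 125, `chase` = 97,
              `attack/in passing` = 26, `attack/<30s` = 35,
              `attack/prolonged` = 4)
  k_values <- c(50, 100, 150, 175, 200, 225, 250, 300, 375)
  list(k_values = k_values, weights = unname(counts) / sum(counts),
       counts = counts)
}

#' Simulate interaction sequences from a latent dominance hierarchy
#'
#' Generates a seeded, fully reproducible record of dyadic agonistic
#' interactions (and, optionally, directional subordination signals) from
#' a known latent hierarchy, so that rating models can be tested against
#' ground truth. Each event samples a dyad (uniformly by default), decides
#' the winner with probability `plogis(steepness * strength difference)`
#' in favour of the latent-stronger individual, and assigns a K value by
#' drawing an intensity category from `intensity` (by default the observed
#' chimpanzee mixture of [default_intensity_mixture()]). Events are spread
#' evenly over `days` consecutive dates, in non-decreasing time order.
#'
#' The latent win model is logistic in the strength difference regardless
#' of the expectation model later used for fitting, so tests of the
#' normal-expectation fit are not circular. Default strengths are evenly
#' spaced one unit apart, and the default steepness gives adjacent
#' individuals a 4:1 odds (0.8 win probability) — a clearly, but not
#' perfectly, linear hierarchy.
#'
#' Signals emulate subordination vocalizations: for each event, with
#' probability `signal_rate` an independently sampled dyad exchanges a
#' signal from the latent-subordinate to the latent-dominant member,
#' reversed with probability `signal_error_rate` (planted errors for
#' validation tests).
#'
#' @param n_individuals Number of individuals (>= 2). Ids are `id01`,
#'   `id02`, ... in decreasing latent strength.
#' @param n_events Number of interactions to generate.
#' @param days Number of calendar days the record spans (default 300,
#'   a field season of ten months).
#' @param strengths Optional numeric vector of latent strengths (default
#'   evenly spaced, strongest first).
#' @param steepness Positive scale applied to strength differences in the
#'   latent win model (default `qlogis(0.8)`, i.e. adjacent win
#'   probability 0.8 at unit spacing).
#' @param intensity A list with `k_values` and `weights` as returned by
#'   [default_intensity_mixture()].
#' @param signal_rate Per-event probability of a subordination signal
#'   (default 0.2).
#' @param signal_error_rate Probability a signal goes in the reversed
#'   direction (default 0).
#' @param rank_bias Non-negative dyad-sampling bias; 0 (default) samples
#'   dyads uniformly, larger values oversample high-strength individuals
#'   in proportion to `exp(rank_bias * strength)`, mimicking field records
#'   in which high-ranking animals are observed more often.
#' @param seed Optional integer seed; the global RNG state is restored
#'   afterwards.
#' @param start_date First date of the record.
#' @return A list with `interactions` (an `elo_interactions` data frame),
#'   `signals` (an `elo_signals` data frame), `latent_order` (ids from
#'   strongest to weakest), and `strengths`.
#' @examples
#' sim <- simulate_hierarchy(6, 200, days = 60, seed = 1)
#' fit <- elo_seq(sim$interactions)
#' @export
simulate_hierarchy <- function(n_individuals, n_events, days = 300,
                               strengths = NULL,
                               steepness = stats::qlogis(0.8),
                               intensity = default_intensity_mixture(),
                               signal_rate = 0.2, signal_error_rate = 0,
                               rank_bias = 0, seed = NULL,
                               start_date = as.Date("2003-10-01")) {
  if (!is.numeric(n_individuals) || n_individuals < 2) {
    stop("'n_individuals' must be at least 2", call. = FALSE)
  }
  n_individuals <- as.integer(n_individuals)
  n_events <- as.integer(n_events)
  stopifnot(n_events >= 0, days >= 1, steepness > 0,
            signal_rate >= 0, signal_rate <= 1,
            signal_error_rate >= 0, signal_error_rate <= 1, rank_bias >= 0)
  if (is.null(strengths)) strengths <- as.numeric(n_individuals:1)
  stopifnot(length(strengths) == n_individuals)
  if (abs(sum(intensity$weights) - 1) > 1e-8 ||
      length(intensity$weights) != length(intensity$k_values)) {
    stop("'intensity' must have matching k_values and weights summing to 1",
         call. = FALSE)
  }
  ids <- sprintf("id%02d", seq_len(n_individuals))
  latent_order <- ids[order(strengths, decreasing = TRUE)]
  start_date <- as.Date(start_date)

  with_seed(seed, {
    samp_w <- exp(rank_bias * (strengths - max(strengths)))
    sample_dyad <- function(n) {
      a <- integer(n); b <- integer(n)
      for (i in seq_len(n)) {
        pair <- sample.int(n_individuals, 2L, prob = samp_w)
        a[i] <- pair[1L]; b[i] <- pair[2L]
      }
      cbind(a, b)
    }
    dyads <- sample_dyad(n_events)
    p_first <- stats::plogis(steepness *
                               (strengths[dyads[, 1L]] -
                                  strengths[dyads[, 2L]]))
    first_wins <- stats::runif(n_events) < p_first
    w <- ifelse(first_wins, dyads[, 1L], dyads[, 2L])
    l <- ifelse(first_wins, dyads[, 2L], dyads[, 1L])
    cat_idx <- if (n_events)
      sample.int(length(intensity$k_values), n_events, replace = TRUE,
                 prob = intensity$weights) else integer(0)
    day_off <- if (n_events)
      floor((seq_len(n_events) - 1L) * days / n_events) else integer(0)
    within <- stats::ave(seq_len(n_events), day_off, FUN = seq_along)
    times <- sprintf("%02d:%02d", 8L + (within - 1L) %/% 60L %% 12L,
                     (within - 1L) %% 60L)
    interactions <- data.frame(
      date = start_date + day_off,
      time = if (n_events) times else character(0),
      winner = ids[w], loser = ids[l],
      k = intensity$k_values[cat_idx],
      outcome = rep("decided", n_events),
      stringsAsFactors = FALSE)
    class(interactions) <- c("elo_interactions", "data.frame")

    emit <- stats::runif(n_events) < signal_rate
    sd_dyads <- sample_dyad(sum(emit))
    dom <- ifelse(strengths[sd_dyads[, 1L]] >= strengths[sd_dyads[, 2L]],
                  sd_dyads[, 1L], sd_dyads[, 2L])
    sub <- ifelse(dom == sd_dyads[, 1L], sd_dyads[, 2L], sd_dyads[, 1L])
    rev <- stats::runif(sum(emit)) < signal_error_rate
    signaller <- ifelse(rev, dom, sub)
    recipient <- ifelse(rev, sub, dom)
    signals <- data.frame(
      date = (start_date + day_off)[emit],
      time = times[emit],
      signaller = ids[signaller], recipient = ids[recipient],
      stringsAsFactors = FALSE)
    class(signals) <- c("elo_signals", "data.frame")

    list(interactions = interactions, signals = signals,
         latent_order = latent_order, strengths = stats::setNames(strengths,
                                                                  ids))
  })
}
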