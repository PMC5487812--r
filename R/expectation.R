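#' Expected probability of winning from a rating difference
#'
#' Converts the difference in Elo-rating between two contestants into the
#' expected probability that the higher-context individual (the one whose
#' rating enters the difference positively) wins the encounter.
#'
#' Two standard functional forms are offered. The `"normal"` model, the
#' default, evaluates the standard normal distribution function at
#' `rating_diff / (200 * sqrt(2))`, i.e. each contestant's performance is
#' drawn from a normal distribution with standard deviation 200 rating
#' points. The `"logistic"` model is the chess convention
#' `1 / (1 + 10^(-rating_diff / 400))`. Both give probability 0.5 at a zero
#' difference, are strictly increasing in the difference, and satisfy
#' `p(d) + p(-d) = 1`; they differ only in tail weight, and for typical
#' dominance data the choice is immaterial to the ordering of individuals.
#'
#' @param rating_diff Numeric vector of rating differences
#'   (focal minus opponent), in Elo points. Must be finite.
#' @param model Character, `"normal"` (default) or `"logistic"`.
#' @return Numeric vector of win probabilities in `[0, 1]`.
#' @examples
#' elo_expected(0)                      # 0.5
#' elo_expected(200, model = "logistic") # ~0.76
#' @seealso [elo_seq()] which applies this expectation sequentially.
#' @export
elo_expected <- function(rating_diff, model = c("normal", "logistic")) {
  model <- match.arg(model)
  if (!is.numeric(rating_diff) || anyNA(rating_diff) ||
      any(!is.finite(rating_diff))) {
    stop("'rating_diff' must be finite numeric", call. = FALSE)
  }
  switch(model,
    normal   = stats::pnorm(rating_diff / (200 * sqrt(2))),
    logistic = 1 / (1 + 10^(-rating_diff / 400))
  )
}

# Rating change applied to the winner (and, negated, to the loser) for a
# single interaction. For a draw each participant moves by k * (0.5 - p_self);
# the winner slot's change is k * (0.5 - p), exactly minus the loser's, so
# every event is zero-sum by construction.
elo_delta <- function(p_winner, k, outcome) {
  if (outcome == "decided") (1 - p_winner) * k else k * (0.5 - p_winner)
}
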