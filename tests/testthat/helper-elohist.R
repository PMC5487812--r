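# Shared fixtures, built in code.

example_path <- function() {
  system.file("extdata", "example_interactions.csv", package = "elohist")
}

# Final ratings of the 9-event worked example (equal start 1000, normal
# expectation), frozen from an independent step-by-step hand calculation
# of the nine sequential updates performed before the package was written.
example_final_oracle <- c(
  ZF = 1128.690768698214,
  TK = 726.445284199437,
  DN = 1242.890748928298,
  MA = 877.934850223988,
  NK = 1024.038347950064
)

# Ratings after the first three events of the worked example, from the
# same hand calculation (10 decimal places).
example_after3_oracle <- c(
  ZF = 1039.9250035831, TK = 846.0433759368, DN = 1114.0316204801,
  MA = 1000, NK = 1000
)

# quick interaction-record constructor
make_ints <- function(winner, loser, k = 200, outcome = 1,
                      date = "2020-01-01", time = NA_character_) {
  n <- max(length(winner), length(loser))
  as_interactions(data.frame(
    Date = rep_len(as.character(date), n),
    Time = rep_len(time, n),
    Winner = rep_len(winner, n), Loser = rep_len(loser, n),
    K = rep_len(k, n), Outcome = rep_len(outcome, n)))
}

# one-event fit from explicit starting ratings; returns the winner's gain
one_event_gain <- function(r_winner, r_loser, k, model = "normal",
                           outcome = 1) {
  fit <- elo_seq(make_ints("W", "L", k = k, outcome = outcome),
                 priors = elo_priors(prior_elo = c(W = r_winner,
                                                   L = r_loser)),
                 model = model)
  unname(coef(fit)["W"] - r_winner)
}
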