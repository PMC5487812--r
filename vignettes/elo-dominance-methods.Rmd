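---
title: "Modelling dominance hierarchies with prior history and variable K"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling dominance hierarchies with prior history and variable K}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elohist)
```

## The model and its assumptions

`elohist` fits a sequential Elo-rating model to a dated record of dyadic
agonistic interactions. Each individual carries a real-valued rating; after
every interaction the winner gains, and the loser loses,

$$\Delta R = (1 - p)\,K,$$

where $p$ is the winner's expected probability of winning given the
pre-interaction rating difference and $K$ scales how much one contest can
move ratings. Draws move each participant by $K(0.5 - p_{\text{self}})$.
The assumptions this encodes:

* dominance is a dyadic property, summarized by the outcome of contests
  with a clear winner and loser;
* surprising outcomes are more informative — an upset moves ratings more
  than an expected win;
* ratings are interval-scale and unbounded; negative values are legal and
  simply mean "far below the baseline";
* every update is zero-sum, so the rating total is an invariant of the
  whole analysis (a useful internal check, exploited heavily in the test
  suite).

### The expectation function

The expectation $p$ must map a rating difference to a win probability,
with $p(0) = 0.5$, strict monotonicity, and $p(d) + p(-d) = 1$. Two
standard forms satisfy this and the package offers both:

* **normal** (default): $p = \Phi\!\big(d / (200\sqrt{2})\big)$, i.e. each
  contestant's performance is normally distributed with standard deviation
  200 points — the form used in the behavioural-ecology lineage of the
  method;
* **logistic**: $p = 1/(1 + 10^{-d/400})$, the chess convention.

The two differ only in tail weight. Because the source literature for the
dominance application does not pin down a single canonical form, the
choice is an explicit `model` argument rather than a hidden constant;
every analysis in this package's tests passes under either, and the
default is `"normal"`.

### Per-interaction K and the intensity of aggression

Holding $K$ constant asserts that a mild threat and a damaging fight carry
the same information about the dominance relationship. `elohist` instead
reads a K value per interaction from the data file, so intensity
assumptions are explicit data, not code. The bundled intensity ladder for
male chimpanzee aggression (`default_intensity_mixture()`) anchors the
customary $K = 200$ at the most commonly observed category (the directed
charging display) and scales in multiples of 25: static threats 50,
approach threats 100, undirected charging displays 150–175, directed
charging displays 200, chases 225, attacks 250, 300 or 375 with severity.
The mixture weights are the observed relative frequencies of those
categories among 405 decided interactions (38, 53, 5, 22, 125, 97, 26,
35, 4). Nothing in the fitting code depends on this ladder — it
parameterizes the simulator and documents a defensible default.

## Starting ratings from prior history

With no other information, all individuals must start at a common
baseline $S_e$ (default 1000), and early ratings are unreliable until the
model "catches up" with reality — the burn-in period. When a prior
ranking exists, `elo_priors()` accepts it in three forms, used in order
of preference:

1. **explicit Elo-ratings** — used exactly as given (appropriate when they
   come from a directly preceding analysis of comparable data);
2. **ordinal ranks** (1 = most dominant, ties allowed);
3. **ordered categories** `alpha`, `high`, `medium`, `low`, mapped to
   ranks $1$, $N/4$, $N/2$, $N - N/4$ ($N$ = all subjects in the
   analysis), which spreads the four categories evenly over the rank
   range.

Rank-based priors become starting ratings through the reciprocal-power
rule

$$E_i = S_e + (x_r - S_{ri})\,K\,S_{ri}^{-I_r},$$

with $x_r$ the median of the supplied ranks and $I_r \ge 0$ the spreading
index. At $I_r = 0$ consecutive ranks are spaced exactly $K$ apart.
Larger $I_r$ stretches the top-ranked individual away while compressing
differences among low ranks — a shape that matches hierarchies with a
clearly dominant alpha over a cluster of low-ranking individuals. Values
around 0.3 stretch the alpha without imposing an extreme pattern; the
index is accepted as any non-negative real.

```{r}
ranks <- c(a = 1, b = 2, c = 3, d = 4, e = 5)
round(rbind(
  linear = starting_ratings(elo_priors(prior_ranks = ranks), letters[1:5]),
  power  = starting_ratings(elo_priors(prior_ranks = ranks,
                                       rank_index = 0.3), letters[1:5])))
```

Three design points were genuinely open and are resolved as follows:

* **Centring.** "Centred on $S_e$" is implemented as a common shift making
  the *mean over ranked individuals* equal $S_e$. A shift preserves every
  pairwise difference the formula produced, and it reduces to the identity
  in the symmetric complete-rank case at $I_r = 0$. Unranked individuals
  are not shifted; they receive $S_e$ exactly, as the categorical-prior
  contract requires.
* **Fractional category ranks** ($N/4$ etc.) enter the formula unrounded;
  rounding would manufacture ties between categories that the mapping
  deliberately separates.
* **$x_r$ under partial priors** is the median of the supplied ranks only;
  unlisted individuals are outside the rank scale by construction.

## The fitted object

`elo_seq()` returns a classed object in the usual R modelling idiom:
`print()`, `summary()`, `coef()` (final ratings), `plot()` (trajectories),
`predict()` (win probabilities for chosen dyads on chosen dates),
`residuals()` (winner's observed score minus expectation — large early
residuals are the burn-in signature), and `simulate()` (outcome
re-draws under the fitted ratings on the observed schedule). Extraction
and validation functions accept either the fit or a trajectory re-read
from disk (`read_trajectory()`), so stored runs remain analysable.

Ordering is deterministic throughout: events are stably sorted by date
then time, ties (including absent times, which sort to the end of their
day) are processed in input order, and within one event the winner's log
row precedes the loser's.

## Daily snapshots and burn-in detection

`elo_snapshot()` reports each individual's rating after the last
interaction at or before the end of the requested day, and ordinal ranks
by competition ranking (tied ratings share the smaller rank: 1, 2, 2, 4),
so equal ratings are never ordered arbitrarily. Whether a day's own
interactions are included is switchable (`include_same_day`, default
`TRUE`): comparing daily ranks against same-day behaviour argues for the
end-of-day reading, but the eve-of-day reading is needed when asking what
the model believed *before* an event, and both are tested.

`detect_burn_in()` operationalizes "the alpha has a stable trajectory":
the earliest date $d$ such that across $[d, d + \texttt{window\_days}]$
(required to lie within the record) one individual holds the uniquely
highest rating every day and never moves more than `tolerance` points
day-over-day. Two deliberate choices:

* A day whose top rating is *shared* is never stable. This is what makes
  an equal start register as burn-in: on day one every individual is tied
  at $S_e$, the alpha identity is unresolved, and stability can only be
  declared once interactions have separated the top.
* Defaults `window_days = 30`, `tolerance = 25` (one eighth of the default
  K) are documented starting points, not calibrated constants; the right
  values scale with the interaction rate of the study system.

## Validation against subordination signals

Directional subordination signals — the chimpanzee pant-grunt is the
motivating example — mark the signaller as subordinate to the recipient.
`consistency_report()` looks up both parties' ratings on each signal's
date and counts a signal as inconsistent when the signaller out-rates the
recipient by more than `class_interval`. The default interval is 0:
every reversed signal counts, however small the gap, because the purpose
is to find categorical errors, and a hierarchy should be judged by its
worst contradictions. The traditional 200-point chess "class interval" is
available as an explicit alternative for users who prefer to exempt
closely rated dyads whose relationship the model deems undecided; equal
ratings are exempt at any interval. Dyads are counted as unordered pairs
among the inconsistent signals, and the summary line prints
`N (dyads) mean ± sd` of the offending rating differences.

Signals are validation data only; they are never fed into the rating
updates. Whether subordination signals should update ratings at all — and
with what K — is a modelling question the package deliberately leaves to
the user's data file.

## The simulator

`simulate_hierarchy()` generates ground-truthed data so every claim above
is testable without field data. It draws, per event, a dyad (uniform by
default), a winner (probability `plogis(steepness × strength
difference)` for the latent-stronger individual), and a K value from the
intensity mixture; events are spread evenly over the configured days.
Optionally it emits subordination signals subordinate→dominant at
`signal_rate` per event, reversed with probability `signal_error_rate`
(planted errors with known counts). Design points:

* The latent win model is *logistic* in strength regardless of the
  expectation used for fitting, so tests of the default normal-expectation
  fit are not circular.
* Default strengths are evenly spaced with adjacent win probability 0.8
  (`steepness = qlogis(0.8)`) — a clear but imperfect linear hierarchy, in
  the range of observed primate data.
* `rank_bias > 0` oversamples strong individuals in the dyad draw,
  mimicking field records in which peripheral or rarely followed
  individuals are undersampled (undersampling, not the model, is a
  plausible source of residual inconsistencies in real data).
* Everything is a deterministic function of `seed`, and the global RNG
  state is restored afterwards.

What the simulator does **not** emulate: fission–fusion party structure
and focal-follow observability, escalation within interactions, coalition
effects, temporal drift in latent strengths, and seasonal variation in
interaction rate. Passing tests therefore demonstrate correctness of the
bookkeeping and the statistical behaviour of the estimator under a
stationary linear hierarchy — not that any particular field data set is
free of sampling artefacts.

## Numerical and scale choices

* Trajectory CSVs store ratings with 17 significant digits, so a written
  trajectory re-reads bit-identically.
* Conservation of the rating total holds to well below $10^{-6}$ over
  $10^4$ events (each update applies one computed delta with both signs).
* Test and acceptance problem sizes — 10–14 individuals, 2,000–10,000
  events over a 300-day span, 20 replicate seeds — were chosen to match a
  realistic single-community field study (a dozen adult and adolescent
  males, several hundred decided interactions per season) while keeping
  the full suite comfortably fast; correlations and proportions reported
  at that scale are stable to the displayed precision across seeds.
* Degenerate inputs are first-class: empty interaction files fit to the
  starting ratings, individuals named only in priors ride along
  unchanged, and an empty signal list yields an all-zero report.

## Known limitations

* K values are user assertions; the package makes them explicit and
  testable but does not estimate them (maximum-likelihood tuning of K is
  out of scope by design).
* Burn-in detection keys on the alpha's trajectory; in groups where the
  alpha is seeded separately from an otherwise tied field, lower ranks can
  still be in burn-in after the alpha stabilizes.
* The prior-initialization spreading index $I_r$ must be chosen by the
  user; deriving it from hierarchy-steepness measures is future work.
* Ratings are comparable only within one analysis; no cross-group or
  cross-period anchoring is attempted.
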