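test_that("the shipped example datafile parses to the expected record", {
  ints <- read_interactions(example_path())
  expect_s3_class(ints, "elo_interactions")
  expect_equal(nrow(ints), 9L)
  expect_setequal(unique(c(ints$winner, ints$loser)),
                  c("ZF", "TK", "DN", "MA", "NK"))
  expect_equal(ints$k, c(100, 200, 200, 275, 200, 200, 200, 200, 100))
  expect_true(all(ints$outcome == "decided"))
  expect_true(!is.unsorted(ints$date))
})

test_that("reader applies the blank-K rule and validates rows", {
  df <- data.frame(Date = "2020-01-02", Time = "", Winner = "a",
                   Loser = "b", K = "", Outcome = "1")
  expect_equal(read_interactions(df, default_k = 150)$k, 150)
  # header-only file gives an empty record
  f <- tempfile(fileext = ".csv")
  writeLines("Date,Time,Winner,Loser,K,Outcome", f)
  expect_equal(nrow(read_interactions(f)), 0L)
  unlink(f)

  expect_error(read_interactions(df[, -1, drop = FALSE]),
               "missing required column")
  expect_error(read_interactions(transform(df, Date = "02/01/2020")),
               "row 1")
  expect_error(read_interactions(transform(df, Outcome = "2")),
               "Outcome")
  expect_error(read_interactions(transform(df, Loser = "a")),
               "winner equals loser")
  expect_error(read_interactions(transform(df, K = "-5")), "positive")
})

test_that("rows are stably sorted by date then time", {
  df <- data.frame(
    Date = c("2020-01-03", "2020-01-01", "2020-01-02", "2020-01-02",
             "2020-01-02"),
    Time = c("09:00", "", "10:15", "08:30", ""),
    Winner = letters[1:5], Loser = letters[6:10], K = "", Outcome = "1")
  ints <- read_interactions(df)
  # explicit sort oracle: order by date, then time with blanks last
  key <- order(as.Date(df$Date), ifelse(df$Time == "", "~", df$Time))
  expect_equal(ints$winner, df$Winner[key])
  # same multiset of rows regardless of input order
  perm <- read_interactions(df[c(4, 1, 5, 3, 2), ])
  expect_equal(perm, ints, ignore_attr = TRUE)
})

test_that("worked example reproduces the independent hand calculation", {
  fit <- elo_seq(example_path())
  expect_equal(fit$n_processed, 9L)
  expect_equal(coef(fit)[names(example_final_oracle)],
               example_final_oracle, tolerance = 1e-12)
  # logistic option differs but conserves the total
  fit_l <- elo_seq(example_path(), model = "logistic")
  expect_equal(sum(coef(fit_l)), 5000, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(coef(fit_l), coef(fit))))
})

test_that("an empty record returns the starting ratings untouched", {
  f <- tempfile(fileext = ".csv")
  writeLines("Date,Time,Winner,Loser,K,Outcome", f)
  fit <- elo_seq(f, priors = elo_priors(prior_ranks = c(a = 1, b = 2,
                                                        c = 3)))
  expect_equal(coef(fit), fit$start)
  expect_equal(fit$n_processed, 0L)
  unlink(f)
})

test_that("doubling K doubles the first rating change", {
  ints <- read_interactions(example_path())
  ints2 <- ints; ints2$k <- ints2$k * 2
  f1 <- elo_seq(ints); f2 <- elo_seq(ints2)
  d1 <- f1$trajectory$rating_after[1] - f1$trajectory$rating_before[1]
  d2 <- f2$trajectory$rating_after[1] - f2$trajectory$rating_before[1]
  expect_equal(d2, 2 * d1, tolerance = 1e-12)
  # later events differ by path dependence, not by a constant factor
  expect_false(isTRUE(all.equal(coef(f2), coef(f1))))
})

test_that("with no priors every individual starts at the baseline", {
  fit <- elo_seq(example_path(),
                 priors = elo_priors(starting_value = 800))
  expect_true(all(fit$start == 800))
  first <- fit$trajectory[1:2, ]
  expect_equal(first$rating_before, c(800, 800))
})

test_that("ratings are conserved across a long mixed-K sequence", {
  sim <- simulate_hierarchy(12, 3000, days = 300, seed = 11)
  fit <- elo_seq(sim$interactions)
  expect_equal(sum(coef(fit)), sum(fit$start), tolerance = 1e-6)
  # per-event: winner and loser deltas cancel throughout
  tr <- fit$trajectory
  drift <- cumsum(tr$rating_after - tr$rating_before)
  expect_lt(max(abs(drift[seq(2, length(drift), by = 2)])), 1e-6)
})

test_that("roster handling covers spectators and overrides", {
  # an individual named only in the priors keeps its start throughout
  fit <- elo_seq(example_path(),
                 priors = elo_priors(prior_ranks = c(ZF = 1, XX = 6,
                                                     DN = 2)))
  expect_true("XX" %in% fit$roster)
  expect_equal(coef(fit)["XX"], fit$start["XX"])
  expect_error(
    elo_seq(example_path(), roster = c("ZF", "TK")),
    "outside the supplied roster")
})

test_that("trajectories export one row per participant and round-trip", {
  fit <- elo_seq(example_path())
  f <- tempfile(fileext = ".csv")
  write_trajectory(fit, f)
  lines <- readLines(f)
  expect_equal(sum(!startsWith(lines, "#")) - 1L, 18L)  # 9 events x 2
  tr <- read_trajectory(f)
  expect_equal(tr$trajectory$rating_after, fit$trajectory$rating_after)
  expect_equal(tr$trajectory$id, fit$trajectory$id)
  expect_equal(tr$start[fit$roster], fit$start)
  # winner row precedes loser row within each event
  expect_equal(tr$trajectory$id[seq(1, 17, by = 2)],
               fit$interactions$winner)
  unlink(f)

  # empty fit writes a header-only table that reads back empty
  fe <- elo_seq(data.frame(Date = character(0), Time = character(0),
                           Winner = character(0), Loser = character(0),
                           K = character(0), Outcome = character(0)),
                priors = elo_priors(prior_ranks = c(a = 1, b = 2)))
  write_trajectory(fe, f)
  tre <- read_trajectory(f)
  expect_equal(nrow(tre$trajectory), 0L)
  expect_equal(tre$start, fe$start)
  unlink(f)
})

test_that("timestamp permutations do not change the fit", {
  sim <- simulate_hierarchy(6, 120, days = 120, seed = 3)
  ints <- sim$interactions   # one event per day: unique timestamps
  set.seed(1)
  shuf <- ints[sample(nrow(ints)), ]
  expect_equal(coef(elo_seq(shuf)), coef(elo_seq(ints)), tolerance = 1e-12)
})
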