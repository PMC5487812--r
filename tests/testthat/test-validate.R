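test_that("signal records parse, sort, and validate", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("Date,Time,Signaller,Recipient",
               "2020-02-01,10:00,b,a",
               "2020-01-15,,c,a",
               "2020-01-15,08:00,b,c"), f)
  sig <- read_signals(f)
  expect_equal(nrow(sig), 3L)
  # chronological, untimed row after the timed row on the same day
  expect_equal(sig$signaller, c("b", "c", "b"))
  writeLines("Date,Time,Signaller,Recipient", f)
  expect_equal(nrow(read_signals(f)), 0L)
  writeLines(c("Date,Time,Signaller,Recipient", "2020-01-01,,a,a"), f)
  expect_error(read_signals(f), "row 1")
  unlink(f)
})

# fixed two-individual hierarchy: A at 1200, B at 1000, no interactions
fixed_fit <- function() {
  elo_seq(data.frame(Date = character(0), Time = character(0),
                     Winner = character(0), Loser = character(0),
                     K = character(0), Outcome = character(0)),
          priors = elo_priors(prior_elo = c(A = 1200, B = 1000)))
}

test_that("inconsistencies are reversed-direction signals only", {
  fit <- fixed_fit()
  up <- data.frame(Date = "2020-01-01", Time = "", Signaller = "B",
                   Recipient = "A")
  rep0 <- consistency_report(fit, up)
  expect_equal(rep0$n_inconsistencies, 0L)
  expect_equal(rep0$n_inconsistent_dyads, 0L)
  expect_true(is.na(rep0$diff_mean))

  down2 <- data.frame(Date = c("2020-01-01", "2020-03-01"), Time = "",
                      Signaller = "A", Recipient = "B")
  rep2 <- consistency_report(fit, down2)
  expect_equal(rep2$n_inconsistencies, 2L)
  expect_equal(rep2$n_inconsistent_dyads, 1L)   # same unordered pair
  expect_equal(rep2$diff_mean, 200)
  expect_equal(rep2$diff_sd, 0)
  expect_equal(nrow(rep2$details), 2L)
  expect_equal(rep2$details$difference, c(200, 200))
})

test_that("the class interval exempts closely rated dyads", {
  fit <- elo_seq(data.frame(Date = character(0), Time = character(0),
                            Winner = character(0), Loser = character(0),
                            K = character(0), Outcome = character(0)),
                 priors = elo_priors(prior_elo = c(A = 1005, B = 1000)))
  sig <- data.frame(Date = "2020-01-01", Time = "", Signaller = "A",
                    Recipient = "B")
  expect_equal(consistency_report(fit, sig)$n_inconsistencies, 1L)
  expect_equal(consistency_report(fit, sig,
                                  class_interval = 200)$n_inconsistencies,
               0L)
  # exactly equal ratings are the same class at any interval
  fit_eq <- elo_seq(data.frame(Date = character(0), Time = character(0),
                               Winner = character(0), Loser = character(0),
                               K = character(0), Outcome = character(0)),
                    priors = elo_priors(prior_elo = c(A = 1000, B = 1000)))
  expect_equal(consistency_report(fit_eq, sig)$n_inconsistencies, 0L)
})

test_that("counts are monotone in the class interval", {
  sim <- simulate_hierarchy(8, 500, days = 150, seed = 9,
                            signal_rate = 0.5, signal_error_rate = 0.3)
  fit <- elo_seq(sim$interactions)
  counts <- vapply(c(0, 50, 100, 200, 1e6), function(ci) {
    consistency_report(fit, sim$signals,
                       class_interval = ci)$n_inconsistencies
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[5], 0)
})

test_that("reversing all signals on a strict order flips consistencies", {
  fit <- elo_seq(data.frame(Date = character(0), Time = character(0),
                            Winner = character(0), Loser = character(0),
                            K = character(0), Outcome = character(0)),
                 priors = elo_priors(prior_elo = c(A = 1400, B = 1100,
                                                   C = 800)))
  sig <- data.frame(Date = "2020-01-01", Time = "",
                    Signaller = c("B", "C", "C", "A"),
                    Recipient = c("A", "A", "B", "B"))
  fwd <- consistency_report(fit, sig)
  rev_sig <- transform(sig, Signaller = Recipient, Recipient = Signaller)
  bwd <- consistency_report(fit, rev_sig)
  expect_equal(fwd$n_inconsistencies + bwd$n_inconsistencies, nrow(sig))
  expect_equal(bwd$n_inconsistencies, nrow(sig) - 1L)  # A->B was the error
})

test_that("ratings are looked up on the signal's own date", {
  fit <- elo_seq(example_path())
  # DN overtakes ZF on 2003-10-13; a ZF->DN signal before that is an
  # inconsistency, the same signal afterwards is not
  sig_before <- data.frame(Date = "2003-08-11", Time = "",
                           Signaller = "ZF", Recipient = "DN")
  sig_after <- data.frame(Date = "2003-10-14", Time = "",
                          Signaller = "ZF", Recipient = "DN")
  expect_equal(consistency_report(fit, sig_before)$n_inconsistencies, 1L)
  expect_equal(consistency_report(fit, sig_after)$n_inconsistencies, 0L)
  # pre-day semantics shift the same-day lookup
  sig_same <- data.frame(Date = "2003-10-13", Time = "",
                         Signaller = "ZF", Recipient = "DN")
  expect_equal(consistency_report(fit, sig_same)$n_inconsistencies, 0L)
  expect_equal(consistency_report(fit, sig_same,
                                  include_same_day = FALSE)$n_inconsistencies,
               1L)
  expect_error(consistency_report(fit, data.frame(Date = "2003-10-14",
                                                  Time = "",
                                                  Signaller = "QQ",
                                                  Recipient = "DN")),
               "not in the roster")
})

test_that("the summary line mirrors the count (dyads) mean-sd layout", {
  fit <- fixed_fit()
  down2 <- data.frame(Date = c("2020-01-01", "2020-03-01"), Time = "",
                      Signaller = "A", Recipient = "B")
  rep2 <- consistency_report(fit, down2)
  expect_output(print(rep2), "2 (1) 200.00 ± 0.00", fixed = TRUE)
  empty <- consistency_report(fit, data.frame(Date = character(0),
                                              Time = character(0),
                                              Signaller = character(0),
                                              Recipient = character(0)))
  expect_equal(empty$n_signals, 0L)
  expect_equal(empty$n_inconsistencies, 0L)
  expect_output(print(empty), "0 (0)", fixed = TRUE)
})
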