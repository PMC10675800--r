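# Build a small signals tibble by hand (attributes as signal_table sets them).
fake_signals <- function(drugs, events, lnror_by_event, event_totals,
                         comparator = "all_reports") {
  grid <- tidyr::expand_grid(drug = drugs, pt = events)
  grid$lnror <- unlist(lapply(seq_along(drugs), function(i)
    vapply(events, function(e) lnror_by_event[[e]][i], numeric(1))))
  grid$a <- 1L
  grid$c <- unname(event_totals[grid$pt])
  if (comparator == "other_reports") grid$c <- grid$c - grid$a
  structure(grid, comparator = comparator)
}

test_that("matrix assembly fills the grid and the column means", {
  sig <- fake_signals(
    drugs = c("d1", "d2"), events = c("E1", "E2"),
    lnror_by_event = list(E1 = c(0, 0), E2 = c(log(2), log(8))),
    event_totals = c(E1 = 100, E2 = 50)
  )
  sm <- assemble_signal_matrix(sig)
  expect_equal(dim(sm$lnror), c(2, 2))
  expect_equal(unname(sm$mean_lnror), c(0, log(4)), tolerance = 1e-12)
  expect_equal(unname(sm$event_totals), c(100, 50))
  expect_equal(sm$lnror["d2", "E2"], log(8))
  # mean_lnror always equals the arithmetic column mean
  expect_equal(sm$mean_lnror, colMeans(sm$lnror), tolerance = 1e-12)
})

test_that("single-drug matrix has mean equal to that drug's row", {
  sig <- fake_signals("only", c("E1", "E2"),
                      list(E1 = 0.3, E2 = -0.2), c(E1 = 10, E2 = 10))
  sm <- assemble_signal_matrix(sig)
  expect_equal(unname(sm$mean_lnror), unname(sm$lnror[1, ]))
})

test_that("missing pairs are detected by name", {
  sig <- fake_signals(c("d1", "d2"), c("E1", "E2"),
                      list(E1 = c(0, 0), E2 = c(0, 0)),
                      c(E1 = 1, E2 = 1))
  expect_error(assemble_signal_matrix(sig[-2, ]), "missing pair")
})

test_that("event totals are comparator-independent", {
  for (cmp in c("all_reports", "other_reports")) {
    sig <- fake_signals(c("d1", "d2"), "E1", list(E1 = c(0.1, 0.2)),
                        c(E1 = 42), comparator = cmp)
    sm <- assemble_signal_matrix(sig)
    expect_equal(unname(sm$event_totals), 42, label = cmp)
  }
})

test_that("event summary exponentiates the mean and rounds half away", {
  sig <- fake_signals(c("d1", "d2"), c("E1", "E2", "E3"),
                      list(E1 = c(0.04, 0.04), E2 = c(1.01, 1.01),
                           E3 = c(0, 0)),
                      c(E1 = 300, E2 = 200, E3 = 100))
  es <- event_summary(assemble_signal_matrix(sig))
  expect_equal(es$pt, c("E1", "E2", "E3"))   # sorted by totals, descending
  expect_equal(es$ror, exp(es$mean_lnror), tolerance = 1e-12)
  expect_equal(es$ror_disp[es$pt == "E1"], 1.04)
  expect_equal(es$ror_disp[es$pt == "E2"], 2.75)
  expect_equal(es$ror_disp[es$pt == "E3"], 1.00)
})

test_that("rounding is half away from zero, not banker's", {
  expect_equal(round_half_away(1.045, 2), 1.05)
  expect_equal(round_half_away(-1.045, 2), -1.05)
  expect_equal(round_half_away(0.125, 2), 0.13)
})

test_that("filters apply strict thresholds in sequence", {
  sig <- fake_signals(
    c("d1", "d2"), c("E1", "E2", "E3"),
    list(E1 = c(0.2, 0.2), E2 = c(-0.1, -0.1), E3 = c(0, 0)),
    c(E1 = 150000, E2 = 150000, E3 = 90000)
  )
  sm <- assemble_signal_matrix(sig)
  # report-count filter alone (strict >)
  f1 <- filter_events(sm, filter_config(min_event_reports = 100000,
                                        require_positive_mean = FALSE))
  expect_equal(f1$events, c("E1", "E2"))
  # the threshold is strict: a total equal to it does not survive
  expect_error(
    filter_events(sm, filter_config(min_event_reports = 150000,
                                    require_positive_mean = FALSE)),
    "removed every event"
  )

  # positivity filter is strict: zero mean excluded
  f2 <- filter_events(sm, filter_config(min_event_reports = 0,
                                        require_positive_mean = TRUE))
  expect_equal(f2$events, "E1")
  # no-op config is the identity
  f3 <- filter_events(sm, filter_config(min_event_reports = 0,
                                        require_positive_mean = FALSE))
  expect_equal(f3$events, sm$events)
  expect_equal(f3$lnror, sm$lnror)
})

test_that("filtering is idempotent and order-preserving; stage counts logged", {
  sig <- fake_signals(
    c("d1", "d2"), paste0("E", 1:6),
    setNames(lapply(c(0.5, -0.2, 0.3, 0, 0.1, 0.4), function(v) c(v, v)),
             paste0("E", 1:6)),
    setNames(c(500, 400, 300, 200, 100, 50), paste0("E", 1:6))
  )
  sm <- assemble_signal_matrix(sig)
  cfg <- filter_config(min_event_reports = 80, require_positive_mean = TRUE,
                       top_n = 3)
  once <- filter_events(sm, cfg)
  twice <- filter_events(once, cfg)
  expect_equal(once$events, twice$events)
  expect_equal(once$lnror, twice$lnror)
  # retained columns keep their original relative order
  expect_identical(once$events, sm$events[sm$events %in% once$events])
  expect_equal(unname(attr(once, "stage_counts")["input"]), 6)
  expect_error(
    filter_events(sm, filter_config(min_event_reports = 10000)),
    "removed every event"
  )
})

test_that("top_n cap keeps the most reported events with lexicographic ties", {
  sig <- fake_signals(
    c("d1", "d2"), c("B", "A", "C"),
    list(B = c(1, 1), A = c(1, 1), C = c(1, 1)),
    c(B = 100, A = 100, C = 200)
  )
  sm <- assemble_signal_matrix(sig)
  f <- filter_events(sm, filter_config(min_event_reports = 0,
                                       require_positive_mean = FALSE,
                                       top_n = 2))
  expect_setequal(f$events, c("C", "A"))  # A beats B on the tie
  expect_identical(f$events, c("A", "C"))  # original column order preserved
})

test_that("planted events gain positive mean lnROR on synthetic data", {
  cfg <- synthetic_opioid_config(n_reports = 60000, seed = 17)
  g <- generate_faers(cfg, render_tables = FALSE)
  st <- signal_table(g$truth, comparator = "other_reports")
  sm <- assemble_signal_matrix(st)
  planted <- unique(cfg$multipliers$pt)
  expect_true(all(sm$mean_lnror[planted] > 0))
})
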