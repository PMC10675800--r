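test_that("contingency counts match brute force under both comparators", {
  pr <- ten_report_pairs()
  t_other <- make_contingency(pr, "drugx", "EVENTX", "other_reports")
  expect_equal(c(t_other$a, t_other$b, t_other$c, t_other$d), c(3, 1, 2, 4))
  t_all <- make_contingency(pr, "drugx", "EVENTX", "all_reports")
  expect_equal(c(t_all$a, t_all$b, t_all$c, t_all$d), c(3, 1, 5, 5))
  expect_error(make_contingency(pr, "nosuch", "EVENTX"), "drug")
  expect_error(make_contingency(pr, "drugx", "NOSUCH"), "term")
})

test_that("Haldane-Anscombe correction adds 0.5 everywhere, exactly once", {
  t0 <- haldane_correct(contingency_table(0, 0, 0, 0))
  expect_equal(c(t0$a, t0$b, t0$c, t0$d), c(0.5, 0.5, 0.5, 0.5))
  t1 <- haldane_correct(contingency_table(10, 20, 30, 60))
  expect_equal(c(t1$a, t1$b, t1$c, t1$d), c(10.5, 20.5, 30.5, 60.5))
  expect_error(haldane_correct(t1), "already")
})

test_that("ROR follows (a*d)/(b*c) on corrected cells", {
  sym <- compute_ror(haldane_correct(contingency_table(5, 5, 5, 5)))
  expect_equal(sym$ror, 1)
  expect_equal(sym$lnror, 0)
  t1 <- compute_ror(haldane_correct(contingency_table(10, 20, 30, 60)))
  expect_equal(t1$ror, 635.25 / 625.25, tolerance = 1e-12)
  t2 <- compute_ror(haldane_correct(contingency_table(0, 10, 50, 1000)))
  expect_equal(t2$ror, (0.5 * 1000.5) / (10.5 * 50.5), tolerance = 1e-12)
  expect_error(compute_ror(contingency_table(0, 10, 50, 1000)),
               "haldane_correct")
})

test_that("Wald interval matches the closed form and is level-monotone", {
  t <- haldane_correct(contingency_table(5, 5, 5, 5))
  ci <- wald_ci(t)
  se <- sqrt(4 / 5.5)
  expect_equal(ci$ci_low, exp(-qnorm(0.975) * se), tolerance = 1e-9)
  expect_equal(ci$ci_high, exp(qnorm(0.975) * se), tolerance = 1e-9)
  expect_equal(ci$ci_low, 0.18797, tolerance = 1e-4)
  expect_equal(ci$ci_high, 5.32010, tolerance = 1e-4)
  # width shrinks when all cells scale up
  big <- haldane_correct(contingency_table(500, 500, 500, 500))
  ci_big <- wald_ci(big)
  expect_lt(ci_big$ci_high - ci_big$ci_low, ci$ci_high - ci$ci_low)
  expect_error(wald_ci(t, level = 1.2), "level")
})

test_that("CI brackets the ROR and exp(lnror) = ror on random tables", {
  set.seed(42)
  for (i in 1:1000) {
    cells <- rpois(4, lambda = sample(c(1, 5, 50), 1))
    t <- haldane_correct(contingency_table(cells[1], cells[2],
                                           cells[3], cells[4]))
    est <- compute_ror(t)
    ci <- wald_ci(t)
    expect_true(ci$ci_low <= est$ror && est$ror <= ci$ci_high)
    expect_equal(exp(est$lnror), est$ror, tolerance = 1e-12)
  }
})

test_that("row swap inverts the ROR exactly", {
  set.seed(7)
  for (i in 1:50) {
    cells <- rpois(4, 8)
    t <- haldane_correct(contingency_table(cells[1], cells[2],
                                           cells[3], cells[4]))
    sw <- haldane_correct(contingency_table(cells[3], cells[4],
                                            cells[1], cells[2]))
    expect_equal(compute_ror(sw)$ror, 1 / compute_ror(t)$ror,
                 tolerance = 1e-12)
    expect_equal(compute_ror(sw)$lnror, -compute_ror(t)$lnror,
                 tolerance = 1e-12)
  }
})

test_that("Fisher exact matches enumerated examples and guards bad input", {
  expect_equal(fisher_exact_two_sided(3, 1, 1, 3), 34 / 70, tolerance = 1e-12)
  expect_equal(fisher_exact_two_sided(2, 2, 2, 2), 1)
  expect_equal(fisher_exact_two_sided(5, 0, 0, 5), 2 / 252, tolerance = 1e-12)
  expect_error(fisher_exact_two_sided(0, 0, 0, 0), "all-zero")
  expect_error(fisher_exact_two_sided(1.5, 1, 1, 1), "integer")
  expect_error(
    fisher_exact_two_sided(haldane_correct(contingency_table(1, 1, 1, 1))),
    "raw"
  )
})

test_that("Fisher exact agrees with stats::fisher.test on random tables", {
  set.seed(11)
  for (i in 1:200) {
    cells <- rpois(4, sample(c(2, 10, 40), 1))
    if (sum(cells) == 0) next
    mine <- fisher_exact_two_sided(cells[1], cells[2], cells[3], cells[4])
    ref <- stats::fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
    expect_equal(mine, min(ref, 1), tolerance = 1e-10)
  }
})

test_that("signal_for_pair composes the component results", {
  pr <- ten_report_pairs()
  row <- signal_for_pair(pr, "drugx", "EVENTX", "other_reports")
  expect_equal(c(row$a, row$b, row$c, row$d), c(3, 1, 2, 4))
  expect_equal(row$ror, (3.5 * 4.5) / (1.5 * 2.5), tolerance = 1e-12)
  expect_equal(row$p_value, fisher_oracle(3, 1, 2, 4), tolerance = 1e-12)
  expect_equal(row$ror, exp(row$lnror), tolerance = 1e-12)
  expect_true(row$ci_low <= row$ror && row$ror <= row$ci_high)
})

test_that("a drug with zero reports yields NA p-value, not a dropped pair", {
  pr <- ten_report_pairs()
  pr$drug_vocab <- c("drugx", "neverseen")
  st <- signal_table(pr, comparator = "other_reports")
  expect_equal(nrow(st), 2)   # 2 vocabulary drugs x 1 event: rectangular
  deg <- st[st$drug == "neverseen", ]
  expect_equal(deg$a + deg$b, 0)
  expect_true(is.na(deg$p_value))
  expect_false(deg$significant)
  expect_true(is.finite(deg$lnror))  # defined via the 1/2 correction
  expect_true(all(is.finite(st$lnror)))
})

test_that("signal_table matches signal_for_pair across the grid", {
  set.seed(3)
  cfg <- synthetic_opioid_config(n_reports = 4000, seed = 3)
  g <- generate_faers(cfg, render_tables = FALSE)
  st <- signal_table(g$truth, comparator = "other_reports")
  pick <- st[sample(nrow(st), 8), ]
  for (i in seq_len(nrow(pick))) {
    single <- signal_for_pair(g$truth, pick$drug[i], pick$pt[i],
                              "other_reports")
    expect_equal(as.data.frame(pick[i, ]), as.data.frame(single),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # deterministic row order: drug then pt, lexicographic
  expect_identical(order(st$drug, st$pt, method = "radix"), seq_len(nrow(st)))
})

test_that("tidy and glance summarize a signal table", {
  pr <- ten_report_pairs()
  st <- signal_table(pr)
  expect_s3_class(tidy(st), "tbl_df")
  gl <- glance(st)
  expect_equal(gl$n_pairs, 1)
  expect_equal(gl$n_reports, 10)
  expect_equal(gl$comparator, "all_reports")
})
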