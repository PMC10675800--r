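#' Build a 2x2 contingency table for one drug-event pair
#'
#' Counts reports in the four cells of the disproportionality contrast:
#' `a` reports with the suspect drug and the event, `b` with the drug without
#' the event, and a comparator row `c`, `d`. Two comparator conventions are
#' supported:
#'
#' * `"all_reports"`: `c` = all reports with the event, `d` = all reports
#'   without it (the drug's own reports are included in the comparator row);
#' * `"other_reports"`: `c`, `d` restricted to reports lacking the drug — the
#'   convention of most published ROR tooling.
#'
#' @param x A `faers_analysis` object, or a list with elements `drug_pairs`
#'   (tibble `caseid`, `drug`), `event_pairs` (tibble `caseid`, `pt`) and
#'   `n_reports`, as returned by [report_pairs()].
#' @param drug Canonical drug label.
#' @param pt Adverse-event preferred term.
#' @param comparator `"all_reports"` or `"other_reports"`.
#' @param rules Drug-name rules used when `x` is a `faers_analysis`.
#' @return A `faers_contingency` object: list with integer fields `a`, `b`,
#'   `c`, `d`, logical `corrected`, and the `comparator` used.
#' @export
make_contingency <- function(x, drug, pt,
                             comparator = c("all_reports", "other_reports"),
                             rules = opioid_rules()) {
  comparator <- match.arg(comparator)
  pr <- report_pairs(x, rules)
  if (!drug %in% pr$drug_vocab) {
    abort(paste0("drug label not in the drug vocabulary: ", drug))
  }
  if (!pt %in% pr$event_vocab) {
    abort(paste0("preferred term not in the event vocabulary: ", pt))
  }
  with_drug <- unique(pr$drug_pairs$caseid[pr$drug_pairs$drug == drug])
  with_event <- unique(pr$event_pairs$caseid[pr$event_pairs$pt == pt])
  n <- pr$n_reports
  a <- length(intersect(with_drug, with_event))
  b <- length(with_drug) - a
  if (comparator == "all_reports") {
    cc <- length(with_event)
    dd <- n - cc
  } else {
    cc <- length(with_event) - a
    dd <- (n - length(with_drug)) - cc
  }
  contingency_table(a, b, cc, dd, comparator = comparator)
}

#' @rdname make_contingency
#' @param a,b,c,d Non-negative cell counts.
#' @param corrected Whether the cells already carry the 1/2 correction.
#' @export
contingency_table <- function(a, b, c, d, corrected = FALSE,
                              comparator = "all_reports") {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(!is.finite(cells))) {
    abort("contingency cells must be finite and non-negative")
  }
  if (!corrected && any(cells != floor(cells))) {
    abort("raw contingency cells must be integers")
  }
  structure(list(a = a, b = b, c = c, d = d, corrected = corrected,
                 comparator = comparator),
            class = "faers_contingency")
}

#' @export
print.faers_contingency <- function(x, ...) {
  cat("<faers_contingency", if (x$corrected) " (corrected)", ">\n", sep = "")
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("drug", x$comparator),
                              c("event+", "event-")))
  print(m)
  invisible(x)
}

# Internal: normalize inputs to (drug_pairs, event_pairs, n_reports).

#' Extract per-report drug-label and event memberships
#'
#' @inheritParams make_contingency
#' @return List with `drug_pairs` (caseid, drug), `event_pairs` (caseid, pt),
#'   `n_reports`.
#' @export
report_pairs <- function(x, rules = opioid_rules()) {
  if (inherits(x, "faers_analysis")) {
    # the drug vocabulary is the rule set: a target drug with zero mapped
    # reports is a legitimate (degenerate) margin, not an unknown label
    list(drug_pairs = map_drugs(x$drugs, rules),
         event_pairs = x$reactions,
         n_reports = x$n_reports,
         drug_vocab = rules$label,
         event_vocab = x$pt_vocabulary)
  } else if (is.list(x) &&
             all(c("drug_pairs", "event_pairs", "n_reports") %in% names(x))) {
    x$drug_vocab <- x$drug_vocab %||% c_sort(unique(x$drug_pairs$drug))
    x$event_vocab <- x$event_vocab %||% c_sort(unique(x$event_pairs$pt))
    x
  } else {
    abort("x must be a faers_analysis or a report_pairs() list")
  }
}

#' Haldane-Anscombe 1/2 correction
#'
#' Adds 0.5 to every cell of a raw 2x2 table, unconditionally, so the odds
#' ratio stays finite with zero cells and small-count bias is reduced.
#' Correcting an already corrected table is an error (prevents silent double
#' correction).
#'
#' @param t A `faers_contingency`.
#' @return The corrected `faers_contingency`.
#' @export
haldane_correct <- function(t) {
  stopifnot(inherits(t, "faers_contingency"))
  if (t$corrected) abort("table is already Haldane-Anscombe corrected")
  contingency_table(t$a + 0.5, t$b + 0.5, t$c + 0.5, t$d + 0.5,
                    corrected = TRUE, comparator = t$comparator)
}

#' Reporting odds ratio of a corrected 2x2 table
#'
#' ROR = (a/b)/(c/d) = (a*d)/(b*c). The table must either carry the 1/2
#' correction or have strictly positive cells; a raw table with a zero cell
#' is rejected with a pointer to [haldane_correct()].
#'
#' @param t A `faers_contingency`.
#' @return List with `ror` and `lnror` (natural log).
#' @export
compute_ror <- function(t) {
  stopifnot(inherits(t, "faers_contingency"))
  if (!t$corrected && min(t$a, t$b, t$c, t$d) == 0) {
    abort("table has a zero cell; apply haldane_correct() first")
  }
  ror <- (t$a * t$d) / (t$b * t$c)
  list(ror = ror, lnror = log(ror))
}

#' Log-scale Wald confidence interval for the ROR
#'
#' Bounds are `exp(lnror -/+ z * sqrt(1/a + 1/b + 1/c + 1/d))` with `z` the
#' standard-normal quantile for the coverage level (1.959964 at 0.95),
#' evaluated on the corrected cells.
#'
#' @param t A corrected `faers_contingency`.
#' @param level Coverage probability in (0, 1).
#' @return List with `ci_low`, `ci_high` on the ROR scale.
#' @export
wald_ci <- function(t, level = 0.95) {
  stopifnot(inherits(t, "faers_contingency"))
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    abort("level must be a single number in (0, 1)")
  }
  if (!t$corrected && min(t$a, t$b, t$c, t$d) == 0) {
    abort("table has a zero cell; apply haldane_correct() first")
  }
  z <- qnorm(1 - (1 - level) / 2)
  lnror <- compute_ror(t)$lnror
  se <- sqrt(1 / t$a + 1 / t$b + 1 / t$c + 1 / t$d)
  list(ci_low = exp(lnror - z * se), ci_high = exp(lnror + z * se))
}

# Vectorized two-sided Fisher exact p over raw integer cells.
# Point-probability rule: sum of hypergeometric probabilities of all tables
# with the observed margins whose probability does not exceed the observed
# table's, within relative tolerance 1e-7.
fisher_p_vec <- function(a, b, c, d, rel_tol = 1e-7) {
  stopifnot(length(a) == length(b), length(b) == length(c),
            length(c) == length(d))
  out <- numeric(length(a))
  for (i in seq_along(a)) {
    ai <- a[i]; bi <- b[i]; ci <- c[i]; di <- d[i]
    if (any(c(ai, bi, ci, di) != floor(c(ai, bi, ci, di))) ||
        any(c(ai, bi, ci, di) < 0)) {
      abort("Fisher exact test needs non-negative integer counts")
    }
    if (ai + bi + ci + di == 0) {
      abort("Fisher exact test undefined for the all-zero table")
    }
    r1 <- ai + bi; r2 <- ci + di; c1 <- ai + ci
    support <- max(0, c1 - r2):min(r1, c1)
    probs <- dhyper(support, r1, r2, c1)
    p_obs <- probs[support == ai]
    out[i] <- min(1, sum(probs[probs <= p_obs * (1 + rel_tol)]))
  }
  out
}

#' Two-sided Fisher exact test for a raw 2x2 table
#'
#' Computes the exact hypergeometric two-sided p-value by the
#' point-probability rule (probabilities no larger than the observed table's,
#' compared with relative tolerance 1e-7, are summed). Defined for raw
#' integer counts only; the Haldane-Anscombe correction affects the ROR and
#' its interval, never this test.
#'
#' @param t A raw `faers_contingency`, or the cell `a` when `b`, `c`, `d` are
#'   given.
#' @param b,c,d Optional cells when `t` is the numeric cell `a`.
#' @return The two-sided p-value.
#' @export
fisher_exact_two_sided <- function(t, b = NULL, c = NULL, d = NULL) {
  if (inherits(t, "faers_contingency")) {
    if (t$corrected) {
      abort("Fisher exact test runs on raw (uncorrected) integer counts")
    }
    fisher_p_vec(t$a, t$b, t$c, t$d)
  } else {
    fisher_p_vec(t, b, c, d)
  }
}

#' Full signal computation for one drug-event pair
#'
#' Composes the pipeline for a single pair: raw contingency table, Fisher
#' exact screening on the raw counts, Haldane-Anscombe correction, ROR with
#' log-scale Wald interval. When the drug margin is empty (`a + b = 0`) the
#' exact test is degenerate; the pair is still returned, with `p_value = NA`
#' and `significant = FALSE`, so downstream matrices stay rectangular.
#'
#' @inheritParams make_contingency
#' @param alpha Significance level for the `significant` flag.
#' @param level CI coverage probability.
#' @return One-row tibble: `drug`, `pt`, `a`, `b`, `c`, `d` (raw counts),
#'   `ror`, `lnror`, `ci_low`, `ci_high`, `p_value`, `significant`.
#' @export
signal_for_pair <- function(x, drug, pt,
                            comparator = c("all_reports", "other_reports"),
                            alpha = 0.05, level = 0.95,
                            rules = opioid_rules()) {
  comparator <- match.arg(comparator)
  t_raw <- make_contingency(x, drug, pt, comparator, rules)
  t_cor <- haldane_correct(t_raw)
  est <- compute_ror(t_cor)
  ci <- wald_ci(t_cor, level)
  p <- if (t_raw$a + t_raw$b == 0) NA_real_ else fisher_exact_two_sided(t_raw)
  tibble(
    drug = drug, pt = pt,
    a = t_raw$a, b = t_raw$b, c = t_raw$c, d = t_raw$d,
    ror = est$ror, lnror = est$lnror,
    ci_low = ci$ci_low, ci_high = ci$ci_high,
    p_value = p,
    significant = !is.na(p) & p < alpha
  )
}

#' Signal table over all drug-event pairs
#'
#' Computes, for every combination of the requested drug labels and preferred
#' terms, the raw 2x2 counts, corrected ROR/lnROR, Wald interval and Fisher
#' exact p. Counting is report-level: a report contributes at most once to
#' any cell regardless of repeated drug or term mentions.
#'
#' @inheritParams signal_for_pair
#' @param drugs,events Label/term vectors; default: the full drug and event
#'   vocabularies of `x` (for a `faers_analysis`, every rule label — a target
#'   drug with zero reports yields a degenerate row with `p_value = NA` —
#'   and every observed preferred term), in lexicographic order.
#' @return A `faers_signals` tibble (one row per pair, ordered by drug then
#'   pt) with the columns of [signal_for_pair()]. Attributes record the
#'   comparator, alpha, CI level and total report count.
#' @export
signal_table <- function(x, drugs = NULL, events = NULL,
                         comparator = c("all_reports", "other_reports"),
                         alpha = 0.05, level = 0.95,
                         rules = opioid_rules()) {
  comparator <- match.arg(comparator)
  pr <- report_pairs(x, rules)
  dp <- distinct(pr$drug_pairs, .data$caseid, .data$drug)
  ep <- distinct(pr$event_pairs, .data$caseid, .data$pt)
  n <- pr$n_reports
  drugs <- drugs %||% c_sort(pr$drug_vocab)
  events <- events %||% c_sort(pr$event_vocab)
  missing_d <- setdiff(drugs, pr$drug_vocab)
  if (length(missing_d)) {
    abort(paste0("drug label(s) not in the drug vocabulary: ",
                 paste(missing_d, collapse = ", ")))
  }
  missing_e <- setdiff(events, pr$event_vocab)
  if (length(missing_e)) {
    abort(paste0("preferred term(s) not in the event vocabulary: ",
                 paste(missing_e, collapse = ", ")))
  }
  dp <- filter(dp, .data$drug %in% drugs)
  ep <- filter(ep, .data$pt %in% events)

  n_drug <- count(dp, .data$drug, name = "n_drug")
  n_event <- count(ep, .data$pt, name = "n_event")
  a_tab <- dp %>%
    inner_join(ep, by = "caseid", relationship = "many-to-many") %>%
    count(.data$drug, .data$pt, name = "a")

  grid <- tidyr::expand_grid(drug = drugs, pt = events) %>%
    left_join(a_tab, by = c("drug", "pt")) %>%
    left_join(n_drug, by = "drug") %>%
    left_join(n_event, by = "pt") %>%
    mutate(
      a = dplyr::coalesce(.data$a, 0L),
      n_drug = dplyr::coalesce(.data$n_drug, 0L),
      n_event = dplyr::coalesce(.data$n_event, 0L),
      b = .data$n_drug - .data$a,
      c = if (comparator == "all_reports") .data$n_event
          else .data$n_event - .data$a,
      d = if (comparator == "all_reports") n - .data$n_event
          else (n - .data$n_drug) - (.data$n_event - .data$a)
    )

  ca <- grid$a + 0.5; cb <- grid$b + 0.5
  cc <- grid$c + 0.5; cd <- grid$d + 0.5
  ror <- (ca * cd) / (cb * cc)
  z <- qnorm(1 - (1 - level) / 2)
  se <- sqrt(1 / ca + 1 / cb + 1 / cc + 1 / cd)
  p <- rep(NA_real_, nrow(grid))
  nondeg <- grid$a + grid$b > 0
  if (any(nondeg)) {
    p[nondeg] <- fisher_p_vec(grid$a[nondeg], grid$b[nondeg],
                              grid$c[nondeg], grid$d[nondeg])
  }

  out <- grid %>%
    mutate(
      ror = ror, lnror = log(ror),
      ci_low = exp(log(ror) - z * se), ci_high = exp(log(ror) + z * se),
      p_value = p,
      significant = !is.na(p) & p < alpha
    ) %>%
    select("drug", "pt", "a", "b", "c", "d", "ror", "lnror",
           "ci_low", "ci_high", "p_value", "significant")
  out <- out[c_order(out$drug, out$pt), ]
  structure(out, class = c("faers_signals", class(tibble())),
            comparator = comparator, alpha = alpha, level = level,
            n_reports = n)
}

#' @export
tidy.faers_signals <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.faers_signals <- function(x, ...) {
  tibble(
    n_pairs = nrow(x),
    n_drugs = length(unique(x$drug)),
    n_events = length(unique(x$pt)),
    n_reports = attr(x, "n_reports"),
    comparator = attr(x, "comparator"),
    alpha = attr(x, "alpha"),
    n_significant = sum(x$significant)
  )
}

#' Write a signal table as TSV
#'
#' @param x A `faers_signals` tibble.
#' @param path Output path.
#' @export
write_signal_table <- function(x, path) {
  write_tsv_plain(as_tibble(x), path)
}
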