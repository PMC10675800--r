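#' Assemble the drug x event lnROR matrix
#'
#' Pivots a signal table into the matrix clustered downstream: one row per
#' drug label, one column per adverse-event preferred term, entries the
#' Haldane-Anscombe-corrected lnROR. Per-event database-wide report totals
#' and the unweighted mean lnROR over drugs are carried alongside. Every
#' requested (drug, event) pair must be present in `signals`.
#'
#' @param signals A `faers_signals` tibble from [signal_table()].
#' @param drugs,events Row/column orders; default: the orders observed in
#'   `signals`.
#' @return A `signal_matrix` object: list with `drugs`, `events`, `lnror`
#'   (numeric matrix), `event_totals` (named, whole-database report counts
#'   per term), `mean_lnror` (named, column means).
#' @export
assemble_signal_matrix <- function(signals, drugs = NULL, events = NULL) {
  stopifnot(is.data.frame(signals),
            all(c("drug", "pt", "lnror", "a", "c") %in% names(signals)))
  drugs <- drugs %||% unique(signals$drug)
  events <- events %||% unique(signals$pt)
  key <- paste(signals$drug, signals$pt, sep = "\r")
  want <- tidyr::expand_grid(drug = drugs, pt = events)
  want_key <- paste(want$drug, want$pt, sep = "\r")
  miss <- !(want_key %in% key)
  if (any(miss)) {
    abort(paste0("signal table is missing pair(s): ",
                 paste(utils::head(paste0("(", want$drug[miss], ", ",
                                          want$pt[miss], ")"), 5),
                       collapse = ", ")))
  }
  idx <- match(want_key, key)
  # expand_grid varies `pt` fastest; fill events down the columns, then flip
  grid <- matrix(signals$lnror[idx], nrow = length(events),
                 ncol = length(drugs), byrow = FALSE)
  grid <- t(grid)
  dimnames(grid) <- list(drugs, events)

  comparator <- attr(signals, "comparator") %||% "all_reports"
  totals_all <- if (comparator == "all_reports") signals$c
                else signals$a + signals$c
  totals <- setNames(totals_all[idx], want$pt)
  totals <- totals[!duplicated(names(totals))][events]

  structure(
    list(
      drugs = drugs,
      events = events,
      lnror = grid,
      event_totals = totals,
      mean_lnror = colMeans(grid)
    ),
    class = "signal_matrix"
  )
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat("<signal_matrix> ", length(x$drugs), " drugs x ", length(x$events),
      " adverse events\n", sep = "")
  cat("  mean lnROR range: [",
      round(min(x$mean_lnror), 3), ", ", round(max(x$mean_lnror), 3), "]\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.signal_matrix <- function(x, ...) {
  as_tibble(as.data.frame.table(x$lnror, responseName = "lnror",
                                stringsAsFactors = FALSE)) %>%
    rename(drug = "Var1", pt = "Var2")
}

#' @export
glance.signal_matrix <- function(x, ...) {
  tibble(n_drugs = length(x$drugs), n_events = length(x$events),
         min_event_total = min(x$event_totals),
         max_event_total = max(x$event_totals))
}

#' Per-event summary: report totals, mean lnROR and its ROR
#'
#' The summary mirrors the published top-adverse-events table: one row per
#' term with the database-wide report count, the unweighted mean lnROR over
#' the drug panel, and its exponential on the ROR scale. Display columns are
#' rounded to two decimals, half away from zero; the raw values are kept.
#' Rows are sorted by report total, descending (ties by term).
#'
#' @param x A `signal_matrix`.
#' @return Tibble: `pt`, `n_reports`, `mean_lnror`, `ror`, and 2-decimal
#'   display columns `mean_lnror_disp`, `ror_disp`.
#' @export
event_summary <- function(x) {
  stopifnot(inherits(x, "signal_matrix"))
  out <- tibble(
    pt = x$events,
    n_reports = unname(x$event_totals),
    mean_lnror = unname(x$mean_lnror),
    ror = exp(unname(x$mean_lnror))
  ) %>%
    mutate(
      mean_lnror_disp = round_half_away(.data$mean_lnror, 2),
      ror_disp = round_half_away(.data$ror, 2)
    )
  out[c_order(-out$n_reports, out$pt), ]
}

#' Event filter configuration
#'
#' @param min_event_reports Retain events reported more than this many times
#'   database-wide (strict inequality). The published analysis used 100,000
#'   on the full FAERS extract.
#' @param require_positive_mean Retain only events whose mean lnROR over the
#'   drug panel is strictly positive.
#' @param top_n Optional cap on the number of events, keeping the most
#'   reported (ties broken lexicographically by term).
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_event_reports = 100000,
                          require_positive_mean = TRUE,
                          top_n = NULL) {
  stopifnot(min_event_reports >= 0, is.logical(require_positive_mean))
  structure(list(min_event_reports = min_event_reports,
                 require_positive_mean = require_positive_mean,
                 top_n = top_n),
            class = "filter_config")
}

#' Apply report-count and mean-lnROR filters to a signal matrix
#'
#' Stage order: (1) keep events with `event_totals > min_event_reports`;
#' (2) if configured, keep events with `mean_lnror > 0` (a mean of exactly 0
#' is excluded); (3) optional `top_n` by report total descending. Column
#' order is preserved throughout, so filtering is idempotent and never
#' reorders. The count of events surviving each stage is attached as
#' attribute `"stage_counts"`.
#'
#' @param x A `signal_matrix`.
#' @param config A [filter_config()].
#' @return The filtered `signal_matrix`.
#' @export
filter_events <- function(x, config = filter_config()) {
  stopifnot(inherits(x, "signal_matrix"), inherits(config, "filter_config"))
  keep <- x$event_totals > config$min_event_reports
  stages <- c(input = length(x$events), after_min_reports = sum(keep))
  if (config$require_positive_mean) {
    keep <- keep & x$mean_lnror > 0
  }
  stages <- c(stages, after_positive_mean = sum(keep))
  if (!is.null(config$top_n) && sum(keep) > config$top_n) {
    kept_idx <- which(keep)
    ord <- kept_idx[c_order(-x$event_totals[kept_idx], x$events[kept_idx])]
    drop_idx <- ord[-seq_len(config$top_n)]
    keep[drop_idx] <- FALSE
  }
  stages <- c(stages, after_top_n = sum(keep))
  if (!any(keep)) {
    abort("event filters removed every event; relax min_event_reports or the positivity requirement")
  }
  out <- structure(
    list(
      drugs = x$drugs,
      events = x$events[keep],
      lnror = x$lnror[, keep, drop = FALSE],
      event_totals = x$event_totals[keep],
      mean_lnror = x$mean_lnror[keep]
    ),
    class = "signal_matrix"
  )
  attr(out, "stage_counts") <- stages
  out
}

#' Write a signal matrix as TSV (drugs as rows, events as columns)
#'
#' @param x A `signal_matrix`.
#' @param path Output path.
#' @export
write_signal_matrix <- function(x, path) {
  df <- as.data.frame(x$lnror)
  df <- cbind(drug = x$drugs, df)
  write_tsv_plain(df, path)
}
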