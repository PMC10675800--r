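#' Column aliases for FAERS quarterly headers
#'
#' FAERS changed identifier column names over the years (legacy quarters use
#' `ISR`/`CASE`, modern quarters `primaryid`/`caseid`). The reader renames any
#' alias to the canonical name before further processing.
#'
#' @return Named list mapping canonical column name to a character vector of
#'   accepted (case-insensitive) header spellings.
#' @export
default_column_aliases <- function() {
  list(
    primaryid = c("primaryid", "isr"),
    caseid    = c("caseid", "case", "case_id"),
    drugname  = c("drugname", "drug_name", "medicinalproduct"),
    role_cod  = c("role_cod", "role_code", "rolecod"),
    pt        = c("pt", "preferred_term", "reactionmeddrapt"),
    indi_pt   = c("indi_pt", "indication_pt")
  )
}

#' Read one FAERS-style quarterly ASCII table
#'
#' Parses a "$"-delimited file with a header row into a tibble of character
#' columns. No quoting is honoured (FAERS files carry none) and trailing empty
#' fields are preserved. Lines whose field count disagrees with the header are
#' skipped with a warning; the number skipped is attached as attribute
#' `"skipped"`. Files are decoded as Latin-1 (FAERS archives are not uniformly
#' UTF-8); undecodable bytes are replaced and counted. Gzip-compressed files
#' (`*.gz`) are read transparently.
#'
#' @param path Path to the file.
#' @param table_kind One of `"DEMO"`, `"DRUG"`, `"REAC"`, `"INDI"`; determines
#'   which identifier columns are required (`primaryid` always; `caseid`
#'   additionally for DEMO and DRUG).
#' @param aliases Column-alias map, see [default_column_aliases()].
#' @return A tibble with canonical identifier columns plus the file's payload
#'   columns, all character. Attributes: `skipped` (malformed line count),
#'   `table_kind`.
#' @export
read_faers_table <- function(path, table_kind = c("DEMO", "DRUG", "REAC", "INDI"),
                             aliases = default_column_aliases()) {
  table_kind <- match.arg(table_kind)
  if (!file.exists(path)) {
    abort(paste0("FAERS ", table_kind, " file not found: ", path))
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  raw_lines <- readLines(con, warn = FALSE)
  close(con)
  lines <- iconv(raw_lines, from = "latin1", to = "UTF-8", sub = "?")
  n_repl <- sum(lines != raw_lines, na.rm = TRUE)
  if (n_repl > 0) {
    inform(paste0(basename(path), ": ", n_repl,
                  " line(s) contained bytes replaced during Latin-1 decoding"))
  }
  if (length(lines) == 0) {
    abort(paste0("Malformed FAERS ", table_kind, " file (no header line): ", path))
  }

  header <- stringr::str_split_1(lines[[1]], stringr::fixed("$"))
  canon <- tolower(trimws(header))
  for (target in names(aliases)) {
    canon[canon %in% tolower(aliases[[target]])] <- target
  }
  required <- c("primaryid", if (table_kind %in% c("DEMO", "DRUG")) "caseid")
  missing_cols <- setdiff(required, canon)
  if (length(missing_cols) > 0) {
    abort(paste0("Malformed FAERS ", table_kind, " header in ", path,
                 ": missing column(s) ", paste(missing_cols, collapse = ", ")))
  }

  body <- lines[-1]
  body <- body[nzchar(body)]
  nf <- length(header)
  if (length(body) == 0) {
    out <- as_tibble(setNames(rep(list(character(0)), nf), canon),
                     .name_repair = "minimal")
    attr(out, "skipped") <- 0L
    attr(out, "table_kind") <- table_kind
    return(out)
  }

  counts <- stringr::str_count(body, stringr::fixed("$")) + 1L
  bad <- counts != nf
  if (any(bad)) {
    warn(paste0(basename(path), ": skipped ", sum(bad),
                " line(s) with field count != ", nf))
    body <- body[!bad]
  }
  mat <- stringr::str_split_fixed(body, stringr::fixed("$"), nf)
  out <- as_tibble(setNames(lapply(seq_len(nf), function(j) mat[, j]), canon),
                   .name_repair = "minimal")
  attr(out, "skipped") <- sum(bad)
  attr(out, "table_kind") <- table_kind
  out
}

#' Deduplicate FAERS case versions
#'
#' A FAERS case may be reported several times; each submission receives a new
#' `primaryid` that encodes the case version. Later versions supersede earlier
#' ones, so the numerically greatest `primaryid` per `caseid` is retained.
#'
#' @param demo Tibble with `caseid` and `primaryid` columns (a DEMO table).
#' @return Tibble with columns `caseid`, `primaryid` (the retained version),
#'   one row per distinct caseid, sorted by caseid.
#' @export
deduplicate_cases <- function(demo) {
  stopifnot(all(c("caseid", "primaryid") %in% names(demo)))
  if (nrow(demo) == 0) {
    return(tibble(caseid = character(0), primaryid = character(0)))
  }
  out <- demo %>%
    select("caseid", "primaryid") %>%
    distinct() %>%
    mutate(.pid_num = suppressWarnings(as.numeric(.data$primaryid))) %>%
    group_by(.data$caseid) %>%
    arrange(dplyr::desc(.data$.pid_num), dplyr::desc(.data$primaryid),
            .by_group = TRUE) %>%
    slice(1L) %>%
    ungroup() %>%
    select("caseid", "primaryid")
  out[c_order(out$caseid), ]
}

#' Build the per-report analysis table
#'
#' Links the four quarterly tables by report identifiers: cases are
#' deduplicated to their latest version, drug rows are restricted to suspect
#' roles (primary/secondary by default; concomitant and interacting drugs are
#' dropped), and duplicate (report, drugname) and (report, preferred term)
#' pairs are collapsed. Reports with no suspect drug or no reaction stay in
#' the denominator (`n_reports`) with empty sets, as they contribute to the
#' background totals of the disproportionality contrasts.
#'
#' DRUG/REAC/INDI rows whose `primaryid` is not a retained case version are
#' ignored; rows referencing a `primaryid` absent from DEMO entirely are also
#' counted in the `orphans` field.
#'
#' @param demo,drug,reac Tibbles from [read_faers_table()]. `reac` must carry
#'   a `pt` column, `drug` a `drugname` and `role_cod` column.
#' @param indi Optional INDI tibble; carried through but unused by the
#'   statistics.
#' @param roles Role codes defining a suspect drug (default `c("PS", "SS")`).
#' @return A `faers_analysis` object: list with tibbles `reports` (caseid,
#'   primaryid plus any demographic payload), `drugs` (caseid, drugname,
#'   role_cod), `reactions` (caseid, pt), scalar `n_reports`, character
#'   `pt_vocabulary`, and `orphans` (count of drug/reaction rows not linkable
#'   to any DEMO report).
#' @export
build_analysis_table <- function(demo, drug, reac, indi = NULL,
                                 roles = c("PS", "SS")) {
  stopifnot(all(c("caseid", "primaryid") %in% names(demo)))
  retained <- deduplicate_cases(demo)

  reports <- demo %>%
    inner_join(retained, by = c("caseid", "primaryid")) %>%
    distinct(.data$caseid, .keep_all = TRUE)
  reports <- reports[c_order(reports$caseid), ]

  orphans <- 0L
  link <- function(tab, kind) {
    if (is.null(tab) || nrow(tab) == 0) return(tab)
    known <- tab$primaryid %in% demo$primaryid
    if (any(!known)) {
      orphans <<- orphans + sum(!known)
      inform(paste0(sum(!known), " ", kind,
                    " row(s) reference a primaryid absent from DEMO; dropped"))
    }
    tab[tab$primaryid %in% retained$primaryid, , drop = FALSE]
  }

  drugs <- link(drug, "DRUG")
  if (!is.null(drugs) && nrow(drugs) > 0) {
    stopifnot(all(c("drugname", "role_cod") %in% names(drugs)))
    drugs <- drugs %>%
      filter(.data$role_cod %in% roles) %>%
      left_join(retained, by = "primaryid", suffix = c(".x", "")) %>%
      distinct(.data$caseid, .data$drugname, .keep_all = TRUE) %>%
      select("caseid", "drugname", "role_cod")
  } else {
    drugs <- tibble(caseid = character(0), drugname = character(0),
                    role_cod = character(0))
  }
  drugs <- drugs[c_order(drugs$caseid, drugs$drugname), ]

  reacs <- link(reac, "REAC")
  if (!is.null(reacs) && nrow(reacs) > 0) {
    stopifnot("pt" %in% names(reacs))
    reacs <- reacs %>%
      left_join(retained, by = "primaryid", suffix = c(".x", "")) %>%
      distinct(.data$caseid, .data$pt) %>%
      select("caseid", "pt")
  } else {
    reacs <- tibble(caseid = character(0), pt = character(0))
  }
  reacs <- reacs[c_order(reacs$caseid, reacs$pt), ]

  if (!is.null(indi)) link(indi, "INDI")

  structure(
    list(
      reports = reports,
      drugs = drugs,
      reactions = reacs,
      n_reports = nrow(reports),
      pt_vocabulary = c_sort(unique(reacs$pt)),
      orphans = orphans
    ),
    class = "faers_analysis"
  )
}

#' @export
print.faers_analysis <- function(x, ...) {
  cat("<faers_analysis>\n")
  cat("  reports:        ", x$n_reports, "\n")
  cat("  suspect drug rows:", nrow(x$drugs),
      " (", length(unique(x$drugs$drugname)), " distinct names)\n", sep = "")
  cat("  reaction rows:  ", nrow(x$reactions),
      " (", length(x$pt_vocabulary), " preferred terms)\n", sep = "")
  if (x$orphans > 0) cat("  orphan rows dropped:", x$orphans, "\n")
  invisible(x)
}

#' Write / read the long-format analysis table
#'
#' The long format is a TSV with columns `caseid`, `primaryid`, `drugname`,
#' `role_cod`, `pt`. Each suspect-drug membership and each reaction membership
#' is one row (the unused columns are empty); a report with neither appears as
#' a single row with both empty, so `n_reports` survives the round trip.
#' Demographic payload columns are not part of this export.
#'
#' @param x A `faers_analysis` object.
#' @param path Output TSV path.
#' @return `write_analysis_table()` returns `path` invisibly;
#'   `read_analysis_table()` returns a `faers_analysis`.
#' @export
write_analysis_table <- function(x, path) {
  stopifnot(inherits(x, "faers_analysis"))
  pid <- setNames(x$reports$primaryid, x$reports$caseid)
  drug_rows <- tibble(
    caseid = x$drugs$caseid, primaryid = unname(pid[x$drugs$caseid]),
    drugname = x$drugs$drugname, role_cod = x$drugs$role_cod, pt = ""
  )
  reac_rows <- tibble(
    caseid = x$reactions$caseid, primaryid = unname(pid[x$reactions$caseid]),
    drugname = "", role_cod = "", pt = x$reactions$pt
  )
  bare <- setdiff(x$reports$caseid, c(drug_rows$caseid, reac_rows$caseid))
  bare_rows <- tibble(caseid = bare, primaryid = unname(pid[bare]),
                      drugname = "", role_cod = "", pt = "")
  out <- bind_rows(drug_rows, reac_rows, bare_rows)
  out <- out[c_order(out$caseid, out$pt, out$drugname), ]
  write_tsv_plain(out, path)
}

#' @rdname write_analysis_table
#' @export
read_analysis_table <- function(path) {
  long <- read_tsv_plain(path)
  stopifnot(all(c("caseid", "primaryid", "drugname", "role_cod", "pt") %in%
                  names(long)))
  reports <- long %>% distinct(.data$caseid, .data$primaryid)
  reports <- reports[c_order(reports$caseid), ]
  drugs <- long %>%
    filter(nzchar(.data$drugname)) %>%
    distinct(.data$caseid, .data$drugname, .data$role_cod) %>%
    select("caseid", "drugname", "role_cod")
  drugs <- drugs[c_order(drugs$caseid, drugs$drugname), ]
  reacs <- long %>%
    filter(nzchar(.data$pt)) %>%
    distinct(.data$caseid, .data$pt)
  reacs <- reacs[c_order(reacs$caseid, reacs$pt), ]
  structure(
    list(
      reports = reports,
      drugs = drugs,
      reactions = reacs,
      n_reports = nrow(reports),
      pt_vocabulary = c_sort(unique(reacs$pt)),
      orphans = 0L
    ),
    class = "faers_analysis"
  )
}
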