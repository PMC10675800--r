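#' Drug-name normalization rules
#'
#' A rule assigns a canonical drug label to verbatim drug-name strings by
#' case-insensitive substring matching: a string receives the label when at
#' least one include pattern is contained in it and no exclude pattern is.
#' Exclusions dominate, which resolves collisions such as CODEINE inside
#' DIHYDROCODEINE or MORPHINE inside APOMORPHINE. Because matching is by
#' containment, salt and hydrate suffixes ("MORPHINE SULFATE",
#' "Fentanyl Citrate") need no extra patterns.
#'
#' `read_drug_rules()` loads rules from a YAML file (a list of records with
#' `label`, `include`, `exclude`); `opioid_rules()` returns the shipped rule
#' set covering the eleven mu-opioid receptor agonists approved in Japan:
#' morphine, fentanyl, oxycodone, codeine, dihydrocodeine, hydromorphone,
#' methadone, tapentadol, pethidine, loperamide and remifentanil.
#'
#' @param path Path to a YAML rules file.
#' @return A tibble with columns `label`, `include` (list of character
#'   vectors), `exclude` (list of character vectors).
#' @export
read_drug_rules <- function(path) {
  raw <- yaml::read_yaml(path)
  stopifnot(length(raw) > 0)
  rules <- tibble(
    label = purrr::map_chr(raw, "label"),
    include = purrr::map(raw, ~ toupper(as.character(.x$include %||% character()))),
    exclude = purrr::map(raw, ~ toupper(as.character(.x$exclude %||% character())))
  )
  if (any(lengths(rules$include) == 0)) {
    abort("every drug rule needs at least one include pattern")
  }
  if (anyDuplicated(rules$label)) abort("duplicate rule labels")
  rules
}

#' @rdname read_drug_rules
#' @export
opioid_rules <- function() {
  read_drug_rules(system.file("extdata", "opioid_rules.yaml",
                              package = "faersignal", mustWork = TRUE))
}

#' Map one verbatim drug-name string to canonical labels
#'
#' @param verbatim Character vector of verbatim drug-name strings.
#' @param rules Rules tibble from [read_drug_rules()] / [opioid_rules()].
#' @return A list (one element per input string) of character vectors of
#'   matched labels; empty vector for non-target names. A pathological string
#'   naming two targets (e.g. a combination product) gets both labels.
#' @export
map_drugname <- function(verbatim, rules = opioid_rules()) {
  up <- toupper(verbatim)
  hit <- matrix(FALSE, nrow = length(up), ncol = nrow(rules))
  for (j in seq_len(nrow(rules))) {
    inc <- Reduce(`|`, lapply(rules$include[[j]],
                              function(p) stringr::str_detect(up, stringr::fixed(p))))
    exc <- FALSE
    if (length(rules$exclude[[j]]) > 0) {
      exc <- Reduce(`|`, lapply(rules$exclude[[j]],
                                function(p) stringr::str_detect(up, stringr::fixed(p))))
    }
    hit[, j] <- inc & !exc
  }
  lapply(seq_along(up), function(i) rules$label[hit[i, ]])
}

#' Add canonical drug labels to a suspect-drug table
#'
#' Expands a table holding verbatim `drugname` strings by the canonical
#' labels they match: rows whose name matches no rule are dropped, rows
#' matching several labels are duplicated (one row per label), and duplicate
#' (caseid, label) pairs are collapsed so one report counts at most once per
#' drug label.
#'
#' @param drugs A tibble with at least `caseid` and `drugname` columns (the
#'   `drugs` slot of a `faers_analysis`, or any long table).
#' @param rules Rules tibble.
#' @return Tibble with columns `caseid`, `drug` (canonical label), one row
#'   per distinct (caseid, drug) pair, deterministically ordered.
#' @export
map_drugs <- function(drugs, rules = opioid_rules()) {
  stopifnot(all(c("caseid", "drugname") %in% names(drugs)))
  if (nrow(drugs) == 0) {
    return(tibble(caseid = character(0), drug = character(0)))
  }
  name_map <- tibble(drugname = unique(drugs$drugname))
  name_map$drug <- map_drugname(name_map$drugname, rules)
  name_map <- tidyr::unnest(name_map, "drug")
  out <- drugs %>%
    select("caseid", "drugname") %>%
    inner_join(name_map, by = "drugname") %>%
    distinct(.data$caseid, .data$drug)
  out[c_order(out$caseid, out$drug), ]
}
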