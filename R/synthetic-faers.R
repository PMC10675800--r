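#' Configuration for the synthetic spontaneous-report generator
#'
#' The generator emulates the data model of FAERS quarterly extracts: each
#' report (case) carries a set of suspect drugs and a set of reaction
#' preferred terms; a fraction of cases is re-emitted as a superseded earlier
#' version; drug names are rendered as verbatim strings with salt/hydrate
#' suffixes and case jitter. Associations are planted through per-(drug,
#' event) reporting-rate multipliers: drug `d` is included in a report with
#' its marginal probability, and event `j` is then included with probability
#' `baseline_j * theta_eff`, where `theta_eff` aggregates the multipliers of
#' the report's drugs (maximum by default, product optionally) and is 1 for
#' drug-free reports. Probabilities driven above 1 are capped and the cap
#' occurrences counted.
#'
#' Per-report drug and event counts are therefore induced by the marginal
#' inclusion probabilities (they follow Poisson-binomial laws) rather than
#' drawn from explicit count distributions; this is what gives every planted
#' pair a closed-form asymptotic lnROR ([expected_lnror()]).
#'
#' @param n_reports Number of distinct cases to generate.
#' @param drug_vocab Tibble `label`, `marginal` for the target drugs (labels
#'   must be mappable by the rules in use).
#' @param event_vocab Tibble `pt`, `baseline` (per-report inclusion
#'   probability for a drug-free report).
#' @param multipliers Tibble `drug`, `pt`, `theta` (unspecified pairs default
#'   to 1; `theta = 1` means no association).
#' @param distractor_vocab Tibble `name`, `marginal`: non-target suspect
#'   drugs (verbatim names used as-is) that must flow through name mapping
#'   unlabeled.
#' @param aggregate `"max"` or `"product"`: how multipliers of multi-drug
#'   reports combine.
#' @param duplicate_rate Fraction of cases also emitted as a superseded
#'   earlier version (demographics perturbed; drugs/reactions identical).
#' @param concomitant_rate Probability that a report carries one concomitant
#'   (role `C`) drug, which suspect-role filtering must drop.
#' @param seed Integer seed; identical configurations generate byte-identical
#'   file sets.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_reports,
                             drug_vocab,
                             event_vocab,
                             multipliers = NULL,
                             distractor_vocab = NULL,
                             aggregate = c("max", "product"),
                             duplicate_rate = 0.05,
                             concomitant_rate = 0.3,
                             seed = 1) {
  aggregate <- match.arg(aggregate)
  drug_vocab <- as_tibble(drug_vocab)
  event_vocab <- as_tibble(event_vocab)
  stopifnot(all(c("label", "marginal") %in% names(drug_vocab)),
            all(c("pt", "baseline") %in% names(event_vocab)))
  multipliers <- if (is.null(multipliers)) {
    tibble(drug = character(0), pt = character(0), theta = numeric(0))
  } else as_tibble(multipliers)
  distractor_vocab <- if (is.null(distractor_vocab)) {
    tibble(name = character(0), marginal = numeric(0))
  } else as_tibble(distractor_vocab)
  probs <- c(drug_vocab$marginal, event_vocab$baseline,
             distractor_vocab$marginal, duplicate_rate, concomitant_rate)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (nrow(multipliers) > 0) {
    stopifnot(all(c("drug", "pt", "theta") %in% names(multipliers)))
    if (any(multipliers$theta < 0)) abort("multipliers must be >= 0")
    if (!all(multipliers$drug %in% drug_vocab$label)) {
      abort("multiplier rows reference unknown drug labels")
    }
    if (!all(multipliers$pt %in% event_vocab$pt)) {
      abort("multiplier rows reference unknown preferred terms")
    }
  }
  if (n_reports < 0) abort("n_reports must be >= 0")
  structure(
    list(n_reports = as.integer(n_reports), drug_vocab = drug_vocab,
         event_vocab = event_vocab, multipliers = multipliers,
         distractor_vocab = distractor_vocab, aggregate = aggregate,
         duplicate_rate = duplicate_rate, concomitant_rate = concomitant_rate,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# multiplier lookup: named list pt -> named theta vector over drugs
multiplier_map <- function(config) {
  mm <- config$multipliers
  out <- list()
  if (nrow(mm) > 0) {
    for (j in unique(mm$pt)) {
      sub <- mm[mm$pt == j, ]
      out[[j]] <- setNames(sub$theta, sub$drug)
    }
  }
  out
}

#' Default study-condition configuration: eleven opioids
#'
#' Emulates the opioid disproportionality study at desk scale: the eleven
#' mu-opioid agonist labels with marginal report probabilities proportional
#' to their published FAERS report counts (scaled to a database where the
#' most reported drug appears in about 7.7% of reports), 20 planted
#' opioid-associated adverse events whose multipliers exceed 1 for every
#' opioid but differ between five pharmacological drug groups (weak opioids;
#' loperamide; strong opioids; tapentadol; remifentanil), and 30 background
#' events with multiplier 1. Distractor suspect drugs (including apomorphine,
#' which the morphine rule must veto) and concomitant drugs exercise name
#' mapping and role filtering.
#'
#' @param n_reports Number of cases (default 50,000).
#' @param seed Integer seed.
#' @inheritParams synthetic_config
#' @return A `synthetic_config`.
#' @export
synthetic_opioid_config <- function(n_reports = 50000, seed = 1,
                                    duplicate_rate = 0.05) {
  drug_vocab <- tibble(
    label = c("oxycodone", "morphine", "fentanyl", "codeine", "hydromorphone",
              "loperamide", "methadone", "tapentadol", "pethidine",
              "dihydrocodeine", "remifentanil"),
    marginal = c(0.0771, 0.0438, 0.0374, 0.0263, 0.0217,
                 0.0174, 0.0117, 0.0051, 0.0042, 0.0025, 0.0010)
  )
  group <- c(oxycodone = "strong", morphine = "strong", fentanyl = "strong",
             hydromorphone = "strong", methadone = "strong",
             codeine = "weak", pethidine = "weak", dihydrocodeine = "weak",
             loperamide = "loperamide", tapentadol = "tapentadol",
             remifentanil = "remifentanil")
  planted <- tibble(
    pt = c("SOMNOLENCE", "CONSTIPATION", "VOMITING", "NAUSEA",
           "DRUG WITHDRAWAL SYNDROME", "OVERDOSE", "DRUG ABUSE",
           "TOXICITY TO VARIOUS AGENTS", "RESPIRATORY DEPRESSION",
           "CONFUSIONAL STATE", "DELIRIUM", "HYPOTENSION", "BRADYCARDIA",
           "CARDIAC ARREST", "ELECTROCARDIOGRAM QT PROLONGED",
           "HEPATIC FAILURE", "URINARY RETENTION", "HALLUCINATION",
           "HYPOXIA", "DIARRHOEA"),
    baseline = c(0.012, 0.010, 0.015, 0.016, 0.006, 0.008, 0.006,
                 0.008, 0.004, 0.010, 0.004, 0.012, 0.006, 0.006, 0.003,
                 0.003, 0.003, 0.005, 0.004, 0.012),
    # per drug-group multiplier profile (all > 1: planted for every opioid)
    strong       = c(4, 4, 3, 3, 5, 4, 3, 4, 4, 3, 3, 2, 2, 2, 2, 1.5, 3, 3, 2, 1.5),
    weak         = c(2, 2, 2, 2, 2, 1.5, 1.5, 2, 2, 2, 2, 1.5, 1.5, 1.5, 1.5, 4, 2, 2, 1.5, 1.5),
    loperamide   = c(1.5, 3, 2, 2, 1.5, 1.5, 1.5, 2, 1.5, 1.5, 1.5, 2, 3, 3, 4, 1.5, 1.5, 1.5, 1.5, 6),
    tapentadol   = c(4, 3, 2, 2, 4, 6, 6, 4, 2, 3, 5, 1.5, 1.5, 1.5, 1.5, 1.5, 2, 4, 1.5, 1.5),
    remifentanil = c(2, 1.5, 1.5, 1.5, 1.5, 1.5, 1.5, 2, 6, 1.5, 1.5, 5, 5, 4, 2, 1.5, 1.5, 1.5, 6, 1.5)
  )
  background_pts <- c(
    "PAIN", "DEATH", "DRUG INTERACTION", "DRUG HYPERSENSITIVITY",
    "LOSS OF CONSCIOUSNESS", "HYPERHIDROSIS", "RESPIRATORY FAILURE",
    "TACHYCARDIA", "MALIGNANT NEOPLASM PROGRESSION", "AGITATION",
    "BLOOD PRESSURE DECREASED", "LETHARGY", "PULMONARY OEDEMA",
    "OXYGEN SATURATION DECREASED", "COMA", "DISORIENTATION",
    "DYSKINESIA", "LIVER FUNCTION TEST ABNORMAL", "MENTAL STATUS CHANGES",
    "ANAPHYLACTIC REACTION", "MEDICATION ERROR", "RESTLESSNESS",
    "HEADACHE", "DIZZINESS", "FATIGUE", "PRURITUS", "RASH",
    "INSOMNIA", "ANXIETY", "DYSPNOEA")
  event_vocab <- bind_rows(
    planted %>% select("pt", "baseline"),
    tibble(pt = background_pts,
           baseline = rep(c(0.03, 0.02, 0.015, 0.01, 0.008, 0.006), 5))
  )
  mult <- planted %>%
    tidyr::pivot_longer(cols = c("strong", "weak", "loperamide",
                                 "tapentadol", "remifentanil"),
                        names_to = "group", values_to = "theta") %>%
    inner_join(tibble(drug = names(group), group = unname(group)),
               by = "group", relationship = "many-to-many") %>%
    select("drug", "pt", "theta")
  distractors <- tibble(
    name = c("APOMORPHINE HYDROCHLORIDE", "ACETAMINOPHEN", "IBUPROFEN",
             "GABAPENTIN", "ALFENTANIL HCL", "SUFENTANIL CITRATE"),
    marginal = c(0.002, 0.03, 0.02, 0.01, 0.001, 0.001)
  )
  synthetic_config(
    n_reports = n_reports, drug_vocab = drug_vocab,
    event_vocab = event_vocab, multipliers = mult,
    distractor_vocab = distractors, aggregate = "max",
    duplicate_rate = duplicate_rate, concomitant_rate = 0.3, seed = seed
  )
}

# Render verbatim drug-name variants: salt/hydrate suffix + case jitter.
# Deterministic given the RNG state; every rendering contains the canonical
# name as a substring, so rule-based mapping recovers the label exactly.
drug_name_variants <- function() {
  c("%s", "%s HYDROCHLORIDE", "%s SULFATE", "%s HCL",
    "%s HYDRATE", "%s TARTRATE")
}

render_drug_names <- function(labels) {
  variants <- drug_name_variants()
  v <- sample.int(length(variants), length(labels), replace = TRUE)
  base <- sprintf(variants[v], toupper(labels))
  style <- sample.int(3, length(labels), replace = TRUE)
  out <- base
  out[style == 2] <- tolower(base[style == 2])
  out[style == 3] <- stringr::str_to_title(base[style == 3])
  out
}

#' Generate a synthetic FAERS-like database
#'
#' Draws reports from a [synthetic_config()] and returns both the ground
#' truth (per-report true drug labels and event terms) and the four
#' FAERS-dialect tables. Fully reproducible: the same configuration (seed
#' included) yields identical output.
#'
#' @param config A `synthetic_config`.
#' @param render_tables If `FALSE`, only the ground truth is built (faster
#'   for large statistical simulations that bypass the file layer).
#' @return A `synthetic_faers` list: `truth` (list with `drug_pairs`,
#'   `event_pairs`, `n_reports`, `cap_count`, `config`) and `tables` (list
#'   `demo`, `drug`, `reac`, `indi`, or `NULL`).
#' @export
generate_faers <- function(config, render_tables = TRUE) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_reports
  dv <- config$drug_vocab
  ev <- config$event_vocab
  xv <- config$distractor_vocab
  mm <- multiplier_map(config)

  caseid <- sprintf("C%08d", seq_len(n))
  all_names <- c(dv$label, xv$name)
  all_marg <- c(dv$marginal, xv$marginal)
  n_all <- length(all_names)

  presence <- matrix(FALSE, nrow = max(n, 0), ncol = n_all)
  for (d in seq_len(n_all)) {
    if (n > 0) presence[, d] <- runif(n) < all_marg[d]
  }
  n_present <- if (n > 0) rowSums(presence) else integer(0)

  cap_count <- 0L
  event_rows <- vector("list", nrow(ev))
  is_target <- seq_len(n_all) <= nrow(dv)
  for (j in seq_len(nrow(ev))) {
    pt <- ev$pt[j]
    th <- mm[[pt]]
    if (n == 0) { event_rows[[j]] <- integer(0); next }
    nonunit <- names(th)[th != 1]
    if (config$aggregate == "max") {
      cand <- rep(-Inf, n)
      cnt <- rep(0L, n)
      for (dname in nonunit) {
        d <- match(dname, all_names)
        pres <- presence[, d]
        cand[pres] <- pmax(cand[pres], th[[dname]])
        cnt <- cnt + pres
      }
      any_unit <- (n_present - cnt) > 0
      cand[any_unit] <- pmax(cand[any_unit], 1)
      cand[n_present == 0] <- 1
      theta_eff <- cand
    } else {
      theta_eff <- rep(1, n)
      for (dname in nonunit) {
        d <- match(dname, all_names)
        pres <- presence[, d]
        theta_eff[pres] <- theta_eff[pres] * th[[dname]]
      }
    }
    p <- ev$baseline[j] * theta_eff
    over <- p > 1
    if (any(over)) {
      cap_count <- cap_count + sum(over)
      p <- pmin(p, 1)
    }
    event_rows[[j]] <- which(runif(n) < p)
  }
  if (cap_count > 0) {
    inform(paste0("event inclusion probability capped at 1 for ",
                  cap_count, " report-event draws"))
  }

  drug_pairs <- tibble(
    caseid = caseid[which(presence[, is_target, drop = FALSE],
                          arr.ind = TRUE)[, 1]],
    drug = dv$label[which(presence[, is_target, drop = FALSE],
                          arr.ind = TRUE)[, 2]]
  )
  drug_pairs <- drug_pairs[c_order(drug_pairs$caseid, drug_pairs$drug), ]
  event_pairs <- tibble(
    caseid = caseid[unlist(event_rows)],
    pt = rep(ev$pt, lengths(event_rows))
  )
  event_pairs <- event_pairs[c_order(event_pairs$caseid, event_pairs$pt), ]

  truth <- list(drug_pairs = drug_pairs, event_pairs = event_pairs,
                n_reports = n, cap_count = cap_count, config = config)

  tables <- NULL
  if (render_tables) {
    tables <- render_faers_tables(config, caseid, presence, all_names,
                                  is_target, event_rows, ev)
  }
  structure(list(truth = truth, tables = tables), class = "synthetic_faers")
}

# Build the four FAERS-dialect tables from the drawn memberships.
render_faers_tables <- function(config, caseid, presence, all_names,
                                is_target, event_rows, ev) {
  n <- config$n_reports
  case_num <- seq_len(n)
  pid1 <- as.character(case_num * 10 + 2)   # retained (latest) version
  pid0 <- as.character(case_num * 10 + 1)   # superseded version
  dup <- if (n > 0) runif(n) < config$duplicate_rate else logical(0)

  age <- if (n > 0) as.character(sample(18:90, n, replace = TRUE)) else character(0)
  sex <- if (n > 0) sample(c("M", "F"), n, replace = TRUE) else character(0)
  demo <- tibble(primaryid = pid1, caseid = caseid, age = age, sex = sex)
  if (any(dup)) {
    # the earlier version differs only in demographics
    demo <- bind_rows(
      demo,
      tibble(primaryid = pid0[dup], caseid = caseid[dup],
             age = as.character(pmin(as.integer(age[dup]) + 1L, 90L)),
             sex = sex[dup])
    )
  }
  demo <- demo[c_order(demo$caseid, demo$primaryid), ]

  # suspect drugs: first present drug per report is PS, the rest SS
  hit <- which(presence, arr.ind = TRUE)
  drug_tab <- tibble(row = hit[, 1], col = hit[, 2]) %>%
    arrange(.data$row, .data$col) %>%
    group_by(.data$row) %>%
    mutate(drug_seq = dplyr::row_number(),
           role_cod = ifelse(dplyr::row_number() == 1, "PS", "SS")) %>%
    ungroup()
  verbatim <- character(nrow(drug_tab))
  tgt <- is_target[drug_tab$col]
  verbatim[tgt] <- render_drug_names(all_names[drug_tab$col[tgt]])
  verbatim[!tgt] <- all_names[drug_tab$col[!tgt]]
  drug <- tibble(
    primaryid = pid1[drug_tab$row], caseid = caseid[drug_tab$row],
    drug_seq = as.character(drug_tab$drug_seq),
    role_cod = drug_tab$role_cod, drugname = verbatim
  )
  # concomitant (role C) drugs, dropped by suspect-role filtering
  conc_vocab <- c("OMEPRAZOLE", "AMLODIPINE", "METFORMIN", "ASPIRIN",
                  "SIMVASTATIN")
  conc <- if (n > 0) runif(n) < config$concomitant_rate else logical(0)
  if (any(conc)) {
    drug <- bind_rows(drug, tibble(
      primaryid = pid1[conc], caseid = caseid[conc],
      drug_seq = "90",
      role_cod = "C",
      drugname = sample(conc_vocab, sum(conc), replace = TRUE)
    ))
  }
  if (any(dup)) {
    prev <- drug[drug$caseid %in% caseid[dup], ]
    prev$primaryid <- pid0[match(prev$caseid, caseid)]
    drug <- bind_rows(drug, prev)
  }
  drug <- drug[c_order(drug$caseid, drug$primaryid, drug$drug_seq,
                       drug$drugname), ]

  reac_rows <- tibble(
    row = unlist(event_rows),
    pt = rep(ev$pt, lengths(event_rows))
  )
  reac <- tibble(primaryid = pid1[reac_rows$row],
                 caseid = caseid[reac_rows$row], pt = reac_rows$pt)
  if (any(dup)) {
    prev <- reac[reac$caseid %in% caseid[dup], ]
    prev$primaryid <- pid0[match(prev$caseid, caseid)]
    reac <- bind_rows(reac, prev)
  }
  reac <- reac[c_order(reac$caseid, reac$primaryid, reac$pt), ]

  indi_vocab <- c("PAIN", "CANCER PAIN", "DIARRHOEA", "ANAESTHESIA",
                  "CHRONIC PAIN")
  has_indi <- if (n > 0) runif(n) < 0.5 else logical(0)
  indi <- tibble(
    primaryid = pid1[has_indi], caseid = caseid[has_indi],
    indi_drug_seq = "1",
    indi_pt = sample(indi_vocab, sum(has_indi), replace = TRUE)
  )
  indi <- indi[c_order(indi$caseid), ]

  list(demo = demo, drug = drug, reac = reac, indi = indi)
}

#' Write a synthetic database as FAERS-dialect ASCII files
#'
#' Emits `DEMO.txt`, `DRUG.txt`, `REAC.txt`, `INDI.txt` ("$"-delimited with
#' header) plus a `ground_truth.tsv` sidecar (caseid-level true drug labels
#' and event terms) and a `seed.txt` recording the seed used.
#'
#' @param gen A `synthetic_faers` object from [generate_faers()] (with
#'   rendered tables).
#' @param dir Output directory (created if needed).
#' @return Named character vector of the file paths, invisibly.
#' @export
write_faers_files <- function(gen, dir) {
  stopifnot(inherits(gen, "synthetic_faers"))
  if (is.null(gen$tables)) {
    abort("generate_faers() was called with render_tables = FALSE")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_dollar <- function(df, path) {
    lines <- c(paste(names(df), collapse = "$"),
               if (nrow(df)) do.call(paste, c(unname(as.list(df)), sep = "$")))
    writeLines(lines, path, useBytes = TRUE)
  }
  paths <- c(
    demo = file.path(dir, "DEMO.txt"), drug = file.path(dir, "DRUG.txt"),
    reac = file.path(dir, "REAC.txt"), indi = file.path(dir, "INDI.txt"),
    truth = file.path(dir, "ground_truth.tsv"),
    seed = file.path(dir, "seed.txt")
  )
  write_dollar(gen$tables$demo, paths[["demo"]])
  write_dollar(gen$tables$drug, paths[["drug"]])
  write_dollar(gen$tables$reac, paths[["reac"]])
  write_dollar(gen$tables$indi, paths[["indi"]])
  truth_long <- bind_rows(
    mutate(gen$truth$drug_pairs, kind = "drug", value = .data$drug) %>%
      select("caseid", "kind", "value"),
    mutate(gen$truth$event_pairs, kind = "event", value = .data$pt) %>%
      select("caseid", "kind", "value")
  )
  truth_long <- truth_long[c_order(truth_long$caseid, truth_long$kind,
                                   truth_long$value), ]
  write_tsv_plain(truth_long, paths[["truth"]])
  writeLines(as.character(gen$truth$config$seed), paths[["seed"]])
  invisible(paths)
}

#' Closed-form asymptotic lnROR implied by a synthetic configuration
#'
#' Derives the four cell probabilities of the (drug, event) contingency
#' contrast analytically from the generator's probability model (exact
#' enumeration over the drugs whose multiplier for the event differs from 1,
#' plus the aggregate presence of multiplier-1 drugs) and returns the lnROR
#' they imply under the chosen comparator. This is the oracle that parameter
#' recovery tests compare pipeline estimates against. Pairs whose inclusion
#' probability can exceed 1 (capping) have no closed form and raise an error.
#'
#' @param config A `synthetic_config`.
#' @param drug Target drug label.
#' @param pt Event preferred term.
#' @param comparator `"all_reports"` or `"other_reports"`.
#' @return The asymptotic lnROR (a single number).
#' @export
expected_lnror <- function(config, drug, pt,
                           comparator = c("all_reports", "other_reports")) {
  comparator <- match.arg(comparator)
  stopifnot(inherits(config, "synthetic_config"))
  dv <- config$drug_vocab
  xv <- config$distractor_vocab
  if (!drug %in% dv$label) abort(paste0("unknown drug label: ", drug))
  j <- match(pt, config$event_vocab$pt)
  if (is.na(j)) abort(paste0("unknown preferred term: ", pt))
  baseline <- config$event_vocab$baseline[j]
  th <- multiplier_map(config)[[pt]]
  th <- th[th != 1]

  all_names <- c(dv$label, xv$name)
  all_marg <- setNames(c(dv$marginal, xv$marginal), all_names)
  enum_names <- union(names(th), drug)
  rest <- setdiff(all_names, enum_names)
  p_rest <- 1 - prod(1 - all_marg[rest])   # P(any multiplier-1 drug present)

  q <- all_marg[enum_names]
  k <- length(enum_names)
  p_event <- 0
  p_event_and_drug <- 0
  for (mask in 0:(2^k - 1)) {
    s <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1)))
    w_enum <- prod(ifelse(s, q, 1 - q))
    present <- enum_names[s]
    present_th <- th[names(th) %in% present]
    for (z in c(FALSE, TRUE)) {
      w <- w_enum * if (z) p_rest else 1 - p_rest
      if (w == 0) next
      any_drug <- any(s) || z
      any_unit <- z || any(!(present %in% names(th)))
      if (config$aggregate == "max") {
        theta_eff <- if (!any_drug) 1
          else max(c(present_th, if (any_unit) 1, -Inf))
      } else {
        theta_eff <- prod(c(present_th, 1))
      }
      pe <- baseline * theta_eff
      if (pe > 1) {
        abort(paste0("pair (", drug, ", ", pt, ") is capped (probability ",
                     format(pe), " > 1); no closed-form lnROR"))
      }
      p_event <- p_event + w * pe
      if (drug %in% present) p_event_and_drug <- p_event_and_drug + w * pe
    }
  }

  q_i <- all_marg[[drug]]
  p_a <- p_event_and_drug
  p_b <- q_i - p_a
  if (comparator == "all_reports") {
    p_c <- p_event
    p_d <- 1 - p_event
  } else {
    p_c <- p_event - p_a
    p_d <- (1 - q_i) - p_c
  }
  log((p_a * p_d) / (p_b * p_c))
}
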