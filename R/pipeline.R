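#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end analysis: where the reports come from
#' (a directory of FAERS-dialect files, a persisted long-format analysis
#' table, or a [synthetic_config()] to generate from), the drug-name rules,
#' the disproportionality settings, the event filters and the cluster counts.
#'
#' @param input Either a directory containing `DEMO.txt`, `DRUG.txt`,
#'   `REAC.txt`, `INDI.txt`; a path to a long-format analysis TSV (from
#'   [write_analysis_table()]); or a `synthetic_config`.
#' @param out_dir Output directory for stage intermediates and results.
#' @param rules Drug-name rules tibble, or path to a YAML rules file.
#' @param comparator,alpha,level See [signal_table()].
#' @param filter A [filter_config()].
#' @param k_drugs,k_events Cluster counts for the two axes.
#' @param roles Suspect role codes to retain.
#' @param quiet Suppress per-stage log lines.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input, out_dir,
                            rules = opioid_rules(),
                            comparator = c("all_reports", "other_reports"),
                            alpha = 0.05, level = 0.95,
                            filter = filter_config(),
                            k_drugs = 5, k_events = 7,
                            roles = c("PS", "SS"),
                            quiet = FALSE) {
  comparator <- match.arg(comparator)
  if (is.character(rules)) rules <- read_drug_rules(rules)
  if (is.character(input) && !file.exists(input) && !dir.exists(input)) {
    abort(paste0("pipeline input path does not exist: ", input))
  }
  if (k_drugs < 1 || k_events < 1) abort("cluster counts must be >= 1")
  structure(
    list(input = input, out_dir = out_dir, rules = rules,
         comparator = comparator, alpha = alpha, level = level,
         filter = filter, k_drugs = k_drugs, k_events = k_events,
         roles = roles, quiet = quiet),
    class = "pipeline_config"
  )
}

#' Run the full signal-detection pipeline
#'
#' Stages, mirroring the analysis flowchart: generate (synthetic input only)
#' -> ingest (read tables, deduplicate cases, build the analysis table) ->
#' map (normalize drug names to canonical labels) -> signals (per-pair ROR /
#' CI / Fisher p) -> summarize (lnROR matrix and per-event summary) -> filter
#' (report-count and positive-mean-lnROR extraction) -> cluster (two-way
#' Ward). Every stage persists its output as TSV under `out_dir`, so the
#' pipeline is resumable from the long-format intermediate and each stage is
#' independently inspectable. A manifest (YAML) records row/report counts at
#' every stage and the effective configuration.
#'
#' Any stage failure aborts with the stage name; files already written for
#' this run are removed.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly (a list; also written to
#'   `out_dir/manifest.yaml`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  note <- function(path) { written <<- c(written, path); path }
  manifest <- list(stages = list(), outputs = list())
  t0_all <- Sys.time()

  log_stage <- function(stage, counts, t0) {
    secs <- round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)
    manifest$stages[[stage]] <<- c(counts, list(seconds = secs))
    if (!config$quiet) {
      inform(paste0("[", stage, "] ",
                    paste(names(counts), unlist(counts), sep = "=",
                          collapse = " "),
                    " (", secs, "s)"))
    }
  }

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      abort(paste0("pipeline failed at stage '", stage, "': ",
                   conditionMessage(e)))
    })
  }

  # -- generate / locate input ------------------------------------------
  input <- config$input
  if (inherits(input, "synthetic_config")) {
    t0 <- Sys.time()
    run_stage("generate", {
      gen <- generate_faers(input, render_tables = TRUE)
      paths <- write_faers_files(gen, file.path(out_dir, "input"))
      for (p in paths) note(p)
      input <- file.path(out_dir, "input")
      log_stage("generate", list(n_reports = gen$truth$n_reports,
                                 cap_count = gen$truth$cap_count), t0)
    })
  }

  # -- ingest ------------------------------------------------------------
  t0 <- Sys.time()
  analysis <- run_stage("ingest", {
    if (dir.exists(input)) {
      demo <- read_faers_table(file.path(input, "DEMO.txt"), "DEMO")
      drug <- read_faers_table(file.path(input, "DRUG.txt"), "DRUG")
      reac <- read_faers_table(file.path(input, "REAC.txt"), "REAC")
      indi_path <- file.path(input, "INDI.txt")
      indi <- if (file.exists(indi_path)) {
        read_faers_table(indi_path, "INDI")
      }
      if (nrow(demo) == 0) abort("DEMO table has no data rows")
      at <- build_analysis_table(demo, drug, reac, indi,
                                 roles = config$roles)
      manifest$stages$ingest_rows <- list(
        demo = nrow(demo), drug = nrow(drug), reac = nrow(reac),
        skipped = attr(demo, "skipped") + attr(drug, "skipped") +
          attr(reac, "skipped"))
      at
    } else {
      at <- read_analysis_table(input)
      if (at$n_reports == 0) abort("analysis table has no reports")
      at
    }
  })
  note(write_analysis_table(analysis, file.path(out_dir, "analysis_table.tsv")))
  log_stage("ingest", list(n_reports = analysis$n_reports,
                           suspect_drug_rows = nrow(analysis$drugs),
                           reaction_rows = nrow(analysis$reactions),
                           orphans = analysis$orphans), t0)

  # -- map ---------------------------------------------------------------
  t0 <- Sys.time()
  mapped <- run_stage("map", map_drugs(analysis$drugs, config$rules))
  note(write_tsv_plain(mapped, file.path(out_dir, "mapped_drugs.tsv")))
  log_stage("map", list(mapped_pairs = nrow(mapped),
                        drugs = length(unique(mapped$drug))), t0)

  # -- signals -----------------------------------------------------------
  t0 <- Sys.time()
  signals <- run_stage("signals", {
    pr <- list(drug_pairs = mapped, event_pairs = analysis$reactions,
               n_reports = analysis$n_reports)
    signal_table(pr, comparator = config$comparator,
                 alpha = config$alpha, level = config$level)
  })
  note(write_signal_table(signals, file.path(out_dir, "signals.tsv")))
  log_stage("signals", list(pairs = nrow(signals),
                            significant = sum(signals$significant)), t0)

  # -- summarize ---------------------------------------------------------
  t0 <- Sys.time()
  sm <- run_stage("summarize", assemble_signal_matrix(signals))
  note(write_tsv_plain(event_summary(sm),
                       file.path(out_dir, "event_summary.tsv")))
  note(write_signal_matrix(sm, file.path(out_dir, "lnror_matrix.tsv")))
  log_stage("summarize", list(drugs = length(sm$drugs),
                              events = length(sm$events)), t0)

  # -- filter ------------------------------------------------------------
  t0 <- Sys.time()
  fm <- run_stage("filter", filter_events(sm, config$filter))
  note(write_signal_matrix(fm, file.path(out_dir, "lnror_matrix_filtered.tsv")))
  log_stage("filter", as.list(attr(fm, "stage_counts")), t0)

  # -- cluster -----------------------------------------------------------
  t0 <- Sys.time()
  cl <- run_stage("cluster",
                  two_way_cluster(fm, k_drugs = config$k_drugs,
                                  k_events = config$k_events))
  note(write_linkage(cl$drug_tree, file.path(out_dir, "drug_linkage.tsv")))
  note(write_linkage(cl$event_tree, file.path(out_dir, "event_linkage.tsv")))
  note(write_clusters(cl$drug_clusters,
                      file.path(out_dir, "drug_clusters.tsv")))
  note(write_clusters(cl$event_clusters,
                      file.path(out_dir, "event_clusters.tsv")))
  note(write_newick(cl$drug_tree, file.path(out_dir, "drug_dendrogram.nwk")))
  note(write_newick(cl$event_tree, file.path(out_dir, "event_dendrogram.nwk")))
  note(write_tsv_plain(
    cbind(tibble(drug = rownames(cl$matrix)), as.data.frame(cl$matrix)),
    file.path(out_dir, "lnror_matrix_reordered.tsv")))
  log_stage("cluster", list(
    drug_clusters = cl$drug_clusters$k,
    event_clusters = cl$event_clusters$k), t0)

  manifest$outputs <- as.list(written)
  manifest$config <- list(
    comparator = config$comparator, alpha = config$alpha,
    level = config$level,
    min_event_reports = config$filter$min_event_reports,
    require_positive_mean = config$filter$require_positive_mean,
    top_n = config$filter$top_n %||% "none",
    k_drugs = config$k_drugs, k_events = config$k_events,
    roles = config$roles,
    seed = if (inherits(config$input, "synthetic_config"))
      config$input$seed else "none"
  )
  manifest$seconds_total <- round(
    as.numeric(difftime(Sys.time(), t0_all, units = "secs")), 2)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}
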