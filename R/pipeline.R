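#' Assemble a pipeline configuration
#'
#' Either `simulate` (a list of [synthetic_scenario()] arguments) or
#' `inputs` (paths: `gtf`, `transcript_fpkm`, `exon_counts`,
#' `library_sizes`, `metadata`, optionally `intron_counts`,
#' `junction_counts`) must be supplied; a YAML file with the same structure
#' is accepted via `pipeline_config_from_yaml()`.
#'
#' @param simulate List of scenario arguments, or `NULL`.
#' @param inputs Named list of input paths, or `NULL`.
#' @param noiseless Passed to [simulate_dataset()] when simulating.
#' @param gene_expressed_min Gene-expression gate in FPKM.
#' @param sweep_thresholds FPKM thresholds for [threshold_sweep()].
#' @param folds Dominance fold thresholds.
#' @param strong_hi,strong_lo Strong-switch FPKM bounds.
#' @param min_tx_len Study-set transcript length filter (nt).
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param seed Seed used when simulating (overrides the scenario's).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = NULL, inputs = NULL,
                            noiseless = TRUE,
                            gene_expressed_min = 1,
                            sweep_thresholds = c(1, 5, 10),
                            folds = c(2, 5),
                            strong_hi = 5, strong_lo = 1,
                            min_tx_len = 300,
                            out_dir = NULL, seed = NULL) {
  if (is.null(simulate) == is.null(inputs)) {
    stop("exactly one of `simulate` or `inputs` must be given",
         call. = FALSE)
  }
  stopifnot(gene_expressed_min >= 0, all(folds > 1),
            strong_hi > 0, strong_lo > 0)
  structure(as.list(environment()), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file mirroring the `pipeline_config()` arguments.
#' @export
pipeline_config_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

load_pipeline_inputs <- function(config) {
  if (!is.null(config$simulate)) {
    args <- config$simulate
    if (!is.null(config$seed)) args$seed <- config$seed
    ds <- simulate_dataset(do.call(synthetic_scenario, args),
                           noiseless = config$noiseless)
    return(list(annotation = ds$annotation, tx_fpkm = ds$tx_fpkm,
                exon = ds$counts$exon, intron = ds$counts$intron,
                junction = ds$counts$junction,
                library_sizes = ds$counts$library_sizes,
                metadata = ds$metadata, dataset = ds))
  }
  inp <- config$inputs
  need <- c("gtf", "transcript_fpkm", "exon_counts", "library_sizes",
            "metadata")
  missing <- setdiff(need, names(inp))
  if (length(missing)) {
    stop("missing input path(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (p in unlist(inp)) {
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  }
  annotation <- read_gtf(inp$gtf)
  tx_wide <- readr::read_tsv(inp$transcript_fpkm, show_col_types = FALSE)
  id_col <- intersect(c("transcript_id", "feature_id"), names(tx_wide))[1L]
  tx_fpkm <- tidyr::pivot_longer(tx_wide, -dplyr::all_of(id_col),
                                 names_to = "sample_id",
                                 values_to = "fpkm") |>
    dplyr::rename(transcript_id = dplyr::all_of(id_col))
  metadata <- read_metadata(inp$metadata)
  library_sizes <- readr::read_tsv(inp$library_sizes, show_col_types = FALSE)
  mismatch <- setdiff(unique(tx_fpkm$sample_id), metadata$sample_id)
  if (length(mismatch)) {
    stop("sample(s) absent from metadata: ",
         paste(mismatch, collapse = ", "), call. = FALSE)
  }
  read_ct <- function(p, annotation) {
    if (is.null(p)) return(NULL)
    ct <- read_count_table(p)
    ct$feature_genes <- tibble::tibble(
      feature_id = ct$lengths$feature_id,
      gene_id = sub(":.*$", "", ct$lengths$feature_id))
    ct
  }
  exon <- read_ct(inp$exon_counts, annotation)
  intron <- read_ct(inp$intron_counts, annotation)
  junction <- if (is.null(inp$junction_counts)) NULL else
    read_count_table(inp$junction_counts)
  list(annotation = annotation, tx_fpkm = tx_fpkm, exon = exon,
       intron = intron, junction = junction,
       library_sizes = library_sizes, metadata = metadata, dataset = NULL)
}

#' Run the dominant-transcript pipeline end to end
#'
#' Study-set construction, exon-based gene expression, major/dominance
#' calls, pool fractions, threshold sweep, recurrence, pairwise switch
#' scans, biotype/retained-intron analysis and (when junction counts are
#' available) junction-based validation, with all per-module tables and a
#' machine-readable summary collected in one report object. When
#' `config$out_dir` is set, TSV/JSON outputs are written with stable
#' ordering and 6-significant-digit floats, so re-runs on the same inputs
#' are byte-identical.
#'
#' @param config A `pipeline_config` (or a YAML path).
#' @return A `txdom_report` object.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- pipeline_config_from_yaml(config)
  stopifnot(inherits(config, "pipeline_config"))
  inp <- load_pipeline_inputs(config)

  study <- build_study_set(inp$annotation, min_tx_len = config$min_tx_len)
  tx_fpkm <- dplyr::filter(inp$tx_fpkm,
                           .data$transcript_id %in%
                             study$transcripts$transcript_id)

  exon_map <- dplyr::filter(inp$exon$feature_genes,
                            .data$gene_id %in% study$genes$gene_id)
  exon_counts <- dplyr::filter(inp$exon$counts,
                               .data$feature_id %in% exon_map$feature_id)
  exon_fpkm <- counts_to_fpkm(exon_counts, inp$exon$lengths,
                              inp$library_sizes)
  gene_fpkm <- gene_expression_from_exons(exon_fpkm, exon_map)

  calls <- call_major(tx_fpkm, gene_fpkm, study,
                      gene_expressed_min = config$gene_expressed_min)
  rel_abund <- relative_abundances(tx_fpkm, study)
  rank_profile <- rank_abundance_profile(rel_abund)
  pool <- pool_fractions(tx_fpkm, calls, study, folds = config$folds)
  tpg <- transcripts_per_gene_ratio(tx_fpkm, gene_fpkm,
                                    min_fpkm = config$gene_expressed_min)
  sweep <- threshold_sweep(tx_fpkm, gene_fpkm, study,
                           thresholds = config$sweep_thresholds,
                           folds = config$folds)
  recurrence <- recurrence_summary(calls)
  longest <- longest_overlap_stats(calls, study)

  scans <- if (dplyr::n_distinct(calls$sample_id) >= 2L) {
    stats::setNames(lapply(config$folds, function(x) {
      pairwise_switch_scan(tx_fpkm, gene_fpkm, calls, x = x,
                           metadata = inp$metadata,
                           strong_hi = config$strong_hi,
                           strong_lo = config$strong_lo,
                           gene_expressed_min = config$gene_expressed_min)
    }), sprintf("x%g", config$folds))
  } else list()

  biotype <- major_biotype_summary(calls, study, tx_fpkm)
  noncoding <- noncoding_major_summary(biotype)
  ri_positions <- retained_intron_positions(calls, study)
  compartments <- if (any(!is.na(inp$metadata$compartment))) {
    compartment_contrast(biotype, inp$metadata, gene_fpkm, calls, study)
  } else NULL

  junction_evidence <- NULL
  junction_agreement <- NA_real_
  if (!is.null(inp$junction)) {
    support <- junction_support(inp$junction$counts, study)
    junction_evidence <- junction_major(support)
    cmp <- calls |>
      dplyr::filter(!is.na(.data$major)) |>
      dplyr::inner_join(junction_evidence, by = c("gene_id", "sample_id")) |>
      dplyr::filter(!is.na(.data$evidence_major))
    if (nrow(cmp) > 0) {
      junction_agreement <- mean(cmp$major == cmp$evidence_major)
    }
  }

  summary <- list(
    n_study_genes = nrow(study$genes),
    n_study_transcripts = nrow(study$transcripts),
    pool_fractions = pool,
    mean_fraction_major = mean(pool$fraction_major),
    transcripts_per_gene = tpg,
    mean_transcripts_per_gene_ratio = mean(tpg$ratio, na.rm = TRUE),
    threshold_sweep = sweep,
    pct_recurrent = if (nrow(recurrence)) 100 * mean(recurrence$recurrent)
                    else NA_real_,
    pct_recurrent_ubiquitous = if (any(recurrence$ubiquitous))
      100 * mean(recurrence$recurrent[recurrence$ubiquitous]) else NA_real_,
    switch_genes = purrr::map_dfr(scans, glance),
    mean_fraction_noncoding_major_pool =
      mean(noncoding$fraction_noncoding_pool),
    median_ri_position = if (nrow(ri_positions))
      stats::median(ri_positions$rel_pos) else NA_real_,
    junction_agreement = junction_agreement)

  report <- structure(list(
    config = config, annotation = study, gene_fpkm = gene_fpkm,
    tx_fpkm = tx_fpkm, calls = calls, rel_abund = rel_abund,
    rank_profile = rank_profile, pool = pool, tpg = tpg, sweep = sweep,
    recurrence = recurrence, longest = longest, scans = scans,
    biotype = biotype, noncoding = noncoding,
    ri_positions = ri_positions, compartments = compartments,
    junction_evidence = junction_evidence, metadata = inp$metadata,
    dataset = inp$dataset, summary = summary), class = "txdom_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

round6 <- function(x) {
  if (is.data.frame(x)) {
    x[] <- lapply(x, round6)
    return(x)
  }
  if (is.numeric(x)) signif(x, 6) else x
}

write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(tbl, name) {
    readr::write_tsv(round6(tbl), file.path(dir, name))
  }
  w(dplyr::arrange(report$calls, .data$sample_id, .data$gene_id),
    "dominance_calls.tsv")
  w(report$sweep, "threshold_sweep.tsv")
  w(dplyr::arrange(report$recurrence, .data$gene_id), "recurrence.tsv")
  w(report$biotype, "biotype_summary.tsv")
  if (nrow(report$ri_positions)) {
    w(dplyr::arrange(report$ri_positions, .data$gene_id, .data$sample_id),
      "retained_intron_positions.tsv")
  }
  events <- purrr::map_dfr(report$scans, ~ .x$events)
  if (nrow(events)) {
    w(dplyr::arrange(events, .data$x, .data$sample_a, .data$sample_b,
                     .data$gene_id), "switch_events.tsv")
  }
  jsonlite::write_json(round6(report$pool), file.path(dir,
                                                      "pool_fractions.json"),
                       dataframe = "rows", digits = NA)
  jsonlite::write_json(round6(report$summary), file.path(dir,
                                                         "summary.json"),
                       dataframe = "rows", digits = NA, auto_unbox = TRUE,
                       na = "null")
  invisible(dir)
}

#' @export
print.txdom_report <- function(x, ...) {
  cat("<txdom_report> ", nrow(x$annotation$genes), " study genes, ",
      dplyr::n_distinct(x$calls$sample_id), " samples\n", sep = "")
  cat("  mean major pool fraction:",
      sprintf("%.3f", x$summary$mean_fraction_major), "\n")
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `txdom_report`.
#' @param ... Unused.
#' @export
tidy.txdom_report <- function(x, ...) x$calls

#' @rdname run_pipeline
#' @export
glance.txdom_report <- function(x, ...) {
  dom <- x$sweep[x$sweep$threshold == x$config$gene_expressed_min, ]
  tibble::tibble(
    n_study_genes = x$summary$n_study_genes,
    n_samples = dplyr::n_distinct(x$calls$sample_id),
    mean_fraction_major = x$summary$mean_fraction_major,
    mean_transcripts_per_gene_ratio =
      x$summary$mean_transcripts_per_gene_ratio,
    mean_pct_dominant_2x = mean(dom$pct_dominant_2x, na.rm = TRUE),
    pct_recurrent = x$summary$pct_recurrent,
    mean_fraction_noncoding_major_pool =
      x$summary$mean_fraction_noncoding_major_pool,
    junction_agreement = x$summary$junction_agreement)
}

#' Validate a pipeline report against generator ground truth
#'
#' Computes major-call accuracy (expressed multi-transcript genes),
#' dominance-class confusion counts, planted-switch recall and gene-level
#' strong-switch precision, and junction-vs-quantifier agreement.
#'
#' @param report A `txdom_report` from a simulated run (or any report, with
#'   `truth` supplied explicitly).
#' @param truth A `synthetic_dataset`'s `truth` list; defaults to the one
#'   attached to the report.
#' @return List with `metrics` (one-row tibble) and
#'   `dominance_confusion` (contingency tibble).
#' @export
validate_against_truth <- function(report, truth = NULL) {
  truth <- truth %||% report$dataset$truth
  if (is.null(truth)) stop("no ground truth available", call. = FALSE)
  cmp <- report$calls |>
    dplyr::filter(!is.na(.data$major), .data$n_transcripts > 1L) |>
    dplyr::inner_join(truth$majors, by = c("gene_id", "sample_id"))
  accuracy <- mean(cmp$major == cmp$true_major)
  confusion <- cmp |>
    dplyr::count(true_dominant_2x = .data$true_fold >= 2,
                 called_dominant_2x = is_dominant(.data$fold_ratio, 2))

  reg <- truth$switches
  recall <- NA_real_
  precision <- NA_real_
  if (nrow(reg) > 0 && length(report$scans) > 0) {
    events <- purrr::map_dfr(report$scans, ~ .x$events) |>
      dplyr::filter(.data$strong)
    key <- function(g, t1, t2, s1, s2) {
      paste(g, pmin(t1, t2), pmax(t1, t2), pmin(s1, s2), pmax(s1, s2))
    }
    found <- key(events$gene_id, events$tx_a, events$tx_b,
                 events$sample_a, events$sample_b)
    planted <- key(reg$gene_id, reg$tx_a, reg$tx_b, reg$sample_a,
                   reg$sample_b)
    recall <- mean(planted %in% found)
    precision <- if (nrow(events)) {
      mean(unique(events$gene_id) %in% reg$gene_id)
    } else NA_real_
  }
  list(metrics = tibble::tibble(
         major_accuracy = accuracy,
         n_compared = nrow(cmp),
         switch_recall = recall,
         strong_switch_gene_precision = precision,
         junction_agreement = report$summary$junction_agreement),
       dominance_confusion = confusion)
}
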