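#' Call the major transcript of each expressed gene
#'
#' The major transcript of a gene in a sample is its highest-FPKM
#' transcript. A gene is considered only when its exon-based expression
#' exceeds `gene_expressed_min` (default 1 FPKM, the conventional minimum
#' for protein detectability); given that the gene is expressed, transcripts
#' are ranked regardless of their own level. FPKM ties for the top rank are
#' broken lexicographically by transcript id and flagged. The fold ratio is
#' expression(major)/expression(runner-up), `Inf` when the runner-up is
#' silent or absent (a single expressed isoform is maximally dominant).
#'
#' @param tx_fpkm Long tibble `transcript_id`, `sample_id`, `fpkm`.
#' @param gene_fpkm Long tibble `gene_id`, `sample_id`, `fpkm`
#'   (exon-based gene expression, see [gene_expression_from_exons()]).
#' @param annotation A `tx_annotation`.
#' @param gene_expressed_min Strict FPKM threshold on gene expression.
#' @return Tibble with one row per expressed gene x sample: `gene_id`,
#'   `sample_id`, `major`, `runner_up`, `major_fpkm`, `runner_up_fpkm`,
#'   `gene_fpkm`, `fold_ratio`, `tie`, `no_call` (gene expressed but every
#'   transcript at 0; `major` is `NA` there), `n_transcripts`.
#' @export
call_major <- function(tx_fpkm, gene_fpkm, annotation,
                       gene_expressed_min = 1) {
  stopifnot(inherits(annotation, "tx_annotation"))
  expressed <- dplyr::filter(gene_fpkm, .data$fpkm > gene_expressed_min) |>
    dplyr::select("gene_id", "sample_id", gene_fpkm = "fpkm")
  tx2gene <- dplyr::select(annotation$transcripts, "transcript_id", "gene_id")
  n_tx <- dplyr::count(tx2gene, .data$gene_id, name = "n_transcripts")

  tx_fpkm |>
    dplyr::inner_join(tx2gene, by = "transcript_id") |>
    dplyr::inner_join(expressed, by = c("gene_id", "sample_id")) |>
    dplyr::arrange(.data$gene_id, .data$sample_id, dplyr::desc(.data$fpkm),
                   .data$transcript_id) |>
    dplyr::group_by(.data$gene_id, .data$sample_id) |>
    dplyr::summarise(
      gene_fpkm = .data$gene_fpkm[1L],
      major = .data$transcript_id[1L],
      major_fpkm = .data$fpkm[1L],
      runner_up = dplyr::nth(.data$transcript_id, 2L,
                             default = NA_character_),
      runner_up_fpkm = dplyr::nth(.data$fpkm, 2L, default = NA_real_),
      .groups = "drop") |>
    dplyr::mutate(
      no_call = .data$major_fpkm == 0,
      major = dplyr::if_else(.data$no_call, NA_character_, .data$major),
      tie = !.data$no_call & !is.na(.data$runner_up_fpkm) &
        .data$major_fpkm == .data$runner_up_fpkm,
      fold_ratio = dplyr::case_when(
        no_call ~ NA_real_,
        is.na(runner_up_fpkm) | runner_up_fpkm == 0 ~ Inf,
        TRUE ~ major_fpkm / runner_up_fpkm)) |>
    dplyr::left_join(n_tx, by = "gene_id") |>
    dplyr::select("gene_id", "sample_id", "major", "runner_up",
                  "major_fpkm", "runner_up_fpkm", "gene_fpkm", "fold_ratio",
                  "tie", "no_call", "n_transcripts")
}

#' x-fold dominance of a major transcript
#'
#' A major transcript is x-fold dominant when it is expressed at least x
#' times as much as the second most abundant transcript of the gene
#' (`fold_ratio >= x`); an infinite ratio is dominant at every x.
#'
#' @param fold_ratio Numeric vector of fold ratios (see [call_major()]).
#' @param x Fold threshold, > 1 (typically 2 or 5).
#' @return Logical vector (`NA` where `fold_ratio` is `NA`).
#' @export
is_dominant <- function(fold_ratio, x) {
  stopifnot(is.numeric(x), length(x) == 1L, x > 1)
  fold_ratio >= x
}

#' mRNA-pool mass explained by major and dominant transcripts
#'
#' Per sample, the FPKM-mass share of major transcripts (and of the x-fold
#' dominant subsets, and of non-coding majors) among all transcripts of the
#' study set. Mitochondrial genes are excluded from numerator and
#' denominator: present in many copies per cell, they would otherwise
#' swamp the pool.
#'
#' @param tx_fpkm Long tibble `transcript_id`, `sample_id`, `fpkm`
#'   (the study-set transcripts).
#' @param calls Output of [call_major()].
#' @param annotation A `tx_annotation`.
#' @param folds Fold thresholds for the dominant subsets.
#' @return Tibble per sample: `sample_id`, `fraction_major`,
#'   `fraction_dominant_<x>x` for each fold, `fraction_noncoding_major`.
#' @export
pool_fractions <- function(tx_fpkm, calls, annotation, folds = c(2, 5)) {
  stopifnot(inherits(annotation, "tx_annotation"))
  mito <- annotation$genes$gene_id[annotation$genes$is_mito]
  tx2gene <- dplyr::select(annotation$transcripts, "transcript_id", "gene_id",
                           "cds_length")
  pool <- tx_fpkm |>
    dplyr::inner_join(tx2gene, by = "transcript_id") |>
    dplyr::filter(!.data$gene_id %in% mito)
  denom <- pool |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(total = sum(.data$fpkm), .groups = "drop")
  if (any(denom$total == 0)) {
    stop("zero total transcript FPKM in sample(s): ",
         paste(denom$sample_id[denom$total == 0], collapse = ", "),
         call. = FALSE)
  }
  mcalls <- calls |>
    dplyr::filter(!is.na(.data$major), !.data$gene_id %in% mito) |>
    dplyr::left_join(dplyr::select(tx2gene, "transcript_id", "cds_length"),
                     by = c(major = "transcript_id"))
  num <- mcalls |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(fraction_major = sum(.data$major_fpkm),
                     fraction_noncoding_major =
                       sum(.data$major_fpkm[.data$cds_length == 0]),
                     .groups = "drop")
  for (x in folds) {
    fx <- mcalls |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::summarise(v = sum(.data$major_fpkm[is_dominant(.data$fold_ratio,
                                                            x)]),
                       .groups = "drop")
    names(fx)[2L] <- sprintf("fraction_dominant_%gx", x)
    num <- dplyr::left_join(num, fx, by = "sample_id")
  }
  out <- dplyr::left_join(denom, num, by = "sample_id") |>
    dplyr::mutate(dplyr::across(dplyr::starts_with("fraction"),
                                ~ dplyr::coalesce(.x, 0) / .data$total)) |>
    dplyr::select(-"total") |>
    dplyr::relocate("fraction_noncoding_major", .after = dplyr::last_col())
  check_pool_ordering(out, folds)
  out
}

# type invariant: 0 <= f5 <= f2 <= major <= 1 (numerical slack only)
check_pool_ordering <- function(pf, folds) {
  eps <- 1e-9
  prev <- pf$fraction_major
  stopifnot(all(prev <= 1 + eps), all(prev >= -eps))
  for (x in sort(folds)) {
    cur <- pf[[sprintf("fraction_dominant_%gx", x)]]
    stopifnot(all(cur <= prev + eps))
    prev <- cur
  }
  invisible(pf)
}

#' Ratio of expressed transcripts to expressed genes
#'
#' Counts transcripts with FPKM above `min_fpkm` and genes with exon-based
#' FPKM above the same threshold, per sample. The ratio can fall below 1
#' because gene expression is estimated from exons, not from transcript
#' sums.
#'
#' @inheritParams call_major
#' @param min_fpkm Strict FPKM threshold for both counts.
#' @return Tibble `sample_id`, `n_transcripts`, `n_genes`, `ratio` (`NA`
#'   with a warning when no gene is expressed).
#' @export
transcripts_per_gene_ratio <- function(tx_fpkm, gene_fpkm, min_fpkm = 1) {
  tx <- tx_fpkm |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(n_transcripts = sum(.data$fpkm > min_fpkm),
                     .groups = "drop")
  gn <- gene_fpkm |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(n_genes = sum(.data$fpkm > min_fpkm), .groups = "drop")
  out <- dplyr::full_join(tx, gn, by = "sample_id") |>
    dplyr::mutate(ratio = dplyr::if_else(.data$n_genes > 0,
                                         .data$n_transcripts / .data$n_genes,
                                         NA_real_))
  if (any(is.na(out$ratio))) {
    warning("sample(s) with no expressed gene: ratio undefined",
            call. = FALSE)
  }
  out
}

#' Dominance summary across gene-expression thresholds
#'
#' For each threshold, counts expressed genes (exon-based gene FPKM strictly
#' above the threshold), their percentage of the study set, and the count
#' and percentage (among expressed genes) of majors that are x-fold dominant
#' at each fold. Counts are non-increasing in the threshold and the dominant
#' subsets are nested.
#'
#' @inheritParams call_major
#' @param thresholds Ascending FPKM thresholds (default 1, 5, 10).
#' @param folds Fold thresholds for dominance (default 2, 5).
#' @param study_set_size Denominator for `pct_study_set`; defaults to the
#'   number of genes in `annotation`.
#' @return Tibble, one row per sample x threshold.
#' @export
threshold_sweep <- function(tx_fpkm, gene_fpkm, annotation,
                            thresholds = c(1, 5, 10), folds = c(2, 5),
                            study_set_size = NULL) {
  stopifnot(!is.unsorted(thresholds))
  if (is.null(study_set_size)) study_set_size <- nrow(annotation$genes)
  purrr::map_dfr(thresholds, function(thr) {
    calls <- call_major(tx_fpkm, gene_fpkm, annotation,
                        gene_expressed_min = thr)
    base <- gene_fpkm |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::summarise(n_expressed = sum(.data$fpkm > thr), .groups = "drop") |>
      dplyr::mutate(threshold = thr,
                    pct_study_set = 100 * .data$n_expressed / study_set_size)
    for (x in folds) {
      dom <- calls |>
        dplyr::filter(!is.na(.data$major)) |>
        dplyr::group_by(.data$sample_id) |>
        dplyr::summarise(n = sum(is_dominant(.data$fold_ratio, x)),
                         .groups = "drop")
      base <- base |>
        dplyr::left_join(dom, by = "sample_id") |>
        dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
      base[[sprintf("pct_dominant_%gx", x)]] <-
        ifelse(base$n_expressed > 0, 100 * base$n / base$n_expressed, NA_real_)
      names(base)[names(base) == "n"] <- sprintf("n_dominant_%gx", x)
    }
    dplyr::relocate(base, "threshold", "sample_id")
  })
}

#' Rank-abundance profile of transcripts within genes
#'
#' Transcripts of each gene-sample are ranked by relative abundance
#' (descending, ties broken by transcript id); for each rank the
#' distribution of fractions over gene-samples is summarised by quartiles.
#'
#' @param rel_abund Output of [relative_abundances()].
#' @param max_rank Highest rank to report (default: all).
#' @return Tibble `rank`, `n`, `q25`, `median`, `q75`, `mean`.
#' @export
rank_abundance_profile <- function(rel_abund, max_rank = Inf) {
  rel_abund |>
    dplyr::filter(!.data$zero_gene) |>
    dplyr::arrange(.data$gene_id, .data$sample_id,
                   dplyr::desc(.data$fraction), .data$transcript_id) |>
    dplyr::group_by(.data$gene_id, .data$sample_id) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$rank <= max_rank) |>
    dplyr::group_by(.data$rank) |>
    dplyr::summarise(n = dplyr::n(),
                     q25 = stats::quantile(.data$fraction, 0.25),
                     median = stats::median(.data$fraction),
                     q75 = stats::quantile(.data$fraction, 0.75),
                     mean = mean(.data$fraction),
                     .groups = "drop")
}

#' Dominance within transcription-start-site groups
#'
#' Applies the major/dominance logic of [call_major()] with the gene's
#' transcript set replaced by each multi-transcript TSS group - a scenario
#' where all compared transcripts are under similar transcriptional control,
#' so abundance differences are attributable to splicing. Singleton groups
#' are excluded.
#'
#' @inheritParams call_major
#' @return Tibble `gene_id`, `tss_group`, `sample_id`, `major`,
#'   `major_fpkm`, `runner_up_fpkm`, `fold_ratio`, `tie`, `group_size`.
#' @export
tss_group_dominance <- function(tx_fpkm, gene_fpkm, annotation,
                                gene_expressed_min = 1) {
  groups <- tss_groups(annotation) |>
    dplyr::filter(.data$group_size > 1L)
  if (nrow(groups) == 0L) {
    return(tibble::tibble(gene_id = character(), tss_group = integer(),
                          sample_id = character(), major = character(),
                          major_fpkm = double(), runner_up_fpkm = double(),
                          fold_ratio = double(), tie = logical(),
                          group_size = integer()))
  }
  expressed <- dplyr::filter(gene_fpkm, .data$fpkm > gene_expressed_min) |>
    dplyr::select("gene_id", "sample_id")
  tx_fpkm |>
    dplyr::inner_join(groups, by = "transcript_id") |>
    dplyr::inner_join(expressed, by = c("gene_id", "sample_id")) |>
    dplyr::arrange(.data$gene_id, .data$tss_group, .data$sample_id,
                   dplyr::desc(.data$fpkm), .data$transcript_id) |>
    dplyr::group_by(.data$gene_id, .data$tss_group, .data$sample_id) |>
    dplyr::summarise(
      major = .data$transcript_id[1L],
      major_fpkm = .data$fpkm[1L],
      runner_up_fpkm = .data$fpkm[2L],
      group_size = dplyr::n(),
      .groups = "drop") |>
    dplyr::mutate(
      tie = .data$major_fpkm == .data$runner_up_fpkm,
      fold_ratio = dplyr::if_else(.data$runner_up_fpkm == 0, Inf,
                                  .data$major_fpkm / .data$runner_up_fpkm))
}

#' Do major transcripts coincide with the longest annotated ones?
#'
#' Among genes with a major call and more than one annotated transcript,
#' the per-sample fraction of majors that are the gene's longest transcript,
#' and the fraction carrying the gene's longest CDS.
#'
#' @param calls Output of [call_major()].
#' @param annotation A `tx_annotation`.
#' @return Tibble `sample_id`, `n_genes`, `frac_major_longest`,
#'   `frac_major_longest_cds`.
#' @export
longest_overlap_stats <- function(calls, annotation) {
  flags <- length_flags(annotation)
  calls |>
    dplyr::filter(!is.na(.data$major), .data$n_transcripts > 1L) |>
    dplyr::inner_join(dplyr::select(flags, "transcript_id",
                                    "is_longest_transcript",
                                    "has_longest_cds"),
                      by = c(major = "transcript_id")) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(n_genes = dplyr::n(),
                     frac_major_longest = mean(.data$is_longest_transcript),
                     frac_major_longest_cds = mean(.data$has_longest_cds),
                     .groups = "drop")
}
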