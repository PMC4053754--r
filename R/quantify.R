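#' Read a feature-by-sample count table
#'
#' Expects the layout `feature_id`, `length`, then one column per sample.
#'
#' @param path TSV file path.
#' @return List with `counts` (long tibble: `feature_id`, `sample_id`,
#'   `count`) and `lengths` (`feature_id`, `length`).
#' @export
read_count_table <- function(path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("feature_id", "length") %in% names(wide)))
  counts <- tidyr::pivot_longer(wide, -c("feature_id", "length"),
                                names_to = "sample_id", values_to = "count") |>
    dplyr::select("feature_id", "sample_id", "count")
  list(counts = counts,
       lengths = dplyr::select(wide, "feature_id", "length"))
}

#' Read a sample metadata table
#'
#' @param path TSV with columns `sample_id`, `condition`, `compartment`,
#'   `replicate`.
#' @return Tibble.
#' @export
read_metadata <- function(path) {
  md <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("sample_id", "condition") %in% names(md)))
  if (anyDuplicated(md$sample_id)) stop("duplicate sample_id in metadata",
                                        call. = FALSE)
  md
}

#' Convert read counts to FPKM
#'
#' FPKM = count x 10^9 / (feature length in nt x library size in mapped
#' reads). Linear in counts: doubling a count doubles its FPKM, doubling the
#' library size halves it.
#'
#' @param counts Long tibble `feature_id`, `sample_id`, `count`.
#' @param lengths Tibble `feature_id`, `length` (nt, one per feature).
#' @param library_sizes Tibble `sample_id`, `library_size` (> 0).
#' @return Long tibble `feature_id`, `sample_id`, `fpkm`.
#' @export
counts_to_fpkm <- function(counts, lengths, library_sizes) {
  stopifnot(all(c("feature_id", "sample_id", "count") %in% names(counts)),
            all(c("feature_id", "length") %in% names(lengths)),
            all(c("sample_id", "library_size") %in% names(library_sizes)))
  if (any(lengths$length <= 0)) {
    stop("non-positive length for feature(s): ",
         paste(utils::head(lengths$feature_id[lengths$length <= 0], 5L),
               collapse = ", "), call. = FALSE)
  }
  if (any(library_sizes$library_size <= 0)) {
    stop("library sizes must be positive", call. = FALSE)
  }
  missing_len <- setdiff(counts$feature_id, lengths$feature_id)
  if (length(missing_len)) {
    stop("no length for feature(s): ",
         paste(utils::head(missing_len, 5L), collapse = ", "), call. = FALSE)
  }
  counts |>
    dplyr::inner_join(lengths, by = "feature_id") |>
    dplyr::inner_join(library_sizes, by = "sample_id") |>
    dplyr::mutate(fpkm = .data$count * 1e9 /
                    (.data$length * .data$library_size)) |>
    dplyr::select("feature_id", "sample_id", "fpkm")
}

#' Gene expression as the mean FPKM of expressed exons
#'
#' A gene's expression in a sample is the average FPKM over its exonic
#' features whose FPKM exceeds `expressed_exon_min` (default 0, i.e. any
#' non-zero exon counts as expressed). Genes with no expressed exon get 0.
#' The estimate is invariant to exon ordering and to splitting an exon into
#' adjacent pieces of equal FPKM.
#'
#' @param exon_fpkm Long tibble `feature_id`, `sample_id`, `fpkm`.
#' @param feature_genes Tibble `feature_id`, `gene_id` mapping exonic
#'   features to genes; every feature in `exon_fpkm` must be mapped.
#' @param expressed_exon_min FPKM threshold (strict) for an exon to count as
#'   expressed.
#' @return Long tibble `gene_id`, `sample_id`, `fpkm` covering every
#'   mapped gene x sample combination.
#' @export
gene_expression_from_exons <- function(exon_fpkm, feature_genes,
                                       expressed_exon_min = 0) {
  unmapped <- setdiff(exon_fpkm$feature_id, feature_genes$feature_id)
  if (length(unmapped)) {
    stop("exonic feature(s) mapped to no gene: ",
         paste(utils::head(unmapped, 5L), collapse = ", "), call. = FALSE)
  }
  exon_fpkm |>
    dplyr::inner_join(feature_genes, by = "feature_id") |>
    dplyr::group_by(.data$gene_id, .data$sample_id) |>
    dplyr::summarise(
      fpkm = ifelse(any(.data$fpkm > expressed_exon_min),
                    mean(.data$fpkm[.data$fpkm > expressed_exon_min]), 0),
      .groups = "drop") |>
    tidyr::complete(gene_id = unique(feature_genes$gene_id),
                    sample_id = unique(exon_fpkm$sample_id),
                    fill = list(fpkm = 0))
}

#' Per-gene relative transcript abundances
#'
#' Each transcript's fraction of its gene's summed transcript FPKM, per
#' sample. Gene-samples with zero total are flagged (`zero_gene`) and their
#' fractions set to `NA`.
#'
#' @param tx_fpkm Long tibble `transcript_id`, `sample_id`, `fpkm`.
#' @param annotation A `tx_annotation` mapping transcripts to genes; every
#'   transcript in `tx_fpkm` must be annotated.
#' @return Tibble `gene_id`, `transcript_id`, `sample_id`, `fpkm`,
#'   `fraction`, `zero_gene`.
#' @export
relative_abundances <- function(tx_fpkm, annotation) {
  stopifnot(inherits(annotation, "tx_annotation"))
  tx2gene <- dplyr::select(annotation$transcripts, "transcript_id", "gene_id")
  unmapped <- setdiff(tx_fpkm$transcript_id, tx2gene$transcript_id)
  if (length(unmapped)) {
    stop("transcript(s) absent from annotation: ",
         paste(utils::head(unmapped, 5L), collapse = ", "), call. = FALSE)
  }
  tx_fpkm |>
    dplyr::inner_join(tx2gene, by = "transcript_id") |>
    dplyr::group_by(.data$gene_id, .data$sample_id) |>
    dplyr::mutate(total = sum(.data$fpkm),
                  zero_gene = .data$total == 0,
                  fraction = dplyr::if_else(.data$zero_gene, NA_real_,
                                            .data$fpkm / .data$total)) |>
    dplyr::ungroup() |>
    dplyr::select("gene_id", "transcript_id", "sample_id", "fpkm",
                  "fraction", "zero_gene")
}

#' Intron expression in FPKM
#'
#' Converts intron counts to FPKM and attaches gene ids, for contrasts of
#' intronic signal (e.g. nucleus vs cytosol incomplete splicing).
#'
#' @inheritParams counts_to_fpkm
#' @param feature_genes Tibble `feature_id`, `gene_id` for intronic features.
#' @return Long tibble `feature_id`, `gene_id`, `sample_id`, `fpkm`.
#' @seealso [gene_intronic_mean()]
#' @export
intron_expression <- function(counts, lengths, library_sizes, feature_genes) {
  counts_to_fpkm(counts, lengths, library_sizes) |>
    dplyr::inner_join(feature_genes, by = "feature_id") |>
    dplyr::select("feature_id", "gene_id", "sample_id", "fpkm")
}

#' Mean intronic FPKM per gene and sample
#'
#' @param intron_fpkm Output of [intron_expression()].
#' @return Tibble `gene_id`, `sample_id`, `intron_mean_fpkm`.
#' @export
gene_intronic_mean <- function(intron_fpkm) {
  intron_fpkm |>
    dplyr::group_by(.data$gene_id, .data$sample_id) |>
    dplyr::summarise(intron_mean_fpkm = mean(.data$fpkm), .groups = "drop")
}

#' Junction-read support for each transcript
#'
#' For genes whose transcripts are all uniquely identifiable by at least one
#' splice junction, computes per-transcript support as the mean read count
#' over that transcript's unique junctions (the average is taken when a
#' transcript has several). Junction ids must encode
#' `"chrom:donor-acceptor:strand"`; ids absent from the annotation are
#' dropped with a warning, and junctions missing from a sample count as 0.
#'
#' @param junction_counts Long tibble `feature_id` (junction id),
#'   `sample_id`, `count`.
#' @param annotation A `tx_annotation`.
#' @return Tibble `gene_id`, `transcript_id`, `sample_id`, `support`,
#'   restricted to fully identifiable genes.
#' @export
junction_support <- function(junction_counts, annotation) {
  uj <- unique_junctions(annotation)
  known <- transcript_junctions(annotation)$junction
  alien <- setdiff(junction_counts$feature_id, known)
  if (length(alien)) {
    warning(length(alien), " junction id(s) not present in the annotation; ",
            "ignored", call. = FALSE)
    junction_counts <- dplyr::filter(junction_counts,
                                     .data$feature_id %in% known)
  }
  ident_genes <- uj$genes$gene_id[uj$genes$fully_identifiable]
  uniq <- dplyr::filter(uj$junctions, .data$gene_id %in% ident_genes)
  samples <- unique(junction_counts$sample_id)
  uniq |>
    dplyr::select("gene_id", "transcript_id", feature_id = "junction") |>
    tidyr::crossing(sample_id = samples) |>
    dplyr::left_join(junction_counts, by = c("feature_id", "sample_id")) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0)) |>
    dplyr::group_by(.data$gene_id, .data$transcript_id, .data$sample_id) |>
    dplyr::summarise(support = mean(.data$count), .groups = "drop")
}

#' Major transcript evidenced by junction reads
#'
#' Argmax of junction support within each gene and sample; ties produce no
#' call (flagged) so that junction-vs-quantifier agreement is conservative.
#'
#' @param support Output of [junction_support()].
#' @return Tibble `gene_id`, `sample_id`, `evidence_major` (`NA` on tie),
#'   `tie`.
#' @export
junction_major <- function(support) {
  support |>
    dplyr::group_by(.data$gene_id, .data$sample_id) |>
    dplyr::summarise(
      n_top = sum(.data$support == max(.data$support)),
      evidence_major = .data$transcript_id[which.max(.data$support)],
      .groups = "drop") |>
    dplyr::mutate(tie = .data$n_top > 1L,
                  evidence_major = dplyr::if_else(.data$tie, NA_character_,
                                                  .data$evidence_major)) |>
    dplyr::select("gene_id", "sample_id", "evidence_major", "tie")
}
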