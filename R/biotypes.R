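#' Biotype breakdown of major transcripts
#'
#' Classifies each major transcript by its annotated biotype and reports,
#' per sample, class counts and the FPKM-mass fraction of the (non-
#' mitochondrial) study-set transcript pool that each class of majors
#' explains. "Coding" is operationalised as a non-zero annotated CDS. The
#' per-class mass fractions recompose the overall major fraction of
#' [pool_fractions()].
#'
#' @param calls Output of [call_major()].
#' @param annotation A `tx_annotation`.
#' @param tx_fpkm Long tibble `transcript_id`, `sample_id`, `fpkm` (pool
#'   denominator).
#' @param classes Biotypes reported individually; anything else maps to
#'   `"other"` (with a message).
#' @return Tibble `sample_id`, `class`, `coding`, `n`, `mass_fraction`.
#' @export
major_biotype_summary <- function(calls, annotation, tx_fpkm,
                                  classes = c("protein_coding",
                                              "retained_intron",
                                              "processed_transcript",
                                              "nonsense_mediated_decay")) {
  stopifnot(inherits(annotation, "tx_annotation"))
  mito <- annotation$genes$gene_id[annotation$genes$is_mito]
  tx_info <- dplyr::select(annotation$transcripts, "transcript_id",
                           "biotype", "cds_length", tx_gene = "gene_id")
  denom <- tx_fpkm |>
    dplyr::inner_join(tx_info, by = "transcript_id") |>
    dplyr::filter(!.data$tx_gene %in% mito) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(total = sum(.data$fpkm), .groups = "drop")
  mcalls <- calls |>
    dplyr::filter(!is.na(.data$major), !.data$gene_id %in% mito) |>
    dplyr::inner_join(tx_info, by = c(major = "transcript_id"))
  unknown <- setdiff(unique(mcalls$biotype), classes)
  if (length(unknown)) {
    message("biotype(s) mapped to 'other': ",
            paste(unknown, collapse = ", "))
  }
  mcalls |>
    dplyr::mutate(class = ifelse(.data$biotype %in% classes, .data$biotype,
                                 "other"),
                  coding = .data$cds_length > 0) |>
    dplyr::group_by(.data$sample_id, .data$class, .data$coding) |>
    dplyr::summarise(n = dplyr::n(), mass = sum(.data$major_fpkm),
                     .groups = "drop") |>
    dplyr::inner_join(denom, by = "sample_id") |>
    dplyr::mutate(mass_fraction = .data$mass / .data$total) |>
    dplyr::select("sample_id", "class", "coding", "n", "mass_fraction")
}

#' Non-coding-major share per sample
#'
#' @param summary_tbl Output of [major_biotype_summary()].
#' @return Tibble `sample_id`, `n_major`, `n_noncoding_major`,
#'   `fraction_noncoding_pool` (FPKM-mass share of non-coding majors).
#' @export
noncoding_major_summary <- function(summary_tbl) {
  summary_tbl |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      n_major = sum(.data$n),
      n_noncoding_major = sum(.data$n[!.data$coding]),
      fraction_noncoding_pool = sum(.data$mass_fraction[!.data$coding]),
      .groups = "drop")
}

#' Compartment contrasts of major-transcript classes
#'
#' Averages biotype-class pool fractions per cellular compartment
#' (unweighted over the compartment's samples) and, when both nucleus and
#' cytosol are present, contrasts gene expression between compartments for
#' genes with non-coding versus coding majors (median log2 nucleus/cytosol
#' ratio over genes expressed in both).
#'
#' @param summary_tbl Output of [major_biotype_summary()].
#' @param metadata Tibble with `sample_id` and `compartment`.
#' @param gene_fpkm Optional long tibble `gene_id`, `sample_id`, `fpkm` for
#'   the expression contrast.
#' @param calls Optional [call_major()] output, needed with `gene_fpkm`:
#'   genes are classed by whether their major is non-coding in the majority
#'   of samples where called.
#' @param annotation Required with `calls` (supplies CDS lengths).
#' @return List with `compartment_summary` and (possibly `NULL`)
#'   `contrast` tibbles.
#' @export
compartment_contrast <- function(summary_tbl, metadata, gene_fpkm = NULL,
                                 calls = NULL, annotation = NULL) {
  stopifnot("compartment" %in% names(metadata))
  comp <- dplyr::select(metadata, "sample_id", "compartment")
  comp_summary <- summary_tbl |>
    dplyr::inner_join(comp, by = "sample_id") |>
    dplyr::filter(!is.na(.data$compartment)) |>
    dplyr::group_by(.data$compartment, .data$class, .data$coding) |>
    dplyr::summarise(mean_n = mean(.data$n),
                     mean_mass_fraction = mean(.data$mass_fraction),
                     .groups = "drop")
  contrast <- NULL
  have <- unique(stats::na.omit(comp$compartment))
  if (all(c("nucleus", "cytosol") %in% have) &&
      !is.null(gene_fpkm) && !is.null(calls) && !is.null(annotation)) {
    cds <- stats::setNames(annotation$transcripts$cds_length,
                           annotation$transcripts$transcript_id)
    status <- calls |>
      dplyr::filter(!is.na(.data$major)) |>
      dplyr::mutate(noncoding = unname(cds[.data$major]) == 0) |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::summarise(noncoding_major = mean(.data$noncoding) > 0.5,
                       .groups = "drop")
    by_comp <- gene_fpkm |>
      dplyr::inner_join(comp, by = "sample_id") |>
      dplyr::filter(.data$compartment %in% c("nucleus", "cytosol")) |>
      dplyr::group_by(.data$gene_id, .data$compartment) |>
      dplyr::summarise(fpkm = mean(.data$fpkm), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "compartment", values_from = "fpkm")
    contrast <- by_comp |>
      dplyr::filter(.data$nucleus > 0, .data$cytosol > 0) |>
      dplyr::inner_join(status, by = "gene_id") |>
      dplyr::group_by(.data$noncoding_major) |>
      dplyr::summarise(n_genes = dplyr::n(),
                       median_log2_nuc_vs_cyt =
                         stats::median(log2(.data$nucleus / .data$cytosol)),
                       .groups = "drop")
  } else if (!all(c("nucleus", "cytosol") %in% have)) {
    message("nucleus/cytosol contrast skipped: compartment(s) absent")
  }
  list(compartment_summary = comp_summary, contrast = contrast)
}

#' Relative positions of retained introns in major transcripts
#'
#' For genes whose major transcript has the `retained_intron` biotype,
#' locates the retained region as the overlap between that transcript's
#' exon union and the intron complement of the gene's *other* (non
#' retained-intron) transcripts, then maps the region's midpoint to a
#' strand-aware relative position on the gene span (0 = transcriptional
#' start, 1 = end). When several regions are retained, the widest is used,
#' ties resolved to the most 3' one. Majors with no identifiable retained
#' region are excluded with a message.
#'
#' @param calls Output of [call_major()].
#' @param annotation A `tx_annotation`.
#' @return Tibble `gene_id`, `sample_id`, `major`, `start`, `end`,
#'   `rel_pos`.
#' @export
retained_intron_positions <- function(calls, annotation) {
  stopifnot(inherits(annotation, "tx_annotation"))
  bio <- stats::setNames(annotation$transcripts$biotype,
                         annotation$transcripts$transcript_id)
  ri_calls <- calls |>
    dplyr::filter(!is.na(.data$major),
                  unname(bio[.data$major]) %in% "retained_intron")
  empty <- tibble::tibble(gene_id = character(), sample_id = character(),
                          major = character(), start = integer(),
                          end = integer(), rel_pos = double())
  if (nrow(ri_calls) == 0L) return(empty)
  ri_tx <- unique(ri_calls$major)
  non_ri <- annotation$transcripts |>
    dplyr::filter(!.data$biotype %in% "retained_intron")
  regions <- purrr::map_dfr(ri_tx, function(tx) {
    g <- annotation$transcripts$gene_id[
      annotation$transcripts$transcript_id == tx]
    others <- dplyr::filter(non_ri, .data$gene_id == g)
    if (nrow(others) == 0L) return(NULL)
    introns <- derive_introns(annotation,
                              transcripts = others$transcript_id)
    introns <- dplyr::filter(introns, .data$gene_id == g)
    if (nrow(introns) == 0L) return(NULL)
    ex <- dplyr::filter(annotation$exons, .data$transcript_id == tx)
    ovl <- GenomicRanges::intersect(
      GenomicRanges::reduce(gene_keyed_granges(ex)),
      gene_keyed_granges(introns))
    if (length(ovl) == 0L) return(NULL)
    w <- GenomicRanges::width(ovl)
    best <- which(w == max(w))
    strand <- annotation$genes$strand[annotation$genes$gene_id == g]
    # most 3' among maximal-width regions
    idx <- if (strand == "-") best[1L] else best[length(best)]
    tibble::tibble(major = tx, gene_id = g,
                   start = GenomicRanges::start(ovl)[idx] - 1L,
                   end = GenomicRanges::end(ovl)[idx])
  })
  dropped <- setdiff(ri_tx, regions$major)
  if (length(dropped)) {
    message(length(dropped), " retained_intron major(s) with no ",
            "identifiable retained region excluded")
  }
  if (nrow(regions) == 0L) return(empty)
  pos <- intron_relative_position(
    dplyr::mutate(regions, index = 1L), annotation)
  ri_calls |>
    dplyr::select("gene_id", "sample_id", "major") |>
    dplyr::inner_join(dplyr::select(pos, "major", "start", "end", "rel_pos"),
                      by = "major")
}

#' Summary statistics for retained-intron positions
#'
#' @param positions Output of [retained_intron_positions()].
#' @param metadata Optional tibble with `sample_id`, `compartment`; when
#'   given, the summary is additionally split by compartment.
#' @return Tibble with `n`, `q25`, `median`, `q75` (plus `compartment`).
#' @export
retained_intron_position_stats <- function(positions, metadata = NULL) {
  summarise_pos <- function(d) {
    dplyr::summarise(d, n = dplyr::n(),
                     q25 = stats::quantile(.data$rel_pos, 0.25),
                     median = stats::median(.data$rel_pos),
                     q75 = stats::quantile(.data$rel_pos, 0.75),
                     .groups = "drop")
  }
  if (is.null(metadata) || !"compartment" %in% names(metadata)) {
    return(summarise_pos(positions))
  }
  positions |>
    dplyr::inner_join(dplyr::select(metadata, "sample_id", "compartment"),
                      by = "sample_id") |>
    dplyr::group_by(.data$compartment) |>
    summarise_pos()
}
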