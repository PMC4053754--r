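#' Cross-sample recurrence of major transcripts
#'
#' A gene's major transcript is recurrent when it is the same in every
#' sample where the gene is expressed; a gene is ubiquitous when expressed
#' in all samples. Genes expressed (with a major call) in fewer than two
#' samples are excluded.
#'
#' @param calls Output of [call_major()] over all samples.
#' @param n_samples Total number of samples (defaults to the number of
#'   distinct samples in `calls`).
#' @return Tibble `gene_id`, `n_samples_expressed`, `n_distinct_majors`,
#'   `recurrent`, `ubiquitous`.
#' @export
recurrence_summary <- function(calls, n_samples = NULL) {
  if (is.null(n_samples)) n_samples <- dplyr::n_distinct(calls$sample_id)
  calls |>
    dplyr::filter(!is.na(.data$major)) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(n_samples_expressed = dplyr::n_distinct(.data$sample_id),
                     n_distinct_majors = dplyr::n_distinct(.data$major),
                     .groups = "drop") |>
    dplyr::filter(.data$n_samples_expressed >= 2L) |>
    dplyr::mutate(recurrent = .data$n_distinct_majors == 1L,
                  ubiquitous = .data$n_samples_expressed == n_samples)
}

#' Detect transcript switch events between two samples
#'
#' A gene undergoes an x-fold switch between transcripts I_k and I_l in
#' samples S_i and S_j when the gene is expressed in both samples and the
#' expression ratio I_k/I_l is at least x in S_i and at most 1/x in S_j.
#' Candidate transcript pairs are the two samples' major transcripts (the
#' cases of interest are genes with different majors in the two samples);
#' identical majors produce no event. A zero-denominator ratio with a
#' positive numerator is `Inf` (passes the >= x side, fails the <= 1/x
#' side); 0/0 produces no event.
#'
#' @param tx_fpkm Long tibble `transcript_id`, `sample_id`, `fpkm`.
#' @param calls Output of [call_major()] (provides the gene-expression gate
#'   and the majors).
#' @param sample_a,sample_b The two sample ids (S_i, S_j).
#' @param x Fold threshold, > 1.
#' @return Tibble `gene_id`, `tx_a`, `tx_b`, `sample_a`, `sample_b`, `x`,
#'   `ratio_a`, `ratio_b`.
#' @export
detect_switch_events <- function(tx_fpkm, calls, sample_a, sample_b, x = 2) {
  stopifnot(x > 1)
  ca <- dplyr::filter(calls, .data$sample_id == sample_a, !is.na(.data$major))
  cb <- dplyr::filter(calls, .data$sample_id == sample_b, !is.na(.data$major))
  cand <- dplyr::inner_join(
    dplyr::select(ca, "gene_id", tx_a = "major"),
    dplyr::select(cb, "gene_id", tx_b = "major"), by = "gene_id") |>
    dplyr::filter(.data$tx_a != .data$tx_b)
  if (nrow(cand) == 0L) {
    return(tibble::tibble(gene_id = character(), tx_a = character(),
                          tx_b = character(), sample_a = character(),
                          sample_b = character(), x = double(),
                          ratio_a = double(), ratio_b = double()))
  }
  fp <- function(tx, s) {
    lookup <- dplyr::filter(tx_fpkm, .data$sample_id == s)
    lookup$fpkm[match(tx, lookup$transcript_id)]
  }
  cand |>
    dplyr::mutate(
      ratio_a = fp(.data$tx_a, sample_a) / fp(.data$tx_b, sample_a),
      ratio_b = fp(.data$tx_a, sample_b) / fp(.data$tx_b, sample_b),
      sample_a = sample_a, sample_b = sample_b, x = x) |>
    dplyr::filter(!is.nan(.data$ratio_a), !is.nan(.data$ratio_b),
                  .data$ratio_a >= x, .data$ratio_b <= 1 / x) |>
    dplyr::select("gene_id", "tx_a", "tx_b", "sample_a", "sample_b", "x",
                  "ratio_a", "ratio_b")
}

#' Annotate switch events with strength and expression dependence
#'
#' A switch is strong when the transcript dominating each sample is at
#' least `strong_hi` FPKM there while the reciprocal transcript is strictly
#' below `strong_lo` FPKM - maximising the chance that the switch is
#' visible at the protein level. A switch is expression dependent when the
#' absolute difference in gene expression between the two samples exceeds
#' the mean of that difference over all genes expressed in both samples of
#' the pair.
#'
#' @param events Output of [detect_switch_events()] (one sample pair).
#' @param tx_fpkm Long tibble `transcript_id`, `sample_id`, `fpkm`.
#' @param gene_fpkm Long tibble `gene_id`, `sample_id`, `fpkm`.
#' @param strong_hi,strong_lo Strong-switch FPKM bounds (>= hi, < lo).
#' @param gene_expressed_min Gate defining "expressed in both samples" for
#'   the expression-dependence mean.
#' @return `events` with `strong` and `expression_dependent` columns.
#' @export
annotate_switch <- function(events, tx_fpkm, gene_fpkm,
                            strong_hi = 5, strong_lo = 1,
                            gene_expressed_min = 1) {
  if (nrow(events) == 0L) {
    events$strong <- logical()
    events$expression_dependent <- logical()
    return(events)
  }
  stopifnot(dplyr::n_distinct(events$sample_a) == 1L,
            dplyr::n_distinct(events$sample_b) == 1L)
  sa <- events$sample_a[1L]
  sb <- events$sample_b[1L]
  fp <- function(tx, s) {
    lookup <- dplyr::filter(tx_fpkm, .data$sample_id == s)
    out <- lookup$fpkm[match(tx, lookup$transcript_id)]
    dplyr::coalesce(out, 0)
  }
  g <- tidyr::pivot_wider(
    dplyr::filter(gene_fpkm, .data$sample_id %in% c(sa, sb)),
    names_from = "sample_id", values_from = "fpkm", values_fill = 0)
  g <- dplyr::filter(g, g[[sa]] > gene_expressed_min,
                     g[[sb]] > gene_expressed_min)
  g$abs_diff <- abs(g[[sa]] - g[[sb]])
  mean_diff <- mean(g$abs_diff)
  events |>
    dplyr::mutate(
      strong = fp(.data$tx_a, sa) >= strong_hi &
        fp(.data$tx_b, sb) >= strong_hi &
        fp(.data$tx_a, sb) < strong_lo &
        fp(.data$tx_b, sa) < strong_lo,
      expression_dependent =
        dplyr::coalesce(g$abs_diff[match(.data$gene_id, g$gene_id)],
                        0) > mean_diff)
}

#' Expression profile of a switch
#'
#' Per-sample log2 ratio lr = log2(expression(I_k)/expression(I_l)); the
#' ratio is undefined (`NA`) when either transcript is silent.
#'
#' @param tx_fpkm Long tibble `transcript_id`, `sample_id`, `fpkm`.
#' @param tx_a,tx_b The switch transcripts (I_k, I_l).
#' @return Tibble `sample_id`, `fpkm_a`, `fpkm_b`, `lr`.
#' @export
switch_profile <- function(tx_fpkm, tx_a, tx_b) {
  wide <- tx_fpkm |>
    dplyr::filter(.data$transcript_id %in% c(tx_a, tx_b)) |>
    tidyr::pivot_wider(names_from = "transcript_id", values_from = "fpkm",
                       values_fill = 0)
  tibble::tibble(
    sample_id = wide$sample_id,
    fpkm_a = wide[[tx_a]],
    fpkm_b = wide[[tx_b]],
    lr = ifelse(wide[[tx_a]] > 0 & wide[[tx_b]] > 0,
                log2(wide[[tx_a]] / wide[[tx_b]]), NA_real_))
}

#' Switches implying a change in protein sequence
#'
#' Keeps strong switch events whose two transcripts both carry an annotated
#' CDS and whose CDS genomic-interval sets differ - a proxy for a protein
#' change that requires no translation. Transcripts differing only in UTRs
#' are excluded, as are events involving a non-coding transcript (those are
#' handled by the biotype analysis).
#'
#' @param events Annotated events (with a `strong` column).
#' @param annotation A `tx_annotation`.
#' @return The qualifying subset of `events`.
#' @export
coding_change_switches <- function(events, annotation) {
  stopifnot("strong" %in% names(events))
  sig <- annotation$cds |>
    dplyr::arrange(.data$transcript_id, .data$start) |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(cds_sig = paste(.data$start, .data$end, sep = "-",
                                     collapse = ";"),
                     .groups = "drop")
  lk <- stats::setNames(sig$cds_sig, sig$transcript_id)
  events |>
    dplyr::filter(.data$strong,
                  .data$tx_a %in% names(lk), .data$tx_b %in% names(lk),
                  unname(lk[.data$tx_a]) != unname(lk[.data$tx_b]))
}

#' Scan all sample pairs for switch events
#'
#' Runs [detect_switch_events()] and [annotate_switch()] over every
#' unordered sample pair, then summarises per-gene involvement and, for
#' replicated designs (metadata with a `condition` column), tallies events
#' across replicate pairs versus condition pairs.
#'
#' @inheritParams annotate_switch
#' @param calls Output of [call_major()].
#' @param x Fold threshold.
#' @param metadata Optional tibble `sample_id`, `condition`, ... used to
#'   classify sample pairs.
#' @return A `switch_scan` object: list with `events`, `gene_summary` and
#'   `pair_summary` tibbles.
#' @export
pairwise_switch_scan <- function(tx_fpkm, gene_fpkm, calls, x = 2,
                                 metadata = NULL, strong_hi = 5,
                                 strong_lo = 1, gene_expressed_min = 1) {
  samples <- sort(unique(calls$sample_id))
  stopifnot(length(samples) >= 2L)
  pairs <- utils::combn(samples, 2L, simplify = FALSE)
  events <- purrr::map_dfr(pairs, function(p) {
    detect_switch_events(tx_fpkm, calls, p[1L], p[2L], x = x) |>
      annotate_switch(tx_fpkm, gene_fpkm, strong_hi = strong_hi,
                      strong_lo = strong_lo,
                      gene_expressed_min = gene_expressed_min)
  })
  gene_summary <- calls |>
    dplyr::distinct(.data$gene_id) |>
    dplyr::mutate(
      in_switch = .data$gene_id %in% events$gene_id,
      in_strong_switch = .data$gene_id %in%
        events$gene_id[events$strong])
  pair_summary <- tibble::tibble(
    sample_a = purrr::map_chr(pairs, 1L),
    sample_b = purrr::map_chr(pairs, 2L)) |>
    dplyr::left_join(dplyr::count(events, .data$sample_a, .data$sample_b,
                                  name = "n_events"),
                     by = c("sample_a", "sample_b")) |>
    dplyr::mutate(n_events = dplyr::coalesce(.data$n_events, 0L))
  if (!is.null(metadata) && "condition" %in% names(metadata)) {
    cond <- stats::setNames(metadata$condition, metadata$sample_id)
    pair_summary <- pair_summary |>
      dplyr::mutate(pair_type = ifelse(
        unname(cond[.data$sample_a]) == unname(cond[.data$sample_b]),
        "replicate", "condition"))
  }
  structure(list(events = events, gene_summary = gene_summary,
                 pair_summary = pair_summary, x = x),
            class = "switch_scan")
}

#' @export
print.switch_scan <- function(x, ...) {
  cat("<switch_scan> x =", x$x, "\n")
  cat(" ", nrow(x$events), "events over", nrow(x$pair_summary),
      "sample pairs;", sum(x$events$strong), "strong\n")
  cat(" ", sum(x$gene_summary$in_switch), "of", nrow(x$gene_summary),
      "genes involved\n")
  invisible(x)
}

#' @rdname pairwise_switch_scan
#' @param x A `switch_scan`.
#' @param ... Unused.
#' @export
tidy.switch_scan <- function(x, ...) x$events

#' @rdname pairwise_switch_scan
#' @export
glance.switch_scan <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x$pair_summary),
    n_events = nrow(x$events),
    n_strong = sum(x$events$strong),
    n_genes = nrow(x$gene_summary),
    n_genes_in_switch = sum(x$gene_summary$in_switch),
    n_genes_in_strong = sum(x$gene_summary$in_strong_switch),
    pct_genes_in_switch = 100 * mean(x$gene_summary$in_switch),
    fold = x$x)
}
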