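#' Read a GENCODE-style GTF into an annotation model
#'
#' Parses gene/transcript/exon/CDS features from a GTF file into a set of
#' linked tibbles (genes, transcripts, exons, CDS). GTF 1-based inclusive
#' coordinates are converted to the package-internal 0-based half-open
#' convention at this boundary; [write_gtf()] converts back.
#'
#' Biotypes are read from `gene_type`/`transcript_type` (GENCODE dialect) or
#' `gene_biotype`/`transcript_biotype` (Ensembl dialect), whichever is
#' present. The transcription start site (TSS) of each transcript is the
#' strand-aware 5'-most exonic base (exon-union start on `+`, end - 1 on `-`).
#'
#' @param path Path to a GTF file.
#' @param mito_chroms Chromosome names treated as mitochondrial.
#' @return A `tx_annotation` object: a list with tibbles `genes`,
#'   `transcripts`, `exons`, `cds` and a `provenance` record.
#' @export
read_gtf <- function(path, mito_chroms = c("MT", "chrM", "M")) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  body <- lines[keep]
  if (length(body) == 0L) {
    warning("empty GTF file: ", path, call. = FALSE)
    return(empty_annotation(source = path))
  }
  nfield <- lengths(strsplit(body, "\t", fixed = TRUE))
  if (any(nfield < 9L)) {
    bad <- which(keep)[which(nfield < 9L)[1L]]
    stop("malformed GTF line ", bad, " in ", path,
         " (expected 9 tab-separated fields)", call. = FALSE)
  }
  # reject records with non-positive width before handing to the importer
  f45 <- utils::read.table(text = body, sep = "\t", quote = "",
                           colClasses = c("NULL", "NULL", "NULL",
                                          "integer", "integer",
                                          rep("NULL", 4L)))
  dropped <- f45[[2L]] <= f45[[1L]] - 1L  # end < start in 1-based terms
  n_dropped <- sum(dropped)
  src <- path
  if (n_dropped > 0L) {
    warning(n_dropped, " GTF record(s) with end <= start rejected",
            call. = FALSE)
    src <- tempfile(fileext = ".gtf")
    writeLines(body[!dropped], src)
    on.exit(unlink(src), add = TRUE)
  }
  gr <- rtracklayer::import(src, format = "gtf")
  mc <- S4Vectors::mcols(gr)
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% names(mc)) return(as.character(mc[[nm]]))
    rep(NA_character_, length(gr))
  }
  feat <- tibble::tibble(
    type          = as.character(mc$type),
    chrom         = as.character(GenomicRanges::seqnames(gr)),
    start         = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end           = GenomicRanges::end(gr),
    strand        = as.character(GenomicRanges::strand(gr)),
    gene_id       = pick("gene_id"),
    transcript_id = pick("transcript_id"),
    gene_biotype  = pick("gene_type", "gene_biotype"),
    tx_biotype    = pick("transcript_type", "transcript_biotype")
  )
  build_annotation(feat, source = path,
                   log = if (n_dropped) paste0("rejected ", n_dropped,
                                               " zero/negative-width records")
                         else character(),
                   mito_chroms = mito_chroms)
}

empty_annotation <- function(source = NA_character_, log = character()) {
  structure(list(
    genes = tibble::tibble(gene_id = character(), biotype = character(),
                           chrom = character(), strand = character(),
                           span_start = integer(), span_end = integer(),
                           n_transcripts = integer(), is_mito = logical()),
    transcripts = tibble::tibble(transcript_id = character(),
                                 gene_id = character(), biotype = character(),
                                 chrom = character(), strand = character(),
                                 tss = integer(), length = integer(),
                                 cds_length = integer(), n_exons = integer()),
    exons = tibble::tibble(transcript_id = character(), gene_id = character(),
                           chrom = character(), start = integer(),
                           end = integer(), strand = character()),
    cds = tibble::tibble(transcript_id = character(), gene_id = character(),
                         chrom = character(), start = integer(),
                         end = integer(), strand = character()),
    provenance = list(source = source, log = log)
  ), class = "tx_annotation")
}

# Assemble a tx_annotation from a flat feature tibble (0-based half-open).
build_annotation <- function(feat, source = NA_character_, log = character(),
                             mito_chroms = c("MT", "chrM", "M")) {
  exons <- feat |>
    dplyr::filter(.data$type == "exon") |>
    dplyr::select("transcript_id", "gene_id", "chrom", "start", "end",
                  "strand") |>
    dplyr::arrange(.data$gene_id, .data$transcript_id, .data$start)
  cds <- feat |>
    dplyr::filter(.data$type == "CDS") |>
    dplyr::select("transcript_id", "gene_id", "chrom", "start", "end",
                  "strand") |>
    dplyr::arrange(.data$gene_id, .data$transcript_id, .data$start)

  tx_bio <- feat |>
    dplyr::filter(!is.na(.data$transcript_id)) |>
    dplyr::distinct(.data$transcript_id, biotype = .data$tx_biotype) |>
    dplyr::filter(!is.na(.data$biotype)) |>
    dplyr::distinct(.data$transcript_id, .keep_all = TRUE)
  cds_len <- cds |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(cds_length = sum(.data$end - .data$start), .groups = "drop")

  transcripts <- exons |>
    dplyr::group_by(.data$transcript_id, .data$gene_id, .data$chrom,
                    .data$strand) |>
    dplyr::summarise(
      tss = ifelse(.data$strand[1L] == "-", max(.data$end) - 1L,
                   min(.data$start)),
      length = sum(.data$end - .data$start),
      n_exons = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::left_join(tx_bio, by = "transcript_id") |>
    dplyr::left_join(cds_len, by = "transcript_id") |>
    dplyr::mutate(cds_length = dplyr::coalesce(.data$cds_length, 0L)) |>
    dplyr::select("transcript_id", "gene_id", "biotype", "chrom", "strand",
                  "tss", "length", "cds_length", "n_exons") |>
    dplyr::arrange(.data$gene_id, .data$transcript_id)

  gene_bio <- feat |>
    dplyr::filter(!is.na(.data$gene_id), !is.na(.data$gene_biotype)) |>
    dplyr::distinct(.data$gene_id, biotype = .data$gene_biotype) |>
    dplyr::distinct(.data$gene_id, .keep_all = TRUE)
  genes <- exons |>
    dplyr::group_by(.data$gene_id, .data$chrom, .data$strand) |>
    dplyr::summarise(span_start = min(.data$start), span_end = max(.data$end),
                     .groups = "drop") |>
    dplyr::left_join(
      dplyr::count(transcripts, .data$gene_id, name = "n_transcripts"),
      by = "gene_id") |>
    dplyr::left_join(gene_bio, by = "gene_id") |>
    dplyr::mutate(is_mito = .data$chrom %in% mito_chroms) |>
    dplyr::select("gene_id", "biotype", "chrom", "strand", "span_start",
                  "span_end", "n_transcripts", "is_mito") |>
    dplyr::arrange(.data$gene_id)

  stopifnot(!anyDuplicated(transcripts$transcript_id))
  structure(list(genes = genes, transcripts = transcripts, exons = exons,
                 cds = cds,
                 provenance = list(source = source, log = log)),
            class = "tx_annotation")
}

#' @export
print.tx_annotation <- function(x, ...) {
  cat("<tx_annotation> ", nrow(x$genes), " genes, ",
      nrow(x$transcripts), " transcripts\n", sep = "")
  if (length(x$provenance$log)) {
    cat("provenance:\n")
    for (l in x$provenance$log) cat("  - ", l, "\n", sep = "")
  }
  invisible(x)
}

#' Restrict an annotation to the protein-coding study set
#'
#' Keeps protein-coding genes and drops any gene having at least one
#' annotated transcript shorter than `min_tx_len` nucleotides (short
#' transcripts are lost during library size selection, so such genes cannot
#' be quantified reliably). Genes whose every transcript is exactly
#' `min_tx_len` long are kept: the rule is strictly "shorter than".
#'
#' @param annotation A `tx_annotation`.
#' @param min_tx_len Minimum transcript length in nt (default 300).
#' @return A filtered `tx_annotation` with kept/dropped counts appended to
#'   its provenance log.
#' @export
build_study_set <- function(annotation, min_tx_len = 300) {
  stopifnot(inherits(annotation, "tx_annotation"))
  coding <- annotation$genes$gene_id[
    !is.na(annotation$genes$biotype) &
      annotation$genes$biotype == "protein_coding"]
  too_short <- annotation$transcripts |>
    dplyr::filter(.data$length < min_tx_len) |>
    dplyr::pull("gene_id") |>
    unique()
  keep <- setdiff(coding, too_short)
  out <- subset_annotation(annotation, keep)
  out$provenance$log <- c(out$provenance$log, sprintf(
    "study set: kept %d of %d genes (%d non-protein-coding, %d with a transcript < %d nt)",
    length(keep), nrow(annotation$genes),
    nrow(annotation$genes) - length(coding),
    length(intersect(coding, too_short)), min_tx_len))
  out
}

subset_annotation <- function(annotation, gene_ids) {
  out <- annotation
  out$genes <- dplyr::filter(annotation$genes, .data$gene_id %in% gene_ids)
  out$transcripts <- dplyr::filter(annotation$transcripts,
                                   .data$gene_id %in% gene_ids)
  out$exons <- dplyr::filter(annotation$exons, .data$gene_id %in% gene_ids)
  out$cds <- dplyr::filter(annotation$cds, .data$gene_id %in% gene_ids)
  out
}

# GRanges keyed by gene_id as seqname: lets interval ops run per gene in one
# vectorised call. 0-based half-open -> IRanges 1-based inclusive.
gene_keyed_granges <- function(tbl) {
  GenomicRanges::GRanges(
    seqnames = tbl$gene_id,
    ranges = IRanges::IRanges(start = tbl$start + 1L, end = tbl$end))
}

#' Derive intronic regions of each gene
#'
#' An intron is a maximal interval inside the gene span (minimum exon start
#' to maximum exon end over all transcripts) that is overlapped by no exon of
#' any transcript of the gene. Single-exon genes, and genes whose transcripts
#' jointly tile their span, yield no introns.
#'
#' @param annotation A `tx_annotation`.
#' @param transcripts Optional character vector of transcript ids: only exons
#'   of these transcripts are used for the complement (the default uses all).
#' @return Tibble with `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand` and `index` (ordinal in genomic order).
#' @export
derive_introns <- function(annotation, transcripts = NULL) {
  stopifnot(inherits(annotation, "tx_annotation"))
  ex <- annotation$exons
  if (!is.null(transcripts)) {
    ex <- dplyr::filter(ex, .data$transcript_id %in% transcripts)
  }
  if (nrow(ex) == 0L) {
    return(tibble::tibble(gene_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          strand = character(), index = integer()))
  }
  span <- ex |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     .groups = "drop")
  sp_gr <- gene_keyed_granges(span)
  ex_gr <- GenomicRanges::reduce(gene_keyed_granges(ex))
  introns <- GenomicRanges::setdiff(sp_gr, ex_gr)
  tibble::tibble(
    gene_id = as.character(GenomicRanges::seqnames(introns)),
    start = GenomicRanges::start(introns) - 1L,
    end = GenomicRanges::end(introns)
  ) |>
    dplyr::inner_join(
      dplyr::select(annotation$genes, "gene_id", "chrom", "strand"),
      by = "gene_id") |>
    dplyr::arrange(.data$gene_id, .data$start) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::mutate(index = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("gene_id", "chrom", "start", "end", "strand", "index")
}

#' Group a gene's transcripts by transcription start site
#'
#' TSS equality is exact coordinate equality of the strand-aware 5'-most
#' exonic base; transcripts sharing it form one group.
#'
#' @param annotation A `tx_annotation`.
#' @return Tibble `gene_id`, `tss`, `tss_group` (id unique within gene),
#'   `transcript_id`, `group_size`.
#' @export
tss_groups <- function(annotation) {
  stopifnot(inherits(annotation, "tx_annotation"))
  annotation$transcripts |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::mutate(tss_group = match(.data$tss, sort(unique(.data$tss)))) |>
    dplyr::group_by(.data$gene_id, .data$tss_group) |>
    dplyr::mutate(group_size = dplyr::n()) |>
    dplyr::ungroup() |>
    dplyr::select("gene_id", "tss", "tss_group", "transcript_id",
                  "group_size") |>
    dplyr::arrange(.data$gene_id, .data$tss_group, .data$transcript_id)
}

#' Splice junctions of every transcript
#'
#' A junction is identified by (chrom, donor, acceptor, strand) in 0-based
#' half-open exon coordinates: donor = exon end, acceptor = next exon start.
#' Single-exon transcripts contribute no junctions.
#'
#' @param annotation A `tx_annotation`.
#' @return Tibble `gene_id`, `transcript_id`, `chrom`, `donor`, `acceptor`,
#'   `strand`, `junction` (encoded `"chrom:donor-acceptor:strand"`).
#' @export
transcript_junctions <- function(annotation) {
  stopifnot(inherits(annotation, "tx_annotation"))
  annotation$exons |>
    dplyr::arrange(.data$transcript_id, .data$start) |>
    dplyr::group_by(.data$gene_id, .data$transcript_id, .data$chrom,
                    .data$strand) |>
    dplyr::reframe(donor = .data$end[-dplyr::n()],
                   acceptor = .data$start[-1L]) |>
    dplyr::mutate(junction = junction_id(.data$chrom, .data$donor,
                                         .data$acceptor, .data$strand)) |>
    dplyr::select("gene_id", "transcript_id", "chrom", "donor", "acceptor",
                  "strand", "junction")
}

junction_id <- function(chrom, donor, acceptor, strand) {
  paste0(chrom, ":", donor, "-", acceptor, ":", strand)
}

#' Transcript-unique junctions and gene identifiability
#'
#' A junction is unique to a transcript when exactly one transcript of the
#' gene contains it; a gene is fully identifiable when every transcript has
#' at least one unique junction (the precondition for calling the major
#' isoform directly from junction reads).
#'
#' @param annotation A `tx_annotation`.
#' @return List of two tibbles: `junctions` (unique junctions, columns as
#'   [transcript_junctions()] plus none else) and `genes` (`gene_id`,
#'   `n_transcripts`, `n_identifiable`, `fully_identifiable`).
#' @export
unique_junctions <- function(annotation) {
  jx <- transcript_junctions(annotation)
  uniq <- jx |>
    dplyr::group_by(.data$gene_id, .data$junction) |>
    dplyr::filter(dplyr::n() == 1L) |>
    dplyr::ungroup()
  per_tx <- annotation$transcripts |>
    dplyr::select("gene_id", "transcript_id") |>
    dplyr::left_join(dplyr::count(uniq, .data$transcript_id, name = "n_unique"),
                     by = "transcript_id") |>
    dplyr::mutate(n_unique = dplyr::coalesce(.data$n_unique, 0L))
  genes <- per_tx |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(n_transcripts = dplyr::n(),
                     n_identifiable = sum(.data$n_unique > 0L),
                     .groups = "drop") |>
    dplyr::mutate(fully_identifiable =
                    .data$n_identifiable == .data$n_transcripts)
  list(junctions = uniq, genes = genes)
}

#' Per-transcript length flags
#'
#' Flags each transcript as longest of its gene and/or carrying the longest
#' CDS, by strict maximum; ties flag all tied transcripts.
#'
#' @param annotation A `tx_annotation`.
#' @return Tibble `transcript_id`, `gene_id`, `length`, `cds_length`,
#'   `is_longest_transcript`, `has_longest_cds`.
#' @export
length_flags <- function(annotation) {
  stopifnot(inherits(annotation, "tx_annotation"))
  annotation$transcripts |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::mutate(is_longest_transcript = .data$length == max(.data$length),
                  has_longest_cds = .data$cds_length == max(.data$cds_length)) |>
    dplyr::ungroup() |>
    dplyr::select("transcript_id", "gene_id", "length", "cds_length",
                  "is_longest_transcript", "has_longest_cds")
}

#' Relative position of introns along the gene, 5' to 3'
#'
#' Maps each intron midpoint onto the gene span, strand-aware: 0 is the
#' transcriptional start, 1 the transcriptional end. Mirroring a gene to the
#' opposite strand maps a position p to 1 - p.
#'
#' @param introns Tibble as returned by [derive_introns()].
#' @param annotation A `tx_annotation` supplying gene spans and strands.
#' @return `introns` with a `rel_pos` column appended.
#' @export
intron_relative_position <- function(introns, annotation) {
  stopifnot(inherits(annotation, "tx_annotation"))
  g <- dplyr::select(annotation$genes, "gene_id", "span_start", "span_end",
                     g_strand = "strand")
  out <- dplyr::inner_join(introns, g, by = "gene_id")
  if (nrow(out) < nrow(introns)) {
    stop("introns reference genes absent from the annotation", call. = FALSE)
  }
  width <- out$span_end - out$span_start
  if (any(width <= 0)) stop("zero-length gene span", call. = FALSE)
  mid <- (out$start + out$end) / 2
  rel <- (mid - out$span_start) / width
  rel[out$g_strand == "-"] <- 1 - rel[out$g_strand == "-"]
  introns$rel_pos <- rel
  introns
}

#' Write an annotation model back to GTF
#'
#' Emits gene, transcript, exon and CDS records with GENCODE-style
#' `gene_type`/`transcript_type` attributes; internal 0-based half-open
#' coordinates are converted back to GTF 1-based inclusive. Round-tripping
#' through [read_gtf()] reproduces the model.
#'
#' @param annotation A `tx_annotation`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path) {
  stopifnot(inherits(annotation, "tx_annotation"))
  tx <- annotation$transcripts
  tx_span <- annotation$exons |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     .groups = "drop")
  gene_bio <- stats::setNames(annotation$genes$biotype,
                              annotation$genes$gene_id)
  rows <- dplyr::bind_rows(
    annotation$genes |>
      dplyr::transmute(type = "gene", chrom = .data$chrom,
                       start = .data$span_start, end = .data$span_end,
                       strand = .data$strand, gene_id = .data$gene_id,
                       transcript_id = NA_character_,
                       gene_type = .data$biotype,
                       transcript_type = NA_character_),
    tx |>
      dplyr::left_join(tx_span, by = "transcript_id") |>
      dplyr::transmute(type = "transcript", chrom = .data$chrom,
                       start = .data$start, end = .data$end,
                       strand = .data$strand, gene_id = .data$gene_id,
                       transcript_id = .data$transcript_id,
                       gene_type = unname(gene_bio[.data$gene_id]),
                       transcript_type = .data$biotype),
    annotation$exons |>
      dplyr::left_join(dplyr::select(tx, "transcript_id",
                                     tx_bio = "biotype"),
                       by = "transcript_id") |>
      dplyr::transmute(type = "exon", chrom = .data$chrom,
                       start = .data$start, end = .data$end,
                       strand = .data$strand, gene_id = .data$gene_id,
                       transcript_id = .data$transcript_id,
                       gene_type = unname(gene_bio[.data$gene_id]),
                       transcript_type = .data$tx_bio),
    annotation$cds |>
      dplyr::left_join(dplyr::select(tx, "transcript_id",
                                     tx_bio = "biotype"),
                       by = "transcript_id") |>
      dplyr::transmute(type = "CDS", chrom = .data$chrom,
                       start = .data$start, end = .data$end,
                       strand = .data$strand, gene_id = .data$gene_id,
                       transcript_id = .data$transcript_id,
                       gene_type = unname(gene_bio[.data$gene_id]),
                       transcript_type = .data$tx_bio)
  ) |>
    dplyr::arrange(.data$gene_id, .data$start,
                   factor(.data$type, c("gene", "transcript", "exon", "CDS")))
  gr <- GenomicRanges::GRanges(
    seqnames = rows$chrom,
    ranges = IRanges::IRanges(start = rows$start + 1L, end = rows$end),
    strand = rows$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "txdominance", type = rows$type,
    phase = ifelse(rows$type == "CDS", 0L, NA_integer_),
    gene_id = rows$gene_id, transcript_id = rows$transcript_id,
    gene_type = rows$gene_type, transcript_type = rows$transcript_type)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Write derived introns as a BED file
#'
#' @param introns Tibble from [derive_introns()].
#' @param path Output BED path (0-based half-open, as BED requires).
#' @return `path`, invisibly.
#' @export
write_introns_bed <- function(introns, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = introns$chrom,
    ranges = IRanges::IRanges(start = introns$start + 1L, end = introns$end),
    strand = introns$strand)
  S4Vectors::mcols(gr)$name <- paste0(introns$gene_id, "_intron",
                                      introns$index)
  S4Vectors::mcols(gr)$score <- 0L
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Study-set filtering report
#'
#' @param annotation A `tx_annotation` (typically after [build_study_set()]).
#' @return One-row tibble with gene/transcript counts and the provenance log
#'   collapsed to a string.
#' @export
study_set_report <- function(annotation) {
  stopifnot(inherits(annotation, "tx_annotation"))
  tibble::tibble(
    n_genes = nrow(annotation$genes),
    n_transcripts = nrow(annotation$transcripts),
    n_multi_transcript = sum(annotation$genes$n_transcripts > 1L),
    n_mitochondrial = sum(annotation$genes$is_mito),
    log = paste(annotation$provenance$log, collapse = "; ")
  )
}
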