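#' Configure a synthetic transcriptome scenario
#'
#' Describes the study conditions emulated by the generator: multi-transcript
#' genes over a shared exon scaffold, per-gene isoform relative abundances
#' under a `"dominant"` scenario (one designated major carrying proportion
#' `dominant_proportion` of the gene's output, the rest split evenly) or a
#' `"uniform"` scenario (symmetric Dirichlet draws), log-normal gene
#' expression, configurable sequencing depth with Poisson count noise,
#' optional non-coding (retained-intron / processed-transcript) majors and
#' planted strong switch events.
#'
#' @param n_genes Number of genes.
#' @param k_transcripts Transcripts per gene (fixed K >= 1).
#' @param scenario `"dominant"` or `"uniform"`.
#' @param dominant_proportion Abundance share of the designated major in the
#'   dominant scenario; must lie in (0.5, 1).
#' @param dirichlet_alpha Symmetric Dirichlet concentration for the uniform
#'   scenario (> 0); large alpha approaches equal shares 1/K.
#' @param gene_log_mean,gene_log_sd Natural-log mean and sd of per-gene
#'   total FPKM (log-normal).
#' @param library_size Mapped reads per sample.
#' @param n_samples Number of samples.
#' @param conditions Optional condition label per sample (defaults to one
#'   condition per sample, i.e. an unreplicated design).
#' @param compartments Optional cellular-compartment label per sample
#'   (`"whole_cell"`, `"cytosol"`, `"nucleus"` or `NA`).
#' @param fraction_noncoding_major Fraction of genes whose designated major
#'   lacks a CDS.
#' @param retained_share Among non-coding majors, the share with biotype
#'   `retained_intron` (the rest are `processed_transcript`).
#' @param ri_target_pos Target strand-aware relative position of planted
#'   retained introns; the generator snaps to the nearest scaffold intron
#'   and records the realised position.
#' @param unique_junction_prob Probability that a gene's transcripts all
#'   carry a unique junction (otherwise two transcripts share an identical
#'   junction chain).
#' @param n_switches Number of planted strong switch events.
#' @param switch_gene_fpkm Total FPKM assigned to switch genes, chosen so
#'   the strong-switch bounds hold by construction.
#' @param exon_width,intron_width Scaffold exon and intron widths (nt).
#' @param read_span Junction read span (nt) used for expected junction
#'   counts.
#' @param intron_leakage Expected intronic signal as a fraction of gene
#'   expression (emulates incomplete splicing; 0 = clean).
#' @param nucleus_leakage_multiplier Multiplier on `intron_leakage` for
#'   samples labelled `nucleus`.
#' @param seed Integer seed fixing all draws.
#' @return A `synthetic_scenario` object.
#' @export
synthetic_scenario <- function(n_genes = 200,
                               k_transcripts = 4,
                               scenario = c("dominant", "uniform"),
                               dominant_proportion = 0.8,
                               dirichlet_alpha = 10,
                               gene_log_mean = 2,
                               gene_log_sd = 1,
                               library_size = 5e6,
                               n_samples = 4,
                               conditions = NULL,
                               compartments = NULL,
                               fraction_noncoding_major = 0,
                               retained_share = 0.5,
                               ri_target_pos = 0.8,
                               unique_junction_prob = 1,
                               n_switches = 0,
                               switch_gene_fpkm = 10,
                               exon_width = 200,
                               intron_width = 150,
                               read_span = 75,
                               intron_leakage = 0,
                               nucleus_leakage_multiplier = 2,
                               seed = 1) {
  scenario <- match.arg(scenario)
  stopifnot(n_genes >= 1, k_transcripts >= 1,
            dirichlet_alpha > 0, library_size > 0, n_samples >= 1,
            exon_width > 0, intron_width > 0, read_span > 0,
            unique_junction_prob >= 0, unique_junction_prob <= 1,
            fraction_noncoding_major >= 0, fraction_noncoding_major <= 1)
  if (scenario == "dominant" &&
      !(dominant_proportion > 0.5 && dominant_proportion < 1)) {
    stop("dominant_proportion must lie in (0.5, 1)", call. = FALSE)
  }
  if ((k_transcripts + 1) * exon_width < 300) {
    stop("infeasible scaffold: transcripts would be shorter than 300 nt",
         call. = FALSE)
  }
  if (!is.null(conditions)) stopifnot(length(conditions) == n_samples)
  if (!is.null(compartments)) stopifnot(length(compartments) == n_samples)
  structure(as.list(environment()), class = "synthetic_scenario")
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat("<synthetic_scenario> ", x$scenario, ": ", x$n_genes, " genes x ",
      x$k_transcripts, " transcripts, ", x$n_samples, " samples, depth ",
      format(x$library_size, big.mark = ","), ", seed ", x$seed, "\n",
      sep = "")
  invisible(x)
}

#' Simulate a gene annotation
#'
#' Builds `n_genes` genes on a single chromosome, each with K transcripts
#' over a shared scaffold of K + 2 exons; transcript k skips internal exon
#' k + 1, which gives every transcript one unique splice junction (subject
#' to `unique_junction_prob`). All transcripts are at least 300 nt. A
#' designated fraction of genes carries a non-coding transcript: either a
#' retained-intron variant (two adjacent scaffold exons merged across their
#' intron, chosen nearest `ri_target_pos`) or a processed transcript (no
#' CDS). Coding transcripts receive CDS intervals covering the internal
#' exons of their chain, so different skip patterns imply different CDS.
#'
#' Uses the current RNG state; call via [simulate_dataset()] for seeded,
#' reproducible output.
#'
#' @param scenario A `synthetic_scenario`.
#' @return A `tx_annotation`; `provenance$synthetic` records the designated
#'   non-coding transcript and realised retained-intron position per gene.
#' @export
simulate_annotation <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  K <- scenario$k_transcripts
  E <- K + 2L
  w <- scenario$exon_width
  iw <- scenario$intron_width
  span_w <- E * w + (E - 1L) * iw
  margin <- 1000L
  n <- scenario$n_genes

  gene_ids <- sprintf("G%05d", seq_len(n))
  strands <- sample(c("+", "-"), n, replace = TRUE)
  offsets <- (seq_len(n) - 1L) * (span_w + margin)

  n_nc <- round(scenario$fraction_noncoding_major * n)
  nc_genes <- if (n_nc > 0) sort(sample.int(n, n_nc)) else integer()
  nc_retained <- rep(FALSE, n)
  if (n_nc > 0) {
    n_ri <- round(scenario$retained_share * n_nc)
    nc_retained[nc_genes[seq_len(n_ri)]] <- TRUE
  }
  dup_gene <- stats::runif(n) > scenario$unique_junction_prob & K >= 2
  dup_gene[nc_genes] <- FALSE  # keep non-coding designations structurally clean

  # scaffold-exon chains per transcript (skip internal exon k+1), as one
  # vectorised template crossed with all genes
  chains <- if (K == 1L) list(seq_len(E)) else
    lapply(seq_len(K), function(k) setdiff(seq_len(E), k + 1L))
  template <- dplyr::bind_rows(lapply(seq_len(K), function(kk) {
    tibble::tibble(k = kk, i = chains[[kk]])
  }))
  ex <- tidyr::crossing(g = seq_len(n), template)
  if (any(dup_gene)) {
    # duplicated-chain genes: transcript K reuses transcript K-1's chain
    dup_rows <- ex$g %in% which(dup_gene)
    keep <- ex[!(dup_rows & ex$k == K), ]
    copy <- ex[dup_rows & ex$k == K - 1L, ]
    copy$k <- K
    ex <- dplyr::arrange(dplyr::bind_rows(keep, copy), .data$g, .data$k,
                         .data$i)
  }
  ex$start <- offsets[ex$g] + (ex$i - 1L) * (w + iw)
  ex$end <- ex$start + w
  ex$is_nc_tx <- FALSE
  synth <- tibble::tibble(
    gene_id = gene_ids, strand = strands,
    nc_transcript = NA_character_, nc_biotype = NA_character_,
    ri_rel_pos = NA_real_, duplicated_chain = dup_gene)
  for (g in nc_genes) {
    nc_idx <- if (strands[g] == "+") 1L else K
    synth$nc_transcript[g] <- sprintf("%s.%d", gene_ids[g], nc_idx)
    synth$nc_biotype[g] <- if (nc_retained[g]) "retained_intron"
                           else "processed_transcript"
    sel <- which(ex$g == g & ex$k == nc_idx)
    ex$is_nc_tx[sel] <- TRUE
    if (nc_retained[g]) {
      # merge the adjacent scaffold pair whose intron midpoint lies
      # nearest the target relative position (strand-aware)
      chain <- ex$i[sel]
      adj <- which(diff(chain) == 1L)
      mid <- ex$end[sel][adj] + iw / 2
      rel <- (mid - offsets[g]) / span_w
      if (strands[g] == "-") rel <- 1 - rel
      pick <- which.min(abs(rel - scenario$ri_target_pos))
      j <- adj[pick]
      synth$ri_rel_pos[g] <- rel[pick]
      ex$end[sel[j]] <- ex$end[sel[j + 1L]]
      ex <- ex[-sel[j + 1L], ]
    }
  }
  ex$transcript_id <- sprintf("%s.%d", gene_ids[ex$g], ex$k)
  ex$tx_biotype <- ifelse(ex$is_nc_tx,
                          synth$nc_biotype[ex$g], "protein_coding")
  # CDS covers the internal exons of each coding transcript's chain
  cds <- ex |>
    dplyr::filter(!.data$is_nc_tx) |>
    dplyr::group_by(.data$g, .data$k) |>
    dplyr::filter(dplyr::row_number() > 1L,
                  dplyr::row_number() < dplyr::n()) |>
    dplyr::ungroup()
  feat <- dplyr::bind_rows(
    dplyr::mutate(ex, type = "exon"),
    dplyr::mutate(cds, type = "CDS")) |>
    dplyr::mutate(chrom = "chr1", strand = strands[.data$g],
                  gene_id = gene_ids[.data$g],
                  gene_biotype = "protein_coding") |>
    dplyr::select("type", "chrom", "start", "end", "strand", "gene_id",
                  "transcript_id", "gene_biotype", "tx_biotype")
  ann <- build_annotation(feat, source = "simulated",
                          log = sprintf("simulated: %d genes x %d transcripts",
                                        n, K))
  ann$provenance$synthetic <- synth
  ann
}

# symmetric Dirichlet(alpha) draws, n x k
rdirichlet_sym <- function(n, k, alpha) {
  g <- matrix(stats::rgamma(n * k, shape = alpha, rate = 1), nrow = n)
  g / rowSums(g)
}

#' Simulate true isoform relative abundances
#'
#' Dominant scenario: the designated major transcript (the gene's
#' non-coding transcript when present, otherwise one drawn at random) gets
#' proportion p, the others split the remainder evenly; shares are constant
#' across samples. Uniform scenario: an independent symmetric Dirichlet
#' draw per gene and sample. Gene totals are log-normal, drawn once per
#' gene; transcript FPKM = total x share.
#'
#' Uses the current RNG state; call via [simulate_dataset()] for seeded
#' output.
#'
#' @param scenario A `synthetic_scenario`.
#' @param annotation Output of [simulate_annotation()].
#' @return Tibble `gene_id`, `transcript_id`, `sample_id`, `fraction`,
#'   `gene_total`, `fpkm`.
#' @export
simulate_abundances <- function(scenario, annotation) {
  stopifnot(inherits(scenario, "synthetic_scenario"),
            inherits(annotation, "tx_annotation"))
  synth <- annotation$provenance$synthetic
  K <- scenario$k_transcripts
  n <- nrow(synth)
  samples <- sprintf("S%02d", seq_len(scenario$n_samples))

  major_idx <- ifelse(
    is.na(synth$nc_transcript),
    sample.int(K, n, replace = TRUE),
    as.integer(sub(".*\\.", "", synth$nc_transcript)))
  gene_total <- stats::rlnorm(n, scenario$gene_log_mean, scenario$gene_log_sd)

  grid <- tidyr::crossing(gene = seq_len(n), k = seq_len(K),
                          sample_id = samples)
  if (scenario$scenario == "dominant") {
    p <- scenario$dominant_proportion
    frac <- ifelse(grid$k == major_idx[grid$gene], p,
                   if (K > 1) (1 - p) / (K - 1) else 0)
    if (K == 1L) frac <- rep(1, nrow(grid))
  } else {
    draws <- rdirichlet_sym(n * scenario$n_samples, K, scenario$dirichlet_alpha)
    # rows of `draws` indexed by (gene, sample); map each grid row to its cell
    cell <- (grid$gene - 1L) * scenario$n_samples +
      match(grid$sample_id, samples)
    frac <- draws[cbind(cell, grid$k)]
  }
  tibble::tibble(
    gene_id = synth$gene_id[grid$gene],
    transcript_id = sprintf("%s.%d", synth$gene_id[grid$gene], grid$k),
    sample_id = grid$sample_id,
    fraction = frac,
    gene_total = gene_total[grid$gene]) |>
    dplyr::mutate(fpkm = .data$gene_total * .data$fraction) |>
    dplyr::arrange(.data$gene_id, .data$transcript_id, .data$sample_id)
}

#' Plant strong switch events
#'
#' For each planted event a coding multi-transcript gene is rescaled to
#' `switch_gene_fpkm` total and its designated major exchanges abundance
#' shares with a second transcript in one sample of a chosen pair, such
#' that the strong-switch bounds (>= 5 FPKM for each sample's dominant
#' transcript, < 1 FPKM for the reciprocal one) hold by construction.
#'
#' Uses the current RNG state; call via [simulate_dataset()] for seeded
#' output.
#'
#' @param abundances Output of [simulate_abundances()].
#' @param scenario A `synthetic_scenario` with `n_switches > 0`.
#' @param annotation Output of [simulate_annotation()].
#' @return List: `abundances` (modified) and `registry` tibble
#'   (`gene_id`, `tx_a`, `tx_b`, `sample_a`, `sample_b`).
#' @export
plant_switches <- function(abundances, scenario, annotation) {
  n_events <- scenario$n_switches
  if (n_events == 0L) {
    return(list(abundances = abundances,
                registry = tibble::tibble(gene_id = character(),
                                          tx_a = character(),
                                          tx_b = character(),
                                          sample_a = character(),
                                          sample_b = character())))
  }
  stopifnot(scenario$n_samples >= 2L, scenario$k_transcripts >= 2L)
  K <- scenario$k_transcripts
  p <- if (scenario$scenario == "dominant") scenario$dominant_proportion
       else 0.8
  total <- scenario$switch_gene_fpkm
  if (total * p < 5 || total * (1 - p) / (K - 1) >= 1) {
    stop("switch_gene_fpkm incompatible with the strong-switch bounds",
         call. = FALSE)
  }
  synth <- annotation$provenance$synthetic
  eligible <- synth$gene_id[is.na(synth$nc_transcript)]
  if (length(eligible) < n_events) {
    stop("insufficient eligible genes for ", n_events, " planted switches",
         call. = FALSE)
  }
  genes <- sample(eligible, n_events)
  samples <- sprintf("S%02d", seq_len(scenario$n_samples))
  registry <- purrr::map_dfr(genes, function(g) {
    pair <- sample(samples, 2L)
    txs <- sort(unique(
      abundances$transcript_id[abundances$gene_id == g]))
    tx_pick <- sample(txs, 2L)
    tibble::tibble(gene_id = g, tx_a = tx_pick[1L], tx_b = tx_pick[2L],
                   sample_a = pair[1L], sample_b = pair[2L])
  })
  minor <- (1 - p) / (K - 1)
  for (i in seq_len(n_events)) {
    r <- registry[i, ]
    sel <- abundances$gene_id == r$gene_id
    abundances$gene_total[sel] <- total
    in_b <- sel & abundances$sample_id == r$sample_b
    dom_tx <- ifelse(abundances$sample_id[sel] == r$sample_b, r$tx_b, r$tx_a)
    abundances$fraction[sel] <-
      ifelse(abundances$transcript_id[sel] == dom_tx, p, minor)
  }
  abundances$fpkm <- abundances$gene_total * abundances$fraction
  list(abundances = abundances, registry = registry)
}

#' Simulate feature-level counts and quantifier output
#'
#' Expected counts follow the FPKM inversion: for each feature, the sum
#' over transcripts containing it of transcript FPKM x feature length x
#' library size / 1e9. Exonic features are the disjoint pieces of each
#' gene's exon union; junction features use a fixed read-span length;
#' intronic features default to zero signal plus an optional leakage
#' fraction of gene expression (doubled in nucleus samples by default, to
#' emulate incomplete splicing). Counts are Poisson draws around the
#' expectation, or exactly the expectation when `noiseless`. Transcript
#' FPKM estimates (the quantifier emulation) are likewise exact when
#' noiseless, otherwise derived from Poisson fragment counts per
#' transcript.
#'
#' @param scenario A `synthetic_scenario`.
#' @param annotation Output of [simulate_annotation()].
#' @param abundances True abundances (possibly with planted switches).
#' @param metadata Sample metadata tibble (for compartment-dependent
#'   leakage).
#' @param noiseless Logical; exact expectations instead of Poisson draws.
#' @return List with `exon`, `intron`, `junction` count tables (each a list
#'   of `counts`, `lengths`, `feature_genes`), `tx_fpkm` (estimated),
#'   `library_sizes`.
#' @export
simulate_counts <- function(scenario, annotation, abundances, metadata,
                            noiseless = TRUE) {
  lib <- scenario$library_size
  samples <- sprintf("S%02d", seq_len(scenario$n_samples))
  library_sizes <- tibble::tibble(sample_id = samples, library_size = lib)
  draw <- function(mu) if (noiseless) mu else stats::rpois(length(mu), mu)

  ## exon bins: disjoint pieces of the per-gene exon union
  bins_gr <- GenomicRanges::reduce(gene_keyed_granges(annotation$exons))
  bins <- tibble::tibble(
    gene_id = as.character(GenomicRanges::seqnames(bins_gr)),
    start = GenomicRanges::start(bins_gr) - 1L,
    end = GenomicRanges::end(bins_gr)) |>
    dplyr::mutate(feature_id = paste0(.data$gene_id, ":", .data$start, "-",
                                      .data$end),
                  length = .data$end - .data$start)
  ex_gr <- gene_keyed_granges(annotation$exons)
  hits <- GenomicRanges::findOverlaps(bins_gr, ex_gr)
  ov_w <- GenomicRanges::width(IRanges::pintersect(
    IRanges::ranges(bins_gr)[S4Vectors::queryHits(hits)],
    IRanges::ranges(ex_gr)[S4Vectors::subjectHits(hits)]))
  cover <- tibble::tibble(
    feature_id = bins$feature_id[S4Vectors::queryHits(hits)],
    bin_len = bins$length[S4Vectors::queryHits(hits)],
    transcript_id =
      annotation$exons$transcript_id[S4Vectors::subjectHits(hits)],
    w = ov_w) |>
    dplyr::group_by(.data$feature_id, .data$bin_len, .data$transcript_id) |>
    dplyr::summarise(w = sum(.data$w), .groups = "drop") |>
    dplyr::filter(.data$w == .data$bin_len) |>
    dplyr::select("feature_id", "transcript_id")
  exon_expected <- cover |>
    dplyr::inner_join(abundances, by = "transcript_id",
                      relationship = "many-to-many") |>
    dplyr::group_by(.data$feature_id, .data$sample_id) |>
    dplyr::summarise(fpkm_sum = sum(.data$fpkm), .groups = "drop") |>
    dplyr::inner_join(dplyr::select(bins, "feature_id", "length"),
                      by = "feature_id") |>
    dplyr::mutate(mu = .data$fpkm_sum * .data$length * lib / 1e9,
                  count = draw(.data$mu))
  exon_tbl <- list(
    counts = dplyr::select(exon_expected, "feature_id", "sample_id", "count"),
    lengths = dplyr::select(bins, "feature_id", "length"),
    feature_genes = dplyr::select(bins, "feature_id", "gene_id"))

  ## junction features
  jx <- transcript_junctions(annotation)
  jx_expected <- jx |>
    dplyr::select("gene_id", "transcript_id", feature_id = "junction") |>
    dplyr::inner_join(abundances, by = c("gene_id", "transcript_id"),
                      relationship = "many-to-many") |>
    dplyr::group_by(.data$feature_id, .data$sample_id) |>
    dplyr::summarise(fpkm_sum = sum(.data$fpkm), .groups = "drop") |>
    dplyr::mutate(mu = .data$fpkm_sum * scenario$read_span * lib / 1e9,
                  count = draw(.data$mu))
  junction_tbl <- list(
    counts = dplyr::select(jx_expected, "feature_id", "sample_id", "count"),
    lengths = jx |>
      dplyr::distinct(feature_id = .data$junction) |>
      dplyr::mutate(length = scenario$read_span),
    feature_genes = dplyr::distinct(jx, feature_id = .data$junction,
                                    .data$gene_id))

  ## intronic features
  introns <- derive_introns(annotation) |>
    dplyr::mutate(feature_id = paste0(.data$gene_id, ":", .data$start, "-",
                                      .data$end),
                  length = .data$end - .data$start)
  leak <- tibble::tibble(
    sample_id = samples,
    leak = scenario$intron_leakage *
      ifelse(!is.null(metadata$compartment) &
               metadata$compartment[match(samples, metadata$sample_id)] %in%
               "nucleus",
             scenario$nucleus_leakage_multiplier, 1))
  gene_totals <- abundances |>
    dplyr::distinct(.data$gene_id, .data$sample_id, .data$gene_total)
  intron_expected <- introns |>
    dplyr::select("feature_id", "gene_id", "length") |>
    dplyr::inner_join(gene_totals, by = "gene_id",
                      relationship = "many-to-many") |>
    dplyr::inner_join(leak, by = "sample_id") |>
    dplyr::mutate(mu = .data$leak * .data$gene_total * .data$length *
                    lib / 1e9,
                  count = draw(.data$mu))
  intron_tbl <- list(
    counts = dplyr::select(intron_expected, "feature_id", "sample_id",
                           "count"),
    lengths = dplyr::select(introns, "feature_id", "length"),
    feature_genes = dplyr::select(introns, "feature_id", "gene_id"))

  ## transcript-level quantifier emulation
  if (noiseless) {
    tx_fpkm <- dplyr::select(abundances, "transcript_id", "sample_id",
                             "fpkm")
  } else {
    tx_len <- dplyr::select(annotation$transcripts, "transcript_id",
                            "length")
    tx_fpkm <- abundances |>
      dplyr::inner_join(tx_len, by = "transcript_id") |>
      dplyr::mutate(mu = .data$fpkm * .data$length * lib / 1e9,
                    count = stats::rpois(dplyr::n(), .data$mu),
                    fpkm = .data$count * 1e9 / (.data$length * lib)) |>
      dplyr::select("transcript_id", "sample_id", "fpkm")
  }

  list(exon = exon_tbl, intron = intron_tbl, junction = junction_tbl,
       tx_fpkm = tx_fpkm, library_sizes = library_sizes)
}

#' Simulate a complete synthetic dataset
#'
#' Seeds the RNG from the scenario and runs annotation, abundance, switch
#' planting and count simulation, assembling ground truth (true major and
#' fold ratio per gene and sample, planted-switch registry, non-coding
#' designations). Identical scenarios produce identical datasets.
#'
#' @param scenario A `synthetic_scenario`.
#' @param noiseless Logical; see [simulate_counts()].
#' @return A `synthetic_dataset` object: list with `scenario`,
#'   `annotation`, `abundances`, `counts`, `tx_fpkm`, `metadata`, `truth`.
#' @export
simulate_dataset <- function(scenario, noiseless = TRUE) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  withr::with_seed(scenario$seed, {
    annotation <- simulate_annotation(scenario)
    abundances <- simulate_abundances(scenario, annotation)
    planted <- plant_switches(abundances, scenario, annotation)
    abundances <- planted$abundances
    samples <- sprintf("S%02d", seq_len(scenario$n_samples))
    metadata <- tibble::tibble(
      sample_id = samples,
      condition = scenario$conditions %||% samples,
      compartment = scenario$compartments %||% NA_character_,
      replicate = as.integer(stats::ave(seq_along(samples),
                                        scenario$conditions %||% samples,
                                        FUN = seq_along)))
    counts <- simulate_counts(scenario, annotation, abundances, metadata,
                              noiseless = noiseless)
    majors <- abundances |>
      dplyr::arrange(.data$gene_id, .data$sample_id,
                     dplyr::desc(.data$fraction), .data$transcript_id) |>
      dplyr::group_by(.data$gene_id, .data$sample_id) |>
      dplyr::summarise(
        true_major = .data$transcript_id[1L],
        true_fold = dplyr::if_else(
          dplyr::n() == 1L | dplyr::nth(.data$fraction, 2L,
                                        default = 0) == 0,
          Inf, .data$fraction[1L] / .data$fraction[2L]),
        gene_total = .data$gene_total[1L],
        .groups = "drop")
    truth <- list(
      majors = majors,
      switches = planted$registry,
      noncoding = annotation$provenance$synthetic,
      pool_fraction_major = abundances |>
        dplyr::inner_join(dplyr::select(majors, "gene_id", "sample_id",
                                        "true_major"),
                          by = c("gene_id", "sample_id")) |>
        dplyr::group_by(.data$sample_id) |>
        dplyr::summarise(
          fraction_major =
            sum(.data$fpkm[.data$transcript_id == .data$true_major]) /
            sum(.data$fpkm),
          .groups = "drop"))
    structure(list(scenario = scenario, annotation = annotation,
                   abundances = abundances, counts = counts,
                   tx_fpkm = counts$tx_fpkm, metadata = metadata,
                   truth = truth),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset> ", x$scenario$scenario, " scenario: ",
      nrow(x$annotation$genes), " genes, ", x$scenario$n_samples,
      " samples, ", nrow(x$truth$switches), " planted switches\n", sep = "")
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Emits GTF annotation, TSV count/expression tables in the package's
#' external layout (`feature_id`, `length`, one column per sample),
#' metadata TSV and a JSON truth registry, all consumable unchanged by the
#' analysis functions.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gtf(dataset$annotation, file.path(dir, "annotation.gtf"))
  wide_counts <- function(tbl) {
    tbl$counts |>
      tidyr::pivot_wider(names_from = "sample_id", values_from = "count",
                         values_fill = 0) |>
      dplyr::inner_join(tbl$lengths, by = "feature_id") |>
      dplyr::relocate("feature_id", "length")
  }
  readr::write_tsv(wide_counts(dataset$counts$exon),
                   file.path(dir, "exon_counts.tsv"))
  readr::write_tsv(wide_counts(dataset$counts$intron),
                   file.path(dir, "intron_counts.tsv"))
  readr::write_tsv(wide_counts(dataset$counts$junction),
                   file.path(dir, "junction_counts.tsv"))
  readr::write_tsv(
    tidyr::pivot_wider(dataset$tx_fpkm, names_from = "sample_id",
                       values_from = "fpkm", values_fill = 0),
    file.path(dir, "transcript_fpkm.tsv"))
  readr::write_tsv(dataset$metadata, file.path(dir, "metadata.tsv"))
  readr::write_tsv(dataset$counts$library_sizes,
                   file.path(dir, "library_sizes.tsv"))
  jsonlite::write_json(
    list(majors = dataset$truth$majors,
         switches = dataset$truth$switches,
         noncoding = dataset$truth$noncoding),
    file.path(dir, "truth.json"), dataframe = "rows", digits = NA,
    na = "null")
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
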