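test_that("GTF parsing converts coordinates and sums exon lengths", {
  ann <- toy_annotation()
  expect_s3_class(ann, "tx_annotation")
  expect_equal(nrow(ann$genes), 1L)
  expect_equal(nrow(ann$transcripts), 2L)
  # 1-based [101,200] becomes 0-based half-open [100,200), width 100
  e1 <- dplyr::filter(ann$exons, transcript_id == "T1")
  expect_equal(e1$start, c(100L, 300L, 500L))
  expect_equal(e1$end, c(200L, 400L, 700L))
  lens <- tibble::deframe(
    dplyr::select(ann$transcripts, transcript_id, length))
  expect_equal(lens[["T1"]], 100 + 100 + 200)
  expect_equal(lens[["T2"]], 100 + 200)
  cds <- tibble::deframe(
    dplyr::select(ann$transcripts, transcript_id, cds_length))
  expect_equal(cds[["T1"]], 80)
  expect_equal(cds[["T2"]], 0)
})

test_that("degenerate and malformed GTF inputs are handled", {
  empty <- withr::local_tempfile(fileext = ".gtf")
  writeLines(character(), empty)
  expect_warning(ann <- read_gtf(empty), "empty")
  expect_equal(nrow(ann$genes), 0L)

  bad <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(toy_gtf_lines(), "chr1\tonly\tthree"), bad)
  expect_error(read_gtf(bad), "malformed GTF line 7")

  rej <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(toy_gtf_lines(),
               gtf_rec("chr1", "exon", 900, 890, "+", "G1", "T1")), rej)
  expect_warning(ann2 <- read_gtf(rej), "rejected")
  expect_equal(nrow(ann2$exons), 5L)
})

test_that("mitochondrial genes are flagged by chromosome name", {
  ann <- toy_annotation(c(
    gtf_rec("chrM", "exon", 1, 400, "+", "GM", "TM"),
    gtf_rec("chr2", "exon", 1, 400, "+", "GN", "TN")))
  expect_equal(
    tibble::deframe(dplyr::select(ann$genes, gene_id, is_mito)),
    c(GM = TRUE, GN = FALSE))
})

test_that("study set keeps protein-coding genes without short transcripts", {
  lines <- c(
    gtf_rec("chr1", "exon", 1, 400, "+", "GA", "TA1"),          # ok, 400 nt
    gtf_rec("chr1", "exon", 1001, 1250, "+", "GB", "TB1"),      # 250 nt
    gtf_rec("chr1", "exon", 2001, 2400, "+", "GB", "TB2"),
    gtf_rec("chr1", "exon", 3001, 3500, "+", "GC", "TC1",
            gene_bio = "lincRNA"))
  ann <- toy_annotation(lines)
  out <- build_study_set(ann)
  expect_equal(out$genes$gene_id, "GA")
  expect_match(out$provenance$log[length(out$provenance$log)],
               "kept 1 of 3")

  # rule is strictly "shorter than": exactly 300 nt passes
  ann300 <- toy_annotation(gtf_rec("chr1", "exon", 1, 300, "+", "GX", "TX"))
  expect_equal(build_study_set(ann300)$genes$gene_id, "GX")

  # min_tx_len = 0 disables the length filter
  expect_equal(build_study_set(ann, min_tx_len = 0)$genes$gene_id,
               c("GA", "GB"))
})

test_that("introns are the complement of the exon union inside the span", {
  # exon union [0,100) u [200,300) u [400,500)
  lines <- c(
    gtf_rec("chr1", "exon", 1, 100, "+", "G", "T1"),
    gtf_rec("chr1", "exon", 201, 300, "+", "G", "T1"),
    gtf_rec("chr1", "exon", 401, 500, "+", "G", "T1"))
  introns <- derive_introns(toy_annotation(lines))
  expect_equal(introns$start, c(100L, 300L))
  expect_equal(introns$end, c(200L, 400L))
  expect_equal(introns$index, c(1L, 2L))

  # transcripts jointly tiling the span leave no introns
  tiled <- c(
    gtf_rec("chr1", "exon", 1, 300, "+", "G", "T1"),
    gtf_rec("chr1", "exon", 201, 500, "+", "G", "T2"))
  expect_equal(nrow(derive_introns(toy_annotation(tiled))), 0L)

  # staggered exons: t1 [0,100)+[300,400), t2 [0,200)+[300,400)
  staggered <- c(
    gtf_rec("chr1", "exon", 1, 100, "+", "G", "T1"),
    gtf_rec("chr1", "exon", 301, 400, "+", "G", "T1"),
    gtf_rec("chr1", "exon", 1, 200, "+", "G", "T2"),
    gtf_rec("chr1", "exon", 301, 400, "+", "G", "T2"))
  st <- derive_introns(toy_annotation(staggered))
  expect_equal(nrow(st), 1L)
  expect_equal(c(st$start, st$end), c(200L, 300L))
})

test_that("TSS grouping is strand-aware and exact", {
  plus <- c(
    gtf_rec("chr1", "exon", 1, 100, "+", "G", "T1"),
    gtf_rec("chr1", "exon", 1, 200, "+", "G", "T2"),
    gtf_rec("chr1", "exon", 51, 200, "+", "G", "T3"))
  g <- tss_groups(toy_annotation(plus))
  expect_equal(sort(unique(g$group_size)), c(1L, 2L))
  expect_setequal(g$transcript_id[g$group_size == 2], c("T1", "T2"))

  # minus strand: same *end* coordinate means same TSS
  minus <- c(
    gtf_rec("chr1", "exon", 1, 200, "-", "G", "T1"),
    gtf_rec("chr1", "exon", 101, 200, "-", "G", "T2"))
  gm <- tss_groups(toy_annotation(minus))
  expect_true(all(gm$group_size == 2L))
  expect_equal(unique(gm$tss), 199L)

  single <- tss_groups(toy_annotation(
    gtf_rec("chr1", "exon", 1, 400, "+", "G", "T1")))
  expect_equal(single$group_size, 1L)
})

test_that("unique junctions and identifiability follow set difference", {
  # T1 junctions {a=100-200, b=300-400}; T2 junctions {a, c=300-500}
  lines <- c(
    gtf_rec("chr1", "exon", 1, 100, "+", "G", "T1"),
    gtf_rec("chr1", "exon", 201, 300, "+", "G", "T1"),
    gtf_rec("chr1", "exon", 401, 600, "+", "G", "T1"),
    gtf_rec("chr1", "exon", 1, 100, "+", "G", "T2"),
    gtf_rec("chr1", "exon", 201, 300, "+", "G", "T2"),
    gtf_rec("chr1", "exon", 501, 600, "+", "G", "T2"))
  uj <- unique_junctions(toy_annotation(lines))
  expect_true(uj$genes$fully_identifiable)
  expect_equal(
    sort(uj$junctions$junction),
    sort(c("chr1:300-400:+", "chr1:300-500:+")))

  # identical junction chains are indistinguishable
  dup <- c(
    gtf_rec("chr1", "exon", 1, 100, "+", "G", "T1"),
    gtf_rec("chr1", "exon", 201, 400, "+", "G", "T1"),
    gtf_rec("chr1", "exon", 1, 100, "+", "G", "T2"),
    gtf_rec("chr1", "exon", 201, 400, "+", "G", "T2"))
  uj2 <- unique_junctions(toy_annotation(dup))
  expect_equal(nrow(uj2$junctions), 0L)
  expect_false(uj2$genes$fully_identifiable)

  # a junction-subset transcript has no unique junction
  sub3 <- c(
    gtf_rec("chr1", "exon", 1, 100, "+", "G", "T1"),
    gtf_rec("chr1", "exon", 201, 300, "+", "G", "T1"),
    gtf_rec("chr1", "exon", 401, 500, "+", "G", "T1"),
    gtf_rec("chr1", "exon", 1, 100, "+", "G", "T2"),
    gtf_rec("chr1", "exon", 201, 300, "+", "G", "T2"))
  uj3 <- unique_junctions(toy_annotation(sub3))
  expect_false(uj3$genes$fully_identifiable)
  expect_false("T2" %in% uj3$junctions$transcript_id)
  expect_true("T1" %in% uj3$junctions$transcript_id)
})

test_that("length flags use strict maxima with ties flagged on all", {
  lines <- c(
    gtf_rec("chr1", "exon", 1, 500, "+", "G", "T1"),
    gtf_rec("chr1", "exon", 1, 800, "+", "G", "T2"),
    gtf_rec("chr1", "exon", 1001, 1800, "+", "G", "T3"),
    gtf_rec("chr1", "CDS", 101, 400, "+", "G", "T1"),
    gtf_rec("chr1", "CDS", 1101, 1550, "+", "G", "T3"))
  fl <- length_flags(toy_annotation(lines))
  expect_equal(fl$is_longest_transcript, c(FALSE, TRUE, TRUE))
  expect_equal(fl$has_longest_cds, c(FALSE, FALSE, TRUE))

  one <- length_flags(toy_annotation(
    gtf_rec("chr1", "exon", 1, 400, "+", "G", "T1")))
  expect_true(one$is_longest_transcript && one$has_longest_cds)
})

test_that("intron relative position is 5'-anchored and strand symmetric", {
  mk <- function(strand) {
    toy_annotation(c(
      gtf_rec("chr1", "exon", 1, 800, strand, "G", "T1"),
      gtf_rec("chr1", "exon", 901, 1000, strand, "G", "T1")))
  }
  plus <- mk("+")
  introns <- derive_introns(plus)   # [800,900), midpoint 850, span [0,1000)
  expect_equal(intron_relative_position(introns, plus)$rel_pos, 0.85)
  minus <- mk("-")
  expect_equal(
    intron_relative_position(derive_introns(minus), minus)$rel_pos, 0.15)

  centre <- toy_annotation(c(
    gtf_rec("chr1", "exon", 1, 450, "+", "G", "T1"),
    gtf_rec("chr1", "exon", 551, 1000, "+", "G", "T1")))
  expect_equal(
    intron_relative_position(derive_introns(centre), centre)$rel_pos, 0.5)
})

test_that("GTF round trip preserves intervals, lengths and biotypes", {
  sc <- synthetic_scenario(n_genes = 10, fraction_noncoding_major = 0.3,
                           seed = 11)
  ann <- simulate_dataset(sc)$annotation
  path <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(ann, path)
  back <- read_gtf(path)
  ord <- function(x) dplyr::arrange(x, gene_id, transcript_id, start)
  expect_equal(ord(back$exons), ord(ann$exons))
  expect_equal(ord(back$cds), ord(ann$cds))
  expect_equal(
    dplyr::arrange(back$transcripts, transcript_id),
    dplyr::arrange(ann$transcripts, transcript_id))
})

test_that("derived introns and exon union partition every gene span", {
  sc <- synthetic_scenario(n_genes = 100, fraction_noncoding_major = 0.25,
                           unique_junction_prob = 0.8, seed = 3)
  ann <- simulate_dataset(sc)$annotation
  introns <- derive_introns(ann)
  for (g in ann$genes$gene_id) {
    ex <- dplyr::filter(ann$exons, gene_id == g)
    ir <- dplyr::filter(introns, gene_id == g)
    span <- c(min(ex$start), max(ex$end))
    covered <- rep(FALSE, span[2] - span[1])
    for (i in seq_len(nrow(ex))) {
      covered[(ex$start[i] - span[1] + 1):(ex$end[i] - span[1])] <- TRUE
    }
    intronic <- rep(FALSE, span[2] - span[1])
    for (i in seq_len(nrow(ir))) {
      intronic[(ir$start[i] - span[1] + 1):(ir$end[i] - span[1])] <- TRUE
    }
    expect_true(all(xor(covered, intronic)))  # exact disjoint partition
  }
})

test_that("unique junctions match a brute-force containment oracle", {
  sc <- synthetic_scenario(n_genes = 60, unique_junction_prob = 0.7,
                           fraction_noncoding_major = 0.2, seed = 5)
  ann <- simulate_dataset(sc)$annotation
  uj <- unique_junctions(ann)
  jx <- transcript_junctions(ann)
  # oracle: count, for every junction string, the transcripts containing it
  oracle <- lapply(split(jx, jx$gene_id), function(d) {
    tab <- table(d$junction)
    d[d$junction %in% names(tab)[tab == 1L], c("transcript_id", "junction")]
  })
  oracle <- dplyr::bind_rows(oracle)
  expect_setequal(
    paste(uj$junctions$transcript_id, uj$junctions$junction),
    paste(oracle$transcript_id, oracle$junction))
})

test_that("strand mirror maps intron positions p to 1 - p", {
  sc <- synthetic_scenario(n_genes = 20, seed = 9)
  ann <- simulate_dataset(sc)$annotation
  introns <- derive_introns(ann)
  pos <- intron_relative_position(introns, ann)$rel_pos
  flipped <- ann
  flipped$genes$strand <- ifelse(ann$genes$strand == "+", "-", "+")
  pos2 <- intron_relative_position(introns, flipped)$rel_pos
  expect_true(all(abs(pos + pos2 - 1) < 1e-12))
})
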