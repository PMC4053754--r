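# two-transcript gene with majors differing between samples
switch_fixture <- function(a1 = 10, b1 = 2, a2 = 1, b2 = 8,
                           gene1 = 6, gene2 = 5) {
  ann <- toy_annotation(c(
    gtf_rec("chr1", "exon", 1, 400, "+", "G", "A"),
    gtf_rec("chr1", "exon", 1, 400, "+", "G", "B")))
  tx <- dplyr::bind_rows(
    fpkm_tbl(A = a1, B = b1, sample_id = "S1"),
    fpkm_tbl(A = a2, B = b2, sample_id = "S2"))
  gene <- dplyr::bind_rows(
    gene_fpkm_tbl(G = gene1, sample_id = "S1"),
    gene_fpkm_tbl(G = gene2, sample_id = "S2"))
  list(ann = ann, tx = tx, gene = gene,
       calls = call_major(tx, gene, ann))
}

test_that("recurrence classifies majors across samples", {
  calls <- tibble::tibble(
    gene_id = c(rep("G1", 3), rep("G2", 2), "G3"),
    sample_id = c("S1", "S2", "S3", "S1", "S2", "S1"),
    major = c("t1", "t1", "t1", "t1", "t2", "t1"))
  out <- recurrence_summary(calls, n_samples = 3)
  g1 <- out[out$gene_id == "G1", ]
  expect_true(g1$recurrent && g1$ubiquitous)
  g2 <- out[out$gene_id == "G2", ]
  expect_false(g2$recurrent)
  expect_false(g2$ubiquitous)
  expect_false("G3" %in% out$gene_id)  # expressed in one sample only
})

test_that("switch detection applies the two-sided ratio rule", {
  fx <- switch_fixture(a1 = 10, b1 = 2, a2 = 1, b2 = 8)
  ev2 <- detect_switch_events(fx$tx, fx$calls, "S1", "S2", x = 2)
  expect_equal(nrow(ev2), 1L)
  expect_equal(ev2$ratio_a, 5)       # 10/2 >= 2
  expect_equal(ev2$ratio_b, 0.125)   # 1/8 <= 1/2
  ev5 <- detect_switch_events(fx$tx, fx$calls, "S1", "S2", x = 5)
  expect_equal(nrow(ev5), 1L)        # 5 >= 5 and 0.125 <= 0.2

  # insufficient fold: 10/6 = 1.67 < 2
  weak <- switch_fixture(a1 = 10, b1 = 6, a2 = 6, b2 = 10)
  expect_equal(nrow(detect_switch_events(weak$tx, weak$calls, "S1", "S2",
                                         x = 2)), 0L)

  # same major in both samples: no candidate pair
  same <- switch_fixture(a1 = 10, b1 = 2, a2 = 8, b2 = 2)
  expect_equal(nrow(detect_switch_events(same$tx, same$calls, "S1", "S2",
                                         x = 2)), 0L)
})

test_that("switch detection is symmetric in the sample pair", {
  fx <- switch_fixture()
  fwd <- detect_switch_events(fx$tx, fx$calls, "S1", "S2", x = 2)
  rev <- detect_switch_events(fx$tx, fx$calls, "S2", "S1", x = 2)
  expect_equal(nrow(rev), 1L)
  expect_equal(rev$tx_a, fwd$tx_b)
  expect_equal(rev$tx_b, fwd$tx_a)
  expect_equal(rev$ratio_a, 1 / fwd$ratio_b)
})

test_that("zero runner-up expression yields an infinite one-sided ratio", {
  fx <- switch_fixture(a1 = 10, b1 = 0, a2 = 0, b2 = 8)
  ev <- detect_switch_events(fx$tx, fx$calls, "S1", "S2", x = 2)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$ratio_a, Inf)
  expect_equal(ev$ratio_b, 0)
})

test_that("strong switches respect the printed FPKM boundaries", {
  # A@S2 = 1 is NOT < 1: boundary case fails the strong rule
  fx <- switch_fixture(a1 = 10, b1 = 0.5, a2 = 1, b2 = 8)
  ev <- annotate_switch(
    detect_switch_events(fx$tx, fx$calls, "S1", "S2", x = 2),
    fx$tx, fx$gene)
  expect_false(ev$strong)

  fx2 <- switch_fixture(a1 = 10, b1 = 0.5, a2 = 0.5, b2 = 8)
  ev2 <- annotate_switch(
    detect_switch_events(fx2$tx, fx2$calls, "S1", "S2", x = 2),
    fx2$tx, fx2$gene)
  expect_true(ev2$strong)
})

test_that("expression dependence compares the gene to the pair mean", {
  # identical gene expression in both samples can never exceed the mean
  fx <- switch_fixture(gene1 = 6, gene2 = 6)
  ev <- annotate_switch(
    detect_switch_events(fx$tx, fx$calls, "S1", "S2", x = 2),
    fx$tx, fx$gene)
  expect_false(ev$expression_dependent)
})

test_that("switch profiles are per-sample log2 ratios with NA sentinels", {
  tx <- dplyr::bind_rows(
    fpkm_tbl(A = 8, B = 2, sample_id = "S1"),
    fpkm_tbl(A = 4, B = 4, sample_id = "S2"),
    fpkm_tbl(A = 5, B = 0, sample_id = "S3"))
  prof <- dplyr::arrange(switch_profile(tx, "A", "B"), sample_id)
  expect_equal(prof$lr, c(2, 0, NA))
})

test_that("coding-change switches require differing CDS interval sets", {
  ann <- toy_annotation(c(
    gtf_rec("chr1", "exon", 1, 400, "+", "G", "A"),
    gtf_rec("chr1", "exon", 1, 500, "+", "G", "B"),
    gtf_rec("chr1", "CDS", 101, 300, "+", "G", "A"),
    gtf_rec("chr1", "CDS", 101, 300, "+", "G", "B"),
    gtf_rec("chr1", "exon", 1001, 1400, "+", "H", "C"),
    gtf_rec("chr1", "exon", 1001, 1400, "+", "H", "D"),
    gtf_rec("chr1", "CDS", 1101, 1300, "+", "H", "C"),
    gtf_rec("chr1", "CDS", 1151, 1350, "+", "H", "D"),
    gtf_rec("chr1", "exon", 2001, 2400, "+", "I", "E"),
    gtf_rec("chr1", "exon", 2001, 2400, "+", "I", "F",
            tx_bio = "processed_transcript")))
  events <- tibble::tibble(
    gene_id = c("G", "H", "I"), tx_a = c("A", "C", "E"),
    tx_b = c("B", "D", "F"), sample_a = "S1", sample_b = "S2",
    x = 2, ratio_a = 10, ratio_b = 0.1, strong = TRUE,
    expression_dependent = FALSE)
  out <- coding_change_switches(events, ann)
  expect_equal(out$gene_id, "H")  # same-CDS and non-coding pairs excluded
})

test_that("pairwise scans cover all pairs and find planted events only", {
  sc <- synthetic_scenario(n_genes = 60, n_samples = 4, n_switches = 4,
                           seed = 21)
  ds <- simulate_dataset(sc)
  gene_fpkm <- gene_expression_from_exons(
    counts_to_fpkm(ds$counts$exon$counts, ds$counts$exon$lengths,
                   ds$counts$library_sizes),
    ds$counts$exon$feature_genes)
  calls <- call_major(ds$tx_fpkm, gene_fpkm, ds$annotation)
  scan <- pairwise_switch_scan(ds$tx_fpkm, gene_fpkm, calls, x = 2,
                               metadata = ds$metadata)
  expect_equal(nrow(scan$pair_summary), choose(4, 2))
  # every strong event sits in a planted gene, and each planted pair is found
  strong <- scan$events[scan$events$strong, ]
  expect_true(all(strong$gene_id %in% ds$truth$switches$gene_id))
  key <- function(g, s1, s2) paste(g, pmin(s1, s2), pmax(s1, s2))
  expect_true(all(
    key(ds$truth$switches$gene_id, ds$truth$switches$sample_a,
        ds$truth$switches$sample_b) %in%
      key(strong$gene_id, strong$sample_a, strong$sample_b)))

  # identical replicate columns yield no events
  tx_rep <- dplyr::bind_rows(
    fpkm_tbl(A = 10, B = 2, sample_id = "R1"),
    fpkm_tbl(A = 10, B = 2, sample_id = "R2"))
  ann <- toy_annotation(c(
    gtf_rec("chr1", "exon", 1, 400, "+", "G", "A"),
    gtf_rec("chr1", "exon", 1, 400, "+", "G", "B")))
  gene_rep <- dplyr::bind_rows(gene_fpkm_tbl(G = 6, sample_id = "R1"),
                               gene_fpkm_tbl(G = 6, sample_id = "R2"))
  rep_scan <- pairwise_switch_scan(tx_rep, gene_rep,
                                   call_major(tx_rep, gene_rep, ann))
  expect_equal(nrow(rep_scan$events), 0L)
})

test_that("five-fold events are a subset of two-fold events", {
  sc <- synthetic_scenario(n_genes = 80, n_samples = 3, n_switches = 6,
                           seed = 22)
  ds <- simulate_dataset(sc)
  gene_fpkm <- gene_expression_from_exons(
    counts_to_fpkm(ds$counts$exon$counts, ds$counts$exon$lengths,
                   ds$counts$library_sizes),
    ds$counts$exon$feature_genes)
  calls <- call_major(ds$tx_fpkm, gene_fpkm, ds$annotation)
  e2 <- pairwise_switch_scan(ds$tx_fpkm, gene_fpkm, calls, x = 2)$events
  e5 <- pairwise_switch_scan(ds$tx_fpkm, gene_fpkm, calls, x = 5)$events
  key <- function(d) paste(d$gene_id, d$tx_a, d$tx_b, d$sample_a,
                           d$sample_b)
  expect_true(all(key(e5) %in% key(e2)))
  # strong implies the five-fold ratio conditions
  strong <- e2[e2$strong, ]
  expect_true(all(strong$ratio_a >= 5 & strong$ratio_b <= 0.2))
})

test_that("replicate pairs are distinguished from condition pairs", {
  sc <- synthetic_scenario(n_genes = 40, n_samples = 4,
                           conditions = c("c1", "c1", "c2", "c2"),
                           seed = 23)
  ds <- simulate_dataset(sc)
  gene_fpkm <- gene_expression_from_exons(
    counts_to_fpkm(ds$counts$exon$counts, ds$counts$exon$lengths,
                   ds$counts$library_sizes),
    ds$counts$exon$feature_genes)
  calls <- call_major(ds$tx_fpkm, gene_fpkm, ds$annotation)
  scan <- pairwise_switch_scan(ds$tx_fpkm, gene_fpkm, calls,
                               metadata = ds$metadata)
  expect_setequal(unique(scan$pair_summary$pair_type),
                  c("replicate", "condition"))
  expect_equal(sum(scan$pair_summary$pair_type == "replicate"), 2L)
})
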