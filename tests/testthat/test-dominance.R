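# three-transcript gene G plus single-transcript gene H
dom_ann <- function() {
  toy_annotation(c(
    gtf_rec("chr1", "exon", 1, 400, "+", "G", "T1"),
    gtf_rec("chr1", "exon", 1, 400, "+", "G", "T2"),
    gtf_rec("chr1", "exon", 1, 400, "+", "G", "T3"),
    gtf_rec("chr1", "exon", 1001, 1400, "+", "H", "H1")))
}

test_that("major calls rank by FPKM with lexicographic tie-breaks", {
  ann <- dom_ann()
  gene <- gene_fpkm_tbl(G = 5, H = 7)
  calls <- call_major(
    dplyr::bind_rows(fpkm_tbl(T1 = 10, T2 = 4, T3 = 1), fpkm_tbl(H1 = 7)),
    gene, ann)
  g <- calls[calls$gene_id == "G", ]
  expect_equal(g$major, "T1")
  expect_equal(g$runner_up, "T2")
  expect_equal(g$fold_ratio, 2.5)
  expect_false(g$tie)
  h <- calls[calls$gene_id == "H", ]
  expect_equal(h$major, "H1")
  expect_equal(h$fold_ratio, Inf)

  tied <- call_major(
    dplyr::bind_rows(fpkm_tbl(T1 = 5, T2 = 5, T3 = 0), fpkm_tbl(H1 = 7)),
    gene, ann)
  tg <- tied[tied$gene_id == "G", ]
  expect_equal(tg$major, "T1")   # lexicographically first
  expect_true(tg$tie)
  expect_equal(tg$fold_ratio, 1)
})

test_that("gene gate and all-zero transcripts control which calls exist", {
  ann <- dom_ann()
  fpkm <- dplyr::bind_rows(fpkm_tbl(T1 = 10, T2 = 4, T3 = 1),
                           fpkm_tbl(H1 = 7))
  # G below gate -> only H called
  calls <- call_major(fpkm, gene_fpkm_tbl(G = 0.5, H = 7), ann)
  expect_equal(calls$gene_id, "H")
  # expressed gene with all transcripts at zero -> flagged no-call
  calls2 <- call_major(
    dplyr::bind_rows(fpkm_tbl(T1 = 0, T2 = 0, T3 = 0), fpkm_tbl(H1 = 7)),
    gene_fpkm_tbl(G = 5, H = 7), ann)
  g <- calls2[calls2$gene_id == "G", ]
  expect_true(g$no_call)
  expect_true(is.na(g$major))
})

test_that("x-fold dominance compares the fold ratio to x", {
  expect_true(is_dominant(2.5, 2))
  expect_false(is_dominant(2.5, 5))
  expect_true(is_dominant(Inf, 2) && is_dominant(Inf, 5))
  expect_false(is_dominant(1, 2))
  expect_error(is_dominant(2, 1))
})

test_that("pool fractions are FPKM-mass shares excluding mitochondria", {
  ann <- toy_annotation(c(
    gtf_rec("chr1", "exon", 1, 400, "+", "GA", "A1"),
    gtf_rec("chr1", "exon", 1, 400, "+", "GA", "A2"),
    gtf_rec("chr1", "exon", 1001, 1400, "+", "GB", "B1"),
    gtf_rec("chr1", "exon", 1001, 1400, "+", "GB", "B2"),
    gtf_rec("chrM", "exon", 1, 400, "+", "GM", "M1")))
  fpkm <- fpkm_tbl(A1 = 10, A2 = 2, B1 = 6, B2 = 2, M1 = 1000)
  gene <- gene_fpkm_tbl(GA = 8, GB = 5, GM = 900)
  calls <- call_major(fpkm, gene, ann)
  pf <- pool_fractions(fpkm, calls, ann)
  expect_equal(pf$fraction_major, 16 / 20)  # mito mass ignored entirely
  # A: 10/2 = 5-fold; B: 6/2 = 3-fold (two-fold only)
  expect_equal(pf$fraction_dominant_2x, 16 / 20)
  expect_equal(pf$fraction_dominant_5x, 10 / 20)
  expect_equal(pf$fraction_noncoding_major, 16 / 20)  # toy gene has no CDS

  # single-transcript genes: the majors are the whole pool
  single <- toy_annotation(c(
    gtf_rec("chr1", "exon", 1, 400, "+", "GA", "A1"),
    gtf_rec("chr1", "exon", 1001, 1400, "+", "GB", "B1")))
  sf <- fpkm_tbl(A1 = 3, B1 = 9)
  sp <- pool_fractions(sf, call_major(sf, gene_fpkm_tbl(GA = 3, GB = 9),
                                      single), single)
  expect_equal(sp$fraction_major, 1)
})

test_that("transcripts-per-gene ratio counts strictly above threshold", {
  tx <- fpkm_tbl(T1 = 5, T2 = 3, T3 = 2, H1 = 0.5)
  gene <- gene_fpkm_tbl(G = 4, H = 2)
  out <- transcripts_per_gene_ratio(tx, gene)
  expect_equal(out$ratio, 3 / 2)

  none <- transcripts_per_gene_ratio(
    fpkm_tbl(T1 = 0.5, H1 = 0.2), gene)
  expect_equal(none$ratio, 0)

  one_each <- transcripts_per_gene_ratio(fpkm_tbl(T1 = 5, H1 = 3), gene)
  expect_equal(one_each$ratio, 1)

  expect_warning(
    transcripts_per_gene_ratio(tx, gene_fpkm_tbl(G = 0.5, H = 0.1)),
    "no expressed gene")
})

test_that("threshold sweep counts expressed genes against the study set", {
  ann <- toy_annotation(c(
    gtf_rec("chr1", "exon", 1, 400, "+", "GA", "A1"),
    gtf_rec("chr1", "exon", 1001, 1400, "+", "GB", "B1"),
    gtf_rec("chr1", "exon", 2001, 2400, "+", "GC", "C1")))
  gene <- gene_fpkm_tbl(GA = 0.5, GB = 3, GC = 8)
  tx <- fpkm_tbl(A1 = 0.5, B1 = 3, C1 = 8)
  sw <- threshold_sweep(tx, gene, ann, thresholds = c(1, 5))
  expect_equal(sw$n_expressed, c(2L, 1L))
  expect_equal(sw$pct_study_set, 100 * c(2, 1) / 3)
})

test_that("dominant subsets are nested at every threshold", {
  ds <- simulate_dataset(synthetic_scenario(n_genes = 120, seed = 6,
                                            scenario = "uniform",
                                            dirichlet_alpha = 2))
  gene_fpkm <- gene_expression_from_exons(
    counts_to_fpkm(ds$counts$exon$counts, ds$counts$exon$lengths,
                   ds$counts$library_sizes),
    ds$counts$exon$feature_genes)
  sw <- threshold_sweep(ds$tx_fpkm, gene_fpkm, ds$annotation)
  expect_true(all(sw$n_dominant_5x <= sw$n_dominant_2x))
  expect_true(all(sw$n_dominant_2x <= sw$n_expressed))
  # counts non-increasing in threshold within each sample
  by_sample <- split(sw, sw$sample_id)
  for (d in by_sample) {
    d <- d[order(d$threshold), ]
    expect_true(all(diff(d$n_expressed) <= 0))
    expect_true(all(diff(d$n_dominant_2x) <= 0))
  }
})

test_that("rank-abundance profile summarises per-rank fractions", {
  ann <- dom_ann()
  # constant (0.8, 0.2) genes
  fpkm <- dplyr::bind_rows(fpkm_tbl(T1 = 8, T2 = 2, T3 = 0))
  ra <- relative_abundances(fpkm, ann)
  prof <- rank_abundance_profile(ra)
  expect_equal(prof$median[prof$rank == 1], 0.8)
  expect_equal(prof$median[prof$rank == 2], 0.2)

  single <- rank_abundance_profile(
    relative_abundances(fpkm_tbl(H1 = 4), ann))
  expect_equal(single$median, 1)
})

test_that("rank-1 median of uniform genes matches a sorted-uniform oracle", {
  # pipeline route: uniform Dirichlet(alpha = 1) abundances through the
  # generator and relative_abundances/rank_abundance_profile
  sc <- synthetic_scenario(n_genes = 2000, n_samples = 1,
                           scenario = "uniform", dirichlet_alpha = 1,
                           seed = 13)
  ds <- simulate_dataset(sc)
  prof <- rank_abundance_profile(
    relative_abundances(ds$tx_fpkm, ds$annotation))
  # oracle: direct Monte-Carlo of sorted flat-Dirichlet draws
  withr::with_seed(99, {
    draws <- matrix(stats::rexp(20000 * 4), ncol = 4)
    draws <- draws / rowSums(draws)
    top <- apply(draws, 1, max)
  })
  expect_lt(abs(prof$median[1] - stats::median(top)), 0.02)
})

test_that("TSS-group dominance analyses only multi-transcript groups", {
  # T1,T2 share a TSS; T3 starts elsewhere
  ann <- toy_annotation(c(
    gtf_rec("chr1", "exon", 1, 400, "+", "G", "T1"),
    gtf_rec("chr1", "exon", 1, 300, "+", "G", "T2"),
    gtf_rec("chr1", "exon", 101, 400, "+", "G", "T3")))
  out <- tss_group_dominance(fpkm_tbl(T1 = 9, T2 = 3, T3 = 5),
                             gene_fpkm_tbl(G = 6), ann)
  expect_equal(nrow(out), 1L)  # singleton group excluded
  expect_equal(out$major, "T1")
  expect_equal(out$fold_ratio, 3)
  expect_true(is_dominant(out$fold_ratio, 2))

  # all-singleton genes yield an empty summary
  solo <- toy_annotation(c(
    gtf_rec("chr1", "exon", 1, 400, "+", "G", "T1"),
    gtf_rec("chr1", "exon", 101, 400, "+", "G", "T2")))
  expect_equal(nrow(tss_group_dominance(fpkm_tbl(T1 = 9, T2 = 3),
                                        gene_fpkm_tbl(G = 6), solo)), 0L)
})

test_that("longest-transcript overlap counts majors among multi-tx genes", {
  ann <- toy_annotation(c(
    gtf_rec("chr1", "exon", 1, 800, "+", "GA", "A1"),
    gtf_rec("chr1", "exon", 1, 400, "+", "GA", "A2"),
    gtf_rec("chr1", "exon", 1001, 1800, "+", "GB", "B1"),
    gtf_rec("chr1", "exon", 1001, 1400, "+", "GB", "B2"),
    gtf_rec("chr1", "CDS", 101, 700, "+", "GA", "A1"),
    gtf_rec("chr1", "CDS", 101, 300, "+", "GA", "A2"),
    gtf_rec("chr1", "CDS", 1101, 1700, "+", "GB", "B1"),
    gtf_rec("chr1", "CDS", 1101, 1300, "+", "GB", "B2")))
  fpkm <- fpkm_tbl(A1 = 10, A2 = 2, B1 = 2, B2 = 10)  # GB major is shorter
  calls <- call_major(fpkm, gene_fpkm_tbl(GA = 6, GB = 6), ann)
  st <- longest_overlap_stats(calls, ann)
  expect_equal(st$frac_major_longest, 0.5)
  expect_equal(st$frac_major_longest_cds, 0.5)

  all_long <- call_major(fpkm_tbl(A1 = 10, A2 = 2, B1 = 10, B2 = 2),
                         gene_fpkm_tbl(GA = 6, GB = 6), ann)
  expect_equal(longest_overlap_stats(all_long, ann)$frac_major_longest, 1)
})
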