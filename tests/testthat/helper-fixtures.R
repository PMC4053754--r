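# Fixtures are built in code at test time: GTF text written to tempfiles,
# long expression tibbles assembled by hand.

# One gene, two transcripts (3 and 2 exons) on the + strand.
# T1 exons (1-based GTF): [101,200] [301,400] [501,700] -> lengths 100+100+200
# T2 exons:               [101,200] [501,700]           -> lengths 100+200
toy_gtf_lines <- function() {
  a <- function(g, t, gb = "protein_coding", tb = gb) {
    sprintf('gene_id "%s"; transcript_id "%s"; gene_type "%s"; transcript_type "%s";',
            g, t, gb, tb)
  }
  c(
    paste("chr1\ttest\texon\t101\t200\t.\t+\t.", a("G1", "T1"), sep = "\t"),
    paste("chr1\ttest\texon\t301\t400\t.\t+\t.", a("G1", "T1"), sep = "\t"),
    paste("chr1\ttest\texon\t501\t700\t.\t+\t.", a("G1", "T1"), sep = "\t"),
    paste("chr1\ttest\tCDS\t321\t400\t.\t+\t0", a("G1", "T1"), sep = "\t"),
    paste("chr1\ttest\texon\t101\t200\t.\t+\t.", a("G1", "T2"), sep = "\t"),
    paste("chr1\ttest\texon\t501\t700\t.\t+\t.", a("G1", "T2"), sep = "\t")
  )
}

toy_gtf <- function(lines = toy_gtf_lines()) {
  path <- withr::local_tempfile(fileext = ".gtf",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

toy_annotation <- function(lines = toy_gtf_lines()) {
  read_gtf(toy_gtf(lines))
}

# GTF record helper for building multi-gene fixtures
gtf_rec <- function(chrom, type, start1, end1, strand, gene, tx = NULL,
                    gene_bio = "protein_coding", tx_bio = gene_bio) {
  attrs <- sprintf('gene_id "%s";', gene)
  if (!is.null(tx)) {
    attrs <- paste(attrs, sprintf('transcript_id "%s";', tx))
  }
  attrs <- paste(attrs, sprintf('gene_type "%s";', gene_bio))
  if (!is.null(tx)) {
    attrs <- paste(attrs, sprintf('transcript_type "%s";', tx_bio))
  }
  sprintf("%s\ttest\t%s\t%d\t%d\t.\t%s\t.\t%s", chrom, type, start1, end1,
          strand, attrs)
}

# long-format expression helper
fpkm_tbl <- function(..., sample_id = "S1") {
  v <- c(...)
  tibble::tibble(transcript_id = names(v), sample_id = sample_id,
                 fpkm = unname(v))
}

gene_fpkm_tbl <- function(..., sample_id = "S1") {
  v <- c(...)
  tibble::tibble(gene_id = names(v), sample_id = sample_id,
                 fpkm = unname(v))
}

# minimal annotation straight from a flat feature table (internal builder),
# for tests that need many genes without GTF round trips
flat_annotation <- function(feat) {
  txdominance:::build_annotation(feat)
}

single_tx_annotation <- function(gene_ids, tx_len = 1000L) {
  n <- length(gene_ids)
  flat_annotation(tibble::tibble(
    type = "exon", chrom = "chr1",
    start = (seq_len(n) - 1L) * (tx_len + 100L),
    end = (seq_len(n) - 1L) * (tx_len + 100L) + tx_len,
    strand = "+", gene_id = gene_ids,
    transcript_id = paste0(gene_ids, ".1"),
    gene_biotype = "protein_coding", tx_biotype = "protein_coding"))
}
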