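sam_line <- function(qname, flag, rname, pos, cigar, seq = "*") {
  paste(qname, flag, rname, pos, 60, cigar, "*", 0, 0, seq, "*", sep = "\t")
}
hdr <- c("@HD\tVN:1.6",
         "@SQ\tSN:locA\tLN:300", "@SQ\tSN:locB\tLN:200")
ann <- locus_annotation(c("locA", "locB"), c(300L, 200L))

test_that("SAM ingestion yields one record per read-locus pair with aggregated locus hits", {
  rec <- read_alignments(c(hdr, sam_line("r1", 0, "locA", 1, "50M")))
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$read_length, 50L)
  expect_equal(rec$aligned_span, 50L)
  expect_false(rec$is_clipped)
  expect_equal(rec$n_loci_hit, 1L)

  # two alignment lines to two loci: both records carry n_loci_hit = 2
  rec2 <- read_alignments(c(hdr,
                            sam_line("r2", 0, "locA", 1, "50M"),
                            sam_line("r2", 256, "locB", 1, "50M")))
  expect_equal(nrow(rec2), 2L)
  expect_equal(rec2$n_loci_hit, c(2L, 2L))

  # repeated alignment to the SAME locus collapses to one record, one hit
  rec3 <- read_alignments(c(hdr,
                            sam_line("r3", 0, "locA", 1, "50M"),
                            sam_line("r3", 256, "locA", 40, "50M")))
  expect_equal(nrow(rec3), 1L)
  expect_equal(rec3$n_loci_hit, 1L)

  # unmapped records are dropped
  rec4 <- read_alignments(c(hdr, sam_line("r4", 4, "*", 0, "*")))
  expect_equal(nrow(rec4), 0L)

  # paired mates are independent reads
  rec5 <- read_alignments(c(hdr,
                            sam_line("p1", 0 + 1 + 64, "locA", 1, "50M"),
                            sam_line("p1", 0 + 1 + 128, "locB", 1, "50M")))
  expect_equal(sort(rec5$read_id), c("p1/1", "p1/2"))
  expect_equal(rec5$n_loci_hit, c(1L, 1L))
})

test_that("malformed SAM and unknown references are hard errors naming the cause", {
  expect_error(read_alignments(c(hdr, "r1\t0\tlocA")), "line 4")
  expect_error(read_alignments(c(hdr, sam_line("r1", 0, "locX", 1, "50M")),
                               annotation = ann), "locX")
})

test_that("the entire-length single-locus filter keeps exactly the clean reads", {
  rec <- read_alignments(c(
    hdr,
    sam_line("clean", 0, "locA", 1, "50M"),
    sam_line("soft", 0, "locA", 1, "45M5S"),
    sam_line("hard", 0, "locA", 1, "48M2H"),
    sam_line("indel", 0, "locA", 1, "20M2I28M"),   # 2 inserted bases
    sam_line("del", 0, "locA", 1, "25M3D25M"),     # deletion: span == length
    sam_line("multi", 0, "locA", 1, "50M"),
    sam_line("multi", 256, "locB", 1, "50M")))
  kept <- filter_full_single_locus(rec)
  # deletions keep all read bases matched, so "del" passes the strict filter
  expect_setequal(kept$read_id, c("clean", "del"))
  # soft-clip is not mapped in its entire length
  expect_false("soft" %in% kept$read_id)
  # idempotence
  expect_identical(filter_full_single_locus(kept), kept)
})

test_that("base counting sums read lengths per locus, zeros included", {
  rec <- read_alignments(c(hdr,
                           sam_line("r1", 0, "locA", 1, "50M"),
                           sam_line("r2", 0, "locA", 100, "50M")))
  tab <- count_base_coverage(filter_full_single_locus(rec), ann)
  expect_equal(tab$raw_bases[tab$locus_tag == "locA"], 100)
  expect_equal(tab$raw_bases[tab$locus_tag == "locB"], 0)
  expect_equal(total_bases(tab), 100)
  expect_error(count_base_coverage(
    data.frame(read_id = "x", target_locus = "locZ", read_length = 50L,
               aligned_span = 50L, n_loci_hit = 1L, is_clipped = FALSE),
    ann), "locZ")
})

test_that("normalization follows raw/(length*total)*scale and conserves the scale constant", {
  tab <- structure(
    data.frame(locus_tag = c("g1", "g2"), raw_bases = c(5000, 5000),
               length = c(1000L, 500L), stringsAsFactors = FALSE),
    total_bases = 10000, class = c("coverage_table", "data.frame"))
  norm <- normalize_coverage(tab, 1e9)
  expect_equal(unname(norm), c(5e5, 1e6))

  # single locus carrying all bases: norm = scale / length
  tab1 <- structure(
    data.frame(locus_tag = "g1", raw_bases = 777, length = 350L),
    total_bases = 777, class = c("coverage_table", "data.frame"))
  expect_equal(unname(normalize_coverage(tab1, 1e9)), 1e9 / 350)

  # scale invariance: doubling all raw bases doubles the total too
  tab2 <- tab
  tab2$raw_bases <- tab$raw_bases * 2
  attr(tab2, "total_bases") <- 20000
  expect_equal(normalize_coverage(tab2, 1e9), norm)

  # conservation: sum(norm * length) == scale_constant, random tables
  set.seed(11)
  for (i in 1:10) {
    nl <- sample(3:30, 1)
    rt <- structure(
      data.frame(locus_tag = sprintf("g%d", 1:nl),
                 raw_bases = sample(0:5000, nl, replace = TRUE),
                 length = sample(100:3000, nl, replace = TRUE)),
      class = c("coverage_table", "data.frame"))
    attr(rt, "total_bases") <- sum(rt$raw_bases)
    nv <- normalize_coverage(rt, 1e9)
    expect_equal(sum(nv * rt$length), 1e9, tolerance = 1e-9)
  }

  attr(tab, "total_bases") <- 0
  tab$raw_bases <- c(0, 0)
  expect_error(normalize_coverage(tab), "empty experiment")
})

test_that("log2 transformation drops zero-coverage loci", {
  v <- to_expression_vector(c(a = 1e6, b = 0, c = 4))
  expect_equal(unname(v["a"]), 19.9316, tolerance = 1e-4)
  expect_equal(unname(v["c"]), 2)
  expect_false("b" %in% names(v))
  expect_equal(attr(v, "n_genes"), 2L)

  empty <- to_expression_vector(c(a = 0, b = 0))
  expect_equal(length(empty), 0L)
  expect_equal(attr(empty, "n_genes"), 0L)
})

test_that("RPKM follows reads*1e9/(length*total_reads)", {
  ann1 <- locus_annotation(c("g1", "g2"), c(1000L, 500L))
  rpkm <- compute_rpkm(c(g1 = 100), ann1, total_reads = 1e6)
  expect_equal(unname(rpkm["g1"]), 100)
  expect_equal(unname(rpkm["g2"]), 0)
  expect_error(compute_rpkm(c(g1 = 0), ann1, total_reads = 0),
               "empty experiment")
})

test_that("annotation readers accept FASTA and TSV and enforce invariants", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">g1 some description", "ACGTACGTAC", ">g2", "ACGT"), fa)
  a <- read_locus_annotation(fa)
  expect_equal(a$locus_tag, c("g1", "g2"))
  expect_equal(a$length, c(10L, 4L))

  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("locus_tag\tlength", "g1\t10", "g2\t4"), tsv)
  expect_equal(read_locus_annotation(tsv), a)

  expect_error(locus_annotation(c("g1", "g1"), c(10L, 4L)), "duplicate")
  expect_error(locus_annotation("g1", 0L), ">= 1")
})
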