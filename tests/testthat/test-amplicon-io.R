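test_that("parse_panel reads BED, derives gene/length and sorts", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr17\t2000\t2100\tTP53_ex5\t0.4",
               "chr17\t1000\t1185\tERBB2_ex20\t0.5",
               "chr2\t500\t600\tALK_ex1\t0.6"), bed)
  p <- parse_panel(bed, gc_column = 5)
  expect_s3_class(p, "amplicon_panel")
  expect_equal(p$chrom, c("chr17", "chr17", "chr2"))  # sorted by position
  expect_equal(p$gene, c("ERBB2", "TP53", "ALK"))
  expect_equal(p$length[1], 185)
  expect_equal(p$gc[1], 0.5)
  expect_equal(p$id, 1:3)
})

test_that("parse_panel computes GC from a reference FASTA", {
  skip_if_not_installed("Biostrings")
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr1", paste(rep("ACGT", 50), collapse = "")), fa)
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t0\t4\tG1_a", bed)
  p <- parse_panel(bed, reference = fa)
  expect_equal(p$gc, 0.5)  # "ACGT"
})

test_that("parse_panel errors are informative", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200\tG1_a", bed)
  expect_error(parse_panel(bed), "no GC provenance")
  writeLines("chr1\t300\t200\tG1_a\t0.5", bed)
  expect_error(parse_panel(bed, gc_column = 5), "start >= end")
})

test_that("merge_overlapping applies the reciprocal >75% rule", {
  # 90% reciprocal overlap: merged into the union interval
  p <- amplicon_panel(c("chr1", "chr1"), c(100, 110), c(200, 210),
                      c("A", "A"), 0.5)
  m <- merge_overlapping(p)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(100, 210))
  # 40% overlap: untouched
  p2 <- amplicon_panel(c("chr1", "chr1"), c(100, 160), c(200, 260),
                       c("A", "B"), 0.5)
  expect_equal(nrow(merge_overlapping(p2)), 2)
  # differing genes concatenated
  p3 <- amplicon_panel(c("chr1", "chr1"), c(100, 110), c(200, 210),
                       c("A", "B"), 0.5)
  expect_equal(merge_overlapping(p3)$gene, "A,B")
})

test_that("merge_overlapping matches the pairwise fixed-point oracle", {
  set.seed(11)
  for (rep in 1:40) {
    n <- sample(2:5, 1)
    start <- sort(sample(0:80, n))
    len <- sample(40:120, n, replace = TRUE)
    p <- amplicon_panel(rep("chr1", n), start, start + len,
                        paste0("G", seq_len(n)), 0.5)
    got <- merge_overlapping(p)
    want <- oracle_merge(as.data.frame(p))
    expect_equal(got[, c("chrom", "start", "end")], want,
                 ignore_attr = TRUE)
    # idempotence
    again <- merge_overlapping(got)
    expect_equal(as.data.frame(again), as.data.frame(got))
  }
})

test_that("assign_read picks the maximum-overlap amplicon", {
  p <- amplicon_panel(c("chr1", "chr1"), c(100, 240), c(200, 400),
                      c("A", "B"), 0.5)
  expect_equal(assign_read("chr1", 150, 250, p), 1L)  # 50 vs 10 bp
  expect_true(is.na(assign_read("chr1", 500, 600, p)))
  # tie: 50 bp with both -> smaller start
  p2 <- amplicon_panel(c("chr1", "chr1"), c(100, 200), c(200, 300),
                       c("A", "B"), 0.5)
  expect_equal(assign_read("chr1", 150, 250, p2), 1L)
})

test_that("count_reads keeps duplicates and matches a per-read oracle", {
  p <- amplicon_panel(c("chr1", "chr1"), c(0, 200), c(100, 300),
                      c("A", "B"), 0.5)
  cnt <- count_reads(rep("chr1", 3), c(10, 20, 30), c(90, 95, 99), p)
  expect_equal(as.integer(cnt), c(3L, 0L))
  # a read repeated (duplicate) still counts: identical spans count twice
  cnt2 <- count_reads(rep("chr1", 4), c(10, 20, 30, 10), c(90, 95, 99, 90), p)
  expect_equal(as.integer(cnt2), c(4L, 0L))
  expect_warning(count_reads(character(0), integer(0), integer(0), p),
                 "empty alignment")
  # 10,000 random reads vs brute-force assignment
  set.seed(3)
  panel <- toy_panel(n = 12)
  rs <- sample(0:1800, 10000, replace = TRUE)
  re <- rs + sample(50:150, 10000, replace = TRUE)
  got <- count_reads(rep("chr1", 10000), rs, re, panel)
  want <- tabulate(oracle_assign(rep("chr1", 10000), rs, re, panel),
                   nbins = nrow(panel))
  expect_equal(as.integer(got), want)
  expect_equal(sum(got) + attr(got, "n_unassigned"), 10000)
})

test_that("assignment is order-independent", {
  set.seed(4)
  panel <- toy_panel(n = 6)
  rs <- sample(0:800, 200, replace = TRUE); re <- rs + 80
  a <- assign_reads(rep("chr1", 200), rs, re, panel)
  o <- sample(200)
  b <- assign_reads(rep("chr1", 200), rs[o], re[o], panel)
  expect_equal(a[o], b)
})

test_that("count tables round-trip losslessly", {
  panel <- toy_panel(n = 8)
  set.seed(9)
  counts <- matrix(rpois(16, 500), 8, 2,
                   dimnames = list(NULL, c("s1", "s2")))
  cm <- count_matrix(panel, counts, total_reads = c(s1 = 5000, s2 = 5000))
  path <- tempfile(fileext = ".tsv")
  write_count_table(cm, path)
  back <- read_count_table(path)
  expect_identical(back$counts, cm$counts)
  expect_equal(back$total_reads, cm$total_reads)
  expect_equal(as.data.frame(back$panel), as.data.frame(cm$panel))
})

test_that("SAM alignments are counted per amplicon", {
  skip_if_not_installed("Rsamtools")
  panel <- amplicon_panel(c("chr1", "chr1"), c(100, 300), c(200, 400),
                          c("A", "B"), 0.5)
  sam <- tempfile(fileext = ".sam")
  # reads: two in A (one a flagged duplicate), one in B, one unmapped,
  # one secondary (ignored)
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:1000",
    "r1\t0\tchr1\t101\t60\t50M\t*\t0\t0\t*\t*",
    "r2\t1024\tchr1\t111\t60\t50M\t*\t0\t0\t*\t*",
    "r3\t256\tchr1\t121\t60\t50M\t*\t0\t0\t*\t*",
    "r4\t0\tchr1\t301\t60\t50M\t*\t0\t0\t*\t*",
    "r5\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*"), sam)
  aln <- read_sam_alignments(sam)
  expect_equal(nrow(aln), 3)  # r1, r2 (duplicate kept), r4
  cnt <- count_reads(aln$chrom, aln$start, aln$end, panel)
  expect_equal(as.integer(cnt), c(2L, 1L))
})
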