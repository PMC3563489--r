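test_that("GFF3 records are converted to 0-based half-open coordinates", {
  path <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr\tsrc\tCDS\t1\t100\t.\t+\t.\tID=g1",
    "chr\tsrc\trRNA\t201\t300\t.\t-\t.\tID=r1",
    "chr\tsrc\trRNA\t401\t500\t.\t-\t.\tID=r2",
    "chr\tsrc\tCDS\t601\t700\t.\t+\t.\tID=g2",
    "chr\tsrc\tCDS\t801\t900\t.\t+\t.\tID=g3",
    "chr\tsrc\ttRNA\t950\t1000\t.\t+\t.\tID=t1"), path)
  ann <- read_gff(path)
  expect_equal(nrow(ann), 6)
  expect_equal(ann$start[ann$feature_id == "g1"], 0)
  expect_equal(ann$end[ann$feature_id == "g1"], 100)
  expect_equal(as.integer(table(ann$category)[c("CDS", "rRNA", "other")]),
               c(3L, 2L, 1L))

  # duplicate identifiers are rejected with the offending line
  writeLines(c("chr\tsrc\tCDS\t1\t10\t.\t+\t.\tID=dup",
               "chr\tsrc\tCDS\t21\t30\t.\t+\t.\tID=dup"), path)
  expect_error(read_gff(path), "duplicate feature_id 'dup' at GFF3 line 2")

  # malformed records carry their line number
  writeLines(c("##gff-version 3", "chr\tonly-two-fields"), path)
  expect_error(read_gff(path), "line 2")
  writeLines("chr\tsrc\tCDS\t0\t10\t.\t+\t.\tID=x", path)
  expect_error(read_gff(path), "invalid coordinates")
})

test_that("annotations round-trip through GFF3", {
  cfg <- small_cfg(seed = 31)
  set.seed(31)
  ann <- generate_annotation(cfg)
  path <- tempfile(fileext = ".gff3")
  write_gff3(ann, path)
  back <- read_gff(path)
  expect_equal(back$feature_id, ann$feature_id)
  expect_equal(back$start, ann$start)
  expect_equal(back$end, ann$end)
  expect_equal(back$category, ann$category)
  expect_equal(attr(back, "contig_length"), cfg$contig_length)
})

test_that("SAM text and the TSV fixture format parse to the same alignments", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6",
    "@SQ\tSN:chr\tLN:10000",
    "r1\t0\tchr\t101\t60\t48M\t*\t0\t0\t*\t*",
    "r2\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*",
    "r3\t256\tchr\t501\t60\t48M\t*\t0\t0\t*\t*",   # secondary: dropped
    "r4\t0\tchr\t201\t60\t10M5D10M\t*\t0\t0\t*\t*"), sam)
  al <- read_alignments(sam, "sam")
  expect_equal(nrow(al), 3)  # secondary gone
  expect_equal(al$start[al$read_id == "r1"], 100)
  expect_equal(al$end[al$read_id == "r1"], 148)
  expect_false(al$mapped[al$read_id == "r2"])
  # CIGAR reference span includes deletions
  expect_equal(al$end[al$read_id == "r4"] - al$start[al$read_id == "r4"], 25)

  # empty SAM yields an empty stream and zero counts downstream
  writeLines("@HD\tVN:1.6", sam)
  empty <- read_alignments(sam, "sam")
  expect_equal(nrow(empty), 0)
  cl <- classify_reads(empty, toy_annotation(), "empty")
  expect_equal(cl$counts$mapped_reads, 0)

  # TSV fixture round trip
  reads <- toy_reads(c(100, 4500), c(148, 4548))
  tsv <- tempfile(fileext = ".tsv")
  write_alignments_tsv(reads, tsv)
  back <- read_alignments(tsv, "tsv")
  expect_equal(back$start, reads$start)
  expect_equal(back$mapped, c(TRUE, TRUE))

  # SAM writer round trip
  sam2 <- tempfile(fileext = ".sam")
  write_sam(reads, sam2, contig_lengths = c(chr = 10000))
  back2 <- read_alignments(sam2, "sam")
  expect_equal(back2$start, reads$start)
  expect_equal(back2$end, reads$end)
})

test_that("reads are classified by containment, priority and overlap", {
  ann <- toy_annotation()
  # containment: rRNA, CDS, intergenic
  reads <- toy_reads(c(1100, 4500, 7000), c(1148, 4548, 7048))
  cl <- classify_reads(reads, ann, "toy")
  expect_equal(cl$counts$reads_rrna, 1)
  expect_equal(cl$counts$reads_cds, 1)
  expect_equal(cl$counts$reads_intergenic, 1)
  expect_equal(unname(cl$cds_counts["cds1"]), 1L)

  # a read overlapping rRNA by 10 bp and intergenic for the rest is rRNA
  edge <- classify_reads(toy_reads(2490, 2538), ann, "edge")
  expect_equal(edge$counts$reads_rrna, 1)

  # priority rRNA > CDS for a read touching both
  both <- toy_reads(c(2400), c(4100))
  pr <- classify_reads(both, ann, "pr")
  expect_equal(pr$counts$reads_rrna, 1)
  expect_equal(pr$counts$reads_cds, 0)

  # unmapped reads are excluded from classification
  mix <- toy_reads(c(1100, 0), c(1148, 0), mapped = c(TRUE, FALSE))
  mx <- classify_reads(mix, ann, "mx")
  expect_equal(mx$counts$total_reads, 2)
  expect_equal(mx$counts$mapped_reads, 1)

  # unknown contig: warning, counted intergenic
  expect_warning(
    un <- classify_reads(toy_reads(10, 58, contig = "plasmid"), ann, "un"),
    "absent from the annotation")
  expect_equal(un$counts$reads_intergenic, 1)

  # categories partition mapped reads and order does not matter
  set.seed(41)
  cfg <- small_cfg(seed = 41)
  ann2 <- generate_annotation(cfg)
  prof <- simulate_abundances(cfg, ann2)
  rr <- sample_reads(prof, ann2, 2e4)
  c1 <- classify_reads(rr, ann2, "s")
  with(c1$counts, expect_equal(reads_rrna + reads_cds + reads_other +
                                 reads_intergenic, mapped_reads))
  shuffled <- rr[rev(seq_len(nrow(rr))), ]
  c2 <- classify_reads(shuffled, ann2, "s")
  expect_equal(c1$counts$reads_rrna, c2$counts$reads_rrna)
  expect_equal(c1$cds_counts, c2$cds_counts)
})

test_that("tabulation averages replicate percentages arithmetically", {
  mk <- function(id, pr, pm, pi) {
    n <- 1e6
    category_counts(id, n, n, round(n * pr / 100), round(n * pm / 100),
                    0, n - round(n * pr / 100) - round(n * pm / 100))
  }
  ov1 <- mk("ov1", 52.48, 41.15, 6.37)
  ov2 <- mk("ov2", 70.13, 24.51, 5.37)
  mo1 <- mk("mo1", 62.57, 30.04, 7.39)
  mo2 <- mk("mo2", 45.73, 46.11, 8.16)
  tab <- tabulate_samples(list(ov1, ov2, mo1, mo2),
                          treatment = c("Ov", "Ov", "Mex-Ov", "Mex-Ov"))
  expect_equal(tab$treatments$pct_rrna[tab$treatments$treatment == "Ov"],
               61.305, tolerance = 1e-4)
  expect_equal(
    tab$treatments$pct_intergenic[tab$treatments$treatment == "Mex-Ov"],
    7.775, tolerance = 1e-4)
  # single replicate: the mean is the replicate itself
  single <- tabulate_samples(list(ov1), treatment = "Ov")
  expect_equal(single$treatments$pct_rrna, single$samples$pct_rrna)
  # percentages recomputed from integer counts agree to 0.01
  expect_equal(ov1$pct_rrna, 52.48, tolerance = 0.01)
  expect_equal(ov1$pct_mrna, 41.15, tolerance = 0.01)
})

test_that("category counts enforce their partition invariant", {
  expect_error(category_counts("x", 10, 10, 5, 5, 5, 5),
               "partition mapped_reads")
  expect_error(category_counts("x", 5, 10, 5, 5, 0, 0),
               "cannot exceed total_reads")
  cc <- category_counts("x", 10, 8, 4, 2, 1, 1)
  expect_equal(cc$pct_rrna + cc$pct_mrna + cc$pct_intergenic +
                 100 * cc$reads_other / cc$mapped_reads, 100)
})
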