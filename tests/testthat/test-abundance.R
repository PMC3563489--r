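test_that("RPKM follows its defining formula", {
  expect_equal(unname(rpkm(c(g = 10), c(g = 1000), 1e6)["g"]), 10)
  # scale invariance: counts and depth scaled together cancel
  counts <- c(a = 3, b = 60, c = 0)
  len <- c(a = 300, b = 1200, c = 900)
  expect_equal(as.numeric(rpkm(counts * 7, len, 7e5)),
               as.numeric(rpkm(counts, len, 1e5)))
  # hand-computed oracle for a 5-gene column
  counts5 <- c(g1 = 10, g2 = 0, g3 = 250, g4 = 4, g5 = 33)
  len5 <- c(g1 = 500, g2 = 800, g3 = 2500, g4 = 400, g5 = 1100)
  by_hand <- c(10 * 1e9 / (500 * 2e6), 0, 250 * 1e9 / (2500 * 2e6),
               4 * 1e9 / (400 * 2e6), 33 * 1e9 / (1100 * 2e6))
  expect_equal(as.numeric(rpkm(counts5, len5, 2e6)), by_hand)
  expect_error(rpkm(counts5, len5, 0), "denominator_reads")
})

test_that("log-log correlation identifies identity, doubling and sign", {
  a <- c(g1 = 1, g2 = 10, g3 = 100, g4 = 1000)
  self <- log_correlation(a, a)
  expect_equal(self$r, 1, tolerance = 1e-12)
  expect_equal(self$slope, 1, tolerance = 1e-12)

  sq <- log_correlation(a, a^2)
  expect_equal(sq$r, 1, tolerance = 1e-12)
  expect_equal(sq$slope, 2, tolerance = 1e-12)

  # r is symmetric, the regression slope is not
  b <- c(g1 = 2, g2 = 8, g3 = 300, g4 = 900)
  ab <- log_correlation(a, b); ba <- log_correlation(b, a)
  expect_equal(ab$r, ba$r, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(ab$slope, ba$slope)))

  # anti-ordered profiles anticorrelate
  expect_lt(log_correlation(a, rev(unname(a)) |> setNames(names(a)))$r, 0)

  # zero handling: zeros are excluded and reported
  z <- c(g1 = 0, g2 = 10, g3 = 100, g4 = 1000)
  res <- log_correlation(a, z)
  expect_equal(res$n_genes, 3)
  expect_equal(res$n_excluded, 1)
  expect_error(log_correlation(a[1:2], a[1:2]), "fewer than 3")
})

test_that("compression is recovered as a flattened regression slope", {
  cfg <- small_cfg(seed = 61)
  set.seed(61)
  ann <- generate_annotation(cfg)
  prof <- simulate_abundances(cfg, ann)
  flat <- apply_treatment(prof, treatment_model(1, 0, 0.5, "half"))
  cds <- prof$category == "CDS"
  a <- setNames(prof$weight[cds], prof$feature_id[cds])
  b <- setNames(flat$weight[cds], flat$feature_id[cds])
  # noise-free: the power law is exact on the log scale
  exact <- log_correlation(a, b)
  expect_equal(exact$slope, 0.5, tolerance = 1e-9)
  expect_equal(exact$r, 1, tolerance = 1e-9)

  # with read sampling the slope estimate stays close to gamma; genes of
  # equal length isolate the compression from the length normalisation
  # (length spread is shared by both RPKM axes but is not compressed)
  cfg <- small_cfg(seed = 63, cds_length_range = c(900, 900))
  set.seed(63)
  ann <- generate_annotation(cfg)
  prof <- simulate_abundances(cfg, ann)
  flat <- apply_treatment(prof, treatment_model(1, 0, 0.5, "half"))
  ctrl <- classify_reads(sample_reads(prof, ann, 3e5), ann, "c")
  trt <- classify_reads(sample_reads(flat, ann, 3e5), ann, "t")
  len <- setNames(ann$end - ann$start, ann$feature_id)
  keep <- names(ctrl$cds_counts)[ctrl$cds_counts >= 20]
  noisy <- log_correlation(rpkm(ctrl$cds_counts, len, ctrl$counts$mapped_reads),
                           rpkm(trt$cds_counts, len, trt$counts$mapped_reads),
                           subset = keep)
  # counting noise on the reference axis attenuates an OLS slope slightly
  expect_lt(abs(noisy$slope - 0.5), 0.1)
})

test_that("technical replicates reproduce above 0.99", {
  cfg <- small_cfg(seed = 62, rrna_read_fraction = 0.5)
  set.seed(62)
  ann <- generate_annotation(cfg)
  prof <- simulate_abundances(cfg, ann)
  r1 <- classify_reads(sample_reads(prof, ann, 1e6), ann, "r1")
  r2 <- classify_reads(sample_reads(prof, ann, 1e6), ann, "r2")
  len <- setNames(ann$end - ann$start, ann$feature_id)
  p1 <- rpkm(r1$cds_counts, len, r1$counts$mapped_reads)
  p2 <- rpkm(r2$cds_counts, len, r2$counts$mapped_reads)
  rep_r <- replicate_reproducibility(p1, p2, counts1 = r1$cds_counts,
                                     dth = 20)
  expect_gt(rep_r$r, 0.99)
  # identical replicates are perfectly correlated
  expect_equal(replicate_reproducibility(p1, p1)$r, 1, tolerance = 1e-12)
})
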