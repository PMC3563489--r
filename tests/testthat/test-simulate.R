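test_that("generated annotations have the requested composition and layout", {
  cfg <- sim_config(contig_length = 5e5, n_cds = 100, n_rrna_operons = 3,
                    rrna_gene_lengths = c(2900, 1500, 120), seed = 1)
  set.seed(1)
  ann <- generate_annotation(cfg)
  expect_equal(sum(ann$category == "CDS"), 100)
  expect_equal(sum(ann$category == "rRNA"), 9)
  # pairwise disjoint and sorted by start
  expect_true(all(diff(ann$start) > 0))
  expect_true(all(ann$start[-1] >= ann$end[-nrow(ann)]))
  expect_true(all(ann$end - ann$start > 0))
  expect_true(all(ann$end <= cfg$contig_length))

  # degenerate config: no CDS at all
  set.seed(2)
  only_rrna <- generate_annotation(sim_config(contig_length = 5e4, n_cds = 0,
                                              seed = 2))
  expect_true(all(only_rrna$category == "rRNA"))

  # determinism under a repeated seed
  set.seed(99); a1 <- generate_annotation(cfg)
  set.seed(99); a2 <- generate_annotation(cfg)
  expect_identical(a1, a2)

  # capacity error when features cannot fit
  expect_error(generate_annotation(sim_config(contig_length = 1e4,
                                              n_cds = 100, seed = 1)),
               "cannot place features")
})

test_that("abundance profiles are normalised with the requested pool shares", {
  cfg <- sim_config(contig_length = 5e5, n_cds = 100,
                    rrna_read_fraction = 0.99,
                    intergenic_read_fraction = 0.005, seed = 3)
  set.seed(3)
  ann <- generate_annotation(cfg)
  prof <- simulate_abundances(cfg, ann)
  expect_equal(sum(prof$weight), 1, tolerance = 1e-12)
  expect_equal(sum(prof$weight[prof$category == "rRNA"]), 0.99,
               tolerance = 1e-9)
  expect_equal(prof$weight[prof$category == "intergenic"], 0.005,
               tolerance = 1e-9)

  # zero spread makes all CDS weights equal
  cfg0 <- sim_config(contig_length = 5e5, n_cds = 50, expr_log_sd = 0,
                     seed = 4)
  set.seed(4)
  prof0 <- simulate_abundances(cfg0, generate_annotation(cfg0))
  w <- prof0$weight[prof0$category == "CDS"]
  expect_equal(max(w) - min(w), 0, tolerance = 1e-15)

  # rRNA requested but absent from the annotation
  cfg_no <- sim_config(contig_length = 5e4, n_cds = 10, n_rrna_operons = 0,
                       seed = 5)
  set.seed(5)
  ann_no <- generate_annotation(cfg_no)
  expect_error(simulate_abundances(cfg_no, ann_no), "no rRNA feature")
})

test_that("sampling from a profile reproduces its category shares", {
  cfg <- sim_config(contig_length = 5e5, n_cds = 100,
                    rrna_read_fraction = 0.99,
                    intergenic_read_fraction = 0.005, seed = 6)
  set.seed(6)
  ann <- generate_annotation(cfg)
  prof <- simulate_abundances(cfg, ann)
  n <- 1e6
  reads <- sample_reads(prof, ann, n)
  cc <- attr(reads, "category_counts")
  # binomial sampling oracle: observed rRNA share within 3 SD of 0.99
  sd3 <- 3 * sqrt(0.99 * 0.01 / n)
  expect_lt(abs(cc[["rrna"]] / n - 0.99), sd3)
  expect_equal(sum(cc), n)
  expect_equal(sum(attr(reads, "feature_counts")), n)

  # empty draw
  empty <- sample_reads(prof, ann, 0)
  expect_equal(nrow(empty), 0)

  # determinism
  set.seed(10); r1 <- sample_reads(prof, ann, 1000)
  set.seed(10); r2 <- sample_reads(prof, ann, 1000)
  expect_identical(r1, r2)

  # every read lies inside the contig and has positive span
  expect_true(all(reads$start >= 0 & reads$end <= cfg$contig_length))
  expect_true(all(reads$end > reads$start))
})

test_that("treatment models transform profiles as specified", {
  cfg <- small_cfg(seed = 7)
  set.seed(7)
  ann <- generate_annotation(cfg)
  prof <- simulate_abundances(cfg, ann)

  # identity parameters are a fixed point
  ident <- apply_treatment(prof, treatment_model(1, 0, 1, "id"))
  expect_equal(ident$weight, prof$weight, tolerance = 1e-12)
  expect_equal(sum(ident$weight), 1, tolerance = 1e-9)

  # closed-form renormalisation: 0.99 rRNA, retention 0.01, no bias
  cfg2 <- sim_config(contig_length = 5e5, n_cds = 100,
                     rrna_read_fraction = 0.99,
                     intergenic_read_fraction = 0, seed = 8)
  set.seed(8)
  ann2 <- generate_annotation(cfg2)
  prof2 <- simulate_abundances(cfg2, ann2)
  dep <- apply_treatment(prof2, treatment_model(0.01, 0, 1, "dep"))
  expect_equal(sum(dep$weight[dep$category == "rRNA"]),
               0.0099 / (0.0099 + 0.01), tolerance = 1e-9)

  # gamma -> 0 limit with no bias equalises mRNA weights
  flat <- apply_treatment(prof, treatment_model(1, 0, 1e-9, "flat"))
  wm <- flat$weight[flat$category == "CDS"]
  expect_lt(diff(range(wm)) / mean(wm), 1e-6)

  # profiles stay normalised after treatment
  set.seed(9)
  tr <- apply_treatment(prof, treatment_model(0.02, 0.35, 0.8, "sel"))
  expect_equal(sum(tr$weight), 1, tolerance = 1e-9)
  expect_true(all(tr$weight >= 0))
})

test_that("stronger mRNA bias degrades downstream log-RPKM correlation", {
  r_for_sd <- function(bias_sd, seed) {
    cfg <- small_cfg(seed = seed, rrna_read_fraction = 0.5,
                     intergenic_read_fraction = 0.02)
    set.seed(seed)
    ann <- generate_annotation(cfg)
    prof <- simulate_abundances(cfg, ann)
    treated <- apply_treatment(prof, treatment_model(1, bias_sd, 1, "b"))
    ctrl_reads <- sample_reads(prof, ann, 5e4)
    trt_reads <- sample_reads(treated, ann, 5e4)
    ctrl <- classify_reads(ctrl_reads, ann, "ctrl")
    trt <- classify_reads(trt_reads, ann, "trt")
    len <- setNames(ann$end - ann$start, ann$feature_id)
    a <- rpkm(ctrl$cds_counts, len, ctrl$counts$mapped_reads)
    b <- rpkm(trt$cds_counts, len, trt$counts$mapped_reads)
    keep <- names(ctrl$cds_counts)[ctrl$cds_counts >= 10]
    log_correlation(a, b, subset = keep)$r
  }
  seeds <- 1:20
  r0 <- mean(vapply(seeds, function(s) r_for_sd(0, s), numeric(1)))
  r3 <- mean(vapply(seeds, function(s) r_for_sd(0.3, 1000 + s), numeric(1)))
  r6 <- mean(vapply(seeds, function(s) r_for_sd(0.6, 2000 + s), numeric(1)))
  expect_gt(r0, r3)
  expect_gt(r3, r6)
})

test_that("simulate_study is reproducible and carries its ground truth", {
  cfg <- small_cfg(seed = 21)
  depths <- c(control = 2e4, combined = 2e4)
  treatments <- default_treatments()[c("control", "combined")]
  s1 <- simulate_study(cfg, treatments, depths, n_replicates = 2,
                       de = list(treatments = "combined", n_genes = 10,
                                 log2fc = 2))
  s2 <- simulate_study(cfg, treatments, depths, n_replicates = 2,
                       de = list(treatments = "combined", n_genes = 10,
                                 log2fc = 2))
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$de_truth, s2$de_truth)
  expect_equal(nrow(s1$manifest), 2 + 4)  # control A only, combined A+B
  expect_equal(abs(s1$de_truth$log2fc), rep(2, 10))
})
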