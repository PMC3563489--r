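test_that("size factors match a brute-force median-of-ratios oracle", {
  m <- cbind(s1 = c(100, 200, 50, 80, 10, 400, 66),
             s2 = c(210, 380, 110, 150, 24, 820, 130),
             s3 = c(55, 95, 22, 41, 6, 190, 35))
  rownames(m) <- paste0("g", 1:7)
  # independent oracle: literal definition, gene by gene (odd gene count,
  # so the median is a single observed ratio)
  gm <- apply(m, 1, function(x) prod(x)^(1 / length(x)))
  oracle <- apply(m, 2, function(col) median(col / gm))
  expect_equal(size_factors(m), oracle, tolerance = 1e-12)

  # identical columns give identical factors
  eq <- cbind(a = c(5, 10, 20), b = c(5, 10, 20))
  rownames(eq) <- paste0("g", 1:3)
  expect_equal(unname(size_factors(eq)), c(1, 1))

  # scale equivariance: doubling one column doubles its factor ratio
  m2 <- m; m2[, 2] <- m[, 1] * 2
  sf2 <- size_factors(m2[, 1:2])
  expect_equal(unname(sf2[2] / sf2[1]), 2, tolerance = 1e-12)

  # genes with zeros are excluded from the median; all-zero input errors
  mz <- m; mz[1, 1] <- 0
  expect_equal(size_factors(mz)[2],
               size_factors(m[-1, ])[2], tolerance = 1e-12)
  zz <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(size_factors(zz), "no gene")
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(71)
  m <- matrix(rnbinom(600, mu = 50, size = 2), ncol = 4,
              dimnames = list(paste0("g", 1:150), paste0("s", 1:4)))
  m <- sweep(m, 2, c(1, 2, 0.5, 1.5), "*")
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(size_factors(m), ref, tolerance = 1e-10)
})

test_that("log2 fold changes are antisymmetric and handle zeros", {
  m <- cbind(a1 = c(10, 20, 0, 0), a2 = c(10, 20, 0, 0),
             b1 = c(40, 20, 8, 0), b2 = c(40, 20, 8, 0))
  rownames(m) <- paste0("g", 1:4)
  sf <- setNames(rep(1, 4), colnames(m))
  g <- factor(c("A", "A", "B", "B"), levels = c("A", "B"))
  res <- log2_fold_change(m, g, sf)
  expect_equal(res$log2fc[1], 2)           # 40 vs 10
  expect_equal(res$log2fc[2], 0)           # equal means
  expect_equal(res$flag[3], "pseudocount") # 0 vs 8
  expect_equal(res$log2fc[3], log2(8.5 / 0.5))
  expect_true(is.na(res$log2fc[4]))        # both zero: undefined
  expect_equal(res$flag[4], "undefined")

  swapped <- log2_fold_change(m, factor(g, levels = c("B", "A")), sf)
  ok <- !is.na(res$log2fc)
  expect_equal(swapped$log2fc[ok], -res$log2fc[ok], tolerance = 1e-12)
})

test_that("DEG selection applies strict inequalities on both filters", {
  res <- data.frame(
    feature_id = paste0("g", 1:6),
    p_value = c(0.005, 0.01, 0.02, 0.0001, 0.009, NA),
    log2fc = c(1.0, 3, 4, -2.5, 1.2, 5))
  sel <- deg_select(res, p_cut = 0.01, fc_cut = 1)
  # by-hand enumeration: p < 0.01 keeps g1, g4, g5; |lfc| > 1 drops g1
  expect_setequal(sel$significant, c("g1", "g4", "g5"))
  expect_setequal(sel$deg, c("g4", "g5"))
  expect_true(all(sel$deg %in% sel$significant))
})

test_that("fold-change correlation shows the closed-form noise attenuation", {
  set.seed(81)
  n <- 4000
  f <- rnorm(n)
  mk <- function(fc) data.frame(feature_id = paste0("g", 1:n),
                                log2fc = fc, p_value = 0.001)
  ident <- fc_correlation(mk(f), mk(f))
  expect_equal(ident$r, 1, tolerance = 1e-12)
  noisy <- fc_correlation(mk(f), mk(f + rnorm(n, sd = 0.1)))
  expect_equal(noisy$r, 1 / sqrt(1.01), tolerance = 0.005)
  expect_error(fc_correlation(mk(f)[1:2, ], mk(f)[1:2, ]), "fewer than 3")
})

test_that("the stand-in test ranks real effects above background", {
  set.seed(82)
  n <- 400
  mu <- exp(rnorm(n, log(50), 1))
  de <- 1:40  # planted 4x up-regulation
  mu_b <- mu; mu_b[de] <- mu_b[de] * 4
  draw <- function(mu) rnbinom(n, mu = mu, size = 10)
  m <- cbind(a1 = draw(mu), a2 = draw(mu), b1 = draw(mu_b), b2 = draw(mu_b))
  rownames(m) <- paste0("g", 1:n)
  res <- diff_expression(m, c("A", "A", "B", "B"))
  expect_equal(attr(res, "p_value_method"), "stand-in normal approximation")
  sel <- deg_select(res)
  planted <- paste0("g", de)
  # most planted genes are called, few null genes leak through
  expect_gt(mean(planted %in% sel$significant), 0.7)
  # the 2-replicate stand-in is somewhat anti-conservative (documented);
  # background leakage stays modest
  expect_lt(mean(setdiff(res$feature_id, planted) %in% sel$significant),
            0.1)
  # recovered effect size centres on log2(4) = 2
  expect_equal(mean(res$log2fc[de]), 2, tolerance = 0.2)
})
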