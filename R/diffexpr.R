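#' Median-of-ratios size factors
#'
#' Per-sample normalisation constants: each sample's factor is the
#' median, over genes with nonzero counts in every sample, of the ratio
#' of that gene's count to its geometric mean across samples. Scaling
#' one sample's counts by `c` scales its factor by `c`.
#'
#' @param m Count matrix (genes x samples) or a [count_matrix()].
#' @return Named vector of positive size factors.
#' @export
#' @examples
#' m <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
#' rownames(m) <- paste0("g", 1:3)
#' size_factors(m)  # s2 twice s1
size_factors <- function(m) {
  if (inherits(m, "count_matrix")) m <- m$counts
  m <- as.matrix(m)
  usable <- rowSums(m == 0) == 0
  if (!any(usable))
    stop("no gene has nonzero counts in every sample: size factors undefined")
  lg <- log(m[usable, , drop = FALSE])
  gm <- rowMeans(lg)
  apply(lg, 2, function(col) exp(median(col - gm)))
}

#' Normalised log2 fold changes between two conditions
#'
#' Counts are divided by their size factors, averaged within condition,
#' and the per-gene fold change is `log2(mean_B / mean_A)` where `A` is
#' the first level of `groups`. When exactly one of the two means is
#' zero, a pseudocount of 0.5 is added to both (flagged per gene) to keep
#' the fold change finite; genes with both means zero are undefined
#' (`NA`, flagged).
#'
#' @param m Count matrix (genes x samples) or a [count_matrix()].
#' @param groups Factor/character vector with one label per sample and
#'   exactly two levels; the first level is the reference condition A.
#' @param sf Size factors; computed with [size_factors()] if omitted.
#' @return Data frame with `feature_id`, `mean_a`, `mean_b`, `log2fc`,
#'   `flag` (`""`, `"pseudocount"` or `"undefined"`).
#' @export
log2_fold_change <- function(m, groups, sf = NULL) {
  if (inherits(m, "count_matrix")) m <- m$counts
  m <- as.matrix(m)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("groups must have exactly two levels")
  if (length(groups) != ncol(m)) stop("one group label per sample required")
  if (is.null(sf)) sf <- size_factors(m)
  norm <- sweep(m, 2, sf, "/")
  ma <- rowMeans(norm[, groups == levels(groups)[1], drop = FALSE])
  mb <- rowMeans(norm[, groups == levels(groups)[2], drop = FALSE])
  flag <- rep("", nrow(m))
  one_zero <- xor(ma == 0, mb == 0)
  flag[one_zero] <- "pseudocount"
  both_zero <- ma == 0 & mb == 0
  flag[both_zero] <- "undefined"
  la <- ifelse(one_zero, ma + 0.5, ma)
  lb <- ifelse(one_zero, mb + 0.5, mb)
  lfc <- ifelse(both_zero, NA_real_, log2(lb / la))
  data.frame(feature_id = rownames(m), mean_a = ma, mean_b = mb,
             log2fc = lfc, flag = flag,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Differential expression with a stand-in significance test
#'
#' Computes median-of-ratios size factors, normalised log2 fold changes,
#' and a per-gene p-value from a deliberately simple stand-in test: the
#' per-gene dispersion `alpha` of a negative-binomial mean-variance
#' relation (`Var = mu + alpha * mu^2`) is estimated by method of
#' moments from the within-condition spread, counts are transformed with
#' the corresponding variance-stabilising function
#' `f(k) = 2 / sqrt(alpha) * asinh(sqrt(alpha * k))` (which reduces to
#' `2 * sqrt(k)` in the Poisson limit), and the difference of
#' condition means on the stabilised scale is referred to a normal
#' distribution with variance `1/n_A + 1/n_B`. P-values are labelled
#' "stand-in" in all outputs; this is a screening statistic, not a full
#' negative-binomial inference.
#'
#' @inheritParams log2_fold_change
#' @return A `diff_expr_result` data frame (`feature_id`, `base_mean`,
#'   `log2fc`, `p_value`, `flag`) with attributes `size_factors`,
#'   `groups` and `p_value_method = "stand-in normal approximation"`.
#' @export
diff_expression <- function(m, groups, sf = NULL) {
  if (inherits(m, "count_matrix")) m <- m$counts
  m <- as.matrix(m)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("groups must have exactly two levels")
  if (is.null(sf)) sf <- size_factors(m)
  lfc <- log2_fold_change(m, groups, sf)
  norm <- sweep(m, 2, sf, "/")
  ia <- groups == levels(groups)[1]
  ib <- !ia
  mu_a <- rowMeans(norm[, ia, drop = FALSE])
  mu_b <- rowMeans(norm[, ib, drop = FALSE])
  # method-of-moments dispersion pooled over the two conditions
  v_a <- if (sum(ia) > 1) apply(norm[, ia, drop = FALSE], 1, var) else 0
  v_b <- if (sum(ib) > 1) apply(norm[, ib, drop = FALSE], 1, var) else 0
  mu_bar <- (mu_a + mu_b) / 2
  v_bar <- (v_a + v_b) / 2
  alpha <- pmax((v_bar - mu_bar) / mu_bar^2, 0)
  alpha[!is.finite(alpha)] <- 0
  vst <- function(kmat, a) {
    out <- 2 * sqrt(kmat)
    pos <- a > 0
    if (any(pos))
      out[pos, ] <- (2 / sqrt(a[pos])) *
        asinh(sqrt(a[pos] * kmat[pos, , drop = FALSE]))
    out
  }
  ya <- rowMeans(vst(norm[, ia, drop = FALSE], alpha))
  yb <- rowMeans(vst(norm[, ib, drop = FALSE], alpha))
  z <- (yb - ya) / sqrt(1 / sum(ia) + 1 / sum(ib))
  p <- 2 * pnorm(-abs(z))
  p[mu_a == 0 & mu_b == 0] <- 1
  out <- data.frame(feature_id = lfc$feature_id,
                    base_mean = mu_bar,
                    log2fc = lfc$log2fc,
                    p_value = p,
                    flag = lfc$flag,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "size_factors") <- sf
  attr(out, "groups") <- levels(groups)
  attr(out, "p_value_method") <- "stand-in normal approximation"
  class(out) <- c("diff_expr_result", "data.frame")
  out
}

#' Select differentially expressed genes
#'
#' Applies the strict filters `p < p_cut` (set `significant`) and
#' `p < p_cut` and `|log2FC| > fc_cut` (set `deg`); both inequalities are
#' strict, so a gene at exactly the cutoff is excluded.
#'
#' @param results A [diff_expression()] result (or any data frame with
#'   `feature_id`, `p_value`, `log2fc`).
#' @param p_cut P-value cutoff (default 0.01).
#' @param fc_cut Absolute log2 fold-change cutoff (default 1).
#' @return List with `significant` and `deg` gene-id vectors; `deg` is
#'   always a subset of `significant`.
#' @export
#' @examples
#' res <- data.frame(feature_id = c("a", "b"), p_value = c(0.005, 0.01),
#'                   log2fc = c(1.5, 3))
#' deg_select(res)  # only "a": p = 0.01 fails the strict cutoff
deg_select <- function(results, p_cut = 0.01, fc_cut = 1) {
  ok <- !is.na(results$p_value)
  sig <- ok & results$p_value < p_cut
  deg <- sig & !is.na(results$log2fc) & abs(results$log2fc) > fc_cut
  list(significant = results$feature_id[sig],
       deg = results$feature_id[deg])
}

#' Correlation of log2 fold changes between two analyses
#'
#' Pearson correlation of per-gene log2 fold changes from two
#' differential-expression analyses (e.g. the same contrast measured
#' under two depletion treatments), over a shared gene set.
#'
#' @param res_a,res_b [diff_expression()] results.
#' @param genes Gene ids to correlate; defaults to all shared genes with
#'   finite fold changes.
#' @return A `correlation_result` list with `r` and `n_genes`.
#' @export
fc_correlation <- function(res_a, res_b, genes = NULL) {
  fa <- setNames(res_a$log2fc, res_a$feature_id)
  fb <- setNames(res_b$log2fc, res_b$feature_id)
  shared <- intersect(names(fa), names(fb))
  if (!is.null(genes)) shared <- intersect(shared, genes)
  shared <- shared[is.finite(fa[shared]) & is.finite(fb[shared])]
  if (length(shared) < 3)
    stop("fewer than 3 shared genes with finite fold changes")
  structure(list(r = cor(fa[shared], fb[shared]),
                 n_genes = length(shared),
                 gene_subset_label = if (is.null(genes)) "all shared genes"
                                     else "supplied gene set"),
            class = "correlation_result")
}

#' Write a differential-expression result table
#'
#' @param results A [diff_expression()] result.
#' @param path_tsv,path_json Output paths (either may be `NULL`); the
#'   JSON is a summary (size factors, DEG counts at the default filters,
#'   p-value method), the TSV the full per-gene table.
#' @return Invisibly, `results`.
#' @export
write_diffexpr <- function(results, path_tsv = NULL, path_json = NULL) {
  if (!is.null(path_tsv))
    write.table(results, path_tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(path_json)) {
    sel <- deg_select(results)
    jsonlite::write_json(
      list(n_genes = nrow(results),
           size_factors = as.list(attr(results, "size_factors")),
           p_value_method = attr(results, "p_value_method"),
           n_significant_p_0.01 = length(sel$significant),
           n_deg_p_0.01_fc_1 = length(sel$deg)),
      path_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(results)
}
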