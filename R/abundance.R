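#' RPKM expression values
#'
#' Reads per kilobase of transcript per million mapped reads:
#' `RPKM = count * 1e9 / (length_bp * denominator_reads)`. The
#' denominator defaults to the sample's total mapped reads; passing the
#' number of reads mapped to annotated features instead is a documented
#' alternative.
#'
#' @param counts Named vector of per-gene read counts.
#' @param lengths Named vector of gene lengths (bases), covering every
#'   gene in `counts`.
#' @param denominator_reads Per-million base, usually total mapped reads.
#' @return Named numeric vector of RPKM values with attribute
#'   `denominator_reads`.
#' @export
#' @examples
#' rpkm(c(g = 10), c(g = 1000), 1e6)  # 10
rpkm <- function(counts, lengths, denominator_reads) {
  if (denominator_reads <= 0) stop("denominator_reads must be > 0")
  lengths <- lengths[names(counts)]
  if (anyNA(lengths)) stop("lengths must cover every gene in counts")
  if (any(lengths <= 0)) stop("gene lengths must be > 0")
  out <- counts * 1e9 / (lengths * denominator_reads)
  attr(out, "denominator_reads") <- denominator_reads
  out
}

#' Log-log correlation of two expression profiles
#'
#' Pearson correlation and least-squares regression of
#' `log10(RPKM_b)` on `log10(RPKM_a)` over a gene subset, the core
#' measure of how strongly a depletion treatment distorts mRNA relative
#' abundance. A regression slope below 1 indicates compression of the
#' dynamic range (flattening) in sample `b` relative to `a`.
#'
#' Genes with zero RPKM in either sample are excluded by default (no
#' pseudocount): the intended subsets are above-threshold genes, where
#' zeros are rare, and a pseudocount would bend the log-log relation at
#' the low end. A pseudocount mode exists for diagnostics.
#'
#' @param a,b Named RPKM vectors (see [rpkm()]); `a` is the x-axis /
#'   reference.
#' @param subset Gene ids to use; defaults to all shared genes.
#' @param pseudocount Value added to both profiles before taking logs;
#'   0 (default) excludes zero genes instead.
#' @param label Subset label recorded in the result.
#' @return A `correlation_result` list: `r`, `n_genes`, `n_excluded`,
#'   `slope`, `intercept`, `gene_subset_label`.
#' @export
#' @examples
#' a <- c(g1 = 1, g2 = 10, g3 = 100)
#' log_correlation(a, a^2)$slope  # 2: doubling on the log scale
log_correlation <- function(a, b, subset = NULL, pseudocount = 0,
                            label = if (is.null(subset)) "all shared genes"
                                    else "subset") {
  genes <- intersect(names(a), names(b))
  if (!is.null(subset)) genes <- intersect(genes, subset)
  x <- a[genes]; y <- b[genes]
  if (pseudocount > 0) {
    x <- x + pseudocount; y <- y + pseudocount
    usable <- rep(TRUE, length(genes))
  } else {
    usable <- x > 0 & y > 0
  }
  n_excluded <- sum(!usable)
  x <- log10(x[usable]); y <- log10(y[usable])
  if (length(x) < 3)
    stop("fewer than 3 usable genes for log correlation")
  fit <- lm(y ~ x)
  structure(list(r = cor(x, y),
                 n_genes = length(x),
                 n_excluded = n_excluded,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 gene_subset_label = label),
            class = "correlation_result")
}

#' Reproducibility between sequencing replicates
#'
#' [log_correlation()] between two replicate expression profiles, on the
#' genes detected above the detection threshold in the first replicate
#' (or on all genes nonzero in the first replicate if no counts are
#' given). Technical replicates of the same library are expected to
#' correlate above 0.99.
#'
#' @param rep1,rep2 Named RPKM vectors.
#' @param counts1 Optional named count vector for replicate 1, used with
#'   `dth` to define the gene subset.
#' @param dth Detection threshold applied to `counts1`.
#' @return A `correlation_result`.
#' @export
replicate_reproducibility <- function(rep1, rep2, counts1 = NULL, dth = 1) {
  subset <- if (!is.null(counts1)) genes_above_dth(counts1, dth)$genes
            else names(rep1)[rep1 > 0]
  log_correlation(rep1, rep2, subset = subset,
                  label = sprintf("replicate-1 genes above DTh = %s",
                                  if (inherits(dth, "dth_estimate"))
                                    dth$dth else dth))
}

#' Write correlation results as TSV/JSON
#'
#' @param results Named list of `correlation_result` objects.
#' @param path_tsv,path_json Output paths (either may be `NULL`).
#' @return Invisibly, `results`.
#' @export
write_correlations <- function(results, path_tsv = NULL, path_json = NULL) {
  df <- do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(comparison = nm, r = r$r, n_genes = r$n_genes,
               n_excluded = r$n_excluded, slope = r$slope,
               intercept = r$intercept, subset = r$gene_subset_label,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(path_tsv))
    write.table(df, path_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(path_json))
    jsonlite::write_json(lapply(results, unclass), path_json,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}
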