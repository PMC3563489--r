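#' Per-sample read category counts
#'
#' Container for the per-sample accounting row: total and mapped reads,
#' reads per category, and percentages of mapped reads. The percentages
#' use mapped reads as the denominator, and `% mRNA` counts CDS-assigned
#' reads only.
#'
#' @param sample_id Sample identifier.
#' @param total_reads,mapped_reads Read totals.
#' @param reads_rrna,reads_cds,reads_other,reads_intergenic Category
#'   counts; they must sum to `mapped_reads`.
#' @return A `category_counts` object (a one-row list).
#' @export
category_counts <- function(sample_id, total_reads, mapped_reads,
                            reads_rrna, reads_cds, reads_other,
                            reads_intergenic) {
  if (reads_rrna + reads_cds + reads_other + reads_intergenic != mapped_reads)
    stop("category counts must partition mapped_reads exactly")
  if (mapped_reads > total_reads)
    stop("mapped_reads cannot exceed total_reads")
  pct <- function(x) if (mapped_reads > 0) 100 * x / mapped_reads else 0
  structure(list(sample_id = sample_id,
                 total_reads = total_reads, mapped_reads = mapped_reads,
                 reads_rrna = reads_rrna, reads_cds = reads_cds,
                 reads_other = reads_other,
                 reads_intergenic = reads_intergenic,
                 pct_rrna = pct(reads_rrna), pct_mrna = pct(reads_cds),
                 pct_intergenic = pct(reads_intergenic)),
            class = "category_counts")
}

#' @export
as.data.frame.category_counts <- function(x, ...) {
  as.data.frame(unclass(x), stringsAsFactors = FALSE)
}

#' Classify mapped reads into rRNA / mRNA / intergenic categories
#'
#' Each mapped read is assigned to exactly one category using at least
#' `min_overlap` base pairs of overlap with an annotated feature and the
#' priority `rRNA > CDS > other > intergenic`: a read touching both an
#' rRNA gene and anything else is counted as rRNA, which avoids inflating
#' the apparent mRNA percentage when features overlap. Reads overlapping
#' no feature (or placed on a contig absent from the annotation, which
#' triggers a warning) are intergenic. Counting is strand-agnostic by
#' default.
#'
#' @param alignments A `read_alignments` data frame (see
#'   [read_alignments()] or [sample_reads()]).
#' @param annotation A `genome_annotation` (see [read_gff()]).
#' @param sample_id Sample label recorded in the output.
#' @param min_overlap Minimum overlap, in bases, for a read to count as
#'   hitting a feature (default 1).
#' @param stranded If `TRUE`, only same-strand overlaps count (requires a
#'   `strand` column in `alignments`).
#' @return A list with `counts` (a [category_counts()] row) and
#'   `cds_counts` (named integer vector of reads per CDS feature, zeros
#'   included: one column of the study's count matrix).
#' @export
classify_reads <- function(alignments, annotation, sample_id = "sample",
                           min_overlap = 1L, stranded = FALSE) {
  validate_annotation(annotation)
  if (nrow(annotation) == 0) stop("annotation is empty")
  total <- nrow(alignments)
  keep_m <- alignments$mapped
  al <- list(contig = alignments$contig[keep_m],
             start = alignments$start[keep_m],
             end = alignments$end[keep_m])
  mapped <- length(al$start)
  cds_idx <- which(annotation$category == "CDS")
  cds_counts <- setNames(integer(length(cds_idx)),
                         annotation$feature_id[cds_idx])
  if (mapped == 0) {
    return(list(counts = category_counts(sample_id, total, 0, 0, 0, 0, 0),
                cds_counts = cds_counts))
  }
  known <- al$contig %in% annotation$contig
  if (any(!known))
    warning(sprintf(paste0("%d reads on contigs absent from the annotation",
                           " (e.g. '%s'); counted as intergenic"),
                    sum(!known), al$contig[which(!known)[1]]))
  ann_gr <- GenomicRanges::GRanges(
    annotation$contig,
    IRanges::IRanges(annotation$start + 1, annotation$end),
    strand = if (stranded) annotation$strand else "*")
  read_gr <- GenomicRanges::GRanges(
    if (all(known)) al$contig else ifelse(known, al$contig,
                                          annotation$contig[1]),
    IRanges::IRanges(al$start + 1, al$end),
    strand = if (stranded && "strand" %in% names(alignments))
      alignments$strand[keep_m] else "*")
  hits <- GenomicRanges::findOverlaps(read_gr, ann_gr,
                                      minoverlap = as.integer(min_overlap),
                                      ignore.strand = !stranded)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  drop <- !known[q]
  if (any(drop)) { q <- q[!drop]; s <- s[!drop] }
  rank <- c(rRNA = 1L, CDS = 2L, other = 3L)[annotation$category[s]]
  ord <- order(q, rank)
  first <- !duplicated(q[ord])
  assigned_q <- q[ord][first]
  assigned_cat <- annotation$category[s[ord][first]]
  n_rrna <- sum(assigned_cat == "rRNA")
  n_cds <- sum(assigned_cat == "CDS")
  n_other <- sum(assigned_cat == "other")
  n_inter <- mapped - n_rrna - n_cds - n_other
  # count-matrix column: among CDS hits, largest overlap wins, then
  # leftmost feature; reads whose category is rRNA/other are excluded
  is_cds_hit <- annotation$category[s] == "CDS"
  if (any(is_cds_hit)) {
    qc <- q[is_cds_hit]; sc <- s[is_cds_hit]
    cat_by_q <- character(mapped)
    cat_by_q[assigned_q] <- assigned_cat
    keep <- cat_by_q[qc] == "CDS"
    qc <- qc[keep]; sc <- sc[keep]
    if (length(qc)) {
      ov <- pmin(al$end[qc], annotation$end[sc]) -
        pmax(al$start[qc], annotation$start[sc])
      ordc <- order(qc, -ov, annotation$start[sc])
      firstc <- !duplicated(qc[ordc])
      hit_cds <- tabulate(match(sc[ordc][firstc], cds_idx),
                          nbins = length(cds_idx))
      cds_counts <- cds_counts + hit_cds
    }
  }
  list(counts = category_counts(sample_id, total, mapped,
                                n_rrna, n_cds, n_other, n_inter),
       cds_counts = cds_counts)
}

#' Build a CDS count matrix from per-sample classifications
#'
#' @param classifications Named list of [classify_reads()] results (names
#'   become sample ids).
#' @param annotation The `genome_annotation` used for classification.
#' @return A [count_matrix()] over CDS features.
#' @export
build_count_matrix <- function(classifications, annotation) {
  cols <- lapply(classifications, `[[`, "cds_counts")
  m <- do.call(cbind, cols)
  colnames(m) <- names(classifications)
  len <- setNames(annotation$end - annotation$start, annotation$feature_id)
  count_matrix(m, len[rownames(m)])
}

#' Tabulate per-sample and per-treatment category percentages
#'
#' Produces the per-sample accounting rows plus replicate-averaged
#' (arithmetic mean) percentage rows per treatment group.
#'
#' @param counts_list List of [category_counts()] rows.
#' @param treatment Character vector of treatment labels, one per sample;
#'   defaults to one group.
#' @return A list of class `table1_report` with data frames `samples` and
#'   `treatments` (columns `treatment`, `n_replicates`, `pct_rrna`,
#'   `pct_mrna`, `pct_intergenic`).
#' @export
#' @examples
#' a <- category_counts("s1", 100, 100, 60, 30, 0, 10)
#' b <- category_counts("s2", 100, 100, 50, 40, 0, 10)
#' tabulate_samples(list(a, b), treatment = c("t", "t"))$treatments
tabulate_samples <- function(counts_list, treatment = NULL) {
  if (!length(counts_list)) stop("at least one sample is required")
  samples <- do.call(rbind, lapply(counts_list, as.data.frame))
  if (is.null(treatment)) treatment <- rep("all", nrow(samples))
  if (length(treatment) != nrow(samples))
    stop("treatment must have one label per sample")
  samples <- cbind(treatment = treatment, samples)
  grp <- split(seq_len(nrow(samples)), treatment)
  grp <- grp[unique(treatment)]  # preserve first-appearance order
  treatments <- do.call(rbind, lapply(names(grp), function(g) {
    i <- grp[[g]]
    data.frame(treatment = g, n_replicates = length(i),
               pct_rrna = mean(samples$pct_rrna[i]),
               pct_mrna = mean(samples$pct_mrna[i]),
               pct_intergenic = mean(samples$pct_intergenic[i]),
               stringsAsFactors = FALSE)
  }))
  structure(list(samples = samples, treatments = treatments),
            class = "table1_report")
}

#' Write per-sample category counts as TSV and JSON
#'
#' @param report A `table1_report` from [tabulate_samples()].
#' @param path_tsv,path_json Output paths (either may be `NULL`).
#' @return Invisibly, the report.
#' @export
write_category_report <- function(report, path_tsv = NULL, path_json = NULL) {
  stopifnot(inherits(report, "table1_report"))
  if (!is.null(path_tsv)) {
    write.table(report$samples, path_tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(unclass(report), path_json, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(report)
}
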