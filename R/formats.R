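#' @keywords internal
validate_annotation <- function(ann) {
  req <- c("feature_id", "contig", "start", "end", "strand", "category")
  if (!all(req %in% names(ann)))
    stop("annotation must have columns: ", paste(req, collapse = ", "))
  if (any(ann$start >= ann$end))
    stop("annotation features must have start < end")
  dup <- ann$feature_id[duplicated(ann$feature_id)]
  if (length(dup))
    stop("duplicate feature_id in annotation: ",
         paste(unique(dup), collapse = ", "))
  invisible(ann)
}

#' Read a GFF3 genome annotation
#'
#' Parses a GFF3 file into the internal annotation table. Features typed
#' `rRNA` become category `rRNA`, features typed `CDS` become `CDS`, and
#' every other typed feature becomes `other`. GFF3 1-based inclusive
#' coordinates are converted to the package's 0-based half-open
#' convention, so a record spanning 1..100 becomes `start = 0, end = 100`
#' (length 100).
#'
#' Feature identifiers are taken from the `ID`, `locus_tag` or `Name`
#' attribute (in that order); records without any are given a synthetic
#' id from their type and line number. Duplicate ids are an error.
#'
#' @param path Path to a GFF3 file.
#' @return A `genome_annotation` data frame with columns `feature_id`,
#'   `contig`, `start`, `end`, `strand`, `category`.
#' @seealso [write_gff3()], [classify_reads()]
#' @export
read_gff <- function(path) {
  lines <- readLines(path)
  contig_len <- NULL
  reg <- grep("^##sequence-region", lines, value = TRUE)
  if (length(reg)) {
    parts <- strsplit(reg[1], "[ \t]+")[[1]]
    if (length(parts) >= 4) contig_len <- as.numeric(parts[4])
  }
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) {
    ann <- data.frame(feature_id = character(0), contig = character(0),
                      start = numeric(0), end = numeric(0),
                      strand = character(0), category = character(0),
                      stringsAsFactors = FALSE)
    class(ann) <- c("genome_annotation", "data.frame")
    return(ann)
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 8))
    stop(sprintf("malformed GFF3 line %d: expected 9 tab-separated fields",
                 idx[which(nf < 8)[1]]))
  get <- function(i) vapply(fields, `[[`, character(1), i)
  start1 <- suppressWarnings(as.numeric(get(4)))
  end1 <- suppressWarnings(as.numeric(get(5)))
  bad <- which(is.na(start1) | is.na(end1) | start1 < 1 | end1 < start1)
  if (length(bad))
    stop(sprintf("malformed GFF3 line %d: invalid coordinates", idx[bad[1]]))
  type <- get(3)
  attrs <- vapply(fields, function(f) if (length(f) >= 9) f[[9]] else "",
                  character(1))
  pick_attr <- function(a, key) {
    m <- regmatches(a, regexec(paste0("(?:^|;)\\s*", key, "=([^;]+)"), a))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
           character(1))
  }
  id <- pick_attr(attrs, "ID")
  alt <- pick_attr(attrs, "locus_tag")
  id[is.na(id)] <- alt[is.na(id)]
  alt <- pick_attr(attrs, "Name")
  id[is.na(id)] <- alt[is.na(id)]
  miss <- is.na(id)
  id[miss] <- sprintf("%s_line%d", type[miss], idx[miss])
  strand <- get(7)
  strand[!strand %in% c("+", "-")] <- "*"
  ann <- data.frame(
    feature_id = id,
    contig = get(1),
    start = start1 - 1,
    end = end1,
    strand = strand,
    category = ifelse(type == "rRNA", "rRNA",
                      ifelse(type == "CDS", "CDS", "other")),
    stringsAsFactors = FALSE)
  dup <- which(duplicated(ann$feature_id))
  if (length(dup))
    stop(sprintf("duplicate feature_id '%s' at GFF3 line %d",
                 ann$feature_id[dup[1]], idx[dup[1]]))
  if (!is.null(contig_len)) attr(ann, "contig_length") <- contig_len
  class(ann) <- c("genome_annotation", "data.frame")
  ann
}

#' Write a genome annotation as GFF3
#'
#' Emits a `##gff-version 3` directive, one `##sequence-region` directive
#' per contig, and one record per feature, converting the internal
#' 0-based half-open coordinates back to GFF3 1-based inclusive.
#'
#' @param annotation A `genome_annotation`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotation, path) {
  validate_annotation(annotation)
  hdr <- "##gff-version 3"
  cl <- attr(annotation, "contig_length")
  for (ctg in unique(annotation$contig)) {
    len <- if (!is.null(cl)) cl else max(annotation$end[annotation$contig == ctg])
    hdr <- c(hdr, sprintf("##sequence-region %s 1 %d", ctg, as.integer(len)))
  }
  type <- ifelse(annotation$category == "other", "misc_feature",
                 annotation$category)
  rec <- sprintf("%s\tribofree\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                 annotation$contig, type,
                 as.integer(annotation$start + 1), as.integer(annotation$end),
                 annotation$strand, annotation$feature_id)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read alignments from SAM text or the tabular fixture format
#'
#' Two formats are supported. `"tsv"` is the package's plain fixture
#' format with header columns `read_id`, `contig`, `start` (0-based),
#' `end` (half-open) and `mapped` (0/1). `"sam"` is SAM text: header
#' lines are skipped, the 1-based `POS` is converted to a 0-based start,
#' the end is derived from the CIGAR reference span (M/D/N/=/X
#' operations), records with the unmapped flag (0x4) are kept but flagged
#' unmapped, and secondary (0x100) / supplementary (0x800) records are
#' dropped so each read contributes one alignment.
#'
#' @param path Input file path.
#' @param format `"tsv"` or `"sam"`.
#' @return A `read_alignments` data frame (`read_id`, `contig`, `start`,
#'   `end`, `mapped`).
#' @export
read_alignments <- function(path, format = c("tsv", "sam")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- read.delim(path, stringsAsFactors = FALSE)
    req <- c("read_id", "contig", "start", "end", "mapped")
    if (!all(req %in% names(df)))
      stop("alignment TSV must have columns: ", paste(req, collapse = ", "))
    bad <- which(df$mapped != 0 & (is.na(df$start) | is.na(df$end) |
                                     df$start >= df$end))
    if (length(bad))
      stop(sprintf("invalid alignment record at data line %d: start >= end",
                   bad[1]))
    out <- data.frame(read_id = as.character(df$read_id),
                      contig = as.character(df$contig),
                      start = as.numeric(df$start),
                      end = as.numeric(df$end),
                      mapped = df$mapped != 0,
                      stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    body <- which(!startsWith(lines, "@") & nzchar(lines))
    if (!length(body)) {
      out <- data.frame(read_id = character(0), contig = character(0),
                        start = numeric(0), end = numeric(0),
                        mapped = logical(0), stringsAsFactors = FALSE)
      class(out) <- c("read_alignments", "data.frame")
      return(out)
    }
    fields <- strsplit(lines[body], "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 11))
      stop(sprintf("unparseable SAM record at line %d: fewer than 11 fields",
                   body[which(nf < 11)[1]]))
    flag <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2)))
    if (anyNA(flag))
      stop(sprintf("unparseable SAM FLAG at line %d", body[which(is.na(flag))[1]]))
    keep <- bitwAnd(flag, 0x100) == 0 & bitwAnd(flag, 0x800) == 0
    fields <- fields[keep]; flag <- flag[keep]; body <- body[keep]
    mapped <- bitwAnd(flag, 0x4) == 0
    pos <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 4)))
    cigar <- vapply(fields, `[[`, character(1), 6)
    span <- cigar_ref_span(cigar)
    bad <- which(mapped & (is.na(pos) | pos < 1 | is.na(span) | span <= 0))
    if (length(bad))
      stop(sprintf("unparseable SAM record at line %d: bad POS/CIGAR", body[bad[1]]))
    out <- data.frame(read_id = vapply(fields, `[[`, character(1), 1),
                      contig = vapply(fields, `[[`, character(1), 3),
                      start = ifelse(mapped, pos - 1, NA_real_),
                      end = ifelse(mapped, pos - 1 + span, NA_real_),
                      mapped = mapped,
                      stringsAsFactors = FALSE)
  }
  class(out) <- c("read_alignments", "data.frame")
  out
}

# Reference-consuming CIGAR span (M, D, N, =, X).
cigar_ref_span <- function(cigar) {
  vapply(cigar, function(cg) {
    if (cg == "*") return(NA_real_)
    m <- regmatches(cg, gregexpr("(\\d+)([MIDNSHP=X])", cg))[[1]]
    if (!length(m)) return(NA_real_)
    op <- substr(m, nchar(m), nchar(m))
    len <- as.numeric(substr(m, 1, nchar(m) - 1))
    sum(len[op %in% c("M", "D", "N", "=", "X")])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Write alignments in the tabular fixture format
#'
#' @param reads A `read_alignments` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignments_tsv <- function(reads, path) {
  out <- data.frame(read_id = reads$read_id, contig = reads$contig,
                    start = reads$start, end = reads$end,
                    mapped = as.integer(reads$mapped))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write alignments as minimal SAM text
#'
#' Emits an `@HD` line, one `@SQ` line per contig, and one record per
#' read with flag 0 (or 4 for unmapped), MAPQ 60, a fully aligned CIGAR
#' and omitted sequence/quality.
#'
#' @param reads A `read_alignments` data frame.
#' @param path Output file path.
#' @param contig_lengths Named vector of contig lengths; defaults to the
#'   maximum end coordinate seen per contig.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, path, contig_lengths = NULL) {
  ctgs <- unique(reads$contig[reads$mapped])
  if (is.null(contig_lengths)) {
    contig_lengths <- vapply(ctgs, function(ctg)
      max(reads$end[reads$mapped & reads$contig == ctg]), numeric(1))
  }
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                   as.integer(contig_lengths)))
  flag <- ifelse(reads$mapped, 0L, 4L)
  pos <- ifelse(reads$mapped, as.integer(reads$start + 1), 0L)
  cig <- ifelse(reads$mapped,
                paste0(as.integer(reads$end - reads$start), "M"), "*")
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*",
                 reads$read_id, flag,
                 ifelse(reads$mapped, reads$contig, "*"),
                 pos, ifelse(reads$mapped, 60L, 0L), cig)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Construct a feature-by-sample count matrix
#'
#' @param counts Integer matrix, features in rows (rownames are feature
#'   ids), samples in columns.
#' @param lengths Named vector of feature lengths (bases).
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have feature rownames")
  if (any(counts < 0)) stop("counts must be nonnegative")
  lengths <- lengths[rownames(counts)]
  if (anyNA(lengths)) stop("lengths must cover every feature")
  if (any(lengths <= 0)) stop("feature lengths must be > 0")
  structure(list(counts = counts, lengths = lengths), class = "count_matrix")
}

#' Write / read a count matrix as TSV
#'
#' The layout is one row per feature with leading columns `feature_id`
#' and `length`, then one column per sample.
#'
#' @param cm A `count_matrix`.
#' @param path File path.
#' @return `path` (writer) or a `count_matrix` (reader).
#' @export
write_count_matrix <- function(cm, path) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- data.frame(feature_id = rownames(cm$counts),
                   length = as.integer(cm$lengths),
                   cm$counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, setdiff(names(df), c("feature_id", "length")),
                    drop = FALSE])
  rownames(m) <- df$feature_id
  count_matrix(m, setNames(df$length, df$feature_id))
}
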