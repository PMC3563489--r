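# shared in-code fixtures

# toy two-feature annotation via the GFF3 parser: rRNA [1000,2500),
# CDS [4000,5000) in 0-based half-open coordinates
toy_annotation <- function() {
  path <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "##sequence-region chr 1 10000",
    "chr\ttoy\trRNA\t1001\t2500\t.\t+\t.\tID=rrna1",
    "chr\ttoy\tCDS\t4001\t5000\t.\t-\t.\tID=cds1"), path)
  read_gff(path)
}

toy_reads <- function(starts, ends, contig = "chr", mapped = TRUE) {
  df <- data.frame(read_id = paste0("r", seq_along(starts)),
                   contig = contig, start = starts, end = ends,
                   mapped = mapped, stringsAsFactors = FALSE)
  class(df) <- c("read_alignments", "data.frame")
  df
}

# small simulation configuration for fast unit tests
small_cfg <- function(seed = 1, ...) {
  sim_config(contig_length = 6e5, n_cds = 300, seed = seed, ...)
}

# an exactly geometric depth histogram: n_k = N * p^(k-1) * (1-p)
exact_geometric_hist <- function(p, N = 4096, k_max = 10) {
  k <- seq_len(k_max)
  structure(data.frame(k = k, n = N * p^(k - 1) * (1 - p)),
            class = c("depth_histogram", "data.frame"))
}
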