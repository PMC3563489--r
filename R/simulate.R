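#' Simulation configuration for a synthetic bacterial RNA-seq library
#'
#' Describes a desk-scale bacterial genome and an rRNA-dominated total-RNA
#' library. Defaults emulate the situation the package is built for: a
#' multi-thousand-CDS genome in which rRNA accounts for roughly 95--98% of
#' total RNA, so that an untreated library spends almost all of its reads
#' on rRNA genes.
#'
#' @param contig_length Length of the single simulated contig (bases).
#' @param n_cds Number of protein-coding genes to place.
#' @param cds_length_range Length range (min, max) for CDS features, bases.
#' @param n_rrna_operons Number of rRNA operons; each contributes one gene
#'   per entry of `rrna_gene_lengths`.
#' @param rrna_gene_lengths Gene lengths within one operon (bases); the
#'   default mimics a bacterial 23S/16S/5S operon.
#' @param min_gap Minimum intergenic gap between placed features (bases).
#' @param expr_log_mean,expr_log_sd Parameters (natural-log scale) of the
#'   lognormal distribution of CDS abundance. The default `expr_log_sd`
#'   of 1.5 spreads expression over roughly four orders of magnitude.
#' @param rrna_read_fraction Fraction of reads in the untreated library
#'   originating from rRNA, in `[0, 1)`.
#' @param intergenic_read_fraction Fraction of reads from intergenic
#'   space, in `[0, 1)`.
#' @param read_length Read length (bases).
#' @param seed Integer seed; all stochastic draws of a simulation flow
#'   from it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [generate_annotation()], [simulate_abundances()],
#'   [simulate_study()]
#' @export
#' @examples
#' cfg <- sim_config(n_cds = 100, contig_length = 2e5)
#' cfg$n_cds
sim_config <- function(contig_length = 3.5e6,
                       n_cds = 3000,
                       cds_length_range = c(300, 1500),
                       n_rrna_operons = 2,
                       rrna_gene_lengths = c(2900, 1500, 120),
                       min_gap = 60,
                       expr_log_mean = 0,
                       expr_log_sd = 1.5,
                       rrna_read_fraction = 0.96,
                       intergenic_read_fraction = 0.02,
                       read_length = 48,
                       seed = 1L) {
  cfg <- list(contig_length = as.numeric(contig_length),
              n_cds = as.integer(n_cds),
              cds_length_range = as.numeric(cds_length_range),
              n_rrna_operons = as.integer(n_rrna_operons),
              rrna_gene_lengths = as.numeric(rrna_gene_lengths),
              min_gap = as.numeric(min_gap),
              expr_log_mean = as.numeric(expr_log_mean),
              expr_log_sd = as.numeric(expr_log_sd),
              rrna_read_fraction = as.numeric(rrna_read_fraction),
              intergenic_read_fraction = as.numeric(intergenic_read_fraction),
              read_length = as.integer(read_length),
              seed = as.integer(seed))
  if (cfg$n_cds < 0) stop("n_cds must be >= 0")
  if (cfg$contig_length <= 0) stop("contig_length must be > 0")
  if (length(cfg$cds_length_range) != 2 || any(cfg$cds_length_range <= 0) ||
      cfg$cds_length_range[1] > cfg$cds_length_range[2])
    stop("cds_length_range must be positive (min, max) with min <= max")
  if (cfg$n_rrna_operons < 0) stop("n_rrna_operons must be >= 0")
  if (any(cfg$rrna_gene_lengths <= 0)) stop("rrna_gene_lengths must be > 0")
  if (cfg$min_gap <= 0) stop("min_gap must be > 0")
  if (cfg$expr_log_sd < 0) stop("expr_log_sd must be >= 0")
  if (cfg$rrna_read_fraction < 0 || cfg$rrna_read_fraction >= 1)
    stop("rrna_read_fraction must be in [0, 1)")
  if (cfg$intergenic_read_fraction < 0 || cfg$intergenic_read_fraction >= 1)
    stop("intergenic_read_fraction must be in [0, 1)")
  if (cfg$rrna_read_fraction + cfg$intergenic_read_fraction >= 1)
    stop("rrna_read_fraction + intergenic_read_fraction must be < 1")
  if (cfg$read_length <= 0) stop("read_length must be > 0")
  class(cfg) <- "sim_config"
  cfg
}

#' Depletion-treatment model
#'
#' Describes how an rRNA removal treatment distorts a library: a
#' multiplicative retention factor on rRNA abundance, a per-gene lognormal
#' bias on mRNA abundance, and a compression exponent that flattens the
#' mRNA dynamic range on the log scale (the signature of selective-priming
#' chemistries).
#'
#' @param rrna_retention Multiplicative factor in `[0, 1]` applied to rRNA
#'   abundance (1 = no depletion, 0 = complete removal).
#' @param mrna_bias_sd Standard deviation (natural-log scale) of the
#'   per-gene multiplicative lognormal bias on mRNA abundance; 0 disables
#'   the bias.
#' @param compression_gamma Exponent in `(0, 1]` applied to mRNA
#'   abundances on the log scale, anchored at their geometric mean:
#'   `w -> gm * (w / gm)^gamma`. Values below 1 flatten the dynamic range
#'   (genes above the typical abundance are pulled down, genes below are
#'   pulled up), reproducing the flattened treated-vs-control regression
#'   observed for selective-priming protocols.
#' @param label Human-readable treatment name.
#'
#' @return An object of class `treatment_model`.
#' @export
#' @examples
#' treatment_model(0.02, 0.15, 0.9, "combined")
treatment_model <- function(rrna_retention, mrna_bias_sd = 0,
                            compression_gamma = 1, label = "treatment") {
  if (rrna_retention < 0 || rrna_retention > 1)
    stop("rrna_retention must be in [0, 1]")
  if (mrna_bias_sd < 0) stop("mrna_bias_sd must be >= 0")
  if (compression_gamma <= 0 || compression_gamma > 1)
    stop("compression_gamma must be in (0, 1]")
  structure(list(rrna_retention = rrna_retention,
                 mrna_bias_sd = mrna_bias_sd,
                 compression_gamma = compression_gamma,
                 label = label),
            class = "treatment_model")
}

#' Default depletion-treatment panel
#'
#' Four library treatments spanning the contrasts the package is designed
#' to measure: an untreated control; a capture-based depletion (modest
#' rRNA removal, no abundance bias); a selective-priming depletion (strong
#' rRNA removal, strong compressive bias); and the combination of the two
#' (strong removal, moderate bias).
#'
#' @return Named list of [treatment_model()] objects.
#' @export
default_treatments <- function() {
  list(control   = treatment_model(1,    0,    1,   "control"),
       capture   = treatment_model(0.90, 0,    1,   "capture"),
       selective = treatment_model(0.02, 0.35, 0.8, "selective"),
       combined  = treatment_model(0.02, 0.15, 0.9, "combined"))
}

#' Generate a synthetic genome annotation
#'
#' Places `n_cds` CDS features and `n_rrna_operons * length(rrna_gene_lengths)`
#' rRNA genes on a single contig, pairwise disjoint, in random order with
#' random strands. Gaps between features are at least `min_gap` bases, with
#' the remaining slack distributed multinomially.
#'
#' Random draws, in order: CDS lengths, placement permutation, gap slack
#' partition, strands. Call `set.seed()` (or use [simulate_study()], which
#' seeds from the configuration) for reproducibility.
#'
#' @param cfg A [sim_config()].
#' @return A `genome_annotation` data frame (see [read_gff()]) sorted by
#'   start, with attribute `contig_length`.
#' @export
#' @examples
#' set.seed(1)
#' ann <- generate_annotation(sim_config(n_cds = 50, contig_length = 2e5))
#' table(ann$category)
generate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n_rrna <- cfg$n_rrna_operons * length(cfg$rrna_gene_lengths)
  cds_len <- floor(runif(cfg$n_cds, cfg$cds_length_range[1],
                         cfg$cds_length_range[2] + 1))
  rrna_len <- rep(cfg$rrna_gene_lengths, times = cfg$n_rrna_operons)
  if (cfg$n_rrna_operons > 0) {
    op <- rep(seq_len(cfg$n_rrna_operons), each = length(cfg$rrna_gene_lengths))
    gi <- rep(seq_along(cfg$rrna_gene_lengths), times = cfg$n_rrna_operons)
    rrna_id <- sprintf("rrna_op%d_g%d", op, gi)
  } else rrna_id <- character(0)
  feat <- data.frame(
    feature_id = c(sprintf("cds_%04d", seq_len(cfg$n_cds)), rrna_id),
    category = rep(c("CDS", "rRNA"), c(cfg$n_cds, n_rrna)),
    length = c(cds_len, rrna_len),
    stringsAsFactors = FALSE)
  n <- nrow(feat)
  if (n == 0) stop("configuration places no features")
  need <- sum(feat$length) + (n + 1) * cfg$min_gap
  if (need > cfg$contig_length)
    stop(sprintf(paste0("cannot place features: %d bases required ",
                        "(features + minimum gaps) but contig_length is %d"),
                 round(need), round(cfg$contig_length)))
  feat <- feat[sample.int(n), , drop = FALSE]
  slack <- cfg$contig_length - need
  extra <- as.vector(rmultinom(1, size = slack, prob = rep(1, n + 1)))
  gaps <- cfg$min_gap + extra
  starts <- cumsum(gaps[seq_len(n)] + c(0, feat$length[-n]))
  ann <- data.frame(
    feature_id = feat$feature_id,
    contig = "contig_1",
    start = starts,
    end = starts + feat$length,
    strand = sample(c("+", "-"), n, replace = TRUE),
    category = feat$category,
    stringsAsFactors = FALSE)
  ann <- ann[order(ann$start), , drop = FALSE]
  rownames(ann) <- NULL
  attr(ann, "contig_length") <- cfg$contig_length
  class(ann) <- c("genome_annotation", "data.frame")
  validate_annotation(ann)
  ann
}

#' Simulate per-feature sampling abundances
#'
#' Draws lognormal CDS abundances and rescales the pools so that rRNA
#' features carry `rrna_read_fraction` of the total sampling weight, a
#' flat intergenic pseudo-feature carries `intergenic_read_fraction`, and
#' the CDS pool carries the remainder. rRNA weight is split among rRNA
#' genes proportionally to their length. Weights sum to 1.
#'
#' @param cfg A [sim_config()].
#' @param annotation A `genome_annotation` (usually from
#'   [generate_annotation()]).
#' @return An `abundance_profile` data frame with columns `feature_id`,
#'   `category`, `weight`; the intergenic pseudo-feature has id
#'   `"__intergenic__"`.
#' @export
simulate_abundances <- function(cfg, annotation) {
  stopifnot(inherits(cfg, "sim_config"))
  is_rrna <- annotation$category == "rRNA"
  is_cds <- annotation$category == "CDS"
  if (cfg$rrna_read_fraction > 0 && !any(is_rrna))
    stop("rrna_read_fraction > 0 but the annotation has no rRNA feature")
  w_rrna <- numeric(0)
  if (any(is_rrna)) {
    len <- annotation$end[is_rrna] - annotation$start[is_rrna]
    w_rrna <- cfg$rrna_read_fraction * len / sum(len)
  }
  cds_share <- 1 - cfg$rrna_read_fraction - cfg$intergenic_read_fraction
  w_cds <- numeric(0)
  if (any(is_cds)) {
    raw <- rlnorm(sum(is_cds), cfg$expr_log_mean, cfg$expr_log_sd)
    w_cds <- cds_share * raw / sum(raw)
  }
  prof <- data.frame(
    feature_id = c(annotation$feature_id[is_rrna],
                   annotation$feature_id[is_cds],
                   "__intergenic__"),
    category = c(rep("rRNA", sum(is_rrna)), rep("CDS", sum(is_cds)),
                 "intergenic"),
    weight = c(w_rrna, w_cds, cfg$intergenic_read_fraction),
    stringsAsFactors = FALSE)
  new_profile(prof)
}

new_profile <- function(prof) {
  if (any(prof$weight < 0)) stop("abundance weights must be >= 0")
  s <- sum(prof$weight)
  if (abs(s - 1) > 1e-9) prof$weight <- prof$weight / s
  class(prof) <- c("abundance_profile", "data.frame")
  prof
}

#' Apply a depletion-treatment model to an abundance profile
#'
#' rRNA weights are multiplied by the treatment's retention factor. Each
#' mRNA weight `w` is compressed about the mRNA geometric mean `gm`
#' (`w -> gm * (w/gm)^gamma`) and multiplied by a per-gene lognormal bias.
#' The intergenic pseudo-feature is scaled together with the mRNA pool,
#' and the profile is renormalised to sum 1. With identity parameters
#' (retention 1, bias 0, gamma 1) the profile is a fixed point.
#'
#' Compression anchored at the geometric mean leaves a typical gene
#' untouched while pulling extreme abundances toward the centre; because
#' the abundance distribution is right-skewed, stronger compression also
#' slightly shrinks the aggregate mRNA pool (Jensen's inequality), so a
#' heavily compressive treatment shows a somewhat smaller enrichment fold
#' than an equally rRNA-depleted but less biased one.
#'
#' @param profile An `abundance_profile`.
#' @param t A [treatment_model()].
#' @param bias_factors Optional vector of per-gene multiplicative bias
#'   factors (one per mRNA feature, in profile order). When `NULL` and
#'   `t$mrna_bias_sd > 0`, factors are drawn `rlnorm(n, 0, mrna_bias_sd)`.
#'   Passing a precomputed vector makes the bias reproducible across
#'   conditions, modelling a protocol whose per-gene distortion is a fixed
#'   property of the chemistry.
#' @return A treated `abundance_profile`; the bias factors used are
#'   attached as attribute `bias_factors` and the treatment label as
#'   attribute `treatment`.
#' @export
apply_treatment <- function(profile, t, bias_factors = NULL) {
  stopifnot(inherits(profile, "abundance_profile"),
            inherits(t, "treatment_model"))
  w <- profile$weight
  mi <- profile$category == "CDS"
  ri <- profile$category == "rRNA"
  ii <- profile$category == "intergenic"
  w[ri] <- w[ri] * t$rrna_retention
  m_old <- sum(profile$weight[mi])
  if (any(mi)) {
    wm <- profile$weight[mi]
    if (t$compression_gamma != 1) {
      pos <- wm > 0
      gm <- exp(mean(log(wm[pos])))
      wm[pos] <- gm * (wm[pos] / gm)^t$compression_gamma
    }
    if (is.null(bias_factors)) {
      bias_factors <- if (t$mrna_bias_sd > 0)
        rlnorm(sum(mi), 0, t$mrna_bias_sd) else rep(1, sum(mi))
    } else if (length(bias_factors) != sum(mi)) {
      stop("bias_factors must have one entry per mRNA feature")
    }
    wm <- wm * bias_factors
    w[mi] <- wm
    if (m_old > 0 && any(ii)) w[ii] <- w[ii] * sum(wm) / m_old
  }
  out <- profile
  out$weight <- w / sum(w)
  attr(out, "bias_factors") <- bias_factors
  attr(out, "treatment") <- t$label
  out
}

#' Plant differential-expression effects into a profile
#'
#' Multiplies the sampling weights of selected genes by `2^log2fc` and
#' renormalises; used to create a second growth condition with known fold
#' changes.
#'
#' @param profile An `abundance_profile`.
#' @param gene_ids Feature ids of the genes to perturb.
#' @param log2fc Log2 fold change(s); recycled to `length(gene_ids)`.
#' @return The perturbed `abundance_profile`, with planted effects stored
#'   in attribute `planted` (data frame of `feature_id`, `log2fc`).
#' @export
plant_fold_changes <- function(profile, gene_ids, log2fc) {
  stopifnot(inherits(profile, "abundance_profile"))
  idx <- match(gene_ids, profile$feature_id)
  if (anyNA(idx)) stop("unknown gene ids: ",
                       paste(gene_ids[is.na(idx)], collapse = ", "))
  log2fc <- rep_len(log2fc, length(idx))
  out <- profile
  out$weight[idx] <- out$weight[idx] * 2^log2fc
  out$weight <- out$weight / sum(out$weight)
  attr(out, "planted") <- data.frame(feature_id = gene_ids, log2fc = log2fc,
                                     stringsAsFactors = FALSE)
  out
}

#' Sample read alignments from an abundance profile
#'
#' Reads are assigned to features (plus the intergenic pseudo-feature)
#' by a single multinomial draw over the profile weights. Within a
#' feature, read start positions are uniform, clipped so the read fits
#' entirely inside the feature; intergenic reads are placed uniformly in
#' the gaps between annotated features. The multinomial ground truth is
#' attached for downstream conservation checks.
#'
#' Random draws, in order: one multinomial over features, one uniform per
#' read (in profile order, intergenic gap choice + placement last), one
#' shuffling permutation.
#'
#' @param profile An `abundance_profile`.
#' @param annotation The matching `genome_annotation`.
#' @param n_reads Number of reads to draw.
#' @param read_length Read length in bases.
#' @return A `read_alignments` data frame (`read_id`, `contig`, `start`,
#'   `end`, `mapped`; 0-based half-open coordinates) with attributes
#'   `feature_counts` (named multinomial draw, including
#'   `"__intergenic__"`) and `category_counts` (reads per category).
#' @export
sample_reads <- function(profile, annotation, n_reads,
                         read_length = 48L) {
  stopifnot(inherits(profile, "abundance_profile"),
            inherits(annotation, "genome_annotation"), n_reads >= 0)
  n_reads <- as.integer(n_reads)
  k <- as.vector(rmultinom(1, n_reads, profile$weight))
  names(k) <- profile$feature_id
  feat_rows <- profile$feature_id != "__intergenic__"
  idx <- match(profile$feature_id[feat_rows], annotation$feature_id)
  if (anyNA(idx)) stop("profile features missing from annotation")
  kf <- k[feat_rows]
  rep_i <- rep(idx, kf)
  fs <- annotation$start[rep_i]
  fe <- annotation$end[rep_i]
  len_eff <- pmin(read_length, fe - fs)
  start <- fs + floor(runif(length(rep_i)) * (fe - len_eff - fs + 1))
  end <- start + len_eff
  k_int <- k[["__intergenic__"]]
  if (k_int > 0) {
    cl <- attr(annotation, "contig_length")
    if (is.null(cl)) cl <- max(annotation$end)
    gs <- c(0, annotation$end)
    ge <- c(annotation$start, cl)
    keep <- ge > gs
    gs <- gs[keep]; ge <- ge[keep]
    usable <- pmax(ge - gs - read_length + 1, 1)
    gap_len <- ge - gs
    gi <- sample.int(length(gs), k_int, replace = TRUE, prob = usable)
    ilen <- pmin(read_length, gap_len[gi])
    istart <- gs[gi] + floor(runif(k_int) * pmax(ge[gi] - ilen - gs[gi] + 1, 1))
    start <- c(start, istart)
    end <- c(end, istart + ilen)
  }
  n <- length(start)
  if (n > 0) {
    perm <- sample.int(n)
    start <- start[perm]; end <- end[perm]
  }
  reads <- data.frame(
    read_id = seq_len(n),
    contig = rep(if (nrow(annotation)) annotation$contig[1] else "contig_1", n),
    start = as.numeric(start),
    end = as.numeric(end),
    mapped = rep(TRUE, n),
    stringsAsFactors = FALSE)
  class(reads) <- c("read_alignments", "data.frame")
  attr(reads, "feature_counts") <- k
  cats <- c(rRNA = "rrna", CDS = "cds", other = "other",
            intergenic = "intergenic")
  cc <- vapply(names(cats), function(cat)
    sum(k[profile$category == cat]), numeric(1))
  names(cc) <- unname(cats)
  attr(reads, "category_counts") <- cc
  reads
}

#' Per-treatment sequencing depths for the default synthetic study
#'
#' Reads per replicate, mirroring the design in which the untreated
#' control is sequenced deepest and progressively fewer reads are spent
#' on better-depleted libraries. Sized so that sampling noise does not
#' drown the treatment effects under the default panel (see the package
#' vignette for the power reasoning).
#'
#' @param treatments Character vector of treatment names.
#' @return Named numeric vector of reads per replicate.
#' @export
default_depths <- function(treatments = names(default_treatments())) {
  base <- c(control = 2e6, capture = 1.4e6, selective = 7e5, combined = 5e5)
  out <- base[treatments]
  out[is.na(out)] <- 5e5
  names(out) <- treatments
  out
}

#' Simulate a complete depletion-evaluation study
#'
#' Generates an annotation and a base abundance profile, optionally plants
#' known fold changes to create a second growth condition, applies each
#' depletion treatment (drawing its per-gene bias once, shared across
#' conditions), and samples reads for every treatment x condition x
#' replicate combination.
#'
#' All randomness is seeded from `cfg$seed`. Draw order: annotation, base
#' abundances, DE gene selection and signs, per-treatment bias vectors
#' (treatment order), then reads sample by sample (treatments in order,
#' conditions within treatment, replicates innermost).
#'
#' @param cfg A [sim_config()].
#' @param treatments Named list of [treatment_model()]s.
#' @param depths Named vector of reads per replicate per treatment.
#' @param n_replicates Replicates per treatment and condition.
#' @param de `NULL`, or a list with elements `treatments` (names of the
#'   treatments also sequenced under the second condition), `n_genes`
#'   (number of planted genes), `log2fc` (effect magnitude; signs are
#'   drawn at random per gene).
#' @return A list with `annotation`, `base_profile`, `profiles` (one per
#'   treatment x condition), `manifest` (data frame of sample metadata),
#'   `reads` (named list of `read_alignments`, one per sample), and
#'   `de_truth` (planted effects, or `NULL`).
#' @export
#' @examples
#' study <- simulate_study(sim_config(n_cds = 200, contig_length = 4e5,
#'                                    seed = 7),
#'                         depths = c(control = 2e4, capture = 2e4,
#'                                    selective = 2e4, combined = 2e4))
#' study$manifest
simulate_study <- function(cfg = sim_config(),
                           treatments = default_treatments(),
                           depths = default_depths(names(treatments)),
                           n_replicates = 2,
                           de = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(names(treatments)) || any(names(treatments) == ""))
    stop("treatments must be a named list")
  if (!all(names(treatments) %in% names(depths)))
    stop("depths must name every treatment")
  set.seed(cfg$seed)
  annotation <- generate_annotation(cfg)
  base <- simulate_abundances(cfg, annotation)
  conditions <- "A"
  de_truth <- NULL
  profiles_base <- list(A = base)
  if (!is.null(de)) {
    conditions <- c("A", "B")
    cds_ids <- base$feature_id[base$category == "CDS"]
    cds_w <- base$weight[base$category == "CDS"]
    eligible <- cds_ids[cds_w >= median(cds_w)]
    n_genes <- min(de$n_genes, length(eligible))
    genes <- sample(eligible, n_genes)
    signs <- sample(c(-1, 1), n_genes, replace = TRUE)
    lfc <- signs * de$log2fc
    profiles_base$B <- plant_fold_changes(base, genes, lfc)
    de_truth <- data.frame(feature_id = genes, log2fc = lfc,
                           stringsAsFactors = FALSE)
  }
  bias <- lapply(treatments, function(t) {
    n_m <- sum(base$category == "CDS")
    if (t$mrna_bias_sd > 0) rlnorm(n_m, 0, t$mrna_bias_sd) else rep(1, n_m)
  })
  profiles <- list()
  for (tn in names(treatments)) {
    conds <- if (!is.null(de) && !(tn %in% de$treatments)) "A" else conditions
    for (cn in conds) {
      profiles[[paste(tn, cn, sep = ".")]] <-
        apply_treatment(profiles_base[[cn]], treatments[[tn]],
                        bias_factors = bias[[tn]])
    }
  }
  manifest <- do.call(rbind, lapply(names(treatments), function(tn) {
    conds <- if (!is.null(de) && !(tn %in% de$treatments)) "A" else conditions
    expand.grid(treatment = tn, condition = conds,
                replicate = seq_len(n_replicates),
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  }))
  manifest$sample_id <- sprintf("%s_%s_rep%d", manifest$treatment,
                                manifest$condition, manifest$replicate)
  manifest <- manifest[, c("sample_id", "treatment", "condition", "replicate")]
  reads <- vector("list", nrow(manifest))
  names(reads) <- manifest$sample_id
  for (i in seq_len(nrow(manifest))) {
    key <- paste(manifest$treatment[i], manifest$condition[i], sep = ".")
    reads[[i]] <- sample_reads(profiles[[key]], annotation,
                               n_reads = depths[[manifest$treatment[i]]],
                               read_length = cfg$read_length)
  }
  list(annotation = annotation, base_profile = base, profiles = profiles,
       manifest = manifest, reads = reads, de_truth = de_truth)
}
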