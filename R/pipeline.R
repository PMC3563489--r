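#' Pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs. Exactly one input mode is
#' active:
#'
#' * `"synthetic"`: simulate a study with [simulate_study()] from
#'   `sim` / `treatments` / `depths` / `n_replicates` / `de`.
#' * `"alignments"`: consume real alignments; requires a non-empty
#'   `manifest` (columns `sample_id`, `treatment`, `condition`,
#'   `replicate`, `path`, `format`) and `annotation_path` (GFF3).
#' * `"fixture"`: run only the metrics stage on bundled or supplied
#'   printed percentages (`read_stats`, `depth_summary`).
#'
#' @param mode Input mode, see above.
#' @param sim A [sim_config()] (synthetic mode).
#' @param treatments Named list of [treatment_model()]s (synthetic mode).
#' @param depths Reads per replicate per treatment (synthetic mode).
#' @param n_replicates Replicates per treatment and condition.
#' @param de Optional planted differential-expression block passed to
#'   [simulate_study()].
#' @param manifest Sample manifest data frame (alignments mode).
#' @param annotation_path GFF3 path (alignments mode).
#' @param read_stats,depth_summary Fixture tables (fixture mode);
#'   default to the bundled study fixtures.
#' @param control Name of the control treatment.
#' @param dth_criterion,dth_tau Threshold rule, see [estimate_dth()].
#' @param fit_range Optional fit range for [fit_geometric()].
#' @param p_cut,fc_cut DEG filters, see [deg_select()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("synthetic", "alignments", "fixture"),
                            sim = sim_config(),
                            treatments = default_treatments(),
                            depths = default_depths(names(treatments)),
                            n_replicates = 2,
                            de = NULL,
                            manifest = NULL,
                            annotation_path = NULL,
                            read_stats = NULL,
                            depth_summary = NULL,
                            control = "control",
                            dth_criterion = "expected_below_one",
                            dth_tau = 10,
                            fit_range = NULL,
                            p_cut = 0.01, fc_cut = 1) {
  mode <- match.arg(mode)
  if (mode == "alignments") {
    if (is.null(manifest) || nrow(manifest) == 0)
      stop("alignments mode requires a non-empty sample manifest")
    req <- c("sample_id", "treatment", "condition", "replicate", "path",
             "format")
    if (!all(req %in% names(manifest)))
      stop("manifest must have columns: ", paste(req, collapse = ", "))
    if (is.null(annotation_path))
      stop("alignments mode requires annotation_path")
  }
  if (mode == "fixture") {
    if (is.null(read_stats)) read_stats <- table1_fixture()
    if (is.null(depth_summary)) depth_summary <- study_design_fixture()
    control <- read_stats$treatment[1]
  }
  structure(list(mode = mode, sim = sim, treatments = treatments,
                 depths = depths, n_replicates = n_replicates, de = de,
                 manifest = manifest, annotation_path = annotation_path,
                 read_stats = read_stats, depth_summary = depth_summary,
                 control = control, dth_criterion = dth_criterion,
                 dth_tau = dth_tau, fit_range = fit_range,
                 p_cut = p_cut, fc_cut = fc_cut),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full depletion-evaluation pipeline
#'
#' Executes, in order: data acquisition (simulation or alignment
#' parsing), read classification, detection-threshold estimation,
#' enrichment metrics, abundance-robustness correlations, and (when a
#' second growth condition is present) differential-expression
#' robustness. Stage errors abort with the stage name; if an output
#' directory is given, outputs produced so far are retained next to a
#' `FAILED` marker.
#'
#' With a fixed simulation seed the run is fully deterministic: re-running
#' the same configuration yields byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory; when given, all stage
#'   outputs, the consolidated `report.json` and a `run_manifest.json`
#'   (seed, parameters, package version) are written there.
#' @return The consolidated report (list), invisibly when `out_dir` is
#'   given.
#' @export
#' @examples
#' cfg <- pipeline_config("fixture")
#' rep <- run_pipeline(cfg)
#' rep$metrics$enrichment_fold
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  on_fail <- function() {
    if (!is.null(out_dir))
      writeLines("pipeline failed; outputs are partial", file.path(out_dir, "FAILED"))
  }
  report <- withCallingHandlers(
    run_pipeline_impl(config, out_dir),
    error = function(e) on_fail())
  if (!is.null(out_dir)) {
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    manifest <- list(package = "ribofree",
                     version = as.character(packageVersion("ribofree")),
                     mode = config$mode,
                     seed = if (config$mode == "synthetic") config$sim$seed,
                     control = config$control,
                     dth_criterion = config$dth_criterion,
                     p_cut = config$p_cut, fc_cut = config$fc_cut)
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(report))
  }
  report
}

run_pipeline_impl <- function(config, out_dir) {
  if (config$mode == "fixture") {
    rep <- stage("metrics", enrichment_report(config$read_stats,
                                              config$depth_summary,
                                              control = config$control))
    if (!is.null(out_dir))
      write_enrichment_report(rep, file.path(out_dir, "metrics.json"),
                              file.path(out_dir, "treatment_summary.tsv"))
    return(list(mode = "fixture", metrics = unclass(rep)))
  }

  if (config$mode == "synthetic") {
    study <- stage("simulate",
                   simulate_study(config$sim, config$treatments,
                                  config$depths, config$n_replicates,
                                  de = config$de))
    annotation <- study$annotation
    manifest <- study$manifest
    reads <- study$reads
    if (!is.null(out_dir))
      write_gff3(annotation, file.path(out_dir, "annotation.gff3"))
  } else {
    manifest <- config$manifest
    annotation <- stage("read annotation", read_gff(config$annotation_path))
    reads <- stage("read alignments", {
      r <- lapply(seq_len(nrow(manifest)), function(i)
        read_alignments(manifest$path[i], manifest$format[i]))
      names(r) <- manifest$sample_id
      r
    })
    study <- NULL
  }

  cls <- stage("classify", {
    out <- lapply(manifest$sample_id, function(sid)
      classify_reads(reads[[sid]], annotation, sample_id = sid))
    names(out) <- manifest$sample_id
    out
  })
  cm <- stage("count matrix", build_count_matrix(cls, annotation))
  condA <- manifest$condition == if ("condition" %in% names(manifest))
    manifest$condition[1] else TRUE
  tab <- stage("tabulate",
               tabulate_samples(lapply(cls[manifest$sample_id[condA]],
                                       `[[`, "counts"),
                                treatment = manifest$treatment[condA]))
  if (!is.null(out_dir)) {
    write_count_matrix(cm, file.path(out_dir, "counts.tsv"))
    write_category_report(tab, file.path(out_dir, "samples.tsv"),
                          file.path(out_dir, "samples.json"))
  }

  # detection threshold per treatment on pooled condition-A replicates
  dth_stage <- stage("detection threshold", {
    out <- list()
    for (tr in unique(manifest$treatment)) {
      sel <- manifest$sample_id[condA & manifest$treatment == tr]
      pooled <- rowSums(cm$counts[, sel, drop = FALSE])
      hist <- depth_histogram(pooled)
      est <- tryCatch({
        fit <- fit_geometric(hist, config$fit_range)
        dth <- estimate_dth(fit, hist, criterion = config$dth_criterion,
                            tau = config$dth_tau)
        list(fit = fit, dth = dth)
      }, error = function(e) e)
      if (inherits(est, "error")) {
        out[[tr]] <- list(pooled = pooled, hist = hist,
                          error = conditionMessage(est))
        next
      }
      out[[tr]] <- list(pooled = pooled, hist = hist, fit = est$fit,
                        dth = est$dth,
                        above = genes_above_dth(pooled, est$dth))
    }
    out
  })
  control <- config$control
  if (!control %in% manifest$treatment)
    stop("pipeline stage 'detection threshold' failed: control treatment '",
         control, "' not in manifest")
  if (!is.null(out_dir) && !is.null(dth_stage[[control]]$fit))
    write_dth_outputs(dth_stage[[control]]$hist, dth_stage[[control]]$fit,
                      dth_stage[[control]]$dth,
                      path_tsv = file.path(out_dir, "depth_histogram.tsv"),
                      path_json = file.path(out_dir, "dth.json"))

  metrics <- stage("metrics", {
    rs <- tab$samples
    n_cds <- sum(annotation$category == "CDS")
    ds <- do.call(rbind, lapply(unique(manifest$treatment), function(tr) {
      sel <- condA & manifest$treatment == tr
      above <- if (!is.null(dth_stage[[tr]]$above))
        dth_stage[[tr]]$above$n_genes else NA_integer_
      data.frame(treatment = tr,
                 observed_reads = sum(vapply(cls[manifest$sample_id[sel]],
                                             function(x) x$counts$total_reads,
                                             numeric(1))) / sum(sel),
                 cds_above_dth = above,
                 fraction_covered = if (!is.na(above) && above > 0)
                   above / n_cds else NA_real_,
                 stringsAsFactors = FALSE)
    }))
    ds_ok <- ds[!is.na(ds$fraction_covered) & ds$fraction_covered > 0, ]
    enrichment_report(rs, if (nrow(ds_ok) >= 2) ds_ok else NULL,
                      control = control)
  })
  if (!is.null(out_dir))
    write_enrichment_report(metrics, file.path(out_dir, "metrics.json"),
                            file.path(out_dir, "treatment_summary.tsv"))

  # replicate-averaged RPKM per treatment (condition A)
  mean_rpkm <- function(tr) {
    sel <- manifest$sample_id[condA & manifest$treatment == tr]
    prof <- vapply(sel, function(sid)
      rpkm(cm$counts[, sid], cm$lengths,
           cls[[sid]]$counts$mapped_reads), numeric(nrow(cm$counts)))
    rowMeans(prof)
  }
  correlations <- stage("abundance correlations", {
    ref_above <- dth_stage[[control]]$above
    if (is.null(ref_above) || ref_above$n_genes < 3) {
      list()
    } else {
      ctrl_prof <- mean_rpkm(control)
      out <- list()
      for (tr in setdiff(unique(manifest$treatment), control)) {
        out[[paste0(tr, "_vs_", control)]] <-
          log_correlation(ctrl_prof, mean_rpkm(tr),
                          subset = ref_above$genes,
                          label = sprintf("%s genes above DTh (n=%d)",
                                          control, ref_above$n_genes))
      }
      out
    }
  })
  if (!is.null(out_dir) && length(correlations))
    write_correlations(correlations,
                       file.path(out_dir, "correlations.tsv"),
                       file.path(out_dir, "correlations.json"))

  diffexpr <- NULL
  de_treatments <- unique(manifest$treatment[manifest$condition !=
                                               manifest$condition[1]])
  if (length(de_treatments)) {
    diffexpr <- stage("differential expression", {
      # mirror the reference procedure: genes entering the DE comparison
      # must be above the detection threshold in every treatment compared
      above_de <- lapply(de_treatments, function(tr) {
        sel <- manifest$sample_id[manifest$treatment == tr]
        pooled <- rowSums(cm$counts[, sel, drop = FALSE])
        hist <- depth_histogram(pooled)
        dth <- tryCatch(
          estimate_dth(fit_geometric(hist, config$fit_range), hist,
                       criterion = config$dth_criterion,
                       tau = config$dth_tau)$dth,
          error = function(e) 1L)
        genes_above_dth(pooled, dth)$genes
      })
      genes_de <- Reduce(intersect, above_de)
      if (length(genes_de) < 3) {
        # degenerate background fit (no decaying low-count regime can
        # leave an absurd threshold); fall back to genes detected in
        # every compared treatment
        detected <- lapply(de_treatments, function(tr) {
          sel <- manifest$sample_id[manifest$treatment == tr]
          rownames(cm$counts)[rowSums(cm$counts[, sel, drop = FALSE]) > 0]
        })
        genes_de <- Reduce(intersect, detected)
      }
      res <- list()
      for (tr in de_treatments) {
        sel <- manifest$treatment == tr
        res[[tr]] <- diff_expression(cm$counts[genes_de,
                                               manifest$sample_id[sel],
                                               drop = FALSE],
                                     groups = manifest$condition[sel])
      }
      out <- list(results = res, deg = lapply(res, deg_select,
                                              p_cut = config$p_cut,
                                              fc_cut = config$fc_cut))
      if (length(res) >= 2) {
        prs <- utils::combn(names(res), 2, simplify = FALSE)
        out$fc_correlation <- lapply(prs, function(pr) {
          genes <- out$deg[[pr[1]]]$significant
          fc <- unclass(fc_correlation(res[[pr[1]]], res[[pr[2]]],
                                       genes = genes))
          # abundance-level correlation of the same pair (condition A,
          # first treatment's above-DTh genes) for the robustness contrast
          ab1 <- dth_stage[[pr[1]]]$above
          ab_r <- if (!is.null(ab1) && ab1$n_genes >= 3)
            log_correlation(mean_rpkm(pr[1]), mean_rpkm(pr[2]),
                            subset = ab1$genes)$r else NA_real_
          c(list(pair = paste(pr, collapse = "_vs_")), fc,
            list(abundance_r = ab_r))
        })
      }
      out
    })
    if (!is.null(out_dir)) {
      for (tr in names(diffexpr$results))
        write_diffexpr(diffexpr$results[[tr]],
                       file.path(out_dir, paste0("diffexpr_", tr, ".tsv")),
                       file.path(out_dir, paste0("diffexpr_", tr, ".json")))
    }
  }

  list(mode = config$mode,
       samples = tab$samples,
       treatments = tab$treatments,
       dth = lapply(dth_stage, function(x)
         if (!is.null(x$dth)) list(dth = x$dth$dth,
                                   criterion = x$dth$criterion,
                                   p_hat = x$fit$p_hat,
                                   r_squared = x$fit$r_squared,
                                   n_above = x$above$n_genes)
         else list(error = "background fit not possible")),
       metrics = unclass(metrics),
       correlations = lapply(correlations, unclass),
       diffexpr = if (!is.null(diffexpr))
         list(deg = lapply(diffexpr$deg, lapply, length),
              fc_correlation = diffexpr$fc_correlation),
       de_truth = if (!is.null(study) && !is.null(study$de_truth))
         study$de_truth)
}
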