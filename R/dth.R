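#' Histogram of reads per transcript
#'
#' Tabulates how many transcripts are covered by exactly `k` reads, the
#' input to the geometric-null detection-threshold fit.
#'
#' @param counts Integer vector of per-transcript read counts (typically
#'   one CDS column of a [count_matrix()]).
#' @return A `depth_histogram` data frame with columns `k` (depth) and
#'   `n` (number of transcripts at that depth); only observed depths are
#'   listed, including `k = 0` when present, and `sum(n)` equals the
#'   number of transcripts.
#' @export
#' @examples
#' depth_histogram(c(0, 1, 1, 2, 5))
depth_histogram <- function(counts) {
  tab <- table(counts)
  out <- data.frame(k = as.integer(names(tab)), n = as.integer(tab))
  out <- out[order(out$k), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("depth_histogram", "data.frame")
  out
}

#' Fit the geometric null to a depth histogram
#'
#' Under a geometric background model, `P(X = k) = p^(k-1) * (1 - p)`,
#' the log10 frequency of transcripts at depth `k` is linear in `k` with
#' slope `log10(p)`. This fits that line by ordinary least squares over
#' the positive-count bins of the histogram and reports the implied
#' geometric parameter `p_hat = 10^slope`.
#'
#' The default fit range runs from `k = 1` to the largest depth with at
#' least 5 transcripts, capped at 50: depth 0 is not part of the
#' geometric support and the sparse upper tail is excluded, where log
#' counts are noisy and would otherwise dominate the fit.
#'
#' @param hist A [depth_histogram()].
#' @param fit_range Optional `c(k_lo, k_hi)` limits; `k_lo` must be at
#'   least 1.
#' @return A `geometric_fit` list: `p_hat`, `slope`, `intercept` (log10
#'   scale), `slope_se`, `r_squared`, `fit_range`, `n_points`.
#' @export
#' @examples
#' h <- depth_histogram(rep(1:5, times = c(160, 80, 40, 20, 10)))
#' fit <- fit_geometric(h)
#' fit$p_hat  # 0.5: counts halve with each extra read
fit_geometric <- function(hist, fit_range = NULL) {
  stopifnot(inherits(hist, "depth_histogram"))
  if (is.null(fit_range)) {
    dense <- hist$k[hist$k >= 1 & hist$n >= 5]
    if (!length(dense))
      stop("cannot fit geometric null: no depth bin with >= 5 transcripts")
    fit_range <- c(1, min(max(dense), 50))
  }
  if (fit_range[1] < 1) stop("fit_range must start at k >= 1")
  pts <- hist[hist$k >= fit_range[1] & hist$k <= fit_range[2] & hist$n > 0, ]
  if (nrow(pts) < 3)
    stop("cannot fit geometric null: fewer than 3 positive-count depths in fit range")
  fit <- lm(log10(n) ~ k, data = pts)
  sm <- summary(fit)
  slope <- unname(coef(fit)[2])
  structure(list(p_hat = 10^slope,
                 slope = slope,
                 intercept = unname(coef(fit)[1]),
                 slope_se = sm$coefficients[2, 2],
                 r_squared = sm$r.squared,
                 fit_range = fit_range,
                 n_points = nrow(pts)),
            class = "geometric_fit")
}

#' Derive the detection threshold from a geometric-null fit
#'
#' The detection threshold (DTh) is the minimum number of reads a
#' transcript must attract before it is called significantly expressed
#' rather than background. Two criteria are available:
#'
#' * `"expected_below_one"` (default): the smallest integer `k` at which
#'   the fitted background line expects fewer than one transcript, i.e.
#'   `intercept + slope * k < 0`.
#' * `"departure"`: the smallest `k` at which the observed count exceeds
#'   `tau` times the fitted background, i.e. where the data visibly
#'   depart from the null; requires `hist`.
#'
#' @param fit A [fit_geometric()] result; the slope must be negative (a
#'   non-decaying background has no finite threshold).
#' @param hist The [depth_histogram()] (needed for `"departure"`).
#' @param criterion Threshold rule, see above.
#' @param tau Departure factor for the `"departure"` criterion.
#' @return A `dth_estimate` list: `dth` (integer, >= 1), `criterion`,
#'   `tau` (departure only).
#' @export
#' @examples
#' f <- structure(list(slope = log10(0.5), intercept = 3), class = "geometric_fit")
#' estimate_dth(f)$dth  # 10
estimate_dth <- function(fit, hist = NULL,
                         criterion = c("expected_below_one", "departure"),
                         tau = 10) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(fit, "geometric_fit"))
  if (!is.finite(fit$slope) || fit$slope >= 0)
    stop("background does not decay (slope >= 0): detection threshold undefined")
  if (criterion == "expected_below_one") {
    dth <- max(1L, as.integer(floor(-fit$intercept / fit$slope)) + 1L)
    return(structure(list(dth = dth, criterion = criterion),
                     class = "dth_estimate"))
  }
  if (is.null(hist))
    stop("the departure criterion requires the depth histogram")
  ks <- hist$k[hist$k >= 1]
  ns <- hist$n[hist$k >= 1]
  expected <- 10^(fit$intercept + fit$slope * ks)
  dep <- which(ns > tau * expected)
  if (!length(dep))
    stop(sprintf("no depth departs from the fitted null by more than %g-fold",
                 tau))
  structure(list(dth = as.integer(ks[dep[1]]), criterion = criterion,
                 tau = tau),
            class = "dth_estimate")
}

#' Genes at or above the detection threshold
#'
#' Selects the genes considered significantly expressed: those covered by
#' at least `dth` reads (inclusive).
#'
#' @param counts Named vector of per-gene read counts.
#' @param dth Integer threshold (>= 1), or a [estimate_dth()] result.
#' @return A list with `genes` (character vector of ids) and `n_genes`.
#' @export
#' @examples
#' genes_above_dth(c(g1 = 0, g2 = 5, g3 = 20, g4 = 21), 20)
genes_above_dth <- function(counts, dth) {
  if (inherits(dth, "dth_estimate")) dth <- dth$dth
  if (dth < 1) stop("dth must be >= 1")
  genes <- names(counts)[counts >= dth]
  list(genes = genes, n_genes = length(genes))
}

#' Export a depth histogram and geometric fit
#'
#' Writes the histogram as TSV and the fit (with threshold, if given) as
#' JSON; optionally draws the diagnostic plot of read depth against log10
#' transcript count with the fitted background line.
#'
#' @param hist A [depth_histogram()].
#' @param fit A [fit_geometric()] result.
#' @param dth Optional [estimate_dth()] result.
#' @param path_tsv,path_json,path_plot Output paths (any may be `NULL`).
#' @return Invisibly, `NULL`.
#' @export
write_dth_outputs <- function(hist, fit, dth = NULL, path_tsv = NULL,
                              path_json = NULL, path_plot = NULL) {
  if (!is.null(path_tsv))
    write.table(hist, path_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(path_json)) {
    payload <- unclass(fit)
    if (!is.null(dth)) payload <- c(payload, unclass(dth))
    jsonlite::write_json(payload, path_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  if (!is.null(path_plot)) {
    grDevices::pdf(path_plot, width = 6, height = 5)
    on.exit(grDevices::dev.off())
    pos <- hist[hist$n > 0 & hist$k >= 1, ]
    plot(pos$k, log10(pos$n), xlab = "read depth (reads per transcript)",
         ylab = "log10 transcript count", pch = 16, cex = 0.6)
    graphics::abline(fit$intercept, fit$slope, col = "red")
    if (!is.null(dth)) graphics::abline(v = dth$dth, lty = 2)
  }
  invisible(NULL)
}
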