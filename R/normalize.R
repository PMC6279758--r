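#' Remove genes with low average count
#'
#' A gene is kept iff its mean raw count over the retained cells is at
#' least `min_mean` (default 1, i.e. "fewer than one count on average" is
#' removed).  Spike-ins are filtered by the same rule; the numbers of
#' endogenous genes and spike-ins kept are reported as a message.
#'
#' @param counts a [count_matrix()] (QC-excluded cells already dropped).
#' @param min_mean minimum mean raw count.
#' @return filtered [count_matrix()].
#' @export
filter_genes <- function(counts, min_mean = 1) {
  stopifnot(inherits(counts, "count_matrix"))
  keep <- rowMeans(counts$counts) >= min_mean
  if (!any(keep)) abort("all genes removed by the mean-count filter")
  out <- subset_counts(counts, genes = keep)
  inform(sprintf("kept %d endogenous genes and %d spike-ins",
                 sum(!out$is_spikein), sum(out$is_spikein)))
  out
}

#' RPKM normalization
#'
#' value(g, c) = counts(g, c) / (length_kb(g) * exon_total(c) / 1e6), with
#' exon_total(c) the cell's total endogenous count.  Spike-ins are
#' normalized with the same (endogenous) denominator, so per-cell sequencing
#' depth divides out of every gene identically.
#'
#' @param counts a [count_matrix()].
#' @return an [expr_matrix()] on the `raw_rpkm` scale.
#' @export
rpkm <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  exon_total <- colSums(counts$counts[!counts$is_spikein, , drop = FALSE])
  if (any(exon_total == 0))
    abort(paste("zero endogenous count sum in cell:",
                colnames(counts$counts)[which(exon_total == 0)[1]]))
  len_kb <- counts$gene_length_bp / 1000
  vals <- sweep(counts$counts / len_kb, 2, exon_total / 1e6, "/")
  expr_matrix(vals, scale = "raw_rpkm", is_spikein = counts$is_spikein)
}

#' Elementwise log2(x + 1)
#'
#' @param expr an [expr_matrix()] on the `raw_rpkm` scale.
#' @return an [expr_matrix()] on the `log2p1` scale.
#' @export
log2p1 <- function(expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (expr$scale != "raw_rpkm")
    abort("log2p1 expects a raw_rpkm matrix (already log-transformed?)")
  expr_matrix(log2(expr$values + 1), scale = "log2p1",
              is_spikein = expr$is_spikein)
}

#' Fit the spike-in technical-noise law CV^2(mu) = a1/mu + alpha0
#'
#' Squared coefficient of variation of each spike-in across cells is
#' regressed on the reciprocal of its mean with a gamma-family generalized
#' linear fit (identity link), the standard approach for spike-in noise
#' calibration.  The fit is done on raw spike-in counts: the spike volume
#' is identical in every well, so counts are directly comparable across
#' cells and dividing by the endogenous depth would confound cellular RNA
#' content with technical noise.  Negative coefficients are clipped at 0
#' with a warning.
#'
#' @param counts a [count_matrix()] containing spike-ins, or a plain
#'   numeric matrix of spike-in counts (spike-ins x cells).
#' @return object of class `technoise_fit`: `a1`, `alpha0`,
#'   `n_spikeins_used`, and the per-spike-in `points` tibble (mu, cv2).
#' @export
fit_technical_noise <- function(counts) {
  if (inherits(counts, "count_matrix")) {
    if (!any(counts$is_spikein)) abort("no spike-ins present")
    m <- counts$counts[counts$is_spikein, , drop = FALSE]
  } else {
    m <- as.matrix(counts)
  }
  mu <- rowMeans(m)
  v <- apply(m, 1, var)
  ok <- mu > 0
  mu <- mu[ok]; v <- v[ok]
  if (length(mu) < 10)
    abort("need at least 10 spike-ins with nonzero mean")
  cv2 <- v / mu^2
  pts <- tibble::tibble(spikein = names(mu), mu = mu, cv2 = cv2)
  if (all(cv2 < 1e-12)) {
    a1 <- 0; alpha0 <- 0
  } else {
    fit <- statmod::glmgam.fit(cbind(alpha0 = 1, a1 = 1 / mu),
                               pmax(cv2, 1e-12))
    a1 <- unname(fit$coefficients["a1"])
    alpha0 <- unname(fit$coefficients["alpha0"])
    if (a1 < 0 || alpha0 < 0) {
      warn("negative technical-noise coefficient clipped at 0")
      a1 <- max(a1, 0); alpha0 <- max(alpha0, 0)
    }
  }
  structure(list(a1 = a1, alpha0 = alpha0,
                 n_spikeins_used = length(mu), points = pts),
            class = "technoise_fit")
}

#' @export
print.technoise_fit <- function(x, ...) {
  cat(sprintf(
    "<technoise_fit> CV^2 = %.4g/mu + %.4g  (%d spike-ins used)\n",
    x$a1, x$alpha0, x$n_spikeins_used))
  invisible(x)
}

#' Predict technical CV^2 at given means
#'
#' @param object a `technoise_fit`.
#' @param mu means at which to evaluate the fitted law.
#' @param ... unused.
#' @return numeric vector of fitted CV^2.
#' @export
predict.technoise_fit <- function(object, mu, ...) {
  object$a1 / mu + object$alpha0
}

#' Select highly variable genes against the spike-in noise law
#'
#' Each endogenous gene's biological-variation score is its observed CV^2
#' minus the technical CV^2 predicted at its mean by the spike-in fit
#' (excess over technical noise), computed in the same raw-count space as
#' the fit so observed and expected share units.  `top_k` mode returns
#' exactly `k` genes (ties broken lexicographically by gene ID);
#' `significance` mode tests the CV^2 ratio against the fitted curve with
#' a chi-square test on `n_cells - 1` degrees of freedom and keeps genes
#' at the requested BH-adjusted FDR.
#'
#' @param counts a [count_matrix()] (filtered; spike-ins ignored here).
#' @param fit a `technoise_fit`.
#' @param mode `"top_k"` or `"significance"`.
#' @param k number of genes for `top_k` mode (classic choice: the same
#'   order as a few hundred genes, e.g. 557 at full scale).
#' @param fdr FDR cutoff for `significance` mode.
#' @return object of class `hvg_selection`: tibble `ranking` (gene, mu,
#'   cv2, score, rank, selected) plus the `selected` gene IDs.
#' @export
select_hvg <- function(counts, fit, mode = c("top_k", "significance"),
                       k = 557, fdr = 0.01) {
  mode <- match.arg(mode)
  stopifnot(inherits(counts, "count_matrix"), inherits(fit, "technoise_fit"))
  m <- counts$counts[!counts$is_spikein, , drop = FALSE]
  n_cells <- ncol(m)
  mu <- rowMeans(m)
  cv2 <- apply(m, 1, var) / mu^2
  score <- cv2 - predict(fit, mu)
  ord <- order(-score, names(mu))
  rk <- tibble::tibble(gene = names(mu)[ord], mu = mu[ord], cv2 = cv2[ord],
                       score = score[ord], rank = seq_along(ord))
  if (mode == "top_k") {
    if (k > nrow(rk)) abort("k exceeds the number of endogenous genes")
    rk$selected <- rk$rank <= k
  } else {
    df <- n_cells - 1
    ratio <- rk$cv2 / pmax(predict(fit, rk$mu), 1e-12)
    p <- stats::pchisq(ratio * df, df = df, lower.tail = FALSE)
    rk$p_adj <- p.adjust(p, "BH")
    rk$selected <- rk$p_adj < fdr
  }
  structure(list(ranking = rk, selected = rk$gene[rk$selected],
                 mode = mode, fit = fit),
            class = "hvg_selection")
}

#' @export
print.hvg_selection <- function(x, ...) {
  cat(sprintf("<hvg_selection [%s]> %d of %d genes selected\n",
              x$mode, length(x$selected), nrow(x$ranking)))
  invisible(x)
}
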