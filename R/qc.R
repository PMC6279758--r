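#' Compute the five per-cell quality-control metrics
#'
#' The metrics are (1) exon reads, (2) percent uniquely mapping reads
#' (unique / total), (3) percent exon reads (exon / unique), (4) the
#' fraction of a cell's endogenous counts carried by its single most
#' expressed gene (a scale-free stand-in for "extreme RPKM values": it
#' flags degenerate libraries dominated by one transcript), and (5) the
#' maximum pairwise Spearman correlation of the cell's log2(RPKM + 1)
#' endogenous expression against every other cell.
#'
#' @param counts a [count_matrix()] over all cells.
#' @param align_summary data frame with columns `cell`, `total_reads`,
#'   `unique_reads`, `exon_reads` covering every cell in `counts`.
#' @return tibble with one row per cell: `cell`, `exon_reads`,
#'   `pct_unique_mapping`, `pct_exon_reads`, `top_gene_fraction`,
#'   `max_spearman`.
#' @export
compute_qc_metrics <- function(counts, align_summary) {
  stopifnot(inherits(counts, "count_matrix"))
  cells <- colnames(counts$counts)
  if (length(cells) < 3)
    abort("need at least 3 cells (max pairwise correlation undefined)")
  al <- as.data.frame(align_summary)
  if (!all(cells %in% al$cell))
    abort("align_summary must cover every cell in counts")
  al <- al[match(cells, al$cell), ]

  endo <- counts$counts[!counts$is_spikein, , drop = FALSE]
  tot <- colSums(endo)
  if (any(tot == 0))
    abort(paste("cell with zero endogenous counts:",
                cells[which(tot == 0)[1]]))
  top_frac <- apply(endo, 2, max) / tot

  lr <- log2p1(rpkm(counts))
  lv <- lr$values[!lr$is_spikein, , drop = FALSE]
  sp <- cor(lv, method = "spearman")
  diag(sp) <- -Inf
  max_sp <- apply(sp, 2, max)

  tibble::tibble(
    cell = cells,
    exon_reads = as.numeric(al$exon_reads),
    pct_unique_mapping = 100 * al$unique_reads / al$total_reads,
    pct_exon_reads = 100 * al$exon_reads / al$unique_reads,
    top_gene_fraction = as.numeric(top_frac),
    max_spearman = as.numeric(max_sp)
  )
}

qc_metric_cols <- c("exon_reads", "pct_unique_mapping", "pct_exon_reads",
                    "top_gene_fraction", "max_spearman")

#' Flag QC outliers and mark cells for exclusion
#'
#' A cell is flagged on a metric when it lies more than `n_sd` standard
#' deviations from that metric's mean (two-sided); exon reads are
#' additionally flagged below a hard floor regardless of the SD rule.  A
#' cell is excluded when it is flagged on at least `min_flags` metrics.
#' Means and SDs are computed once over all cells, prospective outliers
#' included (a single pass, no iteration).  A metric with zero SD flags
#' nothing and triggers a warning.
#'
#' @param qc output of [compute_qc_metrics()].
#' @param n_sd SD multiplier for the outlier rule (default 2).
#' @param exon_read_floor hard minimum exon reads (default 10,000).
#' @param min_flags flags needed for exclusion (default 2).
#' @return `qc` with logical `flag_*` columns, `n_flags` and `excluded`.
#' @export
flag_qc_outliers <- function(qc, n_sd = 2, exon_read_floor = 10000,
                             min_flags = 2) {
  stopifnot(n_sd > 0, exon_read_floor > 0, min_flags >= 1)
  out <- tibble::as_tibble(qc)
  flags <- matrix(FALSE, nrow(out), length(qc_metric_cols),
                  dimnames = list(NULL, qc_metric_cols))
  for (m in qc_metric_cols) {
    x <- out[[m]]
    if (!all(is.finite(x))) abort(paste("non-finite values in metric", m))
    s <- sd(x)
    if (s == 0) {
      warn(paste("zero SD in QC metric", m, "- no cells flagged by it"))
      f <- rep(FALSE, length(x))
    } else {
      f <- abs(x - mean(x)) > n_sd * s
    }
    if (m == "exon_reads") f <- f | (x < exon_read_floor)
    flags[, m] <- f
  }
  colnames(flags) <- paste0("flag_", qc_metric_cols)
  out <- dplyr::bind_cols(out, tibble::as_tibble(flags))
  out$n_flags <- rowSums(flags)
  out$excluded <- out$n_flags >= min_flags
  out
}

#' Compare QC metric distributions between plates
#'
#' Reports, per mapping metric, the two-sample rank-sum p-value between the
#' two plates.  This is a diagnostic only - nothing is acted on - mirroring
#' the practice of checking that plate of origin does not drive genome-wide
#' differences before pooling cells.
#'
#' @param qc output of [compute_qc_metrics()] (flagged or not).
#' @param plate factor/character of plate labels aligned with `qc$cell`.
#' @param metrics metrics to compare; defaults to the three mapping
#'   metrics (exon reads, percent unique, percent exon).
#' @return tibble: metric, p_value, n per plate.
#' @export
plate_bias_report <- function(qc, plate,
                              metrics = c("exon_reads",
                                          "pct_unique_mapping",
                                          "pct_exon_reads")) {
  plate <- as.factor(plate)
  if (nlevels(droplevels(plate)) < 2)
    abort("plate comparison needs at least 2 plates")
  if (nlevels(droplevels(plate)) > 2)
    abort("rank-sum comparison is defined for exactly 2 plates")
  plate <- droplevels(plate)
  g1 <- plate == levels(plate)[1]
  purrr::map_dfr(metrics, function(m) {
    x <- qc[[m]][g1]; y <- qc[[m]][!g1]
    p <- if (length(unique(c(x, y))) == 1) 1
         else suppressWarnings(wilcox.test(x, y, exact = FALSE)$p.value)
    tibble::tibble(metric = m, p_value = p,
                   n_plate1 = length(x), n_plate2 = length(y))
  })
}
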