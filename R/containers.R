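#' Gene-by-cell count container
#'
#' Light S3 wrapper around an integer gene x cell count matrix carrying the
#' two per-gene annotations the pipeline needs: a spike-in flag and the gene
#' model length in base pairs.  Spike-ins (exogenous RNA of known
#' concentration added to every lysate) calibrate the technical-noise model;
#' gene lengths feed RPKM normalization.
#'
#' @param counts non-negative integer matrix, genes as rows, with unique
#'   rownames (gene IDs) and colnames (cell IDs).
#' @param gene_length_bp named positive integer vector covering every gene.
#' @param is_spikein optional named logical per gene; when `NULL`, spike-ins
#'   are flagged by `spikein_prefix` on the gene ID.
#' @param spikein_prefix gene-ID prefix identifying spike-ins (default
#'   `"ERCC-"`).
#' @return object of class `count_matrix` with elements `counts`,
#'   `is_spikein`, `gene_length_bp`.
#' @export
count_matrix <- function(counts, gene_length_bp, is_spikein = NULL,
                         spikein_prefix = "ERCC-") {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  genes <- rownames(counts)
  if (is.null(genes) || anyDuplicated(genes))
    abort("counts must have unique rownames (gene IDs)")
  if (is.null(colnames(counts)))
    abort("counts must have colnames (cell IDs)")
  if (anyNA(counts) || any(counts < 0))
    abort("counts must be non-negative and complete")
  if (any(abs(counts - round(counts)) > 1e-8))
    abort("counts must be integral")
  storage.mode(counts) <- "double"
  counts <- round(counts)
  missing <- setdiff(genes, names(gene_length_bp))
  if (length(missing) > 0)
    abort(paste0("missing gene length for: ",
                 paste(head(missing, 5), collapse = ", ")))
  len <- gene_length_bp[genes]
  if (any(!is.finite(len)) || any(len < 1))
    abort("every gene length must be a finite value >= 1 bp")
  if (is.null(is_spikein)) {
    is_spikein <- startsWith(genes, spikein_prefix)
    names(is_spikein) <- genes
  } else {
    is_spikein <- is_spikein[genes]
  }
  structure(
    list(counts = counts, is_spikein = is_spikein, gene_length_bp = len),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes (%d spike-ins) x %d cells\n",
              nrow(x$counts), sum(x$is_spikein), ncol(x$counts)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix
#'
#' @param x a [count_matrix()].
#' @param genes,cells character or logical or integer index; `NULL` keeps all.
#' @return a `count_matrix`.
#' @export
subset_counts <- function(x, genes = NULL, cells = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  m <- x$counts
  if (!is.null(genes)) m <- m[genes, , drop = FALSE]
  if (!is.null(cells)) m <- m[, cells, drop = FALSE]
  count_matrix(m, x$gene_length_bp, is_spikein = x$is_spikein)
}

#' Expression-matrix container with a recorded scale
#'
#' @param values numeric gene x cell matrix (dimnames required).
#' @param scale one of `"raw_rpkm"`, `"log2p1"`.
#' @param is_spikein named logical per gene (optional, defaults to all FALSE).
#' @return object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, scale = c("raw_rpkm", "log2p1"),
                        is_spikein = NULL) {
  scale <- match.arg(scale)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    abort("values must carry gene and cell dimnames")
  if (any(values < 0) || anyNA(values))
    abort("expression values must be non-negative and complete")
  if (is.null(is_spikein))
    is_spikein <- setNames(rep(FALSE, nrow(values)), rownames(values))
  structure(list(values = values, scale = scale,
                 is_spikein = is_spikein[rownames(values)]),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix [%s]> %d genes x %d cells\n",
              x$scale, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Bulk expression container (samples x genes, log2 scale)
#'
#' Bulk cohort matrices are stored samples-as-rows because every downstream
#' consumer (signature compaction, metagene scoring, the matched-cohort
#' model) is per-sample.  Values are assumed log2-transformed with an offset
#' already applied.
#'
#' @param values numeric samples x genes matrix with unique rownames
#'   (sample IDs) and colnames (gene IDs).
#' @return object of class `bulk_matrix` (a plain matrix subclass).
#' @export
bulk_matrix <- function(values) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    abort("bulk matrix needs unique sample rownames")
  if (is.null(colnames(values)))
    abort("bulk matrix needs gene colnames")
  if (!all(is.finite(values)))
    abort("bulk expression values must be finite")
  structure(values, class = c("bulk_matrix", "matrix", "array"))
}
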