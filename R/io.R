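#' Read a raw count matrix with gene lengths and spike-in flags
#'
#' Counts can come as a TSV (first column gene ID, header row of cell IDs)
#' or as a MatrixMarket coordinate file plus sidecar gene / cell ID lists
#' (one ID per line).  Genes are flagged as spike-ins by ID prefix.  Rows
#' and columns are re-ordered canonically (lexicographic by ID) so the
#' result is independent of on-disk ordering.
#'
#' @param path counts file.
#' @param lengths_path two-column TSV (gene ID, length in bp), no header
#'   required; a header line `gene\tlength_bp` is tolerated.
#' @param format `"tsv"` or `"mtx"`; `"auto"` decides by file extension.
#' @param genes_path,cells_path sidecar ID files, required for `"mtx"`.
#' @param spikein_prefix prefix identifying spike-in IDs.
#' @return a [count_matrix()].
#' @export
read_counts <- function(path, lengths_path, format = c("auto", "tsv", "mtx"),
                        genes_path = NULL, cells_path = NULL,
                        spikein_prefix = "ERCC-") {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste("no such file:", path))
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "tsv"
  if (file.size(path) == 0) abort(paste("empty counts file:", path))
  if (format == "tsv") {
    tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (nrow(tab) == 0 || ncol(tab) < 2)
      abort("counts TSV must have a gene-ID column and at least one cell")
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- tab[[1]]
  } else {
    if (is.null(genes_path) || is.null(cells_path))
      abort("MTX input needs genes_path and cells_path sidecar files")
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(genes_path)
    colnames(m) <- readLines(cells_path)
  }
  if (any(abs(m - round(m)) > 1e-8)) abort("non-integer counts in input")
  lt <- read.delim(lengths_path, header = FALSE, stringsAsFactors = FALSE)
  if (identical(tolower(lt[1, 1]), "gene")) lt <- lt[-1, , drop = FALSE]
  lengths <- setNames(as.numeric(lt[[2]]), lt[[1]])
  m <- m[order(rownames(m)), order(colnames(m)), drop = FALSE]
  count_matrix(m, lengths, spikein_prefix = spikein_prefix)
}

#' Write a count matrix as TSV (genes as rows)
#'
#' @param x a [count_matrix()].
#' @param path output TSV.
#' @param lengths_path optional path for the companion gene-length table.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(x, path, lengths_path = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  tab <- data.frame(gene = rownames(x$counts), x$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(lengths_path))
    write.table(data.frame(gene = names(x$gene_length_bp),
                           length_bp = unname(x$gene_length_bp)),
                lengths_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT dialect: set name, description (discarded),
#' then member genes.  Duplicate members within a set are deduplicated;
#' duplicate set names or memberless lines are errors.
#'
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(paste("no such file:", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort("empty GMT file")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  names_ <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(names_))
    abort(paste("duplicate gene-set name:",
                names_[duplicated(names_)][1]))
  sets <- lapply(parts, function(p) {
    members <- unique(p[-(1:2)][nzchar(p[-(1:2)])])
    if (length(p) < 3 || length(members) == 0)
      abort(paste("gene set", p[1], "has no members"))
    members
  })
  setNames(sets, names_)
}

#' Write a signature profile to JSON
#'
#' Signatures are stored as versioned JSON so they are diffable and
#' language-neutral.  Weights must be +1 or -1.
#'
#' @param profile a [signature_profile()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signature <- function(profile, path) {
  stopifnot(inherits(profile, "signature_profile"))
  if (length(profile$genes) == 0) abort("refusing to write an empty profile")
  if (!all(profile$weights %in% c(-1, 1)))
    abort("signature weights must all be +1 or -1")
  obj <- list(schema_version = 1L,
              genes = profile$genes,
              weights = as.integer(profile$weights),
              seed_gene = profile$seed_gene,
              mean_correlation = profile$mean_correlation,
              population = profile$population)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a signature profile written by [write_signature()]
#'
#' @param path JSON file.
#' @return a [signature_profile()].
#' @export
read_signature <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema_version))
    abort("not a signature file: missing schema_version")
  signature_profile(genes = obj$genes, weights = obj$weights,
                    seed_gene = obj$seed_gene,
                    mean_correlation = obj$mean_correlation,
                    population = obj$population %||% NA_character_)
}
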