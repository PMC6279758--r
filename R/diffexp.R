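#' Wilcoxon rank-sum differential expression (cross-check method)
#'
#' Two-sided rank-sum test per gene (exact when group sizes are small and
#' values untied, normal approximation with tie correction otherwise, the
#' standard R convention), Benjamini-Hochberg adjustment across genes,
#' direction by the difference of group means.  A gene whose values are
#' all identical gets p = 1.
#'
#' @inheritParams rots
#' @param fdr_threshold threshold stored for [sde_genes()] (default 0.001).
#' @return tibble of class `de_result`: gene, d (the rank-sum W statistic,
#'   signed by direction), p_value, direction, fdr, rank.
#' @export
wilcoxon_de <- function(x, in_group, fdr_threshold = 0.001,
                        population = NA_character_) {
  v <- if (inherits(x, "expr_matrix")) x$values else as.matrix(x)
  stopifnot(length(in_group) == ncol(v))
  i1 <- which(in_group); i2 <- which(!in_group)
  if (length(i1) < 3 || length(i2) < 3)
    abort("each group needs at least 3 cells")
  res <- apply(v, 1, function(g) {
    x1 <- g[i1]; x2 <- g[i2]
    if (length(unique(g)) == 1) return(c(W = length(x1) * length(x2) / 2,
                                         p = 1))
    w <- suppressWarnings(wilcox.test(x1, x2, alternative = "two.sided"))
    c(W = unname(w$statistic), p = w$p.value)
  })
  diff <- unname(rowMeans(v[, i1, drop = FALSE]) -
                   rowMeans(v[, i2, drop = FALSE]))
  p <- unname(res["p", ])
  out <- tibble::tibble(
    gene = rownames(v) %||% sprintf("g%05d", seq_len(nrow(v))),
    d = sign(diff) * unname(res["W", ]),
    p_value = p,
    direction = ifelse(diff > 0, "up", "down"),
    fdr = p.adjust(p, "BH")
  )
  out$rank <- rank(out$p_value, ties.method = "first")
  attr(out, "method") <- "wilcoxon"
  attr(out, "fdr_threshold") <- fdr_threshold
  class(out) <- c("de_result", class(out))
  out
}

#' Pairwise overlap of SDE gene sets across methods
#'
#' @param results named list; each element is a `de_result` (its SDE set
#'   is extracted) or a plain character vector of genes.
#' @param fdr_threshold threshold applied to `de_result` elements.
#' @return tibble: method_a, method_b, n_a, n_b, overlap, jaccard.
#' @export
overlap_report <- function(results, fdr_threshold = NULL) {
  if (length(results) < 2) abort("need at least 2 gene lists to compare")
  if (is.null(names(results)))
    names(results) <- paste0("method", seq_along(results))
  sets <- purrr::map(results, function(r) {
    if (inherits(r, "de_result")) sde_genes(r, fdr_threshold) else r
  })
  nm <- names(sets)
  combs <- utils::combn(length(sets), 2)
  purrr::map_dfr(seq_len(ncol(combs)), function(j) {
    a <- sets[[combs[1, j]]]; b <- sets[[combs[2, j]]]
    ov <- length(intersect(a, b))
    un <- length(union(a, b))
    tibble::tibble(method_a = nm[combs[1, j]], method_b = nm[combs[2, j]],
                   n_a = length(a), n_b = length(b), overlap = ov,
                   jaccard = if (un == 0) NA_real_ else ov / un)
  })
}

#' Hypergeometric gene-set over-representation
#'
#' For each gene set, the overlap with the query list (e.g. the top 150
#' SDE genes of a population) is tested against the hypergeometric
#' upper tail (probability of at least the observed overlap when drawing
#' `|query|` genes from the universe), with BH adjustment across sets.
#' The gene ratio is overlap / |query|.
#'
#' @param query character vector of genes (must lie in `universe`).
#' @param universe character vector of all considered genes.
#' @param sets named list of gene sets (see [read_gmt()]).
#' @return tibble: set, set_size (within universe), overlap, gene_ratio,
#'   p_value, p_adj, note.  Sets with no member in the universe are kept
#'   with a note and NA p-values.
#' @export
ora_hypergeometric <- function(query, universe, sets) {
  query <- unique(query)
  universe <- unique(universe)
  if (!all(query %in% universe))
    abort("query genes must be a subset of the universe")
  N <- length(universe); n <- length(query)
  out <- purrr::imap_dfr(sets, function(s, nm) {
    s_u <- intersect(unique(s), universe)
    if (length(s_u) == 0)
      return(tibble::tibble(set = nm, set_size = 0L, overlap = 0L,
                            gene_ratio = NA_real_, p_value = NA_real_,
                            note = "no members in universe"))
    k <- length(intersect(s_u, query))
    p <- phyper(k - 1, length(s_u), N - length(s_u), n, lower.tail = FALSE)
    tibble::tibble(set = nm, set_size = length(s_u), overlap = as.integer(k),
                   gene_ratio = k / n, p_value = p, note = NA_character_)
  })
  out$p_adj <- p.adjust(out$p_value, "BH")
  dplyr::arrange(out, .data$p_value)
}
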