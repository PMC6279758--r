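#' Signature profile object
#'
#' An ordered gene list with per-gene weights of +1 or -1, the seed gene
#' the greedy compaction grew from, and the achieved mean pairwise
#' correlation of the member genes.
#'
#' @param genes character vector (order of addition).
#' @param weights +1/-1 per gene (default all +1).
#' @param seed_gene the seed (default first gene).
#' @param mean_correlation achieved mean pairwise correlation.
#' @param population source population tag.
#' @return object of class `signature_profile`.
#' @export
signature_profile <- function(genes, weights = rep(1, length(genes)),
                              seed_gene = genes[1],
                              mean_correlation = NA_real_,
                              population = NA_character_) {
  if (length(genes) > 0 && !all(weights %in% c(-1, 1)))
    abort("weights must all be +1 or -1")
  if (length(weights) != length(genes))
    abort("one weight per gene required")
  structure(list(genes = as.character(genes), weights = as.numeric(weights),
                 seed_gene = seed_gene, mean_correlation = mean_correlation,
                 population = population),
            class = "signature_profile")
}

#' @export
print.signature_profile <- function(x, ...) {
  if (length(x$genes) == 0) {
    cat("<signature_profile> empty (no coherent gene set found)\n")
  } else {
    cat(sprintf(
      "<signature_profile%s> %d genes, seed %s, mean pairwise r = %.3f\n",
      if (is.na(x$population)) "" else paste0(" ", x$population),
      length(x$genes), x$seed_gene, x$mean_correlation))
  }
  invisible(x)
}

#' @export
length.signature_profile <- function(x) length(x$genes)

mean_pairwise <- function(C, idx) {
  sub <- C[idx, idx, drop = FALSE]
  mean(sub[upper.tri(sub)])
}

#' Greedy correlation-based compaction of a gene list
#'
#' Condenses a differential gene list into a compact co-expressed profile
#' on a bulk cohort.  For every candidate seed gene, the remaining genes
#' are ordered by descending Spearman correlation to the seed (ties broken
#' by gene ID) and added one at a time, stopping before the first addition
#' that would drop the mean over all pairwise Spearman correlations of the
#' set below `r_threshold`.  A set is valid only if it has at least two
#' genes and its mean pairwise correlation is at or above the threshold.
#' The result is the largest valid set over all seeds (ties: higher mean
#' correlation, then lexicographically smaller seed).  Weights are all +1
#' (the input is an upregulated list); signed literature signatures can be
#' built directly with [signature_profile()].
#'
#' @param sde_genes character vector (e.g. the SDE genes of a population).
#' @param bulk a [bulk_matrix()] (samples x genes, log2 scale).
#' @param r_threshold mean pairwise correlation floor (default 0.7).
#' @param population tag stored on the profile.
#' @return a [signature_profile()]; empty (0 genes) with a `diagnostic`
#'   attribute when no seed yields a valid set.
#' @export
compact_profile <- function(sde_genes, bulk, r_threshold = 0.7,
                            population = NA_character_) {
  stopifnot(r_threshold > 0, r_threshold <= 1)
  genes <- intersect(sde_genes, colnames(bulk))
  if (length(genes) < 2)
    abort("need at least 2 of the listed genes present in the bulk matrix")
  C <- cor(unclass(bulk)[, genes, drop = FALSE], method = "spearman")
  best <- NULL
  for (seed in genes) {
    others <- setdiff(genes, seed)
    ord <- others[order(-C[seed, others], others)]
    set_idx <- match(seed, genes)
    cur_sum <- 0  # sum of pairwise correlations within the set
    for (cand in ord) {
      ci <- match(cand, genes)
      new_sum <- cur_sum + sum(C[ci, set_idx])
      n <- length(set_idx) + 1
      if (new_sum / (n * (n - 1) / 2) < r_threshold) break
      set_idx <- c(set_idx, ci)
      cur_sum <- new_sum
    }
    if (length(set_idx) < 2) next
    m <- mean_pairwise(C, set_idx)
    if (m < r_threshold) next
    better <- is.null(best) ||
      length(set_idx) > length(best$idx) ||
      (length(set_idx) == length(best$idx) && m > best$m + 1e-12) ||
      (length(set_idx) == length(best$idx) && abs(m - best$m) <= 1e-12 &&
         seed < best$seed)
    if (better) best <- list(idx = set_idx, m = m, seed = seed)
  }
  if (is.null(best)) {
    out <- signature_profile(character(0), numeric(0), seed_gene = NA,
                             population = population)
    attr(out, "diagnostic") <-
      sprintf("no gene set reached mean pairwise Spearman >= %.2f (%d genes tried)",
              r_threshold, length(genes))
    return(out)
  }
  signature_profile(genes[best$idx], seed_gene = best$seed,
                    mean_correlation = best$m, population = population)
}

#' Metagene score of a signature on a bulk cohort
#'
#' The score of a sample is the weighted average of the expression of the
#' member genes with weights +1 or -1; in centered mode each gene's cohort
#' mean is subtracted first (the "mean combined centered expression" used
#' as an abundance proxy), so the cohort mean score is zero.
#'
#' @param bulk a [bulk_matrix()].
#' @param profile a [signature_profile()] (or a character vector of genes,
#'   all weighted +1).
#' @param centered subtract cohort gene means first (default TRUE).
#' @return tibble: sample, score.
#' @export
metagene_score <- function(bulk, profile, centered = TRUE) {
  if (is.character(profile)) profile <- signature_profile(profile)
  stopifnot(inherits(profile, "signature_profile"))
  present <- profile$genes %in% colnames(bulk)
  if (!any(present)) abort("no profile gene present in the bulk matrix")
  if (!all(present))
    warn(paste("dropping absent profile genes:",
               paste(profile$genes[!present], collapse = ", ")))
  g <- profile$genes[present]
  w <- profile$weights[present]
  m <- unclass(bulk)[, g, drop = FALSE]
  if (centered) m <- scale(m, center = TRUE, scale = FALSE)
  tibble::tibble(sample = rownames(bulk),
                 score = as.numeric(m %*% w) / length(g))
}

#' Gene- and signature-level correlation panels on a bulk cohort
#'
#' The gene-level panel is the Pearson correlation between every pair of
#' genes pooled over the given profiles (block structure along the
#' diagonal indicates coherent signatures); the signature-level panel is
#' the Pearson correlation between metagene score vectors.
#'
#' @param bulk a [bulk_matrix()].
#' @param profiles named list of [signature_profile()]s or gene vectors.
#' @param centered passed to [metagene_score()].
#' @return list: `gene_panel` (matrix with a `profile` attribute mapping
#'   genes to profiles), `signature_panel` (matrix).  Zero-variance
#'   vectors yield NA entries with a warning.
#' @export
correlation_panel <- function(bulk, profiles, centered = TRUE) {
  profiles <- purrr::map(profiles, function(p)
    if (is.character(p)) signature_profile(p) else p)
  gene_map <- purrr::imap_dfr(profiles, function(p, nm) {
    keep <- p$genes %in% colnames(bulk)
    tibble::tibble(gene = p$genes[keep], profile = nm)
  })
  m <- unclass(bulk)[, gene_map$gene, drop = FALSE]
  zero_var <- apply(m, 2, sd) == 0
  if (any(zero_var))
    warn(paste("zero-variance gene(s):",
               paste(colnames(m)[zero_var], collapse = ", "),
               "- correlations reported as NA"))
  gene_panel <- suppressWarnings(cor(m, method = "pearson"))
  gene_panel[zero_var, ] <- NA_real_
  gene_panel[, zero_var] <- NA_real_
  attr(gene_panel, "profile") <- gene_map
  scores <- purrr::map(profiles, function(p)
    metagene_score(bulk, p, centered = centered)$score)
  sm <- do.call(cbind, scores)
  colnames(sm) <- names(profiles)
  signature_panel <- suppressWarnings(cor(sm, method = "pearson"))
  list(gene_panel = gene_panel, signature_panel = signature_panel)
}
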