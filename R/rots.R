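#' Reproducibility-optimized test statistic (ROTS) for two groups
#'
#' One-vs-rest differential expression with a data-adaptive statistic
#' family d(alpha) = |m1 - m2| / (alpha1 + alpha2 * s), where s is the
#' pooled standard error of the mean difference.  The free parameters are
#' chosen to maximize the reproducibility of top-ranked gene lists:
#' for every candidate (alpha1, alpha2) and top-list size k, the expected
#' overlap of top-k lists across `B` pairs of within-group bootstrap
#' resamples is compared against the same quantity under group-label
#' permutation, and the pair (alpha*, k*) maximizing the standardized
#' excess Z_k = (R_k - R0_k) / sd(R_k) is selected.  False discovery
#' rates come from `n_perm` group-label permutations of the optimized
#' statistic (plug-in estimate, monotonized so FDR never decreases as |d|
#' decreases).
#'
#' @param x log-scale expression: an [expr_matrix()] (`log2p1`) or a plain
#'   genes x cells matrix.
#' @param in_group logical per cell: TRUE for the population of interest,
#'   FALSE for the pooled rest.
#' @param B number of bootstrap pairs (default 500).
#' @param n_perm permutations for the FDR estimate (default 1000).
#' @param alpha1_grid candidate alpha1 values paired with alpha2 = 1; the
#'   candidate (alpha1 = 1, alpha2 = 0) - plain mean difference - is always
#'   included.
#' @param K_grid candidate top-list sizes; defaults to a geometric ladder
#'   capped at half the number of genes.
#' @param fdr_threshold threshold defining the significantly
#'   differentially expressed (SDE) set (default 0.001).
#' @param population optional label stored in the result.
#' @param seed integer seed (resampling and permutations).
#' @return tibble of class `de_result` with columns gene, d (signed
#'   optimized statistic), direction ("up" = higher in the in-group),
#'   p_value (pooled permutation p), fdr, rank; attributes `alpha`
#'   (chosen pair), `k_opt`, `z_table`, `method`.
#' @export
rots <- function(x, in_group, B = 500, n_perm = 1000,
                 alpha1_grid = seq(0, 5, by = 0.5), K_grid = NULL,
                 fdr_threshold = 0.001, population = NA_character_, seed) {
  if (missing(seed)) abort("seed is mandatory")
  v <- if (inherits(x, "expr_matrix")) x$values else as.matrix(x)
  stopifnot(length(in_group) == ncol(v), B >= 2)
  i1 <- which(in_group); i2 <- which(!in_group)
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 3 || n2 < 3) abort("each group needs at least 3 cells")
  G <- nrow(v)
  if (is.null(K_grid))
    K_grid <- unique(pmin(c(10L, 25L, 50L, 100L, 250L, 500L),
                          max(2L, floor(G / 2))))
  K_grid <- sort(unique(as.integer(K_grid)))
  kmax <- max(K_grid)
  cand <- rbind(
    if (length(alpha1_grid) > 0)
      cbind(a1 = alpha1_grid, a2 = rep(1, length(alpha1_grid))),
    c(a1 = 1, a2 = 0))
  nc <- nrow(cand)
  v2 <- v^2
  s_floor <- sqrt(.Machine$double.eps)

  stat_parts <- function(idx1, idx2) {
    m1 <- rowMeans(v[, idx1, drop = FALSE])
    m2 <- rowMeans(v[, idx2, drop = FALSE])
    q1 <- rowSums(v2[, idx1, drop = FALSE])
    q2 <- rowSums(v2[, idx2, drop = FALSE])
    k1 <- length(idx1); k2 <- length(idx2)
    pooled <- ((q1 - k1 * m1^2) + (q2 - k2 * m2^2)) / (k1 + k2 - 2)
    pooled <- pmax(pooled, 0)
    s <- sqrt(pooled * (1 / k1 + 1 / k2))
    list(diff = m1 - m2, s = s)
  }
  d_for <- function(parts, a1, a2) {
    denom <- a1 + a2 * parts$s
    if (a2 > 0 && a1 == 0) denom <- pmax(denom, s_floor)
    abs(parts$diff) / denom
  }
  overlap_row <- function(da, db) {
    oa <- order(da, decreasing = TRUE)
    ob <- order(db, decreasing = TRUE)
    posb <- integer(G); posb[ob] <- seq_len(G)
    top_pos <- posb[oa[seq_len(kmax)]]
    vapply(K_grid, function(k) sum(top_pos[seq_len(k)] <= k) / k,
           numeric(1))
  }

  set.seed(seed)
  if (any(stat_parts(i1, i2)$s == 0))
    warn("zero-variance gene(s): pooled SE floored at machine epsilon")

  obs_ov <- array(0, c(B, nc, length(K_grid)))
  null_ov <- array(0, c(B, nc, length(K_grid)))
  all_cells <- c(i1, i2)
  for (b in seq_len(B)) {
    r1 <- list(sample(i1, n1, TRUE), sample(i2, n2, TRUE))
    r2 <- list(sample(i1, n1, TRUE), sample(i2, n2, TRUE))
    pa <- stat_parts(r1[[1]], r1[[2]])
    pb <- stat_parts(r2[[1]], r2[[2]])
    perm <- sample(all_cells)
    p1 <- perm[seq_len(n1)]; p2 <- perm[-seq_len(n1)]
    qa <- stat_parts(sample(p1, n1, TRUE), sample(p2, n2, TRUE))
    qb <- stat_parts(sample(p1, n1, TRUE), sample(p2, n2, TRUE))
    for (ci in seq_len(nc)) {
      obs_ov[b, ci, ] <- overlap_row(d_for(pa, cand[ci, 1], cand[ci, 2]),
                                     d_for(pb, cand[ci, 1], cand[ci, 2]))
      null_ov[b, ci, ] <- overlap_row(d_for(qa, cand[ci, 1], cand[ci, 2]),
                                      d_for(qb, cand[ci, 1], cand[ci, 2]))
    }
  }
  R <- apply(obs_ov, c(2, 3), mean)
  R0 <- apply(null_ov, c(2, 3), mean)
  S <- apply(obs_ov, c(2, 3), sd)
  Z <- (R - R0) / pmax(S, 1e-12)
  best <- which(Z == max(Z), arr.ind = TRUE)[1, ]
  a_star <- cand[best[1], ]
  k_star <- K_grid[best[2]]

  parts <- stat_parts(i1, i2)
  parts$diff <- unname(parts$diff)
  d_obs <- unname(d_for(parts, a_star[1], a_star[2]))

  perm_pool <- numeric(0)
  perm_vals <- matrix(0, G, n_perm)
  for (p in seq_len(n_perm)) {
    perm <- sample(all_cells)
    pp <- stat_parts(perm[seq_len(n1)], perm[-seq_len(n1)])
    perm_vals[, p] <- d_for(pp, a_star[1], a_star[2])
  }
  pool <- sort(as.numeric(perm_vals))
  ord <- order(d_obs, decreasing = TRUE)
  d_sorted <- d_obs[ord]
  cnt <- length(pool) - findInterval(d_sorted - 1e-12, pool)
  fdr_sorted <- pmin((cnt / n_perm) / seq_len(G), 1)
  for (i in (G - 1):1)
    fdr_sorted[i] <- min(fdr_sorted[i], fdr_sorted[i + 1])
  fdr <- numeric(G); fdr[ord] <- fdr_sorted
  p_perm <- numeric(G); p_perm[ord] <- cnt / length(pool)
  rank_ <- integer(G); rank_[ord] <- seq_len(G)

  genes <- rownames(v) %||% sprintf("g%05d", seq_len(G))
  out <- tibble::tibble(
    gene = genes,
    d = sign(parts$diff) * d_obs,
    direction = ifelse(parts$diff > 0, "up", "down"),
    p_value = p_perm,
    fdr = fdr,
    rank = rank_,
    population = population
  )
  attr(out, "method") <- "rots"
  attr(out, "alpha") <- a_star
  attr(out, "k_opt") <- k_star
  attr(out, "z_table") <- list(candidates = cand, K = K_grid, Z = Z,
                               R = R, R0 = R0)
  attr(out, "fdr_threshold") <- fdr_threshold
  class(out) <- c("de_result", class(out))
  out
}

#' Extract the significantly differentially expressed (SDE) gene set
#'
#' SDE genes are the upregulated genes below the FDR threshold.
#'
#' @param de a `de_result` (from [rots()] or [wilcoxon_de()]).
#' @param fdr_threshold override of the threshold stored in the result.
#' @return character vector of gene IDs, ordered by rank.
#' @export
sde_genes <- function(de, fdr_threshold = NULL) {
  thr <- fdr_threshold %||% attr(de, "fdr_threshold") %||% 0.001
  sel <- de$direction == "up" & de$fdr < thr
  de$gene[sel][order(de$rank[sel])]
}
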