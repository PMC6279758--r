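#' PCA reduction of an expression matrix
#'
#' Gene-wise centering, no scaling; columns ordered by decreasing explained
#' variance; deterministic sign convention (the largest-|loading| entry of
#' each component is made positive, so results do not depend on LAPACK's
#' arbitrary sign choice).
#'
#' @param expr an [expr_matrix()] (typically log2p1 over the selected HVGs)
#'   or a plain genes x cells matrix.
#' @param n_pcs number of components to keep (default 30).
#' @return cells x n_pcs score matrix with attribute `explained_variance`
#'   (proportion per component).
#' @export
pca_reduce <- function(expr, n_pcs = 30) {
  v <- if (inherits(expr, "expr_matrix")) expr$values else as.matrix(expr)
  x <- t(v)  # cells x genes
  if (n_pcs > min(dim(x))) abort("n_pcs exceeds min(genes, cells)")
  if (all(apply(x, 2, sd) == 0)) abort("constant expression matrix")
  pc <- prcomp(x, center = TRUE, scale. = FALSE, rank. = n_pcs)
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]
  attr(scores, "explained_variance") <-
    (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_pcs)]
  scores
}

#' Repeated t-SNE, keeping the run with the lowest final KL divergence
#'
#' Runs `n_runs` Barnes-Hut t-SNE embeddings of the PCA scores under
#' distinct sub-seeds derived deterministically from `seed`, and returns
#' the embedding whose final objective (the KL divergence between the
#' high- and low-dimensional affinities) is minimal.  All runs'
#' divergences are kept for inspection.
#'
#' @param scores cells x PCs matrix from [pca_reduce()].
#' @param perplexity t-SNE perplexity (default 27); must satisfy
#'   `perplexity < (n_cells - 1) / 3`.
#' @param theta Barnes-Hut accuracy trade-off (default 0.5).
#' @param n_runs number of restarts (default 50).
#' @param seed integer seed driving the sub-seed sequence.
#' @param max_iter gradient-descent iterations per run.
#' @return list: `embedding` (cells x 2, rownames kept), `kl` (divergence
#'   of the chosen run), `all_kl` (per run), `chosen_run`.
#' @export
tsne_best_of <- function(scores, perplexity = 27, theta = 0.5, n_runs = 50,
                         seed, max_iter = 1000) {
  if (missing(seed)) abort("seed is mandatory")
  stopifnot(n_runs >= 1)
  n <- nrow(scores)
  if (perplexity >= (n - 1) / 3)
    abort("perplexity too large: must be < (n_cells - 1) / 3")
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_runs)
  runs <- lapply(sub_seeds, function(s) {
    set.seed(s)
    fit <- Rtsne::Rtsne(scores, dims = 2, perplexity = perplexity,
                        theta = theta, pca = FALSE, max_iter = max_iter,
                        verbose = FALSE, check_duplicates = FALSE)
    list(y = fit$Y, kl = unname(utils::tail(fit$itercosts, 1)))
  })
  kls <- vapply(runs, `[[`, numeric(1), "kl")
  best <- which.min(kls)
  emb <- runs[[best]]$y
  rownames(emb) <- rownames(scores)
  colnames(emb) <- c("x", "y")
  list(embedding = emb, kl = kls[best], all_kl = kls, chosen_run = best)
}

#' Density-based clustering (DBSCAN)
#'
#' Textbook DBSCAN on 2-D points: a point is a core point iff it has at
#' least `min_pts` neighbours within `eps` (Euclidean; the count includes
#' the point itself); clusters are the connected components of core points
#' plus their border points; unreached points are labelled 0 (noise).
#' Cluster numbering follows discovery order over points sorted by ID, so
#' labels are deterministic.
#'
#' @param points n x 2 matrix (rownames = cell IDs used for the scan
#'   order; row order is used when absent).
#' @param eps neighbourhood radius (default 3.1).
#' @param min_pts core-point density threshold (default 5).
#' @return integer labels (1..k, 0 = noise), named by cell ID.
#' @export
dbscan_cluster <- function(points, eps = 3.1, min_pts = 5) {
  if (eps <= 0) abort("eps must be positive")
  points <- as.matrix(points)
  n <- nrow(points)
  ids <- rownames(points) %||% sprintf("p%06d", seq_len(n))
  scan_order <- order(ids)
  d <- as.matrix(dist(points))
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- lengths(nb) >= min_pts
  labels <- rep(0L, n)
  visited <- rep(FALSE, n)
  k <- 0L
  for (i in scan_order) {
    if (visited[i] || !core[i]) next
    k <- k + 1L
    queue <- i
    visited[i] <- TRUE
    labels[i] <- k
    while (length(queue) > 0) {
      p <- queue[1]; queue <- queue[-1]
      for (q in nb[[p]]) {
        if (labels[q] == 0L) labels[q] <- k   # border or new core
        if (core[q] && !visited[q]) {
          visited[q] <- TRUE
          queue <- c(queue, q)
        }
      }
    }
  }
  setNames(labels, ids)
}

#' Assign noise points to their nearest cluster
#'
#' Each noise point takes the label of its nearest non-noise neighbour
#' (Euclidean; ties broken by the smaller cell index).  This generalizes
#' the manual reassignment of stray outliers to a deterministic rule.
#'
#' @param labels integer labels from [dbscan_cluster()] (0 = noise).
#' @param points the matrix the labels were computed on.
#' @return labels with no zeros.
#' @export
resolve_noise <- function(labels, points) {
  points <- as.matrix(points)
  noise <- which(labels == 0L)
  if (length(noise) == 0) return(labels)
  keep <- which(labels != 0L)
  if (length(keep) == 0) abort("all points are noise: nothing to assign to")
  d <- as.matrix(dist(points))
  for (i in noise) {
    dd <- d[i, keep]
    j <- keep[which.min(dd)]  # which.min takes the first (smaller index) tie
    labels[i] <- labels[j]
  }
  labels
}

#' Hierarchical clustering of cells on a gene subset
#'
#' Distance = 1 - Pearson correlation between cells, average linkage, cut
#' into `k` groups.  Used to check that an independent gene catalogue
#' (e.g. extracellular-matrix genes) reproduces the population structure.
#'
#' @param expr an [expr_matrix()] or genes x cells matrix.
#' @param gene_set character vector of genes; the intersection with the
#'   matrix must be non-empty.
#' @param k number of groups.
#' @return list: `labels` (integer per cell), `hclust` (the dendrogram).
#' @export
hclust_cells <- function(expr, gene_set, k) {
  v <- if (inherits(expr, "expr_matrix")) expr$values else as.matrix(expr)
  gs <- intersect(gene_set, rownames(v))
  if (length(gs) == 0) abort("gene set does not intersect expressed genes")
  if (ncol(v) < k) abort("fewer cells than requested groups")
  d <- as.dist(1 - cor(v[gs, , drop = FALSE]))
  hc <- hclust(d, method = "average")
  list(labels = cutree(hc, k = k), hclust = hc)
}

#' Full population-calling protocol
#'
#' PCA (`n_pcs`), repeated t-SNE with lowest-KL selection, DBSCAN at
#' `eps`, then nearest-cluster reassignment of noise points.
#'
#' @param expr log2p1 [expr_matrix()] restricted to the selected HVGs
#'   (or a genes x cells matrix).
#' @param n_pcs,perplexity,theta,n_runs,eps,min_pts protocol parameters.
#' @param seed integer seed.
#' @return tibble of class `population_call`: cell, population, x, y; with
#'   attributes `kl` (chosen run divergence), `all_kl`, `eps`.
#' @export
call_populations <- function(expr, n_pcs = 30, perplexity = 27, theta = 0.5,
                             n_runs = 50, eps = 3.1, min_pts = 5, seed) {
  scores <- pca_reduce(expr, n_pcs = n_pcs)
  ts <- tsne_best_of(scores, perplexity = perplexity, theta = theta,
                     n_runs = n_runs, seed = seed)
  labels <- dbscan_cluster(ts$embedding, eps = eps, min_pts = min_pts)
  labels <- resolve_noise(labels, ts$embedding)
  out <- tibble::tibble(cell = rownames(ts$embedding),
                        population = as.integer(labels),
                        x = ts$embedding[, 1], y = ts$embedding[, 2])
  attr(out, "kl") <- ts$kl
  attr(out, "all_kl") <- ts$all_kl
  attr(out, "eps") <- eps
  class(out) <- c("population_call", class(out))
  out
}
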