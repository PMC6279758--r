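# Small fixture builders and independent reference implementations used as
# oracles across the suite.  Everything is generated in code; nothing binary.

# tiny count matrix with one spike-in
tiny_counts <- function() {
  m <- matrix(c(10, 0, 5,
                2, 8, 1,
                4, 4, 4), nrow = 3, byrow = TRUE,
              dimnames = list(c("GeneA", "GeneB", "ERCC-00002"),
                              c("c1", "c2", "c3")))
  count_matrix(m, c(GeneA = 2000, GeneB = 1000, `ERCC-00002` = 500))
}

# brute-force DBSCAN reference: pairwise distances, BFS over core points.
# Returns list(core, noise, core_partition): border assignment is ambiguous
# in principle, so comparisons are made on cores and noise plus a
# consistency check for borders.
ref_dbscan <- function(points, eps, min_pts) {
  d <- as.matrix(dist(points))
  n <- nrow(d)
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- which(lengths(nb) >= min_pts)
  comp <- rep(0L, n)
  k <- 0L
  for (i in core) {
    if (comp[i] != 0L) next
    k <- k + 1L
    queue <- i
    comp[i] <- k
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      for (q in intersect(nb[[p]], core)) {
        if (comp[q] == 0L) { comp[q] <- k; queue <- c(queue, q) }
      }
    }
  }
  reachable <- vapply(seq_len(n), function(i)
    any(core %in% nb[[i]]), logical(1))
  noise <- which(comp == 0L & !reachable)
  list(core = core, comp = comp, noise = noise, nb = nb)
}

# exact two-sided rank-sum p-value by enumeration of all group assignments
exact_ranksum_p <- function(x1, x2) {
  pooled <- c(x1, x2)
  n1 <- length(x1)
  r_obs <- sum(rank(pooled)[seq_len(n1)])
  combs <- utils::combn(length(pooled), n1)
  stats_all <- apply(combs, 2, function(idx) sum(rank(pooled)[idx]))
  mu <- mean(stats_all)
  mean(abs(stats_all - mu) >= abs(r_obs - mu) - 1e-9)
}

# direct simulation of the stated greedy compaction order (independent of
# the package implementation): seed -> order by correlation -> grow while
# mean pairwise >= threshold, stop at first violation; best seed wins.
naive_greedy_profile <- function(bulk, genes, r_threshold) {
  C <- cor(unclass(bulk)[, genes, drop = FALSE], method = "spearman")
  best <- NULL
  for (seed in genes) {
    others <- setdiff(genes, seed)
    ord <- others[order(-C[seed, others], others)]
    set <- seed
    for (cand in ord) {
      trial <- c(set, cand)
      sub <- C[trial, trial]
      if (mean(sub[upper.tri(sub)]) < r_threshold) break
      set <- trial
    }
    if (length(set) < 2) next
    sub <- C[set, set]
    m <- mean(sub[upper.tri(sub)])
    if (m < r_threshold) next
    if (is.null(best) || length(set) > length(best$set) ||
        (length(set) == length(best$set) && m > best$m + 1e-12) ||
        (length(set) == length(best$set) && abs(m - best$m) <= 1e-12 &&
           seed < best$seed))
      best <- list(set = set, m = m, seed = seed)
  }
  best
}

# largest subset (exhaustive) whose mean pairwise Spearman >= threshold
exhaustive_best_subset_size <- function(bulk, genes, r_threshold) {
  C <- cor(unclass(bulk)[, genes, drop = FALSE], method = "spearman")
  n <- length(genes)
  best <- 0L
  for (mask in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) < 2 || length(idx) <= best) next
    sub <- C[idx, idx]
    if (mean(sub[upper.tri(sub)]) >= r_threshold) best <- length(idx)
  }
  best
}

# run the full single-cell population pipeline on a simulation
run_population_pipeline <- function(sim, k_hvg = 150, n_runs = 10, seed = 1) {
  qcf <- flag_qc_outliers(compute_qc_metrics(sim$counts, sim$align_summary))
  cm <- subset_counts(sim$counts, cells = qcf$cell[!qcf$excluded])
  cm <- suppressMessages(filter_genes(cm))
  fit <- fit_technical_noise(cm)
  hvg <- select_hvg(cm, fit, k = min(k_hvg, sum(!cm$is_spikein)))
  expr <- log2p1(rpkm(cm))
  call_populations(expr$values[hvg$selected, ], n_pcs = 30, perplexity = 27,
                   n_runs = n_runs, eps = 3.1, min_pts = 5, seed = seed)
}

# 1:1 matched cohort with a binary exposure built from discordant /
# concordant pair counts; the conditional MLE has the closed form
# log(discordant exposed-case / discordant exposed-control).
make_pairs_cohort <- function(n_case_exposed, n_ctrl_exposed,
                              n_concordant = 4) {
  rows <- list()
  s <- 0
  add <- function(x_case, x_ctrl) {
    s <<- s + 1
    rows[[length(rows) + 1]] <<- tibble::tibble(
      set_id = s, case = c(1L, 0L), exposed = c(x_case, x_ctrl))
  }
  for (i in seq_len(n_case_exposed)) add(1, 0)
  for (i in seq_len(n_ctrl_exposed)) add(0, 1)
  for (i in seq_len(n_concordant)) add(1, 1)
  dplyr::bind_rows(rows)
}

# adjusted Rand index (small standard implementation; avoids an extra
# test-only dependency)
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_ <- si * sj / n
  (sij - exp_) / ((si + sj) / 2 - exp_)
}
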