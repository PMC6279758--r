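make_bulk <- function(cols, n = 60, seed = 1) {
  set.seed(seed)
  m <- do.call(cbind, cols(n))
  rownames(m) <- sprintf("s%03d", seq_len(n))
  bulk_matrix(m)
}

test_that("compaction finds a planted single-factor trio among noise genes", {
  bulk <- make_bulk(function(n) {
    f <- rnorm(n)
    out <- list(A = f + rnorm(n, 0, 0.2), B = f + rnorm(n, 0, 0.2),
                C = f + rnorm(n, 0, 0.2))
    for (j in 1:20) out[[paste0("N", j)]] <- rnorm(n)
    out
  }, seed = 2)
  prof <- compact_profile(colnames(bulk), bulk, r_threshold = 0.7)
  expect_setequal(prof$genes, c("A", "B", "C"))
  expect_gte(prof$mean_correlation, 0.7)
  expect_true(all(prof$weights == 1))
})

test_that("a single strong pair survives when nothing else correlates", {
  bulk <- make_bulk(function(n) {
    f <- rnorm(n)
    list(P = f + rnorm(n, 0, 0.15), Q = f + rnorm(n, 0, 0.15),
         X = rnorm(n), Y = rnorm(n), Z = rnorm(n))
  }, seed = 3)
  prof <- compact_profile(colnames(bulk), bulk, r_threshold = 0.7)
  expect_setequal(prof$genes, c("P", "Q"))
  expect_length(prof, 2)
})

test_that("threshold 1 keeps only duplicated columns; no valid set gives an empty profile", {
  bulk <- make_bulk(function(n) {
    f <- rnorm(n)
    list(D1 = f, D2 = f, E = rnorm(n), G = rnorm(n))
  }, seed = 4)
  prof <- compact_profile(colnames(bulk), bulk, r_threshold = 1)
  expect_setequal(prof$genes, c("D1", "D2"))
  expect_equal(prof$mean_correlation, 1)

  none <- make_bulk(function(n)
    list(U = rnorm(n), V = rnorm(n), W = rnorm(n)), seed = 5)
  empty <- compact_profile(colnames(none), none, r_threshold = 0.95)
  expect_length(empty, 0)
  expect_match(attr(empty, "diagnostic"), "no gene set")
})

test_that("greedy result equals the direct greedy simulation on small instances", {
  set.seed(6)
  for (r in 1:12) {
    n_genes <- sample(4:12, 1)
    n <- 40
    f1 <- rnorm(n); f2 <- rnorm(n)
    m <- sapply(seq_len(n_genes), function(j) {
      w <- runif(1)
      w * f1 + (1 - w) * f2 + rnorm(n, 0, runif(1, 0.1, 1))
    })
    colnames(m) <- sprintf("G%02d", seq_len(n_genes))
    rownames(m) <- sprintf("s%03d", seq_len(n))
    bulk <- bulk_matrix(m)
    thr <- runif(1, 0.4, 0.8)
    prof <- compact_profile(colnames(bulk), bulk, r_threshold = thr)
    ref <- naive_greedy_profile(bulk, colnames(bulk), thr)
    if (is.null(ref)) {
      expect_length(prof, 0)
    } else {
      expect_identical(prof$genes, ref$set)
      expect_equal(prof$mean_correlation, ref$m)
      # post-hoc invariant: recomputed mean pairwise correlation >= threshold
      C <- cor(unclass(bulk)[, prof$genes], method = "spearman")
      expect_gte(mean(C[upper.tri(C)]), thr)
      # greedy is at most as large as the best subset (documents sub-optimality)
      expect_lte(length(prof),
                 exhaustive_best_subset_size(bulk, colnames(bulk), thr))
    }
  }
})

test_that("metagene scores are signed weighted averages with centering semantics", {
  m <- matrix(c(2, 4, 6), 1, dimnames = list("s1", c("A", "B", "C")))
  m <- rbind(m, s2 = c(2, 4, 6))
  prof <- signature_profile(c("A", "B", "C"), weights = c(1, 1, -1))
  sc <- metagene_score(bulk_matrix(m), prof, centered = FALSE)
  expect_equal(sc$score, c(0, 0))

  set.seed(7)
  m2 <- matrix(rnorm(40), 10, 4,
               dimnames = list(sprintf("s%02d", 1:10), c("A", "B", "C", "D")))
  b2 <- bulk_matrix(m2)
  p2 <- signature_profile(c("A", "B", "C"), weights = c(1, -1, 1))
  s_base <- metagene_score(b2, p2, centered = TRUE)
  m3 <- m2; m3[, "B"] <- m3[, "B"] + 100  # constant shift of one gene
  expect_equal(metagene_score(bulk_matrix(m3), p2, centered = TRUE)$score,
               s_base$score)
  expect_equal(mean(s_base$score), 0)  # cohort mean zero in centered mode

  dup <- metagene_score(b2, signature_profile("D"), centered = TRUE)
  expect_equal(dup$score, as.numeric(scale(m2[, "D"], scale = FALSE)))

  expect_warning(metagene_score(b2, signature_profile(c("A", "ZZ"))),
                 "absent")
  expect_error(metagene_score(b2, signature_profile("ZZ")), "no profile gene")
})

test_that("correlation panels show planted block structure and NA for flat genes", {
  set.seed(8)
  n <- 80
  f1 <- rnorm(n); f2 <- rnorm(n)
  m <- cbind(a1 = f1 + rnorm(n, 0, 0.3), a2 = f1 + rnorm(n, 0, 0.3),
             a3 = f1 + rnorm(n, 0, 0.3),
             b1 = f2 + rnorm(n, 0, 0.3), b2 = f2 + rnorm(n, 0, 0.3),
             c1 = -f1 + rnorm(n, 0, 0.3),
             flat = rep(1, n))
  rownames(m) <- sprintf("s%03d", 1:n)
  bulk <- bulk_matrix(m)
  suppressWarnings(pan <- correlation_panel(
    bulk, list(A = c("a1", "a2", "a3"), B = c("b1", "b2"),
               anti = "c1", dead = "flat")))
  gp <- pan$gene_panel
  expect_equal(unname(diag(gp)[1:6]), rep(1, 6))
  within_A <- gp[c("a1", "a2", "a3"), c("a1", "a2", "a3")]
  expect_gte(mean(within_A[upper.tri(within_A)]), 0.7)
  expect_lt(abs(mean(gp[c("a1", "a2", "a3"), c("b1", "b2")])), 0.2)
  expect_lt(max(gp[c("a1", "a2", "a3"), "c1"]), -0.5)  # anti-correlated block
  expect_true(all(is.na(gp["flat", 1:6])))
  sp <- pan$signature_panel
  expect_gt(sp["A", "A"], 0.999)
  expect_lt(sp["A", "anti"], -0.5)
})
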