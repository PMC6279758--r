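test_that("PCA: collinear data, rotation invariance, deterministic signs", {
  set.seed(1)
  n <- 40
  t_ <- rnorm(n)
  x <- rbind(g1 = 2 * t_, g2 = -t_, g3 = 0.5 * t_)  # exactly on a line
  colnames(x) <- sprintf("c%02d", 1:n)
  s <- pca_reduce(x, n_pcs = 2)
  ev <- attr(s, "explained_variance")
  expect_equal(ev[1], 1, tolerance = 1e-10)

  y <- matrix(rnorm(5 * n), 5, n,
              dimnames = list(paste0("g", 1:5), colnames(x)))
  q <- qr.Q(qr(matrix(rnorm(25), 5)))   # orthogonal rotation in gene space
  s1 <- pca_reduce(y, 3)
  s2 <- pca_reduce(q %*% y, 3)
  expect_equal(attr(s1, "explained_variance"),
               attr(s2, "explained_variance"), tolerance = 1e-8)

  expect_identical(pca_reduce(y, 3), pca_reduce(y, 3))
  expect_error(pca_reduce(matrix(1, 3, 10,
    dimnames = list(paste0("g", 1:3), paste0("c", 1:10))), 2), "constant")
})

test_that("best-of-n t-SNE is deterministic and returns the argmin run", {
  set.seed(3)
  scores <- matrix(rnorm(60 * 5), 60)
  rownames(scores) <- sprintf("c%02d", 1:60)
  a <- tsne_best_of(scores, perplexity = 8, n_runs = 4, seed = 7,
                    max_iter = 300)
  b <- tsne_best_of(scores, perplexity = 8, n_runs = 4, seed = 7,
                    max_iter = 300)
  expect_identical(a$embedding, b$embedding)
  expect_equal(a$kl, min(a$all_kl))
  expect_length(a$all_kl, 4)

  one <- tsne_best_of(scores, perplexity = 8, n_runs = 1, seed = 9,
                      max_iter = 300)
  expect_length(one$all_kl, 1)
  expect_error(tsne_best_of(scores, perplexity = 30, n_runs = 1, seed = 1),
               "perplexity")
})

test_that("DBSCAN separates well-spaced blobs and labels strays as noise", {
  set.seed(5)
  blob <- function(cx, cy, n) cbind(rnorm(n, cx, 0.1), rnorm(n, cy, 0.1))
  pts <- rbind(blob(0, 0, 20), blob(100, 0, 20), c(50, 500))
  rownames(pts) <- sprintf("c%02d", seq_len(nrow(pts)))
  lab <- dbscan_cluster(pts, eps = 2, min_pts = 5)
  expect_equal(length(unique(lab[1:40])), 2)
  expect_equal(unname(lab[41]), 0L)        # isolated point is noise
  lab_all <- dbscan_cluster(pts, eps = 1e4, min_pts = 5)
  expect_true(all(lab_all == 1L))          # eps beyond the data diameter
  expect_error(dbscan_cluster(pts, eps = 0), "eps")
})

test_that("DBSCAN agrees with a brute-force reference on random instances", {
  set.seed(11)
  for (rep in 1:100) {
    n <- sample(5:50, 1)
    pts <- matrix(runif(2 * n, 0, 10), n)
    rownames(pts) <- sprintf("c%02d", 1:n)
    eps <- runif(1, 0.5, 3)
    min_pts <- sample(2:5, 1)
    lab <- dbscan_cluster(pts, eps = eps, min_pts = min_pts)
    ref <- ref_dbscan(pts, eps, min_pts)
    # identical noise set
    expect_setequal(which(lab == 0L), ref$noise)
    # core points partition identically (up to label renaming)
    a <- lab[ref$core]; b <- ref$comp[ref$core]
    expect_true(all(outer(a, a, "==") == outer(b, b, "==")))
    # borders carry the label of some core neighbour within eps
    borders <- setdiff(which(lab != 0L), ref$core)
    for (b in borders) {
      cores_near <- intersect(ref$nb[[b]], ref$core)
      expect_true(lab[b] %in% lab[cores_near])
    }
  }
})

test_that("noise resolution picks the nearest cluster with index tie-break", {
  pts <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1), c(5, 0))
  rownames(pts) <- sprintf("c%d", 1:5)
  lab <- c(1L, 1L, 2L, 2L, 0L)
  out <- resolve_noise(lab, pts)
  expect_equal(unname(out[5]), 1L)  # equidistant: smaller index wins
  expect_identical(resolve_noise(out, pts), out)  # no noise -> identity
  expect_error(resolve_noise(rep(0L, 5), pts), "all points")

  lab2 <- c(1L, 1L, 2L, 2L, 0L)
  pts2 <- pts; pts2[5, ] <- c(9, 0)
  expect_equal(unname(resolve_noise(lab2, pts2)[5]), 2L)
})

test_that("correlation-distance hierarchical clustering splits anti-correlated cells", {
  set.seed(6)
  base <- rnorm(30)
  x <- cbind(replicate(5, base + rnorm(30, 0, 0.05)),
             replicate(5, -base + rnorm(30, 0, 0.05)))
  rownames(x) <- paste0("g", 1:30)
  colnames(x) <- paste0("c", 1:10)
  hc <- hclust_cells(x, rownames(x), k = 2)
  expect_equal(length(unique(hc$labels[1:5])), 1)
  expect_equal(length(unique(hc$labels[6:10])), 1)
  expect_false(hc$labels[1] == hc$labels[6])

  # duplicated cells merge at zero height first
  x2 <- cbind(x, c11 = x[, 1])
  hc2 <- hclust_cells(x2, rownames(x), k = 2)
  expect_lt(hc2$hclust$height[1], 1e-10)
  expect_equal(unname(hclust_cells(x, rownames(x), k = 1)$labels),
               rep(1L, 10))
  expect_error(hclust_cells(x, paste0("nope", 1:3), 2), "intersect")
  expect_error(hclust_cells(x, rownames(x), k = 11), "fewer cells")
})

test_that("the full protocol recovers the planted populations", {
  hits <- 0L; four <- 0L
  for (r in 1:2) {
    sim <- simulate_sc(sim_config(), seed = 400 + r)
    pc <- run_population_pipeline(sim, n_runs = 5, seed = 500 + r)
    truth <- sim$truth$cells$population[match(pc$cell, sim$truth$cells$cell)]
    if (ari(pc$population, truth) >= 0.9) hits <- hits + 1L
    if (length(unique(pc$population)) == 4) four <- four + 1L
  }
  expect_gte(hits, 1L)
  expect_gte(four, 1L)
})
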