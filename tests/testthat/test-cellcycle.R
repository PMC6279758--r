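make_phase_data <- function(n_per = 12, seed = 1) {
  set.seed(seed)
  phase <- factor(rep(c("G1", "S", "G2M"), each = n_per),
                  levels = c("G1", "S", "G2M"))
  n <- length(phase)
  # ga > gb exactly in G1; gc > gd exactly in G2M; ge > gf exactly in S
  up_in <- function(p) ifelse(phase == p, 2, -2)
  expr <- rbind(ga = up_in("G1"), gb = 0,
                gc = up_in("G2M"), gd = 0,
                ge = up_in("S"), gf = 0)
  expr <- expr + matrix(rnorm(nrow(expr) * n, 0, 0.01), nrow(expr))
  colnames(expr) <- sprintf("c%03d", seq_len(n))
  list(expr = expr, phase = phase)
}

test_that("a pair high only in one phase is trained for exactly that phase", {
  d <- make_phase_data()
  pairs <- train_cycle_pairs(d$expr, d$phase, frac_threshold = 0.5)
  expect_true(any(pairs$G1$gene_a == "ga" & pairs$G1$gene_b == "gb"))
  expect_false(any(pairs$S$gene_a == "ga" & pairs$S$gene_b == "gb"))
  expect_false(any(pairs$G2M$gene_a == "ga" & pairs$G2M$gene_b == "gb"))
  # swapping a and b flips the phase pattern rather than duplicating
  for (P in names(pairs)) {
    keys <- paste(pairs[[P]]$gene_a, pairs[[P]]$gene_b)
    rev_keys <- paste(pairs[[P]]$gene_b, pairs[[P]]$gene_a)
    expect_length(intersect(keys, rev_keys), 0)
  }
})

test_that("pure-noise genes yield no pairs at a strict threshold", {
  set.seed(4)
  phase <- factor(rep(c("G1", "S", "G2M"), each = 15),
                  levels = c("G1", "S", "G2M"))
  expr <- matrix(rnorm(20 * 45), 20,
                 dimnames = list(paste0("n", 1:20), sprintf("c%02d", 1:45)))
  expect_error(train_cycle_pairs(expr, phase, frac_threshold = 0.95),
               "no qualifying pairs")
})

test_that("scores are pair-sign fractions and assignment follows the rule", {
  pairs <- structure(list(
    G1 = tibble::tibble(gene_a = c("a1", "a2"), gene_b = c("b1", "b2")),
    S = tibble::tibble(gene_a = "s1", gene_b = "s2"),
    G2M = tibble::tibble(gene_a = "m1", gene_b = "m2")
  ), class = "marker_pairs")
  expr <- rbind(a1 = c(5, 1), a2 = c(5, 1), b1 = c(1, 5), b2 = c(1, 5),
                s1 = c(1, 1), s2 = c(1, 1),   # tie -> 1/2
                m1 = c(0, 9), m2 = c(9, 0))
  colnames(expr) <- c("cellG1", "cellM")
  out <- classify_phases(expr, pairs)
  expect_equal(out$g1, c(1, 0))
  expect_equal(out$g2m, c(0, 1))
  expect_equal(out$s, c(0.5, 0.5))
  expect_equal(as.character(out$phase), c("G1", "G2M"))

  # missing pair genes are skipped; all skipped is an error
  out2 <- classify_phases(expr[c("a1", "b1", "m1", "m2"), ], pairs)
  expect_equal(out2$g1, c(1, 0))
  expect_error(classify_phases(expr[c("s1", "s2"), ] * 0 + 1,
                               pairs[c("G1", "G2M")] |>
                                 structure(class = "marker_pairs")),
               "skipped")
})

test_that("random pairs on random data concentrate near one half", {
  set.seed(9)
  expr <- matrix(rnorm(60 * 4), 60,
                 dimnames = list(paste0("g", 1:60), paste0("c", 1:4)))
  ab <- t(replicate(1000, sample(rownames(expr), 2)))
  pairs <- data.frame(phase = "G1", gene_a = ab[, 1], gene_b = ab[, 2])
  out <- classify_phases(expr, pairs)
  expect_true(all(abs(out$g1 - 0.5) < 0.1))
})

test_that("classification is invariant to monotone per-cell transformations", {
  d <- make_phase_data(seed = 5)
  pairs <- train_cycle_pairs(d$expr, d$phase, frac_threshold = 0.6)
  base <- classify_phases(d$expr, pairs)
  warped <- apply(d$expr, 2, function(x) exp(x / 2) + 3)  # monotone per cell
  rownames(warped) <- rownames(d$expr)
  expect_equal(classify_phases(warped, pairs)$phase, base$phase)
})

test_that("train/classify recovers held-out phases and training >= held-out", {
  cc <- simulate_cellcycle(n_cells = 400, seed = 15)
  tr <- 1:200; te <- 201:400
  pairs <- train_cycle_pairs(cc$expr[, tr], cc$phase[tr],
                             frac_threshold = 0.7)
  acc_tr <- mean(classify_phases(cc$expr[, tr], pairs)$phase ==
                   cc$phase[tr])
  acc_te <- mean(classify_phases(cc$expr[, te], pairs)$phase ==
                   cc$phase[te])
  expect_gte(acc_te, 0.9)
  expect_gte(acc_tr, acc_te - 0.05)
})

test_that("phase composition rows sum to one and the dividing fraction is exact", {
  call <- tibble::tibble(
    cell = sprintf("c%03d", 1:130),
    g1 = 0, s = 0, g2m = 0,
    phase = factor(c(rep("G2M", 10), rep("G1", 120)),
                   levels = c("G1", "S", "G2M"))
  )
  pops <- tibble::tibble(cell = call$cell,
                         population = c(rep(3L, 10), rep(1L, 120)))
  comp <- phase_composition(call, pops)
  expect_equal(comp$frac_g1 + comp$frac_s + comp$frac_g2m, rep(1, 2))
  expect_equal(comp$frac_g2m[comp$population == 3], 1)
  expect_equal(dividing_fraction(pops, cycling = 3, partner = 1),
               10 / 130)
  expect_equal(round(100 * dividing_fraction(pops, 3, 1), 1), 7.7)
})
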