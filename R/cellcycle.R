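#' Train phase-discriminating marker gene pairs
#'
#' A relative-expression (pair-sign) classifier in the cyclone family: an
#' ordered gene pair (a, b) is a marker for phase P iff expr_a > expr_b in
#' more than `frac_threshold` of P cells AND expr_a < expr_b in more than
#' `frac_threshold` of the cells of every other phase.  Because only the
#' sign of within-cell differences is used, the classifier is invariant to
#' any monotone per-cell transformation of expression.
#'
#' @param expr genes x cells matrix (any monotone scale).
#' @param phase factor per cell with levels G1, S, G2M.
#' @param frac_threshold majority fraction required (default 0.5).
#' @return object of class `marker_pairs`: named list of tibbles
#'   (gene_a, gene_b) per phase.
#' @export
train_cycle_pairs <- function(expr, phase, frac_threshold = 0.5) {
  expr <- as.matrix(expr)
  phase <- factor(phase, levels = c("G1", "S", "G2M"))
  stopifnot(ncol(expr) == length(phase))
  if (any(table(phase) < 10))
    abort("need at least 10 cells per phase to train")
  G <- nrow(expr)
  genes <- rownames(expr) %||% sprintf("g%04d", seq_len(G))
  idx <- split(seq_along(phase), phase)
  # frac_pos[[P]][a, b] = fraction of P cells with expr_a > expr_b
  frac_pos <- lapply(idx, function(cells) {
    acc <- matrix(0, G, G)
    for (cell in cells) {
      x <- expr[, cell]
      acc <- acc + outer(x, x, ">")
    }
    acc / length(cells)
  })
  pairs <- lapply(levels(phase), function(P) {
    others <- setdiff(levels(phase), P)
    ok <- frac_pos[[P]] > frac_threshold
    for (Q in others) {
      # expr_a < expr_b in > threshold of Q cells (strict: ties don't count)
      neg_q <- t(frac_pos[[Q]])  # fraction with expr_b > expr_a
      ok <- ok & (neg_q > frac_threshold)
    }
    diag(ok) <- FALSE
    w <- which(ok, arr.ind = TRUE)
    tibble::tibble(gene_a = genes[w[, 1]], gene_b = genes[w[, 2]])
  })
  names(pairs) <- levels(phase)
  empty <- names(pairs)[vapply(pairs, nrow, integer(1)) == 0]
  if (length(empty) > 0)
    abort(paste0("no qualifying pairs for phase ",
                 paste(empty, collapse = ", "),
                 "; consider lowering frac_threshold"))
  structure(pairs, class = "marker_pairs")
}

#' @export
print.marker_pairs <- function(x, ...) {
  cat("<marker_pairs>",
      paste(sprintf("%s: %d", names(x), vapply(x, nrow, integer(1))),
            collapse = ", "), "\n")
  invisible(x)
}

#' Assign cell-cycle phases from marker pairs
#'
#' Per cell and phase, the score is the fraction of that phase's pairs
#' with expr_a > expr_b (ties count 1/2).  Assignment: G1 if
#' g1 >= 0.5 and g1 >= g2m; G2M if g2m >= 0.5 and g2m > g1; otherwise S
#' (the residual class).  Pairs whose genes are absent are skipped.
#'
#' @param expr genes x cells matrix.
#' @param pairs a `marker_pairs` object (or a data frame with columns
#'   phase, gene_a, gene_b, as read from a pair-list TSV).
#' @return tibble of class `phase_call`: cell, g1, s, g2m, phase.
#' @export
classify_phases <- function(expr, pairs) {
  expr <- as.matrix(expr)
  if (is.data.frame(pairs))
    pairs <- structure(
      lapply(split(pairs, pairs$phase),
             function(d) tibble::tibble(gene_a = d$gene_a, gene_b = d$gene_b)),
      class = "marker_pairs")
  genes <- rownames(expr)
  scores <- lapply(pairs, function(pp) {
    keep <- pp$gene_a %in% genes & pp$gene_b %in% genes
    pp <- pp[keep, , drop = FALSE]
    if (nrow(pp) == 0) return(NULL)
    da <- expr[pp$gene_a, , drop = FALSE]
    db <- expr[pp$gene_b, , drop = FALSE]
    unname(colMeans((da > db) + 0.5 * (da == db)))
  })
  if (all(vapply(scores, is.null, logical(1))))
    abort("all marker pairs were skipped: genes absent from the matrix")
  n <- ncol(expr)
  get <- function(P) scores[[P]] %||% rep(NA_real_, n)
  g1 <- get("G1"); s <- get("S"); g2m <- get("G2M")
  assigned <- ifelse(!is.na(g1) & g1 >= 0.5 & (is.na(g2m) | g1 >= g2m), "G1",
              ifelse(!is.na(g2m) & g2m >= 0.5 & (is.na(g1) | g2m > g1), "G2M",
                     "S"))
  out <- tibble::tibble(
    cell = colnames(expr) %||% sprintf("c%04d", seq_len(n)),
    g1 = g1, s = s, g2m = g2m,
    phase = factor(assigned, levels = c("G1", "S", "G2M"))
  )
  class(out) <- c("phase_call", class(out))
  out
}

#' Phase composition per population
#'
#' @param call a `phase_call` (from [classify_phases()]).
#' @param populations per-cell population labels: a `population_call`
#'   tibble or a named vector aligned with `call$cell`.
#' @return tibble: population, n, frac_g1, frac_s, frac_g2m (rows sum to 1;
#'   empty populations give NaN fractions with a warning).
#' @export
phase_composition <- function(call, populations) {
  if (inherits(populations, "data.frame")) {
    pop <- populations$population[match(call$cell, populations$cell)]
  } else {
    pop <- populations[call$cell]
  }
  all_pops <- sort(unique(pop[!is.na(pop)]))
  out <- purrr::map_dfr(all_pops, function(p) {
    ph <- call$phase[which(pop == p)]
    n <- length(ph)
    if (n == 0) {
      warn(paste("empty population", p))
      return(tibble::tibble(population = p, n = 0L, frac_g1 = NaN,
                            frac_s = NaN, frac_g2m = NaN))
    }
    tibble::tibble(population = p, n = n,
                   frac_g1 = mean(ph == "G1"),
                   frac_s = mean(ph == "S"),
                   frac_g2m = mean(ph == "G2M"))
  })
  out
}

#' Dividing fraction of a merged population pair
#'
#' When a small cycling cluster is the proliferative segment of a larger
#' partner population, the dividing fraction of the merged population is
#' |cycling| / (|cycling| + |partner|).
#'
#' @param populations a `population_call` tibble or vector of labels.
#' @param cycling label of the cycling cluster.
#' @param partner label of the partner cluster.
#' @return fraction in \[0, 1\].
#' @export
dividing_fraction <- function(populations, cycling, partner) {
  pop <- if (inherits(populations, "data.frame")) populations$population
         else populations
  n_c <- sum(pop == cycling)
  n_p <- sum(pop == partner)
  if (n_c + n_p == 0) abort("both populations are empty")
  n_c / (n_c + n_p)
}
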