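#' Configuration for the single-cell simulator
#'
#' Bundles the generative parameters for [simulate_sc()].  The defaults
#' describe a plate-based Smart-seq2 experiment with four fibroblast
#' populations of unequal abundance: two dominant subtypes, one small and
#' one scarce population.  Endogenous genes follow a negative-binomial law
#' with logistic dropout; spike-ins obey a CV^2(mu) = a1/mu + alpha0
#' technical-noise law via a binomial capture-efficiency model; a subset of
#' cells is planted as low quality with collapsed exon reads and degraded
#' mapping metrics.
#'
#' @param n_cells,n_genes,n_spikeins dataset dimensions.
#' @param pop_proportions simplex over populations; its length sets the
#'   number of populations (4 in the default design; other values are an
#'   explicit choice).
#' @param markers_per_pop number of marker genes per population (scalar or
#'   per-population vector).  Marker sets are disjoint.
#' @param marker_log2fc log2 fold change of a marker in its own population.
#' @param nb_dispersion negative-binomial dispersion (1/size).
#' @param libsize_meanlog,libsize_sdlog lognormal endogenous library size.
#' @param dropout_midpoint,dropout_slope logistic dropout: the Bernoulli
#'   keep probability is `plogis(log(mu / midpoint) / slope)`.
#' @param spike_mean_range geometric grid range of spike-in mean counts.
#' @param technoise_a1,technoise_alpha0 planted spike-in noise law
#'   CV^2 = a1/mu + alpha0 (a1 < 1 uses the binomial capture model;
#'   a1 >= 1 an NB stage).
#' @param n_lowquality number of planted low-quality cells.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_cells = 400, n_genes = 600, n_spikeins = 40,
                       pop_proportions = c(0.46, 0.30, 0.14, 0.10),
                       markers_per_pop = 25, marker_log2fc = 2,
                       nb_dispersion = 0.4,
                       libsize_meanlog = log(1e5), libsize_sdlog = 0.25,
                       dropout_midpoint = 1, dropout_slope = 1,
                       spike_mean_range = c(2, 2048),
                       technoise_a1 = 0.5, technoise_alpha0 = 0.1,
                       n_lowquality = 30) {
  if (any(pop_proportions < 0) || abs(sum(pop_proportions) - 1) > 1e-8)
    abort("pop_proportions must be a simplex (non-negative, sum 1)")
  k <- length(pop_proportions)
  markers_per_pop <- rep_len(markers_per_pop, k)
  stopifnot(n_cells > 0, n_genes > 0, n_spikeins >= 0,
            nb_dispersion > 0, technoise_a1 >= 0, technoise_alpha0 >= 0,
            n_lowquality >= 0, n_lowquality <= n_cells,
            sum(markers_per_pop) <= n_genes)
  structure(as.list(environment())[setdiff(ls(), "k")], class = "sim_config")
}

#' Simulate a Smart-seq2-like single-cell experiment with known truth
#'
#' Generates endogenous counts with population structure, spike-in counts
#' obeying a planted technical-noise law, a per-cell alignment summary and
#' the ground truth needed to score every downstream stage.  Endogenous
#' counts for gene g in cell c are NB(mean = libsize_c * base_g * FC, 1/
#' dispersion) thinned by logistic dropout; planted low-quality cells have
#' their endogenous counts binomially thinned to 1-20% and their mapping
#' percentages shifted several population SDs down, so they are outliers in
#' at least two QC metrics.  Spike-ins are unaffected by cell quality (the
#' spike volume is per well, not per cell).
#'
#' @param config a [sim_config()].
#' @param seed integer seed; the run is fully reproducible from it.
#' @return list with `counts` (a [count_matrix()]), `align_summary`
#'   (tibble: cell, total_reads, unique_reads, exon_reads, plate) and
#'   `truth` (list: `cells` tibble with population / lowquality per cell,
#'   `markers` named list of marker gene IDs per population).
#' @export
simulate_sc <- function(config = sim_config(), seed) {
  stopifnot(inherits(config, "sim_config"))
  if (missing(seed)) abort("seed is mandatory")
  set.seed(seed)
  cfg <- config
  k <- length(cfg$pop_proportions)
  G <- cfg$n_genes; N <- cfg$n_cells
  genes <- sprintf("Gene%04d", seq_len(G))
  cells <- sprintf("Cell%04d", seq_len(N))

  pop <- sample.int(k, N, replace = TRUE, prob = cfg$pop_proportions)
  base <- rlnorm(G, meanlog = 0, sdlog = 1.5)

  markers <- vector("list", k)
  idx0 <- 0L
  fc <- matrix(1, G, k)
  for (j in seq_len(k)) {
    mj <- cfg$markers_per_pop[j]
    if (mj > 0) {
      ids <- idx0 + seq_len(mj)
      markers[[j]] <- genes[ids]
      fc[ids, j] <- 2^cfg$marker_log2fc
      idx0 <- idx0 + mj
    } else markers[[j]] <- character(0)
  }
  names(markers) <- paste0("pop", seq_len(k))

  libsize <- rlnorm(N, cfg$libsize_meanlog, cfg$libsize_sdlog)
  mu <- matrix(0, G, N)
  for (j in seq_len(k)) {
    cs <- which(pop == j)
    if (length(cs) == 0) next
    w <- base * fc[, j]
    mu[, cs] <- (w / sum(w)) %o% libsize[cs]
  }
  counts <- matrix(rnbinom(G * N, mu = mu, size = 1 / cfg$nb_dispersion),
                   G, N)
  keep_p <- stats::plogis(log(pmax(mu, 1e-12) / cfg$dropout_midpoint) /
                            cfg$dropout_slope)
  counts <- counts * matrix(rbinom(G * N, 1L, keep_p), G, N)

  lowq <- rep(FALSE, N)
  if (cfg$n_lowquality > 0) {
    bad <- sample.int(N, cfg$n_lowquality)
    lowq[bad] <- TRUE
    for (c in bad) {
      u <- runif(1, 0.01, 0.2)
      counts[, c] <- rbinom(G, counts[, c], u)
    }
  }

  # spike-ins: CV^2 = a1/mu + alpha0 planted exactly (see vignette)
  nsp <- cfg$n_spikeins
  if (nsp > 0) {
    a1 <- cfg$technoise_a1; alpha0 <- cfg$technoise_alpha0
    mu_sp <- exp(seq(log(cfg$spike_mean_range[1]),
                     log(cfg$spike_mean_range[2]), length.out = nsp))
    sdlog <- sqrt(log(1 + alpha0))
    theta <- rlnorm(N, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    sp <- matrix(0, nsp, N)
    if (a1 < 1) {
      qbar <- (1 - a1) / (1 + alpha0)
      n_mol <- pmax(1, round(mu_sp / qbar))
      for (s in seq_len(nsp))
        sp[s, ] <- rbinom(N, n_mol[s], pmin(qbar * theta, 0.99))
    } else {
      for (s in seq_len(nsp)) {
        m_cs <- mu_sp[s] * theta
        sp[s, ] <- if (a1 == 1) rpois(N, m_cs)
                   else rnbinom(N, mu = m_cs, size = m_cs / (a1 - 1))
      }
    }
    sp_names <- sprintf("ERCC-%05d", seq_len(nsp))
    counts <- rbind(counts, sp)
    rownames(counts) <- c(genes, sp_names)
  } else {
    rownames(counts) <- genes
  }
  colnames(counts) <- cells

  lengths <- setNames(c(round(runif(G, 500, 5000)),
                        if (nsp > 0) round(runif(nsp, 250, 2000))),
                      rownames(counts))

  exon <- colSums(counts[seq_len(G), , drop = FALSE])
  pct_unique <- pmin(pmax(rnorm(N, 82, 2), 30), 99)
  pct_exon <- pmin(pmax(rnorm(N, 72, 2), 20), 99)
  if (any(lowq)) {
    shift <- 2 * (3.2 + rexp(sum(lowq), 1))  # beyond 3 population SDs (sd=2)
    pct_unique[lowq] <- pmax(pct_unique[lowq] - shift, 1)
    shift2 <- 2 * (3.2 + rexp(sum(lowq), 1))
    pct_exon[lowq] <- pmax(pct_exon[lowq] - shift2, 1)
  }
  unique_reads <- round(exon / (pct_exon / 100))
  total_reads <- round(unique_reads / (pct_unique / 100))
  align <- tibble::tibble(
    cell = cells,
    total_reads = total_reads,
    unique_reads = unique_reads,
    exon_reads = exon,
    plate = factor(rep(c("P1", "P2"), length.out = N))
  )
  truth <- list(
    cells = tibble::tibble(cell = cells, population = pop, lowquality = lowq),
    markers = markers
  )
  list(counts = count_matrix(counts, lengths),
       align_summary = align, truth = truth)
}

#' Simulate a matched case-control bulk cohort with planted signal
#'
#' Each matched set (one case, `controls_per_case` controls, mirroring a
#' 1:m nested case-control design) draws a per-profile latent abundance
#' with a between-set and a within-set component; signature genes equal the
#' latent abundance plus independent noise, so the mean pairwise
#' correlation among signature genes is controlled by `noise_sd`
#' (r = var(A) / (var(A) + noise_sd^2) with var(A) = 1 + set_sd^2).  The
#' case in each set is drawn with conditional log-odds
#' `beta_true * z`, where z is the standardized centered metagene of the
#' first profile - exactly the covariate the analysis pipeline computes.
#'
#' @param profiles named list; each element is either a character vector of
#'   gene IDs or a single integer size (gene IDs are then generated).
#' @param n_sets number of matched sets (cases).
#' @param controls_per_case controls per case (>= 1).
#' @param beta_true planted conditional log-odds per SD of the metagene.
#' @param noise_sd independent per-gene noise SD.
#' @param set_sd SD of the shared between-set component.
#' @param n_noise_genes unstructured background genes.
#' @param seed integer seed.
#' @return list with `bulk` (a [bulk_matrix()], samples x genes, log2-like
#'   scale), `cohort` (tibble: sample, set_id, case, matching covariates)
#'   and `truth` (list: beta_true, metagene z, profile gene lists).
#' @export
simulate_bulk_cohort <- function(profiles, n_sets = 190,
                                 controls_per_case = 3, beta_true = 0.5,
                                 noise_sd = 0.5, set_sd = 0.5,
                                 n_noise_genes = 50, seed) {
  if (missing(seed)) abort("seed is mandatory")
  stopifnot(controls_per_case >= 1, n_sets >= 1)
  if (n_sets < 10)
    warn("fewer than 10 matched sets: conditional-likelihood fits are unstable")
  set.seed(seed)
  if (is.null(names(profiles)))
    names(profiles) <- paste0("profile", seq_along(profiles))
  gene_lists <- purrr::imap(profiles, function(p, nm) {
    if (is.character(p)) p
    else if (inherits(p, "signature_profile")) p$genes
    else sprintf("%s_g%02d", nm, seq_len(p))
  })
  m <- controls_per_case
  n <- n_sets * (m + 1)
  set_id <- rep(seq_len(n_sets), each = m + 1)
  samples <- sprintf("S%04d", seq_len(n))

  cols <- list()
  latent <- list()
  for (nm in names(gene_lists)) {
    b <- rnorm(n_sets, 0, set_sd)
    A <- b[set_id] + rnorm(n)
    latent[[nm]] <- A
    for (g in gene_lists[[nm]])
      cols[[g]] <- 8 + A + rnorm(n, 0, noise_sd)
  }
  for (j in seq_len(n_noise_genes))
    cols[[sprintf("noise_g%03d", j)]] <- 8 + rnorm(n)
  bulk <- do.call(cbind, cols)
  rownames(bulk) <- samples

  g1 <- gene_lists[[1]]
  sc <- rowMeans(scale(bulk[, g1, drop = FALSE], center = TRUE, scale = FALSE))
  z <- as.numeric(scale(sc))

  case <- integer(n)
  for (s in seq_len(n_sets)) {
    idx <- which(set_id == s)
    p <- exp(beta_true * z[idx]); p <- p / sum(p)
    case[idx[sample.int(length(idx), 1, prob = p)]] <- 1L
  }
  age_levels <- c("<45", "45-55", "55+")
  therapy_levels <- c("ET", "CT", "ET+CT")
  cohort <- tibble::tibble(
    sample = samples,
    set_id = set_id,
    case = case,
    age_group = factor(age_levels[sample.int(3, n_sets, TRUE)][set_id],
                       levels = age_levels),
    therapy = factor(therapy_levels[sample.int(3, n_sets, TRUE)][set_id],
                     levels = therapy_levels)
  )
  list(bulk = bulk_matrix(bulk), cohort = cohort,
       truth = list(beta_true = beta_true, metagene = z,
                    profiles = gene_lists))
}

#' Simulate cycle-phase-labelled expression for the marker-pair classifier
#'
#' For each phase (G1, S, G2M) a block of genes is up only in that phase
#' and a block is down only in that phase (up in the two others), giving
#' well-defined discriminating pairs; the remaining genes are noise.
#'
#' @param n_cells cells to draw (phases sampled uniformly).
#' @param genes_per_class genes per (phase, direction) block.
#' @param effect mean shift of an informative gene in its active phases.
#' @param noise_sd residual SD.
#' @param n_noise_genes uninformative genes.
#' @param seed integer seed.
#' @return list with `expr` (genes x cells matrix) and `phase`
#'   (factor per cell with levels G1, S, G2M).
#' @export
simulate_cellcycle <- function(n_cells = 300, genes_per_class = 10,
                               effect = 2, noise_sd = 0.7,
                               n_noise_genes = 10, seed) {
  if (missing(seed)) abort("seed is mandatory")
  set.seed(seed)
  phases <- c("G1", "S", "G2M")
  phase <- factor(sample(phases, n_cells, replace = TRUE), levels = phases)
  blocks <- list()
  for (p in phases) {
    up <- matrix(0, genes_per_class, 3, dimnames = list(NULL, phases))
    up[, p] <- effect
    dn <- matrix(effect, genes_per_class, 3, dimnames = list(NULL, phases))
    dn[, p] <- 0
    rownames(up) <- sprintf("%s_up%02d", p, seq_len(genes_per_class))
    rownames(dn) <- sprintf("%s_dn%02d", p, seq_len(genes_per_class))
    blocks[[paste0(p, "_up")]] <- up
    blocks[[paste0(p, "_dn")]] <- dn
  }
  means <- do.call(rbind, blocks)
  if (n_noise_genes > 0) {
    nz <- matrix(0, n_noise_genes, 3, dimnames = list(
      sprintf("noise%02d", seq_len(n_noise_genes)), phases))
    means <- rbind(means, nz)
  }
  G <- nrow(means)
  expr <- means[, as.character(phase), drop = FALSE] + 5 +
    matrix(rnorm(G * n_cells, 0, noise_sd), G, n_cells)
  colnames(expr) <- sprintf("CC%04d", seq_len(n_cells))
  names(phase) <- colnames(expr)
  list(expr = expr, phase = phase)
}
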