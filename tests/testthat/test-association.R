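test_that("standardization gives mean zero, unit SD, and is idempotent", {
  d <- tibble::tibble(set_id = 1, case = 0, x = c(3, 5, 9, 13), f = "a")
  z <- standardize_covariates(d, "x")
  expect_equal(mean(z$x), 0)
  expect_equal(sd(z$x), 1)
  z2 <- standardize_covariates(z, "x")
  expect_equal(z2$x, z$x, tolerance = 1e-12)
  expect_error(standardize_covariates(d, "f"), "not numeric")
  d$k <- 2
  expect_error(standardize_covariates(d, "k"), "zero standard deviation")
})

test_that("1:1 binary exposure reproduces the discordant-pair closed form", {
  coh <- make_pairs_cohort(10, 5)
  fit <- fit_conditional_logit(coh, "exposed")
  expect_equal(unname(exp(fit$coefficients)), 2, tolerance = 1e-7)

  set.seed(2)
  for (r in 1:50) {
    a <- sample(3:25, 1); b <- sample(3:25, 1)
    f <- suppressWarnings(
      fit_conditional_logit(make_pairs_cohort(a, b, sample(0:5, 1)),
                            "exposed"))
    expect_equal(unname(exp(f$coefficients)), a / b, tolerance = 1e-6)
  }
})

test_that("estimates and SEs agree with an independent conditional-likelihood fit", {
  skip_if_not_installed("survival")
  withr::local_package("survival")
  sb <- simulate_bulk_cohort(list(v = 7), n_sets = 120, beta_true = 0.6,
                             seed = 5)
  sc <- metagene_score(sb$bulk, signature_profile(sb$truth$profiles$v))
  coh <- dplyr::mutate(sb$cohort, v = sc$score[match(sample, sc$sample)])
  coh <- standardize_covariates(coh, "v")
  coh$grade <- factor(sample(c("G1", "G2", "G3"), nrow(coh), TRUE),
                      levels = c("G1", "G2", "G3"))
  ours <- fit_conditional_logit(coh, c("v", "grade"))
  ref <- survival::clogit(case ~ v + grade + survival::strata(set_id),
                          data = coh)
  expect_equal(unname(ours$coefficients), unname(coef(ref)),
               tolerance = 1e-6)
  expect_equal(unname(ours$se), unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-5)
})

test_that("the conditional MLE matches a brute-force likelihood grid", {
  coh <- make_pairs_cohort(8, 3, 2)
  fit <- fit_conditional_logit(coh, "exposed")
  grid <- seq(-2, 3, by = 1e-4)
  ll <- vapply(grid, function(b) {
    sum(vapply(split(seq_len(nrow(coh)), coh$set_id), function(i) {
      eta <- b * coh$exposed[i]
      eta[coh$case[i] == 1] - log(sum(exp(eta)))
    }, numeric(1)))
  }, numeric(1))
  expect_equal(unname(fit$coefficients), grid[which.max(ll)],
               tolerance = 2e-4)
  expect_equal(fit$loglik, max(ll), tolerance = 1e-6)
})

test_that("adding a set-constant shift to a covariate changes nothing", {
  sb <- simulate_bulk_cohort(list(v = 5), n_sets = 60, beta_true = 0.4,
                             seed = 7)
  sc <- metagene_score(sb$bulk, signature_profile(sb$truth$profiles$v))
  coh <- dplyr::mutate(sb$cohort, v = sc$score[match(sample, sc$sample)])
  f1 <- fit_conditional_logit(coh, "v")
  set.seed(1)
  shift <- rnorm(max(coh$set_id), 0, 5)
  coh$v <- coh$v + shift[coh$set_id]
  f2 <- fit_conditional_logit(coh, "v")
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-6)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
})

test_that("a null effect is covered by the Wald interval at the nominal rate", {
  covered <- vapply(1:100, function(r) {
    sb <- simulate_bulk_cohort(list(v = 4), n_sets = 60, beta_true = 0,
                               noise_sd = 0.5, seed = 9000 + r)
    sc <- metagene_score(sb$bulk, signature_profile(sb$truth$profiles$v))
    coh <- dplyr::mutate(sb$cohort, v = sc$score[match(sample, sc$sample)])
    coh <- standardize_covariates(coh, "v")
    f <- fit_conditional_logit(coh, "v")
    abs(f$coefficients) < 1.96 * f$se
  }, logical(1))
  expect_gte(sum(covered), 93)
})

test_that("degenerate designs fail loudly", {
  coh <- make_pairs_cohort(6, 3)
  coh$exposed2 <- coh$exposed
  expect_error(suppressWarnings(
    fit_conditional_logit(coh, c("exposed", "exposed2"))), "singular")
  bad <- coh; bad$case[1] <- 0L
  expect_error(fit_conditional_logit(bad, "exposed"), "exactly 1 case")
  small <- make_pairs_cohort(2, 1, 0)
  expect_warning(fit_conditional_logit(small, "exposed"), "fewer than 10")
})

test_that("the association table mirrors the matched-cohort reporting layout", {
  set.seed(11)
  sb <- simulate_bulk_cohort(list(v = 6), n_sets = 150, beta_true = 0.5,
                             seed = 13)
  sc <- metagene_score(sb$bulk, signature_profile(sb$truth$profiles$v))
  coh <- dplyr::mutate(sb$cohort, v = sc$score[match(sample, sc$sample)])
  coh <- standardize_covariates(coh, "v")
  coh$node <- factor(sample(c("Negative", "Positive", "Unknown"), nrow(coh),
                            TRUE, prob = c(0.5, 0.4, 0.1)),
                     levels = c("Negative", "Positive", "Unknown"))
  tab <- association_table(coh, c("v", "node"))
  expect_setequal(unique(tab$model), c("univariable", "multivariable"))
  ref_row <- tab[tab$reference & tab$model == "univariable", ]
  expect_equal(ref_row$hr, 1)
  expect_match(ref_row$term, "ref\\.")
  expect_true(all(is.finite(tab$hr)))
  expect_true(all(tab$conf_low[!tab$reference] <= tab$hr[!tab$reference] &
                    tab$hr[!tab$reference] <= tab$conf_high[!tab$reference]))
  # v is independent of node: univariable and multivariable estimates agree
  v_uni <- tab$estimate[tab$term == "v" & tab$model == "univariable"]
  v_mul <- tab$estimate[tab$term == "v" & tab$model == "multivariable"]
  expect_lt(abs(v_uni - v_mul), 0.1)
})
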