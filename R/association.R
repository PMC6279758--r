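#' Center and scale numeric covariates
#'
#' (x - mean) / SD over all subjects (cases and controls jointly), with
#' the n-1 SD denominator, so a regression coefficient is the log odds per
#' standard deviation of the covariate.
#'
#' @param cohort data frame of subjects.
#' @param variables names of numeric columns to standardize.
#' @return `cohort` with the columns replaced by their standardized values.
#' @export
standardize_covariates <- function(cohort, variables) {
  out <- tibble::as_tibble(cohort)
  for (v in variables) {
    x <- out[[v]]
    if (!is.numeric(x)) abort(paste(v, "is not numeric"))
    s <- sd(x)
    if (s == 0) abort(paste(v, "has zero standard deviation"))
    out[[v]] <- (x - mean(x)) / s
  }
  out
}

clr_model_matrix <- function(cohort, variables) {
  f <- stats::as.formula(paste("~", paste(variables, collapse = " + ")))
  mm <- stats::model.matrix(f, data = cohort)
  X <- mm[, -1, drop = FALSE]  # no intercept in a conditional likelihood
  assign_ <- attr(mm, "assign")[-1]
  list(X = X, variable = variables[assign_])
}

clr_loglik_parts <- function(X, case, set_idx, beta) {
  eta <- as.numeric(X %*% beta)
  ll <- 0
  score <- numeric(ncol(X))
  info <- matrix(0, ncol(X), ncol(X))
  for (idx in set_idx) {
    e <- eta[idx]
    w <- exp(e - max(e)); w <- w / sum(w)
    xs <- X[idx, , drop = FALSE]
    xbar <- colSums(xs * w)
    ll <- ll + e[case[idx] == 1] - log(sum(exp(e - max(e)))) - max(e)
    score <- score + X[idx[case[idx] == 1], ] - xbar
    info <- info + crossprod(xs * sqrt(w)) - tcrossprod(xbar)
  }
  list(ll = ll, score = score, info = info)
}

fit_clr_beta <- function(X, case, set_idx, max_iter = 50, tol = 1e-8) {
  beta <- numeric(ncol(X))
  converged <- FALSE
  parts <- NULL
  for (it in seq_len(max_iter)) {
    parts <- clr_loglik_parts(X, case, set_idx, beta)
    if (max(abs(parts$score)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(parts$info, parts$score),
                     error = function(e) abort(
                       "singular information matrix (collinear covariates?)"))
    # dampen huge steps to survive near-separation
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    beta <- beta + step
    if (max(abs(beta)) > 15) break  # separation: likelihood has no maximum
  }
  if (!converged)
    warn("conditional likelihood did not converge (possible separation)")
  parts <- clr_loglik_parts(X, case, set_idx, beta)
  list(beta = beta, loglik = parts$ll, info = parts$info,
       converged = converged)
}

#' Conditional logistic regression for 1:m matched sets
#'
#' Maximizes the conditional likelihood
#' prod over sets of exp(x_case b) / sum_j exp(x_j b)
#' by Newton iteration from b = 0, with standard errors from the observed
#' information.  Matching factors (anything constant within a set) cancel
#' from this likelihood and need not be modelled.  Hazard-ratio-style
#' estimates are exp(b); for standardized numeric covariates this is the
#' relative odds per one SD.  Likelihood-ratio p-values per variable come
#' from refitting without that variable's full level block.
#'
#' @param cohort data frame with one row per subject.
#' @param variables covariate column names (numeric, or factor with the
#'   first level as reference; encode missing categories as an explicit
#'   "Unknown" level).
#' @param set_col,case_col column names of the matched-set ID and the
#'   case indicator (exactly one case per set).
#' @return object of class `cond_logit_fit`.
#' @export
fit_conditional_logit <- function(cohort, variables, set_col = "set_id",
                                  case_col = "case") {
  cohort <- as.data.frame(cohort)
  case <- as.integer(cohort[[case_col]])
  sets <- cohort[[set_col]]
  set_idx <- split(seq_along(case), sets)
  bad <- vapply(set_idx, function(i) sum(case[i]) != 1 || length(i) < 2,
                logical(1))
  if (any(bad))
    abort("every matched set needs exactly 1 case and >= 1 control")
  mm <- clr_model_matrix(cohort, variables)
  informative <- vapply(set_idx, function(i)
    any(apply(mm$X[i, , drop = FALSE], 2, function(z) length(unique(z)) > 1)),
    logical(1))
  if (sum(informative) < 10)
    warn("fewer than 10 informative matched sets: estimates are unstable")
  fit <- fit_clr_beta(mm$X, case, set_idx)
  se <- sqrt(diag(solve(fit$info)))
  lr <- vapply(unique(mm$variable), function(v) {
    keep <- mm$variable != v
    ll0 <- if (!any(keep)) {
      # null model: every subject equally likely to be the case
      sum(vapply(set_idx, function(i) -log(length(i)), numeric(1)))
    } else {
      fit_clr_beta(mm$X[, keep, drop = FALSE], case, set_idx)$loglik
    }
    pchisq(2 * (fit$loglik - ll0), df = sum(!keep), lower.tail = FALSE)
  }, numeric(1))
  structure(list(
    coefficients = setNames(fit$beta, colnames(mm$X)),
    se = setNames(se, colnames(mm$X)),
    variable = setNames(mm$variable, colnames(mm$X)),
    loglik = fit$loglik,
    n_sets = length(set_idx),
    n_informative = sum(informative),
    lr_p = lr,
    converged = fit$converged,
    terms = variables,
    cohort = cohort,
    set_col = set_col, case_col = case_col
  ), class = "cond_logit_fit")
}

#' @export
print.cond_logit_fit <- function(x, ...) {
  cat(sprintf("<cond_logit_fit> %d matched sets (%d informative)%s\n",
              x$n_sets, x$n_informative,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(tidy.cond_logit_fit(x), ...)
  invisible(x)
}

#' Univariable and multivariable association table
#'
#' One conditional-logit fit per variable plus one joint fit, assembled in
#' the layout of a matched case-control results table: hazard-ratio-style
#' estimates with Wald 95% CIs and p-values per coefficient, a
#' likelihood-ratio p per variable, reference levels carried with HR = 1,
#' and numeric rows interpretable per SD when standardized beforehand
#' (see [standardize_covariates()]).
#'
#' @inheritParams fit_conditional_logit
#' @return tibble: model (univariable/multivariable), variable, term, n,
#'   reference, estimate, hr, conf_low, conf_high, p_wald, p_lr.
#' @export
association_table <- function(cohort, variables, set_col = "set_id",
                              case_col = "case") {
  one <- function(fit, model) {
    td <- tidy.cond_logit_fit(fit)
    rows <- list()
    for (v in fit$terms) {
      x <- cohort[[v]]
      if (is.factor(x) || is.character(x)) {
        x <- as.factor(x)
        ref <- levels(x)[1]
        rows[[length(rows) + 1]] <- tibble::tibble(
          model = model, variable = v, term = paste0(ref, " (ref.)"),
          n = sum(x == ref), reference = TRUE, estimate = 0, hr = 1,
          conf_low = NA_real_, conf_high = NA_real_, p_wald = NA_real_,
          p_lr = unname(fit$lr_p[v]))
        for (lv in levels(x)[-1]) {
          cf <- paste0(v, lv)
          r <- td[td$term == cf, ]
          rows[[length(rows) + 1]] <- tibble::tibble(
            model = model, variable = v, term = lv, n = sum(x == lv),
            reference = FALSE, estimate = r$estimate, hr = exp(r$estimate),
            conf_low = exp(r$conf.low), conf_high = exp(r$conf.high),
            p_wald = r$p.value, p_lr = unname(fit$lr_p[v]))
        }
      } else {
        r <- td[td$term == v, ]
        rows[[length(rows) + 1]] <- tibble::tibble(
          model = model, variable = v, term = v, n = length(x),
          reference = FALSE, estimate = r$estimate, hr = exp(r$estimate),
          conf_low = exp(r$conf.low), conf_high = exp(r$conf.high),
          p_wald = r$p.value, p_lr = unname(fit$lr_p[v]))
      }
    }
    dplyr::bind_rows(rows)
  }
  uni <- purrr::map_dfr(variables, function(v)
    one(fit_conditional_logit(cohort, v, set_col, case_col), "univariable"))
  multi <- one(fit_conditional_logit(cohort, variables, set_col, case_col),
               "multivariable")
  dplyr::bind_rows(uni, multi)
}
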