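#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a conditional-logit fit
#'
#' @param x a `cond_logit_fit`.
#' @param conf_level Wald confidence level (default 0.95).
#' @param ... unused.
#' @return tibble: term, variable, estimate, std.error, statistic,
#'   p.value, conf.low, conf.high (log-odds scale).
#' @method tidy cond_logit_fit
#' @export
tidy.cond_logit_fit <- function(x, conf_level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  est <- x$coefficients
  tibble::tibble(
    term = names(est),
    variable = unname(x$variable),
    estimate = unname(est),
    std.error = unname(x$se),
    statistic = unname(est / x$se),
    p.value = 2 * stats::pnorm(-abs(est / x$se)),
    conf.low = unname(est - z * x$se),
    conf.high = unname(est + z * x$se)
  )
}

#' @rdname tidy.cond_logit_fit
#' @method glance cond_logit_fit
#' @export
glance.cond_logit_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, n_sets = x$n_sets,
                 n_informative = x$n_informative, converged = x$converged)
}

#' Tidy a technical-noise fit
#'
#' @param x a `technoise_fit`.
#' @param ... unused.
#' @return tibble with one row per coefficient.
#' @method tidy technoise_fit
#' @export
tidy.technoise_fit <- function(x, ...) {
  tibble::tibble(term = c("a1", "alpha0"),
                 estimate = c(x$a1, x$alpha0))
}

#' @rdname tidy.technoise_fit
#' @method glance technoise_fit
#' @export
glance.technoise_fit <- function(x, ...) {
  tibble::tibble(a1 = x$a1, alpha0 = x$alpha0,
                 n_spikeins_used = x$n_spikeins_used)
}

#' Glance at a differential-expression result
#'
#' @param x a `de_result`.
#' @param ... unused.
#' @return one-row tibble: method, n_genes, n_sde, and for ROTS results
#'   the selected alpha pair and top-list size.
#' @method glance de_result
#' @export
glance.de_result <- function(x, ...) {
  alpha <- attr(x, "alpha")
  tibble::tibble(
    method = attr(x, "method"),
    n_genes = nrow(x),
    n_sde = length(sde_genes(x)),
    alpha1 = if (is.null(alpha)) NA_real_ else unname(alpha[1]),
    alpha2 = if (is.null(alpha)) NA_real_ else unname(alpha[2]),
    k_opt = attr(x, "k_opt") %||% NA_integer_
  )
}
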