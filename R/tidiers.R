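#' Tidy a count-GLM fit
#'
#' @param x A `branch_fit`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `type`, `locus1`,
#'   `locus2`, `kind`, `estimate`, `std.error`, `statistic`, `p.value`
#'   (the latter three when a covariance was computed).
#' @exportS3Method generics::tidy
tidy.branch_fit <- function(x, ...) {
  out <- x$column_meta
  out$estimate <- unname(x$coefficients)
  if (!is.null(x$vcov)) {
    out$std.error <- sqrt(pmax(diag(x$vcov), 0))
    out$statistic <- out$estimate / out$std.error
    out$p.value <- 2 * pnorm(-abs(out$statistic))
  }
  out
}

#' Glance at a count-GLM fit
#'
#' @param x A `branch_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `basis`, `link`, `family`, `logLik`, `AIC`,
#'   `deviance`, `alpha`, `n_params`, `nobs`, `converged`.
#' @exportS3Method generics::glance
glance.branch_fit <- function(x, ...) {
  tibble::tibble(basis = x$basis, link = x$link, family = x$family,
                 logLik = x$loglik, AIC = x$aic, deviance = x$deviance,
                 alpha = x$alpha %||% NA_real_, n_params = x$n_params,
                 nobs = x$nobs, converged = x$converged)
}

#' Tidy a hierarchical-model fit
#'
#' @param x A `hier_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `group` (`"global"`,
#'   `"PLT"`, `"SEP"`), `estimate`.
#' @exportS3Method generics::tidy
tidy.hier_fit <- function(x, ...) {
  p <- x$params
  tibble::tibble(
    term = c("theta_wt", "theta_int", "alpha",
             names(p$phi_plt), names(p$phi_sep)),
    group = c("global", "global", "global",
              rep("PLT", length(p$phi_plt)),
              rep("SEP", length(p$phi_sep))),
    estimate = c(p$theta_wt, p$theta_int, p$alpha,
                 unname(p$phi_plt), unname(p$phi_sep)))
}

#' Glance at a hierarchical-model fit
#'
#' @param x A `hier_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `logLik`, `AIC`, `deviance`, `theta_int`,
#'   `alpha`, `n_params`, `nobs`, `converged`, `grad_norm`.
#' @exportS3Method generics::glance
glance.hier_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, AIC = x$aic, deviance = x$deviance,
                 theta_int = x$params$theta_int, alpha = x$params$alpha,
                 n_params = x$n_params, nobs = x$nobs,
                 converged = x$converged, grad_norm = x$grad_norm)
}
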