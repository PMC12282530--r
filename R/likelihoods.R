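#' Poisson log-likelihood with exposure
#'
#' Log-likelihood of plant branching totals under a Poisson model in which a
#' plant with `t` countable inflorescences and per-inflorescence mean `mu` has
#' total count mean `m = t * mu`.
#'
#' @param y Integer vector of plant branching totals.
#' @param t Positive vector of exposures (countable inflorescences).
#' @param mu Positive vector of per-inflorescence means (recycled if scalar).
#'
#' @return The summed log-likelihood (a scalar).
#' @examples
#' poisson_loglik(0, 1, 1) # log P(0; mean 1) = -1
#' @export
poisson_loglik <- function(y, t, mu) {
  check_count_args(y, t, mu)
  m <- t * mu
  sum(y * log(m) - m - lgamma(y + 1))
}

#' Negative-binomial log-likelihood with exposure
#'
#' NB2 parameterization: a plant's total `y` has mean `m = t * mu` and
#' variance `m + alpha * m^2`, so `alpha` measures plant-to-plant variance in
#' excess of Poisson. At `alpha = 0` the Poisson log-likelihood is returned
#' (the continuous limit); for very small `alpha` a numerically stable
#' asymptotic expansion of the gamma-function terms is used so the limit is
#' approached smoothly.
#'
#' @inheritParams poisson_loglik
#' @param alpha Overdispersion parameter, `alpha >= 0`.
#'
#' @return The summed log-likelihood (a scalar).
#' @examples
#' negbin_loglik(0, 1, 2, 0.5) # = -(1/0.5) * log(1 + 0.5 * 2) = -2 log 2
#' @export
negbin_loglik <- function(y, t, mu, alpha) {
  check_count_args(y, t, mu)
  if (length(alpha) != 1 || is.na(alpha) || alpha < 0) {
    abort("alpha must be a single non-negative number",
          class = "hierepi_domain_error")
  }
  m <- t * mu
  if (alpha == 0) return(sum(y * log(m) - m - lgamma(y + 1)))
  r <- 1 / alpha
  if (alpha < 1e-8) {
    # lgamma(y + r) - lgamma(r) ~ y*log(r) + y(y-1)/(2r) for huge r avoids
    # catastrophic cancellation between two enormous lgamma values
    lg <- y * log(r) + y * (y - 1) / (2 * r)
  } else {
    lg <- lgamma(y + r) - lgamma(r)
  }
  sum(lg - lgamma(y + 1) - r * log1p(m / r) + y * log(m) - y * log(r + m))
}

check_count_args <- function(y, t, mu) {
  if (any(t <= 0)) abort("all exposures t must be > 0",
                         class = "hierepi_domain_error")
  if (any(mu <= 0) || any(!is.finite(mu))) {
    abort("all means mu must be positive and finite",
          class = "hierepi_domain_error")
  }
  if (any(y < 0)) abort("counts y must be non-negative",
                        class = "hierepi_domain_error")
  invisible(TRUE)
}

# NB2 unit deviance vs the plant-level saturated model at a common alpha.
# Saturated fit sets m_i = y_i (limit value for y_i = 0).
nb_deviance <- function(y, m, alpha) {
  t1 <- ifelse(y > 0, y * log(y / m), 0)
  if (alpha == 0) return(2 * sum(t1 - (y - m)))
  r <- 1 / alpha
  2 * sum(t1 - (y + r) * (log(r + y) - log(r + m)))
}

pois_deviance <- function(y, m) {
  2 * sum(ifelse(y > 0, y * log(y / m), 0) - (y - m))
}
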