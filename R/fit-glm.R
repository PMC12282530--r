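#' Fit a Poisson or negative-binomial count GLM with exposure
#'
#' Maximum-likelihood fit of plant branching totals `y` with exposure `t`
#' under a genotype basis (`"intercept"`, `"additive"`, or `"pairwise"`), a
#' link (`"log"` or `"identity"`) applied to the per-inflorescence mean, and a
#' Poisson or NB2 negative-binomial family. Under the log link the additive
#' basis is the multiplicative model of gene action (fold effects of loci
#' multiply on the count scale); the pairwise basis adds all
#' additive/dominance product terms between compatible locus pairs. For the
#' negative-binomial family a single overdispersion parameter `alpha` is
#' estimated jointly with the coefficients.
#'
#' Poisson log-link fits use iteratively reweighted least squares
#' ([stats::glm()]); all other fits maximize the likelihood by BFGS with
#' analytic gradients, initialized from a Poisson or least-squares fit.
#' Identity-link fits whose means go non-positive are refit with a softplus
#' positivity barrier and flagged via `positivity_constrained`.
#'
#' @param records Plant-record tibble with `t`, `y` and genotype columns.
#' @param basis `"intercept"`, `"additive"` or `"pairwise"`.
#' @param link `"log"` or `"identity"`.
#' @param family `"negbin"` or `"poisson"`.
#' @param loci Locus set tibble, see [default_loci()].
#' @param compute_vcov Compute the coefficient covariance from the observed
#'   information? (Skipped for speed in model-comparison loops.)
#' @param control List of optimizer settings: `maxit` (default 1000),
#'   `reltol` (default 1e-12).
#'
#' @return An object of class `"branch_fit"`: a list with elements
#'   `coefficients`, `vcov`, `alpha`, `loglik`, `deviance`, `aic`,
#'   `n_params`, `nobs`, `converged`, `positivity_constrained`,
#'   `column_meta`, `dropped`, `family`, `link`, `basis`, `loci`,
#'   `fitted_mu`.
#' @examples
#' sim <- simulate_branching_study(cross_design(n_plants = 150), seed = 1)
#' fit <- fit_count_glm(sim$records, basis = "additive")
#' glance(fit)
#' @export
fit_count_glm <- function(records,
                          basis = c("additive", "pairwise", "intercept"),
                          link = c("log", "identity"),
                          family = c("negbin", "poisson"),
                          loci = default_loci(),
                          compute_vcov = TRUE,
                          control = list()) {
  basis <- match.arg(basis)
  link <- match.arg(link)
  family <- match.arg(family)
  maxit <- control$maxit %||% 1000
  reltol <- control$reltol %||% 1e-12

  y <- as.numeric(records$y)
  t <- as.numeric(records$t)
  if (any(t <= 0)) abort("all exposures t must be > 0")

  if (basis == "intercept") {
    X <- matrix(1, nrow = nrow(records), dimnames = list(NULL, "(Intercept)"))
    meta <- tibble::tibble(term = "(Intercept)", type = "intercept",
                           locus1 = NA_character_, locus2 = NA_character_,
                           kind = NA_character_)
    dropped <- tibble::tibble(term = character(), reason = character())
  } else {
    X <- build_design(records, loci, pairwise = basis == "pairwise",
                      drop = TRUE)
    meta <- attr(X, "column_meta")
    dropped <- attr(X, "dropped")
    X <- unclass(X)
    attr(X, "column_meta") <- NULL
    attr(X, "dropped") <- NULL
    # data-driven collinearity beyond exact duplicates
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      lose <- qrX$pivot[seq(qrX$rank + 1, ncol(X))]
      warn(sprintf("Dropping %d collinear column(s): %s", length(lose),
                   paste(colnames(X)[lose], collapse = ", ")))
      dropped <- dplyr::bind_rows(dropped, tibble::tibble(
        term = colnames(X)[lose], reason = "collinear"))
      X <- X[, -lose, drop = FALSE]
      meta <- meta[-lose, ]
    }
  }
  p <- ncol(X)
  if (nrow(X) < p) warn("fewer plants than design columns; fit may be unstable")

  fit <- if (family == "poisson" && link == "log") {
    fit_pois_log(X, y, t, compute_vcov)
  } else {
    fit_ml(X, y, t, family, link, maxit, reltol, compute_vcov)
  }

  m_hat <- t * fit$mu
  loglik <- if (family == "negbin") negbin_loglik(y, t, fit$mu, fit$alpha)
            else poisson_loglik(y, t, fit$mu)
  devi <- if (family == "negbin") nb_deviance(y, m_hat, fit$alpha)
          else pois_deviance(y, m_hat)
  n_params <- p + (family == "negbin")
  structure(list(
    coefficients = setNames(fit$theta, colnames(X)),
    vcov = fit$vcov,
    alpha = fit$alpha,
    alpha_se = fit$alpha_se,
    loglik = loglik,
    deviance = devi,
    aic = 2 * n_params - 2 * loglik,
    n_params = n_params,
    nobs = length(y),
    converged = fit$converged,
    positivity_constrained = isTRUE(fit$positivity_constrained),
    column_meta = meta,
    dropped = dropped,
    family = family,
    link = link,
    basis = basis,
    loci = loci,
    fitted_mu = fit$mu,
    y = y,
    t = t
  ), class = "branch_fit")
}

fit_pois_log <- function(X, y, t, compute_vcov) {
  g <- suppressWarnings(
    glm(y ~ X - 1 + offset(log(t)), family = poisson()))
  theta <- unname(coef(g))
  vcov <- NULL
  if (compute_vcov) {
    vcov <- vcov(g)
    dimnames(vcov) <- list(colnames(X), colnames(X))
  }
  list(theta = theta, alpha = NULL, alpha_se = NULL, vcov = vcov,
       mu = as.numeric(exp(X %*% theta)), converged = g$converged)
}

# joint BFGS maximum likelihood over (theta, log alpha)
fit_ml <- function(X, y, t, family, link, maxit, reltol, compute_vcov,
                   softplus = FALSE) {
  p <- ncol(X)
  negbin <- family == "negbin"

  mu_of <- function(eta) {
    if (link == "log") exp(pmin(eta, 40))
    else if (softplus) log1p(exp(pmin(eta, 40))) else eta
  }
  dmu_of <- function(eta, mu) {
    if (link == "log") mu
    else if (softplus) 1 / (1 + exp(-pmin(eta, 40))) else rep(1, length(eta))
  }

  nll <- function(par) {
    theta <- par[seq_len(p)]
    eta <- as.numeric(X %*% theta)
    mu <- mu_of(eta)
    if (any(mu <= 0) || any(!is.finite(mu))) {
      return(1e12 + 1e6 * sum(pmax(-eta, 0)))
    }
    ll <- if (negbin) negbin_loglik(y, t, mu, exp(par[p + 1]))
          else poisson_loglik(y, t, mu)
    if (!is.finite(ll)) return(1e12)
    -ll
  }
  grad <- function(par) {
    theta <- par[seq_len(p)]
    eta <- as.numeric(X %*% theta)
    mu <- mu_of(eta)
    if (any(mu <= 0) || any(!is.finite(mu))) {
      g <- -1e6 * colSums(X * (eta <= 0))
      return(c(g, if (negbin) 0))
    }
    m <- t * mu
    alpha <- if (negbin) exp(par[p + 1]) else 0
    w <- if (negbin) (y - m) / (m * (1 + alpha * m)) else y / m - 1
    gtheta <- -colSums(X * (w * t * dmu_of(eta, mu)))
    if (!negbin) return(gtheta)
    r <- 1 / alpha
    dldr <- sum(digamma(y + r) - digamma(r) + log(r / (r + m)) + 1 -
                  (r + y) / (r + m))
    c(gtheta, r * dldr) # d/d(log alpha) = -r * dl/dr; negated for nll
  }

  init <- ml_init(X, y, t, link, negbin, softplus)
  opt <- optim(init, nll, grad, method = "BFGS",
               control = list(maxit = maxit, reltol = reltol))
  # identity link: if the optimum sits on (or crossed) the positivity
  # boundary, refit with a softplus barrier
  if (link == "identity" && !softplus) {
    eta <- as.numeric(X %*% opt$par[seq_len(p)])
    if (any(eta <= 0) || opt$value >= 1e12) {
      res <- fit_ml(X, y, t, family, link, maxit, reltol, compute_vcov,
                    softplus = TRUE)
      res$positivity_constrained <- TRUE
      return(res)
    }
  }
  theta <- opt$par[seq_len(p)]
  mu <- mu_of(as.numeric(X %*% theta))
  alpha <- if (negbin) exp(opt$par[p + 1]) else NULL
  vcov <- NULL
  alpha_se <- NULL
  if (compute_vcov) {
    H <- optimHess(opt$par, nll, grad)
    cv <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(cv)) {
      vcov <- cv[seq_len(p), seq_len(p), drop = FALSE]
      dimnames(vcov) <- list(colnames(X), colnames(X))
      if (negbin && cv[p + 1, p + 1] > 0) {
        # delta method from log alpha to alpha
        alpha_se <- sqrt(cv[p + 1, p + 1]) * alpha
      }
    }
  }
  list(theta = theta, alpha = alpha, alpha_se = alpha_se, vcov = vcov,
       mu = mu, converged = opt$convergence == 0,
       positivity_constrained = softplus)
}

ml_init <- function(X, y, t, link, negbin, softplus) {
  if (link == "log") {
    g <- suppressWarnings(glm(y ~ X - 1 + offset(log(t)),
                              family = poisson()))
    theta <- unname(coef(g))
    theta[!is.finite(theta)] <- 0
    m0 <- t * exp(pmin(as.numeric(X %*% theta), 40))
  } else {
    w <- suppressWarnings(lm((y / t) ~ X - 1, weights = t))
    theta <- unname(coef(w))
    theta[!is.finite(theta)] <- 0
    eta <- as.numeric(X %*% theta)
    if (any(eta <= 0) && !softplus) {
      # pull towards a feasible interior start
      theta <- theta * 0
      theta[1] <- max(mean(y / t), 0.1)
      eta <- as.numeric(X %*% theta)
    }
    m0 <- t * (if (softplus) log1p(exp(eta)) else pmax(eta, 1e-3))
  }
  alpha0 <- max(sum(((y - m0)^2 - m0) / m0^2) / length(y), 0.01)
  c(theta, if (negbin) log(alpha0))
}

#' @importFrom stats optimHess vcov predict
#' @export
print.branch_fit <- function(x, ...) {
  cat(sprintf("<branch_fit: %s basis, %s link, %s family>\n",
              x$basis, x$link, x$family))
  cat(sprintf("  %d plants, %d parameters%s\n", x$nobs, x$n_params,
              if (x$family == "negbin")
                sprintf(" (alpha = %.4f)", x$alpha) else ""))
  cat(sprintf("  logLik = %.2f, deviance = %.2f, AIC = %.2f%s\n",
              x$loglik, x$deviance, x$aic,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  invisible(x)
}

#' Predict per-inflorescence branching means from a count GLM
#'
#' @param object A `branch_fit`.
#' @param newdata Plant-record or genotype tibble.
#' @param type `"mu"` (per-inflorescence mean) or `"eta"` (linear predictor;
#'   equals `log(mu)` under the log link).
#' @param ... Unused.
#' @return Numeric vector, one value per row of `newdata`.
#' @export
predict.branch_fit <- function(object, newdata, type = c("mu", "eta"), ...) {
  type <- match.arg(type)
  eta <- as.numeric(design_rows(newdata, object) %*% object$coefficients)
  if (type == "eta") return(eta)
  if (object$link == "log") exp(eta)
  else if (object$positivity_constrained) log1p(exp(eta)) else eta
}

# full (undropped) design restricted to a fit's retained columns
design_rows <- function(records, fit) {
  if (fit$basis == "intercept") {
    return(matrix(1, nrow(records), 1, dimnames = list(NULL, "(Intercept)")))
  }
  Xf <- build_design(records, fit$loci, pairwise = fit$basis == "pairwise",
                     drop = FALSE)
  miss <- setdiff(names(fit$coefficients), colnames(Xf))
  if (length(miss) > 0) {
    abort(sprintf("Cannot build design column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  unclass(Xf)[, names(fit$coefficients), drop = FALSE]
}
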