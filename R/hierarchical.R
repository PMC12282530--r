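#' Hierarchical multilinear epistasis parameters
#'
#' Parameter container for the hierarchical epistasis model. Each paralogue
#' pair has a free log-scale effect for every non-wild-type within-pair
#' genotype class (`phi_plt` for PLT3/PLT7, `phi_sep` for EJ2/J2) —
#' equivalent to a full additive + dominance + pairwise-interaction model
#' within each pair. The two within-pair phenotypes are combined through a
#' multilinear function with a single masking parameter `theta_int`:
#' `mu = theta_wt + phi_PLT + phi_SEP - theta_int * phi_PLT * phi_SEP`,
#' and the expected branching events per inflorescence is `exp(mu)`.
#' With `theta_int = 0` the model reduces to multiplicative (log-additive)
#' combination across pairs; `theta_int > 0` means mutations in one pair
#' progressively mask the effects of mutations in the other.
#'
#' @param theta_wt Log mean branching events per inflorescence of the
#'   wild type.
#' @param theta_int Masking interaction between the two pairs.
#' @param phi_plt Named numeric vector: log-scale effect of each non-WT
#'   PLT3/PLT7 class (names as produced by [within_pair_class()]).
#' @param phi_sep Named numeric vector: effects of non-WT EJ2/J2 classes.
#' @param alpha NB2 overdispersion parameter (`>= 0`).
#'
#' @return An object of class `"hier_params"`.
#' @export
hier_params <- function(theta_wt, theta_int, phi_plt, phi_sep, alpha) {
  stopifnot(is.numeric(theta_wt), length(theta_wt) == 1,
            is.numeric(theta_int), length(theta_int) == 1,
            alpha >= 0)
  if (is.null(names(phi_plt)) || is.null(names(phi_sep))) {
    abort("phi_plt and phi_sep must be named by within-pair class")
  }
  if ("WT" %in% c(names(phi_plt), names(phi_sep))) {
    abort("the WT class has effect 0 by definition and is not stored")
  }
  stopifnot(all(is.finite(c(theta_wt, theta_int, phi_plt, phi_sep, alpha))))
  structure(list(theta_wt = theta_wt, theta_int = theta_int,
                 phi_plt = phi_plt, phi_sep = phi_sep, alpha = alpha),
            class = "hier_params")
}

#' @export
print.hier_params <- function(x, ...) {
  cat(sprintf(
    "<hier_params: theta_wt = %.3f, theta_int = %.4f, alpha = %.3f>\n",
    x$theta_wt, x$theta_int, x$alpha))
  cat(sprintf("  %d PLT classes, %d SEP classes\n",
              length(x$phi_plt), length(x$phi_sep)))
  invisible(x)
}

# phi value for each plant's within-pair class; WT -> 0, unknown -> error
phi_lookup <- function(classes, phi, pair) {
  out <- rep(0, length(classes))
  non_wt <- classes != "WT"
  idx <- match(classes[non_wt], names(phi))
  if (anyNA(idx)) {
    abort(sprintf(
      "Unknown %s class(es): %s\nKnown classes: %s", pair,
      paste(unique(classes[non_wt][is.na(idx)]), collapse = ", "),
      paste(names(phi), collapse = ", ")))
  }
  out[non_wt] <- phi[idx]
  out
}

#' Predicted log mean branching under the hierarchical model
#'
#' Evaluates `mu = theta_wt + phi_PLT + phi_SEP - theta_int * phi_PLT *
#' phi_SEP` for each plant/genotype. The expected branching events per
#' inflorescence is `exp(mu)` and a plant's expected total is `t * exp(mu)`.
#'
#' @param params A [hier_params()] object (or a `hier_fit`).
#' @param records Genotype or plant-record tibble.
#' @return Numeric vector of log means, one per row.
#' @export
predict_log_mean <- function(params, records) {
  if (inherits(params, "hier_fit")) params <- params$params
  stopifnot(inherits(params, "hier_params"))
  pp <- phi_lookup(within_pair_class(records, "PLT"), params$phi_plt, "PLT")
  ps <- phi_lookup(within_pair_class(records, "SEP"), params$phi_sep, "SEP")
  params$theta_wt + pp + ps - params$theta_int * pp * ps
}

#' Fit the hierarchical epistasis model by maximum likelihood
#'
#' Maximizes the negative-binomial likelihood with exposure over the
#' wild-type log mean, the within-pair effect tables, the masking parameter
#' `theta_int` and the overdispersion `alpha` (through its logarithm).
#' Optimization runs the Adam optimizer (default 10,000 iterations, learning
#' rate 0.01), stopping early once the largest gradient component falls below
#' `tol`, followed by a BFGS polish for determinism. Initialization starts at
#' the multiplicative model: `theta_wt` and the `phi` tables are seeded from
#' an additive log-link negative-binomial GLM and `theta_int` from zero.
#' Classes never observed in the data are not parameterized.
#'
#' If only one paralogue pair segregates in the data, `theta_int` is
#' unidentifiable; it is fixed at 0 with a warning.
#'
#' @param records Plant-record tibble.
#' @param loci Locus set tibble.
#' @param iterations Maximum Adam iterations.
#' @param learning_rate Adam learning rate.
#' @param tol Gradient infinity-norm threshold declaring convergence.
#' @param theta_int `NULL` to estimate freely, or a number to fix it (used
#'   for profile-likelihood intervals).
#' @param init Optional `hier_params` used as starting point (bypasses the
#'   GLM-based initialization).
#' @param polish Run the BFGS polish step?
#'
#' @return An object of class `"hier_fit"`: `params` ([hier_params()]),
#'   `loglik`, `deviance`, `aic`, `n_params`, `nobs`, `converged`,
#'   `grad_norm`, `iterations_run`, `theta_int_fixed`.
#' @examples
#' sim <- simulate_branching_study(cross_design(n_plants = 150), seed = 7)
#' fit <- fit_hierarchical(sim$records, iterations = 2000)
#' glance(fit)
#' @export
fit_hierarchical <- function(records, loci = default_loci(),
                             iterations = 10000, learning_rate = 0.01,
                             tol = 1e-5, theta_int = NULL, init = NULL,
                             polish = TRUE) {
  y <- as.numeric(records$y)
  t <- as.numeric(records$t)
  cp <- within_pair_class(records, "PLT")
  cs <- within_pair_class(records, "SEP")
  plt_classes <- sort(setdiff(unique(cp), "WT"))
  sep_classes <- sort(setdiff(unique(cs), "WT"))
  kp <- length(plt_classes)
  ks <- length(sep_classes)

  int_fixed_at <- theta_int
  if (kp == 0 || ks == 0) {
    if (is.null(int_fixed_at)) {
      warn(paste("only one paralogue pair segregates;",
                 "theta_int is unidentifiable and fixed at 0"))
      int_fixed_at <- 0
    }
  }
  free_int <- is.null(int_fixed_at)

  ip <- match(cp, plt_classes, nomatch = 0L)  # 0 = WT
  is_ <- match(cs, sep_classes, nomatch = 0L)
  # per-class gradient accumulation; every class 1..k is present by
  # construction, class 0 (WT) may be absent
  class_sums <- function(v, idx, k) {
    rs <- rowsum(v, idx)
    as.numeric(rs[as.character(seq_len(k)), 1])
  }

  unpack <- function(par) {
    twt <- par[1]
    tint <- if (free_int) par[2] else int_fixed_at
    off <- 1 + free_int
    list(twt = twt, tint = tint,
         phiP = par[off + seq_len(kp)],
         phiS = par[off + kp + seq_len(ks)],
         alpha = exp(par[length(par)]))
  }
  mu_of <- function(pr) {
    pp <- c(0, pr$phiP)[ip + 1L]
    ps <- c(0, pr$phiS)[is_ + 1L]
    list(pp = pp, ps = ps,
         mu = pr$twt + pp + ps - pr$tint * pp * ps)
  }
  nll <- function(par) {
    pr <- unpack(par)
    mu <- pmin(mu_of(pr)$mu, 40)
    ll <- negbin_loglik(y, t, exp(mu), pr$alpha)
    if (!is.finite(ll)) return(1e12)
    -ll
  }
  grad <- function(par) {
    pr <- unpack(par)
    mm <- mu_of(pr)
    mu <- pmin(mm$mu, 40)
    m <- t * exp(mu)
    alpha <- pr$alpha
    d <- (y - m) / (1 + alpha * m)  # dl/dmu under the log link
    g_twt <- sum(d)
    g_phiP <- if (kp > 0) class_sums(d * (1 - pr$tint * mm$ps), ip, kp)
    g_phiS <- if (ks > 0) class_sums(d * (1 - pr$tint * mm$pp), is_, ks)
    r <- 1 / alpha
    dldr <- sum(digamma(y + r) - digamma(r) + log(r / (r + m)) + 1 -
                  (r + y) / (r + m))
    g_lalpha <- -r * dldr
    g <- c(g_twt,
           if (free_int) -sum(d * mm$pp * mm$ps),
           if (kp > 0) g_phiP, if (ks > 0) g_phiS,
           g_lalpha)
    -g
  }

  par0 <- hier_init(records, loci, plt_classes, sep_classes, init,
                    free_int, int_fixed_at)
  ll_init <- -nll(par0)

  # Adam with early stopping on the gradient infinity norm
  par <- par0
  m1 <- v1 <- numeric(length(par))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  it_run <- 0L
  gmax <- Inf
  if (iterations > 0) {
    for (it in seq_len(iterations)) {
      g <- grad(par)
      m1 <- b1 * m1 + (1 - b1) * g
      v1 <- b2 * v1 + (1 - b2) * g^2
      mhat <- m1 / (1 - b1^it)
      vhat <- v1 / (1 - b2^it)
      par <- par - learning_rate * mhat / (sqrt(vhat) + eps)
      it_run <- it
      if (it %% 100 == 0) {
        gmax <- max(abs(grad(par)))
        if (gmax < tol) break
      }
    }
  }
  if (polish) {
    opt <- optim(par, nll, grad, method = "BFGS",
                 control = list(maxit = 2000, reltol = 1e-13))
    if (-opt$value >= -nll(par)) par <- opt$par
  }
  if (-nll(par) < ll_init) { # monotone-improvement safeguard
    opt <- optim(par0, nll, grad, method = "BFGS",
                 control = list(maxit = 2000, reltol = 1e-13))
    if (-opt$value >= ll_init) par <- opt$par else par <- par0
  }

  pr <- unpack(par)
  gmax <- max(abs(grad(par)))
  params <- hier_params(
    theta_wt = pr$twt, theta_int = pr$tint,
    phi_plt = setNames(as.numeric(pr$phiP), plt_classes),
    phi_sep = setNames(as.numeric(pr$phiS), sep_classes),
    alpha = pr$alpha)
  ll <- -nll(par)
  n_params <- 1 + free_int + kp + ks + 1
  m_hat <- t * exp(pmin(mu_of(pr)$mu, 40))
  structure(list(
    params = params,
    loglik = ll,
    deviance = nb_deviance(y, m_hat, pr$alpha),
    aic = 2 * n_params - 2 * ll,
    n_params = n_params,
    nobs = length(y),
    family = "negbin", link = "log", basis = "hierarchical",
    converged = gmax < max(tol * 100, 1e-3 * max(1, length(y) / 1000)),
    grad_norm = gmax,
    iterations_run = it_run,
    theta_int_fixed = !free_int,
    loci = loci,
    fitted_mu = m_hat / t,
    y = y,
    t = t
  ), class = "hier_fit")
}

# initialization at the multiplicative model, phi seeded from the
# additive log-link NB GLM predictions
hier_init <- function(records, loci, plt_classes, sep_classes, init,
                      free_int, int_fixed_at) {
  kp <- length(plt_classes)
  ks <- length(sep_classes)
  if (!is.null(init)) {
    stopifnot(inherits(init, "hier_params"))
    phiP <- init$phi_plt[plt_classes]
    phiS <- init$phi_sep[sep_classes]
    phiP[is.na(phiP)] <- 0
    phiS[is.na(phiS)] <- 0
    return(c(init$theta_wt, if (free_int) init$theta_int,
             as.numeric(phiP), as.numeric(phiS),
             log(max(init$alpha, 1e-4))))
  }
  add <- tryCatch(
    fit_count_glm(records, basis = "additive", link = "log",
                  family = "negbin", loci = loci, compute_vcov = FALSE),
    error = function(e) NULL)
  if (is.null(add)) {
    rate <- mean(records$y / records$t)
    return(c(log(max(rate, 1e-3)), if (free_int) 0,
             numeric(kp), numeric(ks), log(0.3)))
  }
  eta_wt <- predict(add, wt_genotype(), type = "eta")
  phi_of <- function(classes) {
    if (length(classes) == 0) return(numeric(0))
    g <- dplyr::bind_rows(lapply(classes, class_to_genotype, loci = loci))
    predict(add, g, type = "eta") - eta_wt
  }
  c(eta_wt, if (free_int) 0, phi_of(plt_classes), phi_of(sep_classes),
    log(max(add$alpha, 1e-4)))
}

# "PLT3:HET|PLT7:MUT" -> genotype row (works for both pair label formats)
class_to_genotype <- function(label, loci = default_loci()) {
  if (label == "WT") return(wt_genotype())
  parts <- strsplit(label, "|", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  genotype_from_assignments(
    setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1)), loci)
}

#' @export
print.hier_fit <- function(x, ...) {
  cat("<hier_fit: hierarchical multilinear epistasis model>\n")
  print(x$params)
  cat(sprintf("  logLik = %.2f, AIC = %.2f, %d parameters%s\n",
              x$loglik, x$aic, x$n_params,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  invisible(x)
}

#' Profile-likelihood confidence interval for the masking parameter
#'
#' Profiles the likelihood over `theta_int`, refitting all other parameters
#' at each candidate value (warm-started from the full fit), and inverts the
#' likelihood-ratio statistic against its chi-square(1) reference. Profiling
#' is preferred over a Wald interval because the curvature can be asymmetric
#' near masking saturation.
#'
#' @param fit A `hier_fit` with freely estimated `theta_int`.
#' @param records The plant records the model was fit to.
#' @param level Confidence level (default 0.95).
#' @param step Initial step size of the bracket search.
#'
#' @return A one-row tibble: `estimate`, `lower`, `upper`, `level`.
#' @export
confint_theta_int <- function(fit, records, level = 0.95, step = 0.02) {
  stopifnot(inherits(fit, "hier_fit"))
  if (fit$theta_int_fixed) abort("theta_int was fixed; no interval available")
  qcut <- qchisq(level, df = 1)
  est <- fit$params$theta_int
  ll_hat <- fit$loglik
  prof <- function(tau) {
    f <- fit_hierarchical(records, loci = fit$loci, iterations = 0,
                          theta_int = tau, init = fit$params, polish = TRUE)
    2 * (ll_hat - f$loglik)
  }
  bound <- function(direction) {
    s <- step
    tau_in <- est
    for (i in 1:60) {
      tau_out <- est + direction * s
      r <- prof(tau_out)
      if (r >= qcut) {
        return(uniroot(function(x) prof(x) - qcut,
                       lower = min(tau_in, tau_out),
                       upper = max(tau_in, tau_out), tol = 1e-6)$root)
      }
      tau_in <- tau_out
      s <- s * 1.7
    }
    direction * Inf
  }
  tibble::tibble(estimate = est, lower = bound(-1), upper = bound(1),
                 level = level)
}

#' Fold effect of a mutant combination in a genetic background
#'
#' Ratio of predicted mean branching with and without `combo`, on top of
#' `background`: `exp(mu(background + combo) - mu(background))`. With
#' `theta_int = 0` this is background-independent (multiplicative gene
#' action); with `theta_int > 0` the fold effect of a PLT combination
#' shrinks as the SEP background effect grows (masking), and vice versa.
#'
#' @param params A [hier_params()] object (or `hier_fit`).
#' @param combo Named character vector of locus-state assignments, e.g.
#'   `c(PLT3 = "MUT")`.
#' @param background Named character vector for the background genotype
#'   (default empty = wild type). Must touch loci disjoint from `combo`.
#' @param loci Locus set tibble.
#'
#' @return The fold change (scalar).
#' @export
fold_effect <- function(params, combo, background = character(0),
                        loci = default_loci()) {
  if (inherits(params, "hier_fit")) params <- params$params
  if (length(intersect(names(combo), names(background))) > 0) {
    abort("combo and background must assign disjoint loci")
  }
  g_bg <- genotype_from_assignments(background, loci)
  g_full <- genotype_from_assignments(c(background, combo), loci)
  exp(predict_log_mean(params, g_full) - predict_log_mean(params, g_bg))
}

#' Multiplicative (no-epistasis-between-pairs) expectation
#'
#' The reference mean branching obtained by multiplying the wild-type mean by
#' the wild-type-background fold effects of two combinations:
#' `exp(theta_wt) * fold(combo1 | WT) * fold(combo2 | WT)`. Used as the
#' no-interaction baseline for response-surface plots and excess ratios.
#'
#' @inheritParams fold_effect
#' @param combo1,combo2 Named locus-state assignment vectors.
#' @return Expected branching events per inflorescence (scalar).
#' @export
multiplicative_expectation <- function(params, combo1, combo2,
                                       loci = default_loci()) {
  if (inherits(params, "hier_fit")) params <- params$params
  exp(params$theta_wt) *
    fold_effect(params, combo1, loci = loci) *
    fold_effect(params, combo2, loci = loci)
}

#' Response surface of the hierarchical model
#'
#' Predicted branching events per inflorescence over a grid of within-pair
#' log-scale phenotypic effects: entry `(u, v)` is
#' `exp(theta_wt + u + v - theta_int * u * v)`. Along either axis (the other
#' pair wild type) the surface is a pure exponential; at
#' `phi = 1 / theta_int` in one pair the surface is flat in the other
#' (complete masking). The surface is symmetric in its two arguments.
#'
#' @inheritParams fold_effect
#' @param phi_plt_grid,phi_sep_grid Numeric grids of within-pair effects
#'   (log-fold units).
#' @return A tibble of class `"hier_surface"` with columns `phi_plt`,
#'   `phi_sep`, `branching`.
#' @export
response_surface <- function(params,
                             phi_plt_grid = seq(0, 5, length.out = 41),
                             phi_sep_grid = seq(0, 5, length.out = 41)) {
  if (inherits(params, "hier_fit")) params <- params$params
  stopifnot(all(is.finite(phi_plt_grid)), all(is.finite(phi_sep_grid)))
  out <- tidyr::expand_grid(phi_plt = phi_plt_grid, phi_sep = phi_sep_grid)
  out$branching <- exp(params$theta_wt + out$phi_plt + out$phi_sep -
                         params$theta_int * out$phi_plt * out$phi_sep)
  class(out) <- c("hier_surface", class(out))
  attr(out, "theta_wt") <- params$theta_wt
  attr(out, "theta_int") <- params$theta_int
  out
}
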