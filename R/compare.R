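#' Percent deviance explained relative to the intercept-only model
#'
#' `100 * (D_null - D_model) / D_null`, the GLM analogue of R-squared. Each
#' deviance is computed against the plant-level saturated model at that fit's
#' own maximum-likelihood parameters (including its own overdispersion
#' estimate for negative-binomial fits).
#'
#' Because each negative-binomial fit estimates its own overdispersion, the
#' default per-model-alpha deviances are not strictly comparable across
#' nested models; supply `common_alpha` to recompute both deviances at one
#' overdispersion value (e.g. the larger model's estimate), which restores
#' monotonicity in model size.
#'
#' @param fit A fitted model (`branch_fit` or `hier_fit`).
#' @param null_fit The intercept-only fit of the same family/link on the same
#'   records (see [fit_count_glm()] with `basis = "intercept"`).
#' @param common_alpha Optional overdispersion at which both deviances are
#'   recomputed.
#'
#' @return Percent deviance explained (scalar).
#' @export
deviance_explained <- function(fit, null_fit, common_alpha = NULL) {
  if (!is.null(null_fit$basis) && null_fit$basis != "intercept") {
    abort("null_fit must be an intercept-only model")
  }
  if (fit$nobs != null_fit$nobs) {
    abort("fit and null_fit must be fit to the same records")
  }
  d_fit <- fit$deviance
  d_null <- null_fit$deviance
  if (!is.null(common_alpha)) {
    d_fit <- nb_deviance(fit$y, fit$t * fit$fitted_mu, common_alpha)
    d_null <- nb_deviance(null_fit$y, null_fit$t * null_fit$fitted_mu,
                          common_alpha)
  }
  if (d_null <= 0) {
    abort("null deviance is zero; deviance explained undefined")
  }
  100 * (d_null - d_fit) / d_null
}

#' Likelihood ratio test between nested fits
#'
#' @param nested,full Fitted models, with `nested` a restriction of `full`.
#' @return A one-row tibble with `statistic`, `df`, `p_value` and a `note`
#'   (marks the boundary case of testing the overdispersion parameter, where
#'   the chi-square reference is conservative).
#' @export
likelihood_ratio_test <- function(nested, full) {
  if (nested$n_params >= full$n_params) {
    abort("nested model must have fewer parameters than the full model")
  }
  stat <- 2 * (full$loglik - nested$loglik)
  if (stat < -1e-6) {
    warn("full model has lower log-likelihood than nested model; refit advised")
  }
  stat <- max(stat, 0)
  df <- full$n_params - nested$n_params
  note <- NA_character_
  if (!is.null(nested$family) && !is.null(full$family) &&
      nested$family == "poisson" && full$family == "negbin" && df == 1) {
    note <- "alpha tested at its boundary; chi-square(1) p is conservative"
  }
  tibble::tibble(statistic = stat, df = df,
                 p_value = pchisq(stat, df, lower.tail = FALSE), note = note)
}

#' AIC evidence ratio
#'
#' `exp((aic_b - aic_a) / 2)`: how many times more likely model `a` is than
#' model `b` in the Akaike sense.
#'
#' @param aic_a,aic_b AIC values of the two models.
#' @return The evidence ratio of model a over model b.
#' @examples
#' relative_likelihood(0, 19.64) # ~18,358
#' @export
relative_likelihood <- function(aic_a, aic_b) {
  stopifnot(is.finite(aic_a), is.finite(aic_b))
  exp((aic_b - aic_a) / 2)
}

#' Synergy in excess of the multiplicative expectation
#'
#' For a within-pair double mutant, estimates how many fold the mean branching
#' exceeds the multiplicative expectation from the two single mutants, under a
#' log-link pairwise fit. The contrast in log space is
#' `mu(double) - mu(single1) - mu(single2) + mu(WT)` evaluated in an
#' otherwise-wild-type background, so only the interaction coefficients of the
#' pair contribute. Reported with a Wald 95% confidence interval and a
#' two-sided z-test (no multiple-testing correction).
#'
#' @param pairwise_fit A log-link `branch_fit` with `basis = "pairwise"` and a
#'   computed covariance.
#' @param locus_pair Character vector of the two locus labels, e.g.
#'   `c("PLT3", "PLT7")` or `c("EJ2pro8", "J2")`.
#' @param combo States of the two loci in the double mutant, e.g.
#'   `c("HET", "MUT")` for `plt3/+ plt7`.
#'
#' @return A one-row tibble: `log_estimate`, `fold`, `ci_lo`, `ci_hi` (fold
#'   scale), `z`, `p_value`.
#' @export
synergy_fold_excess <- function(pairwise_fit, locus_pair, combo) {
  stopifnot(length(locus_pair) == 2, length(combo) == 2)
  if (pairwise_fit$link != "log") {
    abort("synergy contrasts require a log-link fit")
  }
  if (is.null(pairwise_fit$vcov)) {
    abort("pairwise_fit has no covariance; refit with compute_vcov = TRUE")
  }
  loci <- pairwise_fit$loci
  g4 <- dplyr::bind_rows(
    genotype_from_assignments(setNames(combo, locus_pair), loci),
    genotype_from_assignments(setNames(combo[1], locus_pair[1]), loci),
    genotype_from_assignments(setNames(combo[2], locus_pair[2]), loci),
    genotype_from_assignments(character(0), loci))
  Xf <- unclass(build_design(
    g4, loci, pairwise = TRUE, drop = FALSE))
  cvec_full <- Xf[1, ] - Xf[2, ] - Xf[3, ] + Xf[4, ]
  touched <- names(cvec_full)[abs(cvec_full) > 1e-12]
  missing <- setdiff(touched, names(pairwise_fit$coefficients))
  if (length(missing) > 0) {
    abort(sprintf("Contrast touches dropped column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  cvec <- cvec_full[names(pairwise_fit$coefficients)]
  est <- sum(cvec * pairwise_fit$coefficients)
  se <- sqrt(as.numeric(cvec %*% pairwise_fit$vcov %*% cvec))
  z <- if (se > 0) est / se else 0
  tibble::tibble(
    locus1 = locus_pair[1], locus2 = locus_pair[2],
    state1 = combo[1], state2 = combo[2],
    log_estimate = est,
    fold = exp(est),
    ci_lo = exp(est - qnorm(0.975) * se),
    ci_hi = exp(est + qnorm(0.975) * se),
    z = z,
    p_value = if (se > 0) 2 * pnorm(-abs(z)) else 1)
}

#' Cross-validated predictive performance on held-out group means
#'
#' Leave-one-season-out or leave-genotype-group-out cross-validation. For
#' each fold the models are refit on the retained plants; held-out
#' genotype(-season) mean branching rates are estimated independently via
#' [genotype_season_mle()] on the held-out plants, and performance is the
#' squared Pearson correlation between `log(1 + predicted mean)` and
#' `log(1 + held-out MLE mean)`, matching the log(1 + x) scale on which
#' branching phenotypes are usually displayed.
#'
#' @param records Plant-record tibble with `season_id`.
#' @param models Character vector among `"multiplicative"` (additive basis,
#'   log link), `"pairwise"` and `"hierarchical"`.
#' @param scheme `"season"` (folds = seasons) or `"genotype"` (genotypes
#'   partitioned into `k` folds).
#' @param k Number of folds for the genotype scheme.
#' @param seed Seed for the genotype-fold assignment.
#' @param loci Locus set tibble.
#'
#' @return A list of class `"hierepi_cv"` with `folds` (tibble: `model`,
#'   `fold`, `r2`, `n_held`) and `summary` (tibble: `model`, `mean_r2`,
#'   `n_folds`).
#' @export
cross_validate <- function(records,
                           models = c("multiplicative", "pairwise"),
                           scheme = c("season", "genotype"),
                           k = 5, seed = 1,
                           loci = default_loci()) {
  scheme <- match.arg(scheme)
  models <- match.arg(models, c("multiplicative", "pairwise", "hierarchical"),
                      several.ok = TRUE)
  gcols <- c("plt3", "plt7", "j2", "ej2_allele", "ej2_state")
  if (scheme == "season") {
    fold_of <- as.character(records$season_id)
  } else {
    key <- do.call(paste, c(records[gcols], sep = "|"))
    uk <- unique(key)
    assignment <- with_seed(seed, sample(rep(seq_len(k), length.out =
                                               length(uk))))
    fold_of <- as.character(assignment[match(key, uk)])
  }
  folds <- sort(unique(fold_of))
  if (length(folds) < 2) abort("need at least 2 folds")

  rows <- list()
  for (f in folds) {
    train <- records[fold_of != f, ]
    test <- records[fold_of == f, ]
    held <- genotype_season_mle(test)
    if (nrow(held) < 3) {
      inform(sprintf("fold %s skipped: too few held-out estimates", f))
      next
    }
    for (mod in models) {
      pred <- tryCatch({
        if (mod == "hierarchical") {
          hf <- fit_hierarchical(train, loci = loci)
          exp(predict_log_mean(hf$params, held))
        } else {
          bf <- fit_count_glm(train,
                              basis = if (mod == "pairwise") "pairwise"
                                      else "additive",
                              link = "log", family = "negbin", loci = loci,
                              compute_vcov = FALSE)
          predict(bf, held)
        }
      }, error = function(e) NULL)
      if (is.null(pred)) {
        inform(sprintf("fold %s: %s model failed, skipped", f, mod))
        next
      }
      usable <- is.finite(pred) & is.finite(held$mean)
      if (sum(usable) < 3 || var(log1p(held$mean[usable])) == 0) next
      r2 <- cor(log1p(pred[usable]), log1p(held$mean[usable]))^2
      rows[[length(rows) + 1]] <- tibble::tibble(
        model = mod, fold = f, r2 = r2, n_held = sum(usable))
    }
  }
  folds_tbl <- dplyr::bind_rows(rows)
  summary_tbl <- folds_tbl |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(mean_r2 = mean(.data$r2), n_folds = dplyr::n(),
                     .groups = "drop")
  structure(list(folds = folds_tbl, summary = summary_tbl),
            class = "hierepi_cv")
}

#' @export
print.hierepi_cv <- function(x, ...) {
  cat("<cross-validation>\n")
  print(x$summary)
  invisible(x)
}

# run code under a temporary RNG state, restoring the caller's stream
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
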