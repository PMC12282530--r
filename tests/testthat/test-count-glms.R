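test_that("poisson log-likelihood matches closed forms and dpois", {
  expect_equal(poisson_loglik(0, 1, 1), -1)
  expect_equal(poisson_loglik(2, 2, 1.5), dpois(2, 3, log = TRUE))
  set.seed(31)
  y <- rpois(50, 6); t <- sample(5:12, 50, TRUE); mu <- runif(50, 0.1, 3)
  expect_equal(poisson_loglik(y, t, mu),
               sum(dpois(y, t * mu, log = TRUE)), tolerance = 1e-12)
  expect_error(poisson_loglik(1, 1, 0), class = "hierepi_domain_error")
})

test_that("negative-binomial log-likelihood matches the zero-count closed
           form, dnbinom, and the Poisson limit", {
  # closed form for y = 0: -(1/alpha) log(1 + alpha m)
  expect_equal(negbin_loglik(0, 1, 2, 0.5), -2 * log(2))
  set.seed(32)
  y <- rpois(50, 8); t <- sample(5:12, 50, TRUE); mu <- runif(50, 0.1, 3)
  for (alpha in c(0.05, 0.3, 1.5)) {
    expect_equal(negbin_loglik(y, t, mu, alpha),
                 sum(dnbinom(y, size = 1 / alpha, mu = t * mu, log = TRUE)),
                 tolerance = 1e-10)
  }
  expect_equal(negbin_loglik(y, t, mu, 1e-10), poisson_loglik(y, t, mu),
               tolerance = 1e-6)
  expect_equal(negbin_loglik(y, t, mu, 0), poisson_loglik(y, t, mu))
  expect_error(negbin_loglik(1, 1, 1, -0.1), class = "hierepi_domain_error")
})

test_that("a single-genotype negative-binomial fit recovers the sum(y)/sum(t)
           mean exactly", {
  rec <- manual_records(y = c(12, 30, 25, 9, 17), t = rep(10, 5))
  fit <- fit_count_glm(rec, basis = "intercept", link = "log",
                       family = "negbin")
  expect_equal(exp(unname(fit$coefficients[1])), sum(rec$y) / sum(rec$t),
               tolerance = 1e-7)
  expect_equal(fit$aic, 2 * fit$n_params - 2 * fit$loglik)
})

test_that("negative-binomial fits beat Poisson fits on overdispersed data
           and the LRT detects it", {
  sim <- simulate_branching_study(small_design(250), seed = 9)
  pois <- fit_count_glm(sim$records, basis = "additive", family = "poisson",
                        compute_vcov = FALSE)
  nb <- fit_count_glm(sim$records, basis = "additive", family = "negbin",
                      compute_vcov = FALSE)
  expect_gt(nb$loglik, pois$loglik)
  lrt <- likelihood_ratio_test(pois, nb)
  expect_lt(lrt$p_value, 1e-16)
  expect_match(lrt$note, "boundary")
})

test_that("cross-check against an independent NB GLM implementation", {
  skip_if_not_installed("MASS")
  sim <- simulate_branching_study(small_design(200), seed = 10)
  rec <- sim$records
  fit <- fit_count_glm(rec, basis = "additive", link = "log",
                       family = "negbin", compute_vcov = FALSE)
  X <- unclass(design_matrix_additive(rec))
  mf <- data.frame(y = rec$y, X[, -1, drop = FALSE], logt = log(rec$t),
                   check.names = FALSE)
  oracle <- MASS::glm.nb(
    y ~ . - logt + offset(logt), data = mf)
  expect_equal(fit$loglik, as.numeric(stats::logLik(oracle)),
               tolerance = 1e-6)
  expect_equal(fit$alpha, 1 / oracle$theta, tolerance = 1e-3)
  # fitted per-plant means agree
  expect_equal(unname(rec$t * fit$fitted_mu),
               unname(stats::fitted(oracle)), tolerance = 1e-4)
})

test_that("a log-link additive fit recovers means and overdispersion from an
           additive-compatible truth", {
  # truth with purely per-locus effects (no within-pair synergy, no
  # masking): the additive log-link NB model is then exactly specified
  single <- c("PLT3:HET" = 0.10, "PLT3:MUT" = 2.40, "PLT7:HET" = 0.15,
              "PLT7:MUT" = 0.35, "J2:HET" = 0.05, "J2:MUT" = 0.40,
              "EJ2pro7:HET" = 0.05, "EJ2pro7:MUT" = 0.35,
              "EJ2pro8:HET" = 0.05, "EJ2pro8:MUT" = 0.30)
  states <- c("WT", "HET", "MUT")
  phi_plt <- phi_sep <- c()
  for (s3 in states) for (s7 in states) {
    if (s3 == "WT" && s7 == "WT") next
    lab <- within_pair_class(tibble::tibble(plt3 = s3, plt7 = s7), "PLT")
    phi_plt[lab] <- sum(single[paste0(c("PLT3:", "PLT7:"), c(s3, s7))],
                        na.rm = TRUE)
  }
  for (a in c("none", "pro7", "pro8")) for (es in states) for (js in states) {
    if ((a == "none") != (es == "WT")) next
    if (es == "WT" && js == "WT") next
    g <- tibble::tibble(j2 = js, ej2_allele = a, ej2_state = es)
    lab <- within_pair_class(g, "SEP")
    phi_sep[lab] <- sum(single[paste0(c(paste0("EJ2", a, ":"), "J2:"),
                                      c(es, js))], na.rm = TRUE)
  }
  truth <- hier_params(log(0.2), 0, phi_plt, phi_sep, alpha = 0.3)
  sim <- simulate_branching_study(small_design(700),
                                  simulation_config(truth), seed = 12)
  fit <- fit_count_glm(sim$records, basis = "additive", link = "log",
                       family = "negbin")
  expect_lt(abs(fit$alpha - 0.3) / 0.3, 0.2)
  # model predictions match the generative log means on the class grid
  grid <- unique(sim$records[, c("plt3", "plt7", "j2", "ej2_allele",
                                 "ej2_state")])
  expect_lt(max(abs(predict(fit, grid, type = "eta") -
                      predict_log_mean(truth, grid))), 0.35)
  td <- tidy(fit)
  expect_true(all(is.finite(td$std.error)))
  # deterministic refit
  fit2 <- fit_count_glm(sim$records, basis = "additive", link = "log",
                        family = "negbin")
  expect_identical(fit$coefficients, fit2$coefficients)
})

test_that("identity-link fits run and are flagged when positivity binds", {
  sim <- simulate_branching_study(small_design(250), seed = 13)
  fit <- fit_count_glm(sim$records, basis = "additive", link = "identity",
                       family = "negbin", compute_vcov = FALSE)
  expect_true(is.finite(fit$loglik))
  expect_true(all(fit$fitted_mu > 0))
  # log-link additive should beat identity-link additive on multiplicative
  # data (the study's additive-vs-multiplicative comparison); compare at a
  # common overdispersion so the deviances are on one scale
  fit_log <- fit_count_glm(sim$records, basis = "additive", link = "log",
                           family = "negbin", compute_vcov = FALSE)
  null_fit <- fit_count_glm(sim$records, basis = "intercept",
                            family = "negbin", compute_vcov = FALSE)
  a <- fit_log$alpha
  expect_gt(deviance_explained(fit_log, null_fit, common_alpha = a),
            deviance_explained(fit, null_fit, common_alpha = a))
})

test_that("deviance explained matches a hand-computed two-genotype oracle
           and is monotone in model size", {
  g <- dplyr::bind_rows(wt_rows(2),
                        genotype_from_assignments(c(PLT3 = "MUT")),
                        genotype_from_assignments(c(PLT3 = "MUT")))
  rec <- manual_records(y = c(2, 4, 30, 40), t = rep(10, 4), genotype = g)
  fit <- fit_count_glm(rec, basis = "additive", family = "negbin",
                       compute_vcov = FALSE)
  null_fit <- fit_count_glm(rec, basis = "intercept", family = "negbin",
                            compute_vcov = FALSE)
  # explicit NB deviance oracle: D = 2 sum[y log(y/m) - (y + 1/a) log((1 +
  # a y)/(1 + a m))] with each model's own alpha and m = t * mu_hat
  dev_oracle <- function(f) {
    m <- rec$t * f$fitted_mu
    a <- f$alpha
    2 * sum(rec$y * log(rec$y / m) -
              (rec$y + 1 / a) * (log1p(a * rec$y) - log1p(a * m)))
  }
  expect_equal(fit$deviance, dev_oracle(fit), tolerance = 1e-6)
  expect_equal(null_fit$deviance, dev_oracle(null_fit), tolerance = 1e-6)
  expect_equal(deviance_explained(fit, null_fit),
               100 * (dev_oracle(null_fit) - dev_oracle(fit)) /
                 dev_oracle(null_fit), tolerance = 1e-6)
  expect_equal(deviance_explained(null_fit, null_fit), 0)
})

test_that("pairwise deviance explained is at least additive deviance
           explained on the same records", {
  sim <- simulate_branching_study(small_design(250), seed = 14)
  null_fit <- fit_count_glm(sim$records, basis = "intercept",
                            family = "negbin", compute_vcov = FALSE)
  add <- fit_count_glm(sim$records, basis = "additive",
                       family = "negbin", compute_vcov = FALSE)
  pw <- fit_count_glm(sim$records, basis = "pairwise",
                      family = "negbin", compute_vcov = FALSE)
  expect_gte(deviance_explained(pw, null_fit, common_alpha = pw$alpha),
             deviance_explained(add, null_fit, common_alpha = pw$alpha))
})

test_that("likelihood ratio test handles identical fits and textbook
           quantiles", {
  a <- list(loglik = -100, n_params = 3, family = "negbin")
  b <- list(loglik = -100, n_params = 5, family = "negbin")
  lrt <- likelihood_ratio_test(a, b)
  expect_equal(lrt$statistic, 0)
  expect_equal(lrt$p_value, 1)
  c1 <- list(loglik = -100, n_params = 3, family = "negbin")
  c2 <- list(loglik = -100 + 3.84 / 2, n_params = 4, family = "negbin")
  expect_equal(likelihood_ratio_test(c1, c2)$p_value, 0.05, tolerance = 0.01)
  expect_error(likelihood_ratio_test(b, a), "fewer parameters")
})

test_that("AIC evidence ratios reproduce closed forms", {
  expect_equal(relative_likelihood(10, 10), 1)
  expect_equal(relative_likelihood(0, 2), exp(1))
  expect_equal(relative_likelihood(2, 0), exp(-1))
  # a 19.64-point AIC advantage is ~18,400-fold evidence (18,358 at the
  # unrounded difference 2*log(18358) = 19.6356)
  expect_equal(relative_likelihood(-2 * log(18358), 0), 18358)
  expect_equal(relative_likelihood(-19.64, 0), 18358, tolerance = 0.005)
})

test_that("synergy contrasts equal the four-genotype prediction oracle and
           recover injected synergy", {
  truth <- default_truth(theta_int = 0)
  sim <- simulate_branching_study(small_design(900), simulation_config(truth),
                                  seed = 15)
  pw <- fit_count_glm(sim$records, basis = "pairwise", link = "log",
                      family = "negbin")
  ct <- synergy_fold_excess(pw, c("PLT3", "PLT7"), c("HET", "MUT"))
  # oracle: difference of predicted log means over the four genotypes
  g4 <- dplyr::bind_rows(
    genotype_from_assignments(c(PLT3 = "HET", PLT7 = "MUT")),
    genotype_from_assignments(c(PLT3 = "HET")),
    genotype_from_assignments(c(PLT7 = "MUT")),
    wt_rows(1))
  eta <- predict(pw, g4, type = "eta")
  expect_equal(ct$log_estimate, eta[1] - eta[2] - eta[3] + eta[4],
               tolerance = 1e-10)
  # truth injects a known within-pair excess for plt3/+ plt7 (log 3.29-fold)
  true_excess <- truth$phi_plt[["PLT3:HET|PLT7:MUT"]] -
    truth$phi_plt[["PLT3:HET"]] - truth$phi_plt[["PLT7:MUT"]]
  expect_lt(abs(ct$log_estimate - true_excess), 3 * 0.3)
  expect_true(ct$ci_lo < ct$fold, ct$fold < ct$ci_hi)
})

test_that("season-fold cross-validation separates signal from permuted
           labels", {
  des <- cross_design(ej2_alleles = c("pro7", "pro8"), n_plants = 400,
                      seasons = c("A", "B", "C"))
  sim <- simulate_branching_study(des, seed = 16)
  cv <- suppressMessages(
    cross_validate(sim$records, models = "multiplicative",
                   scheme = "season"))
  expect_gt(cv$summary$mean_r2, 0.8)
  # negative control: shuffle genotypes of the held-out records
  rec_perm <- sim$records
  gcols <- c("plt3", "plt7", "j2", "ej2_allele", "ej2_state")
  rec_perm[gcols] <- with_seed_local(17,
    rec_perm[sample(nrow(rec_perm)), gcols])
  cv_perm <- suppressMessages(
    cross_validate(rec_perm, models = "multiplicative", scheme = "season"))
  expect_lt(cv_perm$summary$mean_r2, 0.3)
})
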