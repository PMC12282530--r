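test_that("hierarchical prediction reduces correctly in its special cases", {
  truth <- default_truth()
  wt <- wt_rows(1)
  expect_equal(predict_log_mean(truth, wt), truth$theta_wt)
  # theta_int = 0: effects add in log space (multiply on the count scale)
  t0 <- default_truth(theta_int = 0)
  g <- genotype_from_assignments(c(PLT3 = "MUT", J2 = "MUT"))
  expect_equal(predict_log_mean(t0, g),
               t0$theta_wt + t0$phi_plt[["PLT3:MUT"]] +
                 t0$phi_sep[["J2:MUT"]])
  # full formula
  expect_equal(predict_log_mean(truth, g),
               truth$theta_wt + truth$phi_plt[["PLT3:MUT"]] +
                 truth$phi_sep[["J2:MUT"]] -
                 truth$theta_int * truth$phi_plt[["PLT3:MUT"]] *
                 truth$phi_sep[["J2:MUT"]])
  expect_error(
    predict_log_mean(hier_params(0, 0, c(X = 1), c(Y = 1), 0.1), g),
    "Unknown")
})

test_that("prediction depends on the genotype only through its pair
           classes", {
  truth <- default_truth()
  # two plants from different populations, same classes
  g1 <- tibble::tibble(plt3 = "HET", plt7 = "WT", j2 = "MUT",
                       ej2_allele = "none", ej2_state = "WT",
                       population_id = "A")
  g2 <- g1
  g2$population_id <- "B"
  expect_equal(predict_log_mean(truth, g1), predict_log_mean(truth, g2))
})

test_that("fold effects are masked by the other pair exactly as the
           multilinear form dictates", {
  truth <- default_truth()
  combo <- c(PLT3 = "MUT")
  expect_equal(fold_effect(truth, character(0)), 1)
  f_wt <- fold_effect(truth, combo)
  expect_equal(f_wt, exp(truth$phi_plt[["PLT3:MUT"]]), ignore_attr = TRUE)
  # analytic masking: fold in background = fold_wt^(1 - theta_int * phi_bg)
  for (bg in list(c(J2 = "MUT"), c(EJ2pro8 = "MUT", J2 = "MUT"))) {
    g_bg <- genotype_from_assignments(bg)
    phi_bg <- truth$phi_sep[[within_pair_class(g_bg, "SEP")]]
    expect_equal(log(fold_effect(truth, combo, bg)),
                 log(f_wt) * (1 - truth$theta_int * phi_bg),
                 tolerance = 1e-12)
  }
  # monotone decrease while 1 - theta_int * phi_sep > 0
  phis <- sort(unique(truth$phi_sep[truth$phi_sep < 1 / truth$theta_int]))
  folds <- log(f_wt) * (1 - truth$theta_int * phis)
  expect_true(all(diff(folds) < 0))
  # theta_int = 0: background invariance
  t0 <- default_truth(theta_int = 0)
  expect_equal(fold_effect(t0, combo, c(J2 = "MUT")),
               fold_effect(t0, combo))
  expect_error(fold_effect(truth, c(J2 = "MUT"), c(J2 = "HET")),
               "disjoint")
})

test_that("the response surface has exponential transects, a flat transect
           at phi = 1/theta_int, and axis symmetry", {
  truth <- default_truth()
  grid <- seq(0, 4, by = 0.5)
  surf <- response_surface(truth, grid, grid)
  row0 <- surf[surf$phi_plt == 0, ]
  expect_equal(row0$branching, exp(truth$theta_wt + row0$phi_sep))
  flat <- response_surface(truth, grid, 1 / truth$theta_int)
  expect_equal(var(log(flat$branching)), 0, tolerance = 1e-20)
  # symmetry under exchanging the axes
  surf_t <- response_surface(truth, grid, grid)
  m1 <- matrix(surf$branching, length(grid), byrow = TRUE)
  m2 <- matrix(surf_t$branching, length(grid), byrow = TRUE)
  expect_equal(m1, t(m2))
})

test_that("multiplicative expectation multiplies wild-type fold effects", {
  truth <- default_truth()
  expect_equal(
    multiplicative_expectation(truth, character(0), character(0)),
    exp(truth$theta_wt))
  c1 <- c(PLT3 = "MUT"); c2 <- c(J2 = "MUT")
  expect_equal(
    multiplicative_expectation(truth, c1, c2),
    exp(truth$theta_wt) * fold_effect(truth, c1) * fold_effect(truth, c2))
  t0 <- default_truth(theta_int = 0)
  g <- genotype_from_assignments(c(c1, c2))
  expect_equal(multiplicative_expectation(t0, c1, c2),
               exp(predict_log_mean(t0, g)))
})

test_that("hierarchical fitting is deterministic, improves on its
           multiplicative start, and uses fewer parameters than pairwise", {
  sim <- simulate_branching_study(small_design(250), seed = 21)
  f1 <- fit_hierarchical(sim$records, iterations = 1500)
  f2 <- fit_hierarchical(sim$records, iterations = 1500)
  expect_identical(f1$params, f2$params)
  mult <- fit_count_glm(sim$records, basis = "additive", link = "log",
                        family = "negbin", compute_vcov = FALSE)
  expect_gte(f1$loglik, mult$loglik)
  pw <- fit_count_glm(sim$records, basis = "pairwise", link = "log",
                      family = "negbin", compute_vcov = FALSE)
  expect_lt(f1$n_params, pw$n_params)
  expect_equal(f1$aic, 2 * f1$n_params - 2 * f1$loglik)
})

test_that("with only one pair segregating theta_int is fixed at zero with a
           warning", {
  g <- wt_rows(60)
  g$plt3 <- rep(c("WT", "HET", "MUT"), 20)
  g$plt7 <- rep(c("WT", "MUT"), 30)
  rec <- manual_records(
    y = with_seed_local(22, rpois(60, 10 * exp(0.3 * (g$plt3 == "MUT")))),
    t = rep(10, 60), genotype = g)
  expect_warning(fit <- fit_hierarchical(rec, iterations = 500),
                 "unidentifiable")
  expect_equal(fit$params$theta_int, 0)
  expect_true(fit$theta_int_fixed)
})

test_that("theta_int profile intervals bracket the estimate and tighten the
           likelihood", {
  sim <- simulate_branching_study(small_design(300), seed = 23)
  fit <- fit_hierarchical(sim$records)
  ci <- confint_theta_int(fit, sim$records, level = 0.9)
  expect_lt(ci$lower, ci$estimate)
  expect_gt(ci$upper, ci$estimate)
  # refit at the bound loses ~ qchisq(0.9, 1)/2 log-likelihood units
  f_lo <- fit_hierarchical(sim$records, iterations = 0,
                           theta_int = ci$lower, init = fit$params)
  expect_equal(2 * (fit$loglik - f_lo$loglik), qchisq(0.9, 1),
               tolerance = 0.05)
})
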