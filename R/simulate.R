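#' F2 cross design
#'
#' Describes the segregating-population design: one F2 population per EJ2
#' promoter allele, each segregating PLT3, PLT7, J2 and that population's
#' EJ2 allele, grown in one or more seasons. Defaults mirror the study
#' layout: six populations, each a few hundred plants.
#'
#' @param ej2_alleles EJ2 promoter allele per population.
#' @param n_plants Plants per population (recycled across populations).
#' @param seasons Season identifiers; plants within a population are split
#'   evenly across seasons.
#' @param season_effects Optional log-scale season offsets (recycled),
#'   default 0.
#' @param loci Locus set tibble.
#'
#' @return A list of class `"cross_design"` with `populations` (tibble:
#'   `population_id`, `ej2_allele`, `n_plants`), `seasons` (tibble:
#'   `season_id`, `effect`) and `loci`.
#' @export
cross_design <- function(ej2_alleles = c("pro1", "pro3", "pro4", "pro6",
                                         "pro7", "pro8"),
                         n_plants = 384,
                         seasons = "S1",
                         season_effects = 0,
                         loci = default_loci()) {
  n_plants <- rep_len(n_plants, length(ej2_alleles))
  stopifnot(all(n_plants > 0))
  structure(list(
    populations = tibble::tibble(
      population_id = paste0("F2_", ej2_alleles),
      ej2_allele = ej2_alleles,
      n_plants = as.integer(n_plants)),
    seasons = tibble::tibble(season_id = seasons,
                             effect = rep_len(season_effects,
                                              length(seasons))),
    loci = loci
  ), class = "cross_design")
}

#' Default generative truth for the hierarchical simulator
#'
#' A [hier_params()] set emulating the magnitude of effects seen in the
#' tomato PLT-SEP branching network: a wild type that rarely branches
#' (`exp(theta_wt)` = 0.15 events per inflorescence), strong within-pair
#' synergy (log-scale effects built from reported single and double mutant
#' fold changes, e.g. an 11.24-fold homozygous plt3 effect and several-fold
#' super-multiplicative excesses for within-pair doubles), a masking
#' interaction `theta_int = 0.12` and plant-level overdispersion
#' `alpha = 0.3`.
#'
#' @param theta_wt,theta_int,alpha Override the global parameters.
#' @param ej2_alleles Alleles to build SEP classes for.
#' @return A [hier_params()] object covering every genotype class reachable
#'   in the corresponding [cross_design()].
#' @export
default_truth <- function(theta_wt = log(0.15), theta_int = 0.12,
                          alpha = 0.3,
                          ej2_alleles = c("pro1", "pro3", "pro4", "pro6",
                                          "pro7", "pro8")) {
  e3 <- c(HET = 0.10, MUT = 2.42)   # log(11.24) for homozygous plt3
  e7 <- c(HET = 0.15, MUT = 0.35)
  syn_plt <- matrix(c(0.45, 1.19,   # rows plt3 HET/MUT, cols plt7 HET/MUT
                      1.83, 2.30),  # MUT/HET built to give ~81-fold double
                    2, 2, byrow = TRUE,
                    dimnames = list(c("HET", "MUT"), c("HET", "MUT")))
  phi_plt <- c()
  for (s3 in c("WT", "HET", "MUT")) {
    for (s7 in c("WT", "HET", "MUT")) {
      if (s3 == "WT" && s7 == "WT") next
      lab <- within_pair_class(
        tibble::tibble(plt3 = s3, plt7 = s7), "PLT")
      val <- (if (s3 != "WT") e3[s3] else 0) +
        (if (s7 != "WT") e7[s7] else 0) +
        (if (s3 != "WT" && s7 != "WT") syn_plt[s3, s7] else 0)
      phi_plt[lab] <- val
    }
  }
  ej <- c(HET = 0.05, MUT = 0.40)   # j2 alone is nearly cryptic
  allele_mut <- c(pro1 = 0.25, pro3 = 0.15, pro4 = 0.20, pro6 = 0.22,
                  pro7 = 0.35, pro8 = 0.30)
  # log fold excesses of the homozygous allele x j2 doubles (Table-1 scale)
  allele_syn <- c(pro1 = log(7.05), pro3 = log(6.81), pro4 = log(9.32),
                  pro6 = log(6.49), pro7 = log(16.97), pro8 = log(5.95))
  syn_frac <- matrix(c(0.10, 0.50, 0.35, 1.00), 2, 2, byrow = TRUE,
                     dimnames = list(c("HET", "MUT"), c("HET", "MUT")))
  phi_sep <- c()
  for (js in c("HET", "MUT")) {
    lab <- within_pair_class(
      tibble::tibble(j2 = js, ej2_allele = "none", ej2_state = "WT"), "SEP")
    phi_sep[lab] <- ej[js]
  }
  for (a in ej2_alleles) {
    for (es in c("HET", "MUT")) {
      for (js in c("WT", "HET", "MUT")) {
        g <- tibble::tibble(j2 = js, ej2_allele = a, ej2_state = es)
        lab <- within_pair_class(g, "SEP")
        val <- (if (es == "MUT") allele_mut[a] else 0.05) +
          (if (js != "WT") ej[js] else 0) +
          (if (js != "WT") syn_frac[es, js] * allele_syn[a] else 0)
        phi_sep[lab] <- val
      }
    }
  }
  hier_params(theta_wt = theta_wt, theta_int = theta_int,
              phi_plt = phi_plt, phi_sep = phi_sep, alpha = alpha)
}

#' Simulation configuration
#'
#' @param truth Generative [hier_params()].
#' @param inflorescences_per_plant Constant count or a `function(n)`
#'   returning one exposure per plant (default constant 10, the study's
#'   four primary plus six axillary inflorescences).
#' @param censor_value Counts above this are recorded as `"TMTC"`. The field
#'   protocol caps counting at 60 (`censor_value = 60`); the default `Inf`
#'   applies no censoring so that closed-loop parameter recovery is exact
#'   (the likelihoods carry no censored-data correction). Set 60 when
#'   emulating raw-data artifacts or in robustness tests.
#' @param p_proliferated,p_inhibited Per-inflorescence probabilities of the
#'   excluded outcomes (defaults 0; set positive for robustness tests).
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(truth = default_truth(),
                              inflorescences_per_plant = 10,
                              censor_value = Inf,
                              p_proliferated = 0, p_inhibited = 0) {
  stopifnot(p_proliferated >= 0, p_inhibited >= 0,
            p_proliferated + p_inhibited < 1, censor_value > 0)
  structure(list(truth = truth,
                 inflorescences_per_plant = inflorescences_per_plant,
                 censor_value = censor_value,
                 p_proliferated = p_proliferated,
                 p_inhibited = p_inhibited),
            class = "simulation_config")
}

#' Simulate Mendelian F2 genotypes
#'
#' Each population's four segregating loci (PLT3, PLT7, J2 and its EJ2
#' promoter allele) are drawn independently with the Mendelian 1:2:1
#' WT : heterozygous : homozygous-mutant ratio; the other EJ2 alleles are
#' fixed wild type (a plant carries `ej2_allele = "none"` when homozygous
#' wild type at its population's allele).
#'
#' @param design A [cross_design()].
#' @param seed Integer seed (optional; the caller's RNG stream is restored).
#' @return A genotype tibble: `plant_id`, `population_id`, `season_id`,
#'   `plt3`, `plt7`, `j2`, `ej2_allele`, `ej2_state`.
#' @export
simulate_f2_genotypes <- function(design = cross_design(), seed = NULL) {
  draw <- function() {
    pops <- design$populations
    seasons <- design$seasons$season_id
    out <- purrr::pmap(pops, function(population_id, ej2_allele, n_plants) {
      mendel <- function(n) sample(.states, n, replace = TRUE,
                                   prob = c(0.25, 0.5, 0.25))
      es <- mendel(n_plants)
      tibble::tibble(
        plant_id = sprintf("%s_%04d", population_id, seq_len(n_plants)),
        population_id = population_id,
        season_id = rep_len(seasons, n_plants),
        plt3 = mendel(n_plants),
        plt7 = mendel(n_plants),
        j2 = mendel(n_plants),
        ej2_allele = ifelse(es == "WT", "none", ej2_allele),
        ej2_state = es)
    })
    dplyr::bind_rows(out)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Simulate per-inflorescence branching observations
#'
#' Draws branching counts from the hierarchical model: each plant receives a
#' shared gamma multiplier with mean 1 and variance `alpha` (plant-to-plant
#' variability), and each countable inflorescence an independent Poisson
#' count at rate `exp(mu) * multiplier` (plus any season offset), so plant
#' totals are exactly NB2 with mean `t * exp(mu)` and variance
#' `m + alpha * m^2`. Inflorescences are marked proliferated/inhibited with
#' the configured probabilities, and counts above `censor_value` are
#' recorded as `"TMTC"`.
#'
#' @param genotypes Genotype tibble (see [simulate_f2_genotypes()]).
#' @param config A [simulation_config()].
#' @param season_effects Named log-scale offsets by `season_id` (default
#'   none).
#' @param seed Optional seed.
#' @return A long observation tibble: the genotype columns plus
#'   `inflorescence_index` and `outcome` (readable by [summarize_plants()]).
#' @export
simulate_phenotypes <- function(genotypes, config = simulation_config(),
                                season_effects = NULL, seed = NULL) {
  draw <- function() {
    n <- nrow(genotypes)
    tt <- config$inflorescences_per_plant
    t_i <- if (is.function(tt)) tt(n) else rep_len(as.integer(tt), n)
    stopifnot(all(t_i >= 1))
    mu <- predict_log_mean(config$truth, genotypes)
    if (!is.null(season_effects) && "season_id" %in% names(genotypes)) {
      off <- season_effects[as.character(genotypes$season_id)]
      off[is.na(off)] <- 0
      mu <- mu + off
    }
    alpha <- config$truth$alpha
    g_mult <- if (alpha > 0) rgamma(n, shape = 1 / alpha, rate = 1 / alpha)
              else rep(1, n)
    idx <- rep(seq_len(n), t_i)
    rate <- exp(pmin(mu, 40))[idx] * g_mult[idx]
    counts <- rpois(length(idx), rate)
    u <- runif(length(idx))
    outcome <- as.character(counts)
    outcome[counts > config$censor_value] <- "TMTC"
    outcome[u < config$p_proliferated] <- "proliferated"
    outcome[u >= config$p_proliferated &
              u < config$p_proliferated + config$p_inhibited] <- "inhibited"
    out <- genotypes[idx, ]
    out$inflorescence_index <- unlist(lapply(t_i, seq_len), use.names = FALSE)
    out$outcome <- outcome
    out
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Simulate a full branching study
#'
#' Genotypes, per-inflorescence observations and summarized plant records in
#' one call, reproducible from a single seed.
#'
#' @param design A [cross_design()].
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return A list with `genotypes`, `observations` and `records` (the output
#'   of [summarize_plants()] on the observations).
#' @export
simulate_branching_study <- function(design = cross_design(),
                                     config = simulation_config(),
                                     seed = 1) {
  with_seed(seed, {
    genotypes <- simulate_f2_genotypes(design)
    eff <- setNames(design$seasons$effect, design$seasons$season_id)
    observations <- simulate_phenotypes(genotypes, config,
                                        season_effects = eff)
    records <- suppressWarnings(
      summarize_plants(observations, censor_value = config$censor_value))
    list(genotypes = genotypes, observations = observations,
         records = records)
  })
}

#' Closed-loop parameter-recovery experiment
#'
#' For each replicate: simulate a study from the configured truth, summarize
#' to plant records, fit the multiplicative (additive log-link NB GLM),
#' optionally pairwise, and hierarchical models, and record log-likelihoods,
#' AICs, deviance explained, and the recovered `theta_wt`, `theta_int` (with
#' profile confidence interval) and `alpha`. Fit failures are recorded per
#' replicate, never fatal.
#'
#' @param design A [cross_design()].
#' @param config A [simulation_config()].
#' @param n_replicates Number of simulated studies.
#' @param seed Master seed; replicate seeds are derived deterministically.
#' @param fit_pairwise Include the pairwise-interaction GLM?
#' @param theta_int_ci Compute profile intervals for `theta_int`?
#'
#' @return A list of class `"hierepi_recovery"`: `replicates` (one tibble
#'   row per replicate) and `summary` (means, relative biases, coverage and
#'   AIC-ranking counts).
#' @export
recovery_experiment <- function(design = cross_design(),
                                config = simulation_config(),
                                n_replicates = 20, seed = 1,
                                fit_pairwise = TRUE,
                                theta_int_ci = TRUE) {
  stopifnot(n_replicates >= 1)
  truth <- config$truth
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    rep_seed <- (abs(seed) %% 100000L) * 20000L + r
    row <- tibble::tibble(
      replicate = r, seed = rep_seed, n_plants = NA_integer_,
      loglik_mult = NA_real_, aic_mult = NA_real_, dev_expl_mult = NA_real_,
      loglik_pw = NA_real_, aic_pw = NA_real_, dev_expl_pw = NA_real_,
      loglik_hier = NA_real_, aic_hier = NA_real_, dev_expl_hier = NA_real_,
      theta_wt_hat = NA_real_, theta_int_hat = NA_real_,
      theta_int_lo = NA_real_, theta_int_hi = NA_real_,
      alpha_hat = NA_real_, covered = NA, error = NA_character_)
    res <- tryCatch({
      sim <- simulate_branching_study(design, config, seed = rep_seed)
      recs <- sim$records
      row$n_plants <- nrow(recs)
      null_fit <- fit_count_glm(recs, basis = "intercept", link = "log",
                                family = "negbin", compute_vcov = FALSE)
      mult <- fit_count_glm(recs, basis = "additive", link = "log",
                            family = "negbin", loci = design$loci,
                            compute_vcov = FALSE)
      row$loglik_mult <- mult$loglik
      row$aic_mult <- mult$aic
      row$dev_expl_mult <- deviance_explained(mult, null_fit)
      if (fit_pairwise) {
        pw <- fit_count_glm(recs, basis = "pairwise", link = "log",
                            family = "negbin", loci = design$loci,
                            compute_vcov = FALSE)
        row$loglik_pw <- pw$loglik
        row$aic_pw <- pw$aic
        row$dev_expl_pw <- deviance_explained(pw, null_fit)
      }
      hier <- fit_hierarchical(recs, loci = design$loci)
      row$loglik_hier <- hier$loglik
      row$aic_hier <- hier$aic
      row$dev_expl_hier <- deviance_explained(hier, null_fit)
      row$theta_wt_hat <- hier$params$theta_wt
      row$theta_int_hat <- hier$params$theta_int
      row$alpha_hat <- hier$params$alpha
      if (theta_int_ci && !hier$theta_int_fixed) {
        ci <- confint_theta_int(hier, recs)
        row$theta_int_lo <- ci$lower
        row$theta_int_hi <- ci$upper
        row$covered <- ci$lower <= truth$theta_int &&
          truth$theta_int <= ci$upper
      }
      row
    }, error = function(e) {
      row$error <- conditionMessage(e)
      row
    })
    rows[[r]] <- res
  }
  reps <- dplyr::bind_rows(rows)
  ok <- is.na(reps$error)
  rel_bias <- function(est, true) (mean(est[ok], na.rm = TRUE) - true) / true
  summary <- list(
    n_replicates = n_replicates,
    n_failed = sum(!ok),
    truth = list(theta_wt = truth$theta_wt, theta_int = truth$theta_int,
                 alpha = truth$alpha),
    bias_theta_wt = rel_bias(reps$theta_wt_hat, truth$theta_wt),
    bias_theta_int = rel_bias(reps$theta_int_hat, truth$theta_int),
    bias_alpha = rel_bias(reps$alpha_hat, truth$alpha),
    coverage_theta_int = mean(reps$covered[ok], na.rm = TRUE),
    n_covered = sum(reps$covered[ok], na.rm = TRUE),
    aic_rank_hier_pw_mult = sum(
      ok & !is.na(reps$aic_pw) &
        reps$aic_hier < reps$aic_pw & reps$aic_pw < reps$aic_mult))
  structure(list(replicates = reps, summary = summary),
            class = "hierepi_recovery")
}

#' @export
print.hierepi_recovery <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<recovery experiment: %d replicates (%d failed)>\n",
              s$n_replicates, s$n_failed))
  cat(sprintf("  relative bias: theta_wt %.3f, theta_int %.3f, alpha %.3f\n",
              s$bias_theta_wt, s$bias_theta_int, s$bias_alpha))
  if (!is.nan(s$coverage_theta_int)) {
    cat(sprintf("  theta_int CI coverage: %.2f\n", s$coverage_theta_int))
  }
  invisible(x)
}
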