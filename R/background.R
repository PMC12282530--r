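#' Genotype-season maximum-likelihood branching estimates
#'
#' Estimates the mean number of branching events per inflorescence for every
#' genotype(-season) combination by joint negative-binomial maximum
#' likelihood in which each combination has its own mean (a dummy per
#' combination) and all combinations share a single overdispersion parameter
#' `alpha` representing plant-to-plant variability. The shared `alpha` is
#' profiled over a log grid with the per-combination log means solved by
#' Newton iterations at each candidate. Wald 95% confidence intervals are
#' computed on the log scale from the observed information and
#' back-transformed; combinations whose interval spans more than a
#' thousand-fold range are flagged `wide_ci` (a display filter, never applied
#' to fitting). All-zero combinations sit on the `mean = 0` boundary and are
#' flagged `degenerate`.
#'
#' @param records Plant-record tibble.
#' @param by_season Group by season as well as genotype (default `TRUE` when
#'   a `season_id` column is present).
#' @param level Confidence level.
#'
#' @return A tibble with genotype (and season) columns, `mean`, `ci_lo`,
#'   `ci_hi`, `n_plants`, `n_inflorescences`, `wide_ci`, `degenerate`; the
#'   shared overdispersion estimate is in the `alpha` attribute.
#' @export
genotype_season_mle <- function(records, by_season = TRUE, level = 0.95) {
  gcols <- intersect(c("plt3", "plt7", "j2", "ej2_allele", "ej2_state"),
                     names(records))
  keys <- c(gcols, if (by_season && "season_id" %in% names(records))
                     "season_id")
  if (length(keys) == 0) abort("records has no genotype columns")
  key <- do.call(paste, c(records[keys], sep = "\r"))
  groups <- unique(key)
  gi <- match(key, groups)
  y <- as.numeric(records$y)
  t <- as.numeric(records$t)

  sum_y <- as.numeric(rowsum(y, gi)[as.character(seq_along(groups)), 1])
  sum_t <- as.numeric(rowsum(t, gi)[as.character(seq_along(groups)), 1])
  zero <- sum_y == 0

  # profile log-likelihood in alpha; inner Newton solves each group's
  # log mean eta_g (zero groups are held at the boundary)
  eta_at <- function(alpha) {
    eta <- log(pmax(sum_y, 0.5) / sum_t)
    for (i in 1:40) {
      m <- t * exp(eta[gi])
      score <- rowsum((y - m) / (1 + alpha * m), gi)[, 1]
      info <- rowsum(m * (1 + alpha * y) / (1 + alpha * m)^2, gi)[, 1]
      stepv <- ifelse(zero, 0, score / pmax(info, 1e-12))
      stepv <- pmax(pmin(stepv, 2), -2)
      eta <- eta + stepv
      if (max(abs(stepv)) < 1e-12) break
    }
    eta[zero] <- -30
    eta
  }
  prof <- function(lalpha) {
    alpha <- exp(lalpha)
    eta <- eta_at(alpha)
    negbin_loglik(y, t, exp(eta[gi]), alpha)
  }
  opt <- optimize(prof, interval = c(-10, 3), maximum = TRUE, tol = 1e-8)
  alpha <- exp(opt$maximum)
  eta <- eta_at(alpha)
  m <- t * exp(eta[gi])
  info <- rowsum(m * (1 + alpha * y) / (1 + alpha * m)^2, gi)[, 1]
  se <- 1 / sqrt(pmax(info, 1e-12))
  zq <- qnorm(1 - (1 - level) / 2)

  out <- records[match(groups, key), keys]
  out$mean <- ifelse(zero, 0, exp(eta))
  out$ci_lo <- ifelse(zero, 0, exp(eta - zq * se))
  out$ci_hi <- ifelse(zero, NA_real_, exp(eta + zq * se))
  out$n_plants <- as.integer(table(gi)[as.character(seq_along(groups))])
  out$n_inflorescences <- as.integer(sum_t)
  out$wide_ci <- !zero & (out$ci_hi / out$ci_lo > 1000)
  out$degenerate <- zero
  out <- tibble::as_tibble(out)
  attr(out, "alpha") <- alpha
  out
}

#' Total least squares (orthogonal regression)
#'
#' Fits a line by minimizing orthogonal distances: the first principal axis
#' of the centred point cloud. Unlike ordinary least squares this treats the
#' two variables symmetrically, so swapping `x` and `y` maps the slope to its
#' reciprocal.
#'
#' @param x,y Numeric vectors (at least 2 distinct points).
#' @return A list with `slope` and `intercept`.
#' @examples
#' total_least_squares(1:5, (1:5) + 3)
#' @export
total_least_squares <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2) abort("need at least 2 points")
  cx <- x - mean(x); cy <- y - mean(y)
  S <- cov(cbind(cx, cy))
  if (!all(is.finite(S)) || sum(diag(S)) <= 0) {
    abort("degenerate point cloud: zero total variance")
  }
  ev <- eigen(S, symmetric = TRUE)
  v <- ev$vectors[, 1]
  if (abs(v[1]) < 1e-14) abort("principal axis is vertical; slope undefined")
  slope <- v[2] / v[1]
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}

#' Background-rescaling slopes
#'
#' For each genetic background in one paralogue pair, relates the
#' log-transformed phenotype estimates of the other (focal) pair's mutant
#' combinations in that background to the same combinations in the
#' wild-type background, and fits a total-least-squares line per background.
#' Under multiplicative (log-additive) gene action across pairs the slope is
#' exactly one for every background; under the hierarchical model with
#' masking parameter `theta_int` the slope in a background of within-pair
#' effect `phi` equals `1 - theta_int * phi`, so slopes decrease as mutations
#' accumulate in the background pair.
#'
#' @param mle_table Output of [genotype_season_mle()] (or any tibble with
#'   genotype columns and a `mean` column).
#' @param focal_pair `"SEP"` (EJ2/J2 combinations across PLT backgrounds) or
#'   `"PLT"`.
#' @param season `"pooled"` (log means averaged across seasons per genotype)
#'   or `"within"` (points paired within matching seasons).
#' @param min_points Minimum shared focal combinations per background.
#' @param log1p_scale Use `log(1 + mean)` instead of `log(mean)`.
#'
#' @return A tibble of class `"hierepi_rescaling"`: `background`, `n_points`,
#'   `slope`, `intercept` and a list-column `points` of the paired values;
#'   skipped backgrounds are listed in the `skipped` attribute.
#' @export
background_rescaling <- function(mle_table, focal_pair = c("SEP", "PLT"),
                                 season = c("pooled", "within"),
                                 min_points = 2, log1p_scale = FALSE) {
  focal_pair <- match.arg(focal_pair)
  season <- match.arg(season)
  other <- if (focal_pair == "SEP") "PLT" else "SEP"
  tab <- tibble::as_tibble(mle_table)
  tab$focal <- within_pair_class(tab, focal_pair)
  tab$background <- within_pair_class(tab, other)
  tab$logm <- if (log1p_scale) log1p(tab$mean) else log(tab$mean)
  tab <- tab[is.finite(tab$logm), ]

  has_season <- season == "within" && "season_id" %in% names(tab)
  by <- c("focal", "background", if (has_season) "season_id")
  tab <- tab |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(logm = mean(.data$logm), .groups = "drop")

  wt <- tab[tab$background == "WT" & tab$focal != "WT", ]
  names(wt)[names(wt) == "logm"] <- "logm_wt"
  wt$background <- NULL
  rows <- list()
  skipped <- character(0)
  for (bg in setdiff(unique(tab$background), "WT")) {
    sub <- tab[tab$background == bg & tab$focal != "WT", ]
    pts <- dplyr::inner_join(
      wt, sub[, c("focal", if (has_season) "season_id", "logm")],
      by = c("focal", if (has_season) "season_id"))
    if (nrow(pts) < min_points ||
        (var(pts$logm_wt) == 0 && var(pts$logm) == 0)) {
      skipped <- c(skipped, bg)
      next
    }
    fit <- tryCatch(total_least_squares(pts$logm_wt, pts$logm),
                    error = function(e) NULL)
    if (is.null(fit)) { skipped <- c(skipped, bg); next }
    rows[[length(rows) + 1]] <- tibble::tibble(
      background = bg, n_points = nrow(pts), slope = fit$slope,
      intercept = fit$intercept, points = list(pts))
  }
  if (length(skipped) > 0) {
    inform(sprintf("%d background(s) skipped (too few shared combinations)",
                   length(skipped)))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "skipped") <- skipped
  attr(out, "focal_pair") <- focal_pair
  attr(out, "scale") <- if (log1p_scale) "log1p(mean)" else "log(mean)"
  class(out) <- c("hierepi_rescaling", class(out))
  out
}
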