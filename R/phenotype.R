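#' Summarize per-inflorescence observations into plant-level records
#'
#' Converts a long table of per-inflorescence outcomes into the plant-level
#' records consumed by the count likelihoods. The outcome vocabulary is an
#' integer number of branching events, `"TMTC"` ("too many to count", treated
#' as `censor_value` branching events), `"proliferated"`, or `"inhibited"`
#' (case-insensitive). Proliferated and inhibited inflorescences are excluded
#' and contribute neither to the exposure `t` nor to the total `y`; plants
#' left with no countable inflorescence are omitted with a warning.
#'
#' @param observations Data frame with columns `plant_id`, `outcome` and
#'   optionally `inflorescence_index`; any other columns (genotype, population,
#'   season) are treated as per-plant metadata and carried through.
#' @param censor_value Count recorded for `"TMTC"` inflorescences (default 60,
#'   the field cap above which branches were not counted).
#'
#' @return A tibble with one row per retained plant: metadata columns plus
#'   `t` (number of countable inflorescences) and `y` (total branching
#'   events).
#' @examples
#' obs <- tibble::tibble(plant_id = "p1", inflorescence_index = 1:4,
#'                       outcome = c("3", "0", "TMTC", "proliferated"))
#' summarize_plants(obs)
#' @export
summarize_plants <- function(observations, censor_value = 60) {
  stopifnot(censor_value > 0)
  if (nrow(observations) == 0) {
    return(tibble::tibble(plant_id = character(), t = integer(),
                          y = integer()))
  }
  parsed <- parse_outcomes(observations$outcome, censor_value)
  meta_cols <- setdiff(names(observations),
                       c("inflorescence_index", "outcome"))
  obs <- dplyr::bind_cols(observations[meta_cols],
                          tibble::tibble(.count = parsed$count,
                                         .countable = parsed$countable))
  per_plant <- obs |>
    dplyr::group_by(dplyr::across(dplyr::all_of(meta_cols))) |>
    dplyr::summarise(
      t = sum(.data$.countable),
      y = sum(.data$.count[.data$.countable]),
      .groups = "drop")
  empty <- per_plant$t == 0
  if (any(empty)) {
    warn(sprintf(
      "%d plant(s) had no countable inflorescence and were omitted: %s",
      sum(empty),
      paste(head(per_plant$plant_id[empty], 10), collapse = ", ")))
    per_plant <- per_plant[!empty, ]
  }
  per_plant$t <- as.integer(per_plant$t)
  per_plant$y <- as.integer(per_plant$y)
  per_plant
}

# outcome vocabulary -> (count, countable); errors on malformed input
parse_outcomes <- function(outcome, censor_value) {
  raw <- trimws(tolower(as.character(outcome)))
  is_num <- grepl("^-?[0-9]+$", raw)
  count <- rep(NA_integer_, length(raw))
  count[is_num] <- as.integer(raw[is_num])
  if (any(is_num & count < 0)) {
    abort(sprintf("Negative branching count at observation(s): %s",
                  paste(head(which(is_num & count < 0), 5), collapse = ", ")),
          class = "hierepi_malformed_input")
  }
  tag <- raw[!is_num]
  known <- c("tmtc", "proliferated", "inhibited")
  if (!all(tag %in% known)) {
    abort(sprintf("Unknown outcome tag(s): %s",
                  paste(unique(setdiff(tag, known)), collapse = ", ")),
          class = "hierepi_malformed_input")
  }
  count[raw == "tmtc"] <- as.integer(min(censor_value,
                                         .Machine$integer.max))
  countable <- is_num | raw == "tmtc"
  list(count = ifelse(is.na(count), 0L, count), countable = countable)
}

#' Read a phenotype table from delimited text
#'
#' Reads either a wide per-plant table (columns `t` and `y` present) or a long
#' per-inflorescence table (an `outcome` column present; summarized via
#' [summarize_plants()]). Genotype state columns (`plt3`, `plt7`, `j2`,
#' `ej2_state`) are parsed through [parse_locus_state()], so tokens such as
#' `"m/+"` or `"hom"` are accepted. Rows failing validation (non-positive `t`,
#' negative `y`, unparseable genotype, an EJ2 state without an allele) are
#' rejected with a warning naming their row numbers.
#'
#' @param path Path to a delimited text file with a header.
#' @param delim Field delimiter (default comma).
#' @param col_map Optional named character vector renaming file columns to the
#'   standard names, e.g. `c(plant_id = "Plant", y = "branches")`.
#' @param censor_value Passed to [summarize_plants()] for long tables.
#'
#' @return A tibble of plant records with columns `plant_id`, genotype
#'   columns, `population_id`, `season_id`, `t`, `y`.
#' @export
read_phenotype_table <- function(path, delim = ",", col_map = NULL,
                                 censor_value = 60) {
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      if (!col_map[[std]] %in% names(raw)) {
        abort(sprintf("Mapped column '%s' not found in %s", col_map[[std]],
                      path))
      }
      names(raw)[names(raw) == col_map[[std]]] <- std
    }
  }
  long <- "outcome" %in% names(raw)
  required <- c("plant_id", "plt3", "plt7", "j2", "ej2_allele", "ej2_state",
                if (long) "outcome" else c("t", "y"))
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("Missing required column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  raw$.row <- seq_len(nrow(raw))
  ok <- rep(TRUE, nrow(raw))
  for (col in c("plt3", "plt7", "j2", "ej2_state")) {
    st <- tryCatch(parse_locus_state(raw[[col]]), error = function(e) NULL)
    if (is.null(st)) { # per-row fallback so valid rows survive
      st <- rep(NA_character_, nrow(raw))
      for (i in seq_len(nrow(raw))) {
        st[i] <- tryCatch(parse_locus_state(raw[[col]][i]),
                          error = function(e) NA_character_)
      }
      ok <- ok & !is.na(st)
    }
    raw[[col]] <- st
  }
  raw$ej2_allele <- tolower(trimws(as.character(raw$ej2_allele)))
  raw$ej2_allele[raw$ej2_allele %in% c("", "na", "none") |
                   is.na(raw$ej2_allele)] <- "none"
  # invariant: allele "none" <=> EJ2 homozygous wild type
  raw$ej2_allele[!is.na(raw$ej2_state) & raw$ej2_state == "WT"] <- "none"
  ok <- ok & !(raw$ej2_allele == "none" & !is.na(raw$ej2_state) &
                 raw$ej2_state != "WT")
  if (!long) {
    ok <- ok & !is.na(raw$t) & raw$t >= 1 & !is.na(raw$y) & raw$y >= 0
  }
  if (any(!ok)) {
    warn(sprintf("Rejected %d malformed row(s): %s", sum(!ok),
                 paste(head(raw$.row[!ok], 10), collapse = ", ")))
  }
  raw <- raw[ok, setdiff(names(raw), ".row")]
  if (long) {
    summarize_plants(raw, censor_value = censor_value)
  } else {
    raw$t <- as.integer(raw$t)
    raw$y <- as.integer(raw$y)
    tibble::as_tibble(raw)
  }
}

#' Write plant records to delimited text
#'
#' @param records Plant-record tibble.
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `records`, invisibly.
#' @export
write_phenotype_table <- function(records, path, delim = ",") {
  readr::write_delim(records, path, delim = delim)
  invisible(records)
}

#' Overdispersion summary by genotype group
#'
#' For each genotype (or genotype-season) group, computes the mean branching
#' rate per inflorescence, the variance of per-plant rates, and a
#' variance/mean dispersion index scaled by the mean exposure:
#' `index = mean(t) * var(y/t) / mean(y/t)`. With constant exposure this is
#' the variance/mean ratio of plant totals, so Poisson-distributed branching
#' gives an index near 1 and values substantially above 1 indicate
#' overdispersion. Groups with fewer than 2 plants are skipped and listed in
#' the `skipped` attribute.
#'
#' @param records Plant-record tibble (`t`, `y`, genotype columns).
#' @param grouping `"genotype"` or `"genotype_season"`.
#'
#' @return A tibble with one row per group: group columns, `n_plants`,
#'   `mean_rate`, `var_rate`, `index`.
#' @export
dispersion_summary <- function(records,
                               grouping = c("genotype", "genotype_season")) {
  grouping <- match.arg(grouping)
  if (nrow(records) == 0) abort("records is empty")
  keys <- c("plt3", "plt7", "j2", "ej2_allele", "ej2_state",
            if (grouping == "genotype_season") "season_id")
  keys <- intersect(keys, names(records))
  out <- records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_plants = dplyr::n(),
      mean_rate = mean(.data$y / .data$t),
      var_rate = var(.data$y / .data$t),
      mean_t = mean(.data$t),
      .groups = "drop") |>
    dplyr::mutate(
      index = ifelse(.data$mean_rate > 0,
                     .data$mean_t * .data$var_rate / .data$mean_rate, 0))
  skipped <- out[out$n_plants < 2, keys]
  if (nrow(skipped) > 0) {
    inform(sprintf("%d group(s) with < 2 plants skipped", nrow(skipped)))
  }
  out <- out[out$n_plants >= 2, setdiff(names(out), "mean_t")]
  attr(out, "skipped") <- skipped
  out
}
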