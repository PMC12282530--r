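#' Additive/dominance design matrix
#'
#' Builds the genotype design matrix for the additive model: an intercept plus
#' one additive and one dominance column per locus, using the coding of
#' [additive_dominance_code()]. Plants not carrying a given EJ2 promoter
#' allele are coded homozygous wild type (-1, 0) at that locus. Columns that
#' are constant across plants (for example an allele absent from the dataset)
#' are dropped and recorded with a reason, as are exact duplicates of an
#' earlier retained column.
#'
#' @param records A data frame with genotype columns `plt3`, `plt7`, `j2`,
#'   `ej2_allele`, `ej2_state` (one row per plant).
#' @param loci Locus set tibble, see [default_loci()].
#' @param drop Drop constant/duplicate columns? Set `FALSE` to obtain the full
#'   basis, e.g. for constructing prediction rows.
#'
#' @return A numeric matrix of class `"hierepi_design"` with attributes
#'   `column_meta` (tibble: `term`, `type`, `locus1`, `locus2`, `kind`) and
#'   `dropped` (tibble: `term`, `reason`).
#' @examples
#' recs <- simulate_f2_genotypes(cross_design(n_plants = 20), seed = 1)
#' X <- design_matrix_additive(recs)
#' attr(X, "column_meta")
#' @export
design_matrix_additive <- function(records, loci = default_loci(),
                                   drop = TRUE) {
  build_design(records, loci, pairwise = FALSE, drop = drop)
}

#' Pairwise-interaction design matrix
#'
#' Extends the additive/dominance basis with, for every unordered pair of loci
#' not flagged as mutually exclusive, the four products of their additive and
#' dominance columns (`aa`, `ad`, `da`, `dd`). The first slot of a product tag
#' refers to the lexicographically earlier locus label. Pairs of EJ2 promoter
#' alleles generate no product columns because the alleles never co-occur in
#' one plant. Constant and duplicate columns are dropped with recorded
#' reasons so the retained term count can be reconciled with a given cross
#' design.
#'
#' @inheritParams design_matrix_additive
#' @return See [design_matrix_additive()].
#' @export
design_matrix_pairwise <- function(records, loci = default_loci(),
                                   drop = TRUE) {
  build_design(records, loci, pairwise = TRUE, drop = drop)
}

build_design <- function(records, loci, pairwise, drop) {
  if (nrow(records) == 0) abort("records must contain at least one plant")
  states <- locus_state_matrix(records, loci)
  n <- nrow(states)
  a_code <- c(WT = -1, HET = 0, MUT = 1)
  d_code <- c(WT = 0, HET = 1, MUT = 0)
  L <- nrow(loci)
  sa <- matrix(a_code[states], nrow = n, dimnames = list(NULL, loci$locus))
  sd_ <- matrix(d_code[states], nrow = n, dimnames = list(NULL, loci$locus))

  cols <- list(`(Intercept)` = rep(1, n))
  meta <- list(tibble::tibble(term = "(Intercept)", type = "intercept",
                              locus1 = NA_character_, locus2 = NA_character_,
                              kind = NA_character_))
  for (l in loci$locus) {
    cols[[paste0(l, "_a")]] <- sa[, l]
    cols[[paste0(l, "_d")]] <- sd_[, l]
    meta[[length(meta) + 1]] <- tibble::tibble(
      term = paste0(l, c("_a", "_d")), type = c("additive", "dominance"),
      locus1 = l, locus2 = NA_character_, kind = NA_character_)
  }
  if (pairwise && L >= 2) {
    for (i in seq_len(L - 1)) {
      for (j in seq(i + 1, L)) {
        gi <- loci$exclusive_group[i]
        gj <- loci$exclusive_group[j]
        if (!is.na(gi) && !is.na(gj) && gi == gj) next
        # first slot of the tag = lexicographically earlier label
        pair <- sort(c(loci$locus[i], loci$locus[j]))
        l1 <- pair[1]; l2 <- pair[2]
        base <- paste0(l1, ":", l2)
        prods <- list(
          aa = sa[, l1] * sa[, l2], ad = sa[, l1] * sd_[, l2],
          da = sd_[, l1] * sa[, l2], dd = sd_[, l1] * sd_[, l2])
        for (k in names(prods)) cols[[paste0(base, "_", k)]] <- prods[[k]]
        meta[[length(meta) + 1]] <- tibble::tibble(
          term = paste0(base, "_", names(prods)), type = "product",
          locus1 = l1, locus2 = l2, kind = names(prods))
      }
    }
  }
  X <- do.call(cbind, cols)
  meta <- dplyr::bind_rows(meta)

  dropped <- tibble::tibble(term = character(), reason = character())
  if (drop) {
    keep <- rep(TRUE, ncol(X))
    reasons <- character(ncol(X))
    seen <- list(`(Intercept)` = X[, 1])
    for (k in seq_len(ncol(X))[-1]) {
      v <- X[, k]
      if (length(unique(v)) == 1) {
        keep[k] <- FALSE
        reasons[k] <- "constant"
        next
      }
      dup <- NULL
      for (nm in names(seen)) {
        if (identical(unname(seen[[nm]]), unname(v))) { dup <- nm; break }
      }
      if (!is.null(dup)) {
        keep[k] <- FALSE
        reasons[k] <- paste0("duplicate of ", dup)
      } else {
        seen[[colnames(X)[k]]] <- v
      }
    }
    dropped <- tibble::tibble(term = colnames(X)[!keep],
                              reason = reasons[!keep])
    X <- X[, keep, drop = FALSE]
    meta <- meta[keep, ]
  }
  structure(X, column_meta = meta, dropped = dropped,
            class = c("hierepi_design", class(X)))
}

#' @export
print.hierepi_design <- function(x, ...) {
  meta <- attr(x, "column_meta")
  cat(sprintf("<design matrix: %d plants x %d columns (%d dropped)>\n",
              nrow(x), ncol(x), nrow(attr(x, "dropped"))))
  cat("types:", paste(sprintf("%s=%d", names(table(meta$type)),
                              table(meta$type)), collapse = ", "), "\n")
  invisible(x)
}

#' Within-pair genotype class labels
#'
#' Assigns each plant its genotype class within one paralogue pair: for the
#' `"PLT"` pair the combination of `plt3` and `plt7` states (9 classes); for
#' the `"SEP"` pair the combination of the carried EJ2 promoter allele, its
#' state, and the `j2` state. The all-wild-type class is labelled `"WT"` and
#' corresponds to a within-pair phenotypic effect of zero in the hierarchical
#' model. Labels list only the non-wild-type components, e.g.
#' `"PLT3:HET|PLT7:MUT"` or `"EJ2pro8:MUT|J2:HET"`.
#'
#' @param records Data frame with genotype columns (see
#'   [design_matrix_additive()]).
#' @param pair `"PLT"` or `"SEP"`.
#'
#' @return Character vector of class labels, one per plant.
#' @examples
#' within_pair_class(genotype_from_assignments(c(PLT3 = "HET", PLT7 = "MUT")),
#'                   "PLT")
#' @export
within_pair_class <- function(records, pair = c("PLT", "SEP")) {
  pair <- match.arg(pair)
  if (pair == "PLT") {
    p3 <- as.character(records$plt3)
    p7 <- as.character(records$plt7)
    lab <- paste0(
      ifelse(p3 != "WT", paste0("PLT3:", p3), ""),
      ifelse(p3 != "WT" & p7 != "WT", "|", ""),
      ifelse(p7 != "WT", paste0("PLT7:", p7), ""))
  } else {
    al <- as.character(records$ej2_allele)
    es <- as.character(records$ej2_state)
    j2 <- as.character(records$j2)
    ej <- al != "none" & es != "WT"
    lab <- paste0(
      ifelse(ej, paste0("EJ2", al, ":", es), ""),
      ifelse(ej & j2 != "WT", "|", ""),
      ifelse(j2 != "WT", paste0("J2:", j2), ""))
  }
  ifelse(lab == "", "WT", lab)
}
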