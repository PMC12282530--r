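#' Default locus set for the PLT-SEP branching network
#'
#' The four segregating genes are represented as nine biallelic loci: the two
#' PLETHORA paralogues (`PLT3`, `PLT7`), the SEP gene `J2`, and six mutually
#' exclusive biallelic loci for the multi-allelic `EJ2` promoter series
#' (`EJ2pro1`, `EJ2pro3`, `EJ2pro4`, `EJ2pro6`, `EJ2pro7`, `EJ2pro8`). Each F2
#' population segregates a single `EJ2pro` allele, so the `EJ2pro*` loci carry
#' an `exclusive_group` flag: no pairwise interaction columns are built between
#' them and a plant not carrying an allele is coded homozygous wild type at
#' that locus.
#'
#' @param ej2_alleles Character vector of EJ2 promoter allele identifiers.
#'
#' @return A tibble with one row per locus and columns `locus`, `gene`,
#'   `ej2_allele` (`NA` for non-EJ2 loci) and `exclusive_group`.
#' @examples
#' default_loci()
#' @export
default_loci <- function(ej2_alleles = c("pro1", "pro3", "pro4", "pro6",
                                         "pro7", "pro8")) {
  tibble::tibble(
    locus = c("PLT3", "PLT7", "J2", paste0("EJ2", ej2_alleles)),
    gene = c("PLT3", "PLT7", "J2", rep("EJ2", length(ej2_alleles))),
    ej2_allele = c(NA, NA, NA, ej2_alleles),
    exclusive_group = c(NA, NA, NA, rep("EJ2", length(ej2_alleles)))
  )
}

#' Parse genotype tokens into locus states
#'
#' Maps free-text genotype tokens onto the three within-locus states
#' `"WT"`, `"HET"`, `"MUT"` (homozygous wild type, heterozygous mutant,
#' homozygous mutant). Matching is case-insensitive.
#'
#' @param token Character vector of genotype tokens.
#' @param extra_vocab Optional named character vector of additional synonyms,
#'   e.g. `c("aa" = "MUT")`.
#'
#' @return Character vector of states (`"WT"`, `"HET"`, `"MUT"`).
#' @examples
#' parse_locus_state(c("WT", "m/+", "hom"))
#' @export
parse_locus_state <- function(token, extra_vocab = NULL) {
  vocab <- c(
    "wt" = "WT", "+/+" = "WT", "wt/wt" = "WT", "wt_hom" = "WT",
    "het" = "HET", "m/+" = "HET", "+/m" = "HET", "het_mut" = "HET",
    "hom" = "MUT", "m/m" = "MUT", "mut" = "MUT", "mut_hom" = "MUT"
  )
  if (!is.null(extra_vocab)) {
    names(extra_vocab) <- tolower(names(extra_vocab))
    vocab <- c(vocab, extra_vocab)
  }
  key <- tolower(trimws(as.character(token)))
  out <- unname(vocab[key])
  if (anyNA(out)) {
    bad <- unique(key[is.na(out)])
    abort(sprintf(
      "Unknown genotype token(s): %s (row %s)",
      paste(sQuote(bad), collapse = ", "),
      paste(which(is.na(out))[seq_len(min(5, sum(is.na(out))))], collapse = ", ")
    ), class = "hierepi_parse_error")
  }
  out
}

#' Additive and dominance coding of a locus state
#'
#' Standard quantitative-genetics coding: the additive score `s_a` is -1, 0, 1
#' for homozygous wild type, heterozygous, homozygous mutant; the dominance
#' score `s_d` is 1 for heterozygotes and 0 otherwise, so the dominance
#' coefficient measures the deviation of the heterozygote from the
#' semi-dominant (midpoint) expectation.
#'
#' @param state Character vector of states (`"WT"`, `"HET"`, `"MUT"`).
#'
#' @return A tibble with columns `state`, `s_a`, `s_d`.
#' @examples
#' additive_dominance_code(c("WT", "HET", "MUT"))
#' @export
additive_dominance_code <- function(state) {
  state <- match.arg(as.character(state), .states, several.ok = TRUE)
  tibble::tibble(
    state = state,
    s_a = unname(c(WT = -1, HET = 0, MUT = 1)[state]),
    s_d = unname(c(WT = 0, HET = 1, MUT = 0)[state])
  )
}

# state of every locus in `loci` for each plant: n x L character matrix.
# EJ2pro loci code as the plant's ej2_state when the plant carries that
# allele and "WT" otherwise.
locus_state_matrix <- function(records, loci = default_loci()) {
  n <- nrow(records)
  out <- matrix("WT", nrow = n, ncol = nrow(loci),
                dimnames = list(NULL, loci$locus))
  for (j in seq_len(nrow(loci))) {
    if (is.na(loci$ej2_allele[j])) {
      col <- tolower(loci$locus[j])
      if (!col %in% names(records)) {
        abort(sprintf("records is missing genotype column '%s'", col))
      }
      out[, j] <- as.character(records[[col]])
    } else {
      carrier <- records$ej2_allele == loci$ej2_allele[j]
      out[carrier, j] <- as.character(records$ej2_state[carrier])
    }
  }
  bad <- !(out %in% .states)
  if (any(bad)) {
    abort(sprintf("Invalid locus state(s): %s",
                  paste(unique(out[bad]), collapse = ", ")))
  }
  out
}

# a one-row genotype tibble for the all-wild-type plant
wt_genotype <- function() {
  tibble::tibble(plt3 = "WT", plt7 = "WT", j2 = "WT",
                 ej2_allele = "none", ej2_state = "WT")
}

#' Build a genotype from locus-state assignments
#'
#' Starts from the all-wild-type genotype and applies named assignments such
#' as `c(PLT3 = "MUT", J2 = "HET")`. EJ2 promoter alleles are assigned through
#' their locus label, e.g. `c(EJ2pro8 = "MUT")`. At most one EJ2 allele can be
#' non-wild-type (the alleles never co-occur in a plant).
#'
#' @param assignments Named character vector of `locus = state` pairs.
#' @param loci Locus set tibble, see [default_loci()].
#'
#' @return A one-row genotype tibble with columns `plt3`, `plt7`, `j2`,
#'   `ej2_allele`, `ej2_state`.
#' @examples
#' genotype_from_assignments(c(PLT3 = "MUT", EJ2pro8 = "HET"))
#' @export
genotype_from_assignments <- function(assignments, loci = default_loci()) {
  g <- wt_genotype()
  if (length(assignments) == 0) return(g)
  if (is.null(names(assignments)) || any(names(assignments) == "")) {
    abort("assignments must be a named vector of locus = state pairs")
  }
  unknown <- setdiff(names(assignments), loci$locus)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown locus label(s): %s; known: %s",
                  paste(unknown, collapse = ", "),
                  paste(loci$locus, collapse = ", ")))
  }
  for (loc in names(assignments)) {
    st <- match.arg(assignments[[loc]], .states)
    row <- loci[loci$locus == loc, ]
    if (is.na(row$ej2_allele)) {
      g[[tolower(loc)]] <- st
    } else if (st != "WT") {
      if (g$ej2_allele != "none") {
        abort("At most one EJ2 promoter allele can be assigned per genotype")
      }
      g$ej2_allele <- row$ej2_allele
      g$ej2_state <- st
    }
  }
  g
}
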