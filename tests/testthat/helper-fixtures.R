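# small deterministic fixtures shared across test files

# a two-population design small enough for fast fits
small_design <- function(n = 150, seasons = "S1", season_effects = 0) {
  cross_design(ej2_alleles = c("pro7", "pro8"), n_plants = n,
               seasons = seasons, season_effects = season_effects)
}

# four compatible biallelic loci (no mutual-exclusion flags)
toy_loci <- function(L = 4) {
  tibble::tibble(locus = paste0("L", seq_len(L)),
                 gene = paste0("L", seq_len(L)),
                 ej2_allele = NA_character_,
                 exclusive_group = NA_character_)
}

# random genotype table over the toy loci, all columns named like records
toy_genotypes <- function(n, L = 4, seed = 1) {
  states <- c("WT", "HET", "MUT")
  with_seed_local(seed, {
    g <- tibble::as_tibble(
      setNames(lapply(seq_len(L), function(i) sample(states, n, TRUE)),
               tolower(paste0("L", seq_len(L)))))
    g
  })
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# plant records with explicit genotypes and counts
manual_records <- function(y, t, genotype = NULL) {
  n <- length(y)
  g <- genotype %||% wt_rows(n)
  dplyr::bind_cols(
    tibble::tibble(plant_id = paste0("p", seq_len(n))), g,
    tibble::tibble(population_id = "P1", season_id = "S1",
                   t = as.integer(t), y = as.integer(y)))
}

wt_rows <- function(n) {
  tibble::tibble(plt3 = rep("WT", n), plt7 = "WT", j2 = "WT",
                 ej2_allele = "none", ej2_state = "WT")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
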