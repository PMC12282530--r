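test_that("summarize_plants censors TMTC at 60 and excludes abnormal
           inflorescences", {
  obs <- tibble::tibble(plant_id = "p1", inflorescence_index = 1:4,
                        outcome = c("3", "0", "TMTC", "proliferated"))
  rec <- summarize_plants(obs)
  expect_equal(rec$t, 3L)
  expect_equal(rec$y, 63L) # 3 + 0 + 60
})

test_that("plants with no countable inflorescence are omitted with a
           warning; empty input gives empty output", {
  obs <- tibble::tibble(plant_id = "p1", inflorescence_index = 1:2,
                        outcome = c("proliferated", "inhibited"))
  expect_warning(rec <- summarize_plants(obs), "no countable")
  expect_equal(nrow(rec), 0)
  expect_equal(nrow(summarize_plants(obs[0, ])), 0)
})

test_that("malformed observations raise typed errors", {
  obs <- tibble::tibble(plant_id = "p1", outcome = "-2")
  expect_error(summarize_plants(obs), class = "hierepi_malformed_input")
  obs2 <- tibble::tibble(plant_id = "p1", outcome = "exploded")
  expect_error(summarize_plants(obs2), class = "hierepi_malformed_input")
})

test_that("summarization conserves branching totals and is idempotent", {
  sim <- simulate_branching_study(small_design(60), seed = 42)
  obs <- sim$observations
  parsed <- suppressWarnings(as.integer(obs$outcome))
  parsed[obs$outcome == "TMTC"] <- 60L
  countable <- !obs$outcome %in% c("proliferated", "inhibited")
  expect_equal(sum(sim$records$y), sum(parsed[countable]))
  expect_equal(sum(sim$records$t), sum(countable))
  # idempotence: expand each record back to one observation per
  # inflorescence and re-summarize
  rec <- sim$records
  idx <- rep(seq_len(nrow(rec)), rec$t)
  per_inf <- floor(rec$y / rec$t)
  rem <- rec$y - per_inf * rec$t
  counts <- unlist(lapply(seq_len(nrow(rec)), function(i) {
    v <- rep(per_inf[i], rec$t[i])
    if (rem[i] > 0) v[seq_len(rem[i])] <- v[seq_len(rem[i])] + 1
    v
  }))
  obs2 <- rec[idx, setdiff(names(rec), c("t", "y"))]
  obs2$outcome <- as.character(counts)
  rec2 <- summarize_plants(obs2, censor_value = 1e9)
  rec2 <- rec2[match(rec$plant_id, rec2$plant_id), ]
  expect_equal(rec2$y, rec$y)
  expect_equal(rec2$t, rec$t)
})

test_that("wide tables round-trip bit-identically through write/read", {
  sim <- simulate_branching_study(small_design(40), seed = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_phenotype_table(sim$records, path)
  back <- read_phenotype_table(path)
  expect_equal(as.data.frame(back), as.data.frame(sim$records))
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_phenotype_table(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("long tables match a hand-summed fixture and accept genotype
           synonyms", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "plant_id,plt3,plt7,j2,ej2_allele,ej2_state,outcome",
    "p1,m/+,WT,hom,pro8,m/m,4",
    "p1,m/+,WT,hom,pro8,m/m,TMTC",
    "p1,m/+,WT,hom,pro8,m/m,inhibited",
    "p2,WT,WT,WT,none,WT,0"), path)
  rec <- read_phenotype_table(path)
  expect_equal(rec$t, c(2L, 1L))
  expect_equal(rec$y, c(64L, 0L))
  expect_equal(rec$plt3, c("HET", "WT"))
  expect_equal(rec$ej2_state, c("MUT", "WT"))
})

test_that("rows failing validation are rejected with their row numbers", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "plant_id,plt3,plt7,j2,ej2_allele,ej2_state,t,y",
    "p1,WT,WT,WT,none,WT,10,3",
    "p2,WT,WT,WT,none,WT,0,5",
    "p3,banana,WT,WT,none,WT,10,1"), path)
  expect_warning(rec <- read_phenotype_table(path), "Rejected 2")
  expect_equal(rec$plant_id, "p1")
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("plant_id,plt3\np1,WT", path2)
  expect_error(read_phenotype_table(path2), "Missing required")
})

test_that("dispersion index is 0 for equal rates, ~1 for Poisson data and
           >> 1 for negative-binomial data", {
  rec <- manual_records(y = rep(20, 6), t = rep(10, 6))
  ds <- dispersion_summary(rec)
  expect_equal(ds$var_rate, 0)
  expect_equal(ds$index, 0)

  n <- 5000; t <- 10; mu <- 2
  rec_p <- with_seed_local(101,
    manual_records(y = rpois(n, t * mu), t = rep(t, n)))
  ds_p <- dispersion_summary(rec_p)
  expect_lt(abs(ds_p$index - 1), 0.1)

  alpha <- 0.5; m <- t * mu
  rec_nb <- with_seed_local(102, manual_records(
    y = rpois(n, m * rgamma(n, 1 / alpha, 1 / alpha)), t = rep(t, n)))
  ds_nb <- dispersion_summary(rec_nb)
  # closed form: Var(y) = m + alpha m^2 -> index = 1 + alpha * m = 11
  expect_gt(ds_nb$index, 5)
  expect_lt(abs(ds_nb$index - (1 + alpha * m)) / (1 + alpha * m), 0.25)
})
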