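# Synthetic database generation, inclusion filters and the CSV exchange
# format.

test_that("zero temporal CV yields identical annual matrices", {
  mats <- generate_matrix_set(4, 6, "shrub", temporal_cv = 0, seed = 1)
  for (i in 2:6) expect_equal(mats[[i]], mats[[1]])
})

test_that("survival column sums respect the biological bound", {
  set.seed(41)
  for (arch in GROWTH_FORMS) {
    mats <- generate_matrix_set(sample(2:10, 1), 8, arch,
                                temporal_cv = 0.5)
    for (U in attr(mats, "survival"))
      expect_true(all(colSums(U) <= 1 + 1e-12))
  }
})

test_that("the mean annual matrix hits the growth-rate target exactly", {
  for (tgt in c(-0.1, 0, 0.08)) {
    mats <- generate_matrix_set(3, 5, "herbaceous_perennial",
                                temporal_cv = 0.3,
                                target_log_lambda = tgt, seed = 5)
    expect_lt(abs(log(dominant_eigenvalue(mean_matrix(mats))) - tgt),
              1e-6)
  }
})

test_that("default-archetype matrices are almost always ergodic", {
  set.seed(42)
  n_tot <- 0; n_erg <- 0
  for (i in 1:40) {
    mats <- generate_matrix_set(sample(2:12, 1), 5,
                                sample(GROWTH_FORMS, 1), 0.3)
    erg <- vapply(mats, function(A) is_ergodic(A)$ergodic, logical(1))
    n_tot <- n_tot + length(erg); n_erg <- n_erg + sum(erg)
  }
  expect_gte(n_erg / n_tot, 0.99)
})

test_that("database bookkeeping, determinism and growth-rate spread", {
  cfg <- generator_config(n_species = 10,
                          mean_populations_per_species = 2, seed = 7)
  db1 <- generate_database(cfg)
  db2 <- generate_database(cfg)
  expect_identical(db1, db2)
  expect_equal(length(db1$populations), nrow(db1$bookkeeping))
  expect_lte(length(unique(db1$bookkeeping$species_id)), 10)
  # species share one growth form
  byspecies <- split(db1$bookkeeping$growth_form,
                     db1$bookkeeping$species_id)
  expect_true(all(vapply(byspecies,
                         function(g) length(unique(g)) == 1,
                         logical(1))))
  # asymptotic growth rates distributed near 1
  ll <- unlist(lapply(db1$populations, function(p)
    vapply(p$matrices, function(A) log(dominant_eigenvalue(A)),
           numeric(1))))
  expect_lt(abs(mean(ll)), 0.05)
})

test_that("a dimension effect couples dimension to realized temporal CV", {
  cfg <- generator_config(n_species = 25, dimension_effect = 0.15,
                          seed = 9)
  db <- generate_database(cfg)
  bk <- db$bookkeeping
  expect_gt(cor(bk$matrix_dimension, log(bk$realized_temporal_cv),
                method = "spearman"), 0)
})

test_that("inclusion filters drop short, manipulated and averaged sets", {
  set.seed(44)
  A <- rand_positive_matrix(3)
  mk <- function(id, n, manip = FALSE, meanm = FALSE)
    population_model(id, "S1", "shrub",
                     replicate(n, A, simplify = FALSE),
                     manipulated = manip, is_mean_matrix = meanm)
  pops <- list(mk("P1", 2), mk("P2", 3, manip = TRUE),
               mk("P3", 4, meanm = TRUE), mk("P4", 3), mk("P5", 5))
  res <- apply_inclusion_filters(pops)
  expect_equal(vapply(res$populations, `[[`, character(1),
                      "population_id"), c("P4", "P5"))
  expect_equal(res$exclusions$reason[res$exclusions$population_id == "P1"],
               "fewer than 3 matrices")
  expect_equal(nrow(res$exclusions), 3)
  # identity filter on a compliant set
  ok <- apply_inclusion_filters(list(mk("P4", 3), mk("P5", 5)))
  expect_equal(length(ok$populations), 2)
  expect_equal(nrow(ok$exclusions), 0)
  # explicit species exclusion list
  res2 <- apply_inclusion_filters(list(mk("P4", 3)),
                                  exclude_species = "S1")
  expect_equal(length(res2$populations), 0)
})

test_that("the matrix exchange CSV round-trips a database exactly", {
  cfg <- generator_config(n_species = 6, seed = 12)
  db <- generate_database(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_matrix_csv(db, path)
  back <- read_matrix_csv(path)
  expect_equal(length(back$populations), length(db$populations))
  for (i in seq_along(db$populations)) {
    a <- db$populations[[i]]; b <- back$populations[[i]]
    expect_identical(a$population_id, b$population_id)
    expect_identical(a$species_id, b$species_id)
    expect_identical(a$growth_form, b$growth_form)
    for (j in seq_along(a$matrices))
      expect_identical(unname(a$matrices[[j]]),
                       unname(b$matrices[[j]]))
  }
  # density contract: s x s rows per matrix
  d <- read.csv(path)
  one <- d[d$population_id == db$populations[[1]]$population_id &
             d$matrix_id == "m01", ]
  expect_equal(nrow(one), db$populations[[1]]$dim^2)
})

test_that("malformed exchange CSVs are rejected with the offending line", {
  path <- withr::local_tempfile(fileext = ".csv")
  hdr <- "population_id,species_id,growth_form,matrix_id,row,col,value,manipulated,is_mean_matrix"
  rows <- c("P1,S1,shrub,m01,1,1,0.5,false,false",
            "P1,S1,shrub,m01,1,2,2,false,false",
            "P1,S1,shrub,m01,2,1,-0.3,false,false",
            "P1,S1,shrub,m01,2,2,0.1,false,false")
  writeLines(c(hdr, rows), path)
  expect_error(read_matrix_csv(path), "line 4",
               class = "format_error")
  # ragged matrix: a missing entry
  writeLines(c(hdr, rows[c(1, 2, 4)]), path)
  rows_ok <- sub("-0.3", "0.3", rows)
  writeLines(c(hdr, rows_ok[1:3]), path)
  expect_error(read_matrix_csv(path), class = "format_error")
  # duplicate entry
  writeLines(c(hdr, rows_ok, rows_ok[1]), path)
  expect_error(read_matrix_csv(path), "duplicate",
               class = "format_error")
})

test_that("recovery databases carry their injected truth in bookkeeping", {
  db <- generate_recovery_database(n_species = 5, pops_per_species = 2,
                                   seed = 3)
  bk <- db$bookkeeping
  expect_equal(nrow(bk), 10)
  expect_equal(bk$true_share, plogis(bk$eta))
  expect_true(all(bk$true_share < 0.5))
  # every matrix is positive, hence ergodic
  for (p in db$populations)
    for (A in p$matrices) {
      expect_true(all(A > 0))
      expect_true(is_ergodic(A)$ergodic)
    }
  # the asymptotic magnitude is exact by construction
  p1 <- db$populations[[1]]
  lams <- sort(vapply(p1$matrices, dominant_eigenvalue, numeric(1)))
  expect_equal(unique(round(log(lams), 10)), c(-0.1, 0.1))
})
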