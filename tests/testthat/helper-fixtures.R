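# Fixture builders shared across test files.  All randomness is local to
# the calling test's seed.

# random non-negative matrix with a strictly positive first row; the
# sparse variant keeps diagonal, first row and first column positive so
# the pattern stays irreducible and aperiodic
rand_nonneg_matrix <- function(s, dense = TRUE) {
  A <- matrix(stats::runif(s * s), s, s)
  if (!dense) {
    mask <- matrix(stats::runif(s * s) < 0.5, s, s)
    A[mask] <- 0
    A[1, ] <- stats::runif(s, 0.1, 1)
    A[, 1] <- stats::runif(s, 0.1, 1)
    diag(A) <- stats::runif(s, 0.1, 1)
  }
  A
}

# random strictly positive matrix: irreducible and primitive by
# construction
rand_positive_matrix <- function(s)
  matrix(stats::runif(s * s, 0.05, 2), s, s)

rand_stage_vector <- function(s) stats::runif(s, 0.01, 1)

# a small two-matrix population for simulator tests
rand_two_matrix_population <- function(id = "P1", s = 3) {
  population_model(id, "S1", "shrub",
                   list(rand_positive_matrix(s), rand_positive_matrix(s)))
}

# synthetic per-population summary table for the comparative models
make_summaries <- function(n_species, pops_per_species, f_mean_reactivity,
                           species_sd = 0.1, resid_sd = 0.05) {
  rows <- list()
  for (sp in seq_len(n_species)) {
    u <- stats::rnorm(1, 0, species_sd)
    for (p in seq_len(pops_per_species)) {
      dim <- sample(2:12, 1)
      rows[[length(rows) + 1L]] <- data.frame(
        population_id = sprintf("P%d_%d", sp, p),
        species_id = sprintf("S%d", sp),
        growth_form = sample(GROWTH_FORMS, 1),
        matrix_dimension = dim,
        mean_log_reactivity = f_mean_reactivity(dim) + u +
          stats::rnorm(1, 0, resid_sd),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
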