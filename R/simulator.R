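# Stochastic simulation protocol: each replicate starts with equal numbers
# in every stage, iterates x(t+1) = A(t) x(t) with A(t) drawn i.i.d.
# uniformly from the population's matrix set for a burn-in period, then the
# growth decomposition is measured over the single step following burn-in.
# Stage vectors are renormalized to unit one-norm every step; all emitted
# metrics depend on x only through x/||x||_1, so this changes nothing but
# prevents overflow across long burn-ins.

#' Construct a population model
#'
#' Bundles a set of same-dimension annual projection matrices with the
#' metadata used by the comparative analyses.
#'
#' @param population_id,species_id character identifiers.
#' @param growth_form one of `"herbaceous_perennial"`, `"shrub"`,
#'   `"succulent"`, `"palm"`, `"tree"`.
#' @param matrices non-empty list of non-negative square matrices sharing
#'   one dimension.
#' @param manipulated,is_mean_matrix metadata flags used by the inclusion
#'   filters: experimentally manipulated populations and populations whose
#'   "annual" matrices are averages of several matrices are excluded from
#'   analysis.
#' @return an object of class `population_model`.
#' @export
population_model <- function(population_id, species_id, growth_form,
                             matrices, manipulated = FALSE,
                             is_mean_matrix = FALSE) {
  growth_form <- match.arg(growth_form, GROWTH_FORMS)
  if (length(matrices) == 0L)
    stop_stochtrans("population has no matrices", "empty_model_error")
  dims <- vapply(matrices, nrow, integer(1))
  if (length(unique(dims)) != 1L)
    stop_stochtrans("matrices within a population must share one dimension",
                    "dimension_error")
  for (m in matrices) validate_projection_matrix(m)
  structure(list(
    population_id = as.character(population_id),
    species_id = as.character(species_id),
    growth_form = growth_form,
    matrices = matrices,
    dim = dims[1],
    manipulated = isTRUE(manipulated),
    is_mean_matrix = isTRUE(is_mean_matrix)
  ), class = "population_model")
}

#' Recognized plant growth forms
#' @export
GROWTH_FORMS <- c("herbaceous_perennial", "shrub", "succulent", "palm",
                  "tree")

#' @export
print.population_model <- function(x, ...) {
  cat(sprintf("<population_model> %s (%s, %s): %d matrices of dimension %d\n",
              x$population_id, x$species_id, x$growth_form,
              length(x$matrices), x$dim))
  invisible(x)
}

#' Simulate replicate stochastic trajectories for one population
#'
#' Runs `n_replicates` independent trajectories.  Each starts from the
#' uniform stage vector `(1/s, ..., 1/s)`, projects through `burn_in`
#' i.i.d. uniform matrix draws (renormalizing each step), then draws one
#' further matrix and records the one-step growth decomposition.
#'
#' All replicates are advanced simultaneously: at each step the replicate
#' columns are grouped by the matrix drawn and each group is projected by
#' one matrix product.
#'
#' @param pop a [population_model].
#' @param n_replicates number of replicates (default 1000).
#' @param burn_in number of projection steps before measurement
#'   (default 500).
#' @param seed optional integer; when supplied the population is simulated
#'   under its own RNG stream, leaving the caller's RNG state untouched.
#' @return a `data.frame` of class `metrics_table` with one row per
#'   retained replicate and columns `replicate`, `log_lambda_obs`,
#'   `log_lambda_max`, `log_reactivity`, `log_lambda_abs`,
#'   `population_id`; attribute `n_excluded` counts replicates dropped
#'   because the projected population was extinguished, and attribute
#'   `draw_counts` tallies which matrix was drawn at the measured step.
#' @export
simulate_population <- function(pop, n_replicates = 1000, burn_in = 500,
                                seed = NULL) {
  stopifnot(inherits(pop, "population_model"))
  if (n_replicates < 1 || burn_in < 0)
    stop_stochtrans("need n_replicates >= 1 and burn_in >= 0",
                    "invalid_config_error")
  k <- length(pop$matrices)
  if (k == 0L) stop_stochtrans("population has no matrices",
                               "empty_model_error")
  s <- pop$dim
  lam <- vapply(pop$matrices, dominant_eigenvalue, numeric(1))
  if (any(lam <= 0))
    stop_stochtrans("every matrix must have a positive dominant eigenvalue",
                    "degenerate_input_error")

  run <- function() {
    X <- matrix(1 / s, nrow = s, ncol = n_replicates)
    alive <- rep(TRUE, n_replicates)
    draws <- matrix(
      sample.int(k, (burn_in + 1L) * n_replicates, replace = TRUE),
      nrow = burn_in + 1L)
    for (t in seq_len(burn_in)) {
      idx <- draws[t, ]
      for (j in seq_len(k)) {
        sel <- which(idx == j & alive)
        if (length(sel)) X[, sel] <- pop$matrices[[j]] %*% X[, sel,
                                                             drop = FALSE]
      }
      tot <- colSums(X)
      dead <- alive & tot <= 0
      if (any(dead)) alive[dead] <- FALSE
      ok <- alive
      X[, ok] <- X[, ok, drop = FALSE] /
        rep(tot[ok], each = s)
    }
    # measured step: one fresh draw per replicate
    fin <- draws[burn_in + 1L, ]
    lam_obs <- numeric(n_replicates)
    for (j in seq_len(k)) {
      sel <- which(fin == j & alive)
      if (length(sel))
        lam_obs[sel] <- colSums(pop$matrices[[j]] %*%
                                  X[, sel, drop = FALSE])
    }
    keep <- alive & lam_obs > 0
    lo <- log(lam_obs[keep])
    lm_ <- log(lam[fin[keep]])
    lr <- lo - lm_
    out <- data.frame(
      replicate = which(keep),
      log_lambda_obs = lo,
      log_lambda_max = lm_,
      log_reactivity = lr,
      log_lambda_abs = abs(lm_) + abs(lr),
      population_id = pop$population_id,
      stringsAsFactors = FALSE)
    attr(out, "n_excluded") <- n_replicates - sum(keep)
    attr(out, "draw_counts") <- tabulate(fin[keep], nbins = k)
    class(out) <- c("metrics_table", "data.frame")
    out
  }

  if (is.null(seed)) {
    res <- run()
  } else {
    res <- local_seed_eval(seed, run)
  }
  if (nrow(res) == 0L)
    stop_stochtrans(sprintf("all replicates of %s were degenerate",
                            pop$population_id), "simulation_failed_error")
  res
}

# evaluate fn() under a temporary RNG state seeded with `seed`,
# restoring the caller's state afterwards
local_seed_eval <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  fn()
}

#' Bind replicate metric tables
#'
#' @param results a `metrics_table` or list of them.
#' @return a single `metrics_table` with exclusion counts summed.
#' @export
metrics_table <- function(results) {
  if (inherits(results, "metrics_table")) return(results)
  if (!is.list(results) || length(results) == 0L)
    stop_stochtrans("need a non-empty list of metric tables",
                    "invalid_config_error")
  excl <- sum(vapply(results, function(r) {
    v <- attr(r, "n_excluded"); if (is.null(v)) 0L else v
  }, numeric(1)))
  out <- do.call(rbind, lapply(results, as.data.frame))
  attr(out, "n_excluded") <- excl
  class(out) <- c("metrics_table", "data.frame")
  out
}
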