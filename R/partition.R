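# Collapse per-replicate metrics into the six per-population response
# variables used by the comparative analyses:
#   (i)  r2_asym        variance in net growth explained by asymptotics
#   (ii) r2_trans       variance in net growth explained by transients
#   (iii) prop_abs_trans mean share of the absolute dynamic from transients
#   (iv) mean_log_lambda_obs  stochastic growth rate
#   (v)  mean_log_lambda_max  mean asymptotic growth rate
#   (vi) mean_log_reactivity  mean transient growth ("boom" tendency)

#' Variance in net growth explained by each component
#'
#' Squared Pearson correlations between per-replicate net log growth and
#' each of its two (non-independent) components.  Because the components
#' may covary, the two R-squared values need not sum to 1.
#'
#' @param table a metrics table (rows = replicates).
#' @return named numeric vector `c(r2_asym, r2_trans)`.
#' @export
variance_explained <- function(table) {
  if (nrow(table) < 3L)
    stop_stochtrans("need at least 3 replicates", "undefined_partition_error")
  va <- stats::var(table$log_lambda_max)
  vt <- stats::var(table$log_reactivity)
  if (va <= 0)
    stop_stochtrans(
      "asymptotic component has zero variance; partition undefined",
      "undefined_partition_error", component = "log_lambda_max")
  if (vt <= 0)
    stop_stochtrans(
      "transient component has zero variance; partition undefined",
      "undefined_partition_error", component = "log_reactivity")
  c(r2_asym = stats::cor(table$log_lambda_obs, table$log_lambda_max)^2,
    r2_trans = stats::cor(table$log_lambda_obs, table$log_reactivity)^2)
}

#' Mean transient share of the absolute dynamic
#'
#' Per replicate, \eqn{|\log reactivity| / \log\lambda_{abs}} is the share
#' of the absolute dynamic contributed by transients; the population value
#' is its arithmetic mean over replicates.  Replicates in which both
#' components are exactly zero (\eqn{\log\lambda_{abs} = 0}) carry no
#' information about the split and are excluded (count returned as
#' attribute `n_zero_abs`).
#'
#' @param table a metrics table.
#' @return proportion in \[0, 1\].
#' @export
transient_proportion <- function(table) {
  use <- table$log_lambda_abs > 0
  if (!any(use))
    stop_stochtrans("all replicates have zero absolute dynamic",
                    "undefined_partition_error")
  p <- mean(abs(table$log_reactivity[use]) / table$log_lambda_abs[use])
  attr(p, "n_zero_abs") <- sum(!use)
  p
}

#' Per-population partition summary
#'
#' Computes all six response variables for one population from its
#' simulated metrics table, carrying along the metadata used as model
#' covariates.
#'
#' @param pop the [population_model] the table was simulated from.
#' @param table its metrics table.
#' @return one-row `data.frame` with columns `population_id`,
#'   `species_id`, `growth_form`, `matrix_dimension`, `r2_asym`,
#'   `r2_trans`, `prop_abs_trans`, `mean_log_lambda_obs`,
#'   `mean_log_lambda_max`, `mean_log_reactivity`, `n_replicates_used`.
#' @export
summarize_population <- function(pop, table) {
  r2 <- tryCatch(variance_explained(table), stochtrans_error = function(e) {
    e$message <- sprintf("population %s: %s", pop$population_id, e$message)
    stop(e)
  })
  pt <- tryCatch(transient_proportion(table), stochtrans_error = function(e) {
    e$message <- sprintf("population %s: %s", pop$population_id, e$message)
    stop(e)
  })
  data.frame(
    population_id = pop$population_id,
    species_id = pop$species_id,
    growth_form = pop$growth_form,
    matrix_dimension = pop$dim,
    r2_asym = unname(r2["r2_asym"]),
    r2_trans = unname(r2["r2_trans"]),
    prop_abs_trans = as.numeric(pt),
    mean_log_lambda_obs = mean(table$log_lambda_obs),
    mean_log_lambda_max = mean(table$log_lambda_max),
    mean_log_reactivity = mean(table$log_reactivity),
    n_replicates_used = nrow(table),
    stringsAsFactors = FALSE)
}
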