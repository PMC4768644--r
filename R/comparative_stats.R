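# Comparative hierarchical models across populations:
#  - contribution models: logit-transformed proportion responses regressed
#    on growth form (one intercept per form) and matrix dimension, with a
#    species random intercept;
#  - boom test: intercept-only model for the mean transient growth
#    (is the global tendency to boom or bust different from zero?);
#  - association test: mixed regression of a growth rate on mean
#    log-reactivity with a likelihood-ratio test against the no-slope null.
#
# Inference backend: restricted maximum likelihood via lme4, with
# Satterthwaite-df t intervals (lmerTest).  The importance rule is purely
# interval-based: a fixed effect is "important" iff its 95% interval
# excludes zero.

.LOGIT_EPS <- 1e-6

#' Logit transform with boundary clamping
#'
#' Proportion responses are clamped to `[1e-6, 1 - 1e-6]` before the
#' logit so that simulated values of exactly 0 or 1 remain finite.
#'
#' @param p numeric vector of proportions in `[0, 1]`.
#' @return `log(p' / (1 - p'))` with `p'` the clamped value.
#' @export
logit_transform <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop_stochtrans("proportions must lie in [0, 1]", "domain_error")
  p <- pmin(pmax(p, .LOGIT_EPS), 1 - .LOGIT_EPS)
  stats::qlogis(p)
}

# extract a tidy fixed-effect table with Satterthwaite 95% intervals
.fixef_table <- function(fit) {
  co <- as.data.frame(stats::coef(summary(fit)))
  tcrit <- stats::qt(0.975, pmax(co[["df"]], 1))
  data.frame(
    parameter = rownames(co),
    estimate = co[["Estimate"]],
    lower95 = co[["Estimate"]] - tcrit * co[["Std. Error"]],
    upper95 = co[["Estimate"]] + tcrit * co[["Std. Error"]],
    p_value = co[["Pr(>|t|)"]],
    row.names = NULL, stringsAsFactors = FALSE)
}

.finish_fit <- function(tab, fit, extra = list()) {
  tab$important <- tab$lower95 > 0 | tab$upper95 < 0
  res <- c(list(parameters = tab,
                singular = if (inherits(fit, "merMod"))
                  lme4::isSingular(fit) else NA),
           extra)
  class(res) <- "fit_result"
  res
}

#' @export
print.fit_result <- function(x, ...) {
  print(x$parameters, digits = 4)
  if (!is.null(x$p_null)) cat(sprintf("LRT vs null: chisq = %.3f, p = %.3g\n",
                                      x$chisq, x$p_null))
  invisible(x)
}

# fit with lmerTest, falling back to plain lm when the species grouping
# is degenerate (one population per species leaves the random intercept
# unidentified) or the mixed fit itself degenerates (e.g. an exactly
# deterministic response with zero residual variance)
.fit_mixed <- function(formula_mixed, formula_fixed, data) {
  fixed_fallback <- function() {
    fit <- stats::lm(formula_fixed, data = data)
    co <- as.data.frame(stats::coef(summary(fit)))
    tcrit <- stats::qt(0.975, stats::df.residual(fit))
    tab <- data.frame(
      parameter = rownames(co), estimate = co[["Estimate"]],
      lower95 = co[["Estimate"]] - tcrit * co[["Std. Error"]],
      upper95 = co[["Estimate"]] + tcrit * co[["Std. Error"]],
      p_value = co[["Pr(>|t|)"]],
      row.names = NULL, stringsAsFactors = FALSE)
    list(fit = fit, tab = tab, mixed = FALSE)
  }
  n_sp <- length(unique(data$species_id))
  if (n_sp < 2 || n_sp >= nrow(data)) return(fixed_fallback())
  tryCatch({
    fit <- suppressMessages(suppressWarnings(
      lmerTest::lmer(formula_mixed, data = data,
                     control = lme4::lmerControl(check.conv.singular =
                                                   "ignore"))))
    list(fit = fit, tab = .fixef_table(fit), mixed = TRUE)
  }, error = function(e) fixed_fallback())
}

#' Fit a contribution model
#'
#' Hierarchical regression of one logit-transformed proportion response
#' (`r2_asym`, `r2_trans` or `prop_abs_trans`) on growth form and matrix
#' dimension with a species random intercept.  Growth forms are coded as
#' one intercept per form (no reference level) so per-form predictions
#' and their intervals can be compared directly; the dimension slope is
#' shared across forms.
#'
#' @param summaries data.frame of per-population summaries
#'   ([summarize_population] rows).
#' @param response one of `"r2_asym"`, `"r2_trans"`, `"prop_abs_trans"`.
#' @return a `fit_result`: data.frame of parameter estimates with 95%
#'   intervals and the interval-excludes-zero importance flag.
#' @export
fit_contribution_model <- function(summaries,
                                   response = c("r2_asym", "r2_trans",
                                                "prop_abs_trans")) {
  response <- match.arg(response)
  d <- as.data.frame(summaries)
  d$y <- logit_transform(d[[response]])
  d$growth_form <- factor(d$growth_form)
  one_form <- length(unique(d$growth_form)) < 2
  if (one_form)
    warning("single growth form present; growth-form effects dropped")
  if (length(unique(d$matrix_dimension)) < 2)
    stop_stochtrans("need at least 2 distinct matrix dimensions",
                    "invalid_config_error")
  fm <- if (one_form) y ~ matrix_dimension + (1 | species_id) else
    y ~ 0 + growth_form + matrix_dimension + (1 | species_id)
  ff <- if (one_form) y ~ matrix_dimension else
    y ~ 0 + growth_form + matrix_dimension
  m <- .fit_mixed(fm, ff, d)
  .finish_fit(m$tab, m$fit, list(response = response))
}

#' Test for a global tendency to boom or bust
#'
#' Intercept-only model with a species random intercept for the mean
#' transient growth (`mean_log_reactivity` by default).  The null
#' expectation is an intercept of zero: deviations from stable structure
#' should boom as often as they bust.  Alongside the 95% interval a
#' two-sided tail probability for the intercept is reported.
#'
#' @param summaries per-population summary data.frame.
#' @param response summary column to test (default `mean_log_reactivity`).
#' @return a `fit_result` with elements `tail_prob` and `parameters`.
#' @export
boom_test <- function(summaries, response = "mean_log_reactivity") {
  d <- as.data.frame(summaries)
  d$y <- d[[response]]
  m <- .fit_mixed(y ~ 1 + (1 | species_id), y ~ 1, d)
  tab <- m$tab
  res <- .finish_fit(tab, m$fit, list(response = response,
                                      tail_prob = tab$p_value[1]))
  res
}

#' Association between mean transient growth and a growth rate
#'
#' Mixed regression of a per-population growth-rate response on mean
#' log-reactivity with a species random intercept, plus a likelihood-ratio
#' test (maximum-likelihood fits) against the no-slope null.
#'
#' @param summaries per-population summary data.frame.
#' @param response column name of the response (e.g.
#'   `"mean_log_lambda_obs"` for the stochastic growth rate, or
#'   `"log_lambda_mean_matrix"` if the caller has added the stable growth
#'   rate of each population's mean matrix).
#' @param predictor column name of the predictor.
#' @return a `fit_result` with `chisq` and `p_null` from the LRT.
#' @export
association_test <- function(summaries, response = "mean_log_lambda_obs",
                             predictor = "mean_log_reactivity") {
  d <- as.data.frame(summaries)
  if (nrow(d) < 3)
    stop_stochtrans("need at least 3 populations", "invalid_config_error")
  d$y <- d[[response]]
  d$x <- d[[predictor]]
  m <- .fit_mixed(y ~ x + (1 | species_id), y ~ x, d)
  if (m$mixed) {
    full <- suppressMessages(suppressWarnings(
      lme4::lmer(y ~ x + (1 | species_id), data = d, REML = FALSE,
                 control = lme4::lmerControl(check.conv.singular =
                                               "ignore"))))
    null <- suppressMessages(suppressWarnings(
      lme4::lmer(y ~ 1 + (1 | species_id), data = d, REML = FALSE,
                 control = lme4::lmerControl(check.conv.singular =
                                               "ignore"))))
    lrt <- stats::anova(null, full)
    chisq <- lrt$Chisq[2]; p_null <- lrt[["Pr(>Chisq)"]][2]
  } else {
    full <- stats::lm(y ~ x, data = d)
    null <- stats::lm(y ~ 1, data = d)
    lrt <- stats::anova(null, full)
    chisq <- NA_real_; p_null <- lrt[["Pr(>F)"]][2]
  }
  .finish_fit(m$tab, m$fit,
              list(response = response, predictor = predictor,
                   chisq = chisq, p_null = p_null))
}
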