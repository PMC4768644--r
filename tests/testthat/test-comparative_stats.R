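# Hierarchical comparative models: logit transform, contribution models,
# boom test, reactivity-growth association.

test_that("logit transform matches closed forms and clamps the bounds", {
  expect_equal(logit_transform(0.5), 0)
  expect_equal(logit_transform(0.75), log(3), tolerance = 1e-12)
  expect_equal(logit_transform(1), log((1 - 1e-6) / 1e-6),
               tolerance = 1e-9)
  expect_equal(logit_transform(0), -logit_transform(1))
  expect_error(logit_transform(1.2), class = "domain_error")
  expect_error(logit_transform(-0.1), class = "domain_error")
  # strictly increasing, odd about one half
  p <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(logit_transform(p)) > 0))
  expect_equal(logit_transform(p), -logit_transform(rev(p)),
               tolerance = 1e-12)
})

# summaries with a known logit-scale structure in prop_abs_trans
make_prop_summaries <- function(n_species, pops_per_species, beta0,
                                beta_dim, species_sd = 0.1,
                                resid_sd = 0.1) {
  rows <- list()
  for (sp in seq_len(n_species)) {
    u <- rnorm(1, 0, species_sd)
    gf <- sample(GROWTH_FORMS, 1)
    for (p in seq_len(pops_per_species)) {
      dm <- sample(2:12, 1)
      eta <- beta0 + beta_dim * dm + u + rnorm(1, 0, resid_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        population_id = sprintf("P%d_%d", sp, p),
        species_id = sprintf("S%d", sp), growth_form = gf,
        matrix_dimension = dm, prop_abs_trans = plogis(eta),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

test_that("contribution model recovers a known dimension slope", {
  set.seed(51)
  d <- make_prop_summaries(40, 2, beta0 = -2, beta_dim = 0.2)
  fit <- fit_contribution_model(d, "prop_abs_trans")
  tab <- fit$parameters
  slope <- tab[tab$parameter == "matrix_dimension", ]
  expect_gt(slope$estimate, 0)
  expect_true(slope$lower95 <= 0.2 && 0.2 <= slope$upper95)
  expect_true(slope$important)
  # one intercept per growth form, no reference-level contrast
  forms <- grep("^growth_form", tab$parameter, value = TRUE)
  expect_setequal(sub("growth_form", "", forms),
                  unique(d$growth_form))
  expect_true(all(tab$lower95 <= tab$estimate &
                    tab$estimate <= tab$upper95))
  expect_equal(tab$important, tab$lower95 > 0 | tab$upper95 < 0)
})

test_that("a constant response gives a null slope and no species variance", {
  set.seed(52)
  d <- make_prop_summaries(10, 2, beta0 = 0, beta_dim = 0,
                           species_sd = 0, resid_sd = 0)
  d$prop_abs_trans <- 0.4
  fit <- suppressWarnings(fit_contribution_model(d, "prop_abs_trans"))
  slope <- fit$parameters[fit$parameters$parameter ==
                            "matrix_dimension", ]
  expect_lt(abs(slope$estimate), 1e-6)
})

test_that("fits are invariant to population order and species relabeling", {
  set.seed(53)
  d <- make_prop_summaries(20, 2, beta0 = -1, beta_dim = 0.1)
  f1 <- fit_contribution_model(d, "prop_abs_trans")
  d2 <- d[sample(nrow(d)), ]
  f2 <- fit_contribution_model(d2, "prop_abs_trans")
  expect_equal(f1$parameters$estimate, f2$parameters$estimate,
               tolerance = 1e-6)
  d3 <- d
  d3$species_id <- paste0("renamed_", d3$species_id)
  f3 <- fit_contribution_model(d3, "prop_abs_trans")
  expect_equal(f1$parameters$estimate, f3$parameters$estimate,
               tolerance = 1e-8)
})

test_that("single growth form drops the form effects with a warning", {
  set.seed(54)
  d <- make_prop_summaries(15, 2, beta0 = -1, beta_dim = 0.1)
  d$growth_form <- "tree"
  expect_warning(fit <- fit_contribution_model(d, "prop_abs_trans"),
                 "single growth form")
  expect_false(any(grepl("growth_form", fit$parameters$parameter)))
})

test_that("boom test flags a separated positive mean and is sign-symmetric", {
  set.seed(55)
  d <- make_summaries(20, 2, function(dm) 0.05, species_sd = 0.01,
                      resid_sd = 0.005)
  fit <- boom_test(d)
  ic <- fit$parameters[1, ]
  expect_gt(ic$lower95, 0)
  expect_true(ic$important)
  expect_lt(fit$tail_prob, 0.05)
  d2 <- d; d2$mean_log_reactivity <- -d2$mean_log_reactivity
  fit2 <- boom_test(d2)
  expect_equal(fit2$parameters$estimate[1], -ic$estimate,
               tolerance = 1e-8)
  expect_equal(fit2$parameters$upper95[1] - fit2$parameters$lower95[1],
               ic$upper95 - ic$lower95, tolerance = 1e-8)
})

test_that("association recovers an exact unit slope", {
  set.seed(56)
  d <- make_summaries(15, 2, function(dm) 0, species_sd = 0.05,
                      resid_sd = 0.02)
  d$mean_log_lambda_obs <- d$mean_log_reactivity
  fit <- suppressWarnings(association_test(d))
  slope <- fit$parameters[fit$parameters$parameter == "x", ]
  expect_equal(slope$estimate, 1, tolerance = 1e-6)
})

test_that("association detects a strong injected link and reports an LRT", {
  set.seed(57)
  d <- make_summaries(25, 2, function(dm) 0, species_sd = 0.02,
                      resid_sd = 0.02)
  d$mean_log_lambda_obs <- 0.8 * d$mean_log_reactivity +
    rnorm(nrow(d), 0, 0.005)
  fit <- association_test(d)
  slope <- fit$parameters[fit$parameters$parameter == "x", ]
  expect_gt(slope$estimate, 0)
  expect_true(slope$important)
  expect_lt(fit$p_null, 0.01)
  expect_gt(fit$chisq, 0)
})

test_that("with one population per species the lm oracle is matched", {
  set.seed(58)
  d <- make_summaries(20, 1, function(dm) 0.02 * dm, species_sd = 0,
                      resid_sd = 0.02)
  d$mean_log_lambda_obs <- 0.5 * d$mean_log_reactivity +
    rnorm(nrow(d), 0, 0.01)
  fit <- association_test(d)
  oracle <- lm(mean_log_lambda_obs ~ mean_log_reactivity, data = d)
  slope <- fit$parameters[fit$parameters$parameter == "x", "estimate"]
  expect_equal(slope, unname(coef(oracle)[2]), tolerance = 1e-10)
})
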