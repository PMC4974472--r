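test_that("a single-group Gaussian fit reduces to ordinary least squares", {
  d <- toy_model_data(n_studies = 1)
  fit <- fit_mixed_model(d, model_spec("y", "gaussian",
                                       fixed = c("protected", "elevation")))
  ols <- lm(y ~ protected + elevation, data = d)
  expect_equal(fit$coefficients$estimate, unname(coef(ols)), tolerance = 1e-6)
  expect_equal(fit$n_studies, 1)
  expect_length(fit$random_used, 0)
})

test_that("the Laplace Poisson fit matches the adaptive Gauss-Hermite oracle", {
  d <- toy_model_data(n_studies = 5, n_per = 40, seed = 17)
  fit <- fit_mixed_model(d, model_spec("S", "poisson", fixed = c("protected", "elevation"),
                                       random = "study", olre = FALSE))
  X <- model.matrix(~ protected + elevation, d)
  oracle <- ghq_poisson_fit(d$S, X, d$study_id, n_nodes = 25)
  expect_equal(fit$coefficients$estimate, unname(oracle$beta), tolerance = 1e-3)
})

test_that("a constant response gives a null protection coefficient", {
  d <- toy_model_data(n_studies = 3)
  d$y <- 2.5
  fit <- fit_mixed_model(d, model_spec("y", "gaussian", fixed = "protected"))
  expect_lt(abs(fit$coefficients$estimate[2]), 1e-6)
})

test_that("likelihood-ratio tests follow the chi-square tail", {
  d <- toy_model_data(n_studies = 4)
  full <- fit_mixed_model(d, model_spec("y", "gaussian",
                                        fixed = c("protected", "elevation")))
  red <- fit_mixed_model(full$data, model_spec("y", "gaussian", fixed = "elevation"))
  lrt <- likelihood_ratio_test(full, red)
  expect_equal(lrt$chi_square, 2 * (full$logLik - red$logLik))
  expect_equal(lrt$df, 1)
  expect_equal(lrt$p_value, pchisq(lrt$chi_square, 1, lower.tail = FALSE))
  # equal log-likelihoods: chi-square 0, p 1
  mk <- function(ll, fixed) structure(
    list(logLik = ll, n_fixed = length(fixed) + 1, converged = TRUE,
         n_sites = full$n_sites, spec = list(fixed = fixed, family = "gaussian")),
    class = "fit_result")
  self <- likelihood_ratio_test(mk(-80, c("a", "b")), mk(-80, "a"))
  expect_equal(self$chi_square, 0)
  expect_equal(self$p_value, 1)
  # non-nested terms are refused
  other <- fit_mixed_model(full$data, model_spec("y", "gaussian", fixed = "slope"))
  expect_error(likelihood_ratio_test(full, other), "subset")
})

test_that("percentage differences back-transform the log-scale coefficient", {
  fit <- structure(list(coefficients = data.frame(
    term = c("(Intercept)", "protectedprotected"),
    estimate = c(1, log(1.106)), se = c(0.1, 0))), class = "fit_result")
  pd <- percent_difference(fit, "protected")
  expect_equal(pd$percent_difference, 10.6, tolerance = 1e-9)
  expect_equal(pd$ci_low, 10.6, tolerance = 1e-9)
  expect_equal(pd$ci_high, 10.6, tolerance = 1e-9)
  fit$coefficients$estimate[2] <- 0
  expect_equal(percent_difference(fit, "protected")$percent_difference, 0)
  fit$coefficients$estimate[2] <- -0.5
  fit$coefficients$se[2] <- 0.1
  pd2 <- percent_difference(fit, "protected")
  expect_equal(pd2$percent_difference, 100 * (exp(-0.5) - 1), tolerance = 1e-9)
  expect_equal(pd2$ci_low, 100 * (exp(-0.5 - 1.96 * 0.1) - 1), tolerance = 1e-9)
  expect_equal(pd2$ci_high, 100 * (exp(-0.5 + 1.96 * 0.1) - 1), tolerance = 1e-9)
  # sign flip for reciprocally-defined responses
  expect_equal(percent_difference(fit, "protected", negate = TRUE)$percent_difference,
               100 * (exp(0.5) - 1), tolerance = 1e-9)
  expect_error(percent_difference(fit, "absent"), "not found")
})

test_that("backward elimination drops noise, keeps signal and respects marginality", {
  d <- toy_model_data(n_studies = 6, n_per = 40, seed = 23, beta_prot = 0.6)
  d$noise <- rnorm(nrow(d))
  spec <- model_spec("y", "gaussian", fixed = c("protected", "noise"))
  out <- backward_eliminate(d, spec)
  expect_true("protected" %in% out$spec$fixed)
  expect_false("noise" %in% out$spec$fixed)
  expect_true(all(out$trace$p_value[out$trace$dropped] >= 0.05))
  # a model whose every droppable term is significant is returned unchanged
  out2 <- backward_eliminate(d, model_spec("y", "gaussian", fixed = "protected"))
  expect_identical(out2$spec$fixed, "protected")
  # interactions are tested before their main effects
  d$land_use <- factor(sample(c("primary", "cropland"), nrow(d), replace = TRUE),
                       levels = c("primary", "cropland"))
  spec3 <- model_spec("y", "gaussian",
                      fixed = c("protected", "land_use", "protected:land_use"))
  out3 <- backward_eliminate(d, spec3)
  tr <- out3$trace
  first_main <- suppressWarnings(min(which(tr$term %in% c("protected", "land_use"))))
  last_int <- max(which(tr$term == "protected:land_use"))
  expect_true(is.infinite(first_main) || first_main > last_int)
  # the interaction spec itself refuses marginality violations
  expect_error(model_spec("y", "gaussian", fixed = c("protected", "protected:land_use")),
               "main effects")
})

test_that("the suite fits one model set per defined measure only", {
  w <- generate_world(world_config(n_studies = 8, sites_per_study = c(15, 25),
                                   taxon_pool_size = c(10, 20),
                                   occurrence_fraction = 0, random_seed = 61))
  m <- compute_site_measures(w)
  cl <- assign_protection(w$sites, w$protected_areas)
  md <- prepare_model_data(m, cl)
  suite <- suppressWarnings(fit_measure_suite(md, models = "protection"))
  expect_setequal(names(suite$fits),
                  c("richness", "abundance", "rarefied_richness", "endemicity"))
  expect_true(all(c("measure", "percent_difference", "ci_low", "ci_high") %in%
                    names(suite$contrasts)))
  # an occurrence-only world has no abundance (nor rarefied-richness) model
  w2 <- generate_world(world_config(n_studies = 6, sites_per_study = c(12, 20),
                                    taxon_pool_size = c(8, 15),
                                    occurrence_fraction = 1, random_seed = 62))
  m2 <- compute_site_measures(w2)
  md2 <- prepare_model_data(m2, assign_protection(w2$sites, w2$protected_areas))
  suite2 <- suppressWarnings(fit_measure_suite(md2, models = "protection"))
  expect_setequal(names(suite2$fits), c("richness", "endemicity"))
})

test_that("matched-data models run on exactly the matched subset", {
  fx <- generate_matched_fixture()
  m <- compute_site_measures(fx)
  cl <- assign_protection(fx$sites, fx$protected_areas)
  mt <- match_sites_by_land_use(cl)
  md <- prepare_model_data(m, cl)
  mtd <- prepare_model_data(m[m$site_id %in% mt$site_id, ], mt)
  expect_setequal(mtd$site_id, fx$truth$matched_sites)
  suite <- suppressWarnings(fit_measure_suite(md, mtd,
                                              models = c("protection", "protection_matched")))
  pm <- suite$fits$richness$protection_matched
  expect_true(!is.null(pm))
  expect_lte(pm$fit$n_sites, length(fx$truth$matched_sites))
})
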