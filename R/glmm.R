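#' Specify a mixed-effects model for one biodiversity response
#'
#' @param response Name of the (already transformed) response column.
#' @param family `"poisson"` (log link, for richness counts) or
#'   `"gaussian"` (identity link on a transformed response).
#' @param fixed Character vector of fixed-effect terms; interactions as
#'   `"a:b"`. Marginality is the caller's responsibility at specification
#'   time and is enforced during elimination.
#' @param random Random-intercept terms among `"study"` (study intercept),
#'   `"block"` (block nested in study) and `"obs"` (observation-level
#'   intercept for overdispersion).
#' @param olre `"auto"` adds an observation-level random intercept to
#'   Poisson fits when the Pearson dispersion exceeds 1.5; `TRUE`/`FALSE`
#'   force it.
#' @return A `model_spec` list.
#' @export
model_spec <- function(response, family = c("poisson", "gaussian"),
                       fixed = character(), random = c("study", "block"),
                       olre = "auto") {
  family <- match.arg(family)
  stopifnot(all(random %in% c("study", "block", "obs")))
  # marginality: every interaction must come with its main effects
  for (t in fixed[grepl(":", fixed)]) {
    parts <- strsplit(t, ":", fixed = TRUE)[[1]]
    if (!all(parts %in% fixed))
      stop(sprintf("interaction '%s' listed without all its main effects", t))
  }
  structure(list(response = response, family = family, fixed = fixed,
                 random = random, olre = olre),
            class = "model_spec")
}

random_formula_parts <- function(random) {
  map <- c(study = "(1 | study_id)", block = "(1 | study_id:block_id)",
           obs = "(1 | obs_id)")
  unname(map[random])
}

#' Fit a generalized linear mixed-effects model by maximum likelihood
#'
#' Poisson responses are fitted by Laplace-approximated maximum likelihood
#' (penalized IRLS for the random-effect modes inside an outer optimization
#' over variance components), Gaussian responses by ML so that
#' log-likelihoods are comparable across nested fixed structures. Random
#' terms whose grouping factor has fewer than two levels in the data are
#' dropped (a single-study Gaussian fit therefore reduces to ordinary least
#' squares). Rows with missing response or covariates are dropped and
#' counted. Singular fits (a variance component at zero) are allowed and
#' flagged; non-convergence is flagged and downstream likelihood-ratio
#' tests refuse such fits.
#'
#' @param data Model data frame (see [prepare_model_data()]).
#' @param spec A [model_spec()].
#' @return A `fit_result`: coefficient table with standard errors, variance
#'   components, maximized log-likelihood, convergence/singularity flags,
#'   dimensions, and the underlying model object.
#' @export
fit_mixed_model <- function(data, spec) {
  stopifnot(inherits(spec, "model_spec"))
  vars <- unique(c(spec$response,
                   unlist(strsplit(spec$fixed, ":", fixed = TRUE)),
                   "study_id",
                   if ("block" %in% spec$random) "block_id"))
  vars <- intersect(vars, names(data))
  keep <- stats::complete.cases(data[, vars, drop = FALSE])
  n_dropped <- sum(!keep)
  d <- droplevels(data[keep, , drop = FALSE])
  if (nrow(d) == 0) stop("no rows with a defined response")
  d$obs_id <- seq_len(nrow(d))
  random <- spec$random
  if (spec$family == "gaussian") random <- setdiff(random, "obs")
  random <- Filter(function(r) {
    g <- switch(r, study = d$study_id,
                block = paste(d$study_id, d$block_id),
                obs = d$obs_id)
    length(unique(g)) >= 2
  }, random)

  fit_once <- function(random_terms) {
    rhs <- c(if (length(spec$fixed)) spec$fixed else "1",
             random_formula_parts(random_terms))
    fml <- stats::reformulate(rhs, response = spec$response)
    warns <- character(0)
    fit <- withCallingHandlers({
      if (length(random_terms) == 0) {
        if (spec$family == "poisson")
          stats::glm(fml, data = d, family = stats::poisson())
        else stats::lm(fml, data = d)
      } else if (spec$family == "poisson") {
        lme4::glmer(fml, data = d, family = stats::poisson(),
                    control = lme4::glmerControl(optimizer = "bobyqa",
                                                 calc.derivs = FALSE))
      } else {
        lme4::lmer(fml, data = d, REML = FALSE,
                   control = lme4::lmerControl(optimizer = "bobyqa",
                                               calc.derivs = FALSE))
      }
    }, warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    }, message = function(m) {
      warns <<- c(warns, conditionMessage(m))
      invokeRestart("muffleMessage")
    })
    list(fit = fit, warns = warns)
  }

  f <- fit_once(random)
  olre_used <- "obs" %in% random
  if (spec$family == "poisson" && length(random) > 0) {
    want_olre <- isTRUE(spec$olre) ||
      (identical(spec$olre, "auto") &&
         pearson_dispersion(f$fit) > 1.5)
    if (want_olre && !olre_used) {
      random <- c(random, "obs")
      f <- fit_once(random)
      olre_used <- TRUE
    }
  }
  fit <- f$fit
  mixed <- inherits(fit, "merMod")
  beta <- if (mixed) lme4::fixef(fit) else stats::coef(fit)
  beta <- beta[!is.na(beta)]
  V <- as.matrix(stats::vcov(fit))[names(beta), names(beta), drop = FALSE]
  vc <- if (mixed) {
    v <- lme4::VarCorr(fit)
    out <- vapply(v, function(m) m[1, 1], numeric(1))
    if (spec$family == "gaussian") out <- c(out, residual = attr(v, "sc")^2)
    out
  } else if (inherits(fit, "lm") && !inherits(fit, "glm")) {
    c(residual = sum(stats::resid(fit)^2) / nrow(d))  # ML residual variance
  } else numeric(0)
  converged <- !any(grepl("convergence|failed to converge|pwrssUpdate|Downdated",
                          f$warns, ignore.case = TRUE))
  singular <- mixed && lme4::isSingular(fit, tol = 1e-5)
  ll <- if (mixed || inherits(fit, "glm")) as.numeric(stats::logLik(fit))
        else ml_loglik_lm(fit)
  structure(list(
    coefficients = data.frame(term = names(beta), estimate = unname(beta),
                              se = sqrt(diag(V)), stringsAsFactors = FALSE),
    vcov = V, varcomp = vc, logLik = ll,
    converged = converged, singular = singular, warnings = f$warns,
    n_fixed = length(beta), n_sites = nrow(d),
    n_studies = length(unique(d$study_id)), n_dropped = n_dropped,
    olre = olre_used, random_used = random,
    spec = spec, data = d, model = fit),
    class = "fit_result")
}

# ML log-likelihood of an lm fit (logLik.lm already uses the ML variance)
ml_loglik_lm <- function(fit) as.numeric(stats::logLik(fit))

pearson_dispersion <- function(fit) {
  r <- stats::residuals(fit, type = "pearson")
  df <- length(r) - length(lme4::fixef(fit))
  sum(r^2) / df
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s mixed model: %d sites, %d studies, logLik %.3f%s%s\n",
              x$spec$family, x$n_sites, x$n_studies, x$logLik,
              if (!x$converged) " [NOT CONVERGED]" else "",
              if (x$singular) " [singular]" else ""))
  print(x$coefficients, row.names = FALSE)
  if (length(x$varcomp)) {
    cat("variance components:\n")
    print(round(x$varcomp, 5))
  }
  invisible(x)
}

#' Likelihood-ratio test between nested fits
#'
#' `chi^2 = 2 (l_full - l_reduced)` referred to a chi-square distribution
#' with degrees of freedom equal to the difference in fixed-effect parameter
#' counts. Both fits must be converged maximum-likelihood fits of the same
#' family on the same rows with the same random structure, and the reduced
#' fixed terms must be a subset of the full ones. A log-likelihood that
#' decreases when terms are added (beyond optimizer tolerance) signals a
#' failed fit and raises an error.
#'
#' @param full,reduced `fit_result` objects.
#' @return An `lrt_result` list: `chi_square`, `df`, `p_value`.
#' @export
likelihood_ratio_test <- function(full, reduced) {
  stopifnot(inherits(full, "fit_result"), inherits(reduced, "fit_result"))
  if (!full$converged || !reduced$converged)
    stop("refusing a likelihood-ratio test on a non-converged fit")
  if (!all(reduced$spec$fixed %in% full$spec$fixed))
    stop("reduced fixed terms are not a subset of the full terms")
  if (!identical(full$spec$family, reduced$spec$family))
    stop("families differ")
  if (full$n_sites != reduced$n_sites)
    stop("fits use different numbers of rows; refit on common data")
  chisq <- 2 * (full$logLik - reduced$logLik)
  if (chisq < -1e-3 * max(1, abs(full$logLik)))
    stop("log-likelihood decreased when terms were added; refit required")
  chisq <- max(chisq, 0)
  df <- full$n_fixed - reduced$n_fixed
  if (df < 1) stop("models do not differ in fixed-effect parameters")
  structure(list(chi_square = chisq, df = df,
                 p_value = stats::pchisq(chisq, df, lower.tail = FALSE)),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT: chi-square = %.3f, df = %d, P = %.4g\n",
              x$chi_square, x$df, x$p_value))
  invisible(x)
}

# terms currently droppable: not protected by `keep`, and not a component of
# any remaining interaction (interactions are dropped before their mains)
droppable_terms <- function(fixed, keep) {
  cand <- setdiff(fixed, keep)
  Filter(function(t) {
    parts_t <- strsplit(t, ":", fixed = TRUE)[[1]]
    !any(vapply(setdiff(fixed, t), function(u) {
      parts_u <- strsplit(u, ":", fixed = TRUE)[[1]]
      length(parts_u) > length(parts_t) && all(parts_t %in% parts_u)
    }, logical(1)))
  }, cand)
}

#' Backward elimination of fixed effects by likelihood-ratio tests
#'
#' Repeatedly tests every currently droppable fixed-effect term (a term is
#' droppable when it is not protected by `keep` and no retained interaction
#' contains it, so interactions always leave before their main effects),
#' drops the term with the highest P-value if that P is at least `alpha`,
#' and stops when every droppable term has P below `alpha`. All fits are by
#' maximum likelihood on the full fit's rows.
#'
#' @param data Model data frame.
#' @param spec Starting [model_spec()].
#' @param alpha Retention threshold, default 0.05.
#' @param keep Terms never tested for elimination (the term of interest).
#' @return List: final `spec`, final `fit`, and `trace` — one row per test
#'   with the term, chi-square, df, P and whether it was dropped.
#' @export
backward_eliminate <- function(data, spec, alpha = 0.05, keep = character()) {
  fit <- fit_mixed_model(data, spec)
  # fix the row set so every nested fit is on identical data
  data <- fit$data
  trace <- list()
  repeat {
    cands <- droppable_terms(spec$fixed, keep)
    if (length(cands) == 0) break
    tests <- lapply(cands, function(t) {
      red_spec <- spec
      red_spec$fixed <- setdiff(spec$fixed, t)
      red <- fit_mixed_model(data, red_spec)
      list(term = t, spec = red_spec, fit = red,
           lrt = likelihood_ratio_test(fit, red))
    })
    p <- vapply(tests, function(x) x$lrt$p_value, numeric(1))
    worst <- which.max(p)
    dropped <- p[worst] >= alpha
    for (i in seq_along(tests))
      trace[[length(trace) + 1]] <- data.frame(
        term = tests[[i]]$term, chi_square = tests[[i]]$lrt$chi_square,
        df = tests[[i]]$lrt$df, p_value = tests[[i]]$lrt$p_value,
        dropped = dropped && i == worst, stringsAsFactors = FALSE)
    if (!dropped) break
    spec <- tests[[worst]]$spec
    fit <- tests[[worst]]$fit
  }
  list(spec = spec, fit = fit,
       trace = if (length(trace)) do.call(rbind, trace) else
         data.frame(term = character(), chi_square = numeric(), df = integer(),
                    p_value = numeric(), dropped = logical()))
}

# resolve a term to a single coefficient name (factor terms expand; unique
# prefix match accepted)
resolve_coef <- function(fit, term) {
  nm <- fit$coefficients$term
  if (term %in% nm) return(term)
  hits <- nm[startsWith(nm, term)]
  if (length(hits) == 1) return(hits)
  if (length(hits) == 0)
    stop(sprintf("term '%s' not found among coefficients: %s",
                 term, paste(nm, collapse = ", ")))
  stop(sprintf("term '%s' is ambiguous; matches: %s", term,
               paste(hits, collapse = ", ")))
}

#' Back-transformed percentage difference for one coefficient
#'
#' For a log-link or log-transformed-response model the coefficient `beta`
#' of a contrast is a log ratio; the percentage difference is
#' `100 (exp(beta) - 1)` with the 95% Wald interval
#' `100 (exp(beta +/- 1.96 se) - 1)`. With `negate = TRUE` the coefficient's
#' sign is flipped first (used to report endemicity, modelled through its
#' reciprocal's logarithm).
#'
#' @param fit A `fit_result` from a log-link/log-response model.
#' @param term Coefficient name, or unique prefix (e.g. `"protected"`).
#' @param negate Flip the coefficient sign before back-transforming.
#' @return A one-row data frame: `label`, `estimate` (log scale), `se`,
#'   `percent_difference`, `ci_low`, `ci_high` (all % scale).
#' @export
percent_difference <- function(fit, term, negate = FALSE) {
  cf <- resolve_coef(fit, term)
  i <- match(cf, fit$coefficients$term)
  beta <- fit$coefficients$estimate[i]
  se <- fit$coefficients$se[i]
  if (negate) beta <- -beta
  pct <- function(b) 100 * (exp(b) - 1)
  data.frame(label = cf, estimate = beta, se = se,
             percent_difference = pct(beta),
             ci_low = pct(beta - 1.96 * se),
             ci_high = pct(beta + 1.96 * se),
             stringsAsFactors = FALSE)
}

#' Assemble the modelling data frame
#'
#' Joins the per-site measures to the classified (or matched) site table and
#' builds everything the model formulas reference: the protection factor
#' (reference `unprotected`), the land-use factor (reference `primary`),
#' management and size/age factors, the latitudinal zone (tropical within
#' 23.43665 degrees of the equator), z-scored confounders, and the
#' transformed responses `log_abundance = ln(N + 1)`,
#' `log_rarefied = ln(E[S_n] + 1)` and `log_cwm = ln(CWM log10 range)`.
#'
#' @param measures Output of [compute_site_measures()].
#' @param sites_classified Output of [assign_protection()].
#' @return Model data frame, one row per site.
#' @export
prepare_model_data <- function(measures, sites_classified) {
  d <- merge(measures, sites_classified[, setdiff(names(sites_classified), "study_id")],
             by = "site_id", sort = TRUE)
  d$protected <- factor(ifelse(d$protected, "protected", "unprotected"),
                        levels = c("unprotected", "protected"))
  d$land_use <- factor(d$land_use,
                       levels = intersect(land_use_classes(), unique(d$land_use)))
  d$use_intensity <- factor(d$use_intensity, levels = use_intensity_classes())
  if (!is.factor(d$management_group))
    d$management_group <- factor(d$management_group, levels = management_groups())
  if (!is.factor(d$size_age_class))
    d$size_age_class <- factor(d$size_age_class, levels = size_age_classes())
  d$latitudinal_zone <- factor(latitudinal_zone(d$latitude),
                               levels = c("temperate", "tropical"))
  d$taxonomic_group <- factor(d$taxonomic_group)
  for (v in c("elevation", "slope", "agri_suitability"))
    d[[v]] <- as.numeric(scale(d[[v]]))
  d$log_abundance <- log(d$N + 1)
  d$log_rarefied <- log(d$rarefied_richness + 1)
  d$log_cwm <- log(d$cwm_log_range)
  d
}

measure_definitions <- function() {
  list(
    richness = list(column = "S", family = "poisson", negate = FALSE),
    abundance = list(column = "log_abundance", family = "gaussian", negate = FALSE),
    rarefied_richness = list(column = "log_rarefied", family = "gaussian", negate = FALSE),
    endemicity = list(column = "log_cwm", family = "gaussian", negate = TRUE))
}

confounder_terms <- function() c("elevation", "slope", "agri_suitability")

# per-land-use protection contrasts from a protection x land-use fit:
# beta_protection (+ beta_interaction for non-reference land uses)
protection_by_land_use <- function(fit, negate = FALSE) {
  lus <- levels(fit$data$land_use)
  prot <- resolve_coef(fit, "protectedprotected")
  nm <- fit$coefficients$term
  est <- stats::setNames(fit$coefficients$estimate, nm)
  rows <- lapply(lus, function(lu) {
    int <- paste0(prot, ":land_use", lu)
    sel <- if (lu == lus[1]) prot else c(prot, int)
    if (!all(sel %in% nm)) return(NULL)  # inestimable cell, dropped upstream
    b <- sum(est[sel])
    v <- sum(fit$vcov[sel, sel])
    if (negate) b <- -b
    pct <- function(x) 100 * (exp(x) - 1)
    data.frame(label = paste0("protected:", lu), land_use = lu,
               estimate = b, se = sqrt(v), percent_difference = pct(b),
               ci_low = pct(b - 1.96 * sqrt(v)),
               ci_high = pct(b + 1.96 * sqrt(v)), stringsAsFactors = FALSE)
  })
  missing <- lus[vapply(rows, is.null, logical(1))]
  if (length(missing) > 0)
    warning(sprintf("inestimable protection contrast in land use(s): %s",
                    paste(missing, collapse = ", ")))
  do.call(rbind, rows)
}

#' Fit the full model suite for every defined biodiversity measure
#'
#' For each measure with a defined response the suite runs, on the all-sites
#' data: the protection-only model, the four-level management-category
#' model, and the protection x land-use interaction model; and on the
#' matched-sites data (when supplied): the protection re-run and the
#' five-level size/age-class model. Every model carries the three
#' confounders, which are backward-eliminated; the term of interest is never
#' tested for elimination, and its reported chi-square comes from a single
#' likelihood-ratio test of the final model with and without it. Contrasts
#' are back-transformed to the percentage scale (endemicity's sign is
#' flipped, see [percent_difference()]).
#'
#' @param model_data All-sites model data from [prepare_model_data()].
#' @param matched_data Optional matched-sites model data.
#' @param models Which model families to run.
#' @param alpha Elimination threshold.
#' @return A `measure_suite`: nested list `$fits[[measure]][[model]]` (each
#'   with `fit`, `lrt`, `trace`, `contrasts`) and a tidy `$contrasts` data
#'   frame across everything.
#' @export
fit_measure_suite <- function(model_data, matched_data = NULL,
                              models = c("protection", "management",
                                         "protection_land_use",
                                         if (!is.null(matched_data))
                                           c("protection_matched", "size_age")),
                              alpha = 0.05) {
  defs <- measure_definitions()
  out <- list()
  rows <- list()
  for (m in names(defs)) {
    def <- defs[[m]]
    if (!any(is.finite(model_data[[def$column]]))) next  # undefined measure
    out[[m]] <- list()
    for (mod in models) {
      dat <- if (mod %in% c("protection_matched", "size_age")) matched_data else model_data
      if (is.null(dat) || !any(is.finite(dat[[def$column]]))) next
      focal <- switch(mod,
        protection = , protection_matched = "protected",
        management = "management_group",
        protection_land_use = "protected:land_use",
        size_age = "size_age_class")
      fixed <- switch(mod,
        protection = , protection_matched = c("protected", confounder_terms()),
        management = c("management_group", confounder_terms()),
        protection_land_use = c("protected", "land_use", "protected:land_use",
                                confounder_terms()),
        size_age = c("size_age_class", confounder_terms()))
      keep <- setdiff(fixed, confounder_terms())
      res <- tryCatch({
        spec <- model_spec(def$column, def$family, fixed = fixed)
        elim <- backward_eliminate(dat, spec, alpha = alpha, keep = keep)
        red_spec <- elim$spec
        red_spec$fixed <- setdiff(red_spec$fixed, c(focal,
          if (mod == "protection_land_use") "protected:land_use"))
        red <- fit_mixed_model(elim$fit$data, red_spec)
        lrt <- likelihood_ratio_test(elim$fit, red)
        contrasts <- if (mod == "protection_land_use")
          protection_by_land_use(elim$fit, negate = def$negate)
        else {
          lev <- switch(mod, management = paste0("management_group",
                                                 management_groups()[-1]),
                        size_age = paste0("size_age_class",
                                          intersect(size_age_classes()[-1],
                                                    levels(droplevels(elim$fit$data$size_age_class)))),
                        "protected")
          do.call(rbind, lapply(lev, function(l)
            tryCatch(percent_difference(elim$fit, l, negate = def$negate),
                     error = function(e) NULL)))
        }
        list(fit = elim$fit, lrt = lrt, trace = elim$trace, contrasts = contrasts)
      }, error = function(e) {
        warning(sprintf("model '%s' for measure '%s' failed: %s", mod, m,
                        conditionMessage(e)))
        NULL
      })
      if (is.null(res)) next
      out[[m]][[mod]] <- res
      if (!is.null(res$contrasts) && nrow(res$contrasts) > 0) {
        cc <- res$contrasts
        cc$measure <- m
        cc$model <- mod
        cc$n_sites <- res$fit$n_sites
        rows[[length(rows) + 1]] <- cc
      }
    }
  }
  contrasts <- if (length(rows)) {
    cols <- c("measure", "model", "label", "estimate", "se",
              "percent_difference", "ci_low", "ci_high", "n_sites")
    do.call(rbind, lapply(rows, function(x) x[, cols]))
  } else NULL
  structure(list(fits = out, contrasts = contrasts), class = "measure_suite")
}

#' @export
print.measure_suite <- function(x, ...) {
  cat(sprintf("measure_suite: %d measures modelled\n", length(x$fits)))
  if (!is.null(x$contrasts))
    print(x$contrasts, row.names = FALSE, digits = 4)
  invisible(x)
}
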