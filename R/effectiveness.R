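#' Area-weighted inside/outside ratio across land uses
#'
#' Aggregates per-land-use inside/outside biodiversity ratios into a single
#' global ratio, weighting each land use by the proportion of global
#' terrestrial area it occupies. The default is the weighted arithmetic mean
#' `rho = sum(w_l * rho_l)`. The ratio-of-weighted-means variant
#' `sum(w_l * i_l) / sum(w_l * o_l)` needs the relative outside biodiversity
#' level per land use and is available through `outside_levels`.
#'
#' @param ratios Positive per-land-use ratios `rho_l`.
#' @param weights Non-negative weights summing to 1 (tolerance 1e-9).
#' @param outside_levels Optional positive relative outside biodiversity
#'   levels `o_l`; when supplied the ratio-of-weighted-means is returned.
#' @return The aggregated ratio `rho`.
#' @export
weighted_ratio <- function(ratios, weights, outside_levels = NULL) {
  if (length(ratios) != length(weights))
    stop("ratios and weights must have equal length")
  if (any(!is.finite(ratios)) || any(ratios <= 0))
    stop("all ratios must be finite and > 0")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-9)
    stop(sprintf("weights must sum to 1 (got %.12f)", sum(weights)))
  if (is.null(outside_levels)) return(sum(weights * ratios))
  if (any(!is.finite(outside_levels)) || any(outside_levels <= 0))
    stop("outside_levels must be finite and > 0")
  sum(weights * ratios * outside_levels) / sum(weights * outside_levels)
}

#' Solve the global-state equation for inside and outside biodiversity
#'
#' Given the aggregated inside/outside ratio `rho = i / o`, the protected
#' fraction of land `a` and the global average proportional loss of
#' site-level biodiversity relative to pristine `r`, solves
#' `1 - r = a i + (1 - a) o` for the biodiversity levels inside (`i`) and
#' outside (`o`) protected areas, both as proportions of pristine:
#' `o = (1 - r) / (1 + a (rho - 1))`, `i = rho o`.
#'
#' @param rho Aggregated inside/outside ratio, > 0.
#' @param a Protected fraction of terrestrial area, in `[0, 1)`.
#' @param r Global proportional biodiversity loss relative to pristine,
#'   `< 1`.
#' @return List with `i` and `o`; satisfies the global-state equation to
#'   machine precision.
#' @export
solve_io <- function(rho, a, r) {
  if (!is.finite(rho) || rho <= 0) stop("rho must be finite and > 0")
  if (!is.finite(a) || a < 0 || a >= 1) stop("a must lie in [0, 1)")
  if (!is.finite(r) || r >= 1) stop("r must be < 1")
  denom <- 1 + a * (rho - 1)
  if (denom <= 0) stop("infeasible inputs: 1 + a (rho - 1) must be > 0")
  o <- (1 - r) / denom
  list(i = rho * o, o = o)
}

#' Protected-area effectiveness from inside and outside levels
#'
#' `e = 1 - (1 - i) / (1 - o)`: 0 when protected sites hold no more
#' biodiversity than unprotected ones, 1 (100%) when protected sites are as
#' rich as pristine ones; the scale is bounded at neither end.
#'
#' @param i,o Site-level biodiversity inside / outside protected areas as
#'   proportions of pristine; `o < 1`.
#' @return Effectiveness as a proportion (0.41 means 41%).
#' @export
effectiveness <- function(i, o) {
  if (!is.finite(i) || !is.finite(o)) stop("i and o must be finite")
  if (o >= 1) stop("effectiveness undefined for o >= 1 (unprotected sites at or above pristine)")
  1 - (1 - i) / (1 - o)
}

#' Effectiveness under an alternative management scenario
#'
#' Re-solves the global-state equation with a scenario ratio `rho*` (for
#' example the inside/outside ratio implied by the most restrictive IUCN
#' management categories) while holding the global state `1 - r` and the
#' protected fraction `a` fixed, and evaluates the effectiveness of that
#' counterfactual network.
#'
#' @param rho_star Scenario inside/outside ratio.
#' @param a,r As in [solve_io()].
#' @return List: `i`, `o`, `e` under the scenario.
#' @export
scenario_effectiveness <- function(rho_star, a, r) {
  io <- solve_io(rho_star, a, r)
  list(i = io$i, o = io$o, e = effectiveness(io$i, io$o))
}

#' Protected-area extent required to match a management scenario
#'
#' How much land would need protection, at the current effect per protected
#' hectare, to reach the same average biodiversity outcome as enforcing the
#' scenario ratio `rho*` across the existing network. The scenario outcome
#' level is defined holding the outside level fixed at its current value
#' (`G* = a rho* o + (1 - a) o`); re-solving with the global state held
#' fixed instead leaves the outcome unchanged by construction and is
#' available via `hold = "global_state"` for completeness (it returns `a`).
#' The required fraction solves `a' i + (1 - a') o = G*`, i.e.
#' `a' = (G* - o) / (i - o) = a (rho* - 1) / (rho - 1)`.
#'
#' @param rho Current aggregated ratio.
#' @param rho_star Scenario ratio.
#' @param a,r As in [solve_io()].
#' @param hold `"outside"` (default) or `"global_state"`.
#' @return List: `a_required`, the scenario outcome level `g_star`, and the
#'   current `i`, `o`.
#' @export
required_area <- function(rho, rho_star, a, r, hold = c("outside", "global_state")) {
  hold <- match.arg(hold)
  io <- solve_io(rho, a, r)
  g_star <- if (hold == "outside") a * rho_star * io$o + (1 - a) * io$o else 1 - r
  if (abs(io$i - io$o) < 1e-300) {
    if (abs(g_star - io$o) < 1e-12) return(list(a_required = 0, g_star = g_star,
                                                i = io$i, o = io$o))
    stop("infeasible: current network has no effect (i = o) but the scenario outcome differs")
  }
  list(a_required = (g_star - io$o) / (io$i - io$o), g_star = g_star,
       i = io$i, o = io$o)
}

#' Full effectiveness analysis with Monte Carlo confidence intervals
#'
#' Point estimates of `rho`, `i`, `o`, `e` (and, when a scenario ratio is
#' supplied, `e*` and the required area `a'`) from per-land-use log-ratio
#' estimates, with uncertainty propagated by parametric Monte Carlo: each
#' draw samples every land use's log ratio from a normal with its estimated
#' mean and standard error (the coefficient sampling distribution on the
#' link scale), pushes the draw through the whole algebra, and the 2.5/97.5
#' percentiles of the draws give the interval.
#'
#' @param ratio_table Data frame with columns `land_use`, `estimate` (log
#'   inside/outside ratio) and `se`.
#' @param weights Named numeric of global terrestrial-area proportions per
#'   land use; reordered to match `ratio_table` and must cover it.
#' @param a Protected fraction of land (default 0.154, the global figure).
#' @param r Global proportional biodiversity loss relative to pristine
#'   (default 0.136, an external estimate supplied as input).
#' @param scenario_table Optional data frame like `ratio_table` giving the
#'   scenario (e.g. most-restrictive-management) log ratio; a single row is
#'   recycled across land uses.
#' @param n_draws Monte Carlo draws (default 10000).
#' @param seed Seed for the draws.
#' @return An `effectiveness_result` list: point estimates, 95% CI per
#'   quantity, and the input echo.
#' @export
effectiveness_analysis <- function(ratio_table, weights, a = 0.154, r = 0.136,
                                   scenario_table = NULL, n_draws = 10000,
                                   seed = 1L) {
  stopifnot(all(c("land_use", "estimate", "se") %in% names(ratio_table)))
  w <- weights[ratio_table$land_use]
  if (any(is.na(w)))
    stop("weights missing for land use(s): ",
         paste(setdiff(ratio_table$land_use, names(weights)), collapse = ", "))
  w <- w / sum(w)  # renormalise over the land uses actually estimated
  point <- function(logr, logr_star = NULL) {
    rho <- weighted_ratio(exp(logr), w)
    io <- solve_io(rho, a, r)
    out <- list(rho = rho, i = io$i, o = io$o, e = effectiveness(io$i, io$o))
    if (!is.null(logr_star)) {
      rho_s <- weighted_ratio(exp(logr_star), w)
      out$rho_star <- rho_s
      out$e_star <- scenario_effectiveness(rho_s, a, r)$e
      out$a_required <- required_area(rho, rho_s, a, r)$a_required
    }
    out
  }
  star_mean <- NULL
  if (!is.null(scenario_table)) {
    star_mean <- if (nrow(scenario_table) == 1)
      rep(scenario_table$estimate, nrow(ratio_table)) else scenario_table$estimate
    star_se <- if (nrow(scenario_table) == 1)
      rep(scenario_table$se, nrow(ratio_table)) else scenario_table$se
  }
  est <- point(ratio_table$estimate, star_mean)
  draws <- with_seed(seed, {
    t(vapply(seq_len(n_draws), function(k) {
      logr <- stats::rnorm(nrow(ratio_table), ratio_table$estimate, ratio_table$se)
      ls <- if (is.null(star_mean)) NULL else stats::rnorm(length(star_mean),
                                                           star_mean, star_se)
      p <- tryCatch(point(logr, ls), error = function(e) NULL)
      if (is.null(p)) rep(NA_real_, length(unlist(est)))
      else unlist(p)
    }, numeric(length(unlist(est)))))
  })
  colnames(draws) <- names(unlist(est))
  ci <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  structure(list(estimates = est, ci = ci, n_draws = n_draws,
                 n_failed_draws = sum(is.na(draws[, 1])),
                 inputs = list(ratio_table = ratio_table, weights = w,
                               a = a, r = r, scenario_table = scenario_table,
                               seed = seed)),
            class = "effectiveness_result")
}

#' @export
print.effectiveness_result <- function(x, ...) {
  e <- x$estimates
  fmt <- function(q) sprintf("%.4g [%.4g, %.4g]", e[[q]],
                             x$ci["2.5%", q], x$ci["97.5%", q])
  cat("protected-area effectiveness (point [95% MC CI]):\n")
  cat("  rho (i/o):      ", fmt("rho"), "\n")
  cat("  i, o:           ", fmt("i"), ", ", fmt("o"), "\n", sep = "")
  cat("  effectiveness e:", fmt("e"), "\n")
  if (!is.null(e$e_star)) {
    cat("  scenario e*:    ", fmt("e_star"), "\n")
    cat("  required area a':", fmt("a_required"), "\n")
  }
  invisible(x)
}

#' Default global land-use area weights
#'
#' Proportions of global terrestrial area in each of the eight land-use
#' classes, used to weight per-land-use inside/outside ratios. These are
#' round figures consistent with global land-cover syntheses (about 30%
#' little-disturbed primary vegetation, 20% secondary regrowth, 4%
#' plantation, 15% cropland, 28% pasture, 3% urban); they are inputs, not
#' estimates, and can be overridden wherever weights are accepted.
#'
#' @return Named numeric summing to 1.
#' @export
default_land_use_weights <- function() {
  c(primary = 0.30, secondary_mature = 0.07, secondary_intermediate = 0.07,
    secondary_young = 0.06, plantation = 0.04, cropland = 0.15,
    pasture = 0.28, urban = 0.03)
}
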