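#' Build and validate a run configuration
#'
#' Exactly one of `input_dir` (a bundle on disk) or `synthetic` (a
#' [world_config()]) must be given. The seed is fanned out to per-stage
#' child seeds by fixed offsets, so stages re-run in isolation reproduce the
#' pipeline's behaviour.
#'
#' @param input_dir Directory with `sites.csv`, `community.csv`,
#'   `ranges.csv`, `protected_areas.geojson`.
#' @param synthetic A [world_config()] to generate the inputs instead.
#' @param out_dir Output directory.
#' @param seed Run seed (drives generation and Monte Carlo draws).
#' @param reference_year Year for protected-area age, default 2014.
#' @param match_intensity Match on land use x intensity instead of land use.
#' @param models Model set passed to [fit_measure_suite()].
#' @param weights Land-use area weights for the effectiveness stage.
#' @param a,r Protected land fraction and global biodiversity loss.
#' @param n_draws Monte Carlo draws for effectiveness intervals.
#' @return A validated `run_config` list.
#' @export
run_config <- function(input_dir = NULL, synthetic = NULL, out_dir = tempfile("paeffect_run_"),
                       seed = 1L, reference_year = 2014, match_intensity = FALSE,
                       models = c("protection", "management", "protection_land_use",
                                  "protection_matched", "size_age"),
                       weights = default_land_use_weights(), a = 0.154, r = 0.136,
                       n_draws = 10000) {
  if (is.null(input_dir) == is.null(synthetic))
    stop("exactly one of 'input_dir' and 'synthetic' must be given")
  if (!is.null(synthetic) && !inherits(synthetic, "world_config"))
    synthetic <- do.call(world_config, synthetic)
  structure(list(input_dir = input_dir, synthetic = synthetic,
                 out_dir = out_dir, seed = as.integer(seed),
                 reference_year = reference_year,
                 match_intensity = isTRUE(match_intensity), models = models,
                 weights = weights, a = a, r = r, n_draws = n_draws),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' @param path A `.yaml`/`.yml` or `.json` file whose top-level keys are
#'   [run_config()] arguments (`synthetic` may be a list of [world_config()]
#'   arguments).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$synthetic)) {
    for (f in c("sites_per_study", "taxon_pool_size", "occupancy_range",
                "protection_effect", "land_use_effects", "confounder_effects",
                "range_size_distribution", "abundance_distribution"))
      if (!is.null(cfg$synthetic[[f]])) cfg$synthetic[[f]] <- unlist(cfg$synthetic[[f]])
  }
  if (!is.null(cfg$weights)) cfg$weights <- unlist(cfg$weights)
  do.call(run_config, cfg)
}

#' Validate an input bundle
#'
#' A reporting operation: checks referential integrity (community rows
#' reference known sites and taxa with range entries), coordinate ranges,
#' the eight-class land-use vocabulary, the three-class use-intensity
#' vocabulary, measurement coding and GeoJSON validity, and returns a
#' machine-readable issue list instead of raising.
#'
#' @param x A bundle directory path or a `synthetic_world`-shaped list.
#' @return Data frame with columns `stage`, `type`, `message`; zero rows
#'   means a clean bundle.
#' @export
validate_inputs <- function(x) {
  issues <- list()
  add <- function(stage, type, message)
    issues[[length(issues) + 1]] <<- data.frame(stage = stage, type = type,
                                                message = message,
                                                stringsAsFactors = FALSE)
  world <- if (is.character(x)) {
    tryCatch(read_world(x), error = function(e) {
      add("read", "io", conditionMessage(e))
      NULL
    })
  } else x
  if (!is.null(world)) {
    s <- world$sites; cm <- world$community; rg <- world$ranges
    for (bad in setdiff(unique(cm$site_id), s$site_id))
      add("community", "referential_integrity",
          sprintf("community row references unknown site '%s'", bad))
    for (bad in setdiff(unique(cm$taxon_id), rg$taxon_id))
      add("community", "referential_integrity",
          sprintf("taxon '%s' has no range entry", bad))
    if (any(s$longitude < -180 | s$longitude > 180, na.rm = TRUE) ||
        any(s$latitude < -90 | s$latitude > 90, na.rm = TRUE))
      add("sites", "coordinates", "coordinates outside WGS84 bounds")
    for (bad in setdiff(unique(s$land_use), land_use_classes()))
      add("sites", "vocabulary", sprintf("unknown land use '%s'", bad))
    for (bad in setdiff(unique(s$use_intensity), use_intensity_classes()))
      add("sites", "vocabulary", sprintf("unknown use intensity '%s'", bad))
    for (bad in setdiff(unique(cm$measurement_type), c("abundance", "occurrence")))
      add("community", "vocabulary", sprintf("unknown measurement type '%s'", bad))
    if (any(cm$measurement < 0, na.rm = TRUE))
      add("community", "values", "negative measurement")
    occ <- cm$measurement_type == "occurrence"
    if (any(!cm$measurement[occ] %in% c(0, 1)))
      add("community", "values", "occurrence rows must be coded 0/1")
    if (any(rg$range_km2 <= 0, na.rm = TRUE))
      add("ranges", "values", "range_km2 must be > 0")
    for (pa in world$protected_areas)
      for (ring in pa$rings)
        if (nrow(ring) < 4 || any(ring[1, ] != ring[nrow(ring), ]))
          add("protected_areas", "geometry",
              sprintf("unclosed ring in '%s'", pa$pa_id))
  }
  if (length(issues) == 0)
    data.frame(stage = character(), type = character(), message = character(),
               stringsAsFactors = FALSE)
  else do.call(rbind, issues)
}

config_hash <- function(cfg) {
  js <- jsonlite::toJSON(cfg[setdiff(names(cfg), "out_dir")],
                         auto_unbox = TRUE, digits = 10, force = TRUE)
  v <- utf8ToInt(as.character(js))
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}

#' Run the full analysis pipeline
#'
#' Generates (or reads) the input bundle, validates it, computes the four
#' site-level measures, assigns protection and builds the matched-sites
#' subset, fits the all-sites and matched-sites model suites, runs the
#' effectiveness algebra for richness and abundance (with the
#' most-restrictive-management contrast as the scenario ratio when the
#' management model estimated one), and writes every stage output plus a
#' `report.md` with a provenance block into `config$out_dir`. Collected
#' warnings go into the report. Identical config and seed give identical
#' outputs (modulo the report timestamp).
#'
#' @param config A [run_config()].
#' @return A `pipeline_result` list with all stage outputs, invisibly
#'   written to disk.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  warn_log <- character(0)
  collect <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warn_log <<- c(warn_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))

  world <- stage("inputs", {
    if (!is.null(config$synthetic)) {
      cfg <- config$synthetic
      cfg$random_seed <- child_seed(config$seed, 1L)
      w <- generate_world(cfg)
      write_world(w, config$out_dir)
      w
    } else read_world(config$input_dir)
  })
  issues <- stage("validate", validate_inputs(world))
  if (nrow(issues) > 0)
    stop(sprintf("pipeline stage 'validate' failed: %d issue(s), first: %s",
                 nrow(issues), issues$message[1]), call. = FALSE)

  measures <- stage("measures", collect(compute_site_measures(world)))
  utils::write.csv(measures, file.path(config$out_dir, "site_measures.csv"),
                   row.names = FALSE)

  classified <- stage("spatial", collect(
    assign_protection(world$sites, world$protected_areas,
                      reference_year = config$reference_year)))
  utils::write.csv(classified, file.path(config$out_dir, "sites_classified.csv"),
                   row.names = FALSE)
  matched <- stage("spatial", match_sites_by_land_use(
    classified, match_intensity = config$match_intensity))
  utils::write.csv(matched, file.path(config$out_dir, "sites_matched.csv"),
                   row.names = FALSE)

  model_data <- stage("glmm", prepare_model_data(measures, classified))
  matched_data <- if (nrow(matched) > 0)
    stage("glmm", prepare_model_data(
      measures[measures$site_id %in% matched$site_id, , drop = FALSE], matched))
  else NULL
  suite <- stage("glmm", collect(fit_measure_suite(
    model_data, matched_data, models = config$models)))
  if (!is.null(suite$contrasts))
    utils::write.csv(suite$contrasts, file.path(config$out_dir, "contrasts.csv"),
                     row.names = FALSE)
  write_fits_json(suite, file.path(config$out_dir, "fits.json"))

  eff <- stage("effectiveness", collect({
    out <- list()
    for (m in c("richness", "abundance")) {
      plu <- suite$fits[[m]][["protection_land_use"]]
      if (is.null(plu) || is.null(plu$contrasts) || nrow(plu$contrasts) == 0) next
      rt <- plu$contrasts[, c("land_use", "estimate", "se")]
      mg <- suite$fits[[m]][["management"]]
      sc <- NULL
      if (!is.null(mg) && !is.null(mg$contrasts)) {
        row <- mg$contrasts[mg$contrasts$label == "management_groupI-II", , drop = FALSE]
        if (nrow(row) == 1) sc <- row[, c("estimate", "se")]
      }
      out[[m]] <- effectiveness_analysis(
        rt, config$weights, a = config$a, r = config$r, scenario_table = sc,
        n_draws = config$n_draws, seed = child_seed(config$seed, 3L))
    }
    out
  }))
  if (length(eff) > 0)
    jsonlite::write_json(
      lapply(eff, function(x) list(estimates = x$estimates,
                                   ci = as.data.frame(x$ci),
                                   inputs = x$inputs[c("a", "r", "weights")])),
      file.path(config$out_dir, "effectiveness.json"),
      auto_unbox = TRUE, digits = NA)

  result <- structure(list(world = world, measures = measures,
                           classified = classified, matched = matched,
                           suite = suite, effectiveness = eff,
                           warnings = warn_log, config = config),
                      class = "pipeline_result")
  write_report(result, file.path(config$out_dir, "report.md"))
  invisible(result)
}

write_fits_json <- function(suite, path) {
  out <- lapply(suite$fits, function(models) lapply(models, function(res) {
    list(coefficients = res$fit$coefficients,
         varcomp = as.list(res$fit$varcomp),
         logLik = res$fit$logLik, converged = res$fit$converged,
         singular = res$fit$singular, n_sites = res$fit$n_sites,
         n_studies = res$fit$n_studies,
         lrt = unclass(res$lrt), trace = res$trace)
  }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
}

write_report <- function(result, path) {
  cfg <- result$config
  ln <- character(0)
  p <- function(...) ln <<- c(ln, sprintf(...))
  p("# Protected-area effect analysis report")
  p("")
  p("## Data")
  p("- sites: %d in %d studies (%d protected, %d unprotected)",
    nrow(result$classified), length(unique(result$classified$study_id)),
    sum(result$classified$protected), sum(!result$classified$protected))
  p("- matched-sites subset: %d sites in %d studies",
    nrow(result$matched), length(unique(result$matched$study_id)))
  for (m in names(measure_definitions())) {
    col <- c(richness = "S", abundance = "N", rarefied_richness = "rarefied_richness",
             endemicity = "endemicity")[m]
    p("- %s: defined for %d sites", m, sum(is.finite(result$measures[[col]])))
  }
  p("")
  p("## Contrasts (%% difference, protected vs unprotected)")
  if (!is.null(result$suite$contrasts)) {
    cc <- result$suite$contrasts
    p("")
    p("| measure | model | contrast | %% diff | 95%% CI | n sites |")
    p("|---|---|---|---|---|---|")
    for (i in seq_len(nrow(cc)))
      p("| %s | %s | %s | %.1f | %.1f to %.1f | %d |", cc$measure[i], cc$model[i],
        cc$label[i], cc$percent_difference[i], cc$ci_low[i], cc$ci_high[i],
        cc$n_sites[i])
  } else p("(no estimable contrasts)")
  p("")
  p("## Likelihood-ratio tests and elimination traces")
  for (m in names(result$suite$fits)) for (mod in names(result$suite$fits[[m]])) {
    res <- result$suite$fits[[m]][[mod]]
    p("- %s / %s: chi-square = %.2f, df = %d, P = %.4g; %d elimination test(s)",
      m, mod, res$lrt$chi_square, res$lrt$df, res$lrt$p_value, nrow(res$trace))
  }
  p("")
  p("## Effectiveness")
  if (length(result$effectiveness) > 0) {
    for (m in names(result$effectiveness)) {
      x <- result$effectiveness[[m]]
      e <- x$estimates
      p("- %s: e = %.1f%% [%.1f, %.1f]; rho = %.4f; i = %.4f, o = %.4f",
        m, 100 * e$e, 100 * x$ci["2.5%", "e"], 100 * x$ci["97.5%", "e"],
        e$rho, e$i, e$o)
      if (!is.null(e$e_star))
        p("  - restrictive-management scenario: e* = %.1f%%; required area a' = %.1f%%",
          100 * e$e_star, 100 * e$a_required)
    }
  } else p("(not computed)")
  p("")
  p("## Warnings")
  if (length(result$warnings) > 0)
    for (w in unique(result$warnings)) p("- %s", w)
  else p("(none)")
  p("")
  p("## Provenance")
  p("- config hash: %s", config_hash(unclass(cfg)))
  p("- seed: %d", cfg$seed)
  p("- R version: %s; paeffect %s", as.character(getRversion()),
    as.character(utils::packageVersion("paeffect")))
  p("- generated: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  writeLines(ln, path)
  invisible(path)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: %d sites, %d matched, %d measure(s) modelled, %d warning(s)\n",
              nrow(x$classified), nrow(x$matched), length(x$suite$fits),
              length(x$warnings)))
  invisible(x)
}

#' Forest plot of protection contrasts
#'
#' A basic forest plot (percentage difference with 95% CI per contrast,
#' panelled by measure) of a suite's contrast table. Requires ggplot2.
#'
#' @param contrasts The `contrasts` data frame of a `measure_suite`.
#' @return A ggplot object.
#' @export
plot_contrasts <- function(contrasts) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  ggplot2::ggplot(contrasts,
                  ggplot2::aes(x = percent_difference, y = label,
                               xmin = ci_low, xmax = ci_high,
                               colour = model)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::facet_wrap(~measure, scales = "free") +
    ggplot2::labs(x = "% difference (protected vs unprotected)", y = NULL) +
    ggplot2::theme_minimal()
}
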