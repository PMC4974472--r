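#' Configuration for a synthetic multi-study world
#'
#' Describes a PREDICTS-like collection of independent field studies, each
#' with its own taxon pool, sampling method (abundance counts or
#' presence/absence) and spatial blocks, with sites straddling the boundary
#' of one protected area per study. The defaults describe a world at the
#' scale of the real all-sites dataset (156 studies, roughly 30% of sites
#' protected) carrying the observed global inside/outside ratios.
#'
#' `protection_effect` gives the *target inside/outside ratio* for each
#' measure: the richness ratio multiplies each taxon's site-occupancy
#' probability inside protected areas, and the abundance ratio is the ratio
#' of expected total abundance (so the per-individual rate factor applied
#' inside is `abundance / richness`).
#'
#' @param n_studies Number of independent studies.
#' @param sites_per_study Integer range `c(min, max)`; each study draws its
#'   site count uniformly from this range.
#' @param taxon_pool_size Integer range `c(min, max)` for the per-study
#'   taxon pool.
#' @param blocks_per_study Number of spatial blocks per study.
#' @param protection_effect Named numeric, elements `richness` and
#'   `abundance`: target inside/outside ratios (both > 0).
#' @param land_use_effects Named numeric multiplicative factor on expected
#'   abundance for each of the eight land-use classes (all > 0).
#' @param confounder_effects Named numeric slopes (`elevation`, `slope`,
#'   `agri_suitability`) on log expected abundance per SD of the covariate.
#' @param confounder_protection_correlation Real in \[-1, 1\]: standardised
#'   mean shift of every confounder inside protected areas, emulating
#'   non-random protected-area placement.
#' @param overdispersion Non-negative; 0 gives Poisson counts, positive
#'   values gamma-mix the Poisson mean (negative binomial with this
#'   dispersion parameter `1/size`).
#' @param range_size_distribution Named numeric `meanlog`, `sdlog` of the
#'   log-normal geographic range-size distribution (km2).
#' @param abundance_distribution Named numeric `meanlog`, `sdlog` of the
#'   log-normal per-taxon expected-count distribution.
#' @param occurrence_fraction Fraction of studies recording only
#'   presence/absence (counts thresholded at >= 1).
#' @param occupancy_range Range `c(min, max)` of per-taxon baseline
#'   site-occupancy probabilities.
#' @param protected_fraction Expected fraction of each study's extent (and
#'   hence of its sites) inside the protected area.
#' @param sigma_study,sigma_block SDs of the study-level and block-level
#'   random intercepts on log expected abundance.
#' @param random_seed Integer seed; fully determines the generated world.
#' @return A `world_config` list, validated.
#' @export
world_config <- function(n_studies = 156,
                         sites_per_study = c(25, 60),
                         taxon_pool_size = c(20, 80),
                         blocks_per_study = 3,
                         protection_effect = c(richness = 1.106, abundance = 1.145),
                         land_use_effects = default_land_use_effects(),
                         confounder_effects = c(elevation = -0.10, slope = -0.05,
                                                agri_suitability = 0.10),
                         confounder_protection_correlation = 0.3,
                         overdispersion = 0,
                         range_size_distribution = c(meanlog = 11.5, sdlog = 2),
                         abundance_distribution = c(meanlog = 0.7, sdlog = 1),
                         occurrence_fraction = 0.2,
                         occupancy_range = c(0.10, 0.60),
                         protected_fraction = 0.3,
                         sigma_study = 0.3,
                         sigma_block = 0.15,
                         random_seed = 1L) {
  cfg <- list(n_studies = n_studies, sites_per_study = sites_per_study,
              taxon_pool_size = taxon_pool_size, blocks_per_study = blocks_per_study,
              protection_effect = protection_effect,
              land_use_effects = land_use_effects,
              confounder_effects = confounder_effects,
              confounder_protection_correlation = confounder_protection_correlation,
              overdispersion = overdispersion,
              range_size_distribution = range_size_distribution,
              abundance_distribution = abundance_distribution,
              occurrence_fraction = occurrence_fraction,
              occupancy_range = occupancy_range,
              protected_fraction = protected_fraction,
              sigma_study = sigma_study, sigma_block = sigma_block,
              random_seed = as.integer(random_seed))
  validate_world_config(cfg)
  class(cfg) <- "world_config"
  cfg
}

#' Default land-use multiplicative effects on expected abundance
#'
#' Primary vegetation is the baseline; human-dominated land uses carry
#' progressively lower expected abundance, a typical land-use gradient in
#' site-level biodiversity syntheses.
#'
#' @return Named numeric of length eight.
#' @export
default_land_use_effects <- function() {
  c(primary = 1.00, secondary_mature = 0.95, secondary_intermediate = 0.90,
    secondary_young = 0.85, plantation = 0.70, cropland = 0.60,
    pasture = 0.65, urban = 0.50)
}

validate_world_config <- function(cfg) {
  stopifnot(length(cfg$n_studies) == 1, cfg$n_studies >= 1)
  for (fld in c("sites_per_study", "taxon_pool_size", "occupancy_range")) {
    r <- cfg[[fld]]
    if (length(r) != 2 || any(!is.finite(r)))
      stop(sprintf("'%s' must be a finite range c(min, max)", fld))
    if (r[1] > r[2])
      stop(sprintf("degenerate range in '%s': min > max", fld))
  }
  if (cfg$sites_per_study[1] < 1 || cfg$taxon_pool_size[1] < 1)
    stop("sites_per_study and taxon_pool_size must be >= 1")
  pe <- cfg$protection_effect
  if (!all(c("richness", "abundance") %in% names(pe)))
    stop("protection_effect needs named elements 'richness' and 'abundance'")
  if (any(!is.finite(pe)) || any(pe <= 0))
    stop("protection_effect factors must be finite and > 0")
  lu <- cfg$land_use_effects
  if (!setequal(names(lu), land_use_classes()))
    stop("land_use_effects must be keyed by exactly the eight land-use classes")
  if (any(!is.finite(lu)) || any(lu <= 0))
    stop("land_use_effects must be finite and > 0")
  if (any(!is.finite(cfg$confounder_effects)))
    stop("confounder_effects must be finite")
  rho <- cfg$confounder_protection_correlation
  if (!is.finite(rho) || rho < -1 || rho > 1)
    stop("confounder_protection_correlation must lie in [-1, 1]")
  if (!is.finite(cfg$overdispersion) || cfg$overdispersion < 0)
    stop("overdispersion must be a non-negative real")
  if (cfg$occurrence_fraction < 0 || cfg$occurrence_fraction > 1)
    stop("occurrence_fraction must lie in [0, 1]")
  if (cfg$protected_fraction <= 0 || cfg$protected_fraction >= 1)
    stop("protected_fraction must lie in (0, 1)")
  if (cfg$occupancy_range[2] * max(pe["richness"], 1) > 1)
    stop("occupancy_range upper bound times the richness factor must not exceed 1")
  invisible(cfg)
}

#' Generate a synthetic multi-study world
#'
#' Builds the full input bundle — site table, long-format community table,
#' species range table and one rectangular protected-area polygon per study —
#' from a known generative model, and records the generating truth. Per
#' study: a taxon pool with log-normal expected counts and uniform baseline
#' occupancies; sites placed uniformly over a 1-degree extent partly covered
#' by the protected area; expected count for a taxon at a site is the pool
#' mean times the land-use factor, the protection factor, the exponentiated
#' confounder term and study/block random intercepts; observed counts are
#' Poisson (gamma-mixed when overdispersion is positive) conditional on a
#' Bernoulli occupancy draw. Inside protected areas every taxon's occupancy
#' probability is multiplied by the richness ratio and the count rate by
#' `abundance ratio / richness ratio`, so the expected inside/outside ratios
#' of site richness and total abundance equal the configured targets.
#'
#' @param config A [world_config()].
#' @return A `synthetic_world`: list with elements `sites`, `community`,
#'   `ranges`, `protected_areas` and `truth` (generating parameters, the true
#'   inside/outside ratio per measure and the true protected-site ids).
#' @export
generate_world <- function(config) {
  validate_world_config(config)
  with_seed(config$random_seed, generate_world_impl(config))
}

generate_world_impl <- function(cfg) {
  f_S <- unname(cfg$protection_effect["richness"])
  f_A <- unname(cfg$protection_effect["abundance"]) / f_S  # per-individual rate
  slopes <- cfg$confounder_effects
  lu_classes <- land_use_classes()
  groups <- c("plants", "invertebrates", "vertebrates")

  n_occ <- round(cfg$occurrence_fraction * cfg$n_studies)
  occ_studies <- if (n_occ > 0) sample.int(cfg$n_studies, n_occ) else integer(0)

  sites_l <- vector("list", cfg$n_studies)
  comm_l <- vector("list", cfg$n_studies)
  range_l <- vector("list", cfg$n_studies)
  pas <- vector("list", cfg$n_studies)
  protected_sites <- character(0)

  # disjoint 1-degree study extents on a 2-degree grid, so no site can fall
  # into another study's protected area and the truth labels stay exact
  cells <- expand.grid(x = seq(-170, 168, by = 2), y = seq(-55, 63, by = 2))
  if (cfg$n_studies > nrow(cells))
    stop(sprintf("at most %d studies are supported", nrow(cells)))
  cells <- cells[sample.int(nrow(cells), cfg$n_studies), , drop = FALSE]

  for (j in seq_len(cfg$n_studies)) {
    sid <- sprintf("S%03d", j)
    n_sites <- sample_range(cfg$sites_per_study)
    n_taxa <- sample_range(cfg$taxon_pool_size)
    is_occ <- j %in% occ_studies

    # study extent: 1 x 1 degree box; PA rectangle covers the western strip
    x0 <- cells$x[j]
    y0 <- cells$y[j]
    pa_width <- cfg$protected_fraction
    pa_id <- sprintf("PA%03d", j)
    ring <- cbind(lon = c(x0, x0 + pa_width, x0 + pa_width, x0, x0),
                  lat = c(y0, y0, y0 + 1, y0 + 1, y0))
    iucn <- sample(c("Ia", "Ib", "II", "III", "IV", "V", "VI", "unknown"), 1,
                   prob = c(.05, .05, .2, .1, .25, .1, .15, .1))
    pas[[j]] <- list(pa_id = pa_id, rings = list(ring),
                     iucn_category = iucn,
                     year_established = sample(1930:2013, 1),
                     area_km2 = round(10^stats::runif(1, 1.2, 4.0), 1))

    lon <- stats::runif(n_sites, x0, x0 + 1)
    lat <- stats::runif(n_sites, y0, y0 + 1)
    inside <- lon < x0 + pa_width  # truth label; no site falls on the boundary a.s.
    shift <- cfg$confounder_protection_correlation * inside
    elev <- stats::rnorm(n_sites) + shift
    slp <- stats::rnorm(n_sites) + shift
    agri <- stats::rnorm(n_sites) + shift

    # each study samples a subset of land uses, present on both sides
    study_lus <- sample(lu_classes, sample(3:6, 1))
    land_use <- sample(study_lus, n_sites, replace = TRUE)
    intensity <- sample(use_intensity_classes(), n_sites, replace = TRUE)
    block <- sprintf("B%d", sample.int(cfg$blocks_per_study, n_sites, replace = TRUE))
    site_id <- sprintf("%s_s%03d", sid, seq_len(n_sites))
    protected_sites <- c(protected_sites, site_id[inside])

    u_study <- stats::rnorm(1, 0, cfg$sigma_study)
    u_block <- stats::rnorm(cfg$blocks_per_study, 0, cfg$sigma_block)
    names(u_block) <- sprintf("B%d", seq_len(cfg$blocks_per_study))

    taxon_id <- sprintf("%s_t%03d", sid, seq_len(n_taxa))
    lambda_t <- stats::rlnorm(n_taxa, cfg$abundance_distribution["meanlog"],
                              cfg$abundance_distribution["sdlog"])
    p_t <- stats::runif(n_taxa, cfg$occupancy_range[1], cfg$occupancy_range[2])
    range_km2 <- pmax(stats::rlnorm(n_taxa, cfg$range_size_distribution["meanlog"],
                                    cfg$range_size_distribution["sdlog"]), 10)

    # site-level multiplier on the count rate (taxon-independent)
    log_site <- log(cfg$land_use_effects[land_use]) +
      inside * log(f_A) +
      slopes["elevation"] * elev + slopes["slope"] * slp +
      slopes["agri_suitability"] * agri +
      u_study + u_block[block]
    site_mult <- exp(unname(log_site))

    mu <- outer(site_mult, lambda_t)                     # sites x taxa
    q <- outer(ifelse(inside, f_S, 1), p_t, function(a, b) pmin(a * b, 1))
    occ <- matrix(stats::rbinom(length(q), 1L, as.vector(q)), nrow = n_sites)
    if (cfg$overdispersion > 0) {
      shape <- 1 / cfg$overdispersion
      mu <- mu * matrix(stats::rgamma(length(mu), shape = shape, rate = shape),
                        nrow = n_sites)
    }
    counts <- occ * matrix(stats::rpois(length(mu), as.vector(mu)), nrow = n_sites)

    pos <- which(counts > 0, arr.ind = TRUE)
    meas <- counts[pos]
    if (is_occ) meas <- rep(1L, length(meas))
    comm_l[[j]] <- data.frame(
      site_id = site_id[pos[, 1]],
      taxon_id = taxon_id[pos[, 2]],
      measurement = as.numeric(meas),
      measurement_type = rep(if (is_occ) "occurrence" else "abundance",
                             nrow(pos)),
      stringsAsFactors = FALSE)

    sites_l[[j]] <- data.frame(
      site_id = site_id, study_id = sid, block_id = block,
      longitude = lon, latitude = lat, land_use = land_use,
      use_intensity = intensity, elevation = elev, slope = slp,
      agri_suitability = agri,
      taxonomic_group = sample(groups, 1),
      stringsAsFactors = FALSE)
    range_l[[j]] <- data.frame(taxon_id = taxon_id, range_km2 = range_km2,
                               stringsAsFactors = FALSE)
  }

  pas <- structure(pas, class = "protected_areas")
  truth <- list(
    config = unclass(cfg),
    ratio = list(richness = unname(cfg$protection_effect["richness"]),
                 abundance = unname(cfg$protection_effect["abundance"])),
    protected_sites = protected_sites)
  structure(list(sites = do.call(rbind, sites_l),
                 community = do.call(rbind, comm_l),
                 ranges = do.call(rbind, range_l),
                 protected_areas = pas,
                 truth = truth),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("synthetic_world: %d sites in %d studies, %d community records, %d taxa, %d protected areas\n",
              nrow(x$sites), length(unique(x$sites$study_id)),
              nrow(x$community), nrow(x$ranges), length(x$protected_areas)))
  cat(sprintf("  true inside/outside ratios: richness %.4g, abundance %.4g; %d sites protected\n",
              x$truth$ratio$richness, x$truth$ratio$abundance,
              length(x$truth$protected_sites)))
  invisible(x)
}

#' Small fixed world with a hand-enumerated matched subset
#'
#' Four deterministic studies built to exercise the within-study land-use
#' matching rule, with the exactly matched subset known by construction and
#' stored in `truth$matched_sites`:
#' * M1 — inside \{cropland, primary\}, outside \{cropland, pasture\}: only
#'   the cropland sites match;
#' * M2 — entirely inside the protected area: nothing matches;
#' * M3 — primary vegetation on both sides plus unmatched outside cropland;
#' * M4 — an occurrence-only study with secondary vegetation matched and an
#'   unmatched urban site.
#'
#' @param seed Seed for the (small) stochastic counts; the design — site
#'   placement, land uses, matching truth — is fixed.
#' @return A `synthetic_world` whose `truth` additionally carries
#'   `matched_sites`.
#' @export
generate_matched_fixture <- function(seed = 42L) {
  with_seed(seed, generate_matched_fixture_impl())
}

generate_matched_fixture_impl <- function() {
  # site layout: study, local id, inside?, land use, occurrence study?
  lay <- rbind(
    data.frame(study = "M1", inside = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
               land_use = c("cropland", "cropland", "primary", "primary",
                            "cropland", "cropland", "pasture", "pasture"),
               occ = FALSE),
    data.frame(study = "M2", inside = rep(TRUE, 4),
               land_use = rep("primary", 4), occ = FALSE),
    data.frame(study = "M3", inside = c(TRUE, TRUE, FALSE, FALSE, FALSE),
               land_use = c("primary", "primary", "primary", "primary", "cropland"),
               occ = FALSE),
    data.frame(study = "M4", inside = c(TRUE, TRUE, FALSE, FALSE, FALSE),
               land_use = c("secondary_young", "secondary_young",
                            "secondary_young", "secondary_young", "urban"),
               occ = TRUE))
  studies <- unique(lay$study)
  x0 <- c(M1 = 10, M2 = 20, M3 = 30, M4 = 40)  # 1-degree extents on the equator
  pa_frac <- 0.5
  iucn <- c(M1 = "II", M2 = "unknown", M3 = "IV", M4 = "Ia")
  year <- c(M1 = 2010, M2 = 1980, M3 = 1995, M4 = 1950)
  area <- c(M1 = 100, M2 = 5000, M3 = 350, M4 = 800)

  sites_l <- comm_l <- range_l <- list()
  pas <- list()
  for (j in seq_along(studies)) {
    sid <- studies[j]
    rows <- lay[lay$study == sid, ]
    n <- nrow(rows)
    site_id <- sprintf("%s_s%d", sid, seq_len(n))
    lon <- x0[sid] + ifelse(rows$inside, 0.25, 0.75) +
      seq(0, 0.1, length.out = n)
    lat <- rep(0.5, n) + seq(0, 0.1, length.out = n)
    ring <- cbind(lon = c(x0[sid], x0[sid] + pa_frac, x0[sid] + pa_frac, x0[sid], x0[sid]),
                  lat = c(0, 0, 1, 1, 0))
    pas[[j]] <- list(pa_id = paste0("PA_", sid), rings = list(ring),
                     iucn_category = unname(iucn[sid]),
                     year_established = unname(year[sid]),
                     area_km2 = unname(area[sid]))
    sites_l[[j]] <- data.frame(
      site_id = site_id, study_id = sid, block_id = "B1",
      longitude = lon, latitude = lat, land_use = rows$land_use,
      use_intensity = "light", elevation = stats::rnorm(n),
      slope = stats::rnorm(n), agri_suitability = stats::rnorm(n),
      taxonomic_group = c("plants", "invertebrates", "vertebrates", "plants")[j],
      stringsAsFactors = FALSE)
    taxon_id <- sprintf("%s_t%d", sid, 1:6)
    range_l[[j]] <- data.frame(taxon_id = taxon_id,
                               range_km2 = 10^stats::runif(6, 2, 6),
                               stringsAsFactors = FALSE)
    counts <- matrix(stats::rpois(n * 6, 2), nrow = n)
    pos <- which(counts > 0, arr.ind = TRUE)
    meas <- counts[pos]
    if (rows$occ[1]) meas <- rep(1, length(meas))
    comm_l[[j]] <- data.frame(site_id = site_id[pos[, 1]],
                              taxon_id = taxon_id[pos[, 2]],
                              measurement = as.numeric(meas),
                              measurement_type = if (rows$occ[1]) "occurrence" else "abundance",
                              stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, sites_l)
  # matched truth by hand enumeration of the layout above
  matched <- c(paste0("M1_s", 1:2), paste0("M1_s", 5:6),   # cropland both sides
               paste0("M3_s", 1:4),                        # primary both sides
               paste0("M4_s", 1:4))                        # secondary_young both sides
  truth <- list(config = list(random_seed = NA_integer_),
                ratio = list(richness = 1, abundance = 1),
                protected_sites = sites$site_id[lay$inside],
                matched_sites = matched)
  structure(list(sites = sites, community = do.call(rbind, comm_l),
                 ranges = do.call(rbind, range_l),
                 protected_areas = structure(pas, class = "protected_areas"),
                 truth = truth),
            class = "synthetic_world")
}

#' Write a synthetic world as the standard input bundle
#'
#' Writes `sites.csv`, `community.csv`, `ranges.csv`,
#' `protected_areas.geojson` (RFC 7946, WGS84 decimal degrees) and
#' `truth.json` into `dir`.
#'
#' @param world A `synthetic_world`.
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "synthetic_world"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(world$sites, file.path(dir, "sites.csv"), row.names = FALSE)
  utils::write.csv(world$community, file.path(dir, "community.csv"), row.names = FALSE)
  utils::write.csv(world$ranges, file.path(dir, "ranges.csv"), row.names = FALSE)
  write_protected_areas(world$protected_areas, file.path(dir, "protected_areas.geojson"))
  jsonlite::write_json(world$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read an input bundle from disk
#'
#' Counterpart of [write_world()]; `truth.json` is attached when present so
#' generated worlds round-trip.
#'
#' @param dir Directory containing the bundle.
#' @return A `synthetic_world`-shaped list.
#' @export
read_world <- function(dir) {
  sites <- utils::read.csv(file.path(dir, "sites.csv"), stringsAsFactors = FALSE)
  community <- utils::read.csv(file.path(dir, "community.csv"), stringsAsFactors = FALSE)
  ranges <- utils::read.csv(file.path(dir, "ranges.csv"), stringsAsFactors = FALSE)
  pas <- read_protected_areas(file.path(dir, "protected_areas.geojson"))
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path))
    jsonlite::read_json(truth_path, simplifyVector = TRUE) else NULL
  structure(list(sites = sites, community = community, ranges = ranges,
                 protected_areas = pas, truth = truth),
            class = "synthetic_world")
}

#' Write protected-area polygons as GeoJSON
#'
#' @param pas A `protected_areas` list.
#' @param path Output `.geojson` path.
#' @return `path`, invisibly.
#' @export
write_protected_areas <- function(pas, path) {
  features <- lapply(pas, function(pa) {
    coords <- lapply(pa$rings, function(r)
      lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2])))
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = coords),
         properties = list(pa_id = pa$pa_id,
                           iucn_category = pa$iucn_category,
                           year_established = pa$year_established,
                           area_km2 = pa$area_km2))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read protected-area polygons from GeoJSON
#'
#' Accepts Polygon and MultiPolygon features; properties `pa_id`,
#' `iucn_category`, `year_established` and `area_km2` are carried across
#' (missing ones become `NA`/"unknown").
#'
#' @param path A `.geojson` path.
#' @return A `protected_areas` list; each element has `pa_id`, `rings` (list
#'   of closed two-column lon/lat matrices), `iucn_category`,
#'   `year_established`, `area_km2`.
#' @export
read_protected_areas <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection"))
    stop("expected a GeoJSON FeatureCollection")
  ring_mat <- function(ring) {
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    colnames(m) <- c("lon", "lat")
    m
  }
  pas <- lapply(seq_along(gj$features), function(i) {
    f <- gj$features[[i]]
    g <- f$geometry
    rings <- switch(g$type,
      Polygon = lapply(g$coordinates, ring_mat),
      MultiPolygon = unlist(lapply(g$coordinates,
                                   function(poly) lapply(poly, ring_mat)),
                            recursive = FALSE),
      stop(sprintf("unsupported geometry type '%s'", g$type)))
    p <- f$properties
    list(pa_id = p$pa_id %||% sprintf("feature_%d", i),
         rings = rings,
         iucn_category = p$iucn_category %||% "unknown",
         year_established = p$year_established %||% NA_integer_,
         area_km2 = p$area_km2 %||% NA_real_)
  })
  structure(pas, class = "protected_areas")
}

#' @export
print.protected_areas <- function(x, ...) {
  cat(sprintf("protected_areas: %d polygons\n", length(x)))
  invisible(x)
}
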