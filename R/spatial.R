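#' Even-odd point-in-polygon test
#'
#' Ray-casting containment in longitude/latitude treated as planar
#' coordinates (containment is topological, so no projection is applied).
#' Points lying exactly on an edge or vertex of any ring count as inside —
#' a deterministic, conservative boundary convention. Rings must be closed
#' (first vertex equal to last). Rings spanning more than 180 degrees of
#' longitude are rejected rather than silently mishandled across the
#' antimeridian.
#'
#' @param point Numeric length-2, `(longitude, latitude)`.
#' @param rings A closed two-column matrix, or a list of them (outer ring
#'   plus holes; even-odd counting across all rings handles holes).
#' @return Logical.
#' @export
point_in_polygon <- function(point, rings) {
  if (is.matrix(rings)) rings <- list(rings)
  if (length(point) != 2 || any(!is.finite(point)))
    stop("point must be two finite coordinates")
  px <- point[1]; py <- point[2]
  crossings <- 0L
  for (ring in rings) {
    if (nrow(ring) < 4 || any(ring[1, ] != ring[nrow(ring), ]))
      stop("polygon ring is not closed (first vertex must equal last)")
    if (diff(range(ring[, 1])) > 180)
      stop("polygon spans more than 180 degrees of longitude (antimeridian not supported)")
    x <- ring[, 1]; y <- ring[, 2]
    n <- nrow(ring) - 1L
    for (k in seq_len(n)) {
      x1 <- x[k]; y1 <- y[k]; x2 <- x[k + 1]; y2 <- y[k + 1]
      # on-edge check: collinear and within the segment's bounding box
      cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
      if (abs(cross) <= 1e-12 * max(1, abs(x2 - x1), abs(y2 - y1)) &&
          px >= min(x1, x2) - 1e-12 && px <= max(x1, x2) + 1e-12 &&
          py >= min(y1, y2) - 1e-12 && py <= max(y1, y2) + 1e-12)
        return(TRUE)
      # half-open rule on the vertical extent avoids double-counting vertices
      if ((y1 > py) != (y2 > py)) {
        x_int <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
        if (px < x_int) crossings <- crossings + 1L
      }
    }
  }
  crossings %% 2L == 1L
}

iucn_to_group <- function(category) {
  ifelse(category %in% c("Ia", "Ib", "II"), "I-II",
         ifelse(category %in% c("III", "IV", "V", "VI"), "III-VI", "unknown"))
}

# restrictiveness rank used to resolve overlapping protected areas
group_rank <- function(group) {
  c("I-II" = 3, "III-VI" = 2, "unknown" = 1)[group]
}

#' Assign protection attributes to sites
#'
#' A site is protected when its coordinates fall inside any protected-area
#' polygon (boundary points inclusive). The containing area's IUCN category
#' is collapsed to a management group (Ia/Ib/II to I-II, III-VI to III-VI,
#' missing to unknown) and its age (`reference_year - year_established`) and
#' reported area give the size/age class: young below 20 years, small below
#' 400 km2 (strict inequalities). When a site lies in several areas the most
#' restrictive one wins (I-II over III-VI over unknown), and the overlap is
#' reported in a warning. Ages above 85 years or areas above 12,000 km2 are
#' accepted with a warning, as are missing year/area (class `NA`).
#'
#' @param sites Data frame with `site_id`, `longitude`, `latitude`.
#' @param protected_areas A `protected_areas` list (see
#'   [read_protected_areas()]).
#' @param reference_year Year against which protected-area age is computed;
#'   defaults to 2014, the vintage of the register the thresholds describe.
#' @return `sites` with columns `protected` (logical), `pa_id`,
#'   `management_group` and `size_age_class` appended.
#' @export
assign_protection <- function(sites, protected_areas, reference_year = 2014) {
  n <- nrow(sites)
  protected <- logical(n)
  pa_id <- rep(NA_character_, n)
  group <- rep("unprotected", n)
  size_age <- rep("unprotected", n)
  overlaps <- 0L
  extremes <- 0L
  # bounding-box prefilter: only run the ray cast against candidate polygons
  bbox <- t(vapply(protected_areas, function(pa) {
    xs <- unlist(lapply(pa$rings, function(r) range(r[, 1])))
    ys <- unlist(lapply(pa$rings, function(r) range(r[, 2])))
    c(min(xs), max(xs), min(ys), max(ys))
  }, numeric(4)))
  for (i in seq_len(n)) {
    pt <- c(sites$longitude[i], sites$latitude[i])
    cand <- which(pt[1] >= bbox[, 1] & pt[1] <= bbox[, 2] &
                    pt[2] >= bbox[, 3] & pt[2] <= bbox[, 4])
    hits <- Filter(function(pa) point_in_polygon(pt, pa$rings),
                   protected_areas[cand])
    if (length(hits) == 0) next
    if (length(hits) > 1) {
      overlaps <- overlaps + 1L
      ranks <- vapply(hits, function(pa) unname(group_rank(iucn_to_group(pa$iucn_category %||% "unknown"))),
                      numeric(1))
      hits <- hits[order(-ranks)]
    }
    pa <- hits[[1]]
    protected[i] <- TRUE
    pa_id[i] <- pa$pa_id
    group[i] <- iucn_to_group(pa$iucn_category %||% "unknown")
    age <- reference_year - (pa$year_established %||% NA_integer_)
    area <- pa$area_km2 %||% NA_real_
    if ((!is.na(age) && age > 85) || (!is.na(area) && area > 12000))
      extremes <- extremes + 1L
    size_age[i] <- if (is.na(age) || is.na(area)) NA_character_ else
      paste0(if (age < 20) "young" else "old", "-",
             if (area < 400) "small" else "large")
  }
  if (overlaps > 0)
    warning(sprintf("%d site(s) fell inside more than one protected area; kept the most restrictive", overlaps))
  if (extremes > 0)
    warning(sprintf("%d site(s) in protected areas older than 85 years or larger than 12,000 km2", extremes))
  sites$protected <- protected
  sites$pa_id <- pa_id
  sites$management_group <- factor(group, levels = management_groups())
  sites$size_age_class <- factor(size_age, levels = size_age_classes())
  sites
}

#' Within-study land-use matching across the protection boundary
#'
#' Keeps a site if and only if its land-use class occurs, within the same
#' study, among sites on both sides of the protection boundary; studies with
#' no land use present on both sides drop out entirely. With
#' `match_intensity = TRUE` the matching unit is the land-use x use-intensity
#' combination instead. The operation is idempotent, and every retained
#' study keeps at least one protected and one unprotected site.
#'
#' @param sites Data frame with `study_id`, `land_use`, `protected` (and
#'   `use_intensity` when matching on intensity).
#' @param match_intensity Logical; also require matching use intensity.
#' @return The matched subset of `sites`.
#' @export
match_sites_by_land_use <- function(sites, match_intensity = FALSE) {
  stopifnot(all(c("study_id", "land_use", "protected") %in% names(sites)))
  unit <- if (match_intensity)
    paste(sites$land_use, sites$use_intensity, sep = "|") else sites$land_use
  key <- paste(sites$study_id, unit, sep = "\r")
  both <- tapply(sites$protected, key, function(p) any(p) && any(!p))
  sites[both[key], , drop = FALSE]
}
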