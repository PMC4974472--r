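#' Species richness and total abundance of one site
#'
#' Richness counts the taxa recorded with a positive measurement; abundance
#' sums the measurements. For occurrence-coded rows (0/1) abundance is not a
#' meaningful quantity and callers should treat it as undefined; this
#' function only does the arithmetic.
#'
#' @param measurement Numeric vector of per-taxon abundances (counts or
#'   densities) or 0/1 occurrences at one site.
#' @return List with `S` (integer richness) and `N` (numeric summed
#'   abundance).
#' @export
site_richness_abundance <- function(measurement) {
  if (any(!is.finite(measurement)))
    stop("non-finite measurement")
  if (any(measurement < 0))
    stop("negative abundance")
  list(S = sum(measurement > 0), N = sum(measurement))
}

#' Analytic (hypergeometric) rarefied richness
#'
#' Expected number of species in a uniform random subsample of `n`
#' individuals drawn without replacement from a site's counts:
#' `E[S_n] = sum_i (1 - choose(N - N_i, n) / choose(N, n))` over taxa with
#' `N_i > 0`, where `N` is the site total. Computed with log-binomials for
#' numerical stability at large counts.
#'
#' @param counts Non-negative integer vector of per-taxon counts.
#' @param n Subsample size, `0 <= n <= sum(counts)`.
#' @return Expected species count, a real in `[0, S]`.
#' @export
rarefied_richness <- function(counts, n) {
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be non-negative and finite")
  if (any(!is_wholenumber(counts)))
    stop("rarefaction requires integer counts (individuals)")
  counts <- round(counts[counts > 0])
  N <- sum(counts)
  if (!is_wholenumber(n) || n < 0) stop("n must be a non-negative integer")
  if (n > N) stop(sprintf("subsample size n = %s exceeds total count N = %s", n, N))
  if (n == 0 || length(counts) == 0) return(0)
  # log P(taxon i absent from the subsample); -Inf when N - N_i < n
  log_absent <- lchoose(N - counts, n) - lchoose(N, n)
  log_absent[N - counts < n] <- -Inf
  sum(1 - exp(log_absent))
}

#' Rarefy every site of one study to the study's minimum total count
#'
#' The common subsample size is the smallest site total within the study
#' ("the fewest individuals at any site"). If any site is empty the minimum
#' is 0 and rarefied richness is undefined for the whole study; studies that
#' mix occurrence- and abundance-coded rows, or record non-integer
#' densities, are likewise undefined.
#'
#' @param community Community rows of a single study: columns `site_id`,
#'   `measurement`, `measurement_type`.
#' @param site_ids All site ids belonging to the study (so sites with no
#'   records contribute a zero total).
#' @return List with `n_min` and `rarefied` (named numeric per site; all
#'   `NA` when undefined).
#' @export
study_rarefaction <- function(community, site_ids) {
  und <- function(n_min) list(
    n_min = n_min,
    rarefied = stats::setNames(rep(NA_real_, length(site_ids)), site_ids))
  types <- unique(community$measurement_type)
  if (length(types) > 1 || identical(types, "occurrence")) return(und(NA_integer_))
  if (nrow(community) > 0 && any(!is_wholenumber(community$measurement)))
    return(und(NA_integer_))  # density-valued: rarefaction undefined
  totals <- stats::setNames(rep(0, length(site_ids)), site_ids)
  if (nrow(community) > 0) {
    agg <- tapply(community$measurement, community$site_id, sum)
    totals[names(agg)] <- agg
  }
  n_min <- as.integer(min(totals))
  if (n_min < 1) return(und(n_min))
  rar <- vapply(site_ids, function(s) {
    cts <- community$measurement[community$site_id == s]
    rarefied_richness(cts, n_min)
  }, numeric(1))
  list(n_min = n_min, rarefied = rar)
}

#' Community-weighted mean log10 range size and endemicity
#'
#' The community-weighted mean (CWM) is the abundance-weighted average of
#' log10 geographic range size over the taxa recorded at the site; for
#' occurrence-coded data every recorded taxon gets equal weight. Endemicity
#' is the reciprocal `1 / CWM`, so assemblages dominated by narrow-ranged
#' species score higher. Taxa without a range entry are dropped from both
#' sums (with a warning via the `dropped` element).
#'
#' @param measurement Per-taxon abundances or occurrences at one site.
#' @param taxon_id Taxon ids aligned with `measurement`.
#' @param ranges Data frame with columns `taxon_id`, `range_km2`
#'   (`range_km2 > 0`).
#' @param occurrence Logical; `TRUE` weights all recorded taxa equally.
#' @return List with `cwm` (mean log10 range, km2), `endemicity` (`1/cwm`)
#'   and `dropped` (ids of recorded taxa lacking a range entry). `cwm` and
#'   `endemicity` are `NA` when no recorded taxon has a range entry.
#' @export
endemicity <- function(measurement, taxon_id, ranges, occurrence = FALSE) {
  keep <- measurement > 0
  measurement <- measurement[keep]
  taxon_id <- taxon_id[keep]
  idx <- match(taxon_id, ranges$taxon_id)
  dropped <- taxon_id[is.na(idx)]
  ok <- !is.na(idx)
  if (!any(ok))
    return(list(cwm = NA_real_, endemicity = NA_real_, dropped = dropped))
  r <- ranges$range_km2[idx[ok]]
  if (any(r <= 0)) stop("range_km2 must be > 0")
  w <- if (occurrence) rep(1, sum(ok)) else measurement[ok]
  cwm <- sum(w * log10(r)) / sum(w)
  if (cwm <= 0)
    stop("community-weighted mean log10 range is <= 0; ranges below 1 km2 are not supported")
  list(cwm = cwm, endemicity = 1 / cwm, dropped = dropped)
}

#' Compute the four site-level biodiversity measures for a whole world
#'
#' Joins the community table to the site table, applies
#' [site_richness_abundance()], [study_rarefaction()] (at each study's
#' minimum total) and [endemicity()] per site, and returns one row per site
#' with explicit `NA` for undefined measures: `N` is `NA` for
#' occurrence-only studies, `rarefied_richness` is `NA` for occurrence,
#' density or zero-minimum studies, `cwm_log_range`/`endemicity` are `NA`
#' where no recorded taxon has a range entry.
#'
#' @param world A `synthetic_world`, or any list with `sites`, `community`,
#'   `ranges` of the standard bundle layout.
#' @return Data frame: `site_id`, `study_id`, `S`, `N`, `n_min`,
#'   `rarefied_richness`, `cwm_log_range`, `endemicity`, plus a
#'   `dropped_taxa` attribute counting recorded taxa without range entries.
#' @export
compute_site_measures <- function(world) {
  sites <- world$sites
  community <- world$community
  ranges <- world$ranges
  unknown <- setdiff(community$site_id, sites$site_id)
  if (length(unknown) > 0)
    stop(sprintf("community rows reference %d unknown site id(s), e.g. '%s'",
                 length(unknown), unknown[1]))
  comm_by_site <- split(community, community$site_id)
  res <- data.frame(site_id = sites$site_id, study_id = sites$study_id,
                    S = 0L, N = NA_real_, n_min = NA_integer_,
                    rarefied_richness = NA_real_, cwm_log_range = NA_real_,
                    endemicity = NA_real_, stringsAsFactors = FALSE)
  # per-study measurement type; abundance is undefined for occurrence studies
  site_study <- stats::setNames(sites$study_id, sites$site_id)
  type_by_study <- tapply(community$measurement_type,
                          site_study[community$site_id],
                          function(x) if (length(unique(x)) > 1) "mixed" else x[1])
  abundance_study <- function(sid)
    !is.na(type_by_study[sid]) && type_by_study[sid] == "abundance"
  n_dropped <- 0L
  for (i in seq_len(nrow(res))) {
    if (abundance_study(res$study_id[i])) res$N[i] <- 0
    rows <- comm_by_site[[res$site_id[i]]]
    if (is.null(rows)) next
    occ <- all(rows$measurement_type == "occurrence")
    sn <- site_richness_abundance(rows$measurement)
    res$S[i] <- sn$S
    if (abundance_study(res$study_id[i])) res$N[i] <- sn$N
    e <- endemicity(rows$measurement, rows$taxon_id, ranges, occurrence = occ)
    res$cwm_log_range[i] <- e$cwm
    res$endemicity[i] <- e$endemicity
    n_dropped <- n_dropped + length(e$dropped)
  }
  for (sid in unique(res$study_id)) {
    in_study <- res$study_id == sid
    sr <- study_rarefaction(community[community$site_id %in% res$site_id[in_study], ,
                                      drop = FALSE],
                            res$site_id[in_study])
    res$n_min[in_study] <- sr$n_min
    res$rarefied_richness[in_study] <- unname(sr$rarefied[res$site_id[in_study]])
  }
  if (n_dropped > 0)
    warning(sprintf("%d community record(s) had no range entry and were dropped from endemicity",
                    n_dropped))
  attr(res, "dropped_taxa") <- n_dropped
  res
}
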