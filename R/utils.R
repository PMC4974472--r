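#' Canonical land-use vocabulary
#'
#' The eight land-use classes used throughout: primary vegetation, three
#' successional stages of secondary vegetation, plantation, cropland, pasture
#' and urban. `"primary"` is the reference level in all models.
#'
#' @return Character vector of the eight class names, reference level first.
#' @export
land_use_classes <- function() {
  c("primary", "secondary_mature", "secondary_intermediate", "secondary_young",
    "plantation", "cropland", "pasture", "urban")
}

#' Canonical use-intensity vocabulary
#'
#' @return Character vector: minimal, light, intense.
#' @export
use_intensity_classes <- function() {
  c("minimal", "light", "intense")
}

#' Management-category group levels
#'
#' IUCN categories collapsed into ordered restrictiveness groups:
#' unprotected, III-VI (least restrictive), unknown (a mixture, treated as
#' intermediate), I-II (most restrictive).
#'
#' @return Character vector of the four group labels, reference level first.
#' @export
management_groups <- function() {
  c("unprotected", "III-VI", "unknown", "I-II")
}

#' Size/age class levels for protected areas
#'
#' Young is an age below 20 years, old is 20 years and above; small is an
#' area below 400 km2, large is 400 km2 and above.
#'
#' @return Character vector of the five class labels, reference level first.
#' @export
size_age_classes <- function() {
  c("unprotected", "young-small", "young-large", "old-small", "old-large")
}

# Latitude of the tropics of Cancer/Capricorn; |lat| <= this is tropical.
TROPIC_LATITUDE <- 23.43665

#' Latitudinal zone of a site
#'
#' @param latitude Numeric latitude in decimal degrees.
#' @return Character vector, `"tropical"` where `abs(latitude)` is at most
#'   23.43665 degrees, `"temperate"` otherwise.
#' @export
latitudinal_zone <- function(latitude) {
  ifelse(abs(latitude) <= TROPIC_LATITUDE, "tropical", "temperate")
}

# Evaluate `code` under a local RNG seeded with `seed`, restoring the caller's
# RNG state afterwards so generators do not perturb user simulations.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a per-stage child seed from a run seed; fixed offsets keep stages
# independently re-runnable. Kept below 2^31 - 1.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483629)
}

# uniform draw from an inclusive integer range; safe when min == max
# (sample(x, 1) on a scalar would sample from 1:x)
sample_range <- function(range) {
  vals <- seq.int(range[1], range[2])
  if (length(vals) == 1) vals else sample(vals, 1)
}

is_wholenumber <- function(x, tol = 1e-9) {
  is.finite(x) & abs(x - round(x)) < tol
}

`%||%` <- function(a, b) if (is.null(a)) b else a
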