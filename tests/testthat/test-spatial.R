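unit_square <- cbind(lon = c(0, 1, 1, 0, 0), lat = c(0, 0, 1, 1, 0))

test_that("ray casting containment with boundary-inside convention", {
  expect_true(point_in_polygon(c(0.5, 0.5), unit_square))
  expect_false(point_in_polygon(c(2, 0.5), unit_square))
  expect_false(point_in_polygon(c(-0.1, 0.5), unit_square))
  # points on an edge or vertex count as inside
  expect_true(point_in_polygon(c(1.0, 0.5), unit_square))
  expect_true(point_in_polygon(c(0.5, 0), unit_square))
  expect_true(point_in_polygon(c(0, 0), unit_square))
  # unclosed rings are rejected
  expect_error(point_in_polygon(c(0.5, 0.5), unit_square[1:4, ]), "closed")
  # antimeridian-spanning polygons are rejected, not mishandled
  wide <- cbind(lon = c(-170, 170, 170, -170, -170), lat = c(0, 0, 1, 1, 0))
  expect_error(point_in_polygon(c(0, 0.5), wide), "antimeridian")
})

test_that("holes are excluded by even-odd counting", {
  hole <- cbind(lon = c(0.4, 0.6, 0.6, 0.4, 0.4), lat = c(0.4, 0.4, 0.6, 0.6, 0.4))
  rings <- list(unit_square, hole)
  expect_true(point_in_polygon(c(0.2, 0.2), rings))
  expect_false(point_in_polygon(c(0.5, 0.5), rings))
  expect_true(point_in_polygon(c(0.4, 0.5), rings))  # hole boundary still counts inside
})

pa <- function(id, x0, x1, cat, year, area) {
  list(pa_id = id,
       rings = list(cbind(lon = c(x0, x1, x1, x0, x0), lat = c(0, 0, 1, 1, 0))),
       iucn_category = cat, year_established = year, area_km2 = area)
}

test_that("protection attributes follow the category and threshold rules", {
  pas <- structure(list(pa("P1", 0, 1, "II", 2010, 100)), class = "protected_areas")
  sites <- data.frame(site_id = c("in", "out"), longitude = c(0.5, 3),
                      latitude = c(0.5, 0.5))
  cl <- assign_protection(sites, pas, reference_year = 2014)
  expect_equal(cl$protected, c(TRUE, FALSE))
  expect_equal(as.character(cl$management_group), c("I-II", "unprotected"))
  expect_equal(as.character(cl$size_age_class), c("young-small", "unprotected"))
  # age 20 is old (young is strictly < 20), area 400 is large (small strictly < 400)
  cl2 <- assign_protection(sites[1, ],
                           structure(list(pa("P2", 0, 1, "V", 1994, 400)),
                                     class = "protected_areas"), 2014)
  expect_equal(as.character(cl2$management_group), "III-VI")
  expect_equal(as.character(cl2$size_age_class), "old-large")
  # missing category maps to the unknown group
  cl3 <- assign_protection(sites[1, ],
                           structure(list(pa("P3", 0, 1, "unknown", 2000, 50)),
                                     class = "protected_areas"), 2014)
  expect_equal(as.character(cl3$management_group), "unknown")
})

test_that("overlapping areas resolve to the most restrictive category, with a warning", {
  pas <- structure(list(pa("loose", 0, 1, "V", 2000, 100),
                        pa("strict", 0, 1, "Ia", 2005, 200)),
                   class = "protected_areas")
  sites <- data.frame(site_id = "s", longitude = 0.5, latitude = 0.5)
  expect_warning(cl <- assign_protection(sites, pas, 2014), "more than one")
  expect_equal(cl$pa_id, "strict")
  expect_equal(as.character(cl$management_group), "I-II")
  # polygon order does not matter
  expect_warning(cl_rev <- assign_protection(sites, structure(rev(unclass(pas)),
                                                              class = "protected_areas"), 2014))
  expect_equal(cl_rev$pa_id, "strict")
})

test_that("extreme ages and sizes are accepted with a warning", {
  pas <- structure(list(pa("old", 0, 1, "II", 1900, 50)), class = "protected_areas")
  sites <- data.frame(site_id = "s", longitude = 0.5, latitude = 0.5)
  expect_warning(cl <- assign_protection(sites, pas, 2014), "older than 85")
  expect_equal(as.character(cl$size_age_class), "old-small")
})

test_that("assignment is invariant to site ordering", {
  w <- generate_world(world_config(n_studies = 3, sites_per_study = c(6, 10),
                                   taxon_pool_size = c(5, 8), random_seed = 8))
  cl <- assign_protection(w$sites, w$protected_areas)
  shuffled <- w$sites[rev(seq_len(nrow(w$sites))), ]
  cl2 <- assign_protection(shuffled, w$protected_areas)
  cl2 <- cl2[match(cl$site_id, cl2$site_id), ]
  expect_equal(cl$protected, cl2$protected)
  expect_equal(cl$pa_id, cl2$pa_id)
})

test_that("land-use matching keeps classes present on both sides of the boundary", {
  sites <- data.frame(
    study_id = "A",
    site_id = paste0("s", 1:6),
    land_use = c("cropland", "primary", "cropland", "pasture", "cropland", "pasture"),
    protected = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    use_intensity = c("minimal", "minimal", "minimal", "light", "intense", "light"))
  m <- match_sites_by_land_use(sites)
  expect_setequal(m$site_id, c("s1", "s3", "s5"))  # cropland only
  # a study entirely inside drops out
  all_in <- transform(sites, protected = TRUE)
  expect_equal(nrow(match_sites_by_land_use(all_in)), 0)
  # matching on land use x intensity is stricter
  mi <- match_sites_by_land_use(sites, match_intensity = TRUE)
  expect_setequal(mi$site_id, c("s1", "s3"))
})

test_that("matching is idempotent and keeps both sides in every retained study", {
  w <- generate_world(world_config(n_studies = 10, sites_per_study = c(8, 16),
                                   taxon_pool_size = c(5, 8), random_seed = 33))
  cl <- assign_protection(w$sites, w$protected_areas)
  m1 <- match_sites_by_land_use(cl)
  m2 <- match_sites_by_land_use(m1)
  expect_identical(m1$site_id, m2$site_id)
  if (nrow(m1) > 0) {
    by_study <- split(m1$protected, m1$study_id)
    expect_true(all(vapply(by_study, function(p) any(p) && any(!p), logical(1))))
  }
})

test_that("the fixture's matched subset is recovered exactly", {
  fx <- generate_matched_fixture()
  cl <- assign_protection(fx$sites, fx$protected_areas)
  expect_setequal(cl$site_id[cl$protected], fx$truth$protected_sites)
  m <- match_sites_by_land_use(cl)
  expect_setequal(m$site_id, fx$truth$matched_sites)
})
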