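test_that("richness and abundance are counted and summed directly", {
  expect_equal(site_richness_abundance(c(A = 2, B = 1, C = 0)),
               list(S = 2L, N = 3))
  expect_equal(site_richness_abundance(numeric(0)), list(S = 0L, N = 0))
  # density-valued abundances sum without rounding
  expect_equal(site_richness_abundance(c(0.5, 1.2)), list(S = 2L, N = 1.7))
  expect_error(site_richness_abundance(c(1, -2)), "negative")
  # permutation invariance
  x <- c(3, 0, 7, 1, 2)
  expect_equal(site_richness_abundance(x), site_richness_abundance(rev(x)))
})

test_that("analytic rarefaction equals exhaustive enumeration on small sites", {
  for (counts in list(c(5, 5), c(2, 1), c(3, 2, 1), c(4, 1, 1), 6)) {
    for (n in 0:min(4, sum(counts)))
      expect_equal(rarefied_richness(counts, n), enumerate_rarefaction(counts, n),
                   tolerance = 1e-12, label = sprintf("counts {%s}, n=%d",
                                                      toString(counts), n))
  }
  # every single draw yields exactly one species
  expect_equal(rarefied_richness(c(2, 1), 1), 1.0)
})

test_that("rarefaction identities and monotonicity hold", {
  set.seed(1)
  for (rep in 1:20) {
    counts <- rpois(sample(2:6, 1), 4) + 1
    N <- sum(counts)
    expect_equal(rarefied_richness(counts, N), length(counts))  # E[S_N] = S
    expect_equal(rarefied_richness(counts, 0), 0)               # E[S_0] = 0
    es <- vapply(0:N, function(n) rarefied_richness(counts, n), numeric(1))
    expect_true(all(diff(es) >= -1e-12))                        # nondecreasing in n
  }
})

test_that("rarefaction rejects non-integer counts and oversized subsamples", {
  expect_error(rarefied_richness(c(1.5, 2), 1), "integer")
  expect_error(rarefied_richness(c(2, 2), 5), "exceeds")
  expect_error(rarefied_richness(c(-1, 2), 1), "non-negative")
})

test_that("rarefaction is computed stably in log space at large counts", {
  counts <- c(50000, 30000, 1)
  e <- rarefied_richness(counts, 1000)
  expect_true(is.finite(e) && e > 1 && e < 3)
})

test_that("study-level rarefaction uses the study's minimum site total", {
  comm <- data.frame(site_id = c("a", "a", "b"), taxon_id = c("t1", "t2", "t1"),
                     measurement = c(2, 1, 10), measurement_type = "abundance")
  sr <- study_rarefaction(comm, c("a", "b"))
  expect_equal(sr$n_min, 3L)
  expect_equal(sr$rarefied[["a"]], 2)  # its own total: observed richness
  expect_equal(sr$rarefied[["b"]], rarefied_richness(10, 3))
  # an empty site makes the whole study undefined
  sr0 <- study_rarefaction(comm, c("a", "b", "empty"))
  expect_equal(sr0$n_min, 0L)
  expect_true(all(is.na(sr0$rarefied)))
  # occurrence and mixed studies are undefined
  occ <- transform(comm, measurement_type = "occurrence")
  expect_true(all(is.na(study_rarefaction(occ, c("a", "b"))$rarefied)))
  mixed <- comm
  mixed$measurement_type[1] <- "occurrence"
  expect_true(all(is.na(study_rarefaction(mixed, c("a", "b"))$rarefied)))
})

test_that("analytic rarefaction matches Monte Carlo subsampling", {
  set.seed(42)
  counts <- rpois(6, 8) + 1
  n <- 10
  mc <- mc_rarefaction(counts, n, 10000)
  expect_lt(abs(rarefied_richness(counts, n) - mc$mean), 3 * mc$se)
})

test_that("endemicity follows the community-weighted mean of log10 range size", {
  ranges <- data.frame(taxon_id = c("x", "y"), range_km2 = c(1e4, 1e6))
  e <- endemicity(c(10, 30), c("x", "y"), ranges)
  expect_equal(e$cwm, 5.5)
  expect_equal(e$endemicity, 1 / 5.5, tolerance = 1e-9)
  expect_equal(round(e$endemicity, 5), 0.18182)
  # single taxon: the weighted mean is its own log10 range
  single <- endemicity(5, "x", data.frame(taxon_id = "x", range_km2 = 1e5))
  expect_equal(single$cwm, 5)
  # occurrence data weight all recorded taxa equally
  occ <- endemicity(c(1, 1), c("x", "y"),
                    data.frame(taxon_id = c("x", "y"), range_km2 = c(1e2, 1e4)),
                    occurrence = TRUE)
  expect_equal(occ$cwm, 3)
})

test_that("endemicity is invariant to rescaling abundances and drops rangeless taxa", {
  ranges <- data.frame(taxon_id = c("x", "y", "z"), range_km2 = c(1e3, 1e5, 1e6))
  a <- c(2, 5, 1)
  e1 <- endemicity(a, c("x", "y", "z"), ranges)
  e2 <- endemicity(a * 17.3, c("x", "y", "z"), ranges)
  expect_equal(e1$cwm, e2$cwm, tolerance = 1e-12)
  # taxa lacking ranges drop from both sums
  e3 <- endemicity(c(2, 5, 1, 9), c("x", "y", "z", "unknown"), ranges)
  expect_equal(e3$cwm, e1$cwm)
  expect_equal(e3$dropped, "unknown")
  # nothing with a range entry: undefined
  e4 <- endemicity(1, "unknown", ranges)
  expect_true(is.na(e4$endemicity))
  # sub-km2 ranges would make the weighted mean non-positive
  expect_error(endemicity(1, "x", data.frame(taxon_id = "x", range_km2 = 0.01)),
               "<= 0")
})

test_that("site measures carry the expected defined/undefined pattern", {
  fx <- generate_matched_fixture()
  m <- compute_site_measures(fx)
  occ_sites <- fx$sites$site_id[fx$sites$study_id == "M4"]
  expect_true(all(is.na(m$N[m$site_id %in% occ_sites])))
  expect_true(all(is.na(m$rarefied_richness[m$site_id %in% occ_sites])))
  abundance_sites <- m$site_id[m$study_id %in% c("M1", "M2", "M3")]
  expect_true(all(is.finite(m$N[m$site_id %in% abundance_sites])))
  expect_true(all(m$rarefied_richness <= m$S + 1e-9, na.rm = TRUE))
  expect_true(all(m$S >= 0))
  # referential integrity enforced
  bad <- fx
  bad$community$site_id[1] <- "nope"
  expect_error(compute_site_measures(bad), "unknown site")
})
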