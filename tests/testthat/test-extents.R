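mean_worm <- tibble::tibble(
  specimen_id = "mean", body_length = 3669.4, forebody_length = 717.3,
  oral_sucker_length = 149.1, ventral_sucker_length = 304.1,
  cirrus_sac_reach = 3046.3, cirrus_sac_length = 1045.8,
  post_testicular_region = 1209.8, posterior_testis_length = 197.0,
  distance_between_testes = 140.5, anterior_testis_length = 179.3,
  pre_vitelline_region = 1565.3, vitelline_range = 2121.1)

test_that("organ extents are reconstructed from their anchoring measures", {
  ext <- suppressWarnings(reconstruct_extents(mean_worm))
  g <- function(o) unlist(ext[ext$organ == o, c("anterior", "posterior")])
  expect_equal(g("oral_sucker"), c(anterior = 0, posterior = 149.1))
  expect_equal(g("ventral_sucker"), c(anterior = 717.3, posterior = 1021.4))
  # cirrus-sac anchored by its reach from the posterior extremity
  expect_equal(g("cirrus_sac"), c(anterior = 623.1, posterior = 1668.9),
               tolerance = 1e-9)
  expect_equal(g("posterior_testis"),
               c(anterior = 3669.4 - 1209.8 - 197.0, posterior = 3669.4 - 1209.8))
  expect_equal(g("anterior_testis"),
               c(anterior = 2262.6 - 140.5 - 179.3, posterior = 2262.6 - 140.5))
  # simple forebody anchor
  vs <- suppressWarnings(reconstruct_extents(tibble::tibble(
    specimen_id = "t", body_length = 1000, forebody_length = 200,
    ventral_sucker_length = 100)))
  expect_equal(unlist(vs[vs$organ == "ventral_sucker",
                         c("anterior", "posterior")]),
               c(anterior = 200, posterior = 300))
})

test_that("small overruns are clamped with a warning status, large ones flagged invalid", {
  ext <- suppressWarnings(reconstruct_extents(mean_worm))
  vit <- ext[ext$organ == "vitellarium", ]
  # 1565.3 + 2121.1 = 3686.4 > L: a 0.46% mean-based inconsistency
  expect_equal(vit$status, "clamped")
  expect_equal(vit$posterior, 3669.4)
  expect_match(vit$note, "0.46%")
  big <- tibble::tibble(specimen_id = "x", body_length = 1000,
                        pre_vitelline_region = 500, vitelline_range = 600)
  ext2 <- suppressWarnings(reconstruct_extents(big))
  expect_equal(ext2$status[ext2$organ == "vitellarium"], "invalid")
  # organs without anchors are skipped with a warning
  expect_warning(
    reconstruct_extents(tibble::tibble(specimen_id = "y", body_length = 1000,
                                       cirrus_sac_length = 300)),
    "skipped")
})

test_that("extent binning matches the eighth-division reading of organ position", {
  L <- 3669.4
  expect_equal(localize_extent(0, L / 8, L, parts = 8), 1L)
  # an ovary wholly inside the fourth eighth
  expect_equal(localize_extent(0.40 * L, 0.47 * L, L, parts = 8), 4L)
  expect_equal(localize_extent(0.45 * L, 0.55 * L, L, parts = 2), c(1L, 2L))
  expect_equal(localize_extent(0, L, L, parts = 3), 1:3)
  expect_error(localize_extent(10, 10, L, parts = 8), "anterior < posterior")
  expect_error(localize_extent(0, L + 1, L, parts = 8))
})

test_that("bin occupancy agrees with a dense-sampling oracle and nests across divisions", {
  set.seed(7)
  L <- 1000
  for (i in 1:60) {
    a <- runif(1, 0, L - 1)
    p <- runif(1, a + 0.5, L)
    for (parts in c(2L, 3L, 8L)) {
      expect_equal(localize_extent(a, p, L, parts),
                   bins_by_sampling(a, p, L, parts))
    }
    # eighths collapse onto halves for extents not ending exactly at L/2
    if (abs(a - L / 2) > 1e-6 && abs(p - L / 2) > 1e-6) {
      eighths <- localize_extent(a, p, L, 8)
      halves <- sort(unique(ifelse(eighths <= 4, 1L, 2L)))
      expect_equal(halves, localize_extent(a, p, L, 2))
    }
  }
})

test_that("region fractions support 'completely' and 'mainly' predicates", {
  L <- 1000
  expect_equal(region_fraction(600, 800, L, parts = 2, index = 2), 1.0)
  expect_equal(region_fraction(450, 550, L, parts = 2, index = 2), 0.5)
  expect_equal(region_fraction(480, 600, L, parts = 2, index = 2), 5 / 6)
  expect_error(region_fraction(500, 500, L), "Zero-length")
  # halves partition any extent
  set.seed(8)
  for (i in 1:50) {
    a <- runif(1, 0, 999); p <- runif(1, a + 0.1, 1000)
    expect_equal(region_fraction(a, p, L, 2, 1) + region_fraction(a, p, L, 2, 2),
                 1.0)
  }
})

test_that("interval relations classify separated/touching/overlapping", {
  expect_equal(interval_relation(c(0, 10), c(20, 30)), "separated")
  expect_equal(interval_relation(c(0, 10), c(10, 30)), "touching")
  expect_equal(interval_relation(c(0, 15), c(10, 30)), "overlapping")
  expect_equal(interval_relation(c(10, 30), c(0, 15)), "overlapping")
})
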