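test_that("packaged profiles carry the transcribed summary cells", {
  p <- load_fixture("A. palmi")
  bl <- dplyr::filter(p$stats, measure == "body_length")
  expect_equal(unlist(bl[, c("min", "max", "mean")]),
               c(min = 2912, max = 4563, mean = 3669.4))
  expect_equal(bl$n, 22L)
  cs <- dplyr::filter(load_fixture("A. serrani")$stats,
                      measure == "cirrus_sac_length")
  expect_equal(c(cs$min, cs$max), c(1500, 1860))
  expect_equal(p$categoricals$testes_arrangement, "diagonal")
  expect_error(load_fixture("Nonexistent sp."), "Unknown taxon")
  expect_length(fixture_taxa(), 9)
  # every stored cell satisfies min <= mean <= max
  for (t in fixture_taxa()) {
    s <- load_fixture(t)$stats
    ok <- is.na(s$mean) | (s$min <= s$mean & s$mean <= s$max)
    expect_true(all(ok))
  }
})

test_that("profile stats survive a serialize/reload round-trip", {
  p <- load_fixture("A. heronensis")
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(p$stats, f, na = "")
  back <- readr::read_csv(f, col_types = readr::cols(
    measure = "c", min = "d", max = "d", mean = "d", n = "i",
    variant = "c", provenance = "c", note = "c"))
  expect_equal(as.data.frame(back), as.data.frame(p$stats))
})

test_that("alternative literature values stay as secondary variants", {
  p <- load_fixture("A. epinepheli")
  vs <- dplyr::filter(p$stats, measure == "ventral_sucker_length")
  expect_equal(sort(vs$variant), c("primary", "secondary"))
  expect_equal(vs$min[vs$variant == "secondary"], 280)
})

test_that("synthetic specimens are seed-deterministic and range-contained", {
  x1 <- synth_specimens("A. palmi", n = 22, seed = 1)
  x2 <- synth_specimens("A. palmi", n = 22, seed = 1)
  expect_identical(x1, x2)
  x3 <- synth_specimens("A. palmi", n = 22, seed = 2)
  expect_false(identical(x1, x3))
  expect_equal(nrow(x1), 22)
  expect_error(synth_specimens("A. palmi", n = 5), "seed")

  prof <- load_fixture("A. palmi")
  smry <- summarize_morphometry(x1)
  for (i in seq_len(nrow(smry))) {
    rng <- palmpattern:::profile_range(prof, smry$measure[i])
    expect_gte(smry$min[i], rng[1])
    expect_lte(smry$max[i], rng[2])
  }
  # generated records reconstruct without invalid extents
  ext <- suppressWarnings(reconstruct_extents(x1))
  expect_false(any(ext$status == "invalid"))
  # ventral sucker anterior equals the forebody length exactly
  vs <- dplyr::filter(ext, organ == "ventral_sucker")
  expect_equal(vs$anterior, x1$forebody_length[match(vs$specimen_id,
                                                     x1$specimen_id)])
})

test_that("truncated-normal sampling also honours the printed ranges", {
  x <- synth_specimens("A. palmi", n = 10, seed = 5,
                       sampling = "truncated_normal")
  prof <- load_fixture("A. palmi")
  rng <- palmpattern:::profile_range(prof, "body_length")
  expect_true(all(x$body_length >= rng[1] & x$body_length <= rng[2]))
  # values cluster nearer the printed mean than uniform draws do on average
  expect_lt(abs(mean(x$body_length) - 3669.4), (rng[2] - rng[1]) / 2)
})

test_that("synthetic aligned pairs honour the prescribed differences", {
  p0 <- synth_aligned_pair(100, seed = 11)
  expect_identical(p0$seq_a, p0$seq_b)
  d <- maternus_diffs()
  expect_error(synth_aligned_pair(800, d, seed = 1), "out of range")
  expect_error(
    synth_aligned_pair(1031, tibble::tibble(position = 1032, base_a = "A",
                                            base_b = "G"), seed = 1),
    "out of range")
  expect_error(synth_aligned_pair(1031, d[c(1, 1, 2), ], seed = 1), "distinct")
  bad <- d; bad$base_b[1] <- "A"
  expect_error(synth_aligned_pair(1031, bad, seed = 1), "unequal")
  p1 <- synth_aligned_pair(1031, d, seed = 7)
  p2 <- synth_aligned_pair(1031, d, seed = 7)
  expect_identical(p1, p2)
  chars_a <- strsplit(p1$seq_a, "")[[1]]
  expect_equal(chars_a[d$position], d$base_a)
  expect_equal(strsplit(p1$seq_b, "")[[1]][d$position], d$base_b)
})

test_that("profile patterns expose only organs the source anchors", {
  pat <- profile_pattern("A. palmi")
  expect_setequal(pat$bars$organ,
                  c("oral_sucker", "ventral_sucker", "cirrus_sac",
                    "anterior_testis", "posterior_testis", "vitellarium"))
  expect_equal(pat$body_length, 3669.4)
  # sparser profile: only organs with printed anchors appear
  pat2 <- profile_pattern("A. epinepheli")
  expect_true(all(c("oral_sucker", "posterior_testis") %in% pat2$bars$organ))
  expect_false("ventral_sucker" %in% pat2$bars$organ)  # no forebody printed
  # a profile with no anchorable organs still yields a body-only pattern
  pat3 <- profile_pattern("A. serrani")
  expect_s3_class(pat3, "palm_pattern")
  expect_equal(nrow(pat3$bars), 0)
})
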