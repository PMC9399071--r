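ext_tbl <- function(...) {
  tibble::tribble(~organ, ~anterior, ~posterior, ...)
}

test_that("patterns normalize extents to bar fractions that round-trip", {
  L <- 3669.4
  ext <- ext_tbl("cirrus_sac", 623.1, 1668.9, "oral_sucker", 0, 149.1)
  pat <- palm_pattern(ext, L, "A. palmi")
  cs <- pat$bars[pat$bars$organ == "cirrus_sac", ]
  expect_equal(cs$start_fraction, 0.170, tolerance = 5e-3)
  expect_equal(cs$end_fraction, 0.455, tolerance = 5e-3)
  # the cirrus-sac reach fraction is the complement of the bar start
  expect_equal(1 - cs$start_fraction, 3046.3 / L, tolerance = 1e-9)
  set.seed(5)
  for (i in 1:40) {
    a <- runif(1, 0, L - 1); p <- runif(1, a + 0.1, L)
    b <- palm_pattern(ext_tbl("ovary", a, p), L, "t")$bars
    expect_equal(b$start_fraction * L, a, tolerance = 1e-9)
    expect_equal(b$end_fraction * L, p, tolerance = 1e-9)
  }
  whole <- palm_pattern(ext_tbl("vitellarium", 0, L), L, "t")$bars
  expect_equal(c(whole$start_fraction, whole$end_fraction), c(0, 1))
  empty <- palm_pattern(NULL, L, "t")
  expect_equal(nrow(empty$bars), 0)
  expect_error(palm_pattern(ext_tbl("ovary", -5, 50), L, "t"), "Extents")
})

test_that("bar fractions are invariant under uniform rescaling of a specimen", {
  ext <- ext_tbl("ovary", 400, 470, "cirrus_sac", 170, 455)
  p1 <- palm_pattern(ext, 1000, "t")
  scaled <- dplyr::mutate(ext, anterior = anterior * 3.7,
                          posterior = posterior * 3.7)
  p2 <- palm_pattern(scaled, 3700, "t")
  expect_equal(p1$bars, p2$bars)
})

test_that("absolute plates equalize body axes; relative plates preserve true proportion", {
  p1 <- palm_pattern(ext_tbl("ovary", 800, 1000), 2000, "small")
  p2 <- palm_pattern(ext_tbl("ovary", 1600, 2000), 4000, "large")
  cfg <- plate_config()
  abs_geom <- palmpattern:::plate_geometry(palm_plate(list(p1, p2), "absolute"), cfg)
  hs <- purrr::map_dbl(abs_geom$columns, "height")
  expect_equal(hs[1], hs[2])
  rel_geom <- palmpattern:::plate_geometry(palm_plate(list(p1, p2), "relative"), cfg)
  hs <- purrr::map_dbl(rel_geom$columns, "height")
  expect_identical(hs[2] / hs[1], 2)  # exact proportionality
  # midpoints share one transverse line
  mids <- purrr::map_dbl(rel_geom$columns, function(c) c$y0 + c$height / 2)
  expect_equal(mids[1], mids[2])
})

test_that("the to-scale plate of the packaged congeners is ordered by true size", {
  taxa <- setdiff(fixture_taxa(), "P. maternus")
  pats <- purrr::map(taxa, profile_pattern)
  Ls <- purrr::map_dbl(pats, "body_length")
  names(Ls) <- taxa
  expect_equal(unname(which.max(Ls)), which(taxa == "A. serrani"))
  expect_gt(Ls[["A. palmi"]], Ls[["A. epinepheli"]])
  geom <- palmpattern:::plate_geometry(palm_plate(pats, "relative"))
  hs <- purrr::map_dbl(geom$columns, "height")
  expect_equal(hs / max(hs), unname(Ls / max(Ls)))
})

test_that("SVG output is byte-stable with the prescribed furniture", {
  p1 <- palm_pattern(ext_tbl("ovary", 800, 1000, "cirrus_sac", 300, 900),
                     2000, "taxon one")
  p2 <- palm_pattern(ext_tbl("ovary", 1600, 2000), 4000, "taxon two")
  abs_plate <- palm_plate(list(p1, p2), "absolute")
  expect_identical(render_svg(abs_plate), render_svg(abs_plate))
  f1 <- withr::local_tempfile(fileext = ".svg")
  f2 <- withr::local_tempfile(fileext = ".svg")
  render_svg(abs_plate, f1); render_svg(abs_plate, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  svg <- render_svg(abs_plate)
  lines <- strsplit(svg, "\n")[[1]]
  # seven eighth-gridlines per column, absolute mode only
  expect_equal(sum(grepl('class="gridline"', lines)), 14)
  expect_false(any(grepl('class="scalebar"', lines)))

  rel_plate <- palm_plate(list(p1, p2), "relative")
  rel <- strsplit(render_svg(rel_plate), "\n")[[1]]
  expect_equal(sum(grepl('class="gridline"', rel)), 0)
  sb <- rel[grepl('id="scalebar"', rel)]
  x1 <- as.numeric(sub('.* x1="([0-9.]+)".*', "\\1", sb))
  x2 <- as.numeric(sub('.* x2="([0-9.]+)".*', "\\1", sb))
  cfg <- plate_config()
  expect_equal(x2 - x1, cfg$scale_bar_um * cfg$axis_length / 4000,
               tolerance = 1e-3)
})

test_that("plates render through ggplot2 as well", {
  pat <- profile_pattern("A. palmi")
  gg <- ggplot2::autoplot(palm_plate(list(pat), "absolute"))
  expect_s3_class(gg, "ggplot")
  expect_error(plate_config(axis_length = 0), "positive")
})
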