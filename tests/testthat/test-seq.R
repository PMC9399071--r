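test_that("FASTA pairs are read strictly: exactly two aligned records, upper-cased", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a desc", "acgtacgt", ">b", "ACGTACGA"), f)
  pair <- read_fasta_pair(f)
  expect_equal(pair$id_a, "a")
  expect_equal(pair$seq_a, "ACGTACGT")
  writeLines(c(">a", "ACGT", ">b", "ACGT", ">c", "ACGT"), f)
  expect_error(read_fasta_pair(f), "exactly 2")
  writeLines(c(">a", "ACGT", ">b", "ACG"), f)
  expect_error(read_fasta_pair(f), "not aligned")
  # round-trip through the writer
  p <- synth_aligned_pair(151, seed = 3)
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta_pair(p, f2)
  back <- read_fasta_pair(f2)
  expect_equal(back$seq_a, p$seq_a)
  expect_equal(back$seq_b, p$seq_b)
})

test_that("the six-difference 1031-bp comparison gives 99.4% identity, 5 ts + 1 tv", {
  pair <- synth_aligned_pair(1031, maternus_diffs(), seed = 7)
  res <- compare_aligned(pair)
  expect_equal(res$overlap_length, 1031)
  expect_equal(res$n_diff, 6)
  expect_equal(res$percent_identity, 99.4)
  expect_equal(res$n_transitions, 5)
  expect_equal(res$n_transversions, 1)
  expect_equal(res$differences$position, c(189, 308, 317, 508, 622, 837))
  expect_equal(res$differences$klass,
               c(rep("transition", 4), "transversion", "transition"))
  g <- glance(res)
  expect_equal(g$n_diff, 6)
  expect_equal(nrow(tidy(res)), 6)
})

test_that("identity handles identical pairs and excludes ambiguous columns", {
  p <- synth_aligned_pair(200, seed = 1)
  res <- compare_aligned(p)
  expect_equal(res$percent_identity, 100)
  expect_equal(res$n_diff, 0)
  pn <- aligned_pair("ACGTN", "ACGTA")
  expect_equal(compare_aligned(pn)$overlap_length, 4)
  pg <- aligned_pair("AC-TA", "ACGTA")
  expect_equal(compare_aligned(pg)$overlap_length, 4)
  expect_error(compare_aligned(aligned_pair("NNN", "NNN")), "Zero")
  expect_error(aligned_pair("ACGT", "ACG"), "equal")
  expect_error(aligned_pair("ACXT", "ACGT"), "Invalid")
})

test_that("comparison is symmetric up to swapping the base columns", {
  set.seed(21)
  for (i in 1:20) {
    sa <- random_seq(60); sb <- random_seq(60)
    f <- tryCatch(compare_aligned(aligned_pair(sa, sb)),
                  error = function(e) NULL)
    if (is.null(f)) next
    r <- compare_aligned(aligned_pair(sb, sa))
    expect_equal(f$n_diff, r$n_diff)
    expect_equal(f$n_transitions, r$n_transitions)
    expect_equal(f$differences$base_a, r$differences$base_b)
    expect_equal(f$n_transitions + f$n_transversions, f$n_diff)
  }
})

test_that("difference counts match a per-column brute-force oracle", {
  set.seed(33)
  for (i in 1:50) {
    n <- sample(20:80, 1)
    sa <- random_seq(n); sb <- random_seq(n)
    oracle <- brute_compare(sa, sb)
    if (oracle$overlap == 0) next
    res <- compare_aligned(aligned_pair(sa, sb))
    expect_equal(res$overlap_length, oracle$overlap)
    expect_equal(res$n_diff, oracle$n_diff)
  }
})

test_that("the K2P distance follows its closed form and detects saturation", {
  expect_equal(k2p_distance(P = 0, Q = 0), 0)
  # correction never below the raw difference proportion
  set.seed(9)
  for (i in 1:50) {
    P <- runif(1, 0, 0.2); Q <- runif(1, 0, 0.2)
    expect_gte(k2p_distance(P = P, Q = Q), P + Q - 1e-12)
  }
  expect_true(is.finite(k2p_distance(P = 0.25, Q = 0.25)))
  expect_error(k2p_distance(P = 0.4, Q = 0.2), "Saturation")
  expect_error(k2p_distance(P = 0, Q = 0.5), "Saturation")
})

test_that("K2P agrees with an independent phylogenetics implementation", {
  pair <- synth_aligned_pair(1031, maternus_diffs(), seed = 7)
  res <- compare_aligned(pair)
  bin <- ape::as.DNAbin(rbind(a = strsplit(tolower(pair$seq_a), "")[[1]],
                              b = strsplit(tolower(pair$seq_b), "")[[1]]))
  expect_equal(k2p_distance(res),
               as.numeric(ape::dist.dna(bin, model = "K80")),
               tolerance = 1e-12)
  # and on a denser random divergence
  d <- tibble::tibble(position = seq(5, 400, by = 7))
  set.seed(2)
  d$base_a <- sample(c("A", "C", "G", "T"), nrow(d), replace = TRUE)
  d$base_b <- purrr::map_chr(d$base_a, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1))
  pair2 <- synth_aligned_pair(500, d, seed = 4)
  res2 <- compare_aligned(pair2)
  bin2 <- ape::as.DNAbin(rbind(a = strsplit(tolower(pair2$seq_a), "")[[1]],
                               b = strsplit(tolower(pair2$seq_b), "")[[1]]))
  expect_equal(k2p_distance(res2),
               as.numeric(ape::dist.dna(bin2, model = "K80")),
               tolerance = 1e-12)
})
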