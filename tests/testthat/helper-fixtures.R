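# Shared helpers: small in-code fixtures and independent oracles.

write_temp_csv <- function(df, env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = env)
  readr::write_csv(df, path, na = "")
  path
}

# exact half-up rounding of the rational (100 * a) / b to `d` decimals,
# done in integer arithmetic (valid while 100 * a * 10^d < 2^53)
rational_percent <- function(a, b, d) {
  num <- round(100 * a * 10^d)   # a itself may carry decimals; scale first
  stopifnot(abs(num) < 2^52)
  k <- num %/% b
  frac <- num %% b
  (k + as.integer(2 * frac >= b)) / 10^d
}

# brute-force occupied-bin oracle: dense sampling of the extent interior
bins_by_sampling <- function(a, p, L, parts, n = 20000) {
  xs <- seq(a, p, length.out = n)
  xs <- xs[xs > a & xs < p]                    # interior points only
  sort(unique(pmin(floor(xs / (L / parts)) + 1, parts)))
}

# brute-force per-column comparison oracle for aligned pairs
brute_compare <- function(sa, sb) {
  a <- strsplit(sa, "")[[1]]; b <- strsplit(sb, "")[[1]]
  plain <- c("A", "C", "G", "T")
  overlap <- 0L; n_diff <- 0L
  for (i in seq_along(a)) {
    if (a[i] %in% plain && b[i] %in% plain) {
      overlap <- overlap + 1L
      if (a[i] != b[i]) n_diff <- n_diff + 1L
    }
  }
  list(overlap = overlap, n_diff = n_diff)
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T", "N", "-")) {
  paste(sample(alphabet, n, replace = TRUE,
               prob = c(rep(0.23, 4), 0.04, 0.04)), collapse = "")
}

# minimal two-couplet key definition, written to a temp file
write_tiny_key <- function(couplet2_goto = NULL, ext = "json") {
  def <- list(
    key_id = "tiny", schema_version = "1.0", start = "1",
    taxa = list("sp. one", "sp. two", "sp. three"),
    couplets = list(
      "1" = list(
        A = list(primary = list(list(kind = "categorical",
                                     state = "testes_arrangement",
                                     values = list("tandem"))),
                 auxiliary = list(), taxon = "sp. one"),
        B = list(primary = list(list(kind = "categorical",
                                     state = "testes_arrangement",
                                     values = list("diagonal"))),
                 auxiliary = list(), goto = "2")),
      "2" = list(
        A = list(primary = list(list(kind = "numeric_threshold",
                                     state = "body_length", op = "lt",
                                     value = 2, unit = "mm")),
                 auxiliary = list(),
                 taxon = "sp. two"),
        B = c(list(primary = list(list(kind = "numeric_threshold",
                                       state = "body_length", op = "ge",
                                       value = 2, unit = "mm")),
                   auxiliary = list()),
              if (is.null(couplet2_goto)) list(taxon = "sp. three")
              else list(goto = couplet2_goto)))
    ))
  path <- withr::local_tempfile(fileext = paste0(".", ext),
                                .local_envir = parent.frame())
  if (ext == "json") {
    jsonlite::write_json(def, path, auto_unbox = TRUE)
  } else {
    yaml::write_yaml(def, path)
  }
  path
}

palmi_profile <- function() load_fixture("A. palmi")
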