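# Seeded synthetic generators. The raw per-specimen measurement sheets
# behind published summary tables are rarely available; these generators
# emulate them from the printed min-max ranges so the whole pipeline is
# testable end to end. They are deliberately simple: values are drawn per
# measure within the printed range (uniform, or mean-centred truncated
# normal), with joint consistency enforced by rejection sampling. They do not
# model measurement error or allometry.

# run expr with a local RNG state seeded from `seed`
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate synthetic specimens from a species profile
#'
#' Draws `n` synthetic gravid-worm records whose every measure lies within
#' the profile's printed `[min, max]` range. Records violating joint
#' constraints are rejected and redrawn: parts must not exceed the body
#' length, the cirrus-sac reach must fit within the body, and all
#' reconstructible organ extents must validate under
#' [reconstruct_extents()] (no `invalid` rows at the given tolerance).
#' Identical seeds give identical output.
#'
#' @param profile A `species_profile` ([load_fixture()]) or a taxon name.
#' @param n Number of specimens.
#' @param seed Integer seed (mandatory: generated data must be reproducible).
#' @param sampling `"uniform"` draws uniformly in `[min, max]`;
#'   `"truncated_normal"` draws from a normal centred on the printed mean
#'   (mid-range if absent) with sd = range/4, truncated to the range.
#' @param measures Measures to draw; default: every primary range in the
#'   profile that is a µm length (ratios are recomputed, not drawn).
#' @param max_tries Rejection limit per record.
#' @param tolerance Extent-overrun tolerance passed to
#'   [reconstruct_extents()].
#' @return A specimen tibble in the same shape [read_specimens()] produces.
#' @export
#' @examples
#' x <- synth_specimens("A. palmi", n = 5, seed = 1)
#' range(x$body_length)
synth_specimens <- function(profile, n = 22, seed,
                            sampling = c("uniform", "truncated_normal"),
                            measures = NULL, max_tries = 1000,
                            tolerance = 0.02) {
  sampling <- arg_match(sampling)
  if (missing(seed)) abort("`seed` is mandatory for synthetic data.")
  if (is.character(profile)) profile <- load_fixture(profile)
  stopifnot(inherits(profile, "species_profile"), n >= 1)
  stats <- filter(profile$stats, .data$variant == "primary",
                  !.data$measure %in% ratio_measures())
  if (!is.null(measures)) {
    missing_m <- setdiff(measures, stats$measure)
    if (length(missing_m) > 0) {
      abort(paste0("Profile has no printed range for: ",
                   paste(missing_m, collapse = ", ")))
    }
    stats <- filter(stats, .data$measure %in% measures)
  }
  if (!"body_length" %in% stats$measure) {
    abort("Profile must provide a body_length range.")
  }

  draw_one <- function() {
    v <- map_dbl(seq_len(nrow(stats)), function(j) {
      lo <- stats$min[j]; hi <- stats$max[j]
      if (hi <= lo) return(lo)
      if (sampling == "uniform") return(runif(1, lo, hi))
      mu <- if (!is.na(stats$mean[j])) stats$mean[j] else (lo + hi) / 2
      sd <- (hi - lo) / 4
      repeat {
        x <- rnorm(1, mu, sd)
        if (x >= lo && x <= hi) return(x)
      }
    })
    setNames(as.list(v), stats$measure)
  }

  consistent <- function(rec) {
    L <- rec$body_length
    parts <- intersect(part_length_measures(), names(rec))
    if (any(unlist(rec[parts]) > L)) return(FALSE)
    row <- as_tibble(c(list(specimen_id = "x"), rec))
    ext <- suppressWarnings(reconstruct_extents(row, tolerance = tolerance))
    !any(ext$status == "invalid")
  }

  with_seed(seed, {
    recs <- vector("list", n)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        rec <- draw_one()
        if (consistent(rec)) { ok <- TRUE; break }
      }
      if (!ok) {
        abort(paste0(
          "Rejection limit reached: the profile's printed ranges are jointly ",
          "inconsistent (parts exceeding body length or extents overrunning ",
          "the body beyond tolerance)."))
      }
      recs[[i]] <- as_tibble(c(list(specimen_id = sprintf("synth_%02d", i)),
                               rec))
    }
    bind_rows(recs)
  })
}

#' Generate a synthetic aligned sequence pair with prescribed differences
#'
#' Builds two sequences of the given length that are identical except at the
#' prescribed positions, where they carry the prescribed bases. The shared
#' background is random (seeded, A/C/G/T equiprobable) and contains no gaps
#' or ambiguity codes, so overlap positions coincide with string positions.
#'
#' @param length Alignment length in bp.
#' @param diffs A data frame (or tibble) with columns `position`, `base_a`,
#'   `base_b`: distinct 1-based positions within `length`, with valid,
#'   unequal plain bases. May be empty for an identical pair.
#' @param seed Integer seed (mandatory).
#' @param id_a,id_b Record ids.
#' @return An `aligned_pair`.
#' @export
#' @examples
#' d <- tibble::tibble(position = c(5, 9), base_a = c("A", "T"),
#'                     base_b = c("G", "C"))
#' p <- synth_aligned_pair(20, d, seed = 7)
#' compare_aligned(p)$n_diff
synth_aligned_pair <- function(length, diffs = NULL, seed,
                               id_a = "seq_a", id_b = "seq_b") {
  if (missing(seed)) abort("`seed` is mandatory for synthetic data.")
  stopifnot(is.numeric(length), length >= 1)
  if (is.null(diffs)) {
    diffs <- tibble(position = integer(0), base_a = character(0),
                    base_b = character(0))
  }
  stopifnot(all(c("position", "base_a", "base_b") %in% names(diffs)))
  pos <- as.integer(diffs$position)
  if (anyDuplicated(pos)) abort("Difference positions must be distinct.")
  if (any(pos < 1 | pos > length)) {
    abort(sprintf("Difference position out of range 1..%d.", length))
  }
  plain <- c("A", "C", "G", "T")
  if (nrow(diffs) > 0 &&
      (!all(diffs$base_a %in% plain) || !all(diffs$base_b %in% plain) ||
         any(diffs$base_a == diffs$base_b))) {
    abort("Difference bases must be plain A/C/G/T and unequal.")
  }
  with_seed(seed, {
    bg <- sample(plain, length, replace = TRUE)
    a <- bg; b <- bg
    a[pos] <- diffs$base_a
    b[pos] <- diffs$base_b
    aligned_pair(paste(a, collapse = ""), paste(b, collapse = ""),
                 id_a = id_a, id_b = id_b)
  })
}

#' The six-difference comparison printed for the Indonesian P. maternus
#'
#' The difference catalogue (positions within the 1031-bp compared overlap of
#' the 28S marker, Indonesian vs Australian material) used by the worked
#' examples: three A/G transitions at 189, 308 and 317, T/C at 508, G/T at
#' 622, G/A at 837.
#'
#' @return Tibble with columns `position`, `base_a`, `base_b`.
#' @export
maternus_diffs <- function() {
  tibble(
    position = c(189L, 308L, 317L, 508L, 622L, 837L),
    base_a = c("A", "A", "A", "T", "G", "G"),
    base_b = c("G", "G", "G", "C", "T", "A")
  )
}
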