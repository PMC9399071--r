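# Packaged comparative species profiles: the transcribed summary table for
# the grouper-infecting Allopodocotyle species (plus the bucephalid
# P. maternus), each cell with per-cell provenance.

catalog_path <- function() {
  system.file("extdata", "species_catalog.json", package = "palmpattern",
              mustWork = TRUE)
}

read_catalog <- function() {
  cat_file <- catalog_path()
  cat_json <- jsonlite::read_json(cat_file, simplifyVector = FALSE)
  stats <- readr::read_csv(
    file.path(dirname(cat_file), cat_json$stats_file),
    col_types = readr::cols(
      taxon = "c", measure = "c", min = "d", max = "d", mean = "d",
      n = "i", variant = "c", provenance = "c", note = "c"),
    progress = FALSE)
  list(json = cat_json, stats = stats)
}

#' Taxa available in the packaged profile catalog
#'
#' @return Character vector of taxon labels accepted by [load_fixture()].
#' @export
fixture_taxa <- function() {
  names(read_catalog()$json$taxa)
}

#' Load a packaged species profile
#'
#' Returns the transcribed min/max/mean summary cells and categorical
#' character states for one taxon. Cells the source does not print are simply
#' absent (unknown); alternative values quoted from original references are
#' kept as `variant = "secondary"` rows, never merged.
#'
#' @param taxon One of [fixture_taxa()].
#' @return An object of class `species_profile`: list with `taxon`,
#'   `full_name`, `host`, `locality`, `source`, `stats` (tibble `measure`,
#'   `min`, `max`, `mean`, `n`, `variant`, `provenance`, `note`),
#'   `categoricals` (named list) and `notes`.
#' @export
#' @examples
#' p <- load_fixture("A. palmi")
#' dplyr::filter(p$stats, measure == "body_length")
load_fixture <- function(taxon) {
  cat <- read_catalog()
  if (!taxon %in% names(cat$json$taxa)) {
    abort(paste0("Unknown taxon '", taxon, "'. Available: ",
                 paste(names(cat$json$taxa), collapse = ", ")))
  }
  meta <- cat$json$taxa[[taxon]]
  stats <- filter(cat$stats, .data$taxon == !!taxon)
  stats <- select(stats, -"taxon")
  bad <- !is.na(stats$mean) & (stats$mean < stats$min | stats$mean > stats$max)
  if (any(bad)) {
    abort(paste0("Corrupt profile: mean outside [min, max] for ",
                 paste(stats$measure[bad], collapse = ", ")))
  }
  cats <- map(meta$categoricals %||% list(), function(v) {
    if (is.list(v)) unlist(v) else v
  })
  structure(list(taxon = taxon, full_name = meta$full_name,
                 host = meta$host, locality = meta$locality,
                 source = meta$source, stats = stats,
                 categoricals = cats, caveat = meta$caveat %||% NULL,
                 notes = meta$notes %||% NA_character_),
            class = "species_profile")
}

#' @export
print.species_profile <- function(x, ...) {
  cat(sprintf("%s (%s) -- %s; %s\n", x$taxon, x$full_name, x$host, x$locality))
  cat(sprintf("%d summary cells, %d categorical states\n", nrow(x$stats),
              length(x$categoricals)))
  invisible(x)
}

# Central value of a profile measure: the printed mean when available,
# otherwise the mid-range (documented proxy for taxa summarized only as
# ranges). Primary-variant cells only. NA if the measure is absent.
profile_mean <- function(profile, measure) {
  s <- filter(profile$stats, .data$measure == !!measure,
              .data$variant == "primary")
  if (nrow(s) == 0L) return(NA_real_)
  if (!is.na(s$mean[1])) s$mean[1] else (s$min[1] + s$max[1]) / 2
}

profile_range <- function(profile, measure) {
  s <- filter(profile$stats, .data$measure == !!measure,
              .data$variant == "primary")
  if (nrow(s) == 0L) return(c(NA_real_, NA_real_))
  c(s$min[1], s$max[1])
}

#' Character states of a species profile
#'
#' Instantiates a profile at its central values (printed means, mid-range
#' where no mean is printed) plus its stated categorical states, producing
#' the character-state map that [evaluate_key()] and [classify_group()]
#' consume. The squat/elongate body shape is derived from the length:width
#' ratio (threshold `elongate_threshold`), falling back to the stated
#' categorical when no ratio is computable.
#'
#' @param profile A `species_profile` from [load_fixture()].
#' @param elongate_threshold Length:width ratio at or above which a body
#'   counts as elongate (default 4.25).
#' @return Named list of character states (lengths in µm).
#' @export
profile_states <- function(profile, elongate_threshold = 4.25) {
  stopifnot(inherits(profile, "species_profile"))
  st <- list(
    body_length = profile_mean(profile, "body_length"),
    body_width = profile_mean(profile, "body_width"),
    cirrus_sac_length = profile_mean(profile, "cirrus_sac_length"),
    distance_between_testes = profile_mean(profile, "distance_between_testes"),
    sucker_width_ratio = profile_mean(profile, "sucker_width_ratio"),
    length_width_ratio = profile_mean(profile, "length_width_ratio")
  )
  if (is.na(st$length_width_ratio) && !is.na(st$body_length) &&
      !is.na(st$body_width) && st$body_width > 0) {
    st$length_width_ratio <- st$body_length / st$body_width
  }
  if (!is.na(st$length_width_ratio)) {
    st$body_shape <- if (st$length_width_ratio >= elongate_threshold)
      "elongate" else "squat"
  }
  st <- c(st, profile$categoricals)
  if (is.null(st$body_shape) && !is.null(profile$categoricals$body_shape)) {
    st$body_shape <- profile$categoricals$body_shape
  }
  compact(st[!duplicated(names(st))])
}

#' Character states of measured specimens
#'
#' Builds one character-state map per specimen row from its measurements,
#' merging in categorical states that individual measurements cannot supply
#' (testis arrangement, localization characters, overlap relations) --
#' typically the stated categoricals of the species being emulated.
#'
#' @param specimens Specimen tibble ([read_specimens()], [synth_specimens()]).
#' @param categoricals Named list of categorical states applied to every
#'   specimen (e.g. `load_fixture("A. palmi")$categoricals`).
#' @param elongate_threshold See [profile_states()].
#' @return A list of named state lists, one per row.
#' @export
specimen_states <- function(specimens, categoricals = list(),
                            elongate_threshold = 4.25) {
  stopifnot(is.data.frame(specimens))
  g <- function(row, m) if (m %in% names(row) && !is.na(row[[m]]))
    row[[m]] else NULL
  map(seq_len(nrow(specimens)), function(i) {
    row <- specimens[i, , drop = FALSE]
    st <- list(
      body_length = g(row, "body_length"),
      body_width = g(row, "body_width"),
      cirrus_sac_length = g(row, "cirrus_sac_length"),
      distance_between_testes = g(row, "distance_between_testes")
    )
    osw <- g(row, "oral_sucker_width"); vsw <- g(row, "ventral_sucker_width")
    if (!is.null(osw) && !is.null(vsw) && osw > 0) {
      st$sucker_width_ratio <- vsw / osw
    }
    if (!is.null(st$body_length) && !is.null(st$body_width) &&
        st$body_width > 0) {
      st$length_width_ratio <- st$body_length / st$body_width
      st$body_shape <- if (st$length_width_ratio >= elongate_threshold)
        "elongate" else "squat"
    }
    st <- c(st, categoricals)
    compact(st[!duplicated(names(st))])
  })
}

#' Palm pattern of a species profile
#'
#' Instantiates a profile at its central values (printed mean, else
#' mid-range), reconstructs the organ extents those values anchor, and builds
#' the Palm pattern. Organs whose anchoring measures the source does not
#' print are simply absent from the pattern; extents that cannot be
#' reconstructed validly are dropped.
#'
#' @param profile A `species_profile` or taxon name.
#' @param tolerance Extent-overrun tolerance (fraction of body length).
#' @param palette Organ colours, see [organ_palette()].
#' @return A [palm_pattern()].
#' @export
#' @examples
#' pat <- profile_pattern("A. palmi")
#' pat$bars
profile_pattern <- function(profile, tolerance = 0.02,
                            palette = organ_palette()) {
  if (is.character(profile)) profile <- load_fixture(profile)
  stopifnot(inherits(profile, "species_profile"))
  ms <- unique(filter(profile$stats, .data$variant == "primary")$measure)
  ms <- setdiff(ms, ratio_measures())
  vals <- setNames(map(ms, function(m) profile_mean(profile, m)), ms)
  row <- as_tibble(c(list(specimen_id = profile$taxon), vals))
  ext <- suppressWarnings(reconstruct_extents(row, tolerance = tolerance))
  ext <- filter(ext, .data$status != "invalid")
  palm_pattern(ext, body_length = row$body_length, taxon = profile$taxon,
               palette = palette)
}
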