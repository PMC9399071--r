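#' Read a specimen morphometry table
#'
#' Reads a CSV or TSV table of per-specimen measurements (one row per worm)
#' into a tidy tibble, one column per canonical measure in micrometres.
#' Column headers are matched case-insensitively against the alias list in
#' [measure_aliases()]; a header suffix `"(mm)"` declares millimetre input and
#' triggers conversion by 1000. Unrecognized columns are preserved unchanged
#' (prefixed `extra_` only if they collide with a canonical name).
#'
#' Rows lacking a usable `body_length` are dropped with a warning; non-numeric
#' cells in measure columns become `NA` with a warning.
#'
#' @param file Path to a CSV or TSV file (delimiter sniffed from the first
#'   line; decimal point `.`).
#' @return A tibble with a `specimen_id` column (taken from a `specimen_id` /
#'   `id` column, else generated) and one numeric column per measure present.
#' @export
read_specimens <- function(file) {
  if (!file.exists(file)) abort(paste0("File not found: ", file))
  first <- readLines(file, n = 1L)
  delim <- if (stringr::str_count(first, "\t") >
               stringr::str_count(first, ",")) "\t" else ","
  raw <- readr::read_delim(file, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)
  if (nrow(raw) == 0L) abort("Specimen table is empty.")

  heads <- map(names(raw), normalize_header)
  canon <- map_chr(heads, "canonical")
  is_mm <- map_lgl(heads, "mm")

  id_col <- which(tolower(names(raw)) %in% c("specimen_id", "specimen", "id"))[1]
  specimen_id <- if (!is.na(id_col)) as.character(raw[[id_col]]) else
    sprintf("specimen_%02d", seq_len(nrow(raw)))

  out <- tibble(specimen_id = specimen_id)
  for (j in seq_along(raw)) {
    if (!is.na(id_col) && j == id_col) next
    cn <- canon[[j]]
    if (is.na(cn)) {
      nm <- names(raw)[[j]]
      if (nm %in% c(canonical_measures(), "specimen_id")) nm <- paste0("extra_", nm)
      out[[nm]] <- raw[[j]]
      next
    }
    vals <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(!is.na(raw[[j]]) & raw[[j]] != "" & is.na(vals))
    if (length(bad) > 0) {
      warn(sprintf("Column '%s': %d non-numeric cell(s) set to NA (rows %s).",
                   names(raw)[[j]], length(bad),
                   paste(head(bad, 5), collapse = ", ")))
    }
    if (is_mm[[j]]) vals <- vals * 1000
    if (any(!is.na(vals) & vals < 0)) {
      warn(sprintf("Column '%s': negative value(s) set to NA.", names(raw)[[j]]))
      vals[!is.na(vals) & vals < 0] <- NA_real_
    }
    out[[cn]] <- vals
  }

  if (!"body_length" %in% names(out)) {
    abort("No 'body_length' column could be identified in the table header.")
  }
  drop <- is.na(out$body_length) | out$body_length <= 0
  if (any(drop)) {
    warn(sprintf("%d record(s) rejected for missing or non-positive body_length: %s",
                 sum(drop), paste(out$specimen_id[drop], collapse = ", ")))
    out <- out[!drop, , drop = FALSE]
  }
  # part lengths exceeding body length are flagged, kept, and left to
  # downstream validation (fixation artefacts are a real phenomenon)
  for (m in intersect(part_length_measures(), names(out))) {
    over <- !is.na(out[[m]]) & out[[m]] > out$body_length
    if (any(over)) {
      warn(sprintf("Measure '%s' exceeds body_length in %d record(s).",
                   m, sum(over)))
    }
  }
  out
}

#' Summarize specimen measurements into a species-profile table
#'
#' Collapses a specimen tibble into the min/max/mean(/n) summary cells used in
#' comparative morphometric tables. The mean is arithmetic over the records
#' that carry the measure; `n` counts those records.
#'
#' @param specimens Tibble from [read_specimens()] or [synth_specimens()].
#' @param measures Character vector of measures to summarize; default: all
#'   canonical measure columns present.
#' @return A tibble with columns `measure`, `min`, `max`, `mean`, `n`.
#' @export
#' @examples
#' x <- tibble::tibble(specimen_id = c("a", "b", "c"),
#'                     body_length = c(10, 20, 30))
#' summarize_morphometry(x)
summarize_morphometry <- function(specimens, measures = NULL) {
  stopifnot(is.data.frame(specimens))
  if (is.null(measures)) {
    measures <- intersect(canonical_measures(), names(specimens))
  } else {
    missing_m <- setdiff(measures, names(specimens))
    if (length(missing_m) > 0) {
      abort(paste0("Measure(s) not present in the table: ",
                   paste(missing_m, collapse = ", ")))
    }
  }
  if (length(measures) == 0L) abort("No canonical measure columns to summarize.")
  rows <- map(measures, function(m) {
    v <- specimens[[m]]
    v <- v[!is.na(v)]
    if (length(v) == 0L) {
      abort(paste0("No record carries measure '", m, "'."))
    }
    tibble(measure = m, min = min(v), max = max(v),
           mean = mean(v), n = length(v))
  })
  bind_rows(rows)
}

#' Write a summary table
#'
#' Writes the output of [summarize_morphometry()] either as CSV or as an
#' aligned plain-text table (columns `measure, min, max, mean, n`).
#'
#' @param summary Tibble from [summarize_morphometry()].
#' @param file Output path, or `NULL` to return the text invisibly printed.
#' @param format `"csv"` or `"text"`.
#' @param decimals Decimal places for the text format.
#' @return The file path (csv) or the text lines, invisibly.
#' @export
write_summary <- function(summary, file = NULL, format = c("csv", "text"),
                          decimals = 1) {
  format <- arg_match(format)
  if (format == "csv") {
    if (is.null(file)) abort("`file` is required for csv output.")
    readr::write_csv(summary, file)
    return(invisible(file))
  }
  fmt <- function(x) sprintf(paste0("%.", decimals, "f"), round_half_up(x, decimals))
  body <- sprintf("%-26s %10s %10s %10s %5d", summary$measure,
                  fmt(summary$min), fmt(summary$max), fmt(summary$mean),
                  summary$n)
  header <- sprintf("%-26s %10s %10s %10s %5s", "measure", "min", "max",
                    "mean", "n")
  lines <- c(header, body)
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(file))
  }
  invisible(lines)
}
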