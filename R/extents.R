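# Longitudinal organ extents.
#
# Coordinate convention: the body axis runs from the anterior extremity
# (0 µm) posteriorly to body_length L. An organ extent is the closed
# interval [anterior, posterior]. For binning into halves/thirds/eighths the
# bins are half-open [(k-1)L/p, kL/p), the last bin closed at L.

new_extent_row <- function(specimen_id, organ, anterior, posterior,
                           status = "ok", note = NA_character_) {
  tibble(specimen_id = specimen_id, organ = organ,
         anterior = anterior, posterior = posterior,
         status = status, note = note)
}

#' Reconstruct organ extents from standard taxonomic measurements
#'
#' Digenean descriptions anchor organ positions with a small set of distances
#' rather than coordinates. Given per-specimen measures, this reconstructs
#' longitudinal extents `[anterior, posterior]` (µm from the anterior
#' extremity) for the organs whose anchors are available:
#'
#' * oral sucker: `[0, oral_sucker_length]` (the sucker opens essentially
#'   terminally; no sub-terminal offset is quantified);
#' * ventral sucker: `[F, F + ventral_sucker_length]` with `F` the forebody
#'   length (forebody measured to the anterior margin of the sucker);
#' * cirrus-sac: `[L - R, L - R + cirrus_sac_length]` with `R` the cirrus-sac
#'   reach, the distance from the posterior extremity to the sac's
#'   anterior-most extent;
#' * posterior testis: `[L - PT - PTl, L - PT]` with `PT` the post-testicular
#'   region;
#' * anterior testis: ends `D` (distance between testes) anterior to the
#'   posterior testis;
#' * vitellarium: `[PV, PV + RF]` with `PV` the pre-vitelline region and `RF`
#'   the range of follicles.
#'
#' Extents overrunning `[0, L]` by at most `tolerance * L` (summary means are
#' internally inconsistent at about the half-percent level) are clamped with
#' status `"clamped"`; beyond the tolerance the extent is kept unclamped with
#' status `"invalid"`. Organs whose anchors are missing are skipped with a
#' warning.
#'
#' @param specimens Specimen tibble ([read_specimens()]), or a one-row tibble.
#' @param tolerance Allowed overrun as a fraction of body length (default 0.02).
#' @return A tibble with columns `specimen_id`, `organ`, `anterior`,
#'   `posterior`, `status` (`ok`/`clamped`/`invalid`), `note`.
#' @export
#' @examples
#' x <- tibble::tibble(specimen_id = "mean", body_length = 3669.4,
#'                     cirrus_sac_reach = 3046.3, cirrus_sac_length = 1045.8)
#' reconstruct_extents(x)  # cirrus-sac [623.1, 1668.9]
reconstruct_extents <- function(specimens, tolerance = 0.02) {
  stopifnot(is.data.frame(specimens), "body_length" %in% names(specimens))
  g <- function(row, m) {
    if (m %in% names(row) && !is.na(row[[m]])) row[[m]] else NA_real_
  }
  out <- vector("list", nrow(specimens))
  skipped <- character(0)
  for (i in seq_len(nrow(specimens))) {
    row <- specimens[i, , drop = FALSE]
    id <- if ("specimen_id" %in% names(row)) row$specimen_id else as.character(i)
    L <- row$body_length
    rows <- list()
    add <- function(organ, a, p) {
      if (any(is.na(c(a, p)))) {
        skipped <<- c(skipped, paste0(id, ":", organ))
        return()
      }
      status <- "ok"; note <- NA_character_
      overrun <- max(0 - a, p - L, 0)
      if (overrun > 0) {
        if (overrun <= tolerance * L) {
          note <- sprintf("overrun %.2f%% of body length clamped",
                          100 * overrun / L)
          a <- max(a, 0); p <- min(p, L)
          status <- "clamped"
        } else {
          status <- "invalid"
          note <- sprintf("overrun %.2f%% of body length exceeds tolerance",
                          100 * overrun / L)
        }
      }
      if (a >= p) {
        status <- "invalid"
        note <- "non-positive extent length"
      }
      rows[[length(rows) + 1L]] <<- new_extent_row(id, organ, a, p, status, note)
    }

    add("oral_sucker", 0, g(row, "oral_sucker_length"))
    FB <- g(row, "forebody_length")
    add("ventral_sucker", FB, FB + g(row, "ventral_sucker_length"))
    R <- g(row, "cirrus_sac_reach")
    add("cirrus_sac", L - R, L - R + g(row, "cirrus_sac_length"))
    PT <- g(row, "post_testicular_region")
    PTl <- g(row, "posterior_testis_length")
    add("posterior_testis", L - PT - PTl, L - PT)
    D <- g(row, "distance_between_testes")
    ATl <- g(row, "anterior_testis_length")
    pt_ant <- L - PT - PTl
    add("anterior_testis", pt_ant - D - ATl, pt_ant - D)
    PV <- g(row, "pre_vitelline_region")
    add("vitellarium", PV, PV + g(row, "vitelline_range"))
    out[[i]] <- bind_rows(rows)
  }
  if (length(skipped) > 0) {
    warn(paste0("Organs skipped for missing anchoring measures: ",
                paste(unique(sub(".*:", "", skipped)), collapse = ", ")))
  }
  res <- bind_rows(out)
  if (nrow(res) == 0L) return(new_extent_row(character(0), character(0),
                                             numeric(0), numeric(0))[0, ])
  arrange(res, .data$specimen_id, .data$anterior)
}

#' Locate an organ extent within equal longitudinal divisions of the body
#'
#' The body axis is divided into `parts` equal bins (halves, thirds or
#' eighths), numbered 1 (anterior) to `parts` (posterior). Returns the indices
#' of every bin whose intersection with the extent has strictly positive
#' length; an extent ending exactly on a bin boundary does not occupy the next
#' bin.
#'
#' @param anterior,posterior Extent bounds in µm, `0 <= anterior < posterior
#'   <= body_length`.
#' @param body_length Body length in µm.
#' @param parts Number of divisions: 2, 3 or 8.
#' @return Sorted integer vector of occupied bin indices (1-based).
#' @export
#' @examples
#' localize_extent(0.40 * 3669, 0.47 * 3669, 3669, parts = 8)  # 4
localize_extent <- function(anterior, posterior, body_length, parts = 8) {
  stopifnot(length(anterior) == 1L, length(posterior) == 1L,
            parts %in% c(2L, 3L, 8L))
  if (is.na(anterior) || is.na(posterior) || is.na(body_length)) {
    abort("Extent and body_length must be non-missing.")
  }
  if (!(anterior >= 0 && anterior < posterior && posterior <= body_length)) {
    abort("Extent must satisfy 0 <= anterior < posterior <= body_length.")
  }
  tol <- 1e-9 * body_length
  k <- seq_len(parts)
  lo <- (k - 1) * body_length / parts
  hi <- k * body_length / parts
  inter <- pmin(posterior, hi) - pmax(anterior, lo)
  as.integer(k[inter > tol])
}

#' Fraction of an organ extent lying inside one body region
#'
#' Supports the key predicates "completely in" (fraction == 1) and "mainly in"
#' (fraction > 0.5) a half or third of the body: returns the length of the
#' intersection of the extent with region `index` of `parts` equal divisions,
#' divided by the extent length.
#'
#' @inheritParams localize_extent
#' @param parts Number of equal divisions (2 for halves, 3 for thirds).
#' @param index Region index, 1 (anterior) .. `parts`.
#' @return Fraction in `[0, 1]`.
#' @export
#' @examples
#' region_fraction(0.48 * 1000, 0.60 * 1000, 1000, parts = 2, index = 2)
region_fraction <- function(anterior, posterior, body_length, parts = 2,
                            index = parts) {
  stopifnot(parts >= 2, index >= 1, index <= parts)
  if (any(is.na(c(anterior, posterior, body_length)))) {
    abort("Extent and body_length must be non-missing.")
  }
  if (any(posterior - anterior <= 0)) {
    abort("Zero-length extent has no region fraction.")
  }
  lo <- (index - 1) * body_length / parts
  hi <- index * body_length / parts
  inter <- pmax(0, pmin(posterior, hi) - pmax(anterior, lo))
  inter / (posterior - anterior)
}

#' Qualitative relation between two longitudinal extents
#'
#' Classifies two organ extents along the body axis as `"separated"`,
#' `"touching"` (sharing only a boundary, within `tol`) or `"overlapping"`.
#' Used e.g. for the cirrus-sac vs vitellarium clauses of identification keys.
#'
#' @param a,b Numeric length-2 vectors `c(anterior, posterior)` in µm.
#' @param tol Absolute tolerance (µm) for boundary contact.
#' @return One of `"separated"`, `"touching"`, `"overlapping"`.
#' @export
interval_relation <- function(a, b, tol = 1e-6) {
  stopifnot(length(a) == 2L, length(b) == 2L, a[1] < a[2], b[1] < b[2])
  gap <- max(b[1] - a[2], a[1] - b[2])
  if (gap > tol) "separated" else if (gap >= -tol) "touching" else "overlapping"
}
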