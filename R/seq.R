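# Pairwise comparison of pre-aligned nucleotide sequences: overlap identity,
# a catalogue of differences classified as transitions/transversions, and the
# Kimura 2-parameter distance. No alignment is performed here.

#' Construct an aligned sequence pair
#'
#' @param seq_a,seq_b Nucleotide strings of equal positive length (ACGT, N,
#'   `-`, IUPAC ambiguity codes); normalized to upper case.
#' @param id_a,id_b Sequence identifiers.
#' @return An object of class `aligned_pair`.
#' @export
aligned_pair <- function(seq_a, seq_b, id_a = "seq_a", id_b = "seq_b") {
  stopifnot(is.character(seq_a), is.character(seq_b),
            length(seq_a) == 1L, length(seq_b) == 1L)
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) == 0L || nchar(seq_a) != nchar(seq_b)) {
    abort("Sequences must be non-empty and of equal (aligned) length.")
  }
  allowed <- c("A", "C", "G", "T", "U", "N", "-",
               "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
  chars <- unique(c(strsplit(seq_a, "")[[1]], strsplit(seq_b, "")[[1]]))
  bad <- setdiff(chars, allowed)
  if (length(bad) > 0) {
    abort(paste0("Invalid sequence character(s): ", paste(bad, collapse = ", ")))
  }
  structure(list(id_a = id_a, id_b = id_b, seq_a = seq_a, seq_b = seq_b),
            class = "aligned_pair")
}

#' @export
print.aligned_pair <- function(x, ...) {
  cat(sprintf("Aligned pair (%d bp): %s vs %s\n", nchar(x$seq_a), x$id_a,
              x$id_b))
  invisible(x)
}

#' Read a pre-aligned pair of sequences from a FASTA file
#'
#' The file must contain exactly two records of equal length (already
#' aligned); record ids are preserved and sequences upper-cased.
#'
#' @param file Path to a FASTA file.
#' @return An `aligned_pair`.
#' @export
read_fasta_pair <- function(file) {
  if (!file.exists(file)) abort(paste0("File not found: ", file))
  set <- Biostrings::readBStringSet(file)
  if (length(set) != 2L) {
    abort(sprintf("Expected exactly 2 FASTA records, found %d.", length(set)))
  }
  lens <- Biostrings::width(set)
  if (lens[1] != lens[2]) {
    abort(sprintf("Records are not aligned: lengths %d and %d differ.",
                  lens[1], lens[2]))
  }
  ids <- sub("\\s.*$", "", names(set))
  aligned_pair(as.character(set[[1]]), as.character(set[[2]]),
               id_a = ids[1], id_b = ids[2])
}

#' Write an aligned pair as FASTA
#'
#' @param pair An `aligned_pair`.
#' @param file Output path.
#' @param width Line width for sequence wrapping.
#' @return The file path, invisibly.
#' @export
write_fasta_pair <- function(pair, file, width = 70) {
  stopifnot(inherits(pair, "aligned_pair"))
  wrap <- function(s) {
    starts <- seq(1, nchar(s), by = width)
    substring(s, starts, pmin(starts + width - 1, nchar(s)))
  }
  writeLines(c(paste0(">", pair$id_a), wrap(pair$seq_a),
               paste0(">", pair$id_b), wrap(pair$seq_b)), file)
  invisible(file)
}

is_transition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
}

#' Compare two aligned sequences over their unambiguous overlap
#'
#' The overlap is the set of alignment columns where both bases are plain
#' A/C/G/T (gaps, N and ambiguity codes are excluded). Differences are
#' enumerated with 1-based positions counted over the overlap and classified
#' as transitions (A<->G, C<->T) or transversions (all other pairs). Percent
#' identity is `100 * (overlap - n_diff) / overlap`, printed half-up to one
#' decimal. `P` and `Q` are the transition and transversion proportions of
#' the overlap, the inputs of [k2p_distance()].
#'
#' @param pair An `aligned_pair`.
#' @return An object of class `identity_result` with fields `overlap_length`,
#'   `n_diff`, `n_transitions`, `n_transversions`, `percent_identity`
#'   (1 decimal), `P`, `Q` and `differences` (tibble `position`, `base_a`,
#'   `base_b`, `klass`). [tidy()] returns the difference catalogue,
#'   [glance()] the one-row summary.
#' @export
compare_aligned <- function(pair) {
  stopifnot(inherits(pair, "aligned_pair"))
  a <- strsplit(pair$seq_a, "")[[1]]
  b <- strsplit(pair$seq_b, "")[[1]]
  plain <- c("A", "C", "G", "T")
  in_overlap <- a %in% plain & b %in% plain
  overlap <- sum(in_overlap)
  if (overlap == 0L) abort("Zero unambiguous overlap between the sequences.")
  ao <- a[in_overlap]; bo <- b[in_overlap]
  diff <- ao != bo
  n_diff <- sum(diff)
  pos <- which(diff)                      # 1-based within the overlap
  klass <- ifelse(is_transition(ao[pos], bo[pos]), "transition",
                  "transversion")
  n_ts <- sum(klass == "transition")
  n_tv <- n_diff - n_ts
  structure(list(
    id_a = pair$id_a, id_b = pair$id_b,
    overlap_length = overlap, n_diff = n_diff,
    n_transitions = n_ts, n_transversions = n_tv,
    percent_identity = round_half_up(100 * (overlap - n_diff) / overlap, 1),
    P = n_ts / overlap, Q = n_tv / overlap,
    differences = tibble(position = pos, base_a = ao[pos], base_b = bo[pos],
                         klass = klass)
  ), class = "identity_result")
}

#' @export
print.identity_result <- function(x, ...) {
  cat(sprintf("%s vs %s: %d bp overlap, %d difference(s) (%d ts / %d tv), %.1f%% identity\n",
              x$id_a, x$id_b, x$overlap_length, x$n_diff, x$n_transitions,
              x$n_transversions, x$percent_identity))
  if (x$n_diff > 0) print(x$differences)
  invisible(x)
}

#' @rdname compare_aligned
#' @param x An `identity_result`.
#' @param ... Ignored.
#' @method tidy identity_result
#' @export
tidy.identity_result <- function(x, ...) x$differences

#' @rdname compare_aligned
#' @method glance identity_result
#' @export
glance.identity_result <- function(x, ...) {
  tibble(id_a = x$id_a, id_b = x$id_b, overlap_length = x$overlap_length,
         n_diff = x$n_diff, n_transitions = x$n_transitions,
         n_transversions = x$n_transversions,
         percent_identity = x$percent_identity, P = x$P, Q = x$Q,
         k2p = tryCatch(k2p_distance(x), error = function(e) NA_real_))
}

#' Kimura 2-parameter distance
#'
#' Computes the K2P distance `d = -1/2 * ln((1 - 2P - Q) * sqrt(1 - 2Q))`
#' from the transition proportion `P` and transversion proportion `Q` of a
#' pairwise comparison. The substitution model distinguishes transition and
#' transversion rates; the corrected distance is never below the raw
#' proportion of differing sites `P + Q`.
#'
#' @param result An `identity_result` from [compare_aligned()]; alternatively
#'   supply the proportions `P` and `Q` directly.
#' @param P,Q Transition and transversion proportions, used when `result` is
#'   not given.
#' @return Distance in substitutions per site.
#' @export
#' @examples
#' k2p_distance(P = 5 / 1031, Q = 1 / 1031)
k2p_distance <- function(result = NULL, P = NULL, Q = NULL) {
  if (inherits(result, "identity_result")) {
    P <- result$P; Q <- result$Q
  } else if (is.null(P) || is.null(Q)) {
    abort("Supply either an identity_result or both `P` and `Q`.")
  }
  stopifnot(is.numeric(P), is.numeric(Q), P >= 0, Q >= 0)
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    abort(sprintf(
      "Saturation: K2P distance undefined for P = %.4g, Q = %.4g (1-2P-Q = %.4g, 1-2Q = %.4g).",
      P, Q, w1, w2))
  }
  -0.5 * log(w1 * sqrt(w2))
}
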