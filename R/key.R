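# Declarative quantitative dichotomous keys.
#
# A key is a rooted binary decision structure: numbered couplets, each with
# two leads (A/B). Leads carry *primary* predicates (all must hold to take
# the lead) and *auxiliary* predicates (qualitative corroboration: checked
# and reported as conflicts when they fail, but never blocking). Bounds in
# key files are in the units the printed key uses (mm); character states are
# held internally in µm.

KEY_PRED_KINDS <- c("categorical", "numeric_range", "numeric_threshold",
                    "relative_threshold", "half_location", "eighth_location",
                    "overlap_relation")

unit_factor <- function(unit) {
  switch(unit %||% "um", mm = 1000, um = 1, ratio = 1,
         abort(paste0("Unknown unit in key file: ", unit)))
}

#' Load and validate a key-definition file
#'
#' Reads a dichotomous key from a JSON or YAML definition file and validates
#' it structurally: exactly two leads (A/B) per couplet, at least one primary
#' predicate per lead, known predicate kinds and units, no dangling couplet
#' references, no cycles, all couplets reachable from the start couplet, and
#' every terminal taxon declared.
#'
#' @param file Path to a `.json`, `.yaml` or `.yml` key definition.
#' @return An object of class `key_definition`.
#' @seealso [allopodocotyle_key()] for the packaged grouper-infecting
#'   *Allopodocotyle* key.
#' @export
load_key <- function(file) {
  if (!file.exists(file)) abort(paste0("Key file not found: ", file))
  ext <- tolower(tools::file_ext(file))
  def <- switch(ext,
    json = jsonlite::read_json(file, simplifyVector = FALSE),
    yaml = ,
    yml = yaml::read_yaml(file),
    abort("Key files must be JSON or YAML.")
  )
  errors <- character(0)
  need <- setdiff(c("key_id", "start", "taxa", "couplets"), names(def))
  if (length(need) > 0) {
    abort(paste0("Key file missing required field(s): ",
                 paste(need, collapse = ", ")))
  }
  taxa <- unlist(def$taxa)
  couplets <- def$couplets
  ids <- names(couplets)

  check_pred <- function(p, where) {
    kind <- p$kind %||% "<missing>"
    if (!kind %in% KEY_PRED_KINDS) {
      errors <<- c(errors, sprintf("%s: unknown predicate kind '%s'", where, kind))
      return()
    }
    if (kind == "numeric_range") {
      if (!is.finite(p$min) || !is.finite(p$max) || p$min >= p$max) {
        errors <<- c(errors, sprintf("%s: numeric_range needs finite min < max", where))
      }
    }
    if (kind == "numeric_threshold" && !is.finite(p$value)) {
      errors <<- c(errors, sprintf("%s: numeric_threshold needs a finite value", where))
    }
    if (kind == "categorical" && length(p$values) == 0) {
      errors <<- c(errors, sprintf("%s: categorical needs allowed values", where))
    }
    if (kind %in% c("numeric_range", "numeric_threshold") &&
        !is.null(p$unit) && !p$unit %in% c("mm", "um", "ratio")) {
      errors <<- c(errors, sprintf("%s: unknown unit '%s'", where, p$unit))
    }
  }

  for (id in ids) {
    cp <- couplets[[id]]
    if (!setequal(names(cp), c("A", "B"))) {
      errors <- c(errors, sprintf("couplet %s: must have exactly leads A and B", id))
      next
    }
    for (lab in c("A", "B")) {
      lead <- cp[[lab]]
      where <- sprintf("couplet %s lead %s", id, lab)
      if (length(lead$primary %||% list()) == 0) {
        errors <- c(errors, paste0(where, ": at least one primary predicate required"))
      }
      for (p in lead$primary %||% list()) check_pred(p, where)
      for (p in lead$auxiliary %||% list()) check_pred(p, where)
      has_goto <- !is.null(lead$goto)
      has_taxon <- !is.null(lead$taxon)
      if (has_goto == has_taxon) {
        errors <- c(errors, paste0(where, ": exactly one of goto/taxon required"))
      }
      if (has_goto && !lead$goto %in% ids) {
        errors <- c(errors, sprintf("%s: dangling reference to couplet %s", where, lead$goto))
      }
      if (has_taxon && !lead$taxon %in% taxa) {
        errors <- c(errors, sprintf("%s: terminal taxon '%s' not declared", where, lead$taxon))
      }
    }
  }
  if (!def$start %in% ids) {
    errors <- c(errors, sprintf("start couplet %s does not exist", def$start))
  }

  if (length(errors) == 0) {
    # cycle + reachability check by DFS from the start couplet
    state <- new.env(parent = emptyenv())
    visit <- function(id, stack) {
      if (id %in% stack) {
        errors <<- c(errors, paste0("cycle detected: ",
                                    paste(c(stack, id), collapse = " -> ")))
        return()
      }
      if (!is.null(state[[id]])) return()
      state[[id]] <- TRUE
      for (lab in c("A", "B")) {
        g <- couplets[[id]][[lab]]$goto
        if (!is.null(g)) visit(g, c(stack, id))
      }
    }
    visit(def$start, character(0))
    unreachable <- setdiff(ids, ls(state))
    if (length(unreachable) > 0) {
      errors <- c(errors, paste0("unreachable couplet(s): ",
                                 paste(unreachable, collapse = ", ")))
    }
  }
  if (length(errors) > 0) {
    abort(paste0("Invalid key definition:\n",
                 paste0("  - ", errors, collapse = "\n")))
  }
  structure(list(key_id = def$key_id, title = def$title %||% def$key_id,
                 schema_version = def$schema_version %||% NA_character_,
                 start = def$start, taxa = taxa, couplets = couplets,
                 file = file),
            class = "key_definition")
}

#' The packaged key to grouper-infecting Allopodocotyle species
#'
#' Loads the encoded six-couplet key (seven terminal taxa) shipped with the
#' package.
#'
#' @return A `key_definition`.
#' @export
allopodocotyle_key <- function() {
  load_key(system.file("extdata", "allopodocotyle_key.json",
                       package = "palmpattern", mustWork = TRUE))
}

#' @export
print.key_definition <- function(x, ...) {
  cat(sprintf("Key '%s': %d couplets, %d terminal taxa (start at %s)\n",
              x$key_id, length(x$couplets), length(x$taxa), x$start))
  invisible(x)
}

# All terminal taxa reachable from a couplet (the couplet's subtree).
subtree_taxa <- function(key, id) {
  cp <- key$couplets[[id]]
  out <- character(0)
  for (lab in c("A", "B")) {
    lead <- cp[[lab]]
    out <- c(out, if (!is.null(lead$taxon)) lead$taxon else
      subtree_taxa(key, lead$goto))
  }
  unique(out)
}

describe_predicate <- function(p) {
  switch(p$kind,
    categorical = sprintf("%s in {%s}", p$state,
                          paste(unlist(p$values), collapse = ", ")),
    numeric_range = sprintf("%s in [%g, %g] %s", p$state, p$min, p$max,
                            p$unit %||% "um"),
    numeric_threshold = sprintf("%s %s %g %s", p$state, p$op, p$value,
                                p$unit %||% "um"),
    relative_threshold = sprintf("%s %s %g%% of %s", p$state, p$op,
                                 100 * p$fraction, p$relative_to),
    half_location = sprintf("%s %s in %s half", p$organ, p$completeness, p$half),
    eighth_location = sprintf("%s restricted to eighth(s) %s", p$organ,
                              paste(unlist(p$bins), collapse = ",")),
    overlap_relation = sprintf("%s vs %s: %s", p$organ_a, p$organ_b, p$relation)
  )
}

# Evaluate one predicate against a character-state map.
# Returns list(value = TRUE/FALSE/NA, missing = chr of state names needed).
eval_predicate <- function(p, states) {
  get_state <- function(nm) {
    if (nm %in% names(states) && !is.null(states[[nm]]) &&
        !all(is.na(states[[nm]]))) states[[nm]] else NULL
  }
  res <- function(value, missing = character(0)) list(value = value, missing = missing)

  if (p$kind == "categorical") {
    v <- get_state(p$state)
    if (is.null(v)) return(res(NA, p$state))
    return(res(as.character(v) %in% unlist(p$values)))
  }
  if (p$kind == "numeric_range") {
    v <- get_state(p$state)
    if (is.null(v)) return(res(NA, p$state))
    f <- unit_factor(p$unit)
    return(res(v >= p$min * f && v <= p$max * f))
  }
  if (p$kind == "numeric_threshold") {
    v <- get_state(p$state)
    if (is.null(v)) return(res(NA, p$state))
    b <- p$value * unit_factor(p$unit)
    return(res(switch(p$op, lt = v < b, le = v <= b, gt = v > b, ge = v >= b,
                      abort(paste0("Unknown comparator: ", p$op)))))
  }
  if (p$kind == "relative_threshold") {
    v <- get_state(p$state); ref <- get_state(p$relative_to)
    miss <- c(if (is.null(v)) p$state, if (is.null(ref)) p$relative_to)
    if (length(miss) > 0) return(res(NA, miss))
    b <- p$fraction * ref
    return(res(switch(p$op, lt = v < b, le = v <= b, gt = v > b, ge = v >= b)))
  }
  if (p$kind == "half_location") {
    frac_state <- paste0(p$organ, "_posterior_half_fraction")
    cat_state <- paste0(p$organ, "_half")
    f <- get_state(frac_state)
    if (!is.null(f)) {
      v <- switch(paste(p$half, p$completeness),
        "posterior completely" = abs(f - 1) < 1e-9,
        "posterior mainly"     = f > 0.5,
        "anterior completely"  = f < 1e-9,
        "anterior mainly"      = f < 0.5)
      return(res(v))
    }
    cv <- get_state(cat_state)
    if (is.null(cv)) return(res(NA, c(frac_state, cat_state)))
    cv <- as.character(cv)
    v <- switch(paste(p$half, p$completeness),
      "posterior completely" = cv %in% c("completely_posterior", "posterior"),
      "posterior mainly"     = cv %in% c("mainly_posterior",
                                         "completely_posterior", "posterior"),
      "anterior completely"  = cv %in% "anterior",
      "anterior mainly"      = cv %in% "anterior")
    return(res(v))
  }
  if (p$kind == "eighth_location") {
    st <- paste0(p$organ, "_eighths")
    v <- get_state(st)
    if (is.null(v)) return(res(NA, st))
    v <- as.integer(unlist(v))
    return(res(length(v) > 0 && all(v %in% unlist(p$bins))))
  }
  if (p$kind == "overlap_relation") {
    st <- paste0(p$organ_a, "_", p$organ_b, "_relation")
    v <- get_state(st)
    if (!is.null(v)) return(res(as.character(v) == p$relation))
    ea <- get_state(paste0(p$organ_a, "_extent"))
    eb <- get_state(paste0(p$organ_b, "_extent"))
    if (!is.null(ea) && !is.null(eb)) {
      return(res(interval_relation(ea, eb) == p$relation))
    }
    return(res(NA, st))
  }
  abort(paste0("Unknown predicate kind: ", p$kind))
}

# Lead status under a state map: "hold" (all primaries true), "fail" (any
# false), "unknown" (no false, but needed states missing).
lead_status <- function(lead, states) {
  missing <- character(0)
  vals <- logical(0)
  for (p in lead$primary) {
    r <- eval_predicate(p, states)
    if (is.na(r$value)) missing <- c(missing, r$missing)
    vals <- c(vals, r$value)
  }
  status <- if (any(!vals, na.rm = TRUE)) "fail" else
    if (anyNA(vals)) "unknown" else "hold"
  list(status = status, missing = unique(missing))
}

new_key_result <- function(outcome, taxon = NA_character_,
                           candidates = character(0),
                           missing = character(0), path, conflicts) {
  structure(list(outcome = outcome, taxon = taxon, candidates = candidates,
                 missing_states = missing, path = path, conflicts = conflicts),
            class = "key_result")
}

#' Run a specimen's character states through a dichotomous key
#'
#' Deterministically traverses the key from its start couplet. At each couplet
#' the unique lead whose primary predicates all hold is taken. If, under the
#' known states, both leads hold or neither does, the result is `ambiguous`
#' with the union of both subtrees' taxa as candidates; if a needed state is
#' unknown the result is `insufficient`, naming the missing characters.
#' Auxiliary predicate failures along the path are recorded as conflicts and
#' never block.
#'
#' @param key A `key_definition` from [load_key()].
#' @param states A named list (or one-row data frame) of character states.
#'   Numeric length states are in µm; see the packaged key for state names
#'   (e.g. `testes_arrangement`, `body_length`, `cirrus_sac_length`,
#'   `ovary_half` or `ovary_posterior_half_fraction`,
#'   `uterine_coils_eighths`, `cirrus_sac_vitellarium_relation`).
#' @return An object of class `key_result` with fields `outcome` (`"taxon"`,
#'   `"ambiguous"` or `"insufficient"`), `taxon`, `candidates`,
#'   `missing_states`, `path` and `conflicts`. Use [tidy()] for the path and
#'   [glance()] for a one-row summary.
#' @export
evaluate_key <- function(key, states) {
  stopifnot(inherits(key, "key_definition"))
  if (is.data.frame(states)) {
    stopifnot(nrow(states) == 1L)
    states <- as.list(states)
  }
  known <- c("testes_arrangement", "body_length", "body_width", "body_shape",
             "uterus_half", "gonads_third", "cirrus_sac_length",
             "sucker_width_ratio", "length_width_ratio",
             "distance_between_testes", "ovary_half",
             "ovary_posterior_half_fraction", "anterior_testis_half",
             "anterior_testis_posterior_half_fraction",
             "uterine_coils_eighths", "ovary_eighths",
             "anterior_testis_eighths", "posterior_testis_eighths",
             "cirrus_sac_vitellarium_relation",
             "cirrus_sac_ventral_sucker_relation")
  extras <- setdiff(names(states),
                    c(known, grep("_extent$", names(states), value = TRUE)))
  if (length(extras) > 0) {
    warn(paste0("Unknown character state(s) ignored: ",
                paste(extras, collapse = ", ")))
  }

  path <- tibble(couplet = character(0), lead = character(0),
                 text = character(0))
  conflicts <- tibble(couplet = character(0), lead = character(0),
                      predicate = character(0), note = character(0))
  id <- key$start
  repeat {
    cp <- key$couplets[[id]]
    a <- lead_status(cp$A, states)
    b <- lead_status(cp$B, states)
    st <- c(a$status, b$status)
    if ("unknown" %in% st) {
      # cannot prove a unique lead: missing information
      missing <- unique(c(if (a$status == "unknown") a$missing,
                          if (b$status == "unknown") b$missing))
      cand <- unique(c(
        if (a$status != "fail") lead_taxa(key, cp$A),
        if (b$status != "fail") lead_taxa(key, cp$B)))
      return(new_key_result("insufficient", candidates = cand,
                            missing = missing, path = path,
                            conflicts = conflicts))
    }
    if (a$status == b$status) {
      cand <- unique(c(lead_taxa(key, cp$A), lead_taxa(key, cp$B)))
      return(new_key_result("ambiguous", candidates = cand, path = path,
                            conflicts = conflicts))
    }
    lab <- if (a$status == "hold") "A" else "B"
    lead <- cp[[lab]]
    for (p in lead$auxiliary %||% list()) {
      r <- eval_predicate(p, states)
      if (!is.na(r$value) && !r$value) {
        conflicts <- bind_rows(conflicts, tibble(
          couplet = id, lead = lab, predicate = describe_predicate(p),
          note = p$note %||% NA_character_))
      }
    }
    lead_text <- lead$text %||% NA_character_
    path <- bind_rows(path, tibble(couplet = id, lead = lab,
                                   text = lead_text))
    if (!is.null(lead$taxon)) {
      return(new_key_result("taxon", taxon = lead$taxon,
                            candidates = lead$taxon, path = path,
                            conflicts = conflicts))
    }
    id <- lead$goto
  }
}

lead_taxa <- function(key, lead) {
  if (!is.null(lead$taxon)) lead$taxon else subtree_taxa(key, lead$goto)
}

#' @export
print.key_result <- function(x, ...) {
  cat(switch(x$outcome,
    taxon = sprintf("Identification: %s\n", x$taxon),
    ambiguous = sprintf("Ambiguous among: %s\n",
                        paste(x$candidates, collapse = ", ")),
    insufficient = sprintf("Insufficient states; missing: %s\n",
                           paste(x$missing_states, collapse = ", "))))
  if (nrow(x$path) > 0) {
    cat("Path:", paste0(x$path$couplet, x$path$lead, collapse = " -> "), "\n")
  }
  if (nrow(x$conflicts) > 0) {
    cat(sprintf("%d auxiliary conflict(s):\n", nrow(x$conflicts)))
    cat(paste0("  ", x$conflicts$couplet, x$conflicts$lead, ": ",
               x$conflicts$predicate, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' @rdname evaluate_key
#' @param x A `key_result`.
#' @param ... Ignored.
#' @method tidy key_result
#' @export
tidy.key_result <- function(x, ...) x$path

#' @rdname evaluate_key
#' @method glance key_result
#' @export
glance.key_result <- function(x, ...) {
  tibble(outcome = x$outcome, taxon = x$taxon,
         n_candidates = length(x$candidates),
         candidates = paste(x$candidates, collapse = "; "),
         n_steps = nrow(x$path), n_conflicts = nrow(x$conflicts),
         missing_states = paste(x$missing_states, collapse = "; "))
}

#' Morphological group (A/B/C) of a grouper-infecting Allopodocotyle
#'
#' The grouper-infecting species fall into three morphological groups defined
#' by testis arrangement and cirrus-sac extent: group C has tandem testes;
#' groups A and B have diagonal testes, with the cirrus-sac extending from
#' well anterior of the ventral sucker to well posterior of it (A) or just
#' overlapping the sucker's anterior margin (B).
#'
#' @param states Named list of character states. Requires
#'   `testes_arrangement`; for diagonal testes, either
#'   `cirrus_sac_ventral_sucker_relation` (`"well_posterior"` /
#'   `"just_overlapping_anterior"`) or the two extents
#'   `cirrus_sac_extent` and `ventral_sucker_extent` (length-2 µm vectors),
#'   from which the relation is derived: the cirrus-sac reaching past the
#'   sucker's posterior margin counts as "well posterior".
#' @return A list with `group` (`"A"`, `"B"`, `"C"` or `NA`) and
#'   `missing_states`.
#' @export
classify_group <- function(states) {
  if (is.data.frame(states)) states <- as.list(states)
  ta <- states[["testes_arrangement"]]
  if (is.null(ta) || is.na(ta)) {
    return(list(group = NA_character_, missing_states = "testes_arrangement"))
  }
  if (ta == "tandem") return(list(group = "C", missing_states = character(0)))
  rel <- states[["cirrus_sac_ventral_sucker_relation"]]
  if (is.null(rel)) {
    cs <- states[["cirrus_sac_extent"]]
    vs <- states[["ventral_sucker_extent"]]
    if (!is.null(cs) && !is.null(vs)) {
      rel <- if (cs[2] > vs[2]) "well_posterior"
        else if (cs[2] > vs[1]) "just_overlapping_anterior"
        else "not_reaching"
    }
  }
  if (is.null(rel)) {
    return(list(group = NA_character_,
                missing_states = "cirrus_sac_ventral_sucker_relation"))
  }
  group <- switch(as.character(rel),
                  well_posterior = "A",
                  just_overlapping_anterior = "B",
                  NA_character_)
  list(group = group, missing_states = character(0))
}
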