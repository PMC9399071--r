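# Canonical measurement vocabulary for digenean whole-mount morphometrics.
# All lengths are stored in micrometres (µm); millimetre input is accepted
# only through an explicit "(mm)" column-header suffix.

#' Canonical measure names
#'
#' The package stores one column per measure, named canonically. Length-type
#' measures are in micrometres. `canonical_measures()` returns the full
#' vocabulary; `measure_aliases()` returns the header-alias lookup used by
#' [read_specimens()].
#'
#' @return A character vector of canonical measure names, or a named character
#'   vector mapping lower-case header aliases to canonical names.
#' @export
canonical_measures <- function() {
  c(
    "body_length", "body_width",
    "forebody_length",
    "oral_sucker_length", "oral_sucker_width",
    "ventral_sucker_length", "ventral_sucker_width",
    "pharynx_length", "pharynx_width",
    "oesophagus_length",
    "distance_between_testes",
    "anterior_testis_length", "anterior_testis_width",
    "posterior_testis_length", "posterior_testis_width",
    "post_testicular_region",
    "cirrus_sac_length", "cirrus_sac_width", "cirrus_sac_reach",
    "ovary_length", "ovary_width",
    "pre_ovarian_region", "pre_vitelline_region", "vitelline_range",
    "egg_length", "egg_width",
    "length_width_ratio", "sucker_width_ratio", "sucker_length_ratio"
  )
}

# measures that are dimensionless ratios rather than µm lengths
ratio_measures <- function() {
  c("length_width_ratio", "sucker_width_ratio", "sucker_length_ratio")
}

# part-length measures that must not exceed body_length
part_length_measures <- function() {
  setdiff(canonical_measures(),
          c("body_length", ratio_measures(),
            # reach and regions are distances along the body, still <= L,
            # but egg measures are independent of body length
            "egg_length", "egg_width"))
}

#' @rdname canonical_measures
#' @export
measure_aliases <- function() {
  al <- c(
    "length"                  = "body_length",
    "body length"             = "body_length",
    "width"                   = "body_width",
    "body width"              = "body_width",
    "forebody"                = "forebody_length",
    "forebody length"         = "forebody_length",
    "oral sucker length"      = "oral_sucker_length",
    "oral sucker width"       = "oral_sucker_width",
    "ventral sucker length"   = "ventral_sucker_length",
    "ventral sucker width"    = "ventral_sucker_width",
    "pharynx length"          = "pharynx_length",
    "pharynx width"           = "pharynx_width",
    "oesophagus"              = "oesophagus_length",
    "oesophagus length"       = "oesophagus_length",
    "esophagus length"        = "oesophagus_length",
    "distance between testes" = "distance_between_testes",
    "anterior testis length"  = "anterior_testis_length",
    "anterior testis width"   = "anterior_testis_width",
    "posterior testis length" = "posterior_testis_length",
    "posterior testis width"  = "posterior_testis_width",
    "post-testicular region"  = "post_testicular_region",
    "posttesticular region"   = "post_testicular_region",
    "cirrus-sac length"       = "cirrus_sac_length",
    "cirrus sac length"       = "cirrus_sac_length",
    "cirrus-sac width"        = "cirrus_sac_width",
    "cirrus sac width"        = "cirrus_sac_width",
    "cirrus-sac reach"        = "cirrus_sac_reach",
    "cirrus sac reach"        = "cirrus_sac_reach",
    "ovary length"            = "ovary_length",
    "ovary width"             = "ovary_width",
    "pre-ovarian region"      = "pre_ovarian_region",
    "preovarian region"       = "pre_ovarian_region",
    "pre-vitelline region"    = "pre_vitelline_region",
    "previtelline region"     = "pre_vitelline_region",
    "range of follicles"      = "vitelline_range",
    "vitelline range"         = "vitelline_range",
    "eggs length"             = "egg_length",
    "egg length"              = "egg_length",
    "eggs width"              = "egg_width",
    "egg width"               = "egg_width"
  )
  # canonical names map to themselves
  self <- setNames(canonical_measures(), canonical_measures())
  c(al, self)
}

# Normalize one raw header to (canonical name | NA, mm flag).
normalize_header <- function(h) {
  raw <- stringr::str_trim(h)
  mm <- stringr::str_detect(raw, stringr::regex("\\(\\s*mm\\s*\\)\\s*$",
                                                ignore_case = TRUE))
  key <- stringr::str_remove(raw, stringr::regex("\\(\\s*mm\\s*\\)\\s*$",
                                                 ignore_case = TRUE))
  key <- tolower(stringr::str_trim(key))
  key <- stringr::str_replace_all(key, "\\s+", " ")
  al <- measure_aliases()
  canon <- if (key %in% names(al)) unname(al[[key]]) else NA_character_
  list(canonical = canon, mm = mm, raw = raw)
}

#' Default organ palette for Palm patterns
#'
#' Named colours, in anterior-to-posterior legend order, for the organ bars of
#' a Palm pattern plate. Organs not in the palette receive a deterministic
#' fallback colour derived from the organ name.
#'
#' @return Named character vector of colours.
#' @export
organ_palette <- function() {
  c(
    oral_sucker        = "#1f78b4",
    ventral_sucker     = "#a6cee3",
    cirrus_sac         = "#e31a1c",
    uterine_coils      = "#fdbf6f",
    ovary              = "#ff7f00",
    anterior_testis    = "#33a02c",
    posterior_testis   = "#b2df8a",
    vitellarium        = "#6a3d9a",
    seminal_receptacle = "#cab2d6"
  )
}

# Deterministic fallback colour: hash the organ name onto a fixed wheel.
fallback_color <- function(organ) {
  wheel <- c("#8dd3c7", "#bebada", "#fb8072", "#80b1d3", "#fdb462",
             "#b3de69", "#fccde5", "#d9d9d9", "#bc80bd", "#ccebc5")
  idx <- (sum(utf8ToInt(organ)) %% length(wheel)) + 1L
  wheel[[idx]]
}

organ_color <- function(organ, palette = organ_palette()) {
  ifelse(organ %in% names(palette),
         unname(palette[organ]),
         vapply(organ, fallback_color, character(1)))
}
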