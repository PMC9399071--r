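---
title: "Palm patterns, quantitative keys and pairwise sequence comparison for digenean morphometrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Palm patterns, quantitative keys and pairwise sequence comparison for digenean morphometrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palmpattern)
```

## The problem

Species of intestinal flukes (Digenea) infecting groupers are told apart
almost entirely by morphometry: body length and width, sucker sizes and
their ratios, and — critically — *where along the body axis* the internal
organs lie (ovary, testes, cirrus-sac, uterine coils, vitelline follicle
fields). Published descriptions compress all of this into min–max(mean)
summary cells and free-text phrases such as "ovary mainly in posterior half
of body". This package makes those conventions computable:

* **morphometric core** — reading per-specimen measurement tables,
  summarizing them into comparison-table cells, computing the printed
  "% of body length" and "x:1" ratio quantities, reconstructing organ
  extents from the standard anchoring distances, and locating extents in
  halves/thirds/eighths of the body;
* **Palm patterns** — the schematic bar-diagram representation of a worm (a
  black body bar with coloured organ bars), drawn either body-normalized
  ("absolute", positions comparable) or to scale and midline-aligned
  ("relative", sizes comparable), rendered as deterministic SVG;
* **key engine** — a declarative, validated representation of quantitative
  dichotomous keys, shipped with the encoded key to the grouper-infecting
  *Allopodocotyle* species and the A/B/C morphological-group classifier;
* **sequence comparison** — overlap identity, a transition/transversion
  difference catalogue and the Kimura 2-parameter (K2P) distance for
  pre-aligned pairs;
* **fixtures and generators** — the transcribed comparative profiles of
  nine taxa, and seeded synthetic generators for specimen tables and
  aligned pairs, so the whole pipeline is testable without any downloads.

## Coordinates, units and rounding

All lengths are stored in micrometres. The body axis runs from the anterior
extremity (0) posteriorly to the body length $L$; an organ extent is the
interval $[a, p]$ on that axis. For binning, the body is divided into
half-open bins $[(k-1)L/n,\,kL/n)$ with the last bin closed at $L$, so bin
membership is unambiguous: an extent ending exactly on a boundary does not
occupy the next bin, and a bin counts as occupied only when the intersection
has strictly positive length.

Millimetre input is accepted only through an explicit `"(mm)"` header
suffix; key files use millimetres because printed keys do, and bounds are
converted at load. Printed values are reproduced with half-up rounding
(`round_half_up()`), applied only at presentation — stored values are never
rounded.

Two ratio conventions coexist in descriptions and are kept distinct here:
*ratio of means* (e.g. mean cirrus-sac over mean body length, the "28.5% of
mean body length" convention) and *mean of ratios* (e.g. a "Forebody %"
mean computed per specimen). `percent_of_body()` and `ratio_to_one()`
compute either, depending on which inputs you give them; the summary
functions never silently pick one.

## Reconstructing organ extents

Descriptions anchor organs with distances, not coordinates. With
$L$ = body length, $F$ = forebody length, $R$ = cirrus-sac reach (distance
from the **posterior** extremity to the sac's anterior-most extent),
$PT$ = post-testicular region, $D$ = distance between testes,
$PV$ = pre-vitelline region and $RF$ = range of follicles:

| organ | extent |
|---|---|
| oral sucker | $[0,\ \mathrm{OS}_{len}]$ |
| ventral sucker | $[F,\ F + \mathrm{VS}_{len}]$ |
| cirrus-sac | $[L-R,\ L-R+\mathrm{CS}_{len}]$ |
| posterior testis | $[L-PT-\mathrm{PT}_{len},\ L-PT]$ |
| anterior testis | ends $D$ anterior to the posterior testis |
| vitellarium | $[PV,\ PV+RF]$ |

Design choices worth stating:

* **Oral sucker anchored at 0.** The sucker opens ventro-subterminally, but
  no sub-terminal offset is ever quantified in descriptions, so the offset
  defaults to zero (overridable by supplying a direct extent).
* **Forebody to the anterior margin** of the ventral sucker. Whether
  "forebody" ends at the sucker's anterior margin or centre is convention,
  not measurement; the anterior-margin reading is assumed throughout, which
  makes the reconstructed ventral-sucker anterior equal the forebody length
  exactly (a tested invariant).
* **Clamping tolerance 2% of $L$.** Summary means are internally
  inconsistent: at the packaged table means, $PV + RF = 3686.4$ µm against
  $L = 3669.4$ µm, a 0.46% overrun. Such overruns (≤ 2% of $L$) are clamped
  with a recorded note; larger ones mark the extent `invalid` and it is
  excluded from plotting and key states.
* **Ovary and uterine coils have no printed anchors.** No table distance
  locates them, so they enter patterns and key states only as direct
  extents or categorical statements — the package does not invent
  positions.

```{r}
worm <- tibble::tibble(specimen_id = "mean", body_length = 3669.4,
                       cirrus_sac_reach = 3046.3, cirrus_sac_length = 1045.8,
                       forebody_length = 717.3, ventral_sucker_length = 304.1)
suppressWarnings(reconstruct_extents(worm))
```

## Palm patterns and their rendering

`palm_pattern()` normalizes extents to fractions of $L$;
`palm_plate(..., mode = )` arranges patterns for comparison and
`render_svg()` draws them. Absolute mode maps every body to the same drawn
axis with the seven eighth-division gridlines; relative mode scales drawn
lengths proportionally to true body length and centres all bodies on one
transverse axis, with a 300-µm scale bar (configurable via
`plate_config()`).

Rendering choices: bodies are vertical, anterior up, matching habitus
figures; overlapping organ bars are laid out in parallel lanes by a greedy
deterministic assignment rather than stacked with transparency; the SVG
writer emits fixed element order, fixed ids and fixed number formatting, so
identical inputs give byte-identical documents — the property the test
suite pins down. The published plates of this kind were assembled by hand
in image-editing software, so no pixel-level reference exists; the organ
palette and bar composition are therefore configuration, not a
reproduction, and the tested guarantees are structural (fraction
round-trip, scale invariance, exact proportionality, determinism). A
`ggplot2::autoplot()` view exists for interactive work; the SVG is the
contract output.

```{r}
taxa <- c("A. palmi", "A. epinepheli", "A. heronensis")
plate <- palm_plate(lapply(taxa, profile_pattern), mode = "absolute")
substr(render_svg(plate), 1, 120)
```

## The key engine

Keys are shipped as versioned JSON (or YAML) with explicit units on every
bound, validated at load (two leads per couplet, no cycles, no dangling
references, all couplets reachable, all terminal taxa declared). Evaluation
is three-valued: each lead's primary predicates are true, false or unknown
under the supplied states, and the traversal takes the unique lead that
holds. If both or neither lead holds under known states the result is
`ambiguous` with both subtrees' taxa as candidates — a deliberate refusal
to tie-break silently, because a key is an identification aid, not a
classifier. If a needed state is unknown the result is `insufficient`,
naming the missing characters. This gives two provable properties (both
stress-tested): adding states never changes a resolved outcome, and an
unresolved outcome always keeps the true taxon among its candidates.

Encoding choices for the packaged *Allopodocotyle* key:

* **Primary vs auxiliary.** Decidable, measurable clauses (body length and
  width, cirrus-sac length, half/eighth localization, overlap relations)
  are primary; qualitative descriptors ("testes very well separated",
  encoded as a threshold of 5% of body length on the inter-testis distance)
  and sucker ratios are auxiliary — checked and reported as conflicts,
  never blocking. Sucker ratios are auxiliary throughout because the
  printed couplet values conflict with the comparison table for at least
  one species (couplet 4's "sucker ratio 1:2.4" against the table's
  2.0–2.2).
* **One deliberate deviation:** in couplet 2 lead A the cirrus-sac clause
  ("< 0.5 mm") is auxiliary rather than primary, because the comparison
  table's value for that species is drawing-derived (510 µm) and
  contradicts the printed bound; with the clause primary, the species
  could not key out as itself from its own table values. Body length and
  width remain primary and fully discriminate the couplet; the conflict is
  surfaced in the result rather than hidden.
* **"Mainly" and "completely"** in a half of the body mean region fraction
  > 0.5 and = 1 respectively (after clamping); fractions may be supplied
  directly or as categorical statements.
* **Squat vs elongate** is derived from the length:width ratio with a
  threshold of 4.25, chosen to separate the one squat species (ratio
  2.2–3.7) from the elongate ones on the branch where shape is tested
  (ratios ≥ 4.3 there); it is an encoding choice, documented, not source
  text.
* **Point values** printed without a range ("cirrus-sac 0.75 mm") carry a
  10% tolerance band.
* **Outlier bounds**: "body > 2.7 (2.4 for an outlier) mm" is primary at
  ≥ 2.4 mm with an auxiliary note above 2.7 mm.
* **Overlap relations from statements, not means.** The cirrus-sac vs
  vitellarium relation in couplet 6 is taken from the stated categorical
  ("usually well separated"), because reconstructing both extents from
  summary means manufactures a spurious overlap — the same 0.46%
  mean-inconsistency noted above, amplified: at table means the cirrus-sac
  posterior (1668.9 µm) overruns the pre-vitelline region (1565.3 µm).
  Extent-derived relations stay available via `interval_relation()` as a
  diagnostic.
* Taxa whose table means are not printed are instantiated at mid-range —
  the only neutral point estimate a range supports.
* One profiled taxon (a literature record of uncertain testis arrangement)
  is shipped with its profile but deliberately excluded from the key, as
  its source wording is ambiguous on the primary character.

```{r}
key <- allopodocotyle_key()
evaluate_key(key, profile_states(load_fixture("A. palmi")))
```

## Sequence comparison

`compare_aligned()` counts over the *unambiguous overlap*: columns where
both bases are plain A/C/G/T. Gaps, N and IUPAC ambiguity codes are
excluded entirely rather than partially matched — the convention that
reproduces simple printed difference counts. Transitions are A↔G and C↔T;
everything else is a transversion. Percent identity is rounded half-up to
one decimal. The K2P distance uses the closed form
$d = -\tfrac12 \ln\big((1-2P-Q)\sqrt{1-2Q}\big)$ with transition and
transversion proportions $P$ and $Q$; the log's domain boundary is reported
as an explicit saturation error, and the test suite cross-checks the
implementation against an independent phylogenetics package and verifies
the $d \to P+Q$ limit for small divergences. No alignment, database search
or tree inference is performed here — inputs must be pre-aligned pairs.

```{r}
pair <- synth_aligned_pair(1031, maternus_diffs(), seed = 7)
glance(compare_aligned(pair))
```

## What the synthetic generators emulate — and what they do not

`synth_specimens()` stands in for the raw per-specimen sheet behind a
published summary table: `n` records (default 22, the size of the type
series it emulates), each measure drawn within the printed min–max range,
with joint consistency enforced by rejection (parts within the body,
cirrus-sac reach within the body, reconstructed extents valid at the 2%
tolerance). Uniform-in-range is the default; a truncated normal centred on
the printed mean with sd = range/4 is available for recovery-style checks.
Seeds are mandatory and output is identical across runs for a given seed.

The generators deliberately do **not** model measurement error, allometric
growth, fixation and flattening artefacts, or correlations between
measures beyond the hard consistency constraints; nor do they generate
sequences under a substitution model (the aligned-pair generator plants
prescribed differences on a shared random background). Passing tests on
synthetic data therefore demonstrate that the pipeline is faithful to the
printed ranges and conventions — not that it is robust to the biological
and preparation variance of real material. Because uniform draws within
overlapping printed ranges can legitimately satisfy a neighbouring
species' couplet bounds, the key-recovery check accepts "resolved to, or
ambiguous including, the source species"; with the packaged profiles the
observed recovery is 100%.

## Problem sizes and numerical tolerances

The shipped checks run at desk scale: pairwise comparisons at 1031 bp,
key-property stress tests over ~1000 random partial-state draws, 200
random short pairs against a brute-force column oracle, and 22-specimen
synthetic series. Fraction round-trips are asserted to 1e-9 µm; K2P is
compared to its independent reference to 1e-12 and to the p-distance limit
within 1e-6 at $P, Q \le 10^{-4}$; boundary comparisons in binning use a
relative tolerance of 1e-9 of body length.

## Limitations

* The comparison-table transcription inherits the source's own
  inconsistencies (a typographic reach value corrected against the table,
  drawing-derived cells, single-value cells); per-cell provenance is
  stored so such cells are identifiable, and genuinely unassignable cells
  are stored as unknown rather than guessed.
* Extent reconstruction from summary means is only as consistent as the
  means themselves; the clamping machinery makes the inconsistency visible
  instead of hiding it.
* The key engine encodes one key; it does not construct keys from
  profiles, and it performs no probabilistic matching.
* Percent-identity here is overlap identity of one pre-aligned pair; BLAST
  -style database identity over a different coverage is a different number
  and out of scope.
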