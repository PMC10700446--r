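---
title: "Consistency scoring and automated validation of color-response data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consistency scoring and automated validation of color-response data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colorcons)
```

## Scope and data model

`colorcons` analyzes repeated color-choice data: each participant sees every
inducer symbol a fixed number of times (typically three) and responds with a
color, or with "no color". The package ingests tidy long-format tables (one
row per trial) into a participant-group object holding, per participant, one
*grapheme* per symbol with its ordered trial responses. A response is either
an sRGB triple parsed from a `"#RRGGBB"` hex code or *missing*; missing is a
distinct state, never a color (in particular, it is not black). "No color"
button presses and absent rows are both treated as missing — the package does
not distinguish them, since both simply remove a trial from analysis.
Under-filled symbols are padded with missing responses rather than rejected,
because aborted sessions are common and completeness is the validation
step's job; *over*-filled symbols are a hard error, since they indicate a
malformed table.

## Color spaces

Four working spaces are supported: sRGB (channels in [0, 1]), CIE XYZ, CIELAB
and CIELUV. Conversions use the IEC 61966-2-1 piecewise sRGB gamma
(threshold 0.04045, divisor 12.92, offset 0.055, exponent 2.4), the standard
sRGB/D65 matrix, and the CIE Lab/Luv formulas with their exact rational
constants (216/24389, 24389/27). Two normalization choices matter and are
deliberate:

* **XYZ is scaled so that white has Y = 100.** The published CIELUV cutoff of
  135 presumes CIELUV in standard units (L in [0, 100]); a Y = 1 scale would
  shrink every score by a factor of 100.
* **sRGB stays in [0, 1].** The taxicab cutoff of 1 presumes unit-normalized
  RGB; byte-scale coordinates would inflate scores by 255.

The D65 reference white is taken as the image of sRGB white (1, 1, 1) under
the conversion matrix (≈ (95.047, 100, 108.883)) rather than an
independently rounded triple, so the gray axis maps exactly onto the
achromatic axis (u\* = v\* = 0) and white exactly onto L\* = 100. At zero
luminance the CIELUV chromaticity quotients u′, v′ are 0/0; the package
defines Luv(black) = (0, 0, 0), which keeps pure-black responses
representable and the map continuous. No chromatic adaptation beyond D65 and
no ICC handling are attempted; consistency-test software emits plain sRGB.

## Consistency scores

A grapheme's score is the **sum** of pairwise distances over all unordered
pairs of its trial responses — for three trials, d₁₂ + d₁₃ + d₂₃ — and a
participant's score is the **mean** over scorable graphemes. Sum-then-mean,
rather than any per-pair normalization, is what the published cutoffs were
derived for: 135 for Euclidean distance in CIELUV and 1 for taxicab distance
in unit sRGB, both for three-trial tests, with classification *strictly
below* the cutoff. For other metric/space pairs no default cutoff exists and
the user must supply one. With trial counts other than three the pair-sum
grows with the number of pairs; the package does not rescale, and the
published cutoffs then no longer apply — a documented caveat, not a silent
correction.

By default only complete graphemes (no missing responses) are scored. When
`complete_only = FALSE`, graphemes with at least two usable responses are
scored over the pairs that exist; such scores sit on a smaller pair-count
scale and are intentionally left unscaled, since no published rule covers
that case.

## The validation procedure

Scores are only interpretable when a participant gave enough data and used
enough genuinely different colors. Validation works on the participant's
response colors in the working space and proceeds in a fixed order:

1. **Completeness.** Fewer than `min_complete_graphemes` complete graphemes
   (default 4) is invalid outright; clustering diagnostics are not computed.
2. **Clustering.** Responses (by default only from complete graphemes) are
   clustered with DBSCAN: a point is *core* when its closed Euclidean
   `eps`-neighborhood holds at least `min_pts` points (itself included);
   clusters are maximal density-connected sets of core points plus border
   points; the rest is *noise*.
3. **Dominant color.** If the largest cluster holds at least
   `max_prop_single_cluster` of *all* responses (default 0.8; noise points
   count in the denominator, since the criterion speaks of all given
   responses), the data are invalid.
4. **Distinct colors.** If there are fewer than `min_num_clusters` clusters
   (default 3) *and* the total within-cluster variance falls below
   `safe_twcv` (default 250), the data are invalid.
5. Otherwise valid.

TWCV is defined here as Σ over non-noise clusters of the mean squared
Euclidean distance to the cluster centroid (population denominator n_c,
noise excluded, 0 when no cluster exists). This definition is this package's
own and every internal threshold is calibrated against it.

Defaults are expressed in CIELUV units and mirror the worked criteria
"complete data for at least 4 inducers, at least 3 clearly different
colors, and no more than ~80% of responses of one color": `eps = 20` (about
the radius within which two colors read as shades of the same color in
CIELUV), `min_pts = 4`, `safe_twcv = 250`. The numeric values for
`eps`/`min_pts`/`safe_twcv` have no published reference; they are
calibration choices validated by the archetype-recovery simulations in the
test suite (≥ 95% of well-separated synesthete-like generators classified
valid, ≥ 95% of single-color generators invalid). A `rater_strict` preset
sets `max_prop_single_cluster = 0.6`, matching human-rater criteria under
which using one color for 60% or more of the responses invalidates the data.

Two edge behaviors are worth knowing. Widely scattered responses can produce
*zero* clusters — all noise — and hence TWCV 0; rule 4 then classifies the
data invalid even though the responses vary a great deal. This is the
documented behavior of the rule order, and `min_num_clusters = 0` disables
it. And when `min_pts` exceeds the point count, everything is noise and the
same rule decides; this is not an error.

### Determinism

DBSCAN's partition of core points and its noise set are order-independent,
but border-point assignment classically depends on processing order. The
implementation pins it down: points are processed in input order, cluster
ids are assigned in discovery order from 0, the neighborhood radius is
inclusive (d ≤ eps), and a border point goes to the first cluster that
reaches it. The same input therefore yields byte-identical labelings across
runs and platforms; the test suite checks the order-*invariant* parts
(noise set, core partition, cluster count) against a brute-force
density-connectivity oracle.

## Synthetic respondent archetypes

The generator produces participants with known ground truth, emulating the
response patterns that motivate validation:

* `synesthete` — each symbol tied to one palette color, palettes drawn with
  pairwise sRGB Euclidean separation ≥ 0.5 (clearly different colors), plus
  per-trial Gaussian jitter (`jitter_sd`, default 0.01 sRGB units ≈ small
  trial-to-trial imprecision of a color picker);
* `random` — every response uniform on the sRGB cube (a participant clicking
  arbitrarily);
* `single_color` — one base color plus jitter for every response;
* `light_varying` — hue uniform on the circle, HSL lightness in
  [0.85, 0.97] and saturation in [0, 0.4]: hue-inconsistent but uniformly
  very light responses, the pattern that artificially deflates CIELUV
  scores because light colors crowd together near the top of the space;
* `few_colors` — every response drawn from a small shared palette.

Defaults (10 symbols, 3 trials, palette size 6, no missing responses) are a
typical short grapheme test. Each response can independently go missing with
`missing_rate`. Generation uses R's default RNG under an explicit seed;
group generation derives per-participant sub-seeds as `seed + index`, so a
group is reproducible from one integer. HSL is purely a generation device —
analysis spaces remain the four above.

What the generator does *not* emulate: perceptual response noise correlated
across trials, category effects (letters vs digits), partial-session
missingness patterns, or real color-picker quantization. Passing the
recovery simulations therefore shows that the pipeline separates clearly
distinct archetypes under controlled noise — not that any particular
empirical data set will be classified correctly.

## Screening arithmetic

`ppv()` implements sens·prev / (sens·prev + (1 − spec)(1 − prev)) and
`false_positive_proportion()` its complement. Arguments are proportions
only — 0.011, never 1.1 — a single convention that prevents silent 100×
errors. At sensitivity 0.90, specificity 0.94 and prevalence 0.011 the PPV
is ≈ 0.143: most screen positives in a general-population sample are false
positives, which is the quantitative argument for validating data and for
never equating a sub-cutoff score with synesthesia.

## Numerical and testing choices

Hex parsing accepts upper/lower case with or without `#`; 8-digit alpha hex
is rejected. Out-of-range sRGB input raises an error rather than clamping
(only internal generator jitter clips, by construction). The sRGB→XYZ→sRGB
round trip is exact to < 1e-6 per channel over a 10×10×10 gamut grid, and
the gray axis is achromatic to < 1e-6 in both Lab and Luv. TWCV is checked
against direct formula evaluation to 1e-9. Simulation-based checks use 100
participants per archetype (clustering 30 points each) and the DBSCAN
oracle comparison uses 200 random instances of up to 50 points — sizes at
which the brute-force oracles remain exhaustive while the full suite runs
in well under a minute. All simulation tests use fixed seeds chosen in
advance.

## Limitations

* The TWCV definition and the default `eps`/`min_pts`/`safe_twcv` values are
  this package's calibration; other implementations of the same validation
  idea may place individual borderline participants differently.
* Published cutoffs exist only for two metric/space pairs and only for
  three-trial tests.
* Validation flags *uninterpretable* data, not bad-faith responding; as the
  light-color artifact shows, a flagged participant may simply have data on
  which CIELUV scoring is meaningless. Treat `invalid` as "inspect", not
  "discard", where feasible.
* Automatic `eps` selection (e.g. k-distance elbows) and non-color 3D
  response spaces are out of scope, though the clustering and TWCV machinery
  is dimension-agnostic in principle.
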