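# colorcons

Consistency scoring and automated validity classification for color-response
data from synesthesia consistency tests.

## The problem

In a grapheme–color consistency test, each inducer (a letter, digit, or
spoken vowel) is presented several times — typically three — and the
participant picks the color that best fits it. People with genuine
grapheme–color associations pick nearly the same color for the same inducer
every time; everyone else cannot memorize dozens of arbitrary choices. The
standard statistic is the **consistency score**: per inducer, the sum of
pairwise color distances across its trials,

```
score(g) = Σ_{i<j} d(c_i, c_j),        participant score = mean over inducers,
```

with two published conventions: taxicab distance on unit-normalized sRGB
(synesthesia cutoff **1**) and Euclidean distance in CIELUV (cutoff **135**);
scores *strictly below* the cutoff indicate synesthesia. Both cutoffs assume
three trials per inducer.

A low score is only meaningful if the data are interpretable: a participant
who answers red on every trial, skips most trials, or picks only very light
colors of varying hue scores "consistently" with no association at all.
`colorcons` automates that validity check: the participant's response colors
are clustered with **DBSCAN** (density-based clustering with an explicit
noise class), and the data are classified invalid when there are too few
complete inducers, when a single color cluster holds too large a share of
the responses, or when there are too few distinct clusters and too little
**total within-cluster variance**

```
TWCV = Σ_clusters (1/n_c) Σ_{x∈c} ‖x − μ_c‖² .
```

The package is aimed at perception researchers running consistency tests
(grapheme–color, vowel–color, and similar paradigms) who need reproducible,
shareable scoring and validation criteria instead of manual inspection.

## Worked example

Generate a small synthetic cohort with known ground truth, score it, and
validate it:

```r
library(colorcons)

mix <- list(
  list(archetype_params("synesthete"), 3),    # palette-consistent responders
  list(archetype_params("single_color"), 2),  # one color for everything
  list(archetype_params("random"), 2)         # uniform random colors
)
sim <- gen_group(mix, seed = 42)

group_scores(sim$group, scoring_config("euclidean", "Luv"))
validate_group(sim$group, validation_spec())
```

The score table (merged with the ground truth) prints:

```
  participant_id      score n_graphemes_used synesthetic    archetype
1           p001   9.047582               10        TRUE   synesthete
2           p002  10.478418               10        TRUE   synesthete
3           p003  11.269145               10        TRUE   synesthete
4           p004   7.616035               10        TRUE single_color
5           p005  13.017249               10        TRUE single_color
6           p006 287.675851               10       FALSE       random
7           p007 283.746883               10       FALSE       random
```

Synesthete-like responders land far below the CIELUV cutoff of 135 and
random responders far above it — but so do the single-color responders
(scores 7.6 and 13.0): this is exactly the false positive the validation
step exists to catch. The validation table:

```
  participant_id valid                  reason num_clusters      twcv prop_largest_cluster
1           p001  TRUE                      ok            4  29.10729            0.2000000
2           p002  TRUE                      ok            4  20.09764            0.2000000
3           p003  TRUE                      ok            4  34.51672            0.2000000
4           p004 FALSE  dominant_color_cluster            1   4.01610            1.0000000
5           p005 FALSE  dominant_color_cluster            1  10.97443            1.0000000
6           p006 FALSE too_few_distinct_colors            0   0.00000            0.0000000
7           p007 FALSE too_few_distinct_colors            1 239.28146            0.2333333
```

Both single-color responders are flagged (all responses in one cluster);
their low scores would otherwise have passed as synesthetic. Real data are
ingested from tidy CSV with `read_group_csv()` / `build_group()`; black
responses can be excluded first with
`recode_to_missing(group, "#000000")`.

Screening arithmetic from the same toolbox: with sensitivity 0.90,
specificity 0.94 and a population prevalence of 1.1%,
`ppv(0.9, 0.94, 0.011)` returns `0.1430` — about 86% of screen positives in
a general-population sample are expected to be false positives, which is why
validity checking and a subjective-experience criterion matter.

## Command line

A thin Rscript wrapper exposes the same operations:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "colorcons", package = "colorcons"))')
Rscript $CLI simulate --mixture synesthete=5,random=5 --seed 7 --out data.csv --truth-out truth.csv
Rscript $CLI score    --input data.csv --color-space Luv --metric euclidean --out scores.csv
Rscript $CLI validate --input data.csv --out validity.csv            # flags or --config spec.json
Rscript $CLI plot     --input data.csv --participant-id p001 --out p001.png
Rscript $CLI ppv      --sensitivity 0.9 --specificity 0.94 --prevalence 0.011
```

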