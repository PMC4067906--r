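---
title: "Characterizing visual food stimuli: models, parameters and design choices"
author: "stimChar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing visual food stimuli}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stimChar)
```

## The problem

Food-image experiments compare conditions defined by *content* — high
versus low caloric density, meat versus non-meat, sweet versus savory —
but neural and behavioral responses are also driven by *physical* image
properties: luminance, contrast, color, spatial-frequency content, visual
complexity. A stimulus database therefore ships three kinds of metadata:
physical metrics computed from the pixels, nutrition facts per depicted
portion, and normative ratings aggregated from large participant surveys.
`stimChar` implements all three layers plus a matched-subset selector, and
pairs them with synthetic generators so each layer is testable against
known ground truth.

## Physical metrics

All metrics assume the database convention: an object photographed on a
uniform near-white background. Luminance is `0.2989 R + 0.5870 G +
0.1140 B` (the classic NTSC weights), kept as fractional values on the
0–255 scale — quantizing to integers would bias the downstream means and
SDs that the brightness and contrast metrics are built from.

**The object mask.** "White" is not defined by a photograph; pixels are
classified as background iff all three channels are at or above
`whiteThreshold`. The default 250 is a deliberate compromise: JPEG
compression leaves ringing of a few intensity steps around the background,
which a threshold of 255 would misclassify as object, while thresholds far
below 250 would start carving pixels out of genuinely near-white objects
(whipped cream, mozzarella). The threshold is configurable per run and
echoed into every output row, so a stimulus set characterized under a
different convention remains reproducible. Note the mask is a *threshold*,
not a segmentation: images whose background is not uniformly near-white
are outside the model.

**Color contribution** is computed as proportion-of-sums: each channel is
summed over object pixels and divided by the grand sum. The alternative —
averaging per-pixel proportions — differs on mixed-color objects and is
ill-conditioned for near-black pixels, where tiny channel values produce
wild proportions. For the degenerate all-black object (grand sum 0) the
three channels are reported as contributing equally (1/3 each). An empty
mask is a domain error for all object metrics; the directory pipeline
converts it to `NA` metrics plus a warning so one blank image does not
abort a batch run.

**Contrast** uses the population SD (divisor *n*) by default: the object's
pixels are the complete population of interest, not a sample from a larger
one, and the convention makes two-pixel examples exact. `sdDivisor =
"n-1"` is available for comparability with tools that report sample SDs.

**Spatial frequencies.** The 2D FFT runs on the full luminance frame —
background included, no windowing, no padding — because the quantity of
interest is the spatial-frequency content of the *stimulus as shown*.
Radial averaging assigns each coefficient to the bin given by its
integer-rounded Euclidean distance from the DC bin; rounding (rather than
flooring or annulus edges) centers each bin on its nominal frequency, and
bins beyond `floor(min(h, w)/2)` are discarded because those frequencies
are not represented in every direction. The summary statistic is the
median over the non-DC radial bins: including DC would make the "spatial
frequency" summary a proxy for mean luminance. Both choices are flags
(`includeDC`, and `medianMode = "all_coefficients"` to take the median
over raw 2D coefficients instead of radial bins) since the literature is
not explicit about either convention.

**Complexity.** Edges come from a standard Canny pipeline: Gaussian
smoothing (`cannySigma`, default 1.0 px), Sobel gradients, non-maximum
suppression, hysteresis. The hysteresis thresholds are *fractions of the
gradient-magnitude range* (defaults 0.1/0.2), making the detector
invariant to linear luminance rescaling. Two numerical details matter for
reproducibility: plateau ties in non-maximum suppression are broken
asymmetrically (strictly greater toward the positive gradient neighbor),
so a perfectly symmetric step edge yields a single-pixel outline rather
than a double line; and hysteresis connectivity is 8-connected, grown to a
fixed point. On a solid black square the edge count lands within a few
percent of the geometric perimeter and agrees with scikit-image's `canny`
to well under 10%.

Complexity is the outline-pixel fraction of the frame. *Normalized*
complexity divides it by object size — outline pixels per object pixel —
the dimensionally consistent reading of "proportion of outline pixels per
non-white pixel". A strict-literal mode (dividing the proportion by the
raw pixel count) is kept behind a flag; it differs only by the constant
frame area. Neither variant is scale-*invariant*: magnifying an object by
factor *s* multiplies its outline by *s* and its area by *s²*, so
normalized complexity falls as 1/s. The tests pin exactly this behavior
(halving when a square's side doubles) rather than pretending the measure
is magnification-proof; users comparing objects of very different sizes
should keep that in mind. A perimeter-per-√area variant would be
scale-free but would no longer match the established definition.

## Nutrition metadata

Caloric density is kcal per 100 g; portion totals multiply per-100 g
values by `portion_grams / 100`. A missing portion mass yields missing
totals — never zero, which would silently distort calorie matching. The
high/low **median split** labels densities at or below the median "low"
and above it "high"; sending ties to "low" is arbitrary but deterministic,
and the even-count median is the mean of the central order statistics.
Non-food records and records with missing density are excluded with a
logged count, never imputed. `coderAgreement()` exposes the Pearson-r
cross-validation step used when two human coders independently estimate
the nutrition facts of a subsample.

## Normative ratings

Ratings arrive as one row per participant × image: two dichotomous items
(familiarity, recognizability) and 1–100 VAS scales (complexity, valence,
arousal, plus palatability and desire-to-eat for food images only). The
inclusion rule retains participants with *complete* rating sets — every
applicable scale answered — for at least `minFoodImages` food images
(default 3). Aggregation reports mean/SD/n per scale and percent-yes for
the dichotomous items, overall and per subgroup level (e.g.
`gender=female`); participants missing a subgroup variable are dropped
from that stratification only.

`categoryContrast()` implements the paired design used for image-category
comparisons: each participant's ratings are first averaged within each
image group, and the paired *t* test runs over participants (df = n − 1).
Published paired effect sizes follow two conventions that can differ
substantially, so both are reported and labeled: `d_z` (mean difference
over the SD of difference scores, = t/√n) and `d_av` (mean difference over
the average of the two group SDs). If every participant shows a zero
difference the statistic is reported as t = 0, p = 1 rather than the 0/0
that a textbook formula would produce; constant non-zero differences are
an error. Hunger is averaged across the pre- and post-survey ratings, with
a single-source flag when only one is available.

## The synthetic generators

`generateImage()` produces geometric stimuli — squares, disks,
checkerboards, full-frame sinusoidal gratings, and two-object composites —
on a white canvas defaulting to the 600 × 450 px database standard. Ground
truth (object pixel set, size fraction, exact gray mean and population SD,
grating frequency) is computed *analytically from the parameters*, never
measured back from the raster, so metric tests are genuine oracles.
Images written as PNG round-trip losslessly; a JPEG mode exists precisely
to exercise the white-threshold robustness.

`simulateSurvey()` emulates the multi-sample online-survey design: the
default four samples (n = 638, 831, 496, 23) rate random per-participant
subsets (40/80, 25/40, 17/35, 5/35 non-food/food) from pools of 568 food
and 315 non-food images. VAS responses are latent per-image means plus
Gaussian noise, rounded to integers and clamped to [1, 100] — matching how
a 100-point VAS digitizes — and three documented subgroup effects can be
injected and later recovered: a gender shift on desire to eat (default
−8.3 VAS points, female minus male), a vegetarian/vegan shift on
meat-image palatability (default −36.5), and a linear hunger slope on
desire (default 0.3 points per hunger point, a value chosen once as a
plausible medium-size state effect). Noise SD defaults to 20 points, the
order of between-rater spread in normative food-image data.
`generateNutrition()` draws macronutrients from realistic per-100 g ranges
(protein 0–30 g, carbohydrate 0–70 g, fat 0–40 g; portions 20–400 g) and
sets caloric density by the Atwater factors (4/4/9 kcal per g) plus
optional noise, with category proportions matching a large published
food-image database.

What the generators deliberately do **not** emulate: photographic texture
and shading gradients, correlated rating scales within participants,
response styles (extreme/midpoint usage), and item nonresponse beyond a
uniform completion probability. Passing tests therefore certify the
arithmetic and the statistical machinery on controlled input, not the
psychometrics of any real survey.

## Matched stimulus-set selection

`matchStimulusSets()` balances condition subsets on nuisance features. All
features are standardized by the pooled SD of the *full candidate pool* —
a denominator that stays constant while subsets change — and the objective
is the maximum absolute standardized mean difference over features and
condition pairs, so no single feature can stay badly unbalanced while a
sum shrinks. Two solution paths:

- For two-condition problems whose subset-pair count is at most
  `enumLimit` (default 5 × 10⁵), the optimum is found by exhaustive
  enumeration. This was a deliberate design change after measuring the
  alternative: the max-over-features objective has needle-like global
  optima (the minimum over hundreds of thousands of subset pairs), and
  swap-based local search — even with plateau-breaking tie rules, hundreds
  of restarts, and perturbation kicks — reliably stalled at 1.5–10× the
  optimum, while enumeration at desk scale costs well under a second.
- Larger problems use multi-start best-improvement swap hill-climbing with
  a sum-of-squares tie-break on plateaus and perturbation-and-redescend
  kicks, keeping the best end point. The objective never increases within
  a descent, and the whole procedure is deterministic given `seed`.

All-constant features are excluded with a warning (their SMD is
undefined); requesting more images than a condition offers is an error;
when the subset is the whole pool the reported SMDs are simply the
full-pool differences.

## Problem sizes and tolerances in the test suite

The suite verifies analytic metric agreement at 10⁻⁹ on 50+ generated
objects (150 × 120 px canvases keep the FFT and Canny runs fast),
grating-peak recovery exactly for 2–32 cycles on 128 × 96 frames, Parseval
at 10⁻⁶ relative, Canny-versus-reference agreement within 10% on a
120-px square, type-I calibration of the paired contrast over 1000
simulated null surveys of 40 raters × 12 food images (expected rejection
0.05 ± 0.007), effect recovery at 400–500 participants, and matching
optimality against exhaustive search on pools of 12 per condition. These
sizes were chosen so the full suite runs in well under a minute while
leaving each statistical check enough resolution to fail if the underlying
computation drifts.

## Known limitations

- The white-threshold mask is not a segmentation; colored or gradient
  backgrounds break the object/background split.
- Normalized complexity scales as 1/side under magnification (see above).
- Color contribution discards hue/saturation structure by design; no
  perceptual color space is used.
- The paired contrast assumes each included participant rated both image
  groups; participants spanning only one group are dropped, which can bias
  contrasts if spanning correlates with the outcome.
- The matcher's exhaustive path covers two conditions; three or more
  conditions always use the heuristic, whose result is a certified-feasible
  selection but not a certified optimum.
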