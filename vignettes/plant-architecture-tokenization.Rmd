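---
title: "Organ-level plant architecture: model, token codec, simulator and metrics"
author: "phytoken"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Organ-level plant architecture: model, token codec, simulator and metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytoken)
```

## The architecture model

phytoken works with shoot systems of vegetative cowpea at the organ level.
The repeating structural unit is the *phytomer*: an internode carrying a
petiole and the leaf or leaflets it bears. Shoots are chains of phytomers;
lateral shoots emerge from vegetative buds at the nodes, giving a nested
branching hierarchy whose depth we call the *branching order* (primary shoot
is order 0; orders above 3 are not supported). In cowpea the first node of
the seedling bears two opposite *unifoliate* leaves; all later nodes carry
*trifoliate* leaves (three leaflets on one petiole). We follow that
convention: the primary shoot is typed unifoliate (label 1), its first
phytomer has two single leaves, and every subsequent phytomer and lateral
shoot is trifoliate (label 3).

Each organ carries the geometric parameters of the cowpea parameter table
(`default_parameter_table()`): lengths and radii in metres, angles in
degrees, dimensionless scales. The table rows are constants or sampling
distributions (uniform or normal) with separate unifoliate/trifoliate
variants where the two contexts differ. A plant additionally carries a base
position, base rotation (pitch, yaw, roll) and an age in days.

Architectures serialize to a small XML dialect (`write_architecture_xml()`)
with shoots as depth-first siblings and floats at 6 significant digits.
Serialization is deterministic, so canonical documents round-trip
byte-identically; arbitrary doubles round-trip to within the 6-digit
precision. One plant per file.

## The token codec

A plant is a sequence over a 228-ID vocabulary:

* **Organ tokens 0–23.** `ID = branching_order * 6 + organ_code` with codes
  0 shoot, 1 internode, 2 petiole, 3–5 leaf slots; the primary shoot tag is
  "00", its internode "01", a first-order lateral "10" and its leaflets
  "13", "14", "15".
* **Parameter tokens 24–222.** A 199-value quantization grid: the
  deduplicated ascending union of the constants {0, −10, 10, 90, 1, 3}, the
  2.5° angle grid over [−40°, 360°] (161 points), and four 10-point decimal
  grids covering [0.1, 1], [0.01, 0.1], [0.001, 0.01] and [0.0001, 0.001]
  metres. Values quantize to the nearest grid point, ties broken toward the
  smaller value, so in-coverage error is at most half the local grid gap
  (≤ 1.25° on the angle grid).
* **Special tokens 223–227.** SOS, EOS, META_OPEN, META_CLOSE, PAD.

Trifoliate petiole curvature is drawn from Uniform(−200, −50), outside grid
coverage. The codec therefore keeps a per-parameter *prescale* registry:
`petiole_curvature` is multiplied by 1/10 before lookup (landing exactly on
the 2.5-step angle grid) and divided by 1/10 on decode. The registry is
explicit and invertible; all other parameters use factor 1.

A sequence is framed as SOS, a META block with three quantized plant-level
quantities (width, height, vegetation fraction of the image window), a
four-token plant header (base pitch, yaw, roll, age), then one block per
shoot in depth-first order — the shoot token with its four parameters
(type, base pitch/yaw/roll), then per phytomer the internode (4 params),
petiole (4, or 5 with `leaflet_scale` for trifoliate), and leaf tokens
(4 params each), with any child shoot's block emitted immediately after the
phytomer it attaches to — and finally EOS. The per-organ parameter counts
and orders, the metadata order and the plant header are conventions of this
package, documented here and enforced symmetrically by the tokenizer and
the grammar-checking detokenizer; the detokenizer distinguishes unifoliate
from trifoliate petioles by whether a fifth parameter token follows, and
reads leaf slots greedily (one or two "3"-code leaves, or exactly the
"3","4","5" leaflet triple).

`detokenize(tokenize_architecture(A))` equals `A` with every parameter
replaced by its quantized value; a second round trip is token-exact. The
token stream does not carry the base position (irrelevant to single-plant
imagery), which decodes as the origin.

```{r}
p <- generate_plant(seed = 1, age_days = 10)
seq <- tokenize_architecture(p, plant_metadata(0.3, 0.2, 0.1))
utils::head(format_tokens_human(seq), 14)
```

## The synthetic population generator

`generate_plant(seed, age_days)` emulates daily vegetative growth from a
day-0 seedling:

* every shoot apex initiates a new phytomer each time its phyllochron
  elapses (`phyllochron_days`, default 3);
* every node without a lateral may break its bud once per day
  (`lateral_bud_break_prob`, default 0.02) while the branching order is
  below 3, creating a one-phytomer trifoliate lateral;
* internodes are created at the table's initial dimensions (length 0.002 m,
  radius 0.0015 m) and elongate linearly (default 0.005 m/day) toward a
  saturating maximum (default 0.05 m). Elongation is computed analytically
  from organ age, so it consumes no randomness.

All other stored parameters are the raw values sampled at organ creation,
consumed in a fixed documented order, so a plant is fully determined by
`(seed, config)` and the day-`d` architecture is a structural prefix of the
day-`d+1` architecture under the same seed.

The growth-rule constants are not part of the parameter table — they are
internal to the growth process being emulated — so they are exposed in
`generator_config()` and were calibrated once against the intended
population scale: at the defaults, day-39 plants carry tens of shoots and
hundreds of phytomers and leaves, with population maxima around 400 leaves.
The phyllochron of 3 days puts ~14 phytomers on a 39-day primary shoot,
within the realistic range for vigorous vegetative cowpea.

What the generator emulates — and what it does not: it reproduces the
*parameter distributions* and the topological growth pattern (nested
branching to order 3, monotone organ accumulation), which is what the
distribution-recovery and codec tests exercise. It does not model
environmental response, organ senescence, reproductive transition, root
systems, or correlated parameter variation within a plant; leaves and
petioles appear at their sampled mature dimensions rather than expanding
over days. Passing tests therefore certify the codec, the grammar, and
distributional fidelity to the table — not biological realism of any single
plant's ontogeny.

`parameter_recovery()` quantifies distributional fidelity: for every stored
sampled parameter it computes the p = 1 Wasserstein distance between the
empirical values and a deterministic quantile sample of the specified
distribution, normalized by the reference range. Internode length and
radius are excluded by design (growth moves them off their initial
constants). Over 4,000 plants every parameter's normalized distance is
below 0.05, most below 0.01.

## Geometry and traits

`reconstruct_geometry()` composes rotations root→leaf with z up and
right-handed frames. Angle triples apply as intrinsic rotations
pitch → yaw → roll, `M = Ry(pitch) Rz(yaw) Rx(roll)`; the source names the
three angles but not a composition order, so this order is fixed here and
used everywhere. Per phytomer the frame first rotates about its local z by
the phyllotactic angle (azimuth accumulates along the shoot), then pitches.
Petiole curvature is rendered as a circular arc in the petiole's pitch
plane, discretized in 5 segments, reading the stored value as bend per
metre of petiole length (degrees/m) — with trifoliate petioles of
0.06–0.08 m this gives gentle 3–16° droops, the only reading of
Uniform(−200, −50) consistent with plausible petiole shapes. Leaflets
attach at the arc end with fixed structural azimuths (0/180° for the two
unifoliate leaves, 0/±60° for a trifoliate triple; lateral leaflets scaled
by `leaflet_scale`). These azimuths are geometric conventions, not stored
parameters, so stored distributions stay exactly those of the table.

Leaf laminae are squares of side `scale * sqrt(unit_leaf_area)` in the leaf
frame's x–y plane; the unit-leaf prototype area defaults to 1 m² so that
leaf area is simply `scale²` (an absolute cowpea calibration can be passed
via `unit_leaf_area`). Traits derived from the geometry:

* `plant_height()` — highest organ point above the base;
* `total_leaf_area()` and leaf counts;
* `leaf_inclination_distribution()` — angle between each leaf normal and
  the vertical, folded to [0°, 90°], as a normalized histogram over 10 bins
  of 9° by default (bin edges at multiples of 9° match the reporting
  convention for canopy inclination). Folding the *normal-vs-vertical*
  angle was chosen over the complementary lamina-vs-horizontal angle; the
  two coincide after folding for planar laminae.
* `bounding_metadata()` — width/height of the bounding box plus the
  vegetation fraction, from a top-view orthographic rasterization of the
  leaf squares on a 256×256 grid over the image window (the raster
  resolution is configurable; coarse grids bias the fraction by at most a
  one-cell layer per leaf edge).

All of these are invariant to rigid rotation about the vertical axis, which
the test suite checks to 1e-9.

```{r}
tr <- plant_traits(p)
c(height_m = tr$height_m, leaves = tr$leaf_count, area_m2 = tr$total_leaf_area_m2)
```

## Evaluation metrics

For aligned (teacher-forcing style) sequence pairs, `token_accuracy()` and
`weighted_f1()` follow the standard one-vs-rest confusion tallies per token
ID with supports taken from the reference, weighted over IDs 0–227.

`bleu4()` is corpus-level: clipped 1–4-gram precisions pooled over all
pairs, geometric mean, multiplied by the brevity penalty
`min(1, exp(1 − Σ l_ref / Σ l_gen))`. No smoothing: a zero n-gram precision
gives 0, documented. Identical corpora score exactly 100%.

`rouge_l()` implements the LCS-based F-score in the orientation used by the
reference formulation this package mirrors: `R = LCS/len(gen)`,
`P = LCS/len(ref)`, `β = P/R`, `F = (1+β²)RP/(R+βP)` — note the unsquared
`β` in the denominator and the swapped R/P denominators relative to
conventional ROUGE. That orientation is kept deliberately for fidelity
(identical sequences still score exactly 1); `standard = TRUE` switches to
the conventional definition for comparison.

`wasserstein_1d()` computes the empirical p-Wasserstein distance via the
quantile formulation (for p = 1, the earth mover's distance). The
"normalized" variant divides by the *reference sample's range*, a choice
this package fixes because the bare term is ambiguous; a zero-range
reference yields 0 when the distance is 0 and `Inf` otherwise, making
incomparability explicit. The test suite pins the implementation against
brute-force assignment and ECDF-integral oracles.

`regression_metrics()` reports R², RMSE and MAPE (percent), excluding
zero-valued truths from MAPE with an explicit count.

## Numerical choices and degenerate inputs

* Quantization ties break toward the smaller grid value, with a 1e-12
  absolute guard so exact half-gap ties are stable under floating point.
* Grid deduplication rounds to 12 decimals before `unique()`; all intended
  grid values are exactly representable at that precision.
* Out-of-coverage values clamp to the nearest grid end (the prescale
  registry exists precisely to keep real parameters in coverage).
* Empty geometry has height 0 and vegetation fraction 0; an inclination
  histogram requires at least one leaf and errors otherwise.
* Near-vertical leaves project to degenerate quadrilaterals in the top
  view and contribute no raster cells.
* The detokenizer is a single-pass recursive-descent parser; every grammar
  violation reports the 1-based token index.

## Problem sizes used by the shipped checks

The package's own test suite exercises: 1,000 generated plants (seeds
0–999, ages cycling 0–39) for the codec round trip; 4,000 plants for
distribution recovery; 100,000 random values for the quantization bound;
exhaustive LCS enumeration to length 8 and transport oracles to 50 points;
and 100 plants for rotation invariance. These sizes were chosen as the
smallest populations at which the distributional checks are statistically
comfortable (sampling noise an order of magnitude below the 0.05
acceptance band).

## Known limitations

* Interoperability with external simulators' XML schemas is best-effort:
  the dialect here is self-contained and lossless for this data model, but
  element and attribute names of other tools may require a mapping layer.
* The curvature unit is genuinely ambiguous in the source material
  (degrees vs 1/m); the stored number is passed through unchanged and only
  the geometry module commits to a reading.
* Parameter draws are independent across organs and days; real plants show
  within-plant correlations the generator does not emulate.
* The unit-leaf prototype is a square; absolute areas and vegetation
  fractions inherit that simplification.
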