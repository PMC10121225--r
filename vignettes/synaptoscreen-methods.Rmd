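---
title: "Methods: automated synaptic phenotyping with synaptoscreen"
author: "synaptoscreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated synaptic phenotyping with synaptoscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synaptoscreen)
```

## The assay and its readout

High-content synaptic phenotyping screens image co-cultures of human
induced neurons and astrocytes in 96-well plates, three fluorescence
channels per field: a nuclear stain (DAPI), a dendrite marker (MAP2) and a
presynaptic marker (SYNAPSIN1). Each well is imaged as 12 fields, each
field as a short z-stack (5–8 slices). The primary readout is
**presynaptic density**: the number of presynaptic puncta colocalized with
the dendrite mask, divided by the dendrite mask area. Around this readout
the platform measures neurite coverage (a proxy for neurite outgrowth) and
nuclei counts (a proxy for viability), normalizes every treated well
against intra-plate vehicle (0.1% DMSO) controls, and calls hits from
intra-plate Z-scores.

synaptoscreen implements this pipeline end to end in R, plus a synthetic
field/plate simulator with planted ground truth so that every stage can be
validated without access to the original images.

## The imaging pipeline

Per field, in order (the order mirrors the stage list of the original
analysis; whether illumination correction preceded or followed alignment
there is not documented — the order below is this package's choice):

1. **Maximum projection** per channel: `out[y,x] = max_z in[z,y,x]`.
2. **Alignment** (`alignChannels()`): the integer translation of the
   dendrite plane maximizing its mutual information with the nuclear plane
   is found by exhaustive search over a ±10 px window (64-bin joint
   histograms, natural log). The same translation is applied to the
   presynaptic plane, whose camera path matches the dendrite channel's.
   Ties on the MI surface resolve to the smaller shift magnitude, then
   lexicographically — an arbitrary but deterministic rule that makes the
   search exactly reproducible by an independent brute-force oracle.
   Constant planes skip alignment with a warning.
3. **Illumination correction** (`buildIlluminationFunction()`): per
   channel, the per-pixel mean over all fields of the plate is smoothed
   with a large Gaussian (filter size 100 × 100 px, `sigma = size/2.355`),
   normalized to mean 1, and divided out. Smoothing uses antisymmetric
   ("linear") boundary padding, which preserves linear intensity ramps
   exactly; with the more common replicate padding the estimated surface
   flattens near borders and a planted linear gain is only partially
   removed.
4. **Rescale** each plane to [0, 1] (min → 0, max → 1; a constant plane
   maps to zeros).
5. **Neurite segmentation**: a tubeness (ridge) measure at Gaussian scale
   σ = 2 px — the magnitude of the negative principal curvature of the
   smoothed plane's Hessian, clipped at zero and scale-normalized —
   followed by a white tophat (disk radius 8 px) to suppress wide residual
   structure. The enhanced plane is thresholded by **three-class Otsu**
   (exhaustive maximization of between-class variance on a 256-bin
   histogram of the [0, 1] range); the mask is the union of the middle and
   upper classes by default (`neurite_foreground = "upper"` restricts it).
   The named operator and its scale come from the original pipeline; the
   exact ridge formula is unpublished, so a Hessian ridge measure — the
   standard member of that filter family — is used and judged by
   planted-truth recovery.
6. **Puncta detection**: white tophat with a disk structuring element
   (radius 5 px), two-class Otsu binarization, watershed de-clumping on
   the enhanced intensity (EBImage's deterministic watershed; saddle
   tolerance 0.05, neighbourhood 2 px), and an equivalent-diameter filter
   retaining `1 ≤ 2·sqrt(area/π) ≤ 6` px. Two numerical choices here are
   the package's own:
   - *Speckle radius 5 rather than "just above the maximum punctum
     radius"* (which would be 4): the opening with a radius-5 disk exactly
     reconstructs — and the tophat therefore fully suppresses — any
     object of diameter ≥ 10 px. With radius 4 such objects leak a thin
     tophat ring that fragments into spuriously in-range "puncta".
   - *A robust noise gate*: the binarization threshold is the larger of
     the Otsu threshold and `median + 7·MAD` of the enhanced plane.
     Two-class Otsu always splits a histogram, including the pure
     shot-noise histogram of a signal-free field; the gate (7 was chosen
     as the smallest integer at which signal-free simulated fields yield
     zero puncta across seeds, without affecting true-punctum recovery)
     makes "no signal → no puncta" hold. Setting
     `speckle_noise_floor = 0` disables it, restoring pure Otsu.
7. **Colocalization**: a punctum is on-neurite iff its pixel set overlaps
   the mask in at least one pixel ("contained within or only partly
   touching"); the on-neurite count is therefore monotone in the mask.
8. **Measurements**: neurite area (px), on-neurite punctum count, nuclei
   count (nucleus detector at a permissive 8 µm minimum diameter — this
   counts all nuclei, unlike the plating-QC neuronal subset), and total
   punctum area (all retained puncta). One CSV row per field, with the
   long column names of the original output schema
   (`AreaOccupied_MAP2PositiveNeurites`, …).

Coordinates are 0-based `(y, x)`, areas in pixels; no physical-unit
conversion happens inside the pipeline.

## Plating-consistency QC

`detectNuclei()` approximates the proprietary detector of the original
platform with Gaussian smoothing (σ = 2), two-class Otsu, hole filling and
a watershed split on the distance transform; only the published diameter
criterion (> 20 µm) is algorithmic fact, so the detector is validated by
planted-truth recovery rather than by algorithmic identity.
`classifyNeuronal()` applies rule-based gates — intensity, contrast, area
band, roundness, and mean dendrite signal in a 3 px perinuclear annulus
(the "distinct dendrite-positive soma" criterion) — with defaults
calibrated on the simulator; a nucleus is neuronal iff all gates pass.
`plateConsistency()` accepts a plate iff every well's neuronal count lies
in [4000, 12,000] **and** the intra-plate covariance (100·SD/mean, sample
SD) is below 8%. The published account plots the band without stating
whether one outlier well fails a plate; the strict interpretation
(`band_fraction = 1`) is the default because the published example counts
imply it, with the fraction configurable for laxer policies.

## Screen analytics

Field records flow through three QC filters, aggregation, normalization
and hit calling:

- **Field filter**: keep fields whose neurite area lies within mean ± SD
  over the scope (inclusive bounds). The two published phrasings of the
  scope ("inter-plate basis … across all fields" vs. "intra-batch mean")
  are reconciled by defaulting to all fields of the batch with a per-plate
  option.
- **Well filter**: ≥ 5 surviving fields. Well metrics are means over
  surviving fields, except density, which is the ratio of well-level
  aggregates (total on-neurite count / total neurite area) — the
  well-basis definition of the readout.
- **Condition filter**: ≥ 2 of the 3 replicate wells; condition metrics
  are means over surviving wells. The hit rule is evaluated at condition
  level (whether the original evaluated it per well or per condition is
  unstated; `min_wells` and the rule thresholds are configurable).
- **Normalization**: percent-of-control per plate, then intra-plate
  Z-scores `(X − mean(controls))/sd(controls)` with sample SD, computed
  in-sample (no leave-one-out for control wells). Control-well Z-scores
  average exactly zero per plate, and all Z-scores are invariant under
  affine rescaling of a plate — both are asserted by tests.
- **Hit calling**: *toxic* iff `z_density ≤ −3` AND `z_map2 ≤ −2` (the
  conjunction matters: collapsing density alone is not called toxic);
  *enhancer_candidate* iff `z_density ≥ +2` without the neurite collapse.
  The original screen selected enhancers from the ranked Z-plot without
  printing a positive cutoff; +2 is this package's declared default.
- **Pattern correction** (`patternCorrect()`, off by default): the
  original used a proprietary tool, so the package reconstructs the intent
  transparently — a per-batch additive row/column pattern estimated by
  two-way median polish over the wells with known expected value (vehicle
  controls of every plate plus all-vehicle sentinel plates), subtracted
  from every well. Estimated effects smaller than 3× their sampling scale
  (residual MAD / √cells) are zeroed, so a pattern-free batch passes
  through unchanged while planted drift is removed and true single-well
  effects, never being part of the reference set, are preserved.

## Power utilities

Effect sizes are pooled-SD Cohen's d. Power uses the normal (z)
approximation — matching the normal-test power routine the original
analysis names — in the one-sample formulation: for the one-sided
"greater" alternative, `power = Φ(√n·d − z_{1−α})`, and the required
sample size inverts it in closed form,
`n = ((z_{1−α} + z_{power})/d)²` (two-sided solutions are refined by
`uniroot` so that power at the returned n reproduces the target to
1e−9). At α = 0.05, one-sided, 95% power this yields n = 270.55, 43.29
and 16.91 for d = 0.2, 0.5 and 0.8; the continuous value is the
authoritative output and the nearest integer is reported alongside,
since printed "around n = …" values mix rounding conventions.

```{r power}
sapply(c(0.2, 0.5, 0.8), function(d)
  requiredN(d, power = 0.95, alpha = 0.05, alternative = "greater")$n)
```

## The simulator: what it emulates, and what it does not

`generateField()` renders the assay's structure, not its optics:

- *Neurites*: smoothed random-walk polylines dilated to the configured
  width with a Gaussian intensity profile — curvilinear networks without
  any biological growth model.
- *Puncta*: 2-D Gaussian spots whose FWHM matches the requested
  equivalent diameter, centroids sampled uniformly on the neurite mask
  (on-neurite) or its complement (off-neurite).
- *Nuclei*: two classes of ellipses — neuronal (brighter, rounder, with a
  dendrite-channel soma blob that also gives the nuclear/dendrite channel
  pair the mutual structure alignment needs) and astrocytic (dimmer,
  elongated, no soma), both rendered with a radial intensity falloff
  (bright centre) as in real chromatin/soma staining. Nuclei prefer
  centre spacing of ≥ 70% of their summed semi-axes, relaxed
  progressively on crowded fields (real cultures clump; the watershed
  separates touching nuclei).
- *Depth*: objects occupy up to three focal planes; each z-slice sees
  every plane blurred by its defocus distance, so maximum projection is
  meaningful without 3-D optics.
- *Noise and artifacts*: Poisson shot noise on the photon-scale signal
  plus additive Gaussian read noise (the standard camera model); integer
  channel shifts applied jointly to the dendrite and presynaptic channels
  (the alignment stage searches integer translations only); a
  multiplicative illumination plane `a + b·y + c·x` and optional radial
  vignette.
- *Defaults*: 0.6 µm/px (consistent with puncta of 0.4–1.6 µm² spanning
  roughly 1–3 px), 5–8 slices, 12 fields/well, 60 inner wells with two
  vehicle columns. The camera bit depth and true pixel size of the
  original instrument are unpublished; these defaults are declared, not
  inferred.

Passing tests on this simulator demonstrate that the pipeline recovers
planted structure under the stated noise model. They do **not**
demonstrate robustness to what the simulator omits: realistic PSFs and
spectral bleed-through, autofluorescence and debris, cell clumping at
high density, focus drift, or biologically structured variation in
punctum brightness. Results on real images depend on those factors and on
gate re-calibration.

`generatePlate()` draws per-field object counts as Poisson variates
around the spec's values, scaled per well by an effect map (density
multipliers; viability multipliers on nuclei), truncated (puncta at twice
their mean, nuclei at mean + 2) so a field's object budget stays
bounded. `simulateFieldRecords()`
is the table-level counterpart — it draws per-field *measurements* from
the same generative statistics without rendering pixels — used where
screen-scale layouts (many plates, 12 fields/well) would make image
rendering disproportionate.

## Problem sizes, determinism, degenerate inputs

- Test and acceptance runs use scaled study conditions chosen once: the
  image-based recovery plate is 60 wells × 4 fields at 160 × 160 px with
  planted density multipliers spanning 0.5–2×; shift recovery uses 50
  planted shifts on 96 × 96 px fields; screen-level properties use eight
  96-well plates at the full 12 fields/well via the table-level
  simulator; the Monte-Carlo power check uses 20,000 replicates.
- All randomness flows from one top-level seed through a documented
  per-field derivation (`(seed + 7919·k) mod 2³¹−1`); identical seed and
  configuration reproduce outputs byte-for-byte, and every output file
  carries a manifest line (package version, config hash, seed).
- Degenerate inputs are defined, not accidental: constant planes rescale
  to zeros and skip alignment with a warning; histograms with too few
  levels fall back from three- to two-class Otsu with a warning; zero
  neurite area makes density undefined (flagged and excluded); a plate
  without surviving controls, or with zero control SD, fails QC rather
  than emitting infinities.

## Known limitations

- The tubeness formula, de-clumping tie-breaks (delegated to EBImage's
  watershed), nucleus detector and pattern correction approximate named
  but unpublished proprietary components; they are validated against
  planted truth, not against the originals' outputs.
- The normal-approximation power model ignores variance estimation (no
  t-correction) by design, matching the original analysis; at small n it
  is optimistic.
- Plating QC counts nuclei per sampled field area; the original
  instrument sampled 25 fields/well under a different acquisition, and
  whether its per-well counts were extrapolated is undocumented. Absolute
  count thresholds therefore transfer to real data only after calibrating
  the sampled area.
- The classifier gates are simulator-calibrated constants, not learned;
  real-data use requires re-calibration on annotated fields.
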