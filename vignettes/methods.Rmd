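---
title: "Methods: quantifying sex differences in whole-brain retrograde tracing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying sex differences in whole-brain retrograde tracing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tracequant)
```

## The problem

Monosynaptic retrograde tracing with glycoprotein-deleted (ΔG) rabies virus
labels two cell populations in two fluorescence channels: *starter cells*
co-infected by an AAV helper (mCherry) and the rabies virus (GFP), and
*presynaptic cells* (GFP only) that project onto the starters. Counting both
populations per brain region, per injected hemisphere, turns histology into a
region-by-region connectivity profile that can be compared between groups —
here, male versus female mice injected in the medial amygdala (MeA) or
orbital cortex (ORB).

`tracequant` implements the full quantification chain:

1. **detection** — per-channel cell detection on coronal section images,
2. **registration** — landmark-based affine mapping into 2-D atlas label
   masks,
3. **quantify** — per-hemisphere region count tables, quality control, and
   the three normalized metrics,
4. **stats** — per-region exact Wilcoxon–Mann–Whitney comparison under
   Benjamini–Hochberg FDR control,
5. **fixtures** — a synthetic-data generator (atlas mosaics, rendered
   two-channel images with ground truth, dimorphic cohorts) so every stage
   is testable without raw imagery, which is not publicly deposited for
   this kind of study.

## Metrics

For one hemisphere sample with region counts $p_r$ (presynaptic) and $s_r$
(starter), $S = \sum_r s_r$, $P = \sum_r p_r$:

* **PPS** (presynaptic per starter): $\mathrm{PPS}_r = p_r / S$ — the
  connectivity "strength" of region $r$, robust to injection efficiency.
* **FPR** (fraction per region): $\mathrm{FPR}_r = p_r / P$ — the
  composition of the input, $\sum_r \mathrm{FPR}_r = 1$.
* **Starter distribution**: $s_r / S$, used by quality control.

Cells whose mapped coordinate falls outside the atlas mask are kept as an
explicit "unassigned" pseudo-region (id 0): they stay in the FPR and
starter-distribution denominators (so the normalizations are checkable) but
are never entered into per-region hypothesis tests.

## Quality control and inclusion, read literally

The gates use exactly the comparisons of their source wording:

* total starters **≥ 20** (inclusive),
* **strictly more than** 60 % of starters inside the injection-target
  subtree ("over 60%") — the broad amygdala subtree for MeA injections, the
  ORB subtree for ORB injections,
* a region enters testing iff its mean presynaptic count is **strictly
  greater than** 30 in males **or** in females.

Boundary fixtures (19 starters; exactly 60.0 %; mean exactly 30) pin these
in the test suite. Sections are pooled per hemisphere *before* QC; the
hemisphere is the experimental unit throughout.

The anterior–posterior analysis window is fixed to bregma +3.5 … −4.5 mm
(olfactory bulb and cerebellum excluded). Both boundaries are treated as
closed: the source states the window approximately ("~"), and a closed
interval is the deterministic choice.

## Exact rank-sum statistics

At this study's sample sizes (n = 7 vs 7 and 4 vs 4 hemispheres) the
attainable two-sided p-values are discrete; a normal approximation would
miss them. `rank_sum_exact()` therefore computes the exact conditional null
distribution of the rank sum over all $\binom{n_1+n_2}{n_1}$ assignments of
the observed mid-ranks. The implementation is a subset-sum dynamic program
over doubled mid-ranks (doubling makes tied mid-ranks integral); the test
suite checks it against a literal `combn()` enumeration on 500 random tied
datasets. Two-sided p is `2 * min(lower tail, upper tail)` clipped at 1 — a
declared convention, as the source does not state one. Complete separation
at 4 v 4 gives p = 2/70 → 0.029; U = 4 at 7 v 7 gives p = 24/3432 → 0.007.
Beyond 12 per group the function switches to the normal approximation with
tie and continuity corrections.

`bh_fdr()` is the Benjamini–Hochberg step-up at level 0.05 (the study's
"q-value"). Direction per region is decided by group medians, in keeping
with the rank-based test; group means are reported for display.
`sign_imbalance()` tests direction imbalance across regions; the default is
the exact two-sided binomial sign test against ½. The original report used
a Fisher's exact construction whose 2×2 table cannot be recovered from the
text, so a Fisher mode (observed split vs balanced expectation) is provided
behind a flag, and no numerical claim is tied to it.

## Detection choices

* **Threshold**: background median + `threshold_k` × robust sd
  (1.4826 × MAD), default `threshold_k = 5`. Robust statistics keep the
  threshold insensitive to the bright cells themselves.
* **Pre-smoothing**: a Gaussian of σ = 1 px (matched filter) before
  thresholding. Without it, noise-ragged component boundaries inflate the
  crack-length perimeter and deflate circularity; with it, digitized disks
  score ≈ 1.
* **Roundness**: isoperimetric circularity $4\pi A / P^2$, with $P$
  estimated as 4-neighbour crack length × π/4 (the crack length of a smooth
  digital contour overestimates the true perimeter by ≈ 4/π). The pure
  formula is exported as `circularity()`.
* **SNR**: (component mean − background median) / robust background sd,
  with background statistics taken from sub-threshold pixels. The
  background subtraction makes the quantity offset-invariant, i.e. an
  actual signal-to-noise ratio.
* **Starter matching**: greedy one-to-one pairing of rabies and helper
  centroids in ascending distance order, accepted within
  `max_overlap_dist_px = 5` (≈ one cell radius at the fixture scale). The
  source specifies only that "overlap distance determined" starter calls;
  the numeric threshold and the matching rule are declared package
  defaults, all overridable.
* Defaults `min_area_px = 20`, `max_area_px = 500`, `min_circularity =
  0.4`, `min_snr = 3` stand in for the original GUI's user-adjustable
  values, which are not published.

## Registration choices

The transform family is affine (6 degrees of freedom), fitted by least
squares on ≥ 3 user landmark pairs; the original workflow is a
semi-automated point-matching GUI whose transform family is unstated.
Affine keeps small-landmark behaviour exactly testable: 3 non-collinear
pairs interpolate (rms 0), a generating affine is recovered to ≈ 1e−9 from
4 exact pairs. Label lookup is nearest-neighbour (labels are categorical);
coordinates are 0-based (x = column, y = row) in all serialized artifacts.
Points exactly on the midline column tie-break to the section's declared
hemisphere, since each hemisphere is imaged and analyzed separately.

## What the synthetic generator does and does not emulate

`make_synthetic_atlas()` builds mirrored mosaic slices (elliptical
footprint, nearest-seed patches, identical left/right labels) —
structurally like registered coronal label masks, without real anatomy.
`render_section()` draws each cell as a Gaussian-blurred disk whose peak
sits `peak_intensity` above an additive Gaussian background; `"both"`-
channel cells appear in helper and rabies channels. `simulate_cohort()`
draws, per hemisphere, total starters ~ Poisson(`starter_mean` = 50,
conditioned ≥ 1; 90 % placed in the target region, 10 % spill so the QC
target rule is exercisable in both directions) and per-region presynaptic
counts ~ Poisson(PPS × starters), with the sex effect multiplicative on
PPS (`male_multiplier`), matching the fold-difference character of the
observed dimorphism (hundreds vs tens of PPS in the MeA data). Counts are
Poisson because no count-noise model is published; an optional
negative-binomial switch (`overdispersion`) is exposed, default off.

Not emulated: tissue texture and autofluorescence, section-to-section
registration error, real atlas anatomy, bilateral correlation within
animals. A green pipeline test therefore establishes the *software's*
correctness and calibration under a stated generative model — it does not
re-establish the biological effect sizes, and the cohort-level numbers of
the original study (e.g. 385 ± 148.4 vs 67.4 ± 20.7 PPS; 29 significant
regions; 46/50 male-higher) are not reproducible without the unreleased
raw data and are not claimed by any test.

What the tests *do* compute: under the null generator (multiplier 1, 50
regions, 7 v 7, 100 seeds) the mean fraction of FDR-5 % rejections stays
≤ 0.10; with multiplier 5 on 10 designated regions, ≥ 8 of the 10 are
flagged in ≥ 80 % of seeds; detection on rendered images at SNR 5 with
4-radius spacing achieves recall and precision ≥ 0.95 against ground truth
(2 px tolerance).

## Numerical and degenerate-input conventions

* Constant images yield zero detections, not an error; non-finite pixels
  are an error.
* Zero starters make PPS undefined and zero presynaptic cells make FPR
  undefined — both are errors, not NaNs.
* Tier aggregation (`aggregate_counts()`) conserves totals exactly; counts
  whose ancestor chain lacks the requested tier accumulate under the root.
* All generators are pure functions of (arguments, seed) and leave the
  caller's RNG state untouched.
* The TIFF reader/writer is a deliberate in-package codec (uncompressed,
  little-endian, grayscale uint8/16/32 and float32, multi-page): no
  TIFF-capable R package is available in the supported environment, and
  the test suite cross-checks the codec against an independent external
  implementation.

## Known limitations

* Affine registration cannot absorb nonlinear tissue distortion; the
  original semi-automated alignment may.
* Greedy starter matching is not globally minimum-weight; at realistic
  cell spacing (pairs within ~1 radius) the two coincide, and the one-to-one
  and partition invariants hold regardless.
* The crack-length × π/4 perimeter is tuned for blob-like objects; long
  axis-aligned rectangles get inflated circularity. Cells are blobs.
* Fisher-mode `sign_imbalance()` is one plausible reconstruction of an
  under-specified published test and should not be quoted against the
  original's p-value.
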