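---
title: "Quantifying NET formation and degradation: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying NET formation and degradation: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netlapse)
```

## The measurement problem

A NETosis time-lapse assay watches two DNA stains: a membrane-permeable one
(Hoechst/DAPI) that marks every nucleus from the start, and a
membrane-impermeable one (Sytox) that only stains DNA once the membrane is
compromised — released NETs and lysed cells. Three pixel fates follow.
Background pixels never see DNA and fluctuate around a (possibly drifting)
baseline. Pixels inside a released NET light up and then dim as the NET is
dispersed or enzymatically degraded: a rise to a peak followed by a decay.
Pixels over a necrotic cell light up and stay lit: a rise to a plateau. The
package classifies every pixel into one of these three fates from the shape
of its trace, then estimates degradation kinetics from the netotic pixels
only, and a cell census from the DAPI channel and the necrotic region.

## Normalization: the common background as an internal standard

Wide-field time-lapse intensity is not stable: lamp intensity, focus and
exposure drift multiply whole frames by slowly varying factors. Because the
classifier thresholds absolute trace features, such drift must be removed
first. The package uses the video's own background as the standard:

1. every pixel trace is smoothed along time with a Gaussian kernel
   (`smoothing_sigma`, default 1 frame, truncated at 4σ and renormalized,
   symmetric-reflect boundaries);
2. for each *non-trivial* frame, the pixels below the frame's Otsu threshold
   are collected; the intersection over frames is the *common background* —
   pixels that never belonged to a cell or NET;
3. the per-frame mean over that mask is the time-variable scaling curve, and
   dividing each frame by it gives the dimensionless background-rescaled
   stack used for classification (and for nothing else).

Any per-frame multiplicative drift applied to the normalization input scales
mask, threshold and scaling curve together and cancels exactly; the test
suite asserts bit-identical label maps under linear, sinusoidal and random
drifts up to ±30%. One caveat is worth stating plainly: temporal smoothing
does not commute with per-frame scaling, so drift is cancelled exactly at
the normalization stage (its purpose), while drift interacting with the
smoothing window leaves sub-tolerance residues that in practice never move a
label — classification margins are wide (rescaled maxima of cell pixels sit
several-fold above the gate).

Two numerical guards matter here. A frame is *trivial* — skipped when
intersecting — if its intensity range is zero or its Otsu split leaves less
than 1% of pixels on either side; without this, a uniform or noise-only
frame yields a meaningless threshold that poisons the intersection. And the
scaling curve is floored at `1e-6 ×` the global maximum so a pathological
all-dark frame cannot produce a division blow-up. Otsu runs on the
*smoothed* stack, matching the order of the processing chain (smoothing is
the first step); the choice is deliberate since the alternative (raw frames)
is equally defensible but mixes two noise scales.

## The three-class rule

For a rescaled trace with maximum `M`, final value `F`, and post-extremum
step fractions `p⁺` (strictly increasing steps after the minimum) and `p⁻`
(strictly decreasing steps after the maximum):

* necrotic: `M > 5` and `p⁺ > 0.5` and `F > 0.9·M`;
* netotic: `M > 5` and `p⁻ > 0.5` and `F < M`;
* background: otherwise.

All comparisons are strict. Three decisions close gaps the rule leaves open:

* **Precedence.** A noisy plateau can satisfy both rules (`F` can land
  between `0.9·M` and `M`), so the necrotic rule is tested first. Listing
  order aside, this is the conservative choice: it keeps marginal plateau
  pixels out of the netotic pool that feeds the kinetics.
* **Zero-derivative steps** count in the denominator of `p⁺`/`p⁻` but in
  neither numerator: "time spent increasing" is read as strictly increasing,
  so a flat stretch is not evidence of either direction.
* **Ties in extrema** break to the earliest frame, which makes peak
  alignment deterministic; an extremum on the last frame has an empty
  post-extremum window and its fraction is defined as 0.

The vectorized classifier is verified pixel-for-pixel against a plain
nested-loop transliteration of the rule (`oracle_classify()`) on hundreds of
random stacks; both live in the package so the equivalence can be re-checked
at any time.

The gate of 5, the 0.5 time fraction and the 0.9 plateau fraction are the
assay's published operating point and are exposed in `run_config()` rather
than hard-coded; lowering the gate can only move pixels out of background
(a monotonicity the tests assert), never the reverse.

## Kinetics: from netotic pixels to a half-life

Classification uses the rescaled signal; kinetics do not. From the pixels
labelled netotic, `n_sample_pixels` (default 1000) are drawn uniformly
without replacement, and their **raw smoothed** traces are collected along
with each trace's peaking time. Traces are aligned at their peaks (cells
lyse at different times; alignment isolates post-peak behaviour), normalized
affinely from [pre-peak minimum, peak] to [0, 1] — post-peak values below
the pre-peak minimum legitimately map below 0 and are not clipped — and
summarized into pointwise median/Q1/Q3 curves. Relative timepoints covered
by fewer than 25% of traces are trimmed: quartiles computed from a handful
of extreme-offset traces are noise, and the default keeps the analysis
window where the sample actually is. Flat traces (peak equals pre-peak
minimum) carry no kinetics and are dropped with a logged count.

The 50%- and 80%-lifetimes are the times for a normalized curve to first
fall from 1 to 0.5 / 0.2, linearly interpolated between the two bracketing
frames. Linear interpolation gives sub-frame resolution without assuming a
decay model; on densely sampled analytic exponentials it agrees with a root
finder to well under 0.1 min, and on 15-min grids the worst-case
interpolation error is a fraction of a frame. A curve that never reaches the
level is reported *censored* together with its observed span — censoring is
never imputed, and a 12-h half-life observed for 10 h post-peak will (and
should) come back censored at the 0.2 level. The unit of output is one
half-life per field of view (the median curve's 50%-lifetime); comparisons
across conditions are left to the caller.

## Census and net span

The initial cell count is the number of connected components of the
Otsu-thresholded first DAPI frame with area in `kernel_area_bounds`
(default [1000, 4000] px, inclusive at both ends); the necrotic count gates
necrotic-labelled components at [5000, 10000] px. The netotic count is
`initial − necrotic`, floored at 0 with a warning — the identity assumes
every initial cell resolves to one of the two fates, which holds by
construction in the synthetic scenes and approximately in stimulated wells.
Net span divides the total netotic area by that count and carries a
permanent `underestimate` flag: overlapping NETs share pixels, so the true
per-cell extent is larger. Connectivity defaults to 8 (the usual imaging
convention for blob counting) and is configurable; component labelling is
implemented over the pixel adjacency graph and cross-checked against an
independent 4-connectivity labeller in the tests.

## What the synthetic generator emulates — and what it does not

`synthetic_scene()` / `random_scene()` build fields of view with the
statistical structure the classifier assumes: a flat background
(default level 100) with additive Gaussian noise (default SD 5, clipped at
0), per-frame multiplicative drift, disk-shaped nuclei with areas inside the
census gate, and Sytox kinetics per fate — netotic pixels rise linearly over
30 min to a peak 8× background and decay exponentially with the configured
half-life; necrotic pixels rise to 90% of their amplitude and then climb
slowly to their maximum at the final frame, keeping them strictly inside the
plateau criterion. The 8× peak leaves margin over the >5 gate at the default
noise; the defaults were fixed once, from what a PMA time-lapse at 15-min
cadence plausibly looks like, before being used in any validation.

Real videos differ in ways the generator deliberately ignores: no optics
(PSF blur, shot noise, vignetting), no cell motility or NET drift, no
partial-volume pixels at footprint edges, no overlapping NETs, no focus
excursions. Passing the synthetic validation therefore demonstrates that the
algorithms are implemented correctly and are robust to noise and global
drift of the modelled kind — not that the biological operating point of a
particular microscope is reproduced. Validation problem sizes were chosen to
make the suite comfortably reproducible on a laptop: classification scenes
of 256×256 px × 61 frames (15-min frames, 15 h), census scenes up to
560×560 px at zero noise, and five seeds per half-life in
{90, 180, 360, 585, 720} min; at these sizes the recovered median-curve
half-life lands within one frame interval (±15 min) of truth and a true
two-fold half-life difference (195 vs 390 min) is recovered as a ratio
within [1.8, 2.2].

## Degenerate inputs and error semantics

Single-frame stacks, negative intensities and non-finite values are rejected
at construction. A video whose every frame is trivial (e.g. frame-uniform)
cannot yield a background estimate and errors with a diagnosis, as does an
empty background intersection (field too crowded). Zero netotic pixels is an
explicit "no NETs detected" error rather than an empty result, because every
downstream quantity is undefined. A frame with zero intensity range cannot
be Otsu-thresholded and the endpoint NET-area call says so. Requesting more
sample pixels than exist takes all of them and flags the trace set as
exhausted. Net span with zero estimated netotic cells is an error, not a 0
or an `Inf`.

## Layout conventions

Stacks are `(row, col, frame)` arrays wrapped in a light `video_stack`
object — the native R/EBImage layout — with the frame interval carried as
user-supplied metadata (default 15 min) rather than parsed from TIFF tags,
whose dialects are unreliable. All times are minutes internally; hours
appear only in printed summaries. Integer stacks round-trip through 16-bit
TIFF bit-exactly; label maps use 0/1/2 in an 8-bit TIFF. Tabular results are
tibbles throughout, `tidy()`/`glance()` follow their usual contracts, and
`autoplot()` renders the two result types (class maps, summary curves) as
ggplots.

## Known limitations

The classifier is pixel-wise: it neither segments nor tracks objects, so a
pixel crossed by two events reports their superposition. The census identity
ignores quiescent survivors (counted as netotic) and cells arriving after
frame 0. Net span is a lower bound by design. Half-lives are read from
median curves, not fitted decay models — robust, but blind to
multi-exponential behaviour. And the common-background mask is slightly
dim-biased (it keeps pixels below noise-frame Otsu cuts), which the
rescaling inherits as a small, constant, and therefore harmless, scale
factor.
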