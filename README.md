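# netlapse

Quantification of neutrophil extracellular trap (NET) formation and
degradation from two-channel live-cell time-lapse microscopy.

When neutrophils undergo NETosis they expel their chromatin as an
extracellular web that a membrane-impermeable DNA dye (Sytox) lights up; as
the NET is dispersed or degraded the signal decays again. Cells that die by
lysis without NET release (necrosis) also become Sytox-positive, but their
signal rises and then stays at a plateau. `netlapse` turns a two-channel
time-lapse — a Hoechst/DAPI channel marking all nuclei plus a Sytox channel —
into per-field summaries of how many cells made NETs and how fast those NETs
decayed. It is aimed at labs running plate-based NETosis / NET-degradation
assays (e.g. PMA stimulation imaged every 15 min for 10–15 h).

## Method

Every pixel's Sytox trace is smoothed along time with a Gaussian kernel and
divided, frame by frame, by the mean intensity of the *common background* —
the pixels that sit below the per-frame Otsu threshold in every non-trivial
frame, i.e. were never part of a cell or NET. This background-rescaled,
dimensionless trace is immune to global contrast drift. Writing `M` for its
maximum, `F` for its final value, and `p⁺`/`p⁻` for the fraction of strictly
increasing steps after the trace minimum and strictly decreasing steps after
the maximum, each pixel is classified as

* **necrotic** if `M > 5` and `p⁺ > 0.5` and `F > 0.9·M` (rise and plateau),
* **netotic** if `M > 5` and `p⁻ > 0.5` and `F < M` (rise and decay),
* **background** otherwise,

with the necrotic rule tested first. Downstream, 1000 random netotic pixels
are sampled and their *raw* smoothed traces are aligned at their peaks,
normalized between the pre-peak minimum (0) and the peak (1), and summarized
into pointwise median/Q1/Q3 curves. The **50%-lifetime** of the median curve
— the time for it to fall from 1 to 0.5, linearly interpolated between
frames — is the field's NET half-life; the 80%-lifetime (fall to 0.2) is
reported alongside. The cell census counts frame-0 DAPI components with area
in [1000, 4000] px (valid nuclei) and necrotic-region components in
[5000, 10000] px (valid necrotic cells); netotic cells are estimated as
initial − necrotic, and the *net span* is the total netotic area divided by
that count (a deliberate underestimate, since NETs overlap). A seeded
synthetic-scene generator produces two-channel videos with known pixel
classes, counts and decay half-lives for validating every stage.

## Worked example

```r
library(netlapse)

scene <- random_scene(n_netotic = 4, n_necrotic = 2, n_frames = 61,
                      decay_half_life = 360, seed = 42)   # truth: T1/2 = 6 h
vid <- generate_video(scene)
fit <- quantify_video(vid$dapi, vid$sytox, run_config(seed = 42))
fit
#> <net_quant>
#> <pixel_class_map> 256x256: 65.2% background, 15.3% netotic, 19.6% necrotic
#>   census: 6 initial, 2 necrotic, 4 netotic
#>   NET half-life (median curve): 369 min (6.16 h)

tidy(fit)
#> # A tibble: 6 × 5
#>   fraction curve  lifetime_min censored observed_span_min
#>      <dbl> <chr>         <dbl> <lgl>                <dbl>
#> 1      0.5 median         369. FALSE                  765
#> 2      0.5 q1             366. FALSE                  765
#> 3      0.5 q3             373. FALSE                  765
#> 4      0.2 median          NA  TRUE                   765
#> 5      0.2 q1              NA  TRUE                   765
#> 6      0.2 q3              NA  TRUE                   765
```

The classifier recovered all six cells (4 netotic + 2 necrotic) and
estimated the NET half-life at 369 min against a simulated truth of 360 min
— within one 15-min frame. The 80%-lifetime is censored: a 6-h half-life
needs ~14 h after the peak to fall to 0.2, longer than this video's post-peak
span (765 min), so the package reports the censoring rather than
extrapolating. `glance(fit)` condenses the field into one row (counts, total
NET area of 10000 px, span of 2500 px/cell, half-life);
`autoplot(fit$curves_norm)` draws the median curve with its quartile ribbon
and `autoplot(fit$labels)` the class map. A command-line wrapper with
`simulate` / `classify` / `lifetimes` / `counts` / `netarea` subcommands
lives in `inst/scripts/netlapse-cli.R`.

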