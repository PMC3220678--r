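# retrotrack

Retrospective quantification of protein nuclear–cytoplasmic translocation in
single-channel fluorescence time-lapse microscopy.

## The problem

Shuttling proteins such as STAT transcription factors are imaged live in one
fluorescence channel (e.g. a YFP fusion); a nuclear counterstain cannot be
used on living cells without perturbing them, and before stimulation the
nucleus is usually the *dim* part of the cell — so segmenting every frame
prospectively is fragile. The retrospective strategy images the field live
(13 frames, one per 10 min, is the typical design), then fixes and stains
the same field. Segmentation is done **once**, on the high-contrast fixed
images, and the masks are carried *backwards* through the registered live
series. Cell identity comes from the end point, so there is no tracking —
but a cell that moved during the course invalidates its own mask, and such
cells must be detected automatically.

`retrotrack` implements that pipeline for R, on top of
[EBImage](https://bioconductor.org/packages/EBImage/):

1. **Registration** — integer-pixel translation by masked normalized
   cross-correlation (FFT-exhaustive over the search window), chained
   frame-to-frame: the last frame aligns to the fixed target image, each
   earlier frame to the already-registered next frame. Exposed borders are
   tracked in validity masks, never as fake zeros.
2. **Segmentation** — nuclei from the fixed nuclear stain
   (Laplacian-of-Gaussian edges → flood fill → Otsu intersection → watershed
   splitting → size filter); cytoplasm from the first registered frame (Otsu
   foreground, seeded watershed with nuclei as seeds, intersected with each
   nucleus dilated by *d* px); nuclear masks eroded by *e* px before any
   measurement; edge-touching cells excluded.
3. **Mask QC** — per-nucleus s.d. is regressed on mean over a stationary
   control population (robust IRLS, bisquare); a cell is *matched* iff its
   first-frame (mean, s.d.) pair lies below the upper boundary of the
   99.5% prediction band, otherwise *mismatched or false* (motile or
   mis-segmented). Shape QC flags outliers in perimeter/solidity/intensity.
4. **Quantification** — per cell and frame: the N:C ratio (normalized to 1
   at time 0), nuclear accumulation NA = I(t)/I(0), nuclear increment
   NI = (I(t) − I(t−1))/I(0), difference variation |V1 − V2|/(V1 + V2)
   between mask settings, responder calls against the pre-treatment 95th
   percentile of raw N:C ratios, and the time of maximal import speed on a
   20-minute NI grid.
5. **Simulation** — `simulateField()` generates ground-truthed synthetic
   fields (delayed-logistic import kinetics, conservative cytoplasm
   depletion, motile cells, stage drift, uneven fixation dimming) so every
   stage is testable without microscope data.

## Worked example

```r
library(retrotrack)

## stationary control: cells imaged once live, then fixed
ctl <- simulateControl(SimConfig(nCells = 100, moverFraction = 0,
                                 responderFraction = 0, seed = 2))
fit <- fitRobustLine(controlMaskStats(ctl$field), alpha = 0.005)
fit
#> RobustFit: sd = 0.047802 * mean + 11.033  (scale 2.922, n = 100, alpha = 0.005)

## a stimulated field: 40 cells, 13 frames at 10-minute intervals
sim <- simulateField(SimConfig(nCells = 40, seed = 1))
res <- analyzeField(sim$field, PipelineConfig(d = 8, e = 3), controlFit = fit)
table(res$classes$label)
#>             matched mismatched_or_false
#>                  38                   2

summ <- summarizePopulation(res$traces, res$classes, "na")
subset(summ, stratum == "matched_only" & frame %in% c(1, 5, 9, 13))
#>         stratum frame t_min median   p05  p95 mean    sd n_cells
#>    matched_only     1    10   1.00 1.000 1.00 1.00  0.00      38
#>    matched_only     5    50   1.14 0.991 1.89 1.59  2.07      38
#>    matched_only     9    90   2.21 0.989 3.43 3.21  6.89      38
#>    matched_only    13   130   2.39 0.989 3.49 4.19 11.86      38

pre  <- res$traces$raw_nc[res$traces$frame == 1]
post <- res$traces$raw_nc[res$traces$frame == 13]
resp <- callResponders(pre, post)
sprintf("threshold %.4f; %d of %d cells responded", resp$threshold,
        sum(resp$responder), length(post))
#> "threshold 0.9248; 31 of 40 cells responded"

tms <- vapply(split(res$traces, res$traces$cell_id),
              function(df) timeToMaxSpeed(df$na, df$t_min), 0)
table(tms[resp$responder])
#>  40  60  80 100
#>   2  16  11   2
```

Reading the output: the median NA of matched cells rises from 1.0 to ~2.4
(nuclear fluorescence more than doubles by 130 min), while the 5th
percentile stays at ~1 — the non-responding minority. The mean/s.d. columns
are dominated by one motile cell whose end-point mask sat on empty
background at the first frames (a low-s.d. case the upper-band classifier
deliberately does not gate on); the median and percentiles are the robust
summaries used downstream. Most responders reach their maximal import speed
60–80 minutes after the first frame.

A command-line front end over the same functions is installed at
`inst/scripts/retrotrack` (subcommands `simulate`, `register`, `segment`,
`classify`, `quantify`; see `--help`), with an example configuration in
`inst/extdata/pipeline-config.yaml`.

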