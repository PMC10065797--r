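# lgkinetics

Quantitative analysis of blood-progenitor kinetics in the *Drosophila*
larval lymph gland, built around long-term dual-reporter live imaging
(dome-MESO-GFP marking JAK-STAT–active progenitors, eater-dsRed marking
plasmatocyte commitment; frames every 15 s).

## The science

The lymph gland is the larval hematopoietic organ. Its progenitors sit in
a medullary zone near the heart tube and differentiate outward into the
cortical zone. Tracking single cells through both reporters lets three
questions be answered quantitatively:

1. **How do progenitors differentiate?** Each cell's dsRed:GFP ratio over
   time is either *sigmoid* — a slow phase, a rapid switch, then
   saturation — or *linear*, a constant-rate drift in cells that already
   co-express both reporters. The package jointly min–max normalizes the
   two channels, fits a 4-parameter logistic and a line to the ratio, and
   selects the class by corrected AIC with an ambiguity margin plus a
   sanity rule: a fit only counts as a sigmoid when its midpoint and its
   whole 10–90% fast phase lie inside the recording and its amplitude
   clears the fit noise. The differentiation rate is the OLS slope of the
   ratio over the fast phase (sigmoid) or the whole track (linear).
   Infection shifts cells toward faster, earlier, higher-amplitude
   differentiation — per-video activation events rise more than 2-fold
   (25 events / 6 videos vs 11 / 8, a 3.03-fold change).
2. **How do progenitors divide?** Mitosis duration is the
   breakdown-to-completion interval plus a 10-min onset offset (40 frames
   at 15 s before nuclear-envelope breakdown). Division axes are classed
   in the organ's cylindrical frame: within 45° of the dorsal–ventral axis
   is a *z*-mitosis, otherwise a *ρ*-mitosis (~90% of events). In-plane
   orientations relative to the heart tube are summarized on [0°, 180°)
   and checked for normality with a Q-Q linearity report. Critical-size
   metrics (pre-mitotic mother area ≈ 72 µm², daughter regrowth) come from
   the same event records.
3. **Where do events happen?** Lobes are rigidly aligned so the heart
   tube runs along the y-axis with the lobe facing +x, event positions are
   binned into a proportional 5×5 grid over the lobe's bounding box, and
   per-video maps are summed and compared by Pearson correlation with the
   conventional none/weak/moderate/strong categories.

Two supporting modules complete the pipeline: *histo-cytometry* (25/50/75%
slice selection, Laplacian-of-Gaussian nucleus detection with
non-maximum suppression, seeded subsampling and GFP×dsRed quadrant gating
with Otsu-derived thresholds) and *FUCCI* phase calling (E2f1-GFP /
CycB-RFP degron logic: green-only → G1, red-only → S, both → G2, a dark
run flanked by G2 then G1 → M).

Because the original recordings are too large to ship, the package
includes labeled synthetic generators that emulate the statistical
structure of every data type — logistic/linear dual-reporter tracks,
division cohorts with moment-matched truncated-normal durations inside an
ellipsoidal lobe, Gaussian-blob nucleus images and FUCCI traces — so every
stage is tested against ground truth.

## Worked example

```r
library(lgkinetics)

## differentiation: simulate, normalize, classify ---------------------------
track <- simulate_differentiation_track(
  differentiation_model("sigmoid_wt"), n_frames = 1320, seed = 42)
norm <- normalize_dual_channel(track)
fit <- classify_trajectory(norm)
fit
#> <trajectory_fit> cell sim1 - class: sigmoid rate 0.2343 per min
round(fit$logistic, 3)
#>       b       A      t0     tau
#>  -0.021  16.092 198.644  13.654
c(fit$fast_phase, diff(fit$fast_phase))   # 10-90% window, ln(81)*tau wide
#> t_start   t_end
#>   168.6   228.6    60.0

## division kinetics --------------------------------------------------------
cohort <- simulate_division_cohort(division_cohort_model(n_events = 500),
                                   seed = 42)
s <- division_summary(cohort)$summary
#> n = 500 | rho 87.2% | duration 56.6 +/- 27.5 min | mother area 70.8 um2

## spatial heat map ---------------------------------------------------------
geom <- default_geometry()
pos <- do.call(rbind, lapply(cohort, function(e) e$position_um[1:2]))
al <- align_lobe(pos, geom)
build_heatmap(al$points, al$boundary)
#> <lg_heatmap> 5 x 5 grid, 500 events binned, 0 excluded
#>      [,1] [,2] [,3] [,4] [,5]
#> [1,]    5   12   19   19    4
#> [2,]   11   24   43   47    7
#> [3,]   16   33   36   24   24
#> [4,]   15   27   32   29   16
#> [5,]    1   14   22   17    3

## FUCCI phase calling ------------------------------------------------------
tr <- simulate_fucci_trace(
  data.frame(phase = c("G2", "M", "G1"), duration_min = c(30, 10, 30)),
  noise_cv = 0.1, seed = 1)
table(call_phase(tr))
#>  G1  G2   M
#> 120 120  40
```

## Command line

`exec/lgk` drives the same pipeline from the shell:

```sh
lgk simulate --what tracks --n 5 --seed 7 --out tracks.csv
lgk normalize --in tracks.csv --out norm.csv
lgk classify  --in tracks.csv --out classes.csv
lgk simulate --what divisions --n 100 --seed 3 --out events.csv
lgk divisions --in events.csv --out quant.csv      # + quant_summary.json
lgk heatmap --events events.csv --out map.json
lgk heatmap-compare map_a.json map_b.json
lgk histocyto --image stack.tif --out cells.csv    # + cells_summary.json
lgk fucci --in traces.csv --out phases.csv
```

All stages accept `--config config.yaml` (see `lg_config()` for the keys:
frame interval, onset offset, grid size, ρ/z angle threshold, AICc margin,
fast-phase quantiles, ratio floor, blob diameter/quality, sample size,
gates, noise, seed) and `--seed`.

## Methods

See `vignettes/lymph-gland-kinetics.Rmd` for the models, parameter
rationale, numerical choices and known limitations.
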