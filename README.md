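# faprox

Quantification of post-Golgi secretion hotspots at focal adhesions from
two-channel fluorescence microscopy.

## What it is for

Cells do not exocytose everywhere: secreted cargo accumulates at discrete
sites, and a central claim in adhesion biology is that these sites sit
next to focal adhesions (FAs). Testing that claim from images requires an
unbiased spatial statistic, not eyeballing. `faprox` provides the full
quantification chain for a cell biologist with an FA channel (e.g.
paxillin) and a cargo channel (e.g. a RUSH-released cargo captured on the
coverslip):

* **Segmentation** of FAs and cargo by Gaussian filtering + thresholding
  (explicit or Otsu-over-ROI), with recorded parameters.
* **The enrichment statistic**: exact per-pixel Euclidean distance to the
  nearest FA pixel, the whole-cell baseline distribution, and the per-bin
  ratio

  `R(b) = p_cargo(b) / p_roi(b)`

  where `p_cargo(b)` is the fraction of cargo pixels whose FA distance
  falls in bin `b`, and `p_roi(b)` the same fraction over *all* pixels of
  the cell ROI. `R = 1` everywhere means no spatial bias (the behavior of
  a homogeneously distributed membrane marker); `R >> 1` near zero is the
  hotspot signature. A scalar summary `enrichment_near(d_cut)` integrates
  both histograms below a cutoff.
* **Spot detection and counting** (Find-Maxima-style prominence-filtered
  local maxima), densities per cell and per µm², and normalized
  secreted-spot intensity.
* **Vesicle kinetics**: greedy nearest-neighbor tracking (velocity µm/s,
  covered distance µm), kymographs along polylines, temporal (time-of-peak)
  projections.
* **Colocalization and statistics**: object-based one-to-one matching,
  Pearson's r over a ROI, the supernatant/(supernatant+lysate) secreted
  fraction for pulse-chase blots, and Student's t comparisons with
  mean ± SEM summaries.
* **A seeded synthetic-microscopy generator** with ground truth (FA blobs,
  cargo at controlled distances, vesicle movies with PSF + Poisson +
  read noise), so the whole chain is testable without real data.
* **A CLI pipeline** (`exec/faprox`) with subcommands `simulate`,
  `segment`, `enrich`, `track`, `kymo`, `coloc`, `pearson`, `sunset`,
  `run`; JSON configs, CSV/TIFF/JSON outputs, one `--seed`.

## Worked example

Simulate a cell whose cargo is secreted next to FAs (half-normal offsets,
scale 0.5 µm), then quantify it as real data would be:

```r
library(faprox)

cfg <- simulation_config(cargo_mode = "fa_proximal", offset_scale_um = 0.5,
                         n_fas = 15, n_spots = 60, seed = 42)
scene <- simulate_cell_scene(cfg)
roi <- scene$truth$roi_mask

fa_seg    <- segment_objects(scene$fa_image,    roi)
cargo_seg <- segment_objects(scene$cargo_image, roi)
count_objects(fa_seg, min_area = 4)
#> [1] 14

prof <- enrichment_profile(cargo_seg$labels > 0, fa_seg$labels > 0, roi,
                           pixel_size = 0.1, bin_width = 0.5)
head(as.data.frame(prof), 4)
#>   bin_start_um bin_end_um p_cargo  p_roi ratio
#> 1          0.0        0.5 0.83054 0.1123 7.393
#> 2          0.5        1.0 0.14877 0.1185 1.256
#> 3          1.0        1.5 0.00985 0.1048 0.094
#> 4          1.5        2.0 0.01084 0.0886 0.122

enrichment_near(prof, 1)
#> [1] 4.24

spots <- detect_spots(scene$cargo_image, roi, min_distance = 3,
                      prominence = 50)
spot_density(spots, roi, 0.1)
#> $per_cell: 35    $per_area: 0.0965  # spots / um^2
```

Reading: 83% of cargo pixels lie within 0.5 µm of an FA versus 11% of all
cell pixels (`R = 7.4`), cargo is 4.2-fold enriched within 1 µm, and
beyond 1 µm the ratio collapses below 1 — the hotspot signature. A
`cargo_mode = "uniform"` control gives `R ≈ 1` in every bin (14 of the 15
simulated FAs were recovered at this threshold; one pair merged). For real
data, replace the simulation by `read_tiff()` + `read_roi_json()` and the
same calls apply, or run everything at once with `run_pipeline()` /
`faprox run --config analysis.json --out outdir`.

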