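---
title: "Quantifying secretion hotspots at focal adhesions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying secretion hotspots at focal adhesions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faprox)
```

## The question and the statistic

Post-Golgi carriers deliver newly synthesized cargo to the plasma
membrane. If exocytosis is not spatially random but concentrated at
hotspots next to focal adhesions (FAs), then pixels occupied by secreted
cargo should sit closer to FA pixels than a randomly chosen pixel of the
same cell does. `faprox` turns that comparison into a reproducible
statistic:

1. Segment the FA channel and the cargo channel inside a cell region of
   interest (ROI).
2. Compute the exact Euclidean distance transform of the FA mask, giving
   every pixel its distance $d$ (in micrometers) to the nearest FA pixel.
3. Histogram the distances of cargo pixels, $p_\mathrm{cargo}(b)$, and of
   *all* ROI pixels, $p_\mathrm{roi}(b)$, into uniform bins
   $b = [kw, (k+1)w)$, each normalized to fractions.
4. Report the enrichment ratio
   $$R(b) = \frac{p_\mathrm{cargo}(b)}{p_\mathrm{roi}(b)},$$
   and the scalar summary
   $R_{<d_c} = \sum_{b < d_c} p_\mathrm{cargo}(b) \big/ \sum_{b < d_c} p_\mathrm{roi}(b)$.

$R \equiv 1$ means cargo is placed like a uniformly sampled ROI pixel — the
behavior of a homogeneously distributed membrane marker. $R > 1$ in the
first bins with a compensating deficit at large distances is the hotspot
signature. Because both numerator and denominator are fractions over the
same cell, $R$ is invariant to cell size, to uniform intensity rescaling,
and satisfies the identity $\sum_b R(b)\,p_\mathrm{roi}(b) = 1$, which the
test suite asserts to $10^{-9}$ on random inputs.

Two deliberate conventions (both exposed as parameters):

* the baseline includes FA pixels themselves, and cargo overlapping FAs
  counts in the first bin (`exclude_fa_overlap = FALSE` by default) — the
  distance is measured "to the closest FA pixel", with no exclusion;
* cargo pixels are *object* pixels from segmentation, not raw intensity
  weights: segmentation precedes measurement.

The bin width default is 0.5 µm. No published value exists for this
choice; it is about five pixels at the default calibration and keeps
single-pixel quantization well below bin resolution.

## Segmentation and spot detection

Objects are segmented by Gaussian filtering (default $\sigma$ = 1 px)
followed by thresholding. The original analyses adjusted thresholds per
image by hand; as a reproducible stand-in, the default threshold is Otsu's
method computed **over ROI pixels only**, and every `label_mask` records
the `sigma_used` / `threshold_used` actually applied. Labeling is
8-connected. Raising the threshold can never increase the foreground pixel
count (a tested invariant).

Vesicle counting replaces interactive Find-Maxima clicking with a
deterministic rule: local maxima of the lightly smoothed image
($\sigma$ = 1 px) are kept when they rise more than `prominence` above the
local background (the window minimum; window half-width
$\max(2\,\texttt{min\_distance}, 5)$ px), candidates closer than
`min_distance` are pruned brighter-first with ties broken by lower
(row, col), and centroids are refined by background-subtracted intensity
weighting in a window capped at 3 px — PSF-scale, so that a large
`min_distance` cannot drag a centroid toward a neighboring structure. On
noiseless sums of well-separated Gaussians the detector returns exactly
one spot per peak with < 0.5 px error (tested).

Counts are normalized per cell and per ROI area (µm²); secreted-spot
intensity is reported as mean spot-pixel intensity over mean ROI intensity
in the same channel, which cancels any global scaling. "Manual selection"
of objects has no stated criterion in the source workflow; the surrogate
here is an explicit `min_area` filter recorded with the result.

## Vesicle kinetics

Tracking is greedy nearest-neighbor linking between consecutive frames
with a hard displacement cutoff and **no gap closing** — an auditable
replacement for manual tracking. Fragmentation is reported, never hidden;
the linker never merges two same-frame detections. Track length $L$ is the
covered distance (sum of step lengths, µm) and velocity is the mean path
speed $v = L / ((n-1)\,\Delta t)$; single-point tracks are flagged with
$v = L = 0$.

Kymographs sample each frame by bilinear interpolation at unit arc-length
steps along a polyline, averaging `line_width` perpendicular offsets
(odd, default 3 px — the usual reslice convention; the width actually used
by the original interactive tools is not stated). The temporal projection
keeps the per-pixel maximum and the earliest frame index attaining it,
i.e. the information content of a temporal color-code image.

## Colocalization and group statistics

Object-based colocalization matches spots of two channels within a frame
one-to-one, greedily by increasing centroid distance with a cutoff
(default 3 px ≈ one vesicle radius; the original per-vesicle manual
criterion is unstated, so the radius is an exposed parameter). Pixel-based
colocalization is Pearson's $r$ over ROI pixels. The secreted fraction for
pulse-chase blot quantification is
$F(t) = I_\mathrm{sup}(t) / (I_\mathrm{sup}(t) + I_\mathrm{lys}(t))$,
scale-invariant and bounded in $[0, 1]$. Group comparisons use Student's
two-sample $t$ test with pooled variance by default (Welch behind a flag),
reporting mean ± SEM per group.

## The synthetic-microscopy generator

No imaging data are deposited with the source study, so every stage is
validated against a seeded generator whose geometry emulates the imaging
setting:

* **Field**: 256 × 256 px at 0.1 µm/px (a ~26 µm cell in a TIRF-like
  field). The pixel size is a package default, not a published value.
* **ROI**: a centered ellipse (semi-axes 0.42 of the field) or any
  polygon.
* **FAs**: `n_fas` (default 20) anisotropic Gaussian blobs, FWHM
  1.2 × 0.4 µm, placed in a band near the ROI edge and oriented radially
  (paxillin-like peripheral streaks). The *true* FA mask is the half-max
  contour. Placements are rejection-sampled to keep a 1-px gap so
  ground-truth counts are unambiguous; 1,000 failures abort.
* **Cargo**: `fa_proximal` spots sit at $|N(0, d_0)|$ µm outside the FA
  boundary ($d_0$ = `offset_scale_um`, default 0.5 µm), offset along the
  analytic outward normal of the anchoring blob with one corrective step
  so the realized nearest-mask distance equals the drawn offset (a naive
  center-to-boundary direction is tangentially biased on elongated blobs);
  `uniform` spots are uniform over ROI pixels (the homogeneous-marker
  control); `on_fa` spots sit on FA pixels. An optional hard-core distance
  `min_spot_separation_px` emulates vesicle size when resolvable spots are
  required.
* **Movies**: vesicles move at constant programmed speed along random
  polylines long enough for the movie; with `tracks_share_paths`, several
  vesicles reuse one polyline at staggered starts (3 frames), waiting at
  the path start until released and stopping at the path end if they
  outrun it.
* **Noise**: Poisson shot noise on signal + background plus Gaussian read
  noise, clamped at zero — the standard camera model. Defaults (amplitude
  200, background 10, read noise 2 photons) give peak SNR ≈ 13. Setting
  `background = 0`, `gaussian_read_noise_sd = 0`, `shot_noise = FALSE`
  yields a truly noiseless render for oracle tests.

One integer seed drives a single RNG stream; identical configs are
bit-identical, and the caller's RNG state is left untouched.

**What a green test does not establish.** The generator produces isolated
Gaussian spots on flat backgrounds inside a convex cell. It does not
emulate uneven illumination, out-of-focus haze, vesicle shape, motion
blur, photobleaching, FA turnover, or segmentation ambiguity on dim
structures. Ground-truth recovery here validates the *computations*; it
does not certify performance on real micrographs, where thresholds must be
chosen per dataset (and are recorded for that reason).

## Numerical choices and degenerate inputs

* Distances are pixel-center to pixel-center; the transform is the exact
  two-pass parabolic-envelope algorithm (C++), property-tested against an
  exhaustive oracle on random masks up to 64 × 64.
* Pixel coordinates are 0-based (row, col) with centers on integers; ROI
  membership is the even-odd rule on pixel centers, so a rectangle meant
  to include pixel rows 2..5 runs from 1.5 to 5.5.
* Empty masks error early with specific messages ("no FA pixels", "no
  cargo signal", "no secreted spots") rather than returning NaN; a
  threshold above the intensity range is *not* an error and returns an
  empty, zero-object mask.
* $R(b)$ is `NA` (flagged) in bins with an empty baseline; bins beyond the
  largest observed ROI distance are omitted.
* Ties: spot detection prefers the brighter candidate, then lower
  (row, col); temporal projection takes the earliest frame.
* Matching (tracking and colocalization) is greedy in increasing distance,
  not bipartite-optimal: deterministic, O(n²) worst case, and verified
  against exhaustive assignment on small instances where they coincide.

## File contracts

Images travel as uncompressed grayscale TIFF (uint8/16 or float32, single
or multi-page; the package ships its own minimal baseline codec because
the supported R stack has none), ROIs as JSON polygons
(`{"polygon": [[row, col], ...]}`), tables as CSV with unit-suffixed
headers (`_um`, `_um_s`, `_per_um2`), and run metadata as a JSON MANIFEST
carrying the full parameter set and seed. CLI configs are JSON. Reruns of
`run_pipeline()` with the same config and seed are byte-identical, which
the acceptance suite checks on the CSV bytes.

## Known limitations

* Greedy linking fragments crossing trajectories rather than resolving
  them; there is no gap closing, by design.
* Otsu-over-ROI is a stand-in for per-image manual thresholding; on
  bimodal backgrounds it can differ substantially from an expert's choice.
* The enrichment statistic attributes no secretion event to an individual
  FA; it is a population statement over pixels.
* Headline biological effect sizes from the source experiments (fractions
  of marker-positive carriers, depletion effects on secretion) depend on
  undeposited live-cell data and are out of scope; the package validates
  its machinery on synthetic ground truth instead.
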