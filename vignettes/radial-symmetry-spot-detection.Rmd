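---
title: "Radial-symmetry spot detection: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radial-symmetry spot detection: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radialspots)
```

# The problem

Single-molecule FISH and related spatial-omics methods encode their signal
as diffraction-limited fluorescent spots: point emitters imaged as the
microscope's point spread function (PSF), a blob a few pixels across.
Quantitative analysis needs every spot detected and its center located
with sub-pixel accuracy, across noise levels and, for 3D stacks, despite
the axial elongation of the PSF.

`radialspots` implements a radial-symmetry detector for this task. In
noise-free data, the intensity gradients around a radially symmetric spot
all point at its center, so the center is the intersection point of the
gradient lines. With noise the lines no longer intersect; the center
becomes the least-squares solution, and robustness comes from RANSAC over
the gradient set.

# The pipeline

1. **Seeding.** The image is band-pass filtered with a difference of
   Gaussians, `G(sigma) - G(k*sigma)` with `k = 1.6` (the classic
   Laplacian-of-Gaussian approximation), and strict local maxima above an
   intensity threshold become integer-pixel seeds. `sigma` must match the
   spot scale and `threshold` the spot intensity; everything else has
   workable defaults.
2. **Gradients.** Around each seed a patch of side `2r + 1` is read
   (default `r = 3`, a 7×7×7 patch). Finite-difference gradients live on
   the dual grid of inter-pixel cell centers — one per 2×2(×2) cell, i.e.
   `(2r)^n` gradients, 216 for the 3D default. An optional affine
   background (fitted to the patch boundary only) removes smooth
   fluorescence gradients.
3. **Localization.** The center minimizes
   `sum_k w_k d_k^2`, where `d_k` is the distance from the center to the
   line through gradient position `p_k` along direction `g_k`, solved in
   closed form from the normal equations
   `[sum w_k (I - u_k u_k^T)] p = sum w_k (I - u_k u_k^T) p_k`.
   Weights default to the squared gradient magnitude, which suppresses
   noise-dominated flat cells.
4. **RANSAC.** Two random gradients propose a center; gradients whose
   lines pass within `epsilon` (default 0.5 px) are its consensus. The
   best consensus (largest, ties by smaller mean residual) is refit on all
   of its inliers, inliers are re-selected once against the refit center,
   and a final refit gives the reported center. A spot needs at least
   `min_inliers` (default 30) supporters; pure-noise candidates die here.
   In multi-consensus mode the accepted inliers are removed and RANSAC
   repeats, which splits pairs of spots so close that the seeding stage
   merged them.
5. **Postprocessing.** Detections closer than `min_separation`
   (default 0.5 px) are reduced to the strongest (most inliers, then
   brightest); intensity is measured by n-linear interpolation at the
   sub-pixel center or by refitting a fixed-shape Gaussian's amplitude and
   offset over the inlier pixels; a binary mask can partition detections.

# Anisotropy

A 3D PSF is typically 2–4× longer axially than laterally. Instead of
resampling the image, the fit applies a scale vector `s = (1, 1, a)` to
gradient positions and `s^-1` to gradient vectors, solves in the rescaled
(isotropic) space, and maps the center back. The convention is that `a`
**compresses** the axial coordinate: `sigma_axial = sigma_lateral / a`, so
a PSF twice as long axially means `a = 0.5`. The same factor rescales the
axial DoG sigma at the seeding stage so elongated blobs are seeded at the
right scale.

`estimate_anisotropy()` recovers `a` from the data: it fits a free-sigma
axis-aligned elliptical Gaussian to patches around the brightest seeds
(Levenberg–Marquardt, up to 100 spots) and reports the median of
`mean(sigma_x, sigma_y) / sigma_z`. On simulated scenes the estimate is
within a few percent of truth, and it is invariant to global intensity
scaling because only shape parameters enter the ratio.

When the PSF is elongated, the support radius should follow the detector's
coverage rule — the patch should span about twice the PSF's central peak.
For `sigma_z = 3` px that means `support_radius = 6`; with the default
radius 3 the patch truncates the axial tails and axial accuracy degrades
measurably.

# Borders

All filters and patches use mirror extension at the image border, and seed
maxima are evaluated against the mirror-extended neighborhood, so spots
near (or on) an edge keep their seed instead of silently disappearing.
Two further rules keep border localization honest:

* gradients whose dual-grid cell touches mirror-padded pixels are flagged
  `fabricated` and excluded from fits — mirrored pixels duplicate interior
  data and otherwise bias the center toward the border;
* a fitted center that lands inside the mirror padding is the ghost image
  of the real spot and is reflected back across the border plane.

Border spots remain the least accurate detections (one-sided data); users
benchmarking localization may wish to exclude detections within a couple
of sigma of the volume faces.

# Block-wise execution and determinism

Large chunked volumes are processed per block. Interiors are half-open
intervals tiling the image exactly once; a block owns the seeds whose
integer position falls in its interior. Each block reads its interior plus
a margin (the DoG kernel half-width of the wider Gaussian, plus one pixel
for maxima detection), which makes its DoG values exact on the pixels it
can own; patches and intensities are read from the full, lazily loaded
image. Every RANSAC stream is seeded from the global seed and the seed's
global position, so the output is identical — table for table — for every
block layout, single block included. This is deliberately stronger than
per-block seeding, which would make results depend on the decomposition.

The chunked store is a minimal self-contained directory format (a JSON
attributes file plus raw little-endian float64 chunk files) with lazy
region reads; TIFF input/output covers conventional integer camera data.

# The simulator

`simulate_scene()` renders the benchmark conditions: spot positions
uniform over a 256×256×32 volume, peak brightnesses normal
(default mean 1000, sd 100 photons, floored at 1), a Gaussian PSF with
lateral/axial sigmas (default 1.5 px), expected counts
`I_pred = baseline + sum_spots brightness * exp(-sum_d (x_d - c_d)^2 / (2 sigma_d^2))`
on a constant baseline (default 100 photons), Poisson shot noise with mean
`I_pred`, and additive Gaussian read noise (`noise_sd`). A pair mode
places spot pairs at exact separations in random directions to probe
close-spot resolution. Scenes are bit-reproducible from their parameters
and seed.

What the simulator does *not* emulate: realistic PSF side lobes
(Airy/Gibson–Lanni), camera gain and offset maps, structured or
cell-shaped background, spot clusters, and chromatic effects. Passing
tests on these scenes therefore demonstrate correctness of the estimator
under the stated model, not performance on arbitrary real data.

# Benchmarking

`match_detections()` pairs detections with ground truth greedily by
ascending distance (one-to-one, within `max_distance = 3` px by default)
and reports F1 = 2TP/(2TP+FP+FN), the mean Euclidean error over matches,
and the mean *signed* per-axis offset. The signed offset is the standard
probe for pixel-origin convention mismatches between tools;
`correct_offset()` removes it. `grid_search()` runs the detector over a
parameter grid on simulated scenes and returns per-point aggregates and
the F1-argmax (ties to lower error), the same procedure used to give each
tool its best parameters in cross-tool comparisons.

# Numerical choices and degenerate inputs

* Gradient kernels are the unnormalized difference `(+1, -1)` with
  `(1/2, 1/2)` averaging; any global positive scaling of gradients cancels
  in the fit.
* Gradients with magnitude below 1e-12 are dropped before normalization;
  a normal matrix whose smallest eigenvalue is below 1e-10 of the largest
  is reported as a degenerate (all-parallel) fit.
* RANSAC uses the adaptive standard iteration bound
  `N = log(1 - confidence) / log(1 - w^2)` with `w` the current best
  inlier fraction (confidence 0.99), capped at `max_iterations = 1000`,
  on a Mersenne–Twister stream whose seed derives from the global seed
  and the candidate's position.
* DoG plateau ties are not maxima; the redundancy filter (greedy, by
  inlier count, then intensity, then lexicographic position) catches
  residual duplicates.
* Mask lookups round half away from zero, consistent with pixel-center
  coordinates.
* `auto_threshold()` offers a robust (MAD-based) noise floor for the DoG
  threshold, useful when sweeping noise levels with otherwise fixed
  parameters.

# Study sizes used by the tests

The test-suite experiments run at the benchmark geometry (256×256×32,
30 spots; 100-spot scenes for anisotropy estimation; 48×48×20 scenes for
close pairs) with three to five seeded replicates per condition, and
smaller 96×96×24 scenes for unit fixtures. One property worth knowing
when reproducing the axial-accuracy comparison: the axial error of
2×-stretched spots (corrected with `a = 0.5`, radius 6) fluctuates
substantially between scenes — roughly 1.4–3.5× the isotropic axial error
per scene, with a long-run mean near 2.2× — because a handful of
near-border spots dominate the scene mean. The paired three-scene
comparison in the acceptance suite sits just below 2×.

# Known limitations

* Very dense fields and spot clouds: multi-consensus helps at moderate
  separations (about two lateral sigmas), but gradients of very close
  spots bias one another, and a small spurious midpoint consensus can
  appear between two strong spots.
* High noise: with `epsilon = 0.5` and `min_inliers = 30`, detection
  collapses once the read-noise sd approaches a quarter of the spot peak
  brightness.
* The anisotropy factor is global; depth-dependent PSF changes are not
  modeled.
* 2D images are fully supported, but the anisotropy machinery is inert
  there; spatiotemporal (4D) localization is out of scope.
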