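# radialspots

Sub-pixel detection of diffraction-limited fluorescent spots in 2D and 3D
microscopy images — the core measurement behind single-molecule FISH,
spatial transcriptomics and spatial genomics, where every mRNA or barcode
appears as a PSF-shaped blob a few pixels across and biology is read off
the list of spot positions and intensities.

## Method

A radially symmetric spot has the property that the image gradients around
it point at its center. `radialspots` turns that into an estimator:

1. **Seeding.** Candidate locations are strict local maxima of a
   difference-of-Gaussians filtered image, `G(σ) − G(kσ)` with `k = 1.6`,
   thresholded on intensity.
2. **Gradient field.** Around each seed, finite-difference gradients are
   computed on the dual (inter-pixel) grid of a `(2r+1)^n` patch —
   `(2r)^n` gradients, 216 for the default radius 3 in 3D.
3. **Radial-symmetry fit.** The center `p_c` minimizes the weighted sum of
   squared point-to-line distances `Σ_k w_k d_k²` to the gradient lines,
   solved in closed form:
   `[Σ w_k (I − û_k û_kᵀ)] p_c = Σ w_k (I − û_k û_kᵀ) p_k`.
4. **RANSAC.** Repeated two-gradient samples find the largest consensus of
   gradients within distance `ε` (default 0.5 px) of a common center; the
   center is refit on the inliers. Spots need ≥ `min_inliers` (default 30)
   supporters. Multi-consensus mode extracts several spots from one seed,
   resolving pairs the seeding stage merged.
5. **Anisotropy.** Axially elongated 3D PSFs are handled without image
   resampling by scaling gradient positions with `s = (1, 1, a)` and
   gradient vectors with `s⁻¹` (with `σ_axial = σ_lateral / a`); the
   factor `a` can be estimated from the image itself.
6. **Postprocessing.** Redundancy filtering at 0.5 px, intensity by
   n-linear interpolation or Gaussian refit, optional binary-mask
   classification, CSV output (`x,y,z,t,c,intensity`).

Large chunked volumes run block-wise with lazy reads and
position-derived RANSAC seeds, so detection tables are identical for
every block layout. A ground-truth simulator (Gaussian PSF, Poisson shot
noise, additive read noise) and a benchmark module (greedy one-to-one
matching, F1, per-axis signed offsets, Euclidean error, parameter grid
search) complete the toolkit.

## Worked example

```r
library(radialspots)

params <- simulation_params(n_spots = 30, noise_sd = 10, rng_seed = 7)
scene  <- simulate_scene(params)           # 256 x 256 x 32, ~1000-photon spots
config <- run_config(sigma = 1.5, threshold = 20, seed = 42)
spots  <- detect_spots(scene$image, config)
nrow(spots)
#> [1] 29
head(spots[order(spots$x), c("x", "y", "z", "intensity", "n_inliers")], 3)
#>            x         y         z intensity n_inliers
#> 25  2.216669 208.13769 13.574799 1067.4759       156
#> 20 16.743943  98.67599  2.445761  989.8312       162
#> 15 17.792763  47.22192 21.517401 1004.4674       165

match_detections(scene$truth, spots)
#> <benchmark_result> tp=29 fp=0 fn=1 F1=0.9831
#>   mean Euclidean error 0.0269 px; per-axis offset [-0.0040, -0.0034, 0.0042]
```

29 of 30 spots are recovered with a mean localization error of 0.027 px
and per-axis offsets consistent with zero (no coordinate-convention
shift). The missing spot is one of a pair only 3.7 px apart that the
seeding stage merged; multi-consensus RANSAC separates it:

```r
spots2 <- detect_spots(scene$image, run_config(sigma = 1.5, threshold = 20,
                                               ransac = "multi", seed = 42))
match_detections(scene$truth, spots2)
#> <benchmark_result> tp=30 fp=0 fn=0 F1=1.0000
#>   mean Euclidean error 0.1094 px; per-axis offset [0.0677, -0.0198, -0.0355]

estimate_anisotropy(scene$image, dog_params(sigma = 1.5, threshold = 20))
#> [1] 0.9980754
```

The anisotropy estimate of ~1.0 correctly reports an isotropic PSF; on
scenes rendered with `σ_z = 2 σ_xy` it returns ~0.5, the factor to pass as
`anisotropy` for unbiased axial localization.

A command-line interface is installed as `exec/radialspots` inside the
package directory, with subcommands `detect`, `simulate`, `benchmark`,
`sweep` and `estimate-anisotropy`:

```sh
RS=$(Rscript -e 'cat(file.path(find.package("radialspots"), "exec", "radialspots"))')
Rscript "$RS" simulate --shape 256,256,32 --n-spots 30 --seed 7 \
        --out scene.tif --truth truth.csv
Rscript "$RS" detect --input scene.tif --output spots.csv --threshold 20
Rscript "$RS" benchmark --truth truth.csv --detections spots.csv
```

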