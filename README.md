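# srhmap — spectral unmixing and selective sampling for stimulated Raman histology

`srhmap` is an R toolkit for **high-content stimulated Raman histology
(HC-SRH)**: turning a hyperspectral stimulated Raman scattering (SRS) image
cube of a tissue section into label-free chemical concentration maps of five
major tissue components — unsaturated lipids, cellular protein,
extracellular matrix (ECM), saturated lipids, and water — and rendering them
as a pseudo-color histology image. It is aimed at microscopists and image
analysts working with spectroscopic SRS data in the crowded C-H stretch
window (≈2800–3100 cm⁻¹), where component bands overlap too much for simple
band-ratio imaging.

## The method in brief

A pixel spectrum *y* (M channels) follows the linear mixing model
*y ≈ Aᵀc*, where rows of *A* are the K unit-norm reference spectra and
*c ≥ 0* the per-pixel concentrations. Every pixel is unmixed independently by
the **non-negative LASSO**

> min₍c ≥ 0₎ ‖y − Aᵀc‖₂² + λ‖c‖₁,  λ = 0.01 by default,

solved by deterministic cyclic coordinate descent in compiled code. Around
this core the package provides:

* **`generate_phantom()`** — a synthetic tissue phantom (Gaussian band-model
  spectra, duct/necrosis/adipocyte/fiber morphology, Gaussian noise) with
  exact ground truth, used to validate every stage;
* **`stv_denoise()`** — anisotropic total-variation denoising over the two
  spatial axes and the spectral axis (monotone accelerated dual scheme);
* **`rfe_select()`** + **`sample_balanced_pixels()`** — selective spectral
  sampling: recursive feature elimination over channels, driven by the
  abundance MSE on a component-balanced sample of 2100 pixels (5 × 420),
  so a 45-channel sweep can shrink to 5 channels for a 9× acquisition
  speed-up (`acquisition_speedup(45, 5)`);
* **`ssim()` / `psnr()` / `quality_report()`** — image-quality scoring of
  channel-reduced maps against the full-spectrum result;
* **`stitch_grid()`** — tile-grid fusion with phase-correlation refinement
  and feather blending;
* **`render_merged()`** — additive pseudo-color rendering (yellow
  unsaturated lipid, red protein, blue ECM, cyan saturated lipid, grey
  water) plus percentile contrast stretch;
* TIFF + JSON sidecar cube I/O, CSV spectra libraries, JSON manifests
  (`read_cube()`, `read_library()`, `write_maps()`, ...), and a thin CLI
  (`exec/srh`) with `simulate`, `denoise`, `unmix`, `select-channels`,
  `evaluate`, `render` and `stitch` subcommands.

## Worked example

Generate the default noisy phantom (64 × 64 px, 45 channels over
2820–3030 cm⁻¹, 2% noise), unmix it, score the maps against ground truth,
then select 5 channels by RFE and score the reduced result against the
full-spectrum maps:

```r
library(srhmap)

ph <- generate_phantom(phantom_spec(seed = 17))
maps <- unmix_cube(ph$cube, ph$library, unmix_params(lam = 0.01))
quality_report(maps, ph$truth)
#> <quality_report>
#>               name      ssim  psnr_db data_range
#>  unsaturated_lipid 0.8441537 39.50365        2.0
#>   cellular_protein 0.7474293 28.94118        1.0
#>                ecm 0.7778649 34.91864        2.0
#>    saturated_lipid 0.8115706 35.07159        1.0
#>              water 0.5632418 30.40188        0.6
#> mean SSIM 0.7489, mean PSNR 33.77 dB

smp <- sample_balanced_pixels(ph$cube, maps, sampler_params(seed = 17))
sub <- rfe_select(smp, ph$library, unmix_params(), target_k = 5)
sub
#> <channel_subset> 5 channels: 2853.4, 2915.5, 2920.2, 2963.2, 3030 cm^-1 (40 eliminated)

evaluate_subset(ph$cube, ph$library, unmix_params(), sub, maps)
#> <quality_report>
#>               name      ssim  psnr_db data_range
#>  unsaturated_lipid 0.8166320 31.89976  1.9990942
#>   cellular_protein 0.6802038 25.11934  1.0260312
#>                ecm 0.8680003 30.17539  2.0308528
#>    saturated_lipid 0.7663903 25.96267  1.0270119
#>              water 0.4663672 23.95762  0.6650192
#> mean SSIM 0.7195, mean PSNR 27.42 dB

acquisition_speedup(45, 5)
#> [1] 9
```

Reading the numbers: against ground truth the full-spectrum unmixing reaches
mean SSIM ≈ 0.75 at 2% noise (water is lowest — its broad featureless band
makes it the hardest component). Restricting to the 5 RFE-selected shifts
costs only ≈ 0.03 mean SSIM relative to the 45-channel result while the
acquisition cost model reports a 9× speed factor. `render_merged(maps)`
returns the pseudo-color histology image; `write_maps(maps, "maps/")` saves
per-component TIFFs with a manifest recording λ, the normalization tag and
the channel subset.

The same pipeline from the shell:

```sh
srh simulate --out cube.tif --height 64 --width 64 --noise-sd 0.02 --seed 17
srh denoise  --cube cube.tif --out cube_dn.tif
srh unmix    --cube cube_dn.tif --library cube_library.csv --out maps/
srh select-channels --cube cube.tif --library cube_library.csv --maps maps/ \
    --out subset.json --target-k 5 --n-pixels 2100 --n-subsets 5 --seed 17
srh render   --maps maps/ --out merged.png
```

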