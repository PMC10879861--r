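---
title: "High-content stimulated Raman histology: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{High-content stimulated Raman histology: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srhmap)
```

## The problem

Stimulated Raman scattering (SRS) microscopy images a tissue section at one
Raman shift (wavenumber, cm^-1) at a time; sweeping the shift yields a
hyperspectral cube: two spatial axes and one spectral axis. In the C-H
stretch window (~2800-3100 cm^-1) the SRS signal is strong but the bands of
the major tissue constituents — saturated and unsaturated lipids, cellular
protein, extracellular matrix (ECM) and water — overlap heavily. High-content
stimulated Raman histology (HC-SRH) turns such a cube into one concentration
map per constituent by linear spectral unmixing, then renders the maps as a
pseudo-color histology image. `srhmap` implements that computational pipeline
end to end: tile fusion, spectral total-variation denoising, sparsity-penalized
unmixing, recursive-feature-elimination (RFE) channel selection for fast
acquisition, SSIM/PSNR quality scoring, and rendering — validated against a
synthetic tissue phantom with known ground truth.

## The mixing model and the unmixing objective

SRS signal is linear in analyte concentration, so a pixel spectrum
$y \in \mathbb{R}^M$ is modelled as $y \approx A^\top c$, where the rows of
$A \in \mathbb{R}^{K \times M}$ are the $K$ reference (endmember) spectra and
$c \ge 0$ collects the per-pixel concentrations. Each pixel is unmixed
independently by the non-negative LASSO:

$$\hat c \;=\; \arg\min_{c \ge 0} \;\; \lVert y - A^\top c\rVert_2^2 \;+\; \lambda \lVert c \rVert_1 .$$

Conventions that matter, because LASSO scalings differ between libraries:

* the residual term carries **no** $1/2$ or $1/(2M)$ factor, so the
  coordinate-wise soft threshold sits at $\lambda/2$;
* reference spectra are scaled to **unit Euclidean norm** when a
  `ref_library()` is built (recorded in its `normalization` tag). The pixel
  spectrum $y$ is *not* normalized. How the reference spectra were scaled is
  genuinely open in this problem; fixing unit norm makes a single
  $\lambda$ transferable across libraries, and the choice is recorded in
  every output manifest;
* $\lambda = 0.01$ is the working default, fine-tunable to trade channel
  crosstalk against bias;
* non-negativity is enforced by default because the outputs are
  concentrations; `nonneg = FALSE` gives the unconstrained LASSO for
  methodological comparisons (negative values are clipped only when maps are
  assembled).

The solver is cyclic coordinate descent started from $c = 0$, which for this
convex problem makes the result deterministic. It uses precomputed Gram
quantities ($G = AA^\top$, $b = Ay$), so a sweep costs $O(K^2)$ per pixel
independent of the channel count, and it is implemented in compiled code
because channel selection re-solves it roughly a thousand times per
elimination pass. Convergence is declared when the largest coordinate change
in a sweep falls below `tol` (default 1e-10) relative to the largest
coefficient. On ill-conditioned designs (nearly collinear references)
coordinate descent converges linearly with a constant that degrades with the
squared condition number; the default sweep cap (20000) covers condition
numbers far beyond the default library's (~22).

A practical wrinkle reproduced here: pure cellular protein cannot be measured
directly, so `derive_protein_reference()` builds it by subtracting a scaled
unsaturated-lipid spectrum from a cell spectrum. The scale $\alpha$ is fitted
only on channels within ±10 cm^-1 of the ~3009 cm^-1 =C-H band, which is
specific to unsaturated lipid; anchoring on a lipid-only marker keeps protein
signal from leaking into $\alpha$. The exact scaling rule used in practice
varies between labs; ours is a declared choice, clipped at zero and
renormalized.

## The synthetic phantom: what it emulates, and what it does not

Real tissue cubes are large, proprietary and ground-truth-free, so the test
bed is `generate_phantom()`. It emulates:

* **Spectra** — each component is a sum of Gaussian bands placed near the
  canonical C-H features (~2850 CH2 symmetric, ~2880 CH2 asymmetric,
  ~2930 CH3, the ~3009 =C-H band of unsaturated lipid, a broad water O-H
  shoulder rising past 3050 cm^-1). ECM is the protein model blue-shifted by
  a uniform 8 cm^-1, mirroring the collagen blue shift that separates the two
  in tissue. Bands are *modelled*, not digitized from any published figure.
  The default library is genuinely hard but solvable: pairwise cosine
  similarities 0.21-0.98 (protein/ECM the worst pair), condition number ~22.
* **Morphology** — the default 64 x 64 scene contains a duct (protein
  annulus) with a necrotic core (saturated-lipid disk), two adipocyte rings
  (unsaturated lipid), ECM fibers, and a water background over the whole
  field of view (water coexists with everything, so truth maps deliberately
  do not sum to 1). Every component dominates at least 420 pixels, which is
  what the balanced sampler needs at its defaults.
* **Noise** — additive white Gaussian per channel at `noise_sd` (default
  0.02) times the peak noise-free signal; after lock-in detection SRS noise
  is approximately Gaussian. A Poisson option was considered and deferred.

It does **not** emulate optical point-spread blur, stage drift, etalon
fringes, laser power drift across tiles, or fingerprint-window spectra.
Passing tests therefore certify the *algorithms* under the linear mixing
model with Gaussian noise — not performance on any particular instrument's
tissue data.

With `noise_sd = 0` the generated cube satisfies the mixing model to machine
precision, so ordinary least squares must recover the truth exactly; that
self-consistency check anchors the whole validation chain.

## Spectral total-variation denoising

Before unmixing, the cube can be denoised by solving the anisotropic
Rudin-Osher-Fatemi problem

$$\min_u \; \tfrac12 \lVert u - y \rVert_2^2 + \lambda_{tv}\, \mathrm{TV}(u),$$

where TV sums absolute forward differences with equal weights over the
selected axes (both spatial axes plus the spectral axis by default; Neumann
boundaries). Whether the original spectral-TV formulation coupled the spatial
axes is not documented, so the coupling is exposed as
`axes = "all" | "spatial" | "spectral"` rather than guessed.

The dual problem is solved by a monotone accelerated projected-gradient
scheme (MFISTA-style): a projected-gradient step from the extrapolated dual
point is *accepted only if it lowers the primal objective*; on rejection the
momentum is restarted at the incumbent. This guarantees a non-increasing
objective trace (recorded in the output provenance) while keeping the
accelerated rate in practice. Stagnation is detected on the raw iterate, not
the incumbent, so a paused incumbent cannot trigger a premature stop. The
step size is $1/(4 n_{axes})$, the standard Lipschitz bound for the TV dual
gradient. Defaults: `weight = 0.05` (interpreted relative to the cube
maximum, so the effective $\lambda_{tv}$ is `weight * max(cube)`),
`max_iters = 200`, `tol = 1e-4`; `weight = 0` short-circuits to the identity.
Output is clipped at zero; the dual form preserves the mean exactly before
that clip.

## Selective spectral sampling (RFE)

Acquisition time scales with the number of spectral channels
(`acquisition_cost()` = channels x pixels x dwell), so reducing 45 channels
to 5 accelerates imaging 9-fold. Channels are chosen by backward recursive
feature elimination driven by unmixing fidelity:

1. **Balanced sampling.** RFE is run on a small pixel subset: 2100 pixels in
   5 component-balanced groups of 420 by default, each group drawn uniformly
   without replacement from the pixels whose dominant (argmax-abundance)
   component is that group's. Balancing stops abundant components (water
   background) from monopolizing the criterion.
2. **Greedy elimination.** While more than `target_k` channels survive, each
   surviving channel is tentatively removed, the sample is re-unmixed on the
   remaining channels, and the MSE between those abundances and the
   full-spectrum abundances is computed — an unweighted mean over pixels and
   components, which is adequate precisely because the sample is balanced.
   The channel whose removal hurts least is discarded; ties break toward the
   lowest wavenumber for determinism. The per-step MSE trace is kept.
3. **Scale preservation.** After restriction the library spectra are sliced,
   *not* renormalized, so reduced-channel abundances stay on the
   full-spectrum concentration scale — otherwise comparing reduced maps to
   full-spectrum maps by SSIM/PSNR would be meaningless.

The MSE is computed on abundance vectors rather than reconstructed spectra or
rendered images: the criterion of record is the unmixing result itself.
Different sampled subsets can select slightly different channel sets of
similar quality — the spectra are broad, so several near-optimal subsets
exist. The tests therefore assert the *performance* of the selected subset,
never the identity of specific shifts, except on a planted instance where
three channels provably carry all inter-component contrast and both greedy
RFE and exhaustive search over all 56 subsets must find exactly those.

## Quality metrics

`ssim()` is the mean local structural similarity over a sliding 7 x 7 uniform
window (valid region only), stabilizers $C_1 = (0.01R)^2$,
$C_2 = (0.03R)^2$, unbiased variances. `psnr()` is
$10 \log_{10}(R^2/\mathrm{MSE})$, with identical inputs reported as `Inf`.
For component-wise scoring (`quality_report()`), the data range $R$ of each
component is the maximum of the *reference* (full-spectrum) map, so PSNR
stays comparable across channel subsets; aggregation over components is an
unweighted mean, recorded in the report. Whether published SSIM/PSNR figures
for channel-reduced histology were computed on concentration maps or rendered
images is generally unstated; maps are used here, consistent with the RFE
criterion.

## Rendering and stitching

`render_merged()` normalizes each map to its own maximum, multiplies by its
RGB color (yellow unsaturated lipid, red cellular protein, blue ECM, cyan
saturated lipid, grey water), sums and clips to [0,1]. Additive blending is a
declared choice: overlaps mix (red + blue = magenta), single-component pixels
are invertible, and the image is per-component scale-invariant. Water is
drawn at weight 0.5 by default so the grey background does not wash out
structure; `enhance_contrast()` provides the percentile stretch (default
1-99%) used to bring up low-contrast channels. Renders are qualitative
surfaces only.

`stitch_grid()` fuses a rectangular grid of overlapping tiles: nominal
placement on the grid, optional per-tile translation estimated by phase
correlation on the mean-over-channels image (searched within ±25% of the
nominal overlap — galvo/stage tiling has negligible rotation, so
translation-only, integer-pixel registration suffices at this scale), and
linear feather weights across overlaps. Because fusion divides by the
accumulated weight, regions where tiles agree are reconstructed exactly;
global position optimization and flat-fielding are out of scope.

## Numerical and design choices, in one place

* LASSO: objective exactly as written above; soft threshold $\lambda/2$;
  coordinate descent from zero in fixed cyclic order (deterministic);
  Gram-based updates; defaults `lam = 0.01`, `tol = 1e-10`,
  `max_iters = 20000`.
* Channel indices are 1-based inside R; user-facing output always prints
  cm^-1 values, never indices.
* TV: anisotropic, equal axis weights, Neumann boundaries, monotone
  accelerated dual ascent, objective trace exposed; non-convergence returns
  the best iterate with a provenance flag rather than an error.
* RFE ties break toward the lowest wavenumber; the "representative field of
  view" is the whole cube unless a rectangular ROI is given.
* Persistence: multi-page 32-bit TIFF plus JSON sidecar (not OME-TIFF, to
  stay desk-simple); samples are stored divided by a recorded
  `intensity_scale`, making round trips lossless to ~1e-9 relative — beyond
  32-bit float precision. Manifests record $\lambda$, the normalization tag
  and the channel subset, so any map is reproducible from its inputs.
* Degenerate inputs: a constant plane percentile-stretches to all zeros; an
  all-zero residual in protein derivation is an error (degenerate input); a
  component with too few dominant pixels fails the sampler with the
  component's name.

## Validation problem sizes

The shipped tests and the acceptance script run, by choice, at desk scale:
64 x 64 x 45 phantoms for unmixing and channel selection (the full
2100-pixel sampler budget is kept), 40-48 px phantoms for the denoising
property sweeps, 80 x 80 phantoms cut 2 x 2 for stitching, and 8-10 channel
problems for the exact oracles (exhaustive support enumeration is exponential
in K). The degradation ladder mirrors the 45/20/10/5 channel progression over
ten phantom seeds in the test suite and three seeds in the acceptance script.

## Known limitations

* The phantom's Gaussian band models and Gaussian noise are idealizations;
  real SRS cubes carry non-Raman background, spectral distortions and
  tile-dependent illumination that this package does not model.
* Endmember spectra are assumed *given*; there is no endmember extraction,
  and no spatial regularization in the unmixing.
* Registration is integer-pixel and translation-only; stitching does not
  globally optimize tile positions.
* SSIM here is single-scale; no perceptual metrics.
* Absolute calibration of SRS intensity to molar concentration is out of
  scope: "concentration" maps are in arbitrary, internally consistent units.
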