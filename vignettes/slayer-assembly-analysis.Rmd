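---
title: "Quantifying S-layer self-assembly: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying S-layer self-assembly: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slakit)
```

## The scientific problem

Many bacteria coat themselves with a crystalline surface layer (S-layer)
built from a single protein — in *Caulobacter crescentus*, the 98 kDa
protein RsaA, which assembles into a hexameric lattice with a 22 nm repeat
on top of the lipopolysaccharide (LPS) outer membrane. The question this
package's pipeline addresses is *how* such a macromolecular crystal is built
and maintained on a growing, curved cell surface without dedicated
enzymatic machinery: newly secreted monomers diffuse across the outer
membrane until they are captured at the edges of existing 2D crystals, and
cell-surface regions of high Gaussian curvature (poles, division plane)
concentrate lattice defects where new material is preferentially
incorporated.

Testing that picture quantitatively requires five analyses, each of which
is one module here:

1. **Axial binary profiles** of two-color super-resolution cell images —
   where along the cell is new S-layer added?
2. **Molecule counting in puncta** — how many monomers are in a nucleated
   crystal patch?
3. **Bound/unbound classification of single-molecule tracks** against
   immobile nucleation seeds — do molecules stop diffusing only where
   crystals already are?
4. **Diffusion estimation** from pooled 3D mean squared displacements —
   how fast do anchored monomers explore the surface?
5. **Gaussian curvature of surface meshes** — does curvature concentrate
   where assembly is observed?

Because the underlying imaging data are not publicly deposited, the package
carries a first-class synthetic-data module that generates images, tracks
and meshes with known ground truth, and every analysis stage is validated
against that truth.

## Models and their assumptions

### Diffusion with motion blur and localization error

A molecule diffusing with coefficient $D$ and localized with per-axis
errors $s_1, s_2, s_3$ under a camera exposure $\tau_E$ has the 3D mean
squared displacement

$$\mathrm{MSD}_{3D}(\tau) \;=\; 6D\left(\tau - \frac{\tau_E}{3}\right)
  \;+\; 2\,(s_1^2 + s_2^2 + s_3^2).$$

The $\tau_E/3$ term corrects for motion blur (the camera reports the
average position over the exposure, which shrinks apparent displacements)
and the constant offset for localization error. `fit_diffusion()` fixes
$\tau_E$ and the calibrated $s_i$ and profiles out $D$, which makes the fit
a weighted linear regression with a closed-form solution; the model is
fitted to the first 4 lags, where the linear approximation is most
informative and trajectory-to-trajectory variance smallest. A
`fit_offset = TRUE` escape hatch estimates the offset jointly for users
without an error calibration.

Key assumptions: free (non-anomalous) diffusion over the fitted lags,
uncorrelated Gaussian localization errors, and full-frame exposure
($\tau_E$ equal to the frame interval by default: 50 ms at 20 frames/s).

### Bound/unbound classification

Over a sliding window of 20 frames (1 s), the root mean squared deviation
(RMSD) of a trajectory from the window's mean position is small for an
immobile molecule — of the order of the localization precision — and much
larger for a diffusing one. The classifier is a single threshold on that
statistic; the study's calibrated value, 2σ above the mean of the
localization-precision-limited RMSD mode, is 57.3 nm, and a frame is
*bound* iff RMSD < 57.3 nm (strictly: a value at the threshold is
unbound). Proximity to a nucleation seed uses the same strict convention,
d~NS~ < 300 nm. Both constants are exposed by `binding_defaults()`, and
`calibrate_threshold()` re-derives the threshold from pooled RMSD values
for new data sets.

### Axial binary profiles

Each cell image is registered (integer-pixel cross-correlation of each
fluorescence channel against the transmitted-light gradient), rotated
horizontal (Radon scan), its axis fitted (2nd-order polynomial through
per-column transmitted-light maxima; smoothing spline above 6 µm for
filamentous cells), and a 200 nm outline band constructed around the cell
boundary. Fluorescence is smoothed (σ = 0.9 px), thresholded, intersected
with the band, and every positive pixel projected onto the axis into 40
equi-length bins, separately for the upper and lower cell half. A bin is
positive if it receives at least one pixel. Across cells, each bin yields a
binomial observation ($n = 2\times$ cells) whose uncertainty is reported as
a 95% Wilson score interval — chosen for its correct small-sample coverage
at fractions near 0 and 1, exactly where these profiles live.

### Molecule counting

Crystal puncta are detected as local maxima more than 10 robust SDs
(median/MAD) above background, fitted by non-linear least squares to an
axis-aligned elliptical Gaussian, and integrated analytically
($2\pi A \sigma_x \sigma_y$, offset excluded). Photons convert to molecule
counts via

$$\text{molecules} = \frac{\text{photons}}{\mu}\times
  \frac{\text{bleach correction}}{\text{labeling efficiency}},$$

where $\mu$ is the median integrated photon count of isolated single
molecules (median rather than mean: robust to rare unresolved doubles; the
mean is available via an argument), the bleaching correction is the ratio
of molecules detected in paired confocal vs STED fields, and the labeling
efficiency is the measured in vitro dye stoichiometry (0.5–0.9 in
practice).

### Discrete Gaussian curvature

Per-vertex curvature uses the angle-deficit estimator
$K_v = (2\pi - \sum_i \theta_i)/A_v$ with barycentric vertex areas by
default. Its virtue is an *exact* discrete Gauss–Bonnet identity: on any
closed mesh $\sum_v K_v A_v = 2\pi\chi$ ($= 4\pi$ for genus 0) to machine
precision, which the test suite asserts on every mesh it builds — a strong,
free correctness check. The Meyer-style mixed Voronoi area is available via
`area = "mixed"`; it is the better choice when *pointwise* accuracy
matters, because barycentric areas do not converge at the slim-triangle
pole fans of ring meshes, whereas the mixed areas do (the refinement
convergence test uses them).

## The synthetic-data generators

`simulate_tracks()` draws Brownian sub-steps, averages
`n_substeps_per_exposure = 10` positions per exposure to emulate motion
blur (sub-stepping converges to the continuous-exposure limit assumed by
the $\tau_E/3$ correction), adds independent per-axis Gaussian errors, and
optionally binds molecules at seed positions: capture is first-order within
a capture radius (`on_rate = Inf` for deterministic capture on contact),
release is first-order with `off_rate`, and bound molecules are immobile.
Defaults are the tracking conditions of the experiments this package
models: 30 tracks × 500 frames, 20 frames/s, 50 ms exposure,
$s = (93, 93, 91)$ nm, $D = 0.077$ µm²/s.

`simulate_cell_image()` renders a spherocylindrical (optionally crescent)
cell: a transmitted-light channel whose intensity is the projected chord
depth (so its per-column maxima trace the midline), and fluorescence
channels in which labeled molecules on the projected surface shell are
binned to pixels, convolved with a Gaussian PSF, and Poisson-sampled.
Label patterns cover the observed biology: `label_uniform()` (steady-state
S-layer), `label_polar()` (polar-enriched new assembly), `label_cracks()`
(crack-like body features), `label_puncta()` (nucleated patches with known
molecule counts). Photon totals are conserved exactly by the renderer, so
counting pipelines can be validated against construction.

What the generators deliberately do **not** model: EM-gain/read noise
(photon shot noise only), the double-helix PSF (3D positions arrive already
localized), true on-surface diffusion in 3D (2D experiments are simulated
in the projection plane, which is what the downstream 2D analyses consume),
and the real spatial statistics of secretion sites, which the source
experiments could not observe either — the label pattern is a free choice,
not an assertion. Passing tests therefore demonstrate correctness of the
*analysis* under known ground truth, not realism of every camera artifact.

## Numerical choices and edge cases

* **Binarization threshold.** The intensity threshold is Otsu's method on
  smoothed intensities within a dilated outline (parameter-free and
  reproducible), with a fixed-quantile override. No specific rule is
  canonical for this step; population profiles on synthetic data are
  insensitive to the choice at realistic SNR.
* **Orientation score.** The Radon scan scores each angle by projection
  *energy* (sum of squared bin values) rather than raw bin variance: total
  intensity is angle-invariant, so energy is maximal exactly when mass
  concentrates into fewest bins, and unlike the raw variance it is
  monotone under the 1-px binning used here.
* **Outline centering.** Both outline modes center the 200 nm band on the
  physical surface: the thresholded-fluorescence boundary is eroded by
  `boundary_offset_nm` (≈ PSF half-width + layer half-thickness, default
  50 nm) because the fluorescent shell blurs outward, and the
  transmitted-light mode marks the maximum-gradient point along rays cast
  from the axis (with radial fans beyond the axis ends to cover the
  poles). This keeps the two modes consistent on fully labeled cells.
* **RMSD window placement.** The window's value is assigned to its center
  frame, which halves the state-transition lag bias relative to a trailing
  window; trailing placement would only shift classifications near switch
  points.
* **Low-RMSD mode identification.** The calibration fits a Gaussian to the
  histogram (Freedman–Diaconis bins) of values below the first *pronounced*
  KDE anti-mode (density < 0.7 × mode density); when no such valley
  exists, the window is taken symmetric about the mode
  (mode + (mode − 1st percentile)), which spans the full low peak. A
  naive "below the median" fallback was rejected: fitting a 3-parameter
  Gaussian to only the rising half of a peak is ill-conditioned.
* **Ties and conventions.** Pixels exactly on the axis count as the upper
  half; axial bins are half-open `[i/40, (i+1)/40)` with the last bin
  closed; pixel centers sit at 0-based integer coordinates with y
  increasing downward; "upper" means smaller row index. Proximity and
  binding thresholds are both strict `<`.
* **Pooled MSD SEM.** Pooling weights lags by pair count, which equals
  averaging the flat list of squared displacements — the most literal
  reading of "pooling the data". Overlapping pairs are included (standard
  practice), so the reported SEM understates the estimator's true spread
  at lags > 1; accuracy statements therefore rest on ground-truth recovery
  rather than SEM coverage, and the simulation test inflates the SEM by
  the standard overlapping-pair factor $\sqrt{(2\ell^2+1)/(3\ell)}$.
* **Degenerate inputs.** Empty layer masks are legal (cells without label
  exist in de novo assembly experiments) and give all-negative profiles;
  blank images, isotropic objects, short tracks, degenerate backgrounds
  (SD = 0) and sub-minimum calibrations (< 10 molecules, < 500 RMSD
  values) raise errors naming the problem.

## Problem sizes

The test suite and the acceptance script size their simulations as a
scientist would size a pilot: 10 replicates of 30 × 500-frame trajectories
for diffusion recovery, 8-cell populations for profile shapes, 5 fields ×
12 puncta for molecule counting, meshes of a few thousand vertices for
curvature. These sizes hold Monte-Carlo error comfortably below the
tolerances being asserted (e.g. D is recovered within ~1% at these sizes,
against a 15% acceptance band).

## Known limitations

* Cells arrive pre-cropped, one per record, with the stalk side supplied by
  metadata — there is no multi-cell segmentation or automatic
  swarmer/stalked classification (both were manual in the source
  experiments).
* Drift correction is translation-only, matching the scanning conditions it
  emulates.
* The greedy nearest-neighbor track linker is deterministic and adequate
  for the sparse single-molecule regime; it is not a multi-hypothesis
  tracker and will mis-link dense crossing trajectories.
* The "asymmetric Gaussian" punctum model is axis-aligned; a rotation term
  can be added but is unidentifiable at the SNR of small puncta.
* Whether integrated photons should include the fitted offset is not
  canonically defined; the analytic integral excluding the offset is used
  here and stated wherever counts are reported.

## A worked end-to-end run

```{r example, eval = FALSE}
library(slakit)

# diffusion: simulate at the study conditions and recover D
trk <- simulate_tracks(track_sim_config(rng_seed = 1))
curve <- pool_msd(lapply(split_tracks(trk), compute_msd, max_lag = 6))
fit <- fit_diffusion(curve, tau_e = 0.05, s_nm = c(93, 93, 91))
print(fit)

# profiles: a polar-labeled population
profs <- lapply(1:8, function(i) {
  sim <- simulate_cell_image(image_sim_config(
    label_pattern_a = label_polar(600, polar_fraction = 0.9),
    rng_seed = i))
  profile_cell(sim$record, mode = "incomplete_layer")$profiles$a
})
pop <- population_fraction(profs)
plot(pop)

# curvature: poles carry all the Gaussian curvature
mesh <- gaussian_curvature(make_spherocylinder_mesh(3000, 400, 48))
sum(mesh$K * mesh$area) / (4 * pi) # discrete Gauss-Bonnet: exactly 1
head(curvature_profile(mesh))
```
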