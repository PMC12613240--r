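---
title: "Quantitative CEST-MRI processing with cestr: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative CEST-MRI processing with cestr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cestr)
```

# The problem

Chemical exchange saturation transfer (CEST) MRI probes dilute, exchangeable
protons (amide backbone protons, aliphatic protons sensed through relayed
NOEs, semi-solid macromolecular protons) by saturating them off-resonance
and reading out the attenuation of the water signal. The normalized readout
is the Z-spectrum

$$Z(\Delta\omega) = M_\mathrm{sat}(\Delta\omega) / M_0,$$

acquired at a series of frequency offsets around the water resonance. At
3 T in healthy brain the tissue contrasts of interest are small (a few
percent), so quantification hinges on a chain of corrections: per-voxel
normalization against drifting equilibrium images, static-field (B0)
correction, saturation-amplitude (B1) correction, denoising, and relaxation
compensation. `cestr` implements this full chain together with a synthetic
multi-subject brain-slab phantom whose regional ground truth is
parameterized from published healthy-volunteer group reference values, so
that the entire pipeline can be validated end-to-end on a desk-scale
problem.

# Signal models

## Four-pool Lorentzian decomposition

Low-power Z-spectra (nominal B1 of 0.6 and 0.9 uT, 57 offsets within
±250 ppm) are decomposed voxel-wise as

$$Z(\Delta\omega) = z_0 - c - \sum_{i}
  A_i \frac{(\Gamma_i/2)^2}{(\Gamma_i/2)^2 + (\Delta\omega - \delta_i)^2}$$

with pools: direct water saturation (DS, centre fitted within ±0.3 ppm of
0), amide (+3.5 ppm), relayed NOE (−3.5 ppm) and semi-solid MT (−2.5 ppm),
plus a constant plateau $c$ that absorbs the broad background produced by
pulsed presaturation. Amplitudes are bounded to $[0, 1)$; width bounds
(DS [0.3, 5], amide [0.3, 3], rNOE [1, 8], ssMT [10, 100] ppm) are disjoint
between rNOE and ssMT so the two overlapping negative-offset pools cannot
swap roles. The fit is bounded nonlinear least squares (L-BFGS-B with
analytic gradients, compiled objective), started from fixed values
(amplitudes 0.05, widths at the physiologic priors, $z_0 = 1$), converging
on relative cost change below ~1e-8 within 400 iterations. Note that $z_0$
and the plateau enter the model only through their difference; the pair is
deliberately kept (both bounded) because all derived contrasts depend only
on $z_0 - c$ and the pool terms, so the one-dimensional ridge is harmless.

From a fitted model, a labeled spectrum $Z_\mathrm{lab}$ (all pools) and a
reference spectrum $Z_\mathrm{ref}$ (pool of interest removed) are
evaluated at the pool centre, giving

* $\mathrm{MTR_{Rex}} = 1/Z_\mathrm{lab} - 1/Z_\mathrm{ref}$ (relaxation
  compensated),
* $\mathrm{LD} = Z_\mathrm{ref} - Z_\mathrm{lab}$ (plain Lorentzian
  difference),
* $\mathrm{AREX} = \mathrm{MTR_{Rex}} / T_1$ (additionally compensating the
  T1 scaling, in 1/s).

## APTw asymmetry

The conventional high-power (2 uT) series samples 16 offsets around
±3.5 ppm. After normalization by its single leading M0 frame, replicate
offsets are averaged and each side is fitted with a quadratic in offset;
the asymmetry $\mathrm{APTw} = [Z(-3.5) - Z(+3.5)] \times 100\%$ is
evaluated at $\pm 3.5 + \delta\omega_0$ voxel-wise (B0-corrected
evaluation). The fluid-suppressed variant multiplies APTw by
$(0.35 / Z(-3.5))^2$, down-weighting fluid-like voxels whose Z at −3.5 ppm
is high; the reference constant 0.35 is exposed in the configuration. The
source equation for this suppression factor is typographically garbled in
the literature this pipeline follows; the reading adopted here
($0.35^2 / Z_{-3.5}^2$) matches the originally cited method.

## Field mapping

B0 and relative B1 come from a WASABI series (31 offsets within ±2 ppm,
nominal 3.7 uT, 5 ms rectangular pulse — parameters of the original WASABI
publication, all configurable, since the consuming protocol does not print
them). The model

$$Z(\Delta\omega) = \left| c - d \,
 \sin^2\!\big(\tan^{-1}\tfrac{\gamma B_1}{\Delta\omega - \delta\omega_0}\big)
 \sin^2\!\big(\tfrac12 t_p \sqrt{(\gamma B_1)^2 +
 (\Delta\omega-\delta\omega_0)^2}\big) \right|$$

is oscillatory in B1, so each voxel is fitted from a multi-start grid
($\delta\omega_0 \in \{-0.6, \dots, 0.6\}$ ppm step 0.2; relative B1
$\in \{0.5, \dots, 1.5\}$ step 0.25) with the linear pair $(c, d)$ profiled
in closed form, followed by Nelder-Mead refinement; grid ties go to the
smallest water shift. T1 comes from a saturation-recovery series,
$S(t) = A(1 - e^{-t/T_1})$, with $A$ profiled and T1 found by 1-D
minimization on (0.05, 10) s; the recovery delays default to
{0.3, 0.8, 1.5, 2.5, 4.0} s (not printed in the consuming protocol,
configurable).

## Preprocessing

*Normalization.* Two M0 frames (−300 ppm) bracket each low-power series;
M0 at every acquisition index is linearly interpolated between them by
index (frame timing is uniform within a series, so index interpolation is
equivalent to time interpolation), which removes a linear scanner drift
exactly. The APTw series has a single M0 and uses it throughout.

*B0 correction.* Spectra are resampled at `offsets + b0` with
shape-preserving monotone-cubic interpolation on the sorted unequally
spaced grid (avoids ringing at the DS dip). Resampling beyond the measured
range is flagged invalid, never extrapolated; shifts above 1 ppm invalidate
the voxel.

*Denoising.* Masked spectra form a voxels-by-offsets matrix that is
column-centred, truncated to the leading principal components and
reconstructed. The default component count keeps everything above a
Marchenko-Pastur noise edge (noise variance estimated from the lower half
of the eigenvalue spectrum). The Malinowski indicator minimum is available
as an option but is *not* the default: on the phantom its shallow minimum
(k = 3) discards clearly supra-noise components that carry the smooth
B1/B0/regional gradients, and that truncation bias surfaces downstream as a
spurious contrast-vs-B1 correlation after the two-point correction (R² up
to ~0.01 against a target of ≤ 0.0008). The noise-edge default retains
those components (k ≈ 12 on the default phantom) and leaves the corrected
contrasts B1-independent.

*Pipeline order* is normalize → B0-correct → denoise → fit, matching the
narrative order of the protocol this pipeline follows; denoising is applied
to the low-power series only (whether the 16-offset APTw series was ever
denoised is unstated there, and with 16 points there is little for a PCA to
work with).

## Two-point B1 correction

Each MTR_Rex/LD/AREX contrast is computed at both nominal saturation
amplitudes; per voxel the two actual amplitudes are
$\mathrm{relB1} \times (0.6, 0.9)$ uT and the straight line through the two
(B1, contrast) points is evaluated at 0.7 uT. Extrapolation is permitted —
it is required wherever relative B1 < 0.78 (e.g. frontally), exactly as in
the in-vivo setting the pipeline reproduces.

# The synthetic phantom: a stated world

`phantom_config()` fixes the conditions of the emulated study: a
48 × 40 × 8 slab of 1.7 × 1.7 × 3 mm voxels, 10 subjects, Gaussian noise of
0.7% of M0 per frame, 2% linear M0 drift per series, a smooth polynomial B0
field bounded by 0.05 ppm, and a smooth relative-B1 field spanning
0.74–1.05 with its minimum in the frontal lobe (frontal WM mean ≈ 0.74).
An ellipsoidal brain mask holds a WM core and GM shell, partitioned
anterior→posterior into frontal (FL), parietotemporal (ParTem) and
occipital (OC) regions with a posterior-medial calcarine (Ccs) wedge; every
(tissue, region) ROI exceeds 100 voxels, and occipital WM exceeds 1000
voxels per subject so that the pooled cohort supports the 10,000-voxel
B1-correlation check.

Regional ground truth (APTw %, MTR_Rex amide/rNOE/ssMT at 0.7 uT, T1)
comes from published 3-T group reference values per tissue and region;
per-subject truth adds independent Gaussian jitter with the published
between-subject SDs. Pool amplitudes are then *inverted* per voxel so that
the analytic MTR_Rex at the voxel's actual B1 equals the truth scaled
linearly through the origin, $C(B_1) = C(0.7\,\mu T)\, B_1/0.7$. Because
the pool's own Lorentzian equals 1 at its centre, each step of the
fixed-point inversion has the closed form
$A = Z_\mathrm{ref} - 1/(\mathrm{target} + 1/Z_\mathrm{ref})$; sweeps over
the three pools converge to a forward error below 1e-6. The linear-in-B1
construction makes the two-point correction exact by construction, so the
corrected maps should depend on relative B1 only through noise — which is
precisely what the acceptance check verifies.

Invented, configurable lineshape constants (the fit-parameter table of the
emulated protocol lives in a supplement that is not reproduced here): DS
amplitude 0.85, FWHM 1.4 ppm; plateau 0.10 (WM) / 0.07 (GM); pool FWHMs
amide 1.0, rNOE 3.5, ssMT 25 ppm; $z_0 = 1$. The APTw series is modeled as
per-side quadratics anchored at Z(−3.5) = 0.50 (WM) / 0.55 (GM) with slope
0.05/ppm and curvature 0.02/ppm², B1-independent (amide labeling treated as
saturated at 2 uT; the emulated protocol applies no B1 correction to APTw,
and a B1-dependent APTw would make truth recovery ill-posed). The APTw
acquisition order alternates the leading sign between offset pairs so that
the linear M0 drift cancels to first order in the asymmetry; an
always-negative-first order would leave a ~+0.06% bias at 2% drift.

What the phantom does *not* emulate: realistic anatomy or atlases, CSF
partial volume, vascular hyperintensities, motion, Bloch-McConnell
saturation physics (the generator and the fit share the phenomenological
Lorentzian model — so a green recovery validates the processing chain, not
the biophysical adequacy of Lorentzian lineshapes), covariance between
regional jitters, or B1-dependent lineshape changes. Inter-subject
variability is jitter on contrast truths only; fields and geometry repeat
across subjects.

# Statistics

Per (tissue, region, contrast) the ROI mean, SD (n−1) and median are
computed per subject; the group table holds the mean and SD of per-subject
medians. Region pairs within each tissue, and combined GM vs WM, are
compared with two-sided Mann-Whitney U tests — exact by enumeration (with
midranks under ties) up to a pooled n of 20, tie-corrected normal
approximation with continuity correction beyond. Shapiro-Wilk p-values are
reported per group but never switch the test, matching the emulated
analysis, and raw p-values are reported by default (no multiplicity
correction there either; a Holm option exists). Coefficients of variation
(100·SD/mean of subject medians) are computed for the ratio-scaled
contrasts only; APTw is interval-scaled (its zero is an arbitrary baseline
crossing), so a CV request for it is refused rather than silently computed.
Voxels are treated as exchangeable within an ROI (no spatial
autocorrelation model) — the voxel-level tests are therefore permissive,
as in the analysis they mirror.

# Numerical choices and degenerate inputs

* WASABI voxels that do not converge, or T1 estimates pinned at the search
  boundary (e.g. a constant recovery signal, consistent with any
  $t \gg T_1$), are flagged in quality masks, never silently filled.
* Replicate offsets are averaged before fitting; fits are invariant to
  acquisition order.
* A non-positive interpolated M0 removes the voxel from the mask; a
  non-positive $Z_\mathrm{lab}$ or $T_1$ yields NA contrast values.
* Rank-1 input to the denoiser returns unchanged with a warning.
* Seeds: one master seed; per-subject streams are drawn deterministically
  from it (all below 2^31). Identical configuration and seed reproduce
  every series bit-for-bit.

# Known limitations

* The geometric layout of the label volume is schematic; ROI volume ratios
  (hence combined-ROI medians) only approximate an in-vivo atlas. With the
  default layout the combined-GM pooled median sits on the parietotemporal
  value, within the published combined-GM numbers.
* The group-level acceptance quantities are means over 10 jittered
  subjects, so they carry a sampling SD of (published SD)/√10 by
  construction; for the APTw cells the published SDs are large (0.35–0.68%)
  and individual seeds can land 2σ from the nominal value. This is a
  property of the stated world, not of the estimator.
* The two-point correction extrapolates below relative B1 ≈ 0.78; with
  linear truth this is exact, but on real data extrapolation amplifies
  noise frontally.
* The NIfTI layer implements the NIfTI-1 subset this package writes
  (float64, diagonal RAS+ sform); it reads common scalar datatypes but is
  not a general-purpose NIfTI implementation.
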