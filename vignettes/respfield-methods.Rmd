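---
title: "Extracting respiratory field regressors from fMRI phase: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting respiratory field regressors from fMRI phase: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respfield)
```

## The physical model

A gradient-echo EPI volume is a complex image; its phase at echo time $TE$
encodes the local off-resonance field,
$\varphi(\mathbf{r}) = 2\pi \gamma B_0\, \delta(\mathbf{r})\, TE$, with
$\delta$ the fractional field offset (we work in parts per billion, ppb;
1 ppb at 3 T is about 0.128 Hz). The field inside the head splits into

* a **local field**, generated by tissue susceptibility inside the brain,
  which carries BOLD-related contrast changes, and
* a **harmonic background field**, generated by sources *outside* the brain
  (chest, torso, shim environment). A source-free field satisfies Laplace's
  equation, so this part obeys the spherical-mean-value property.

Chest motion during breathing moves susceptibility distributions outside the
head, so respiration modulates the *harmonic* part of the field. That is the
signal this package extracts: it is independent of local BOLD contrast by
construction, which is precisely what makes it safe to use as a noise
regressor.

## The processing chain

For each of the $N$ volumes (time along the fourth axis):

1. **Laplacian unwrapping.** The wrapped phase $\varphi_w$ satisfies
   $\nabla^2 \varphi = \cos\varphi_w \nabla^2 \sin\varphi_w -
   \sin\varphi_w \nabla^2 \cos\varphi_w$, an identity that only involves
   wrap-invariant quantities. We evaluate both forward Laplacians and the
   inverse spectrally on an even-symmetric mirror extension of the grid
   (Neumann-like boundaries — the head does not tile periodically, and
   mirror extension suppresses edge ringing). The inverse fixes the
   Laplacian's nullspace by returning a zero-mean solution. Phase outside
   the brain mask is zeroed first: where the magnitude is ~0 the phase is
   meaningless noise, and the spectral solver would smear it inward.
2. **Unit conversion** to ppb via
   $\delta = \varphi / (2\pi TE) / (\gamma B_0) \cdot 10^9$,
   $\gamma = 42.577$ MHz/T.
3. **Regularized SHARP.** The filter $C = \delta_{\mathrm{Dirac}} -
   \mathrm{SMV}$ (spherical-mean-value kernel) annihilates harmonic fields.
   Applying $C$, restricting to a mask eroded by the kernel radius (so every
   retained voxel sees a complete sphere), and inverting with Tikhonov
   regularization $|C|^2/(|C|^2+\lambda)$ yields the local field; the
   harmonic background is the remainder, `total - local`, on the eroded
   mask.
4. **Low-rank decomposition.** The harmonic-field series is reshaped into an
   $M \times N$ matrix $P$ (mask voxels by timepoints) and truncated to rank
   5 by SVD — the best rank-5 approximation in the Frobenius norm. $P$ is
   used as-is, without temporal de-meaning: the static background then loads
   onto one near-constant component, which the next step naturally rejects.
5. **Component selection.** Each scaled right singular vector
   $\tilde v_i(t) = \sigma_i v_i(t)$ is scored by the $L_1$ norm of its
   first difference (divided by TR for unit coherence; the factor is common
   to all components and cannot change the argmax). Respiration is the
   component with *maximal instantaneous variation*: a static offset has a
   huge singular value but a near-zero derivative, slow drift has a small
   derivative, and white noise at realistic levels carries far less energy.
   The selected index is frequently not 1. Exact ties break towards the
   smallest index, and the SVD sign ambiguity is fixed by making the spatial
   map's mean non-negative — the inhale/exhale polarity is not identifiable
   from the decomposition alone, so downstream comparisons use absolute
   correlation.
6. **Solid-harmonic projection.** The rank-1 respiratory field series is
   projected, volume by volume, onto the 16 real regular solid harmonics up
   to third order (Cartesian polynomials; column order and explicit forms
   are documented in the basis code). Coordinates are centred on the
   eroded-mask centroid and scaled by half the largest mask extent, which
   keeps the cubic columns well conditioned; the basis is not orthogonal on
   an arbitrary mask and no orthogonality is assumed — all guarantees are
   least-squares guarantees. Because the zeroth column is the constant 1,
   its coefficient is directly a field offset in ppb.
7. **Regressor.** The zeroth-order coefficient per volume, on the volume
   clock $t_n = n \cdot TR$.

### Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| SVD rank | 5 | – | temporal field dynamics are low rank; five components capture effectively all variance in practice |
| harmonic order | 3 | – | conventional field-expansion order; respiration itself would need only order 1 |
| SMV kernel radius | 4 × voxel | mm | conventional QSM choice; larger kernels erode more brain |
| SHARP $\lambda$ | $10^{-2}$ | – | Tikhonov weight; small enough to keep dipole-field recovery above $r = 0.99$ on noiseless phantoms, large enough to damp the near-null low frequencies of $C$ |
| erosion depth | kernel radius / voxel | voxels | every retained voxel must see a complete averaging sphere |
| peak-match window | 0.575 | s | half the 1.15 s volume TR |
| belt low-pass | 2 | Hz | respiration is below ~0.7 Hz; 2 Hz is conservative |
| belt despike threshold | 5 | robust SDs | impulsive sensor artifacts are far outside this band |

## Belt comparison and respiratory phase

The reference belt trace is de-spiked (running median, MAD threshold) and
low-pass filtered (zero-phase Butterworth). Clock offset between belt and
scanner is estimated by maximizing absolute cross-correlation over ±5 s.
Peaks are detected as local maxima with prominence at least 0.2 × IQR,
separated by at least half the dominant period (autocorrelation's first
off-zero maximum), with parabolic sub-sample refinement; matching is greedy
nearest-in-time one-to-one within the window, and the overlap fraction uses
the larger peak count as denominator (the stricter convention). Respiratory
phase is synthesized two ways: the RETROICOR-style histogram method
($\phi = \pi\,\mathrm{sign}(\dot R)\,\mathrm{CDF}(R)$) and the analytic
signal's instantaneous phase (Hilbert). At zero slope (breath-hold
plateaus) the histogram sign carries over the last nonzero sign: phase is
genuinely undefined during a hold and we mirror that limitation rather than
invent behaviour.

## The phantom: what it emulates and what it does not

`simulate_phantom_epi()` builds, by default, a 32 × 32 × 20 ellipsoidal
"brain" of 2.5 mm voxels, 120 volumes at TR 1.15 s, TE 30 ms, 3 T:

* **Breathing** is a train of raised-cosine breaths, free breathing at a
  4.8 s mean period with 20% uniform per-breath jitter — the typical adult
  resting period. Controlled protocols (shallow / deep / free / hold,
  hold duration drawn in 10–20 s) are available via
  `control_protocol_segments()`.
* **Static local field** from a spherical susceptibility inclusion (100 ppb,
  dipole-kernel convolution $1/3 - k_z^2/k^2$).
* **Static background** from a strong source outside the mask (3000 ppb);
  its field is harmonic inside the brain and steep enough to wrap the phase
  near the brain edge, exercising the unwrapper.
* **Respiratory background** $B(\mathbf r, t) = w(t) \sum_{lm} g_{lm}
  S_{lm}(\mathbf r)$ with a 2.5 ppb zeroth-order gain and higher-order gains
  chosen so in-mask excursions span a few negative ppb to about +10 ppb,
  strongest at the periphery. There is no quantitative in-vivo model of the
  higher-order spatial structure, so the $l > 0$ gains are set for
  conditioning and realism of magnitude, not from measurement.
* **Noise**: complex Gaussian at 2% of the unit magnitude (EPI SNR ≈ 50).
  The exported phase is the angle of the noisy complex signal, so phase
  noise grows realistically where magnitude is low and is uniform outside
  the mask.
* **Belt**: the waveform at 500 Hz plus slow sinusoidal drift, white noise
  and impulsive spikes.

Deliberately absent: EPI distortion and ghosting, subject motion, cardiac
pulsation, multiband reconstruction artifacts, and any BOLD signal. Passing
the end-to-end tests therefore shows the *method* recovers a known
respiratory field under realistic SNR and wrap conditions; it does not show
robustness to motion or reconstruction artifacts in real data.

## Numerical choices and degenerate inputs

* Phase is stored in $(-\pi, \pi]$; out-of-range input is rewrapped with a
  warning; exactly $-\pi$ maps to $\pi$ silently.
* The spectral Laplacian uses continuous eigenvalues $-(2\pi k)^2$ on the
  mirrored grid. A stencil-eigenvalue variant was tried and discarded: its
  discretization error on the unwrap identity (which mixes $|\nabla\varphi|^2$
  terms) is orders of magnitude larger for steep phase.
* Mask erosion is an FFT convolution with a sphere indicator, thresholded
  with a tolerance far below one voxel count, so it is exact.
* Processing is strictly per-volume and embarrassingly parallel in time;
  results do not depend on volume order, and identical inputs give
  bit-identical outputs (LAPACK's SVD is deterministic).
* A constant trace yields an empty peak set (not an error), but respiratory
  phase on a constant trace is an error: there is no phase to define.
* With fewer than two matched peak pairs, period metrics are reported `NA`;
  the overlap fraction is always defined.
* An ill-conditioned solid-harmonic basis (condition number above $10^8$,
  e.g. a nearly planar mask) triggers a warning naming the condition number.

## Aliasing

Respiration is recoverable only if TR is shorter than half the breath
period. The pipeline warns when the regressor's dominant frequency reaches
90% of the volume-rate Nyquist frequency. This catches breathing *near* the
limit; it cannot catch breathing far *beyond* it, because a tone at, say,
0.6 Hz sampled at 0.87 Hz folds to 0.27 Hz and is mathematically
indistinguishable from genuine 0.27 Hz breathing — jittered super-Nyquist
breathing folds to a signal statistically close to legitimate slow
breathing as well. We verified this on phantoms: the folded regressor's
peak overlap with the true breath times collapses below 0.5, while no
regressor-only statistic we examined (dominant frequency, spectral
concentration, peak-interval dispersion) separates the aliased regime
robustly. Users with fast-breathing populations need a shorter TR, not a
better detector.

## Problem sizes used in the test suite

The packaged tests run the full chain on 32 × 32 × 20 × 120 phantoms
(about 1100 eroded-mask voxels) and smaller grids for unit properties;
these sizes give sub-minute suites while leaving every stage's behaviour —
wrapping, erosion, rank separation, conditioning — qualitatively identical
to full-resolution data. The same defaults drive `scripts/acceptance.R`.

## Known limitations

* The regressor's sign relative to inspiration is not identifiable; align
  by absolute correlation against a reference before interpreting polarity.
* The harmonic field is estimated on the eroded mask; a thin mask plus a
  large kernel can erode to nothing (the error message names the depth).
* Cardiac pulsation is an order of magnitude faster than respiration and is
  not recoverable at volume TR; the method makes no attempt at it.
* Coefficient magnitudes for $l > 0$ depend on the centring and scaling
  convention of the basis and are not comparable across masks; the zeroth
  coefficient is convention-free (plain ppb).
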