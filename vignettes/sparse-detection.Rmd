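---
title: "Sparse-representation tumor detection: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse-representation tumor detection: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srhsi)
```

## The detection model

A medical hyperspectral cube assigns each pixel a reflectance spectrum
$x \in \mathbb{R}^B$ (default $B = 81$ bands, 600–1000 nm at 5 nm). The
working assumption of sparse-representation classification is that spectra
of one tissue class lie near a low-dimensional subspace spanned by training
spectra of that class. Stacking $N_{nc}$ noncancerous and $N_c$ cancerous
training spectra as columns gives the concatenated dictionary
$A = [A_{nc}\; A_c]$, and a test spectrum is decomposed as
$x \approx A\gamma$ with $\gamma$ sparse. Writing $\hat\alpha$ and
$\hat\beta$ for the noncancerous and cancerous blocks of the recovered
$\hat\gamma$, the class residuals
$r_{nc}(x) = \lVert x - A_{nc}\hat\alpha\rVert_2$ and
$r_c(x) = \lVert x - A_c\hat\beta\rVert_2$ are compared through
$D(x) = \log_{10}\!\big(r_{nc}(x)/r_c(x)\big)$; a pixel is called cancerous
exactly when $D(x) > 0$. Ties ($D = 0$, including pixels orthogonal to the
whole dictionary) fall to the noncancerous side — the conservative choice,
fewer false positives. Only the sign of $D$ matters for the decision, so the
logarithm base is immaterial; base 10 is used. Both residuals are floored at
$10^{-12}$ before the ratio so that exact in-class reconstructions (test
pixel equal to an atom) produce a large finite score rather than a
divide-by-zero.

The assumptions worth keeping in mind: tissue classes must be approximately
linearly representable by few training spectra of their own class;
reflectance (not raw radiance) is the right feature space, because
calibration removes illumination and dark-current structure that would
otherwise dominate the atoms; and the two dictionary blocks must both be
populated — the rule is purely relative.

## Sparse solvers

Two recovery routes are exposed through `solver_config()`:

* **Greedy (orthogonal matching pursuit)** — default. At each step the atom
  with maximal absolute correlation with the residual enters the support and
  coefficients are re-fit by least squares; iteration stops at residual
  $\le \varepsilon$, at `max_atoms`, or when no atom decreases the residual.
  Residual norms are non-increasing by construction.
* **Basis pursuit** — $\min \lVert\gamma\rVert_1$ subject to
  $\lVert x - A\gamma\rVert_2 \le \varepsilon$. For $\varepsilon \le 10^{-6}$
  (effectively the equality form) the problem is solved exactly as a linear
  program by an internal dense two-phase simplex with Bland's rule: a vertex
  optimum has exact zeros, which keeps reported supports free of numerical
  dust. For larger $\varepsilon$ the equivalent penalized $\ell_1$ (lasso)
  path is traced with warm starts via glmnet, the penalty is bisected onto
  the error-constraint boundary, and the solution is polished to the exact
  KKT point of its active set. The two regimes meet at the scale where the
  feasibility slack ($10^{-6}$) stops being meaningful.

Parameters and defaults:

| parameter | default | meaning |
|---|---|---|
| `eps` | `NULL` | absolute error tolerance $\varepsilon$; `NULL` means relative |
| `eps_rel` | 0.05 | $\varepsilon = 0.05\,\lVert x\rVert_2$; reflectance noise scales with signal, so a relative default transfers across scenes |
| `max_atoms` | 10 | greedy sparsity cap; a handful of spectra spans a tissue class, and the cap bounds per-pixel cost |

The support of a solution is reported as the indices with
$|\gamma_j| > 10^{-10}$. An exhaustive $\ell_0$ oracle (`brute_force_l0()`,
all supports up to a size cap, least squares on each) ships as first-class
code: it is the combinatorial ground truth used by the test-suite to validate
both practical solvers, and is usable on any instance with at most $10^6$
candidate supports.

With the default `eps_rel`, a pixel far outside the dictionary span (a glare
pixel under a small dictionary) can make the basis-pursuit constraint
infeasible; the solver then raises a diagnostic error rather than returning
a silently wrong answer. In the full pipeline the dictionary has hundreds of
atoms spanning all of $\mathbb{R}^B$, so this arises only in reduced
settings; the greedy solver, which always returns its best effort, is the
pipeline default.

## Preprocessing

Calibration converts raw radiance to relative reflectance per pixel and
band, $R = (I_{raw} - I_{dark})/(I_{white} - I_{dark})$, using a white
reference board in the scene and a closed-shutter dark frame. Where
$|I_{white} - I_{dark}|$ falls below a guard (default $10^{-9}$) the output
is set to 0 and the location is logged in a `calibration_warnings`
attribute — dead bands must be visible, not NaN.

Denoising is a per-band 2-D median filter. The window defaults to
$3\times3$: the smallest window that removes single-pixel saliva speckle
without eroding tumor margins; it is configurable for coarser noise. Borders
are mirror-padded (edge not repeated), avoiding dark-border artifacts.
Denoising runs on raw counts *before* calibration, matching an acquisition
chain in which impulse noise originates at the sensor/scene; the two orders
genuinely differ and only the fixed order is asserted by the tests. The
filter is spatial (2-D) per band, not spatio-spectral: glare and speckle are
spatially localized but spectrally broad, so a 3-D median would mix
information across the very dimension used for classification.

## Post-processing and evaluation

Glare destroys spectra of isolated interior pixels, which then fail
detection and leave holes inside the tumor region. `fill_holes()` sets every
background connected component not connected to the image border to
foreground; foreground is never removed, so the mask only grows. Background
connectivity defaults to 4 (the standard dual of 8-connected foreground,
avoiding topological paradoxes); 8 is available.

Evaluation uses the pixel-level definitions: FNR = false negatives over all
tumor pixels, FPR = false positives over all normal pixels, accuracy =
correct over all labeled pixels — "accuracy" is implemented as overall pixel
accuracy, the only definition consistent with a single recognition-rate
number. Unlabeled (255) pixels are excluded from dictionaries and from
every count, but are still classified, mirroring partially annotated
clinical scenes. `run_pipeline()` reports rates both on the held-out test
pixels (the headline, matching a 10%/90% train/test protocol) and over all
labeled pixels. Hole filling can only convert false negatives to true
positives and true negatives to false positives, so it never raises FNR —
an invariant the tests assert on random masks.

## The scene simulator

No public MHSI tumor database exists, so the package carries a simulator
whose defaults are its reference study conditions, fixed once:

* 64 × 64 pixels × 81 bands (600–1000 nm at 5 nm);
* class mean spectra from `default_signatures()`: a smooth logistic rise
  across the red/NIR edge for normal tissue, plus a smooth NIR bump for the
  tumor class whose supremum-norm height is the `separation` parameter,
  default 0.15 reflectance units;
* i.i.d. per-band Gaussian noise around the class mean, sd 0.03 for both
  classes (so the default separation is 5× the noise sd);
* one elliptical tumor covering about 11% of the frame (parametric ground
  truth with exact areas; arbitrary masks can be supplied instead);
* saliva glare: each pixel independently with probability 0.01 has its
  reflectance set to 1.5 (above white — specular saturation) across a random
  contiguous band range, since specular reflection is spectrally broad;
* illumination: a smooth lamp spectrum of a few thousand counts; dark
  current 100 counts with 0.5-count Gaussian read noise, which exercises the
  calibration guard realistically.

Raw counts are produced by inverting the calibration equation with the same
white/dark frames that are handed to the pipeline, so a zero-noise,
zero-glare scene round-trips through `normalize_reflectance()` to
floating-point accuracy — an identity the acceptance suite checks at
$10^{-10}$.

What the simulator does *not* emulate: spatial correlation of tissue texture,
tongue-motion blur, shot-noise/read-noise separation, wavelength-dependent
optical blur, and intra-class spectral mixtures near tumor margins. Passing
tests therefore demonstrate the correctness and self-consistency of the
pipeline under its stated statistical model, not clinical performance;
real-tissue accuracy claims require real data.

## Numerical choices and degenerate inputs

* Dictionary atoms are unit-$\ell_2$ normalized by default; sparse coding
  over unnormalized atoms biases selection toward bright spectra. All-zero
  training spectra are rejected at normalization.
* The greedy solver terminates on any step that fails to decrease the
  residual (numerically dependent atoms), returning the last good support.
* `brute_force_l0` breaks ties (residuals within $10^{-9}$) toward smaller
  support, then smaller residual, then lexicographic support — making the
  oracle deterministic on instances with exact multiple representations.
* Simulated reflectance is clamped at 0 (the Gaussian noise model can
  otherwise produce physically meaningless negative reflectance, and raw
  counts must be non-negative); with the default means ≥ 0.22 and sd 0.03
  the clamp is a ≥ 7σ event, leaving the configured means intact in
  practice.
* ENVI I/O stores reflectance as 32-bit float and raw counts as unsigned
  16-bit by default (camera bit depth vs. calibrated data); 64-bit float is
  available when bit-exact round trips of double data are needed. The
  stored-sample type is a package decision — the acquisition hardware
  description fixes only the spectral grid.
* Train/test splitting guarantees at least one training and one test pixel
  per class regardless of rounding.

## Problem sizes in the test-suite

The suite validates the solvers on 100 random instances ($B$ 8–12, $N$
12–16, planted sparsity ≤ 2, pairwise atom coherence below 0.5 by per-atom
rejection sampling — whole-matrix rejection is infeasible at these shapes)
against the exhaustive oracle; the pipeline on five 64 × 64 × 81 reference
scenes per run (a size where per-seed accuracy stabilizes well above the
95% regression bound while a full run stays in seconds); and the morphology
on 50 random blob masks against an algorithmically independent
dilation-fixpoint oracle. All stochastic tests are seeded; the pipeline is
bit-deterministic under fixed seeds, which the suite asserts by comparing
serialized reports of repeated runs.
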