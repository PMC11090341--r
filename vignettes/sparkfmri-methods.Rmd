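---
title: "Methods: synthetic comparison of non-Cartesian and Cartesian fMRI encoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic comparison of non-Cartesian and Cartesian fMRI encoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sparkfmri)
```

This vignette documents the models implemented in **sparkfmri**, the
assumptions behind them, the parameters that matter, and the numerical
decisions taken where the design was genuinely open. Everything stated
here is computed by the test suite or by `scripts/acceptance.R`; nothing
is quoted from external data.

## 1. What the package emulates

A two-arm fMRI encoding comparison at desk scale: a variable-density
non-Cartesian multi-shot scheme with compressed-sensing reconstruction
versus an accelerated Cartesian EPI scheme with linear reconstruction,
both driven through an identical synthetic retinotopic-mapping study.
The full-scale protocol the presets mirror is 48 shots per volume at a
50 ms unitary TR (volumetric TR 2.4 s), TE 20 ms, ~26.9 ms readouts,
1 mm voxels over a 192 mm FOV, and two 120-volume runs of a 32 s rotating
wedge (9 cycles per run). `paper_scale_preset()` records these constants;
the desk preset (`default_pipeline_config()`) runs the same machinery on
a 40×40 single-slice phantom.

## 2. Sampling-pattern optimization

Shots live in normalized k-space Ω = [−1,1]^d. The target density
π_{C,D} (plateau κ inside radius C, decay κ(C/|x|)^D outside) is
discretized on a lattice (64/axis in 2D, 32/axis in 3D) and normalized to
unit Riemann mass; the attraction integral is evaluated as a Riemann sum
on that lattice, which keeps gradients cheap and reproducible.

The energy F = F_attraction − F_repulsion is minimized by projected
gradient descent:

* the Euclidean norm in both terms is smoothed as √(‖·‖² + ε²), ε = 1e−8,
  to avoid the undefined subgradient at coincident points;
* the per-point gradient of the *mean* energy scales as 1/p, so the step
  (default 0.2) is applied to p×gradient — i.e. quoted as a typical
  per-point displacement;
* backtracking halves the step (≤ 20 times) until the **projected**
  candidate does not increase the energy, so the recorded trace is
  non-increasing by construction;
* the constraint projection is cyclic clipping — box, echo-time crossing
  by whole-shot translation (which preserves discrete derivatives), first
  differences clipped to α·δt, second differences to β·δt² — iterated up
  to 50 times to a 1e−3 relative tolerance, with an independent
  finite-difference audit (`pattern_audit()`).

Two consequences are worth knowing. First, cyclic clipping is an
approximation to the exact convex projection; combined with speed-bound
saturation it makes nearly fully stretched spokes almost rigid, so the
optimizer reaches a constrained stationary point after few accepted
steps. The contracts that hold (and are tested) are monotone energy, a
clean constraint audit, and a radial-CDF Kolmogorov distance strictly
below the radial initialization. Second, initialization matters:
jittered radial spokes are generated at 80 % of the speed bound so the
projection has slack; seeded, hence bitwise-reproducible.

## 3. Encoding operator

The forward model evaluates
y_c(j) = N^{−1/2} Σ_x S_c(x) m(x) e^{−i2πk_j·x} e^{−iδω₀(x)t_j}
with the image lattice centered at zero and k normalized so k = 1 is the
Nyquist edge; on the full Cartesian grid this is exactly the unitary DFT
(a unit impulse at the origin voxel has flat spectrum 1/√N — this
convention is pinned by a test). Arbitrary trajectories use an explicit
non-uniform DFT (cached as a matrix when it fits in memory, streamed in
chunks otherwise); Cartesian masks use FFT kernels. At desk scale the
exact NDFT is both faster to implement and easier to audit than gridding,
and its adjoint is exact by construction (inner-product agreement ~1e−16,
tested at 1e−6).

Off-resonance is handled by time segmentation. The spec'd variant —
linear interpolation between L segment phases — has interpolation error
of order (2πΔB₀·T/L)²/8 ≈ 0.1 at realistic ΔB₀ (±50 Hz over a 27 ms
readout with L = 8), and cannot meet the 1e−3 accuracy contract; we use
the standard SVD-derived temporal basis instead (fit on a quantile spread
of the off-resonance histogram; per-voxel coefficients are exact
projections), which reaches ~4e−5 at L = 8. The adjoint is the exact
adjoint of the segmented forward operator, so reconstruction convergence
is unaffected by the approximation. A brute-force per-sample-phase
operator (`method = "exact"`) serves as the oracle.

The EPI comparator mask keeps every r-th phase-encode line (and
partition in 3D) inside a partial-Fourier window, with one readout train
per excitation and an even echo spacing anchored at TE — vendor details
like ramp sampling are out of scope.

## 4. Reconstruction

CS solves ½‖Am − y‖² + λ‖Ψm‖₁ with POGM (standard momentum recursion,
final-iterate output, no restarts), step 1/L from ≤ 50 power iterations
with a 1 % safety inflation, complex image penalized. Ψ is the
periodized orthonormal Daubechies 4-tap DWT, 3 levels; orthonormality
makes the proximal step exact and is tested to 1e−10. Coarse-scale
coefficients are excluded from the penalty so the image mean is never
shrunk (hence λ→∞ yields the coarse-scale least-squares image, not zero
— the package follows this exclusion deliberately). λ is quoted relative
to the largest detail coefficient of the adjoint image so presets
transfer across scales; `lambda_line_search()` implements the tSNR-vs-
PSNR criterion on a short synthetic series and returns the full audit
table. Volumes are reconstructed independently (scan-and-repeat).

The Cartesian arm uses linear reconstruction only: zero-filled inverse
FFT with conjugate coil combination, or CG least squares on the
calibrated multi-coil operator (15 iterations by default). In the
pipeline the least-squares path is used — it is the desk-scale stand-in
for a calibrated parallel-imaging reconstruction and remains strictly
linear.

## 5. Synthetic study

`make_phantom()` builds concentric smoothed compartments (WM core, GM
ribbon, CSF shell) inside an elliptical support with a seeded smooth
boundary perturbation, plus a posterior GM patch whose voxels carry
polar angles mirrored across hemispheres. BOLD is a **phase-delayed
cosine**: baseline·(1 + drift) + a·cos(2πn_cyc t/N_vol − sφ_v − d_h + ψ_s)
with AR(1) Gaussian noise. A convolved HRF is deliberately not used: the
analysis estimates and removes exactly one phase delay, so the cosine
model is sufficient and exactly identifiable — the noiseless round trip
(simulate → GLM → phase maps) recovers φ_v to <1e−6 rad and pins every
sign convention, including the counter-clockwise wedge origin ψ = π.

Defaults (the study conditions): 120 volumes/run, TR 2.4 s, P_cyc 32 s
(⇒ n_cyc = 9), amplitude 2 % of a baseline of 100, d_h = π/4, noise SD 2
(temporal SNR ≈ 50), AR(1) 0.3, drift 0.01 units/volume, 4 coils,
ΔB₀ ≤ 20–50 Hz, 30 dB measurement SNR. Motion enters only as nuisance
regressor coupling (no geometric resampling — realignment is out of
scope). What the generator does **not** emulate: physiological noise
spectra, T2* decay within the readout, susceptibility-realistic field
maps, HRF shape variability; passing tests therefore validate the
machinery, not real-data effect sizes.

## 6. GLM, F tests, phase maps

The 240×20 design is block-diagonal (task quadrature pair, 6 motion,
linear drift, baseline per session). Absent motion leaves aliased
all-zero columns: `fit_glm()` drops them by default (ranks and dof follow
the numerical rank) or raises a degeneracy error naming the columns.
The printed dof convention (ν1 = 16, ν2 = 220) needs the full-rank
design, i.e. non-degenerate motion regressors (`simulate_motion()`).

Prewhitening is a single Cochrane–Orcutt pass with a **pooled,
projection-bias-corrected** AR(1) estimate: the raw lag-1 autocorrelation
of OLS residuals is biased low by roughly Q/N (~0.05 here), most of the
recovery tolerance; we instead solve for the ρ whose implied expected
residual lag-1 ratio, tr(M T M V(ρ))/tr(M V(ρ)), matches the observed
pooled ratio. This is deterministic and recovers ρ = 0.4 within ±0.01
at V = 500.

Two effect-of-interest nestings are implemented. `mode = "paper"`
(default) takes the reduced model to be the four task regressors alone,
reproducing the printed ν1 = rank(X) − rank(X₀) = 16; since that reduced
model has no intercept, any nonzero baseline makes the statistic
non-central, so it cannot act as an activation detector on raw series —
the pipeline therefore thresholds `mode = "conventional"` (reduced =
full minus task, ν1 = 4) and reports both sets of dof. The default
statistic carries the proper dof ratio so p-values are valid; the
unscaled (RSS₀−RSS)/RSS ratio is available as `statistic = "paper_raw"`.
The test battery calibrates both modes on zero-mean null data (mean F =
ν2/(ν2−2); strategy-ii false-positive rate 0.001 on 50 000 voxels).

Phase maps use the two-argument arctangents of the session quadrature
pairs, φ_Clock = atan2(−m₁, −m₂), φ_CClock = atan2(−m₃, m₄), then
d_h = (φ_Clock+φ_CClock)/2 and φ = (φ_Clock−φ_CClock)/2. Two deliberate
choices: (i) the maps are computed from the task **coefficients** rather
than z scores — atan2 is scale-free and the two coefficients of a session
share a standard error by quadrature symmetry, whereas the nonlinear t→z
mapping distorts the angle and saturates (z clipped at 40) as residual
variance vanishes; (ii) the half-angle formulas identify (φ, d_h) only up
to a joint π shift, resolved by assuming d_h ∈ [0, π) (a positive delay
under half a stimulus cycle; `resolve_delay = FALSE` gives the plain
arithmetic). Thresholding strategies: BH–FDR at 0.05; p<0.001
(z > 3.09); p<0.05 with face-connected clusters ≥ 5 voxels
(6-connectivity in 3D — the most conservative standard choice). z
conversions are clipped at |z| = 40 to avoid p-underflow infinities.

## 7. Metrics and the desk-scale comparison

tSNR is mean/SD after linear detrending (population SD; detrending can
be disabled), zero-variance voxels flagged. Tissue specificity assigns
each activated voxel to its argmax tissue with a 0.34 probability floor
and ties going to "other"; table averages round half-away-from-zero to 2
decimals (the printed-table convention). The one-sided two-sample KS
test is computed directly from the signed ECDF difference with the
asymptotic p = exp(−2mD²) (the D statistic is cross-checked against
`stats::ks.test`). Residual normality is the fraction of voxels passing
Shapiro–Wilk at 1 %.

The default pipeline compares the two schemes at a matched sample budget
(600 k-space points per volume each) on a 40×40 phantom with 120-volume
runs. Problem sizes were chosen once so that both arms are adequately
powered (the Cartesian arm's detection t-statistic is ≈ 5 at these
settings; at 40-volume runs it sits at the threshold and the
between-scheme Dice becomes seed-fragile). The Cartesian in-plane
acceleration is 2 rather than the protocol's 4×2 because a single phase
axis at R = 4 with four coils is at the parallel-imaging limit in 2D.

## 8. Known limitations

* The trajectory optimizer is the documented cyclic-clipping
  approximation: it satisfies its audit and improves the density fit,
  but does not match exact-projection/multi-resolution implementations.
* The NDFT is exact but O(MN); it is a desk-scale choice, not a route to
  1 mm whole-brain volumes.
* EPI timing ignores ramp sampling and navigator corrections; no
  geometric distortion correction is modeled (the full-scale protocols
  correct it with separately acquired data, out of scope here).
* CS tSNR is biased upward by the ℓ1 prior's variance reduction; the
  comparison reports it as-is and the residual-normality check guards
  the GLM's Gaussianity assumption.
* Real-data headline quantities (participant-level Dice ranges, voxel
  counts, KS p-values) depend on 7 T scans that are not deposited; the
  package reproduces the *machinery* and its desk-scale analogues only.
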