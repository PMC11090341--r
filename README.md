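# sparkfmri

Desk-scale machinery for comparing two fMRI k-space encoding strategies —
an optimization-driven variable-density **non-Cartesian (SPARKLING-style)
scheme** reconstructed by ℓ1-wavelet compressed sensing, and an
**accelerated Cartesian EPI** comparator reconstructed linearly — on a
fully synthetic retinotopic-mapping study, so no scanner data is needed.
It is aimed at MR-physics and fMRI-methods researchers who want a tested,
reproducible sandbox for the whole chain: trajectory design → multi-coil
off-resonance encoding → per-volume reconstruction → prewhitened GLM →
retinotopic phase maps → quality metrics.

## The models at the core

**Sampling design.** A pattern `K` of `Nc` shots × `Ns` samples in
normalized k-space Ω = [−1,1]^d is found by minimizing the
attraction–repulsion energy

    F(K) = (1/p) Σ_i ∫ ‖x − K_i‖ ρ(x) dx  −  (1/2p²) Σ_{i,j} ‖K_i − K_j‖

subject to hardware constraints: each shot crosses the k-space origin at
the echo time, and its discrete speed/acceleration are bounded by
α = (1/K_max)·min(γG_max/2π, 1/(FOV·δt)) and β = γS_max/(2πK_max).
The target density ρ = π_{C,D} is flat inside radius `C` and decays as
`(C/|x|)^D` outside (protocol values C = 0.25, D = 2).

**Acquisition & reconstruction.** The forward operator is
`y_c(j) = N^{-1/2} Σ_x S_c(x) m(x) exp(−i2π k_j·x) exp(−iδω₀(x) t_j)`
with coil maps `S_c` and off-resonance δω₀ = 2πΔB₀, handled by SVD-based
time segmentation with an exact adjoint. CS reconstruction minimizes
`½‖Am − y‖² + λ‖Ψm‖₁` (orthonormal Daubechies wavelets) with POGM; the
Cartesian comparator uses zero-filled or CG least-squares linear
reconstruction.

**Statistics.** Two wedge runs (clockwise / counter-clockwise, 120 volumes
at TR 2.4 s, 32 s period ⇒ 9 cycles/run) enter a block-diagonal 240×20
design (quadrature task pair, 6 motion, drift, baseline per session), fit
by AR(1)-prewhitened least squares. Effect-of-interest F tests
(ν1 = 16, ν2 = 220 in the printed convention), z maps, three thresholding
strategies (BH–FDR 0.05; p<0.001 ⇔ z>3.09; p<0.05 + cluster ≥ 5), and
retinotopic phase maps φ = (φ_Clock − φ_CClock)/2 after cancelling the
haemodynamic delay d_h = (φ_Clock + φ_CClock)/2.

## Worked example

```r
library(sparkfmri)

hw  <- hardware_constraints(dt = 5e-4, Kmax = 1 / (2 * 0.003))
rho <- target_density(C = 0.25, D = 2, grid_shape = c(64, 64))
K0  <- init_radial_pattern(Nc = 8, Ns = 64, d = 2, hw = hw, seed = 1)
K   <- optimize_pattern(K0, rho, n_iter = 100)
K
#> Sampling pattern: 8 shots x 64 samples (p = 512) in 2D
#>   worst TE offset 0.00e+00, speed excess 3.55e-15, accel excess -9.99e-01
radial_ks_distance(pattern_points(K), rho)   # 0.146, down from 0.176 at init
psf_report(K, c(64, 64))
#> PSF: FWHM = 2.31 x 2.51 voxels, main-to-sidelobe ratio = 2.49
```

Every shot passes the finite-difference constraint audit (TE crossing
exact, speed at the bound, slew far below it), and the optimized points
match the target radial law better than the radial initialization.

The full synthetic comparison — phantom, both encodings, reconstruction,
GLM, metrics — is one call:

```r
report <- run_pipeline(default_pipeline_config(seed = 1))
report
#> Synthetic encoding-scheme comparison
#>   mean tSNR (support): non-Cartesian CS 128.2 vs Cartesian LS 34.0
#>   Dice overlap of strategy-ii activation masks: 0.620
#>   activated voxels (strategy ii): 108 vs 50
#>   tissue % of activated voxels (GM/WM/CSF/other):
#>     non-Cartesian: 69.4 15.7 14.8 0.0
#>     Cartesian:     100.0 0.0 0.0 0.0
#>   KS right-shift: D = 0.513 (p = 1.4e-07); left-shift: D = 0.173 (p = 0.16)
#>   residual-normality fraction at 1%: 0.947
```

The two schemes recover overlapping visual-cortex activation (Dice
0.62), the non-Cartesian CS series has the higher temporal SNR, detects
more suprathreshold voxels whose z scores are significantly
right-shifted, and activations stay predominantly in gray matter — the
qualitative pattern the machinery is built to measure. Takes a few
minutes on one core. `run_pipeline(config)` also accepts a YAML/JSON file
and writes NIfTI maps, CSV tables and a JSON report when `output_dir`
is set.

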