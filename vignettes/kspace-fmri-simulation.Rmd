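---
title: "Simulating fMRI acquisitions in k-space: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating fMRI acquisitions in k-space: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

ksim simulates a task-based fMRI experiment the way the scanner sees it:
one radio-frequency excitation at a time, each followed by a readout
("shot") that samples a trajectory through spatial-frequency (k-) space
while the object itself keeps evolving. A frame-wise reconstruction and a
GLM scoring stage close the loop, so that any combination of sampling
pattern, acquisition model, and reconstruction strategy can be ranked
against a ground truth that is known exactly. This vignette explains the
models implemented, the parameters that matter, and the design choices
made where more than one reasonable option existed.

## The forward model

### Steady-state contrast

The object is a weighted mixture of a few tissue classes. Each tissue
carries a proton density $\rho$, a longitudinal relaxation time $T_1$,
and an effective transverse relaxation time $T_2^*$. Under a spoiled
gradient-recalled-echo (GRE) sequence with repetition time $TR$, echo
time $TE$ and flip angle $\alpha$, the steady-state signal of tissue $i$
is

$$\mu_i \;=\; \rho_i \sin\alpha\,
  \frac{1 - e^{-TR/T_{1,i}}}{1 - \cos\alpha\, e^{-TR/T_{1,i}}}
  \, e^{-TE/T_{2,i}^*},$$

implemented in `gre_contrast()`. The flip angle maximising this
expression is the Ernst angle $\cos\alpha = e^{-TR/T_1}$; at
$TR = 50$ ms and the gray-matter $T_1$ of 2 s that is about $12.8^\circ$,
which is why the default scenarios use $\alpha = 12^\circ$. The voxel-wise
contrast is the fraction-weighted mixture
$\mu(\mathbf r) = \sum_i w_i(\mathbf r)\,\mu_i$ (`contrast_volume()`),
linear in the fraction fields.

Default tissue values are 7T-like (WM: $\rho$ 0.77, $T_1$ 1330 ms,
$T_2^*$ 26 ms; GM: 0.86, 2000 ms, 33 ms; CSF: 1.0, 4000 ms, 100 ms).
They are configuration, not constants: any `tissue_params()` list can be
substituted, and `T2s = Inf` disables decay for a tissue.

### Shot-level signal

A shot acquires $N$ complex samples at k-space locations
$\mathbf k(t_n)$ and times $t_n$ relative to the echo. Two engines share
one convention set (normalised coordinates in $[-0.5, 0.5)$ cycles/FOV,
centred integer voxel coordinates, kernel $e^{-2\pi i\,\mathbf
k\cdot\mathbf r}$, no normalisation of the forward sum):

* the **basic Fourier engine** evaluates
  $y_\ell[t_n] = \mathcal F\{S_\ell\,\mu\}[\mathbf k(t_n)]$ per coil
  $\ell$ — relaxation during the readout is ignored;
* the **extended engine** keeps the per-tissue decay and an optional
  static off-resonance term,
  $$y_\ell[t_n] = \sum_i e^{-t_n/T_{2,i}^*} \sum_{p=1}^P c_p[t_n]\,
  \mathcal F\{b_p\, S_\ell\, w_i\,\mu_i\}[\mathbf k(t_n)],$$
  at a cost of $N_{tis}\cdot P\cdot L$ Fourier evaluations per shot.

The time axis is echo-centred: $\Delta t = T_{obs}/N$ and the sample
crossing the k-space centre is acquired exactly at $t = 0$, so the decay
factor is 1 at the echo and the contrast is referenced to $TE$. (An
alternative convention spans exactly $[-T_{obs}/2, T_{obs}/2]$ at spacing
$T_{obs}/(N-1)$, but then an even-length readout never samples $t = 0$
and the in-out spiral cannot cross the centre at the echo; the
echo-exact convention was preferred.)

The off-resonance phase $e^{-2\pi i\,\Delta f(\mathbf r)\,t}$ is
approximated by $P$ separable terms anchored at equally spaced time
segments, $b_p(\mathbf r) = e^{-2\pi i \Delta f(\mathbf r)\tau_p}$, with
minimum-norm least-squares coefficients $c_p(t)$ fitted over the
histogram of field values (`build_off_resonance()`). A constant field is
represented exactly with $P = 1$; a smooth $\pm 50$ Hz map over a 25 ms
readout needs $P = 8$ for a residual below $10^{-3}$. The scenario
presets do not use off-resonance content — the interface exists so that
the extended engine is complete, and its accuracy is tested, but the
study-level hypotheses keep $\Delta f \equiv 0$.

All transforms are exact: Cartesian-on-grid samples go through the FFT,
stacked readouts (constant on-grid $k_z$ per shot) through a $z$-axis FFT
plus an exact 2D non-uniform DFT, and arbitrary locations through an
exact 3D non-uniform DFT written in C++. There is no gridding/kernel
approximation anywhere, so forward/adjoint pairs satisfy the dot-product
identity to machine precision — at the price of an $O(NM)$ cost for
fully non-Cartesian trajectories, acceptable at the matrix sizes the
package targets.

### BOLD dynamics between shots

Brain activity is modelled as a change $\Delta R_2^*$ of the gray-matter
relaxation rate inside a region of interest. At echo time $TE$ the
contrast factor is linearised to
$1 - TE\cdot\Delta R_2^*\,\tilde h(t)$ (`bold_contrast()`; the exact
exponential is available behind `exact = TRUE` — at the default
$\Delta R_2^* = -1$ Hz and $TE = 25$ ms the two differ by $3\times
10^{-4}$). $\tilde h$ is the experimental paradigm convolved with a
canonical double-gamma haemodynamic response (peak around 5–6 s,
undershoot around 15 s), rescaled so its maximum is exactly 1; the peak
factor is then $1.025$, a 2.5% signal increase. The undershoot makes
$\tilde h$ briefly negative after each block; it is applied as-is (the
normalisation pins the maximum, not the range), because clamping it
would make the simulated time course diverge from the GLM regressor and
bias effect-size recovery by several percent.

State updates are organised as a chain of pure handlers applied between
consecutive shots at `TR_shot` resolution: each maps (baseline state,
shot index, time) to a new state, recomputing — never accumulating — its
effect. Purity is what makes the streaming contract cheap: the state
before any shot can be replayed exactly, so shots may be simulated in
any order or concurrently, and the container payload is bit-identical to
the sequential run.

### Noise

Thermal noise is circular complex Gaussian over the coil dimension with
per-sample covariance $(E/\mathrm{SNR_i})\,\Sigma$, where $E$ is the
mean squared contrast over the head support and $\mathrm{SNR_i}$ the
user-set input SNR. Defining $E$ as a mean (not a sum) keeps
$\mathrm{SNR_i}$ values comparable across matrix sizes. Draws are
sub-seeded per shot by a deterministic integer mix of the master seed
and the shot counter, which is also why parallel generation cannot
change the realisation. The acceptance-style checks verify the empirical
per-sample variance to 3% and the cross-coil covariance to 5% over
$10^5$ draws.

## Sampling patterns

* `epi_3d()` — fully sampled plane-per-shot Cartesian readout;
  serpentine raster within a plane, phased so the $(k_x, k_y) = (0,0)$
  sample of every plane sits exactly at the echo. Planes are ordered
  **centre-out (centric)** by default. This matters for dynamics: with a
  time-varying object, the volume's low frequencies — which set the
  apparent amplitude and timing of the BOLD response — should be
  acquired in a short window rather than smeared across the whole
  `TR_vol`. With ascending order, the temporal mixing leaks task-locked
  signal into ROI neighbours and attenuates the recovered effect size by
  about 4% at `TR_vol` near 2 s; with centric order the end-to-end test
  recovers the injected modulation to better than 1%.
* `spiral_inout()` — Archimedean in-out spiral: inward arm, exact
  centre crossing at the echo, point-mirrored outward arm (gradient
  continuity through the centre). The default of 12 revolutions with a
  3000-sample, 30 ms readout passes a 40 mT/m, 180 T/m/s hardware audit
  at 3 mm resolution and 192 mm FOV (`gradients_and_slew()`).
* `stack_of_spirals()` — variable-density $k_z$ stack: a fixed central
  band (rounded fraction of planes, always containing $k_z = 0$) is
  acquired every frame; outer planes are subsampled by the acceleration
  factor, either as a fixed stride subset ("scan and repeat") or as a
  fresh seeded draw per frame (dynamic). Plane-wise golden-angle
  rotation of the spirals decorrelates the aliasing across planes.
  Published scenario tables sometimes fix the shots-per-volume count
  directly rather than deriving it; `n_center` and `n_outer_per_frame`
  are therefore explicit overrides.
* `read_trajectory()` / `write_trajectory()` — lossless binary exchange
  (and a CSV dialect for inspection) so externally optimised readouts
  can be injected without the package having to reproduce their design
  procedure.

## Reconstruction

The baseline is the density-compensated adjoint: exact inverse FFT for
fully sampled Cartesian frames; for non-Cartesian frames,
radius-proportional weights (floored a few sample spacings from the
centre) followed by a one-parameter least-squares intensity calibration
$c = \mathrm{Re}\langle A\hat x, y\rangle / \|A\hat x\|^2$. The analytic
radius rule matches the $1/r$ sampling density of a spiral but leaves
the global scale undetermined; the calibration fixes it from the data.
On a noiseless full stack of spirals this combination reconstructs the
phantom at about 40 dB PSNR. Coils are combined by conjugate-sensitivity
weighting with the simulator's own maps (coil knowledge is treated as an
oracle throughout).

The compressed-sensing path minimises, per frame,

$$\tfrac12 \sum_\ell \|F_{\Omega} S_\ell x - y_\ell\|_2^2
  + \mu \|\Psi x\|_1,$$

with $\Psi$ an orthogonal periodized wavelet transform (sym8, 3 levels
by default; db4 and Haar available). Periodization keeps the transform
exactly orthogonal on any even-length axis, which the test suite checks
numerically; the proximal step is complex magnitude soft-thresholding of
the detail bands (the coarse band is left unpenalised so the intensity
scale is not shrunk). Solvers are POGM (default) and FISTA, step
$1/L$ with $L$ from 20 power iterations; stopping on a relative cost
change below `tol` (evaluated every few iterations) or `max_iter`, with
a divergence guard at ten times the initial cost. When a whole series is
reconstructed, the Lipschitz estimate from the first frame (plus a 25%
margin) is shared across frames.

The weight $\mu$ can be estimated per frame by a SURE rule: the noise
scale is the quadrature mean of the real- and imaginary-channel MADs of
the finest detail subband of the adjoint image, and the soft threshold
minimising Stein's unbiased risk estimate over all detail coefficients
is rescaled to the data-fidelity Hessian of a full readout. Two points
deserve emphasis. First, the estimator is intentionally *not* blind to
aliasing: undersampling artefacts of the (real-valued) object load the
real channel, so poorly initialised frames are strongly regularised.
Second, when an initialisation is available the estimate is computed on
the residual-corrected image $x_0 + A^H_{dc}(y - A x_0)$, so as a
warm-started series converges the apparent noise — and the weight —
shrinks; on a dynamic stack-of-spirals series the reported $\mu_t$ of
later warm frames falls below that of the cold first frame, reproducing
the behaviour that motivates the warm/refined strategies. The corollary
is that on structured noiseless data the estimated weight is small (of
order $10^{-3}$ of the signal scale on the test phantom) but not zero —
a signal-blind MAD estimator cannot distinguish fine signal texture from
noise exactly; identically zero data do return $\mu = 0$.

Three sequencing strategies are provided (`reconstruct_series()`): cold
(every frame from zero), warm (each frame initialised with the previous
solution), and refined (a warm pass, then a second pass over all frames
initialised with the final warm volume). With time-varying undersampling
the refined pass is the mechanism by which every frame benefits from the
k-space coverage accumulated over the whole run.

## Evaluation

`glm_tstats()` fits an ordinary least-squares GLM per voxel (task
regressor plus constant; optional cosine drifts) and forms the one-sided
$t$ statistic of the task coefficient. The task regressor is the same
normalised haemodynamic signal used by the simulator, sampled at frame
timestamps. The default timestamp is the acquisition time of the shot
crossing the k-space centre of each volume — that is the moment the
volume's low-frequency content is set, and with `TR_vol` of one to two
seconds the first-shot convention would lag the truth by half a volume
and dominate the effect-size error budget ("start" remains available).

Voxels whose temporal standard deviation falls below $10^{-5}$ of their
mean (floored at $10^{-3}$ of the volume's peak mean) are flagged
degenerate, get $t = 0$, and are excluded from threshold sweeps: the raw
container stores data as float32, and temporal variation at the
representation granularity must not reach a noiseless $t$ test.

Detection is scored against the known ROI with confusion counts,
precision, recall, balanced accuracy, and the precision–recall curve
(activation is rare, so PR is preferred to ROC); the PR-AUC uses
trapezoidal integration over recall with the recall-0 endpoint closed by
duplicating the first precision. Image quality is PSNR (peak referenced
to the ideal contrast at TE) and SSIM (Gaussian window, standard
constants); temporal SNR is reported both raw and after regressing out
the task component, since genuine activation would otherwise inflate the
apparent noise. Effect-size recovery is measured as
$\hat\beta / (w_{GM}\,\mu_{GM})$ — the modulation of the gray-matter
compartment — because the BOLD factor multiplies only the GM part of a
voxel's signal; the uncorrected ratio to the full baseline is attenuated
by the GM volume fraction (about 0.69 on the synthetic phantom), which
is partial-volume physics, not an estimation error.

## The synthetic phantom

`make_synthetic_phantom()` builds three nested smoothed ellipsoidal
shells (WM core, GM shell, CSF rind) with a seeded low-frequency radius
perturbation, Gaussian-smoothed into fuzzy fractions that never sum
above 1. It emulates what the pipeline actually needs from an anatomy:
a compact head support, a closed gray-matter shell in which an ROI can
be placed, tissue-specific relaxation, and partial-volume boundaries. It
does not emulate cortical folding, vasculature, susceptibility
interfaces, or more than three tissue classes — so passing tests
demonstrate correctness of the acquisition/reconstruction/scoring chain,
not realism of anatomy-dependent effects (e.g. the exact spatial
statistics of aliasing, or off-resonance behaviour near air cavities).
Real tissue maps can be supplied as per-tissue NIfTI fractions through
`read_phantom_nifti()`.

The ROI is the fuzzy GM segmentation (threshold 0.5 by default —
majority fraction) intersected with an ellipsoid placed posteriorly,
mimicking an occipital activation site.

## Scenario orchestration and reproducibility

`run_scenario()` drives the whole chain from one YAML description;
presets ship in `inst/scenarios/` (a full-scale Cartesian run and an
accelerated stack-of-spirals run, with desk-scale `tiny_*` variants; an
import-based preset expects an external trajectory file). Timing
derives from the shot budget: `n_shots = floor(run_length / TR_shot)`,
`TR_vol = N_s · TR_shot`, trailing shots that do not fill a volume are
dropped with a warning. Every random draw — phantom perturbation, noise
per shot, dynamic plane selection per frame — is sub-seeded from the
single master seed, so a rerun with the same configuration and seed
reproduces the raw-data container and the report byte for byte. The
manifest records the configuration, its hash, versions, and per-stage
wall times.

The raw container is a reduced ISMRMRD-style dialect: the same
per-acquisition record content (counters, per-sample trajectory,
interleaved complex float32 data) in a self-contained little-endian
binary layout with a JSON header, documented in the package source —
chosen so the reader requires nothing beyond base R.

## Numerical choices and test scale

The test suite and the acceptance script run at desk scale by design:
$16^3$ phantoms for unit-level checks, $32^3$ for the end-to-end
detection run (75 frames, 2400 shots), $8^3$ grids against the
brute-force DFT oracle, $10^5$ draws for noise calibration and $10^5$
voxels for type-I-error control. These sizes were chosen so each
property is measured well inside its tolerance (e.g. Monte-Carlo
standard errors a factor of three below the asserted bounds) while the
whole suite stays in the minutes range on a single core. The T2*
artifact bound for fully sampled EPI (maximal voxel discrepancy between
the two engines, about 2.3% of the peak at $32^3$ with default tissues)
is insensitive to the phantom seed.

## Known limitations

* No motion, physiological noise, or scenario-level off-resonance
  content: the handler and interpolator interfaces support them, but
  only the BOLD handler ships.
* Frame-wise reconstruction only; no low-rank + sparse or learned 4D
  methods.
* Single-echo GRE only; the steady-state contrast equation would have
  to be replaced for spin-echo or multi-echo sequences.
* Coil sensitivities and (when used) field maps are oracles shared
  between simulation and reconstruction; estimation error is out of
  scope.
* The BOLD effect modulates magnitude only — the phase of the object is
  untouched by design.
* The exact non-uniform DFT makes fully 3D non-Cartesian runs at large
  matrix sizes slow; stacked and Cartesian readouts take fast exact
  paths.
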