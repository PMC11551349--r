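---
title: "Models and methods behind ramanmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ramanmix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramanmix)
```

This vignette documents the models implemented by `ramanmix`, their
assumptions, the tunable parameters and defaults, the numerical choices
made where the design was genuinely open, and what the synthetic-data
checks do and do not establish about real Raman data.

## Mixing models and the unmixing problem

A Raman spectrum over `b` wavenumber bands is treated as a vector
`x ∈ ℝᵇ`. Under the linear mixing model (LMM), `x = Mα (+ ε)`, where the
`b × n` nonnegative matrix `M` holds the endmember signatures and
`α ∈ ℝ₊ⁿ` the fractional abundances, subject to the abundance
nonnegativity constraint (ANC) and, when abundances are proportions, the
sum-to-one constraint (ASC). The bilinear Fan model adds every ordered
pairwise interaction `αₖmₖ ⊙ αₗmₗ`, a first-order account of multiple
scattering between species sharing the focal volume. Internally
endmembers are stored as rows of an `n × b` matrix (matching the
spectra-in-rows dataset layout); the `b × n` column convention of the
LMM is honored at the decoder-weight boundary by transposing.

Two container decisions matter downstream. Intensities are *not* forced
nonnegative: the LMM noise term and baseline subtraction both push bands
below zero, so nonnegativity is an invariant of endmembers and
abundances only. And scene geometry is pure metadata: pixels are stored
row-major with the origin top-left and z-layers outermost, so
`reshape_scene()` never touches intensity values.

## Unmixing autoencoders

The autoencoder formulation makes the decoder the mixing function. The
encoder `E: ℝᵇ → ℝᵐ` produces latent codes `z`, interpreted as
abundances; the decoder is a single linear layer without bias and with
nonnegative weights, `x̂ = Wz`, whose columns are interpreted as
endmembers, or its Fan extension
`x̂ = Wz + Σₖ Σ_{l≠k} zₖwₖ ⊙ zₗwₗ`. The decoder is the exact algebraic
mirror of the generator's mixer — `decode()` and `mix_spectra()` agree to
machine precision for matching model kinds, and a test enforces this — so
a trained Fan decoder cannot drift from the simulated physics.

Constraints are architectural rather than penalized:

* ANC + ASC: a row-softmax latent activation.
* ANC only: the softly rectified tanh `(1/γ)·log(1 + exp(γ·tanh(x)))`
  with `γ = 10`, strictly positive and bounded just above 1
  (`≈ 1.0000454`), so codes behave like fractional abundances without
  being forced onto the simplex.
* `W ≥ 0`: after *every* Adam step the decoder weights are projected
  onto the nonnegative orthant (a projection, not a penalty — the
  literal reading of clipping during training). The per-epoch minimum
  decoder weight is recorded so tests can assert the constraint at every
  checkpoint.

Training is self-supervised with the spectral angle distance
`SAD(x, x̂) = arccos(⟨x, x̂⟩ / ‖x‖‖x̂‖)` averaged over the minibatch;
`loss = "sad_mse"` adds `λ·MSE` with `λ = 1000` to break scale
invariance where absolute intensity is informative (high-SNR data with a
weak solvent endmember). The MSE term averages over bands; whether to
normalize over bands or sum was open, and the band mean was chosen so
`λ` has the same meaning at any `b` (the choice is recorded in the
config). Defaults: Adam at learning rate 0.001, batch size 64
(unspecified upstream; 64 is stable on 10k-spectrum datasets at desktop
scale and is configurable), 10 epochs for synthetic-scale data.

### Encoders

* **dense** — `b → 128 → m`, Leaky ReLU slope 0.02.
* **deep_dense** — hidden widths 512, 256, 128, 64, 32.
* **conv** — two parallel 1D convolution banks (16 filters of length 3
  and 16 of length 5, ReLU, zero padding) over the raw spectrum; the 32
  channels are merged back to width `b` by a position-wise linear map
  across channels, then fed to the dense encoder. The "merge" layer was
  open to interpretation; the position-wise reading is the minimal one
  that restores dimension `b` before the dense head.
* **transformer** — each of the `b` scalar samples is a token, linearly
  embedded to width 32; one transformer block (2 attention heads of size
  32, feed-forward 64 → 32 with ReLU, dropout 0.10 and layer
  normalization after both sublayers) processes the token sequence,
  which is then mean-pooled and passed to the final dense layer of size
  `m`. Scalar-token embedding and the absence of positional encoding
  are interpretations of an underspecified design; a sinusoidal
  positional encoding is available behind
  `encoder_spec(positional_encoding = TRUE)`, and mean pooling was
  chosen over flattening to keep the head size independent of `b`.
* **conv_transformer** — the convolution banks produce the 32-channel
  token sequence directly (the transformer width is therefore fixed at
  32 for this encoder).

All forward and backward passes run on a small reverse-mode autodiff
engine written for this package; every architecture's gradients are
checked against central finite differences in the test suite (relative
error ≤ 1e-4 at perturbation 1e-6). Weights initialize Glorot-uniform
from the training seed, so a fit is bit-reproducible given (seed,
config, data). The decoder can be pre-initialized from a supplied
endmember set and optionally frozen, which turns the model into a
nonblind abundance estimator against known signatures.

Numerical guards: the training loss clips the cosine to
`[-1 + 1e-7, 1 - 1e-7]` before `arccos` so the gradient
`-1/√(1-c²)` stays finite on near-perfect reconstructions. The *metric*
`sad()` clips to exactly `[-1, 1]`: a guard band there would floor every
perfect match at `acos(1 - 1e-7) ≈ 4.5e-4` rad and mask genuinely exact
recovery.

## Classical comparators

**VCA** projects the data to an `n`-dimensional signal subspace
(truncated SVD), using a projective projection when the estimated SNR
exceeds the conventional `15 + 10·log₁₀(n)` dB threshold and a
mean-removed affine lift otherwise, then grows the endmember set by
repeatedly taking the data point most extreme along a random direction
orthogonal to the span of the current set. **N-FINDR** inflates a
simplex: in an `(n-1)`-dimensional principal subspace it starts from `n`
random *distinct* spectra and sweeps all (vertex, pixel) replacements,
accepting any that increase `|det([1; V])|`, until a full sweep makes no
improvement (at most `nfindr_max_sweeps = 10`). Initializing from
distinct spectra matters on patchwise-constant scenes: duplicate initial
vertices give a zero-volume simplex that no single replacement can
improve. Both extractors return rows of the data (the pure-pixel
assumption), break extreme-point ties to the lowest pixel index, and are
deterministic given their seed. Selected pixels can dip below zero from
dark noise, so extractor outputs are projected onto the nonnegative
orthant to satisfy the endmember convention.

**NNLS** solves `min_{α≥0} ‖Mᵀα − x‖₂` per spectrum via Lawson–Hanson
(`pracma::lsqnonneg`). **FCLS** adds the ASC through the standard
augmented row of weight `δ = 1e5` followed by renormalization to an
exact unit sum (tolerance 1e-6 by construction). The active-set solver
can stall at that row scaling when endmembers are near-collinear, so the
implementation backs `δ` off by decades (never below 100) for the
affected spectrum; because of the final renormalization the solution is
insensitive to the precise `δ`, which grid-search oracle tests confirm
at 1e-6.

## The synthetic generator

The generator emulates the benchmark study conditions and is the basis
of most tests; its defaults *are* those conditions.

* **Endmembers** — `npeaks ~ U{5..9}` Gaussian peaks on `b = 1000`
  bands; peak height `h = h1·h2` with `h1 = 1 + 5·h_β`,
  `h_β ~ Beta(1, 3)` (so `E[h1] = 2.25`), `h2 ~ U(0.1, 1)`; center
  `~ U(10, b−10)`; width `σₚ = wₚ·σ`, `σ ~ U(0.1, 1)` in band units with
  `wₚ = 1` for clean peaks. The peak expression `hₚσₚ√(2π)·N(bₚ, σₚ)` is
  read as a Gaussian density rescaled so its maximum equals `hₚ`. Taken
  at face value these clean peaks are at most one band wide — sharper
  than experimental Raman lines; the law is reproduced as stated, and a
  `width_multiplier` knob (default 1) exists for visually broader peaks.
  *Noisy* endmembers add `U{50..99}` small peaks with `h1 = 1/3` and
  `wₚ = 2`; whether the small peaks redraw `h2` was unstated, and they
  do (the minimal deviation from the clean-peak law). Every per-peak
  draw is recorded on the returned object so the distributional laws are
  directly testable.
* **Scenes** (all ANC+ASC exact by construction) — *Chessboard*:
  100 × 100 pixels in 20 × 20 one-hot patches, each patch's endmember
  uniform i.i.d.; with 25 patches and 5 endmembers a seed misses some
  endmember ~2% of the time, so benchmark fixtures use
  `require_all_endmembers = TRUE`, which redraws the assignment (the
  draw count is recorded). *Gaussian*: `n` isotropic bumps equally
  spaced on the scene diagonal, pixel-normalized; the spatial spread was
  unstated and defaults to `H/n` pixels, which produces the intended
  range of overlaps. *Dirichlet*: i.i.d. symmetric Dirichlet(1) — the
  canonical uniform-on-the-simplex "random mixture of everything", again
  an unstated concentration chosen once.
* **Artifacts** — per spectrum: i.i.d. `N(0, σ_N)` dark noise on every
  band; with probability `p_B` the smooth baseline
  `B_j = h_B·atan(π·j/b)` (1-based `j`); with probability `p_S` one
  cosmic spike of magnitude `h_S·U(0.75, 1.25)` at a band uniform on
  `{2, …, b−2}` (read as a 1-based discrete uniform; exactly one spike
  per hit spectrum). Defaults `σ_N = 0.1`, `p_B = 0.25`, `h_B = 2`,
  `p_S = 0.1`, `h_S = 5`. Flags record which artifact hit which
  spectrum.
* **Scenarios** — `ideal` (clean, linear, no artifacts), `artifacts`
  (clean + artifacts), `realistic` (noisy endmembers + artifacts),
  `bilinear` (noisy + Fan + artifacts). `bilinear` × Chessboard is
  rejected: one-hot abundances annihilate every cross term.
* **Reproducibility** — one root seed expands into independent child
  streams per stage (endmembers, scene, artifacts), so the same
  endmembers recur across scenarios and each stage is independently
  reproducible.

What the generator does *not* emulate: instrument response (detector
binning, laser lineshape), wavenumber-calibration error, spatially
correlated noise, and the band-widths of real Raman lines. Tests passing
on synthetic data therefore establish algorithmic correctness under the
stated laws, not instrument-level fidelity; the preprocessing presets
mirror protocols for real data but are exercised here on simulated
fixtures.

## Preprocessing

`crop_spectra()` keeps bands with axis values in a closed cm⁻¹ interval
(membership by wavenumber, never index). `despike()` flags bands whose
modified z-score of first differences, `0.6745·(∇y − med)/MAD`, exceeds
the threshold (default 8) and replaces them by the mean of non-spike
neighbors within `kernel = 3` bands, one-sided at boundaries; on a
noiseless spectrum whose gradient is mostly zero the MAD collapses and
any isolated peak looks like a spike — an inherent property of the
scheme, which assumes the gradient distribution is set by noise or dense
spectral structure. `denoise_savgol()` wraps `signal::sgolayfilt`
(cubic, window 7 by default; reproduces polynomials up to the fit order
exactly). Baseline correction is a Whittaker smoother with
second-difference penalty: **AsLS** iterates asymmetric weights (`p` for
points above the baseline, `1 − p` below; defaults `λ = 1e6`,
`p = 0.01`, 50 iterations, tolerance 0.001), and **ASPLS** (defaults
`λ = 1e5`, 100 iterations) replaces the fixed asymmetry with a logistic
reweighting of the residuals plus a penalty locally scaled by
`|r|/max|r|`; published ASPLS variants differ in these internals, and
any implementation with the stated (λ, order, iterations, tolerance)
contract is acceptable — this one removes an amplitude-2 arctan baseline
to below 5% of its height, which is the property the tests pin.
Normalization is global (`global_vector`: divide by the dataset-wide
max |value|; `global_minmax`: affine map of the dataset range onto
[0, 1]). The presets `"sugar"` (crop 400–1800 cm⁻¹, ASPLS, vector
normalization) and `"cell"` (crop 700–1800 cm⁻¹, despike, Savitzky–
Golay, AsLS, min-max) compose these with the parameters above and log
every executed step.

## Evaluation protocol

Estimated endmembers are matched to ground truth by the Hungarian
algorithm (an O(n³) potentials implementation, verified against
exhaustive search for all `n_true ≤ 6` in tests; no assignment solver is
available among the package's dependencies) minimizing total SAD. When
`n > n_true` endmembers were extracted, surplus estimates stay
unmatched and only the `n_true` matched pairs — and the correspondingly
permuted abundance columns — enter the metrics. Per dataset, SAD is
aggregated as the *mean* over matched endmembers and abundance MSE
(`‖α − α̂‖²/n` per spectrum) as the mean over spectra; whether per-run
SAD should be the mean or the sum over endmembers was unstated, and the
mean is used and flagged in outputs.

`run_benchmark()` spans the 11 dataset variants (4 scenarios × 3 scenes
minus bilinear Chessboard) with shared dataset/model seeds across
scenarios, latent dimension 5 on `ideal` and 6 elsewhere, linear
decoders on linear variants and Fan decoders on bilinear ones, and both
constraints enforced. The full scale mirrors the benchmark study
(100 × 100 scenes, 5 × 5 replicate seeds); the default `reduced` scale
(50 × 50 scenes, 2 × 2 replicates) preserves the grid structure at
desktop cost, and the test suite exercises the bookkeeping at 10 × 10 ×
50 bands. `profile_runtime()` times each method end to end — including
autoencoder training, the convention that makes AE and classical costs
comparable — on ideal Chessboard datasets of perfect-square sizes, three
repetitions per cell, CPU only, excluding generation and I/O.

Problem sizes used by the shipped tests were chosen for desktop-scale
runs: the recovery checks train on one full-size 10,000-spectrum
dataset (five model seeds), the head-to-head ordering check uses 50 × 50
Dirichlet scenes with 2 × 2 replicates, and unit tests use scenes of a
few hundred pixels with 40–200 bands. The transformer encoders are
exercised at reduced band counts: attention is quadratic in `b`, and the
pure-R engine makes full-length (b = 1000) transformer training a
batch-job rather than a test-suite workload.

## Known limitations

* The autodiff engine is single-threaded R; dense and convolutional
  models train comfortably at benchmark scale, but transformers at full
  spectral length are slow (no GPU path is provided, by design).
* `extract_endmembers()` lifts a decoder column that collapsed to all
  zeros (an unused surplus component) to a tiny constant so the
  container invariant holds; the accompanying warning should be heeded
  when `m` greatly exceeds the true endmember count.
* The chessboard scene's uniform patch assignment does not guarantee
  every endmember appears; use `require_all_endmembers = TRUE` when a
  complete ground truth is required.
* FCLS enforces the ASC through a soft augmented row plus
  renormalization; abundances are exact to 1e-6, not to machine
  precision.
* Serialized binary containers use R's native RDS arrays; no vendor
  instrument formats (WDF, SPC) are read.
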