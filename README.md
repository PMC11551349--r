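# ramanmix

Hyperspectral unmixing of Raman spectra with physics-constrained
autoencoders, classical geometric comparators, and a synthetic
Raman-mixture generator with known ground truth.

## The problem

Raman measurements from complex samples — cells, tissue, chemical
mixtures — are superpositions of the signatures of the pure chemical
species present. A measured spectrum `x ∈ ℝ₊ᵇ` over `b` wavenumber bands
is modelled under the linear mixing model (LMM) as

    x = M α = Σᵢ αᵢ mᵢ,

where the columns `mᵢ` of the nonnegative `b × n` matrix `M` are the
*endmember* signatures and `α` the *fractional abundances*, constrained
nonnegative (ANC, `αᵢ ≥ 0`) and often sum-to-one (ASC, `‖α‖₁ = 1`).
Nonlinear interactions are captured by the bilinear Fan model, which adds
all pairwise Hadamard terms `αₖ mₖ ⊙ αₗ mₗ`. *Hyperspectral unmixing* is
the inverse problem: recover `M` and the `α`s from the measurements alone.

`ramanmix` is aimed at spectroscopists and chemometricians who need
blind (or nonblind) unmixing of single-point, imaging, or volumetric
Raman scans. It provides:

* **Unmixing autoencoders** — self-supervised models whose decoder *is*
  the mixing function: a single nonnegative linear layer `x̂ = W z` (or
  its bilinear Fan extension), so the decoder weights are the learned
  endmembers and the encoder's latent activations the abundances. The
  ANC/ASC are built into the architecture (softmax latent for ANC+ASC, a
  softly rectified tanh `log(1 + exp(γ tanh x))/γ`, `γ = 10`, for ANC
  alone; decoder weights clipped to `≥ 0` after every optimizer step).
  Five encoders are available — dense, deep dense, 1D-convolutional,
  transformer, and convolutional transformer — trained with Adam on the
  scale-invariant spectral angle distance (SAD) loss, optionally with an
  added MSE term (`SAD + λ·MSE`, `λ = 1000`). The networks and their
  reverse-mode gradients are implemented natively in R and verified
  against finite differences in the test suite.
* **Classical comparators** — N-FINDR (simplex-volume maximization) and
  vertex component analysis (VCA, orthogonal-projection extremes) for
  endmember extraction; NNLS and fully constrained least squares (FCLS)
  for abundance estimation.
* **A synthetic Raman-mixture generator** — endmembers as superpositions
  of Gaussian peaks with published stochastic laws, three abundance
  scenes (Chessboard / Gaussian / Dirichlet), linear or Fan mixing, and
  realistic artifacts (Gaussian dark noise, arctan baselines, cosmic
  spikes), with the full ground truth in a generation record.
* **Preprocessing recipes** — spectral cropping, modified-z-score
  despiking, Savitzky–Golay denoising, AsLS/ASPLS baseline correction,
  global normalization, plus the named presets `"sugar"` and `"cell"`.
* **Evaluation** — Hungarian matching of estimated to true endmembers
  under SAD, abundance MSE, a benchmark grid over 11 dataset variants,
  and a runtime profiler; results come back as tibbles ready for dplyr
  and ggplot2 (`autoplot()` methods included).

## Worked example

Generate a default synthetic benchmark dataset (10,000 spectra on a
100 × 100 Chessboard scene, 1,000 bands, 5 clean endmembers, linear
mixing, no artifacts), unmix it blind with a dense autoencoder, and
score against the ground truth:

```r
library(ramanmix)

sim <- generate_raman_dataset("chessboard", "ideal", seed = 42)
sim
#> <raman_simulation> scenario 'ideal', scene 'chessboard', seed 42
#> <spectral_dataset> 10000 spectra x 1000 bands, axis 1..1000 cm^-1, scene 100x100

res <- unmix(sim$dataset, method = "dense", n_endmembers = 5,
             epochs = 10, seed = 1)
evaluate_unmixing(res, sim$record)
#> # A tibble: 1 × 5
#>   method mean_sad abundance_mse n_est n_true
#>   <chr>     <dbl>         <dbl> <int>  <int>
#> 1 dense  0.000951 0.00000000109     5      5

glance(res$fit)
#> # A tibble: 1 × 8
#>   encoder decoder     m asc   epochs n_train final_loss min_decoder_weight
#>   <chr>   <chr>   <dbl> <lgl>  <int>   <int>      <dbl>              <dbl>
#> 1 dense   linear      5 TRUE      10   10000    0.00121                  0
```

`mean_sad` is the Hungarian-matched mean spectral angle between learned
and true endmembers in radians (0.00095 rad ≈ 0.05°: the decoder columns
are the true signatures to visual identity), and `abundance_mse` the mean
per-spectrum `‖α − α̂‖²/n` (≈ 10⁻⁹: the softmax latent reproduces the
one-hot patch abundances). `min_decoder_weight = 0` confirms the
nonnegativity projection was active throughout. On this ideal scene with
abundant pure pixels the classical pipeline is exact as well
(`unmix(sim$dataset, "vca", n_endmembers = 5)` gives matched SAD
≈ 1.5 × 10⁻⁸); the autoencoders' advantage appears on noisy, artifact-laden
and bilinear variants (`scenario = "realistic"`, `"bilinear"`), which the
test suite checks head-to-head.

`autoplot(res$endmembers)`, `autoplot(res$abundances)` and
`autoplot(res$fit)` draw the signatures, the abundance scene maps and the
training trace; `run_benchmark()` and `profile_runtime()` reproduce the
method-comparison grid and wall-time scaling tables. A command-line
interface (`inst/cli/ramanmix`) exposes `generate`, `preprocess`,
`unmix`, `evaluate`, `benchmark` and `profile`, writing a reproducibility
manifest beside every output.

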