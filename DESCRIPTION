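Package: ramanmix
Title: Hyperspectral Unmixing of Raman Spectra with Physics-Constrained
    Autoencoders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for blind and nonblind hyperspectral unmixing of Raman
    spectra. Implements physics-constrained autoencoder models (dense, deep
    dense, convolutional, transformer and convolutional-transformer encoders;
    linear and bilinear Fan decoders) trained with a spectral-angle loss, the
    classical geometric comparators N-FINDR and vertex component analysis
    (VCA) with non-negative and fully constrained least-squares abundance
    estimation, a synthetic Raman-mixture generator with known ground truth
    (Gaussian-peak endmembers, Chessboard/Gaussian/Dirichlet abundance
    scenes, linear and bilinear Fan mixing, dark noise, arctan baselines and
    cosmic-spike artifacts), composable preprocessing recipes (cropping,
    despiking, Savitzky-Golay denoising, asymmetric least-squares baseline
    correction, normalization), and a ground-truth evaluation protocol based
    on Hungarian endmember matching with spectral-angle and abundance
    mean-squared-error metrics, plus benchmarking and runtime-profiling
    harnesses and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    dplyr,
    generics,
    ggplot2,
    Matrix,
    pracma,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
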