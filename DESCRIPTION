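Package: EcoSound
Title: Acoustic Indices and Sparse Spectro-Temporal Decomposition for
    Ecoacoustics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Community-level ecoacoustic analysis of soundscape recordings.
    Computes the standard acoustic indices (NDSI, acoustic entropy H with its
    spectral and temporal factors, ADI, AEI, ACI and the Bioacoustic Index)
    from WAV audio, and provides spectro-temporal alternatives that preserve
    joint time-frequency structure: sparse approximation of spectrogram
    patches with learned or Gabor dictionaries via Orthogonal Matching
    Pursuit, and shift-invariant 2D probabilistic latent component analysis
    (SI-PLCA2D) of constant-Q spectrograms with a sparsity prior providing
    automatic relevance determination. A synthetic dawn-chorus generator with
    known species richness, call timing and signal-to-noise ratio makes every
    behaviour testable without field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, graphics, signal, jsonlite, optparse
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'wav.R'
    'audio-spectra.R'
    'indices.R'
    'sparse-dict.R'
    'plca.R'
    'synth.R'
    'cli.R'
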