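Package: blockspec
Title: Blocked Spectral Analysis and Time-Frequency Transforms for Large Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signal processing and spectral analysis for long, possibly
    out-of-core, uniformly sampled time series such as extracellular
    electrophysiology recordings. Provides linear-phase FIR filter design
    with exact spline transition bands, blocked overlap-save FFT
    convolution with fused group-delay correction and downsampling,
    multitaper spectra and spectrograms built on discrete prolate
    spheroidal sequences, analytic (Morse, Morlet, Bump) continuous
    wavelet transforms computed purely in the frequency domain, wavelet
    synchrosqueezing, analytic-signal envelope and phase estimation,
    seeded synthetic-signal generators, and a uniform dry-run /
    preallocated on-disk output contract for computations whose inputs or
    outputs do not fit in memory.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    yaml,
    signal,
    optparse,
    parallel,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
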