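---
title: "Methods and design notes for blockspec"
author: "blockspec maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for blockspec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`blockspec` is a signal-processing toolbox for long, uniformly sampled
recordings — the motivating case is extracellular electrophysiology,
where a single session can be hours of data across hundreds of channels,
but nothing in the package is specific to neural data. This vignette
explains the models and algorithms behind each family of functions, the
parameters that matter and their defaults, the numerical conventions the
implementation commits to, and what the synthetic test surface does and
does not establish about real data.

## FIR filter design with spline transition bands

`lowpass_prototype()` evaluates a closed-form linear-phase low-pass
impulse response. In radian frequency $\omega = 2\pi f/f_s$, with
transition edges $\omega_1 < \omega_2$, midpoint
$\omega_0 = (\omega_1+\omega_2)/2$ and width
$\Delta = \omega_2 - \omega_1$, the taps at integer offsets $n$ from the
center are

$$h(n) = \frac{\sin(\omega_0 n)}{\pi n}
  \left[\frac{\sin(\Delta n / 2p)}{\Delta n / 2p}\right]^{p}.$$

The first factor is the ideal low-pass at the transition midpoint; the
bracketed factor is, in the frequency domain, the $p$-fold convolution
of unit-area boxcars of total width $\Delta$. Consequently the
transition band is exactly $[\omega_1, \omega_2]$, the response passes
through exactly one half of the gain step at $\omega_0$ (−6.02 dB for a
1 → 0 step), and the roll-off becomes smoother and faster-decaying as
the spline power $p$ grows. Because the design is analytic — no linear
system is solved and no exchange algorithm iterates — it has none of the
failure modes of least-squares or Remez designs (all-zero solutions for
narrow low bands, non-convergence), while remaining $L_2$-optimal in the
sense inherited from the ideal prototype. The default $p = 2$ gives a
smooth, compactly supported spline transition; it is exposed on every
design entry point.

`design_fir()` composes arbitrary piecewise-constant magnitude
responses as a telescoping sum of prototypes,
$h = \sum_k (g_k - g_{k+1})\,\mathrm{LP}_k + g_{K+1}\,\delta$. The
construction was an open choice (any basis of low-passes spans the same
responses); the telescoping form was chosen because it preserves exact
tap symmetry and the transition-midpoint property by construction.
Tap counts are forced odd so the group delay $(M-1)/2$ is an integer
number of samples — required for exact delay correction during
filtering. `estimate_taps()` is search-based (doubling plus bisection
against the measured stop-band ripple of a canonical mid-band design):
there is no closed-form tap-count rule for this prototype family, and a
measured criterion stays honest about what a given length actually
achieves.

## Blocked overlap-save convolution

`filter_data_fir()` evaluates long convolutions with overlap-save FFT
blocks: each FFT of length $L$ (5-smooth, by default the smallest such
length at least four times the kernel length) produces
$L - M + 1$ new output samples. Three operations are fused into this
single pass — convolution, group-delay correction (the output is the
"same"-length convolution advanced by $(M-1)/2$ samples), and
decimation by `ds` (only indices $0, ds, 2\,ds, \dots$ of the corrected
stream are kept) — so a full-rate intermediate is never materialized.
Boundary policy is zero extension: samples within a group delay of
either end are attenuated, and downstream analyses should treat them as
tainted. The per-block arithmetic is independent of how blocks are
grouped into chunked reads and of how channels are distributed across
workers, so the output is invariant to `chunk_hint` and `n_workers`
(and bit-identical between in-memory and on-disk outputs); the test
suite asserts this directly.

## Multitaper spectral estimation

`get_tapers()` computes discrete prolate spheroidal sequences — the
orthonormal tapers maximizing spectral energy concentration in
$[-W, W]$ — as eigenvectors of the symmetric tridiagonal matrix that
commutes with the concentration operator, using LAPACK's `dstevr` for
the top $L$ eigenpairs, so taper generation scales to long windows.
Concentration values are evaluated as quadratic forms of the sinc
kernel via FFT autocorrelation in $O(N\log N)$; for small $N$ the test
suite checks both quantities against the dense concentration-matrix
eigenproblem. `mtm_spectrum()` averages the $L$ per-taper direct
estimates with uniform $1/L$ weights; adaptive (eigenvalue-weighted)
combination is deliberately out of scope. Conventions worth knowing:

* The `half_bandwidth_hz` argument is the one-sided half-bandwidth $W$.
  Smoothing spans $2W$ of spectrum, and the default taper count is
  $\max(1, \lfloor 2NW/f_s\rfloor - 1)$, the Shannon-number heuristic.
* Output is one-sided with DC and Nyquist not doubled, so white noise
  of variance $\sigma^2$ sits at $2\sigma^2/f_s$ and the integrated
  spectrum recovers $\sigma^2$.
* No detrending is applied unless `detrend = "mean"` is requested.

`mtm_spectrogram()` applies the estimator over sliding windows (shared
taper set, centered timestamps, trailing partial window dropped).

## Analytic-wavelet CWT in the frequency domain

The CWT is computed per scale as the inverse DFT of
$X(\omega_k)\,\Psi^*(a\,\omega_k)$ — a pointwise product on the
discrete frequency grid. The wavelet is only ever sampled in the
frequency domain: a truncated time-domain wavelet would, by the Gibbs
phenomenon, leak onto negative frequencies and destroy numerical
analyticity precisely at scales near Nyquist, which is where analytic
phase estimates are most fragile. Three analytic families are provided
(Morse with $\gamma, \beta$; Morlet with $\omega_0$; Bump with
$\mu, \sigma$), all normalized to peak value 2 so a unit real tone at a
scale's center frequency produces coefficients of magnitude about 1.
Scales map to frequencies through the wavelet's peak frequency (the
standard convention for analytic families), on geometric grids with a
fixed number of voices per octave. Defaults: Morse $\gamma = 3$,
$\beta = 20$ (narrowband; $\beta = 10$ is a common temporally-compact
alternative), Morlet $\omega_0 = 6$, Bump $\mu = 5$, $\sigma = 0.6$.

**Boundary convention.** The transform is defined on the signal-length
DFT grid, so boundaries are periodic: the `full` method is one exact
length-$N$ transform per scale, and coefficient rows of real input are
exactly one-sided by construction. Zero extension was considered and
rejected because truncating a padded result back to $N$ samples
measurably breaks row analyticity, and because no finite block length
reproduces zero-extended output at scales whose frequency response has
not decayed at Nyquist. Edge samples within a wavelet support
half-width of either end mix information from both ends of the
recording and should be treated as tainted; no cone-of-influence
masking is applied.

**Blockwise path.** `method = "overlap_save"` convolves block by block
(reading input with wraparound to honor the periodic convention), with
per-scale FFT lengths sized from the wavelet's measured time support:
the half-width is grown until the $\ell_1$ mass of the kernel outside
the kept window falls below $10^{-9}$ of its total, which bounds the
relative truncation error near $10^{-9}$ — comfortably inside the
$10^{-8}$ agreement the tests demand between the two paths. (A simpler
peak-relative amplitude threshold was rejected: it leaves tail mass
orders of magnitude above the target agreement.) Scales whose
frequency response exceeds $10^{-12}$ of peak at Nyquist have kernels
with $1/t$ ringing and no usable compact support; both paths compute
those scales with the signal-length transform. Scales are independent
work items (`n_workers`), and with a preallocated output store each row
is written as produced, so the full matrix never resides in memory.

## Synchrosqueezing

`wsst()` sharpens the CWT along the frequency axis. The time
derivative of the coefficients is computed by the same pipeline with an
extra $j\omega$ multiplier (one conjugation convention shared by both
transforms, so the ratio below is exact for analytic tones), and the
phase transform

$$\omega_f(a, b) = \frac{1}{2\pi}\,
  \Im\!\left[\frac{\partial_b W(a,b)}{W(a,b)}\right]$$

gives each coefficient an instantaneous frequency. Coefficients are
then added into the frequency bin containing their $\omega_f$ — a
simple additive accumulation, with no $da/a$ weighting; this is a
deliberate literal choice that makes per-column mass conservation exact
and keeps the operation a redistribution of CWT content rather than a
reconstruction operator (reconstruction-oriented variants weight by
scale). Points with $|W|$ below `eps_rel` (default $10^{-8}$) of the
global maximum are unmapped and dropped, as is mass falling outside the
bin range; nothing is redistributed. Bins default to the analysis
grid's own centers with half-open edges at geometric means of
neighbors, values at the top edge dropped. Reassignment acts only along
frequency, so time resolution and uniform time sampling are preserved.

## Analytic signal, envelope, phase

`analytic_signal()` uses the one-sided spectrum construction (DC and
even-length Nyquist unscaled, positive frequencies doubled, negative
zeroed) at the exact data length for every $N$ — padding to a
convenient FFT length and truncating back would reintroduce
negative-frequency content, so it is deliberately avoided at some FFT
cost for awkward lengths. The real part equals the input to machine
precision and odd lengths simply lack a Nyquist bin. Phase is
cosine-referenced (zero at local maxima of the band-limited
oscillation), wrapped to $(-\pi, \pi]$ unless unwrapping is requested.
`signal_envelope()` optionally band-passes first (delay-corrected,
through the convolution engine) and applies no smoothing unless a
smoothing filter is passed explicitly.

## Out-of-core execution contract

Every bulk operation works against an *array store*: anything with a
shape, an element type, and sample-axis slice read/write. Backings
provided: an in-memory matrix and a flat binary file with a JSON
sidecar, laid out `(channels, samples)` with each channel contiguous.
The calling pattern for data that does not fit in memory is uniform:
run the entry point with `describe = TRUE` (or `dry_run()`) to get the
exact output geometry, preallocate a disk store of that shape, and pass
it as `out`. Filtering with fused decimation writes only the
downsampled result — the only write path; no full-rate temporary ever
exists. Storage arithmetic uses binary prefixes throughout
(`storage_estimate()`: MiB $= 2^{20}$, GiB $= 2^{30}$ bytes). Input
chunk sizes and worker counts trade memory and wall-clock for nothing
else: results are invariant to both, and byte-identical between
backings.

## Synthetic test surface

The generators in `make_tones()`, `make_chirp()` and
`make_lfp_surrogate()` are the package's entire test surface; no
external recordings are needed. The surrogate emulates the features of
hippocampal field potentials that the analysis methods target: a slow
theta carrier (default 8 Hz), a faster gamma rhythm (60 Hz) whose
envelope is phase-locked to theta with adjustable coupling depth,
optional Gaussian-windowed ripple bursts (200 Hz, 20 ms half-width),
and $1/f$ background noise produced by spectral shaping of seeded white
noise (exponent 1, exposed). Default amplitude ratios (theta 1, gamma
0.3, ripple 1, noise SD 0.2) are typical of well-placed CA1 recordings.
What the surrogate does **not** emulate: nonstationary frequency drift,
asymmetric (sawtooth-like) theta cycles, movement and reference
artifacts, inter-channel correlation structure, and spike
contamination. Tests passing on these fixtures therefore establish the
*numerical* contracts of the methods (oracle equivalence, invariances,
calibration on known ground truth), not robustness to every property of
real recordings.

## Problem sizes and numerical tolerances

The test and reference-computation sizes are chosen to exercise every
code path at desk scale: convolution oracles on $\sim 3\times 10^3$
samples, blockwise-vs-full CWT on $10^4$ samples across 40–57 scales
including near-Nyquist ones, multitaper calibration on 100 seeded
white-noise realizations of $2^{11}$ samples with 8 tapers,
out-of-core equivalence on 4 channels × 4–5 × 10⁴ samples across three
chunk sizes and two worker counts, and the reference filter design at
12 501 taps (the transition-midpoint property is asserted to ±0.1 dB,
which requires $M \gtrsim 20 f_s/\Delta$). Key tolerances: direct-vs-
blocked convolution $10^{-9}$ relative; full-vs-blockwise CWT $10^{-8}$;
row analyticity $10^{-10}$; DPSS energy $10^{-10}$ and orthogonality
$10^{-8}$; SST column conservation $10^{-10}$.

## Known limitations

* FFTs run single-threaded; `fft_threads` in `run_config()` is carried
  for configuration compatibility but does not enable threading.
* Sharp spectral edges at Nyquist make near-Nyquist CWT scales fall
  back to signal-length transforms; for signals much longer than
  memory, keep the grid's top frequency below about 40% of $f_s$ or
  budget for those rows.
* No inverse CWT/SST, no adaptive multitaper weighting, no minimum-
  phase or IIR designs, no streaming/real-time operation.
* Periodic CWT boundaries mean recordings with large DC offsets or
  trends should be detrended before wavelet analysis; edge regions
  within one wavelet support of either end are tainted in any case.
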