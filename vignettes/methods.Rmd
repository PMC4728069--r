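---
title: "Methods: entropy-guided wavelet packet denoising of birdsong"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: entropy-guided wavelet packet denoising of birdsong}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Field recordings of birdsong have a low and variable signal-to-noise
ratio: the song is transient and band-limited, while much of the
background (wind, rain, recorder hiss, distant machinery) is
approximately stationary and, in its high-frequency part, approximately
Gaussian. `wpdenoise` removes this stationary component by shrinkage in
a wavelet packet basis.

The wavelet packet transform recursively splits *both* the low-pass
(approximation) and high-pass (detail) branch of a two-channel filter
bank, so level $L$ holds $2^L$ nodes of equal bandwidth. Unlike the
plain discrete wavelet transform, this resolves high frequencies as
finely as low ones, which matters because birdsong energy commonly sits
between 500 Hz and 10 kHz. In such a basis a tonal, harmonically
structured song concentrates into few large coefficients while
stationary noise spreads over all of them, so soft thresholding

$$\hat s_i = \mathrm{sign}(s_i)\,\max(|s_i| - t,\, 0)$$

suppresses the noise floor at a small, continuous cost to the signal.
Soft rather than hard thresholding is used because the shrinkage map is
continuous and non-expansive, which avoids the ringing that keep-or-kill
thresholding creates around large coefficients.

Two data-driven rules make the procedure self-tuning per recording:

**Depth selection.** The non-normalized Shannon entropy of a node's raw
coefficients,
$$S = -\sum_i s_i^2 \ln s_i^2, \qquad 0 \ln 0 := 0,$$
acts as an impurity measure. The tree is grown top-down one full level
at a time and growth stops at the first level $L$ whose maximum node
entropy is below the maximum at $L+1$; that $L$ is used. Ties (equal
maxima) keep the decomposition going. The depth is additionally capped
at $\min(\texttt{level\_cap}, \lfloor \log_2(n/\ell) \rfloor)$ where
$\ell$ is the filter length, so that every node keeps at least one
filter length of coefficients. Simple narrowband calls stop shallow;
complex broadband songs go deep.

**Threshold selection.** The noise scale $\hat\sigma$ is the population
standard deviation of the level-1 detail node — the finest time scale,
where for band-limited song almost all energy is noise — and the global
threshold is $t = 4.5\,\hat\sigma$, applied to every leaf node. Under
the Gaussian noise assumption $\pm 4.5\sigma$ covers 99.99% of noise
samples, so what survives thresholding is, with high probability,
signal.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `wavelet_name` | `"dmey"` | analysis basis; `select_wavelet()` picks by input–output correlation, and the discrete Meyer wavelet wins on tonal birdsong-like material |
| `level_cap` | 10 | upper bound on tree depth; observed entropy-selected depths rarely approach it |
| `threshold_multiplier` | 4.5 | threshold in units of $\hat\sigma$; larger removes more noise and more signal |
| `threshold_mode` | `"soft"` | `"hard"` available for comparison |
| `boundary_mode` | `"symmetric"` | half-point reflection; `"periodic"` (critically sampled periodization) is exactly energy-conserving for orthonormal wavelets and is used in the energy tests |
| `exempt_approximation` | `FALSE` | leave leaf 0 unthresholded; useful when low-frequency content must survive untouched |
| `post_filter_band` | none | optional `(low, high)` Hz band for the conventional post-filter |

The post-filter (`design_filter()`/`apply_filter()`) is a linear-phase
windowed-sinc FIR design: order chosen from a transition width of 10%
of the governing cutoff, Hamming window up to 53 dB of stopband
attenuation (Blackman beyond), applied with group-delay compensation so
the overall operation is zero-phase. The filter family and order are
not dictated by the denoising model; this choice is predictable,
unconditionally stable and phase-neutral, which is what a measurement
pipeline wants.

## Numerical design choices

**The dmey bank is completed biorthogonally.** The standard 62-tap FIR
approximation of the Meyer scaling filter is only approximately
orthogonal: its lag-0 autocorrelation is 1.00224, and using the same
filter on analysis and synthesis sides leaves a round-trip error of
order $10^{-2}$. We keep the published filter on the analysis side
(coefficients, entropies and thresholds therefore match the standard
table) and compute the synthesis filter as the dual that solves the
perfect-reconstruction conditions $\sum_k s_k h_{k+2m} = \delta_{m0}$,
taking the solution closest to $h$ via a truncated SVD (singular values
below $10^{-8}$ dropped). The correction is about $2\times10^{-3}$ per
tap, the dual keeps a >50 dB stopband, and multi-level round-trips are
exact to about $10^{-10}$. Haar and Daubechies banks are orthogonal and
need no dual; `db1`–`db20` are computed by spectral factorisation of
the Daubechies polynomial rather than stored as tables.

**Boundary handling.** Symmetric (half-point) extension is the default
because reflection introduces no artificial discontinuity at the edges
of an audio excerpt. Periodization is provided because it is critically
sampled: with orthonormal filters the transform is then an orthogonal
matrix and leaf energy equals signal energy to machine precision, which
the tests exploit. Odd-length nodes are padded by repeating the edge
sample and trimmed on reconstruction; every level of the tree is
retained so trimming lengths are always known exactly.

**Interpretation choices where the procedure is underdetermined.**
Several details admit more than one reading; the package fixes them as
follows. "Lowest level detail coefficients" is read as the *level-1*
(finest-scale) detail node, matching standard practice of estimating
$\sigma$ from finest-scale details. The threshold is one global value
applied at every leaf node, not re-estimated per node. The
approximation leaf is thresholded by default (the most literal reading
of "a threshold to each node"); `exempt_approximation` provides the
common alternative. The per-level entropy comparison aggregates by the
maximum over all nodes of a level, not per parent–child triple. The
entropy uses the natural logarithm on raw, unnormalized coefficients,
so it is amplitude-dependent; this is accepted as-is, which is one
reason input normalization (below) matters. Pearson correlation for
wavelet selection is computed over the full-length time-domain samples.

**Amplitude normalization.** WAV input is normalized to $[-1, 1]$ at
load time, and the synthetic fixture generator likewise rescales its
mixture by its peak when that peak exceeds 1, exactly as a recorder's
gain staging would. This is not cosmetic: the entropy
$-\sum s^2 \ln s^2$ changes sign around $|s| = 1$, and feeding the
depth-selection rule signals with amplitudes far above 1 makes the
per-level entropy maxima negative and stops growth at level 1,
destroying the signal. Thresholding itself is scale-equivariant (both
coefficients and $\hat\sigma$ scale together); only depth selection is
amplitude-aware.

**Degenerate inputs.** Silence denoises to silence ($\hat\sigma = 0$,
threshold 0). Constant signals are rejected by `select_wavelet()`
(correlation undefined). Metrics raise explicit degenerate-metric
errors for zero noise power, zero after-variance, and identical
PSNR inputs rather than returning infinities. A band covering the full
spectrum makes the post-filter a no-op by construction.

## The synthetic generator

`noisy_tone_fixture()` emulates the structure of an annotated field
recording: a phase-continuous stepped tone (20/40/80 Hz segments,
100 ms each, by default) with 500 ms of pure noise padded before and
after, standing in for the hand-labelled "silence" margins used to
compute SnNR and the success ratio on real data. Noise colours are
white (i.i.d. Gaussian), pink and brown (white noise spectrally shaped
by $f^{-1/2}$ and $f^{-1}$, DC bin zeroed, renormalized to unit
variance so colour changes only the tilt). "Strength" is an RMS ratio:
noise at 100% of signal RMS means a true SNR of 0 dB. Strengths for
the benchmark sweep default to 25–200%, spanning mild pollution to
noise twice as strong as the signal. Brown noise is renormalized to
unit variance despite its random-walk character so that the strength
parameter stays meaningful. Fixtures carry their ground-truth noise
track, so true SNR is computable alongside the blind SnNR, and the two
can be compared directly.

What the generator does *not* emulate: harmonic stacks, frequency
modulation, reverberation, transient interference (clicks of other
animals, rain drops) and non-stationary noise generally. Passing tests
on these fixtures therefore demonstrates correct mechanics and the
expected stationary-noise behaviour, not performance on real field
recordings; on real data the method's known failure modes (below)
apply.

## Problem sizes used in the tests

The default fixture is 1.3 s at 8 kHz (10 400 samples), for which the
entropy rule typically selects a 7-level tree (128 leaf nodes). The
benchmark sweep runs 3 colours × 5 strengths × 20 seeds = 300
denoising runs; property tests use 100 random round-trips at lengths
512–16 384 and 50 depth-selection fixtures against an exhaustive
oracle. Sigma-recovery uses $2^{15}$-sample unit-variance noise over
20 seeds, and the Gaussian coverage check draws $10^7$ samples.

## Known limitations

* Non-stationary and strongly non-Gaussian noise is not removed; brown
  noise in particular concentrates where the signal lives and survives
  thresholding (the benchmark shows gains near zero). Down-sampling
  (`downsample()`) is the practical rescue when the offending noise is
  above the song's frequency range.
* The entropy depth rule is a heuristic: it compares per-level maxima
  only, and its behaviour is amplitude-dependent by construction.
* Very faint calls embedded in strong noise fall below the $4.5\sigma$
  threshold and are removed along with the noise.
* Overlapping songs are denoised as one signal; no source separation is
  attempted.
* Multichannel recordings are reduced to channel 1.
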