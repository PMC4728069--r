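# wpdenoise

Wavelet packet denoising for birdsong field recordings.

Automated acoustic monitoring leaves ecologists with terabytes of
unattended recordings in which the target vocalisations sit on top of
wind, rain, insects, machinery and recorder self-noise. `wpdenoise`
implements a denoising pipeline built for exactly this situation: it
needs no clean reference signal, adapts its parameters to each
recording, and is followed (optionally) by a conventional band-pass or
low-pass filter keyed to the species' frequency range.

## The algorithm

For a recording `x` sampled at `fs`:

1. **Mother wavelet.** Default is the 62-tap discrete Meyer wavelet
   (`dmey`); `select_wavelet()` can instead pick the candidate that
   maximises the Pearson correlation between the input and its denoised
   output (Haar and Daubechies `db1`–`db20` are also available).
2. **Decomposition depth.** The wavelet packet tree (both approximation
   and detail branches split at every level, `2^L` nodes at level `L`)
   is grown top-down. Using the non-normalized Shannon entropy of a
   node's coefficients `s`,

   `S = −Σᵢ sᵢ² ln(sᵢ²)`   (with 0·ln 0 = 0),

   growth stops at the first level `L` whose maximum node entropy is
   smaller than the maximum at level `L+1`.
3. **Threshold.** The noise scale σ̂ is the standard deviation of the
   finest-scale (level-1) detail coefficients; the threshold is
   `t = 4.5 σ̂`, which covers 99.99% of Gaussian noise.
4. **Shrinkage.** Every leaf node is soft-thresholded:
   `sign(s)·max(|s| − t, 0)`.
5. **Inversion.** The tree is inverted to give the denoised waveform
   (exact reconstruction; the dmey bank is completed biorthogonally so
   round-trips are accurate to ~1e-10).
6. **Post-filter.** Optionally, a zero-phase FIR band-pass/low-pass
   filter with the species' frequency band (`species_bands()` ships
   ranges for kiwi, kakapo, ruru and several passerines) removes
   residual out-of-band noise.

Quality is measured without ground truth via labelled intervals
(Audacity-style TSV): `snnr()` (signal-plus-noise to noise ratio,
`10·log₁₀((S+N)/N)` from song vs. silence regions), `success_ratio()`
(`log₁₀` of the before/after variance ratio of the noise-only margins;
\> 0 means the noise floor dropped), and a modified `psnr()`. A
synthetic module (`stepped_tone()`, `click()`, `colored_noise()`,
`mix_at_strength()`, `noisy_tone_fixture()`) generates annotated
fixtures with known noise tracks, including white, pink (1/f) and brown
(1/f²) noise at a stated percentage of signal RMS.

## Worked example

```r
library(wpdenoise)

# a 20/40/80 Hz stepped tone with 500 ms noise margins, plus white
# Gaussian noise at 100% of the tone's RMS (true SNR = 0 dB)
fx  <- noisy_tone_fixture(strength_pct = 100, color = "white", seed = 1)
fx$rec
#> <annotated_recording> 1.300 s, 2 noise / 1 song intervals

best_level(fx$rec$audio)
#> [1] 7

den <- denoise(fx$rec$audio)          # dmey, 4.5 sigma soft threshold
metrics_report(fx$rec, den)
#>   snnr_before_db snnr_after_db success_ratio psnr_db song_power noise_power
#> 1          2.886         25.97         3.001   13.48    0.08457     0.04351

select_wavelet(fx$rec$audio, c("db2", "db10", "dmey"))$scores
#>    db2   db10   dmey
#> 0.3672 0.3935 0.4180   # dmey wins, and is the package default
```

The entropy rule picked a 7-level tree; denoising raised the SnNR of
the recording from 2.9 dB to 26.0 dB, and the variance of the
noise-only margins fell by a factor of 10^3.0 ≈ 1000 (success ratio
3.0 > 0, i.e. successful). In the same sweep framework, white noise is
removed best, pink noise well, and brown noise barely — its spectrum
concentrates in the same low-frequency bands as the signal and violates
the Gaussian assumption behind the threshold.

A command-line interface is installed with the package
(`exec/wpdenoise`):

```sh
wpdenoise synth tone --strength 100 --seed 1 --out tone.wav
wpdenoise denoise tone.wav --variant DF --band 0,500 --labels tone.labels.tsv
wpdenoise metrics tone.wav tone.labels.tsv --denoised tone.DF.wav
wpdenoise bench --strengths 25,50,100,150,200 --seeds 20
```

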