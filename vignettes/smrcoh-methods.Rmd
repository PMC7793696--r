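---
title: "Simulating and analysing SMR-coherence neurofeedback: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing SMR-coherence neurofeedback: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`smrcoh` simulates and analyses closed-loop neurofeedback training of EEG
coherence between Cz and CPz in the sensorimotor-rhythm band (SMR,
12–15 Hz). This vignette documents the generative models, the estimators,
the protocol simulator and the statistics, together with the numerical
choices behind them and what the simulation does and does not capture about
real data.

## Why simulate

Training studies of this kind record two referenced EEG channels plus EOG at
256 Hz over ten sessions, each with one baseline and six 3-minute feedback
runs. The raw recordings are typically not shareable, so an analysis
pipeline cannot be validated against the original data. Every estimator in
this package is therefore validated against synthetic recordings with known
ground truth: known coupling (with a closed-form coherence target), known
artifact positions, and known learning trends.

## Generative model

**Background.** Broadband EEG background is spectrally shaped Gaussian
noise with power spectrum proportional to $f^{-\alpha}$. The default
$\alpha = 1$ (pink noise) is the typical resting-EEG approximation; the
exponent is a free parameter in $[0, 2]$. Variance is calibrated exactly to
the requested standard deviation (default 8 µV per EEG channel, 15 µV for
EOG).

**Coupling.** The SMR component of the two channels shares a band-limited
Gaussian source $s$: with coupling $c \in [0, 1]$,

$$x = \sqrt{c}\, s + \sqrt{1 - c}\, n_1, \qquad
  y = \sqrt{c}\, s_{\tau} + \sqrt{1 - c}\, n_2,$$

where $n_1, n_2$ are independent noises with the same in-band spectrum as
$s$ and $s_\tau$ is $s$ delayed by a lag $\tau$ (default 18 ms). All three
components are unit variance, so the cross-spectrum at in-band frequencies
is $c\,S(f)$ while both auto-spectra are $S(f)$; the magnitude-squared
coherence is exactly $c^2$ at every in-band bin, and the coherency phase is
$\omega\tau$. The 18 ms default is approximately a quarter period at the
13.5 Hz band centre, which places nearly all of the coherency in its
imaginary part. One could instead weight the source by $c$ and the noise by
$\sqrt{1-c^2}$; that alternative parameterisation yields band MSC $c^4$,
and we deliberately chose the square-root weighting so that the familiar
"MSC = coupling²" identity holds and every recovery test has a closed-form
target.

**Volume conduction.** Zero-lag mixtures $x = a_1 s + \epsilon_1$,
$y = a_2 s + \epsilon_2$ (optionally several shared sources) model the
instantaneous spread of one neural source to adjacent electrodes. Because
the mixing is instantaneous, the cross-spectrum is real: MSC can be large
while the imaginary part of coherency is zero in expectation. This is the
null case that motivates analysing imaginary coherence at adjacent channels.

**Artifacts.** Blinks are 400 ms raised-cosine transients with amplitude
ratio EOG : Cz : CPz = 1 : 0.4 : 0.2 (frontal dominance; configurable) and
300 µV default peak. Muscle events are 500 ms Hann-enveloped bursts of
30–100 Hz noise (40 µV SD) on the EEG channels. Onsets are Poisson; the
default rates (3 blinks/min, 1 burst/min) were chosen once so that the
offline rejection removes roughly 9% of epochs, a typical figure for this
kind of recording. The ground-truth mask marks the samples where the
transient exceeds 40% of its peak envelope — the gentle cosine flanks
neither trip any rejection criterion nor meaningfully contaminate an epoch,
so they are not counted as "affected".

**Learning.** A simulated learner has baseline coupling $c_0$ and linear
trends: coupling in session $s$, run $r$ is
$c_0 + \beta_{\text{session}}(s-1) + \beta_{\text{run}}(r-1) + \eta$ with
run-level jitter $\eta \sim N(0, \sigma^2)$ (default $\sigma = 0.02$),
clipped to $[0, 0.95]$. Band amplitudes can carry analogous relative
trends. The coupling actually used for each run is recorded as metadata,
making parameter-recovery experiments possible.

**What the simulation does not capture.** No head model or lead field —
"volume conduction" is an abstract zero-lag mixture, not a physical forward
solution; no nonstationarity beyond linear trends and artifacts; no
reactive behaviour (a simulated learner's coupling does not respond to the
feedback it receives); only the three named channels. Consequently, passing
tests demonstrate that the estimators and statistics behave correctly under
the stated generative assumptions — not that a specific human cohort would
produce any particular effect size.

## Preprocessing

Runs are cut into non-overlapping 1-s epochs (trailing partial seconds
discarded). An epoch is rejected when any EEG channel shows a
consecutive-sample step above 50 µV, an absolute value above 120 µV, or a
peak-to-peak range below 0.5 µV within any sliding 100 ms window, or when
the EOG channel exceeds 100 µV in magnitude. The low-activity criterion is
interpreted as a peak-to-peak range over a stride-1 sliding window — the
standard flatline check in EEG software; "activity" could also be read as a
windowed SD, and the choice is configurable rather than asserted. The EOG
amplitude threshold is an automated proxy for what is often manual ocular
rejection; 100 µV is deliberately below the 120 µV absolute criterion so
that blinks are caught on EOG before their attenuated EEG copies matter.
Rejection is epoch-level and all-channel, because coherence needs paired
epochs.

## Spectral estimation

Per kept epoch: demean, taper, FFT; auto- and cross-spectra are averaged
across epochs and normalized by the window power so that the one-sided
spectrum integrates to the unwindowed variance (Parseval within 1% on white
noise). The taper is a split-cosine-bell with 10% total taper — the
convention behind a "Hanning window, 10%" setting in common EEG analysis
software; a full Hann window is `taper_fraction = 1`.

Coherency is computed from the epoch-averaged spectra
(average-then-normalize, the standard definition; a
normalize-then-average per-epoch variant is available for sensitivity
analysis). Band summaries average the bins whose centres fall in
$[f_{lo}, f_{hi}]$ inclusive — at the 1 Hz resolution of 1-s epochs the SMR
band comprises exactly the 12, 13, 14 and 15 Hz bins. The imaginary part is
kept signed; rectifying it before averaging would bias the volume-conduction
null upward. With fewer than two epochs the estimator refuses to run: the
MSC of a single epoch is identically 1.

Under independence the epoch-averaged MSC has positive bias of order
$1/n_\text{epochs}$; tests check that this bias shrinks accordingly (about
0.006 at the 180 epochs of a full run).

**Band power.** Complex demodulation multiplies the signal by
$e^{-2\pi i f_c t}$ at the band centre $f_c$, applies a zero-phase
(forward–backward) 4th-order Butterworth low-pass at half the bandwidth,
and scales instantaneous power so a pure amplitude-$A$ sinusoid at $f_c$
yields $A^2/2$. The demodulation and the squared-magnitude filter response
$|H|^2$ are applied in the frequency domain (the modulation is a circular
spectrum shift whenever $f_c$ lies on the FFT grid), which is exact for the
filter's steady state; the circular boundary affects only the first and
last fraction of a second, and calibration tests exclude those edge
seconds. An FFT band power (sum of auto-spectral bins) provides an
independent cross-check; the two agree within 10% on stationary narrowband
input.

## The closed-loop protocol

The online display updates at 1 Hz. The coherence bar shows band MSC over a
trailing window of 8 one-second epochs (MSC because that is the measure fed
back in the experiment being modelled; the offline analysis favours the
imaginary part). Earlier updates use all epochs available so far, minimum
two, so the first bar value appears at $t = 2$ s. The theta and beta bars
show the current epoch's demodulation power on Cz. No artifact handling is
applied online — the modelled acquisition system's online artifact checks
are undocumented, so the simulator models none — while the offline pipeline
rejects as above.

Thresholds come from the baseline run: mean online coherence for the
feedback bar, mean + 1 sample SD for each control bar. After every feedback
run the coherence threshold is reset to that run's mean online coherence
(a running mean over all previous runs is available as an alternative);
control thresholds never change within a session. An update is "green" when
theta and beta are below their thresholds and coherence is above (up-group)
or below (down-group) its threshold; the reward counter increments once per
entry into the green state, which reads the described counter semantics as
discrete events — a per-second accrual mode is available.

Both the window length and the online measure are configurable, since the
real-time estimator of the commercial system is not publicly specified;
the offline estimators are the precisely defined part of the pipeline.

## Trend statistics

For one group and one outcome the learning model is

`outcome ~ session + run + session:run + (1 | subject) + (0 + session | subject) + (0 + run | subject)`

with session and run as numeric covariates (run 1 = baseline run; coding
configurable). F tests are sequential (Type I) in the order session, run,
interaction, with Satterthwaite denominator degrees of freedom (lmerTest).
Random slopes are entered uncorrelated with the intercept for stability at
cohort sizes around 10. A two-stage estimator — per-subject OLS, then a
one-sample t across subjects (df = n − 1) — is always computed as a
cross-check; on balanced designs its slope estimates coincide with the
mixed model's fixed effects (identical per-subject design matrices make the
GLS estimate an equal-weight average of per-subject OLS estimates). When
the mixed fit fails or is singular, the result is flagged and the two-stage
estimates stand in.

Monte-Carlo calibration runs on datasets generated directly at the summary
level (random intercept + random slopes + residual noise,
`simulate_trend_dataset`), because the property being checked — the size of
the session test — concerns the statistics, not the signal processing: over
200 null cohorts of 10 subjects × 10 sessions × 7 runs the empirical
rejection rate at nominal 0.05 falls within [0.01, 0.12], and with an
injected slope of 0.03/session the mean recovered slope over 100 replicates
is within two Monte-Carlo SEs of the truth. A separate end-to-end test runs
the full signal path (simulate → EDF → reject → estimate → model) on a
10 up + 10 down cohort and checks the recovered group pattern: positive,
significant session and run trends in the up-group, null in the down-group.

Cousineau–Morey standard errors recentre each subject
($y'_{ij} = y_{ij} - \bar y_{i\cdot} + \bar y_{\cdot\cdot}$), take
per-condition SEs of the recentred values and inflate by
$\sqrt{C/(C-1)}$; they are invariant to per-subject additive constants.
Paired pre/post comparisons use the paired t (df = n − 1) with Bonferroni
adjustment $\min(1, p \times \text{family size})$; the family size defaults
to the number of repeated measures per construct and must be supplied
explicitly where families are ambiguous. Per-strategy slope summaries
regress coherence on run number within each (subject, session) and average
the slopes per reported strategy label, a subject contributing to every
label it reported.

## Numerical and design notes

* All generators draw from R's RNG; per-run sub-seeds are drawn once from
  the master seed (`sample.int(2^31 - 1)`), so identical seeds give
  bit-identical recordings and whole-study determinism.
* Band-limited noise uses brick-wall FFT masking with per-realization
  variance normalization; delays are frequency-domain phase ramps
  (circular, fractional-sample exact).
* EDF export uses 16-bit quantization against per-channel symmetric
  physical ranges as printed in the header; round trips are exact to within
  half a quantization step (about 0.005 µV at ±150 µV). EDF was chosen as
  the interchange format as the most universal EEG exchange standard; a
  minimal BrainVision reader is provided as a read-only alternate dialect.
* Degenerate inputs are refused loudly: fewer than two epochs, zero in-band
  auto-spectra, missing cells in the error-bar matrix, zero-variance paired
  differences (flagged, p reported as undefined).
* Problem sizes in the tests: full 180-s runs wherever the protocol is
  exercised; the coupling-recovery oracle uses a 100× longer realization of
  the same generator; Monte-Carlo calibration uses 200 null and 100
  alternative cohorts at the study's own design size (10 × 10 × 7).

## Known limitations

* The closed-form MSC target holds at in-band frequencies of the coupled
  pair generator; once the pair is embedded in background EEG, in-band
  background power attenuates measured coherence below the nominal $c^2$
  (by a factor of about 0.67 at the default amplitudes). Recovery tests on
  composite recordings therefore check ordering and trend sign, not
  absolute level.
* Real ocular rejection is often manual; the EOG threshold proxy is
  deliberately simple and has no false-negative guarantee for low-amplitude
  ocular activity.
* The mixed model assumes linear trends; saturating learning curves would
  need a different fixed-effect structure.
* Reported p values for the down-regulation (null) group in any single
  simulated study are subject to ordinary type-I error.
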