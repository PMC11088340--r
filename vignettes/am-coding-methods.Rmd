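---
title: "Models and methods for amplitude-modulation coding analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for amplitude-modulation coding analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amcoder)
```

`amcoder` implements a complete analysis chain for studying how auditory
neurons — and behaving animals — encode sinusoidal amplitude modulation (AM),
and how a sensitizing manipulation (the motivating case is systemic
salicylate, which raises pure-tone thresholds while *improving* AM
sensitivity in the inferior colliculus) shifts the measured thresholds. This
vignette explains the models, the tunable parameters, the synthetic-data
generators that make the chain testable without recordings, and the
numerical choices behind the fits.

## Stimuli

**SAM noise.** Each trial is a band-limited pink-noise carrier (1/f power
between 2 and 48 kHz, synthesized in the frequency domain with random
phases, so the band limits are exact and the waveform is reproducible from
a seed) that switches from an unmodulated (UM) to a modulated segment,
$y_{mod} = y\,(1 + m \sin(2\pi f_{mod} t + \varphi))$, with depth
$m \in [0,1]$. Two details prevent non-AM detection cues:

* the UM segment is a *spectrally matched* noise, obtained by randomizing
  the phases of the Fourier spectrum of an independent SAM instance
  (`make_matched_um()`). Its magnitude spectrum — including sideband power —
  is identical to the SAM segment's, but the periodic envelope is destroyed;
* segments are joined by a 20-ms cross-fade weighted by $\cos\theta$ and
  $\sin\theta$, $\theta \in [0, \pi/2]$, so the summed instantaneous power
  of the two uncorrelated noises is constant through the transition.

The modulator starts at the phase where its instantaneous value matches the
UM power. The default closed form is
$\varphi = \arcsin(\sqrt{1 + m^2/2} - 1)$; exact power continuity requires
dividing the arcsin argument by $m$, and `am_phase_offset(mode = "power")`
implements that variant — it is the only mode for which the squared envelope
at the transition equals the AM-segment mean power $1 + m^2/2$. Both are
kept because published descriptions of this stimulus family differ in
exactly this detail. The playback rate defaults to 97,656.25 Hz, a standard
rate of the TDT hardware family commonly used for ultrasonic mouse stimuli;
it only scales the time axis.

**Dynamic random chords (DRC).** Brief tones on a 5-ms × 1/12-octave ×
5-dB grid (2–64 kHz, 25–70 dB SPL) with independently randomized onsets,
frequencies and levels, and variable durations drawn from a discretized
exponential ($\lambda$ = 30 ms, truncated to 20–200 ms). "Density two per
octave" is enforced as *time-averaged concurrency*: with per-octave
occupancy target $q = \mathrm{density}/12$ and mean duration $E[L]$ bins,
the per-bin onset probability is $p = q/((1-q)E[L])$, the exact
steady-state solution of the renewal process in which an occupied
time–frequency bin cannot start a new tone. (The naive
$p = \mathrm{density}/(12 E[L])$ undershoots the target concurrency by the
factor $1/(1+pE[L])$ once overlap exclusion is in force.) Tone ramps occupy
one bin each and are painted at full level, since the level matrix has no
partial-level code.

**Input scalings.** Receptive-field models see the DRC through a lookup
scale $s(t,f)$ with 70 dB SPL defined as 1 and silence as 0: `pow`
($10^{(x-70)/10}$), `amp` ($10^{(x-70)/20}$), `dB0`/`dB20`/`dB40` (linear
in decibels above the reference, $(x-\mathrm{ref})/(70-\mathrm{ref})$ for
$x > \mathrm{ref}$, else 0), and `binary` (presence). The dB scales are
normalized by decibels *above reference* so that every scale meets the
common endpoints (silence → 0, 70 dB → 1); this is the only reading under
which the six scales are mutually comparable.

## Synthetic data generators

The generators are first-class, tested code: they define the statistical
structure each analysis assumes, and parameter-recovery tests against them
are the package's main evidence of correctness. What they deliberately do
**not** model: adaptation, refractoriness, correlated noise across units or
trials, non-Poisson count dispersion, and any non-stationarity within a
session. Passing tests therefore certify the estimators under the stated
model assumptions, not under every pathology of real recordings.

**AM units** fire as inhomogeneous Poisson processes whose AM-segment
intensity follows a von Mises phase profile,
$\lambda(t) \propto e^{\kappa m\cos(2\pi f_{mod}(t-\delta)+\psi-\pi/2)}/I_0(\kappa m)$,
normalized so the cycle-averaged rate is $r_{base}(1 + \mathrm{gain\ slope}
\cdot m)$. The von Mises shape was chosen over a rectified sinusoid because
it is non-negative by construction, reduces to the sinusoidal modulator
$1 + \kappa m \sin(\cdot)$ at small concentration, and actually attains the
perfect-locking limit (vector strength $I_1/I_0 \to 1$) as
$\kappa m \to \infty$. Condition multipliers scale gain and concentration
per condition label — the salicylate analogue multiplies both.

**LNP units** compute the context-model rate (below) on the scaled DRC,
half-wave rectify it (the minimal constraint giving valid Poisson rates; an
exponential nonlinearity is available) and draw independent Poisson counts
per repetition. Default fields are Gabor-like: a Gaussian excitatory lobe
with a delayed inhibitory sidelobe, peak weight ~3–4.5 spikes/bin per unit
input. At those amplitudes a 20-repetition unit comfortably passes the
signal-power inclusion rule, mimicking the "reliable responder" population
the receptive-field analysis is meant for.

**Behavioral sessions** draw licks with hit probability
$fa + (1-fa-\mathrm{lapse})\cdot\mathrm{logistic}((x-\theta)\beta)$ in
$x = 20\log_{10} m$ dB, and hit latencies
$\mathrm{floor} + \mathrm{scale}\cdot e^{-(x-\theta)\beta}\cdot
\mathrm{lognormal}(\sigma)$, reproducing the inverse depth–latency relation
of trained mice; catch-trial licks occur at the false-alarm rate with
at-threshold latencies. Defaults ($fa$ = 0.1, lapse = 0.05, slope = 1/dB,
floor = scale = 0.25 s, $\sigma$ = 0.3) are typical of head-fixed lick
tasks. Note the analysis estimates the threshold from the latency-based
ROC, not from the generator's logistic midpoint directly; with the default
false-alarm and lapse rates the d′ = 1 crossing sits a few tenths of a dB
above the planted midpoint, well inside the ±2 dB recovery tolerance the
tests use.

## AM-sensitivity metrics

Temporal coding is quantified by **phase-projected vector strength**: spike
times in the analysis window (by default the last 500 ms of the AM segment,
excluding onset transients) become phases $\theta = 2\pi f_{mod} t$; each
trial's resultant is projected onto the global mean phase of all spikes,
$VS_{PP,t} = VS_t \cos(\theta_t - \theta_c)$. Unlike classic vector
strength, which returns 1 for any single-spike trial, randomly phased
low-count trials average toward zero. Zero-spike trials contribute 0, the
convention of the metric's source literature.

Rate coding uses the firing rate over the same window. Either metric is
compared per depth against the depth-0 (UM) trials of the same block by ROC
analysis — the natural neural analogue of the behavioral catch-trial
comparison — using the Mann–Whitney formulation with ties counted ½. The
AUC is clipped to $[0.5/N_{pairs}, 1 - 0.5/N_{pairs}]$ (the same rule
applied to behavioral hit/false-alarm rates) and converted to
$d' = |\sqrt{2}\,\Phi^{-1}(AUC)|$. The $\sqrt 2$ factor is the standard
equal-variance relation; because typography in the field sometimes reads as
$2\Phi^{-1}$, `dprime_from_auc(convention = "2")` provides that variant for
sensitivity analyses. The **modulation threshold** is the lowest-depth
upward crossing of $d' = 1$ under linear interpolation in dB; a curve that
never reaches 1 has no threshold, and one starting above 1 is censored at
the lowest tested depth.

## Receptive-field estimation

**Inclusion.** With $N$ repetitions, the unbiased signal-power estimator is
$\hat P(\mu) = (N P(\bar r) - \overline{P(r^{(n)})})/(N-1)$, with $P(\cdot)$
the time-averaged squared deviation from the mean; noise power is the
complement, so signal + noise equals mean total power identically. Units
enter the analysis iff signal ≥ 2 × noise.

**Simple model (ASD).** The STRF is the posterior mean of a linear Gaussian
model whose prior covariance is $\rho^2\, K_t(\ell_t) \otimes K_f(\ell_f)$
with squared-exponential factors over lag and log-frequency. The prior
scale, the two length scales and the noise variance maximize the marginal
likelihood. Numerics: sufficient statistics $X^\top X$, $X^\top y$ are
computed once; each evidence evaluation rotates them into the prior
eigenbasis (cost $D^3$ for $D$ weights), where both the log-determinant and
the posterior solve are stable even when smoothness drives prior
eigenvalues toward zero. The optimizer is Nelder–Mead over the four
log-hyperparameters from two initializations (length scales of 1 and 2.5
bins — evidence surfaces can be multimodal), with the noise variance
initialized at the residual variance of a light ridge fit; parameters are
soft-bounded at $e^{\pm 18}$. The intercept is profiled out by centering.
As both length scales shrink the posterior collapses to ridge regression
with penalty $\sigma^2/\rho^2$, a limit the tests verify.

**Context model (ALS).** The context-gain model multiplies each tone's PRF
contribution by $1 + \sum_{m,n} w^{\tau\varphi}_{m,n}\, s(i-j-m, k+n)$ — a
context gain field over relative time ($\tau$, default 0–20 ms in tests,
configurable) and relative frequency ($\varphi$, default ±½ octave in
tests). For fixed CGF the model is linear in the PRF on a context-modulated
stimulus; for fixed PRF it is linear in the CGF on PRF-filtered stimulus
products. Alternating these two exact penalized least-squares solves
minimizes one objective — residual sum of squares plus both smoothness
penalties — so the objective is provably non-increasing, which the fit
records per half-step and tests assert. The PRF step reuses the
ASD-optimized prior of the initializing simple fit; the CGF step uses a
fixed squared-exponential smoother with bandwidths 0.5 time bin (2.5 ms)
and 2 frequency bins (1/6 octave) and unit marginal prior variance —
appropriate for gain modulations of order one. Both solves run in their
prior eigenbases; an explicit inverse-covariance formulation is avoided
because near-singular smoothness priors make it numerically treacherous
(in development it broke the monotonicity guarantee). Stimulus bins beyond
the band edges enter context sums as silence. Iteration stops when the
relative objective change falls below $10^{-5}$ (cap 50); an oscillating
run returns its best iterate, flagged.

A **permutation null** for the CGF (`cgf_permutation_null()`) re-solves the
CGF step on circularly shifted responses with the PRF held fixed; the
observed statistic goes through the identical solve, so a context-free unit
lands inside its own null.

**Prediction scoring.** Normalized predictive power is
$(P(r) - P(r-\rho))/\hat P(\mu)$: 1 for a perfect prediction of noise-free
data, 0 for any constant, negative when generalization fails.
Cross-validation reserves a random disjoint tenth of the *time bins*
(matching how DRC responses are scored in this literature) per fold, with
fold sets redrawn each repetition. Hyperparameters are optimized once on
the full response and held fixed across folds: per-fold evidence
re-optimization changes the estimates negligibly at these data sizes but
dominates the compute; fold refits re-solve the weights (simple model) or
re-run warm-started ALS (context model) on training bins only. The warm
start and shared hyperparameters introduce a slight optimism common to both
models being compared, so model *contrasts* (context vs simple, scale vs
scale) are unaffected.

## Pure-tone analysis

FRA responses are smoothed with a Gaussian kernel spike density (σ = 5 ms
for tuning maps — wide enough to stabilize 100-ms tone responses, narrow
enough to keep onsets; σ = 2 ms wherever single-trial timing matters). The
significance-bounded tuning area uses a permutation test of evoked minus
spontaneous rate (evoked window 0–100 ms from tone onset; spontaneous
window the final 50 ms of the 200-ms intertrial interval): circular shifts
of spike times within trials build the null, the maximum statistic across
cells controls the family-wise error, and only the contiguous significant
region containing the peak is kept. This is the package's own construction
— the tuning-area algorithms cited in the experimental literature are not
fully specified in print — and it preserves the contract that matters
downstream: CF is the frequency of the significant cell at the lowest
significant level (ties to the larger response) and MT is that level. The
threshold-shift-versus-CF trend is summarized by ordinary least squares of
$\Delta MT$ on $(\log_{10} CF)^2, \log_{10} CF, 1$ with CF in kHz; OLS is
used because the printed analyses of such curves report no weighting.

## Population decoder

Trial-averaged PSTHs (bin 1/256 s = 3.90625 ms; the "3.9 ms" of the
literature read as the exact binary fraction) for fully modulated minus
unmodulated stimuli in the reference condition form a units × time
difference matrix; its first principal component over units is the
**AM-encoding component**, signed so the full-depth difference projects
positively. Single-trial kernel spike densities (σ = 2 ms) projected onto
this component give a one-dimensional population signal; a trial's
**simulated response latency** is the first post-transition crossing of a
detection level, plus a 100–200 ms non-decision time, with non-crossing
trials counted as no-responses. Decoder parameters are fitted by grid
search minimizing the RMS difference between simulated and behavioral
latency CDFs evaluated on a 10-ms grid (below behavioral latency
resolution, above the simulation bin width), averaged over stimulus groups;
no-response mass appears naturally as a CDF plateau below 1. For threshold
readouts without a behavioral reference, the pipeline places the detection
level halfway between the median pre-transition peak and the median
full-depth post-transition peak — between the two distributions the
crossing must separate. Decoder d′ uses the same latency ROC as the
behavioral analysis (shorter latency = stronger evidence, no-responses
share the worst rank), so decoder and behavioral thresholds are directly
comparable.

## Behavioral psychometrics

Hit rates per stimulus cell and false-alarm rates from catch trials are
clipped to the exact rational bounds $[0.5/N, 1-0.5/N]$ before any d′
conversion. Sensitivity per depth comes from the latency ROC against catch
trials; the evidence orientation (shorter latency ranks higher, no-response
worst) is the one consistent with the inverse depth–latency relation. The
mixed-effects modeling used for significance testing in experimental work
is deliberately out of scope — the package exports tidy tables any such
tool consumes.

## Problem sizes used by the test suite

The suite exercises every stage at sizes a laptop CPU handles in minutes,
chosen once as the smallest instances at which the estimators operate in
their intended regime: STRF fixtures use a 1.5-octave DRC band (18
frequency bins), a 9-lag (45-ms) PRF window and a 5 × 13-bin CGF, with
60-s × 20-repetition stimuli for recovery benchmarks and 30-s stimuli for
the 20-unit model-comparison and scaling studies; population studies use 8
units × 15 trials × 6 depths × 2 conditions; behavioral recovery uses
300-trial sessions across 20 seeds. Cross-validated scores in the test
suite use 10 folds × 1 repetition (the package default is 20 repetitions,
matching common practice).

## Known limitations

* The ASD evidence ascent is a general-purpose simplex optimizer; on very
  smooth, low-noise data a gradient-based optimizer would converge faster.
* ALS converges to a local optimum of the bilinear objective; the simple-fit
  initialization makes this reproducible but not globally optimal.
* The CGF prior variance is fixed rather than evidence-optimized; grossly
  mis-scaled inputs would need it adjusted.
* The decoder assumes a single detection level shared across depths and
  conditions, as the threshold-crossing model prescribes; evidence
  accumulation (drift-diffusion) dynamics are not modeled.
* Generators draw independent Poisson spikes; estimator variances on real,
  correlated data will be larger than the recovery tests suggest.
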