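---
title: "Quantifying pupil-linked arousal coupling in resting-state fMRI"
author: "pupilAAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pupil-linked arousal coupling in resting-state fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupilAAS)
```

## The scientific problem

During quiet rest, pupil size fluctuates slowly (~0.05-0.1 Hz) without any
luminance change. These fluctuations are thought to track the activity of
the ascending arousal system (AAS) — small neuromodulatory nuclei such as
the locus coeruleus (LC), ventral tegmental area, substantia nigra, raphe
nuclei and basal forebrain. Testing that idea with fMRI requires relating
a 250 Hz pupil trace to ROI-averaged BOLD series sampled every 2 s, while
the BOLD signal in these brainstem nuclei is dominated by cardiac and
respiratory noise, and while the hemodynamic transfer between neural
activity and BOLD (the HRF) may be faster in the subcortex than the
canonical cortical response.

`pupilAAS` implements that full analysis chain, and — because the central
question is *temporal*: does AAS BOLD follow the pupil with a canonical
~5 s delay or near-instantaneously? — it provides three complementary
estimators of the pupil-BOLD temporal relationship:

1. a **TTP sweep**: GLMs using pupil regressors convolved with
   double-gamma HRFs whose delay-of-response parameter runs over 1-6 s;
2. **lagged cross-correlation** of the unconvolved pupil and BOLD series
   over lags -8..+8 s in 2 s steps (negative lag = pupil precedes);
3. **cross-spectral density** locating the frequency band that carries
   the coupling.

A fourth component, **blind point-process HRF deconvolution**, estimates
region- and participant-specific HRFs from spontaneous BOLD excursions.

## The models

### First-level GLM

Each session contributes a block with its own intercept, discrete-cosine
drift basis (cut-off 1/128 Hz, `floor(2*N*TR/cutoff)` columns), the
33-column nuisance design, and one pupil regressor. Residual lag-1
autocorrelation is estimated by Yule-Walker on the OLS residuals and both
sides are prewhitened with the `(1, -rho)` filter (Prais-Winsten scaling
of the first sample) before refitting; the coupling statistic is the t of
the unweighted mean of the session pupil betas, on `n - rank(X)` degrees
of freedom.

A subtlety worth recording: with ~40 smooth columns projected out of 150
samples, the residual autocorrelation estimate is biased negative (about
-0.12 under white noise), and prewhitening with that spurious negative
rho inflates the t statistics of smooth regressors — we measured a 6.8%
type-I rate at a nominal 5%. The package therefore corrects the estimate
by the regression-induced expectation computed from the hat matrix (the
same correction used in fMRI residual-autocorrelation literature). After
the correction the full pipeline's null rejection rate is 5.0% (2000
null sessions; the acceptance suite re-verifies this).

### Nuisance model (33 columns)

Six motion parameters; fifth-order Fourier expansions of cardiac and
respiratory phase (10 + 10 columns); six slow cardiorespiratory
regressors (heart-rate frequency, heart-rate variability, raw belt
amplitude, respiratory frequency, respiratory amplitude, respiration
volume per time); and one ventricle noise regressor. Cardiac phase is
linear time within each inter-beat interval; respiratory phase is the
histogram-equalized belt amplitude signed by the belt derivative
(inhale/exhale). Phases are evaluated at each volume's temporal midpoint
(an explicit choice — no slice timing is in scope). Window lengths for
the slow regressors (6 s cardiac, 12 s respiratory) follow the RVT /
RETROICOR literature conventions; they are labelled as conventions
because the regressor definitions in common use leave the windows open.

### Pupil preprocessing

Fixed order: (1) blink interpolation — every invalid run widened by
100 ms before onset and 400 ms after offset, linearly interpolated from
the flanking valid samples; (2) optional first-order derivative at the
native 250 Hz (computing it before downsampling preserves constriction /
dilation structure that TR-level differencing would alias); (3) a 1 s
backward shift compensating the pupil's physiological lag behind the
neural activity that drives it; (4) resampling to the TR grid by bin
means, where samples beyond 3 SD from their own bin mean are dropped and
the mean recomputed. Sessions with more than 25% raw invalid samples are
excluded (strict inequality at the boundary). The trailing partial bin,
if any, is truncated to the volume grid.

### Blind HRF deconvolution

The cleaned, standardized BOLD series is modelled as a Dirac train of
spontaneous neural events convolved with an unknown kernel plus noise.
Events are detected as upward crossings of +1 SD (one event per
suprathreshold excursion; a per-excursion delta avoids the collinear
adjacent deltas that flagging every suprathreshold sample would create).
Because a BOLD excursion expresses its neural event some seconds late,
the fit searches onset shifts of 0-4 volumes (0-8 s) moving the deltas
*earlier*, and keeps the shift maximizing R^2. The kernel is the fitted
mixture of the canonical double-gamma and its temporal and dispersion
derivatives; the reported time-to-peak (TTP) is the argmax of that
mixture on a 0.1 s grid. Sessions are cleaned independently, z-scored
and concatenated; events within 32 s of a seam are dropped because the
convolution would leak across sessions.

Two caveats are inherent to the method and documented here rather than
hidden: (i) the three-function basis can only represent kernels peaking
within roughly +/-1 s of the canonical peak, and the shift search moves
in whole TRs, so kernels peaking far earlier than ~4 s alias to a
shifted solution; recovery claims are therefore made on the kernel
argmax scale within the 4-5.5 s range that resting-state estimates
actually occupy. (ii) event detection is thresholded on the observed
BOLD, so the estimated absolute TTP carries a common detection latency;
*differences* between regions (the subcortical-faster-than-cortical
ordering) survive this bias, and the parameter-recovery suite tests
exactly that contrast. The threshold direction is positive-only by
default ("one or more SD away from the mean" could include negative
excursions; a `twoSided` flag exposes the alternative).

### Unconvolved analyses

Cross-correlation uses `r(lag) = cor(bold(t), pupil(t + lag))` over the
shrinking overlap — no zero padding, which would bias r toward zero
asymmetrically across lags. Negative lag means the pupil precedes the
BOLD signal; the convention string is attached to every result object so
a silent sign flip cannot survive a round trip. For these analyses the
BOLD series is nuisance-regressed and demeaned but *not* prewhitened:
the `(1, -rho)` filter is a differencing operation that would shift the
apparent cross-correlation peak (we observed a spurious +2 s shift when
prewhitening was applied to the smooth coupled component). AR(1)
handling belongs to the GLM and deconvolution paths, where it serves
inference, not description.

Cross-spectra use Welch averaging with 10-sample windows overlapping by
3, a Hann taper per segment (window and overlap are the conventional
settings; the taper choice is ours and exposed), and zero padding to 256
points. The padding exists because spectral peaks of interest (down to
~0.01 Hz) are finer than a 10-sample window's native resolution; it
interpolates the spectrum without adding information, and the transform
length is an argument, not a constant.

### Group statistics

Per-participant statistics (t values, Fisher-z correlations) feed
one-sample t tests, FDR-corrected (Benjamini-Hochberg) within the chosen
family — nine-ROI families for main effects, lags-within-ROI for the
cross-correlation bins; the family definition is an argument because
reasonable analysts disagree. The "main effect of TTP" is a one-way
repeated-measures ANOVA with participant as blocking factor (the minimal
test matching a within-subject factor across six levels). Full-vs-partial
coupling is a paired two-sided t on Fisher-z values.

## The synthetic-data generator

The generator's defaults are the study conditions: 5-minute sessions,
TR = 2 s (150 volumes), pupil at 250 Hz, blink gaps at 15/min lasting
100-400 ms during which the trace drops to the tracker floor, slow pupil
power in 0.04-0.1 Hz, cardiac activity at 60 bpm with 2% inter-beat
jitter, respiration at 18/min with slow amplitude modulation, and noise
SD 0.5 on unit-gain coupling.

The smooth pupil signal is 4th-order-Butterworth band-passed Gaussian
noise, standardized. Filtering runs at a decimated 2 Hz rate and the
result is spline-interpolated back to 250 Hz: the band edges are three
orders of magnitude below the native Nyquist, where a direct high-rate
digital filter would be numerically degenerate. The band choice itself
is a modelling stance — the resting pupil spectrum outside the coupling
band is not well characterized, so we do not claim to emulate it.

The pupil is the neural signal delayed by `pupilLag` (default 1 s),
because the physiological pupil lags its neural drive — that is the very
reason the preprocessing applies a 1 s backward shift. Without this lag
in the generator the shift over-compensates and the TTP sweep recovers
`true TTP + 1` systematically; with it, recovery is unbiased.

BOLD is built from the *undelayed* neural signal: `gain * neural(t +
lag) + noise` in lag mode (lag a multiple of TR; negative = pupil
precedes, matching the result convention), or neural convolved with a
double-gamma kernel of configurable TTP in HRF mode, or pure noise in
null mode. Physiological bleed adds aliased cardiac/respiratory
sinusoids with random phase, giving the RETROICOR block something real
to remove. Ground truth (lag, TTP, neural series, event onsets) is
recorded before noise is added. One integer seed determines everything.

What the generator does **not** emulate — and hence what green tests do
not establish about real data: image-space artifacts and motion-BOLD
interactions, non-Gaussian and non-white BOLD noise beyond the injected
physiological components, gaze-dependent pupil foreshortening, saccadic
pupil transients, and HRF shape variability beyond the double-gamma
family.

## Numerical choices and degenerate inputs

* TR-bin outlier rejection uses the bin's own SD; a bin losing every
  sample falls back to its original mean with a warning.
* All-invalid pupil traces, flat-line pulse traces, constant belt
  signals, and zero-variance group inputs raise errors rather than
  propagating NaN.
* `|rho| >= 0.99` is clamped with a warning; `|r| >= 1` is clamped
  before the Fisher transform.
* Kernels are unit-peak normalized by default (t statistics are
  invariant to kernel scale; unit peak eases plotting); unit-sum and
  unnormalized modes exist.
* The delay parameter `p1` is called "TTP" in sweep APIs for continuity
  with the convention that names the canonical kernel "6 s TTP", even
  though the kernel argmax is `~p1 - p3`; the sampled argmax is always
  available as `peakTime()`.
* An event train whose every onset falls inside the seam guard, or a
  series with no suprathreshold excursion, raises an
  estimation-impossible error for that ROI; the study runner quarantines
  the participant and continues.

## Problem sizes used in validation

The test and acceptance suites run entirely on synthetic data at desk
scale: lag recovery over studies of 20 simulated participants, TTP
recovery over studies of 10, deconvolution ordering over 20, null
calibration over thousands of single-session fits. These sizes give the
Monte-Carlo error bands quoted in the tests while keeping a full run in
minutes on one CPU.

## Worked example

```{r example, eval = FALSE}
cfg <- simulationConfig(couplingMode = "lag", couplingLag = 0,
                        boldNoiseSd = 0.5, nRois = 2, seed = 7)
study <- simulateStudy(nParticipants = 10, nSessions = 2, cfg)
res <- runStudy(study, outDir = "results")
head(res$groupSweep)    # group t per (ROI, TTP), FDR within ROI
head(res$groupXcorr)    # group z per (ROI, lag)
res$anovaTtp            # main effect of TTP per ROI
```

## Known limitations

Beyond the deconvolution caveats above: the pipeline operates on ROI
averages only (no voxelwise maps or cluster inference); sub-TR lags are
out of scope (the lag grid is the TR grid); the CSD frequency axis below
~0.05 Hz rests on 20 s windows and should be read qualitatively; and the
generator's per-participant jitter is Gaussian on TTP and gain only.
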