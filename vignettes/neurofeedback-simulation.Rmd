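---
title: "Simulating closed-loop fMRI neurofeedback: models, filters and learners"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating closed-loop fMRI neurofeedback: models, filters and learners}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurofb)
```

## The problem

In fMRI neurofeedback, a participant watches a score decoded in real time
from their own brain activity and tries to drive it up. The measured BOLD
signal is a delayed, temporally blurred transform of the underlying neural
activity, so the learner faces a temporal credit-assignment problem: which
past activity (or action) caused the change in feedback just observed? This
package simulates the whole closed loop outside the scanner so that feedback
schedules (continuous vs. intermittent), physiological response shapes, and
self-regulation mechanisms (deliberate strategy vs. automatic reinforcement
of spontaneous activity) can be studied cheaply and reproducibly.

## The simulated cortex

`voxel_model()` builds the measured "brain": by default a 10×10×10 cube of
3 mm voxels. Twenty percent of voxels are tuned to grating orientation
(2.5% to each of 0°, 22.5°, …, 157.5°); the rest are untuned and carry no
stimulus-driven signal. A tuned voxel responds to a grating at orientation
$\theta$ with

$$w(d) = (1/16)^{d/90}, \qquad d = \min(|\theta-\theta_{pref}| \bmod 180,\ 180-|\theta-\theta_{pref}| \bmod 180),$$

a decaying exponential with full output at the preferred orientation and
1/16 at the orthogonal one. Orientation space is periodic with period 180°,
so the largest possible distance is 90°.

Every voxel also carries spontaneous activity with standard deviation
$\sigma_n$ (the tuning peak is 1, so the voxelwise SNR is $1/\sigma_n$).
Three noise models are provided:

* **Gaussian random field** (default): i.i.d. Gaussian noise smoothed with a
  Gaussian kernel of 5 mm FWHM and re-standardized so each voxel keeps
  marginal SD $\sigma_n$ exactly. FWHM is the neuroimaging convention for a
  smoothing "kernel size"; re-standardization makes the SNR statement exact
  rather than approximate at grid edges.
* **i.i.d. Gaussian**: no spatial correlation.
* **Orientation mixture**: a half-and-half mixture of i.i.d. Gaussian noise
  and $c \cdot$ the stimulus pattern of a uniformly random orientation,
  redrawn independently every TR. The scalar $c$ solves
  $\mathrm{Var}(g) = \mathrm{Var}(s)$ and
  $\mathrm{Var}(g) + \mathrm{Var}(s) = \sigma_n^2$ on tuned voxels, using the
  analytic moments of $w(d)$ under a uniform orientation. A fresh orientation
  per TR keeps the signal unbiased and memoryless; the paper-level idea being
  emulated is spontaneous activity that carries visual structure with no bias
  toward any particular orientation.

What the generator does **not** emulate: measurement/scanner noise (all
simulated variability is spontaneous activity), voxel-sampling biases, or
any temporal autocorrelation of spontaneous activity beyond what the
physiological filter induces. Conclusions from passing tests therefore
speak to the model world, not directly to scanner data.

## Physiological filters

`make_filter()` builds the four causal TR-lag filters (TR = 2 s), each
normalized to unit weight sum (steady-state gain 1):

| kind | weights | interpretation |
|------|---------|----------------|
| `impulse` | `[1]` | direct electrophysiology-like capture |
| `delay` | `[0,0,0,1]` | pure 6-s lag |
| `blur` | `[0.2 × 5]` | 10-s moving average |
| `hrf` | 15 signed weights | canonical double-gamma BOLD response |

The HRF is a double-gamma sampled on the TR grid $t = 0, 2, \dots, 28$ s:
a response gamma of shape 6 and scale 0.9 s (the Glover-style
parameterization, time-to-peak just under 5 s) minus an undershoot gamma of
shape 16, scale 1, at ratio 1/6; the small negative undershoot is retained
and the signed sum normalized to 1. The exact discrete weights are not
arbitrary — three behavioral constraints pin the parameterization down:
(i) the lag-0 weight must be (essentially) zero, since an HRF-filtered
signal carries *no immediate information* and a learner crediting only
current activity must stay flat; (ii) the learning dynamics of the automatic
learner depend on the *differences* between adjacent weights (see below),
and the well-established anti-learning of a pure-delay internal model
requires the lag-3 weight to sit on the falling flank ($h[3] < h[2]$);
(iii) the support spans 15 TRs. Sampling a gamma peaking exactly at 5 s
puts $h[2]$ and $h[3]$ within 3% of each other — a knife edge on which the
delay model neither learns nor anti-learns — while the scale-0.9 response
satisfies all three constraints robustly. A consequence worth stating
plainly: the discrete argmax falls at lag 2 (the 4 s sample), not at the
6 s delay lag; no discretization can place the argmax at lag 3 and
simultaneously make a lag-3 internal model anti-learn.

## Decoding and feedback

`train_classifier()` fits L1-penalized multinomial logistic regression
(glmnet) with the penalty chosen by cross-validation (`lambda.min`), playing
the role of sparse logistic regression: a strict subset of voxel weights is
exactly zero. Class probabilities are the softmax of the affine decision
function. For the cognitive protocols the feedback score is the dot product
of the 8 class probabilities with a tuning curve shifted to peak at the
target, so a grating 22.5° off target still scores 0.50 rather than 0 — a
smooth thermometer signal. Success requires the mean score over the last 3
TRs to *strictly* exceed 0.85 (ties fail, reading "exceeded" literally).

Intermittent feedback scores stimulate the model for 3 TRs and average the
decoded feedback over the following 3 TRs. The impulse filter leaves no
stimulus signal in that window and is rejected with an error.

## The automatic learner

Automatic conditioning reinforces spontaneous activity. With total activity
$a[n] = a_s[n] + a_c[n]$, measured pattern $p[n] = (a * h)[n]$, feedback
$f[n]$ the target-class softmax output, and learning signal
$l[n] = f[n] - f[n-1]$, the continuous update is

$$a_c \leftarrow a_c + \alpha\, l[n] \,(a * m)[n],$$

where $m$ is the learner's *internal model* — its hypothesis about the
physiological filter, used to weight its memory of recent activity.
Two numerical readings were open:

* **Accumulation.** The update is applied as an increment (`+=`), not an
  assignment: the conditioned signal integrates over time and saturates only
  because $l \to 0$ as $f$ approaches its ceiling. No clipping or decay is
  applied.
* **Baseline.** $f[0]$ is initialized at chance $1/m$, so the first learning
  signal is the deviation from chance and $\alpha = 0$ is exactly
  stationary.

A first-order analysis explains the qualitative outcomes the simulations
show: the expected drift of the conditioned signal is proportional to
$\sum_j m[j]\,(h[j] - h[j-1])$. A matched internal model always yields
positive drift; an impulse model under the HRF gives $h[0] \approx 0$ (no
learning); a delay model under the HRF samples the falling flank
($h[3] < h[2]$, negative drift — anti-learning); blur under blur telescopes
to $0.2\,h[4]$ (slow learning), while impulse under blur captures the full
immediate weight $0.2$ (faster, matching the observed blur–impulse
advantage).

Intermittent conditioning gates $a_c$ on a 3-TR cue followed by a 3-TR wait;
the trial feedback is the mean decoded output over the wait window, and the
trial-level learning signal reinforces the mean cue-period activity.
Physiological carryover is reset between trials — the real-time protocol's
return-to-baseline period exists precisely to justify this.

Rates and sizes follow the protocol conventions: a learning rate of 1% per
20 s of simulated time (0.1%/TR continuous, 1%/trial intermittent) and 5
simulated hours (9000 TRs or 900 trials). The `hours` and `reps` arguments
scale experiments; headline pattern-correlation analyses use 1000
replicates, the conditioning-grid comparisons use 200, which keeps the
quartile band stable while holding a full grid run to minutes.

## Monte-Carlo engine and reproducibility

All replicates of a conditioning experiment advance in lockstep inside
compiled code; one TR is a handful of matrix operations over a voxels ×
replicates state. Spontaneous activity is generated inside the engine by a
seeded xoshiro256++ generator (Box–Muller normals), with the engine seed
drawn from R's RNG so that a single experiment-level seed governs
everything. Results are therefore reproducible given `(seed, reps)`; a
single replicate is not separately re-runnable, which we accepted in
exchange for a lockstep engine. The stepwise functions (`step_continuous()`,
`step_impulse()`, `run_intermittent_trial()`) are the readable reference
implementation; the test suite holds the engine to exact (1e-12) agreement
with them and with an expanded-sum oracle on supplied noise.

## Analysis conventions

Learning curves are aggregated as the replicate mean with a 50% confidence
band (the 25th–75th percentile across replicates); an optional 200-s moving
average is display-only smoothing. `categorize_learning()` labels outcomes
by the final band: *successful* (band above chance), *anti* (band below),
*none* (neither, and no significant positive OLS slope of the mean curve at
0.05), *trending* otherwise — coarse by design, so the mean final value is
reported alongside for ranking. Pattern correlations are the mean of
per-replicate Pearson r (never the correlation of the mean pattern);
zero-variance patterns yield undefined r and are excluded with a count.
Surface placements are random bijections, which leave correlations
unchanged.

## Degenerate inputs and edge conventions

* `noise_sigma = 0` produces exactly zero spontaneous activity in every
  noise model.
* Pre-session history is zero-padded (sessions start from rest); a learner
  buffer shorter than the filter support is an error.
* Orientations are reduced modulo 180° everywhere; per-TR grating averages
  use the circular mean on doubled angles, since the arithmetic mean is
  ill-defined across the 0/180 wrap.
* With both or neither rotation keys pressed the grating holds still; the
  agent command is integrated piecewise-constantly at the control rate
  (default 60 Hz, any rate of at least one tick per TR is accepted).
* Targets tied exactly at the 0.85 threshold fail (strict inequality).
* Uneven target splits (14 hidden targets over 8 orientations; 63
  intermittent targets) are drawn as equally as possible, counts differing
  by at most 1.

## Known limitations

The cognitive protocols replace the human with scriptable reference agents
(oracle, hold-still, greedy hill-climber, distance-bisection); they bound
what the environment permits, and make no claim about human strategy, so
group-level human comparisons are out of reach by construction. The decoder
is a fixed component: no generalization study is attempted, and the exact
sparse-regression implementation (L1 + CV here, automatic relevance
determination in parts of the literature) shifts pattern-correlation
magnitudes by a few hundredths while leaving every qualitative contrast
intact. The internal model itself is fixed per experiment; how a learner
might acquire one is outside the model's scope.
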