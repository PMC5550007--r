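# neurofb

A simulation testbed for closed-loop fMRI neurofeedback.

In fMRI neurofeedback a participant watches a score decoded in real time from
their own brain activity and learns to drive it up. The measured BOLD signal
is a *delayed and temporally blurred* transform of the underlying neural
activity, which creates a hard temporal credit-assignment problem — and is a
leading suspect for why many participants never learn to self-regulate.
`neurofb` rebuilds the whole loop in software so that feedback schedules,
hemodynamic response shapes and self-regulation mechanisms can be compared
without a scanner. It is aimed at neurofeedback researchers designing
protocols and at computational neuroscientists studying reinforcement
learning under delayed, blurred reward.

The package provides:

* **A voxel model of early visual cortex** — a 10×10×10 cube of 3 mm voxels,
  20% tuned to grating orientations with tuning curve
  `w(d) = (1/16)^(d/90)` (full output at the preferred orientation, 1/16 at
  orthogonal), plus spontaneous activity: spatially correlated Gaussian
  random fields (5 mm FWHM), i.i.d. Gaussian noise, or a half-and-half
  mixture of Gaussian noise and a random orientation signal.
* **Four causal temporal filters** at TR = 2 s, each normalized to unit
  weight sum: instantaneous impulse, canonical double-gamma HRF (15 TRs),
  pure 6-s delay, and 10-s moving-average blur. They serve both as the
  physiological response `h` and as a learner's internal model `m`.
* **Sparse multinomial decoders** (L1-penalized logistic regression, CV
  penalty) mapping voxel patterns to class probabilities, with the
  tuning-curve feedback score, the strict 85% success rule, and the
  intermittent (stimulate 3 TRs, average the next 3) feedback calculation.
* **Cognitive target-search protocols** — continuous and intermittent, with
  pluggable agents standing in for the participant (oracle, hold-still,
  greedy hill-climber, distance-bisection), published trial timings
  (20 / 13 / 8 s at 1×/2×/6× acceleration) and the time-to-target metric
  `20·trials − 5` s.
* **An automatic learner** that conditions spontaneous activity by
  reinforcement: `a_c ← a_c + α·(f[n] − f[n−1])·(a*m)[n]` under continuous
  feedback, or cue-gated trial updates under intermittent feedback, with a
  compiled lockstep Monte-Carlo engine, learning-curve aggregation (mean and
  50% CI), outcome categorization and pattern-correlation analysis.

## Worked example

The central contrast: an undelayed (impulse) feedback signal is easy to
condition, while a mismatched internal model under the HRF *anti-learns* —
it conditions the opposite pattern. On the two-voxel demonstration system
(`W = [(1,−1),(−1,1)]`, α = 1, σ = 0.25, chance = 0.5):

```r
library(neurofb)

run_two_voxel_demo("impulse", "impulse", n_steps = 300, reps = 1000, seed = 7)
#> <nf_learning_curve> impulse-impulse (continuous), 1000 reps x 300 steps
#>   final feedback: mean 0.993, 50% CI [0.991, 0.997], chance 0.500

run_two_voxel_demo("hrf", "delay", n_steps = 300, reps = 1000, seed = 8)
#> <nf_learning_curve> hrf-delay (continuous), 1000 reps x 300 steps
#>   final feedback: mean 0.151, 50% CI [0.107, 0.186], chance 0.500
```

The first learner's target-class output climbs from chance (0.5) to 0.99;
the second is driven far *below* chance (0.15) because crediting activity a
fixed 3 TRs back misattributes the HRF-filtered feedback changes.

The cognitive feedback score is the dot product of the decoded class
probabilities with a target-shifted tuning curve, so near-misses still score
high — with all probability mass one class (22.5°) away from the target the
thermometer shows 50%, two classes away 25%:

```r
cognitive_feedback(c(0, 1, 0, 0, 0, 0, 0, 0), target = 0)
#> [1] 0.5
cognitive_feedback(c(0, 0, 1, 0, 0, 0, 0, 0), target = 0)
#> [1] 0.25
```

Full-scale experiments follow the same pattern, e.g. five simulated hours of
intermittent cue-gated conditioning of the 10° pattern in the full V1 model:

```r
setup <- v1_conditioning_setup(seed = 1)
run_conditioning_experiment(setup$model, setup$classifier, target = 10,
                            physio = "hrf", schedule = "intermittent",
                            hours = 5, reps = 200, seed = 5)
```

`run_named_experiment()` packages the standard experiment bundles
(two-voxel demos, the 20-condition filter×internal-model grid, surface
pattern conditioning, reference-agent searches) and writes CSV + JSON
manifests; `inst/cli/neurofb.R` is a thin command-line wrapper around it.

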