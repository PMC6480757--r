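---
title: "Models and methods behind mentalspeed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mentalspeed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mentalspeed` implements a measurement pipeline for individual-differences
research on mental speed: trial screening, a battery of single RT scores,
ex-Gaussian and EZ-diffusion parameterization, attentional-blink (AB) and
recall-1-back working-memory (WMC) scoring, and worst-performance-rule (WPR)
RT-band analyses. This vignette documents the models, the defaults and why
they are set where they are, the numerical choices, and what the synthetic
generator does and does not emulate.

## Screening

Responses faster than 200 ms are treated as anticipations. Slow and fast
outliers are flagged by a *liberal* Tukey criterion — beyond three times the
interquartile range above the third or below the first quartile — computed
per person × task so that a slow person's ordinary responses are not flagged
by a fast person's distribution. Trials following an error are excluded
because post-error slowing and related adjustments contaminate them.

Two points are deliberately fixed and documented rather than inherited from
any convention:

- **Order of rules.** Post-error trials are removed first; the Tukey
  quartiles are then computed on the post-error-free trials. The order
  matters only marginally (post-error trials are a few per cent), but it is
  fixed so results are reproducible.
- **Adjacency.** "Post-error" is defined on original presentation indices:
  trial *t* is flagged iff trial *t − 1* is present in the table and was an
  error. An error trial can itself be post-error; the first trial of a block
  never is. Defining adjacency this way (rather than "previous row after
  removals") makes screening idempotent: screening a screened table removes
  nothing further.

Error trials themselves are retained — they carry the error-rate
information. All RT-based scores later use correct retained trials only;
error scores use all retained trials.

## The score battery

Per person × task: mean reciprocal RT (`mean(1000/rt)`, responses per
second — the analog of count-per-time scoring and, by Jensen's inequality,
at least `1000/mean(rt)`); mean, median, and mean log RT; quantiles at
.20/.40/.60/.80/1.00 (the last being the maximum of retained trials — the
alternative reading as a high interpolated quantile is rejected because the
retained maximum is well-defined after screening); SD, log variance, and
IQR; error rate and its probit. Zero-error cells are routine in easy tasks,
so the probit uses the `(e + 0.5)/(n + 1)` adjustment to stay finite; the
package treats this as a tool decision, since any finite rule is one.

Every quantile in the package — screening fences, score quantiles, band
medians — uses type-7 linear interpolation, stated once (`ms_quantile()`).

Winsorization for correlational analyses clamps the `ceiling(0.025 · n)`
most extreme values per side to the nearest retained order statistic,
per score and per task, across persons. The rule is idempotent and, at
n = 40, clamps exactly one value per side. Ground-truth columns from the
generator are never winsorized.

## Ex-Gaussian model

RT is modelled as Normal(μ, σ) + Exponential(τ): μ and σ describe the
distribution body, τ the slow tail; mean = μ + τ, variance = σ² + τ²,
skewness = 2τ³/(σ² + τ²)^{3/2}. The density

f(t) = (1/τ) exp((μ−t)/τ + σ²/2τ²) Φ((t−μ)/σ − σ/τ)

is evaluated through the identity
`log f = −log τ − z²/2 + [u²/2 + log Φ(u)]` with `z = (t−μ)/σ` and
`u = z − σ/τ`. The bracketed term is computed directly for `u > −6` and by
an asymptotic Mills-ratio expansion below, because the direct form cancels
catastrophically when σ/τ is large — precisely the region a likelihood
optimizer visits when data are nearly Gaussian. The τ → 0 limit is the
Gaussian density.

**Maximum likelihood** is the reference estimator: Nelder–Mead on
(μ, log σ, log τ), five starts (method-of-moments plus jittered restarts),
relative log-likelihood tolerance 1e-8, with a minimum of 40 correct trials
per cell (cells below it return missing parameters rather than unstable
fits). **The two-step estimator** mirrors a kernel/bootstrap tradition:
step 1 finds the density mode with a Gaussian kernel estimate and subtracts
the ex-Gaussian mode offset — the mode sits right of μ by an amount
determined by (σ, τ), here evaluated at moment estimates — to get μ̂;
step 2 sets τ̂ to the mean over bootstrap resamples of
(resample mean − μ̂), and σ̂ follows from the variance identity. A naive
kernel-mode estimate without the offset correction is biased by roughly +τ
when the tail is modest, which is why the correction is built in. The
two-step path exists for comparability; recovery guarantees in the test
suite attach to the MLE.

**Fit diagnostic.** Per person, observed RT quantiles at 10/25/50/75/90%
are compared with model-implied quantiles (CDF inversion by bisection,
tolerance 1e-6 ms); across persons the package reports the Pearson
correlation of observed with implied values at each level. For a single
person the root-mean-square quantile discrepancy (ms) is reported instead —
a direct misfit measure that grows under misspecification.

## EZ diffusion

The two-boundary diffusion decision process (drift ν, separation a,
unbiased start a/2, scaling constant s, non-decision time T_er) admits a
closed-form inversion of (Pc, MRT, VRT) — accuracy over all trials, mean
and variance of correct RTs in seconds. With L = logit(Pc):

x = L(L·Pc² − L·Pc + Pc − ½)/VRT, ν = sign(Pc − ½)·s·x^{1/4},
a = s²L/ν, T_er = MRT − (a/2ν)·(1 − e^y)/(1 + e^y), y = −νa/s².

The forward mapping is the exact inverse by construction (VRT is read back
off the drift relation), so the round trip is an identity to floating-point
precision. Conventions: s = 0.1 (scale-fixing only), RTs in seconds,
correct trials after screening. Perfect accuracy is mapped inward by
Pc → 1 − 1/(2n) (the paper-trail for whether studies do this is typically
silent; it is documented here as a tool decision). Pc = 0.5 is refused —
drift is unidentified at chance — and negative T_er is returned flagged as
a possible model violation. Tasks with more than two response alternatives
cannot be described by a two-boundary process and are refused with reason
`more_than_two_alternatives`.

The independent oracle is an Euler–Maruyama simulation of the Wiener
process (dX = ν·dt + s·√dt·dW, absorbing at 0 and a). The discrete step
induces a boundary-overshoot bias of order √dt — the path can cross and
return between observations — so recovery checks run at dt = 0.05–0.1 ms,
where the bias is well under the tolerances tested. The simulator is
chunked (1024 steps per vectorized block) for speed; chunking does not
change the trajectory law. Absorption probabilities are validated against
the closed form P(upper) = 1/(1 + exp(−aν/s²)).

## Attentional blink and WMC

Only trials with a correct T1 report enter the AB analysis. The per-lag
T2|T1 proportions form the report function; AB magnitude is the pooled
proportion over lags 7–8 minus the pooled proportion over lags 2–3.
Pooling is trial-weighted (sum of hits over sum of T1-correct trials), not
an unweighted mean of two proportions: after T1 conditioning the per-lag
counts are unequal, and an unweighted mean would give low-count lags undue
influence. The magnitude is allowed to be negative; flooring at zero would
bias reliability and correlation analyses. Confidence bands for the
across-person median report function use a percentile bootstrap over
persons (seeded).

Recall-1-back tasks are scored with partial credit: the proportion of
correct responses over all displays of the test block. Under the full
4-load × {6, 9, 12}-update crossing the test block has 108 displays.

## RT bands and relations

For the WPR analysis the correct-trial RTs per person × task are sorted and
cut into 20 contiguous bands; the band median is the score. Extreme-value
screening is deliberately *not* applied here — the analysis is about the
slow tail — and the median within each band already discards the few most
extreme values. When the trial count is not a multiple of 20, remainder
trials are assigned one-per-band starting from the slowest band, so the
slow bands keep the most trials where the median's robustness matters most.
Error trials are excluded for consistency with every other RT score (the
choice is documented as the package's, since conventions differ).

Criterion composites z-standardize each indicator across persons and
average what is available per person. Correlations are Pearson on
pairwise-complete pairs (optionally winsorized at 2.5% per side) with 95%
Fisher-z intervals; classical disattenuation `r/√(rel_x·rel_y)` is provided
as a lightweight observed-score stand-in for latent correlations, clipped
to [−1, 1] with a flag — clipping means the observed correlation exceeds
what the stated reliabilities permit. Latent-variable (SEM) estimation is
out of scope by design; the disattenuated values are labelled as such.

## The synthetic generator

`sim_config()` defaults describe a nine-task battery: 3 task types
(search, comparison, substitution; complexity grades 0/1/2) × 3 materials,
two blocks of 60 analyzed trials plus two warm-ups per block; two RSVP
tasks with 3 × 48 trials (lags 1–8 balanced, 18 analysis trials per lag,
one warm-up per block); three recall-1-back tasks with 12 runs crossing 4
loads with {6, 9, 12} updates (108 displays). Sample-size default is 129
persons. Base ex-Gaussian parameters per task type
(search 330/40/68 ms, comparison 750/103/228 ms, substitution
945/130/312 ms) and diffusion parameters (ν 0.40/0.22/0.18, a
0.093/0.145/0.160, T_er 0.26/0.55/0.65 s) grade with complexity the way
observed batteries do, so the qualitative descriptive ordering — mean and
SD of RT rising from search to substitution at roughly constant accuracy —
is reproduced by construction and verified by test.

Persons carry four latent standard-normal traits — S (general slowness),
L (attentional lapses), W (WMC ability), B (blink depth) — correlated by a
configurable positive-semidefinite matrix (checked by eigendecomposition;
the offending eigenvalue is named on rejection). Trait→parameter maps are
log-linear for strictly positive parameters (μ, σ, τ, ν, a, T_er), so
positivity is guaranteed; the complexity grade scales the S effect on
distribution position (`μ_i = μ0·exp(b_mu(1 + c)S_i)`). Error rate is
logistic in L, recall-1-back ability linear in W with a logistic display
model `P(correct) = plogis(θ_i − β·load)`, T1 accuracy logistic in W, and
blink depth logistic in B. The per-person report function has lag-1 sparing
(a configurable fraction of the blink spared at lag 1), its minimum at
lags 2–3, a linear recovery over lags 4–6, and its asymptote at lags 7–8 —
so the pooled-magnitude estimator is unbiased for the generative depth,
which the tests exploit. The generative link between speed traits and blink
depth is not asserted: it is a free loading (`b_depth`, and the S–B, L–B
entries of the correlation matrix) that users set.

Reproducibility: one master seed; every person × task cell draws from a
substream seeded by a position-sensitive polynomial hash of
(seed, stage, person, task). Identical seeds give bit-identical tables, and
any subset of persons can be regenerated alone.

**What the generator does not emulate:** sequential dependencies (no true
post-error slowing — post-error trials are distributionally ordinary, so
screening tests count exclusions rather than detect slowing), inter-trial
parameter variability of the full diffusion model, material effects within
a task type, practice/fatigue trends, and missingness. Passing recovery
tests therefore shows the estimators and scoring rules are correct under
the stated models, not that real data satisfy those models.

## Problem sizes and numerical tolerances

The test suite and the verification script use sizes chosen to make
Monte-Carlo error small relative to each assertion: trait-recovery at
2000 persons (correlations within ±0.05), ex-Gaussian recovery bias over
200 replicates of 500 trials (bias < 3 ms), fit-quality at 200 persons ×
500 trials (r > 0.99 per quantile level), EZ recovery from 5000 Wiener
trials at dt = 0.05 ms (±5% per parameter), AB depth recovery over 500
persons (±0.02), and WPR trajectories at 500 persons × 240 trials.

Two verification-design choices deserve explanation:

- The fit-quality check draws per-person (μ, σ, τ) independently with
  battery-like dispersion rather than through the trait-linked generator.
  Under shared trait loadings μ and σ co-vary and partially cancel in the
  fast quantiles, shrinking the between-person variance there and
  attenuating the correlation — a property of that loading structure, not
  of the diagnostic being verified.
- The WPR flat-trajectory scenario (criterion linked to distribution
  position only) uses 240 trials per person — 12 per band — and a position
  loading of 0.15. With only 6 trials per band, the slowest band's median
  inherits substantial sampling noise from the exponential tail, and the
  trajectory declines by attenuation even though the population trajectory
  is flat. Flatness is a statement about reliable band scores, and the
  scenario is sized so band scores are reliable.

Other numerical choices: ex-Gaussian CDF inversion by bisection to 1e-6 ms;
optimizer tolerance 1e-8 with five starts; the moment-based starting values
clip skewness at 0.01 and cap τ at 0.95·SD so starts stay in the interior;
the Wiener simulator caps trajectories at 20 s (never reached at sane
parameters) and floors simulated RTs at 1 ms.

## Known limitations

- The two-step ex-Gaussian estimator is a documented reconstruction of a
  sketched procedure; its kernel bandwidth (the `stats::density` default)
  and bootstrap scheme are package defaults, and its estimates can differ
  from the MLE on skew-atypical data. Differences are reported, not hidden.
- EZ assumes an unbiased starting point and no inter-trial variability;
  negative fitted T_er signals a violation and is flagged, not repaired.
- Disattenuated correlations require externally supplied reliabilities and
  inherit their errors; they are not a substitute for latent-variable
  modelling.
- The band-partition rule for trial counts not divisible by 20 is one of
  several defensible conventions; it is fixed and documented, and band
  trajectories should be compared only across analyses using the same rule.
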