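---
title: "Adaptive seamless Bayesian dose-response methodology"
author: "asbdose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive seamless Bayesian dose-response methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical machinery: the
response transformation, the hierarchical piecewise model and its priors,
the derived dose quantities, the sample-size calculators, the adaptive
decision engine, and what the synthetic-data generator does and does not
emulate.

## The endpoint and its transformation

The surrogate endpoint is a tinnitus loudness questionnaire (TLQ): "scale
your tinnitus loudness from 1 to 10", asked 21 times per session. A session
has four phases: PRE (probes T1–T5, no stimulation), a transient at
stimulation onset (T6), ONLINE (T7–T16, one probe after each of ten
2-minute picture blocks under stimulation), and POST (T17–T21).

Raw scores are made comparable across phases by detrending each point
against the starting point of its block — T1 for the PRE block, T5 for
T6–T16, T16 for the POST block — which isolates the cumulative variation
within each phase and damps longitudinal carry-over. The detrended series is
then reversed, so that larger values mean *reduced* loudness ("the more,
the better"), and shifted by a constant. The shift defaults to 5 because the
prior on the PRE-end level centres there, so the transformed scale sits near
5 at the anchors; it is purely a convenience and cancels from all contrasts.

Two consequences of this chain matter for interpretation:

* The transformed series is pinned to the shift constant at T1 by
  construction. Any latent deviation of the true process at T1 (noise,
  occasion effect) becomes a constant offset on the PRE segment that no
  analysis of the transformed data can recover. Treatment contrasts are
  unaffected because they difference across arms, not against T1.
* T5 and T16 act as references for the *following* block but are themselves
  detrended against their own block's reference; only T1 maps exactly to
  the shift constant.

The PRE reference is taken at T1, the block's starting point. The
stability-point alternative (fitting a level first) was considered and
rejected: with five points and a shallow slope the starting point is the
only estimator that needs no auxiliary model.

## The hierarchical piecewise model

The transformed response of series $i$ at time point $j$ is

$$Y_{ij} \mid \mu_{ij}, \sigma^2 \sim N(\mu_{ij}, \sigma^2),$$

with a piecewise mean: linear drift $G_P(j)=a_i+b_i(j-5)$ over PRE
(parameterised so $a$ is the level at the PRE end), a transient bridge at
T6, a four-parameter logistic $G_O(j)=f_i+(c_i-f_i)/(1+e^{-d_i(j-e_i)})$
over ONLINE (floor $f$, plateau $c$, growth intensity $d$, inflection time
$e$), and an exponential approach $G_S(j)=c_i+(g_i-c_i)(1-e^{-h_i(j-16)})$
to the POST floor $g$ with intensity $h$. The curve is intentionally
discontinuous at the phase boundaries; no continuity constraint is imposed
or tested.

The transient bridge is taken as the midpoint $(a_i+f_i)/2$ plus a
subject-level deviation $\gamma_{T}$: the onset probe sits between the PRE
endpoint and the online floor while stimulation ramps up. A variant
$f_i + a_i/2$ is available via `transient = "half_a"` for sensitivity
analysis; the midpoint is the default because it is the only reading with
coherent units.

Each curve quantity $q \in \{a,\dots,h\}$ carries fixed effects
$q_i = \beta_{0q} + \beta_{1q}\,\mathrm{SP}_i + \beta_{2q}\,\mathrm{tP}_i +
\beta_{3q}\,\mathrm{Start}_i + \gamma_{q,\mathrm{Id}(i)}$, with PEI the
reference arm and Start the raw first response of the series, entering
uncentred on its 1–10 scale (its tight prior is calibrated for that scale).
Subject random effects are shared across a subject's three sessions; every
subject-session additionally receives an occasion effect
$\gamma_{Od} \sim N(0, \lambda^2_{Od})$. The default random-effect set is
$\{c, e, f, T\}$ — the quantities whose between-subject variances the pilot
analysis could resolve — and the full nine-effect set is available through
`asb_fit(random = ...)`.

### Priors

Normal priors (second argument a **variance**) on the fixed effects:

| quantity | intercept | treatment effects | Start |
|---|---|---|---|
| a | N(5.0, 0.1) | N(0, 0.25) | N(0, 0.001) |
| b | N(0.0, 0.1) | N(0, 0.25) | N(0, 0.001) |
| c | N(4.0, 1.0) | N(0, 0.25) | N(0, 0.001) |
| d | N(2.0, 0.25) | N(0, 0.25) | N(0, 0.001) |
| e | N(11.0, 1.0) | N(0, 0.25) | N(0, 0.001) |
| f | N(4.5, 2.0) | N(0, 0.25) | N(0, 0.001) |
| g | N(5.0, 0.1) | N(0, 0.25) | N(0, 0.001) |
| h | N(0.0, 0.1) | N(0, 0.25) | N(0, 0.001) |

Precisions of all variance components ($1/\sigma^2$, $1/\lambda^2_{Od}$,
each active $1/\lambda^2_q$) carry the conventional diffuse Gamma(0.001,
0.001). The occasion variance had no documented prior in the pilot
analysis; giving it the same diffuse Gamma as the other components is this
package's choice. All hyperparameters are overridable via `asb_priors()`.

### Sampling and diagnostics

Sampling runs in JAGS (Gibbs/slice updates) with one seeded
Mersenne–Twister RNG per chain and initial values at the prior locations
with seeded jitter of one prior standard deviation — overdispersed starts,
so that chains dropped into different basins expose a multimodal posterior
(the POST mirror mode in particular) instead of jointly collapsing into
one mode; this is also the regime the Gelman–Rubin diagnostic presumes. A
fit is reproducible bit-for-bit given its seed. Initialisation failures
retry with fresh jitter up to three times.
Variance components are sampled as precisions, guaranteeing positivity in
every draw.

The convergence battery reports, per parameter: the Gelman–Rubin potential
scale reduction factor in the Brooks–Gelman form
$\sqrt{((n-1)/n\,W + B/n)/W}$ (duplicated chains give exactly
$\sqrt{(n-1)/n}$); the Geweke z-test of the first 10% against the last 50%
of a chain; and a Heidelberger–Welch check. For the latter the package
evaluates the Cramér–von Mises stationarity statistic on the *full* chain
(this is what `stationarity_pass` reports) and separately runs the
customary iterative schedule that discards initial 10% segments until a
stationary portion remains (`kept_start`, `converged`); the halfwidth test
compares the 95% halfwidth of the retained mean to 10% of its magnitude.
The full-chain reading is deliberate: a chain whose first half sits at a
different level *has not converged from its starting point*, even though
its second half passes in isolation. Non-convergence flags in
`summary()` use a Bonferroni familywise level (0.05 divided by the number
of monitored parameters), matching how multiple comparisons were handled in
the pilot analysis. Spectral densities at zero come from `coda`'s AR-fit
estimator; the Cramér–von Mises tail probability uses the standard
four-term Bessel series, saturated at 1 beyond $q = 2$ where the truncated
series stops converging (the CDF there already exceeds 0.9996).

### Identifiability of the POST segment

The pair $(g, h)$ has a mirror mode: over a five-point window, decay from
$c$ towards $g < c$ with $h > 0$ is nearly indistinguishable from the
branch $h < 0$ with $g > c$ (the exponential run-away truncated at T21).
Informative priors centred at $g = 5$, $h = 0$ keep the posterior
well-defined but both branches receive mass, so POST parameters should be
read jointly (e.g. through the carry-over $g - a$ or the fitted curve), not
marginally. The simulator's default truth keeps the POST decay mild for the
same reason.

## Derived quantities, delta and dose

From the fitted curve: online gain $c-f$; carry-over $g-a$; the time points
where the online logistic first/last differs from its floor/plateau by the
minimum clinical efficacy $\delta$,
$$\mathrm{DMin} = e - \tfrac{1}{d}\log\tfrac{c-f-\delta}{\delta}, \qquad
  \mathrm{DMax} = e + \tfrac{1}{d}\log\tfrac{c-f-\delta}{\delta},$$
defined when $c - f > 2\delta$ and $d \neq 0$ (they satisfy
$G_O(\mathrm{DMin}) = f+\delta$, $G_O(\mathrm{DMax}) = c-\delta$ and
$\mathrm{DMin}+\mathrm{DMax} = 2e$). Dose is intensity × elapsed
stimulation minutes, with the default timeline mapping model time to
minutes as $2(j-6)$: onset at T6 (dose 0), 2-minute probe spacing, 40
mA·min for a full 2 mA session. `derive_quantities()` pushes every
posterior draw through these maps, excluding (and counting) draws that
violate the preconditions or fall outside the stimulation window.

$\delta$ is half the PEI effect. Descriptively it is computed as half the
displacement of the mean online transformed response from the mean PRE
response across PEI series; in posterior form it is $0.5\,(c-f)$ at PEI
covariates per draw. The two agree when the online curve spends most of the
window at its plateau and differ (descriptive < posterior) when the
logistic rises late; both are reported rather than reconciled.

The individuals control chart uses natural limits at mean ± 2.66 × mean
moving range — the standard moving-range estimate of three sigmas; the
constant is an argument.

## Sample-size calculators

Exact formulas behind the three calculators (all with
$z^2 = (z_{1-\alpha/2}+z_{1-\beta})^2$, one-sided variants available):

* **CV difference** (efficacy of the active control):
  $n = \lceil z^2 (cv_1^2+cv_2^2)/(cv_2-cv_1)^2 \rceil$.
* **Repeated measures** (treatment difference over $m$ online probes with
  intra-class correlation $\rho$):
  $n = \lceil \mathrm{groups}\; z^2 \sigma^2 (1+(m-1)\rho)/(m\delta^2)\rceil$.
* **Dose contrast** (profile contrast over the online means):
  $n = \lceil z^2 \sigma^2 \sum c_j^2 / (\sum c_j \mu_j)^2 \rceil$.

These are the package's documented defaults behind a common interface; the
published tables this design family reports could not be tied to a single
closed form, so the test suite pins the calculators to worked arithmetic
examples and to their monotonicity properties (nondecreasing in power,
nonincreasing in significance level and effect size) rather than to any
table. `posterior_sample_size()` evaluates a calculator on every posterior
draw of its inputs, yielding the sample-size distribution and a sequential
sampling plan at the 25/50/75/90% quantiles (nondecreasing by
construction), with precondition-violating draws excluded and counted.

## Uncertainty reduction and the adaptive engine

Between interims $i-1$ and $i$, for any quantity: (1) test equivalence of
the posterior means with a normal-approximation Bayes factor
$BF_{01} = N(d;0,se)/N(d;0,\sqrt{se^2+\tau^2})$, where $d$ is the mean
difference, $se$ combines both posterior sds, and $\tau = 5$ spans the
plausible effect range of the 10-point scale ($BF_{01} > 3$, substantial
evidence, declares equivalence; both knobs are arguments); (2) compare
equal-tailed 95% interval lengths; (3) report $R = L_i/L_{i-1}$ and
$UR = (1-R)\times 100\%$. For a Normal mean UR follows the $1/\sqrt{n}$
law, e.g. exactly 50% between cohorts of 5 and 20 observations. A
coefficient-of-variation variant replaces lengths with posterior CVs.

The processed-$\delta$ state machine applies three outcomes at each
$\delta$-confirmation interim, using a credibility margin defaulting to
half the working $\delta$ (the published design names no numeric rule; the
margin fraction is an argument): interval wider than the margin — retain
the anterior $\delta$ and continue N3 interims; within margin with a
significant difference ($BF_{01} < 1/3$) — replace $\delta$ and re-adapt;
within margin and insignificant — $\delta$ is valid and confirmation ends.
The decision engine then maps the posterior probabilities of H1
(SP-PEI equivalence within $\pm\delta$), H2 (tP superiority beyond
$\delta$) and Dose (positive dose-response) to the roadmap actions: stop
when H2 is credibly rejected; define the dose window and go multisession
when H2 and Dose are both credible; eliminate the PEI session when H1 is
credible; otherwise continue with N4/N5/N6 interims (N6 is N5 recomputed
conditional on credible H2 — an interpretation, flagged as such). While
$\delta$ is merely processed, every conclusion carries its posterior
probability as a certainty ratio and recruitment stays on N3.

## The simulator and what passing tests mean

`simulate_tlq()` generates full Williams-crossover cohorts from the model
itself: balanced random assignment over the six sequence orderings, subject
and occasion effects, Normal noise around the piecewise curve, and
inversion of the transformation chain back to integer Likert scores
(rounding half away from zero, clamping to 1–10, with a warning when more
than 20% of values clamp). Start values are drawn uniformly from {4,…,8},
the mid-scale baselines typical of this population.

Default truth (chosen once as the package's study conditions): intercepts
$a=5, b=0, c=5.9, d=2, e=9, f=5, g=5.1, h=0.2$; treatment effects $+0.4$
(SP) and $+0.7$ (tP) on $c$ and $-0.5$ on $e$; Start effects 0;
$\sigma^2=0.2$; random-effect sds 0.3/0.7/0.3/0.2 on $c/e/f/T$; occasion
sd 0.2. This gives a PEI online gain of 0.9, so the minimum clinical
efficacy sits near 0.4 transformed units — the magnitude a pilot in this
population reports — while remaining inside the priors so that recovery
experiments are a fair calibration check.

The recovery experiment (`parameter_recovery()`) runs at 20 subjects × 20
replicates with 2 chains × 2000 iterations. By default it fits the model's
own latent transformed response (`response = "latent"`) — the calibration
check proper: data drawn from the hierarchical model, fitted by it. The
`response = "likert"` mode instead pushes the reconstructed integer scores
back through the transformation chain before fitting; because the chain
anchors T1 (see above) and adds rounding error, PRE-segment parameters are
structurally misspecified under that mode and nominal coverage is not
expected for them — the mode exists to quantify exactly that cost. the operating-characteristic
harness defaults to a fast normal-approximation interim analysis
(per-series online-vs-PRE contrasts) so that hundreds of simulated trials
are tractable, with `method = "mcmc"` available when fidelity to the full
model matters. These sizes are the package's chosen experiment scale: large
enough that binomial error on an 80% coverage bound is modest, small enough
to run routinely.

What the simulator does **not** emulate: integer-scale floor/ceiling
behaviour beyond simple clamping (real respondents saturate
asymmetrically); response-time variability in probe timestamps (the dose
timeline is exact); missing probes and dropouts (the transform requires
complete 21-point series; imputation is out of scope); serial correlation
beyond the occasion effect; and any coupling between the Start covariate
and the trajectory other than through the fixed effects (the generating
baseline is the covariate, while the reconstructed T1 score can differ from
it by the T1 noise). Passing tests therefore demonstrate internal
consistency of model, transform and inference — not robustness to these
real-data features.

## Numerical choices and degenerate inputs

* Logistic evaluation inside the sampler uses JAGS's `ilogit`; POST
  exponentials can overflow only for $|h|$ far outside the prior's support,
  in which case initialisation retries with fresh jitter.
* Initialisation dispersion is a fit control (`init_jitter`, default one
  prior sd): overdispersed starts for ordinary fits, tighter starts for
  near-degenerate residual variances where a far-started chain cannot reach
  the peaked posterior within the burn-in.
* `dmin_dmax()` rejects $\delta \le 0$, $d = 0$ and gains below $2\delta$
  with errors naming the violated inequality; posterior propagation
  excludes such draws and reports the excluded fraction instead of failing.
* Constant chains short-circuit the diagnostics (Geweke z = 0, halfwidth
  ratio 0, stationarity pass) rather than dividing by a zero spectral
  density.
* Draw files store values as `%.17g` text, so round-trips are bit-exact.
* Williams assignment draws `floor(n/6)` full permutation blocks plus a
  without-replacement remainder, guaranteeing per-ordering counts within 1.
* Likert reconstruction rounds half away from zero — symmetric around the
  scale midpoint, unlike banker's rounding.

## Known limitations

* The POST mirror mode above; read $(g,h)$ jointly.
* At pilot scale (6 subjects) the posterior for $\delta$ is wide, and
  descriptive and posterior $\delta$ can differ by a factor approaching 2
  when the online inflection is late; the adaptive engine is designed to
  consume that uncertainty (processed-$\delta$ states), not hide it.
* The equivalence Bayes factor is a normal approximation; with strongly
  skewed posteriors (e.g. variance components) use the CV-based
  uncertainty-reduction mode.
* The fast operating-characteristic engine ignores random-effect shrinkage
  and will be slightly anticonservative for small cohorts relative to the
  full MCMC analysis.
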