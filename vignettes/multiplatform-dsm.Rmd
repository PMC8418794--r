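---
title: "Multi-platform density surface models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-platform density surface models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdsm)
```

## The model

Density surface modelling is a two-stage method for estimating spatial
abundance from transect surveys. Stage one models the observation process: a
detection function $g(x)$ gives the probability of detecting an object at
perpendicular (line) or radial (point) distance $x$, and integrating distance
out yields the average detection probability within the covered strip,

$$p = \frac{1}{w}\int_0^w g(x)\,dx \quad\text{(lines)},\qquad
  p = \frac{2}{w^2}\int_0^w r\,g(r)\,dr \quad\text{(points)}.$$

Stage two models counts $n_i$ aggregated to short effort segments $i$ of area
$a_i$ with a GAM: $\mathbb{E}[n_i] = a_i\,p(\hat\theta; z_i)\,
\exp(\beta_0 + \sum_m f_m(x_{im}))$, where the $f_m$ are penalized spline
basis expansions and the product $a_i p_i$ — the "effective area" — enters as
an offset on the log link. The count distribution is Tweedie, negative
binomial, Poisson or quasi-Poisson.

When several survey platforms contribute data, each platform $k$ has its own
detection process $p_k(\theta_k; z_{j_k})$: different key functions
(half-normal vs hazard-rate), binned vs exact distances, strips with certain
detection ($p_k \equiv 1$), or double-observer protocols with imperfect
trackline detection. `mdsm` fits one segment-count model across all
platforms, with three variants of increasing flexibility:

* **A** — shared intercept and smooths: platform differences are attributed
  to detectability alone;
* **B** — per-platform intercepts $\beta_k$ (an unpenalized factor with no
  global intercept): densities differ by a constant factor;
* **C** — factor-smooth interactions: a common intercept, shared smooths,
  and per-platform *deviation* smooths $f(x, k)$ fitted as centred
  deviations from the reference surface, each deviation with its own
  shrinkage penalty.

Because the deviation smooths in C are centred and fully penalized
(shrinkage bases), sending their smoothing parameters to infinity recovers
variant A exactly; the test suite checks this collapse to a fitted-value gap
below $10^{-3}$. A consequence worth knowing: C cannot absorb a *constant*
between-platform density shift — that is variant B's job, and a combined
B+C structure can be requested through the `formula` argument of
`fit_dsm()`.

Two practical devices complete the data model. Simultaneous protocols (e.g.
birds on the water by line transect and flying birds by strip, recorded on
the same effort) are handled by duplicating segments — $n_1$ physical
segments become $2 n_1$ analysis rows, each copy with its own platform,
detectability and count. Predictions on such designs are made per platform
and summed, because the platforms record disjoint behavioural subsets of one
population; this summation applies to variant A as well, not only B/C.
Second, trackline detection failure and availability enter as multipliers:
the offset is $\log(a\,p\,g(0)\,u)$.

### Trackline detection from double-observer data

For independent-observer platforms, each observer's detections are Bernoulli
trials for the other: an object seen by observer 2 is a success for observer
1 if it was a duplicate. A pooled logistic model for the conditional
detection probability (distance plus optional covariates; per-observer terms
via `observer` in the formula) is fitted by maximum likelihood, and the
combined trackline probability under full independence is
$g(0) = p_1(0) + p_2(0) - p_1(0)p_2(0)$. The platform's detectability is the
product $g(0)\,p(\hat\theta; z)$; its parameter vector stacks both parts
with a block-diagonal covariance, so both feed variance propagation. Point
independence (independence assumed only at zero distance) is deliberately
out of scope; full independence is the implemented observer mode.

### Variance propagation

Each non-strip platform's detection fit carries a covariance
$V_{\theta_k}$; assuming independence between platforms these stack into the
block-diagonal $V_\theta$. To propagate this first-stage uncertainty, the
count model is refitted with extra columns $D$: for each platform, the
per-segment derivative $\partial \log p_k / \partial \theta_k$ at
$\hat\theta_k$ (zero elsewhere). The coefficients on $D$ are treated as a
random effect with mean zero and covariance *fixed* at $V_\theta$ — its
precision enters as a ridge penalty whose smoothing parameter is pinned at
1, while the original smoothing parameters and any Tweedie/negative-binomial
nuisance parameters are also held at their estimates. Fixing the prior is
what makes this *propagation* rather than re-estimation: the refit may move
coefficients slightly (the spatial covariates inform detectability), and its
posterior covariance $V_{\beta,\theta}$ includes the $\beta$–$\theta$
cross-covariance rather than assuming it zero. With $V_\theta = 0$ the
procedure is a no-op (verified to $10^{-6}$), and when the detection
covariates are spatially constant the propagated CV agrees with the
delta-method combination $\sqrt{\mathrm{cv}_{\mathrm{GAM}}^2 +
\mathrm{cv}_p^2}$ (the package also provides `delta_detection_cv()` as the
independence-assuming alternative and as a fallback if the refit fails).

### Abundance and its uncertainty

Abundance is $\hat N = \mathbf{a} \exp(X_p \beta)$ over a prediction grid.
Uncertainty comes from posterior simulation: draw $\beta^*_b$,
$b = 1,\dots,B$, from the coefficient posterior, recompute
$\hat N^*_b = \mathbf{a}\exp(X_p\beta^*_b)$, and summarize empirically —
total and per-cell means, variances and CVs. Two samplers are provided: a
multivariate normal approximation $N(\hat\beta, V_{\beta,\theta})$, and an
adaptive random-walk Metropolis–Hastings chain on the penalized-likelihood
posterior for when the normal approximation is doubtful (skewed posteriors,
small counts). Fixed multipliers with external uncertainty (an aerial g(0)
of 0.67, an availability of 0.37, say) never enter the refit; their CVs are
combined at the end by the squared-CV rule
$\mathrm{cv}_{\mathrm{tot}} = \sqrt{\sum_c \mathrm{cv}_c^2}$, which assumes
independence between those external estimates and the survey.

## Tunable parameters

* `truncation_w` (distance units; per platform): observations beyond it are
  dropped before fitting. Bin cutpoints must start at 0 and end at `w`; bins
  are half-open $[c_j, c_{j+1})$ with the last closed — boundary ties have
  probability zero under continuous models, so one uniform convention is
  used.
* Detection scale covariates enter as $\sigma = \exp(z^\top\theta_\sigma)$
  (log link, the multiple-covariate distance sampling convention) and must
  be segment-level, because detectability re-enters the count model through
  a per-segment offset; observation-level covariates are rejected at fit
  time. The hazard-rate shape is parameterized $b = 1 + \exp(\phi)$ to
  enforce $b > 1$.
* `k` per smooth term: the maximum basis size, honoured exactly as
  configured (e.g. 5 for small environmental smooths, up to ~100 for a
  spatial smooth on a data-rich survey). Default basis `"ts"` — thin-plate
  regression splines with shrinkage, so REML can remove a whole term.
* `family`: `"tweedie"` is the default for overdispersed counts; its power
  parameter is estimated jointly within the REML iteration (the fitting
  engine supports this natively and it removes a layer of grid profiling).
* `B`: posterior draws; 1000 in examples and tests, 10000 recommended for
  reported intervals. MH burn-in is `B/5` with the proposal scaled towards
  0.2–0.4 acceptance; thinning 1.

## Numerical choices

Average detection probabilities use closed forms for the half-normal
(`pnorm`/`expm1`-based, stable for $w \ll \sigma$) and adaptive quadrature
at absolute tolerance $10^{-10}$ for the hazard-rate; the two routes agree
to $10^{-8}$ where both exist. Gradients $\partial\log p/\partial\theta$ use
central finite differences with step $10^{-5}(1+|\theta|)$ — checked against
the analytic half-normal derivative to $10^{-5}$ — rather than an analytic
fast path, keeping one code path for all keys. Detection likelihoods are
maximized by BFGS from $\sigma_0 = 0.6\,w$; the covariance is the inverse
observed information, with an eigenvalue check and a pseudo-inverse fallback
(flagged by a warning) for non-positive-definite Hessians. Logistic
separation in the conditional model triggers a weak ridge refit. The
penalized-spline stage (bases, penalized IRLS, REML, factor smooths,
Tweedie/NB families) is delegated to `mgcv`, the standard engine for these
models; this package's contribution is everything around it — the
multi-platform offsets, the MRDS combination, the fixed-prior propagation
refit and the posterior abundance machinery.

## The simulator

`sim_design()`/`simulate_survey()` generate multi-platform surveys with
known truth: animals placed by an inhomogeneous Poisson process (intensity
evaluated at segment centres), parallel north-south lines split into equal
segments, uniform within-strip distances, availability thinning, per-key
detection thinning, independent per-observer Bernoulli detections with
duplicates for double-observer platforms, and optional distance binning.
Overdispersion is available as a gamma-mixed Poisson (negative binomial);
group sizes as $1 + \mathrm{Poisson}(\lambda)$. Each platform runs under its
own RNG substream (root seed + platform index, in registry order), making
tables reproducible and platforms independent.

Three profiles define the study conditions used throughout the tests: a
minimal single-platform design (20 segments); a seabird-style design —
one-sided binned line transect (cutpoints 0/50/100/200/300 m) plus a
simultaneous one-sided 300 m strip on duplicated segments, with a 60/40
swimming/flying behavioural split; and a two-survey design — shipboard
independent-observer hazard-rate platform truncated at 6 km plus an aerial
hazard-rate platform truncated at 900 m with fixed $g(0) = 0.67$ and
availability 0.37 (CVs 0.1 each). Densities and transect counts were chosen
once so that a typical replicate yields a few hundred detections — enough
for stable detection fits at desk scale.

What the simulator does *not* emulate bounds what passing tests show about
real data: no animal movement or responsive avoidance, no spatial
correlation in availability, no observation-level detection covariates, no
group-size-dependent detectability, and intensity constant within a segment.
Recovery and coverage results here demonstrate internal consistency of the
estimator chain, not robustness to those field realities.

## Verification design

Independent oracles back each stage: quadrature vs closed forms for $p$;
a grid-search likelihood maximizer for the half-normal scale; a generic IRLS
GLM for unpenalized count fits (agreement to $10^{-8}$); an explicit
compound-Poisson-gamma series for the Tweedie log-density; the
inclusion–exclusion arithmetic for $g(0)$; and the delta method for
propagated CVs. Calibration checks run on seeded simulations: the
half-normal scale is recovered within 3 Monte Carlo SEs (and bias under 5%)
over 100 replicates of 500 distances; a between-platform density ratio of 2
is recovered by variant B within 3 SEs; and 95% posterior intervals for
total abundance cover the simulated truth in 90–98% of 200 surveys
(single-platform design, 60 segments, Poisson counts, $B = 300$ draws —
sizes chosen to keep the whole study at desk scale).

## Known limitations

Detection parameters cannot be shared across platforms; each platform's
detection function is fitted separately (sharing would require a joint
likelihood across protocols). Variant C omits per-platform intercepts by
construction (see above). Availability is a fixed per-segment multiplier,
not a fitted sub-model (no dive-cycle or hidden-Markov availability).
Observed-vs-expected diagnostics use plain Pearson aggregation of fitted
means — with rounded published inputs this reproduces a platform-blind
statistic exactly but can differ in the second decimal from values computed
on unrounded expectations. The MH sampler supports Poisson, negative
binomial and Tweedie (not quasi-Poisson, which has no likelihood to sample).
Group size enters only through summed individual counts; size-biased
detection is out of scope.
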