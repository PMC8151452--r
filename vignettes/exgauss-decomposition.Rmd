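---
title: "Ex-Gaussian decomposition of masked-priming response times"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ex-Gaussian decomposition of masked-priming response times}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exgaussrt)
```

## The model

Response times (RTs) from recognition tasks are positively skewed: a roughly
Gaussian body with a long slow tail. The ex-Gaussian distribution models an
RT as the sum of a normal component, with location $\mu$ and scale $\sigma$
(both in ms), and an independent exponential component with mean $\tau$ (ms).
Its density is

$$f(x) = \frac{1}{\tau}\exp\!\left(\frac{\mu-x}{\tau} +
  \frac{\sigma^2}{2\tau^2}\right)
  \Phi\!\left(\frac{x-\mu}{\sigma} - \frac{\sigma}{\tau}\right),$$

with mean $\mu+\tau$, variance $\sigma^2+\tau^2$ and skewness
$2\tau^3/(\sigma^2+\tau^2)^{3/2}$. Decomposing an RT distribution into
$(\mu, \sigma, \tau)$ separates shifts of the distribution body from changes
in the tail, which is why the model is popular for chronometric data; the
package treats the components purely descriptively and takes no position on
their cognitive interpretation.

The experimental design the package mirrors is a masked-priming
celebrity-recognition study: two participant groups (Spain, USA; 50 each),
targets that are faces or written names, test stimuli (celebrities, to be
identified) versus distractors (unknowns, to be rejected), and four prime
conditions (identity, related, unrelated of the same nature, unrelated of a
different nature). Crossing these gives 32 condition cells; correct-response
RTs are pooled across participants within each cell and each pooled sample
is fitted separately.

## Preprocessing

Two exclusion rules are applied before fitting, in either order (they
commute): RTs of incorrect responses are dropped, and RTs outside the
250–1500 ms window are trimmed. The bounds are inclusive — only strictly
smaller or larger values are excluded. Trimming more than 5% of trials
raises a warning, not an error: the 5% figure is an aim for a clean dataset,
and an analysis of a noisier one should proceed with the flag visible.
Hit rates are computed per cell on all trials, before any RT-based
exclusion, so a fast-but-wrong response still counts against accuracy.

The pooled descriptives are the mean $M$, standard deviation $S$ and
skewness statistic $t = m_3/S^3$, using population ($1/n$) moments. The
population convention is deliberate: it makes the sample statistics the
exact empirical counterparts of the closed-form moments above, so the
moment-based starting values below are the exact inverse of the moment map.

## Maximum-likelihood fitting

Each pooled cell is fitted by maximising the log-likelihood
$\ell(\mu,\sigma,\tau)$ with a maximum-ascent search in parameter space.
The starting point inverts the moment identities:
$\tau_0 = S\,(t/2)^{1/3}$, $\mu_0 = M - \tau_0$,
$\sigma_0 = \sqrt{S^2 - \tau_0^2}$. Two fallbacks absorb samples the map
cannot handle: for $t \le 0$ a Gaussian-dominant start
($\tau_0 = 0.1\,S$), and for $t \ge 2$, where $\sigma_0^2$ would be
non-positive, a floor of $\sigma_0 = 0.05\,S$.

The ascent follows the analytic gradient with a backtracking line search:
the initial step is scaled per parameter by $S^2/n$ (a rough inverse
curvature derived from the start), halved until the likelihood increases,
and re-grown after accepted steps. Steps that would push $\sigma$ or $\tau$
below $10^{-6}\,S$ are rejected, keeping the search in the original
parameter space rather than reparameterising — the convergence criterion,
a gradient modulus below $\varepsilon = 10^{-8}$, is stated in that space.

Two numerical points matter in practice:

* **Log-domain evaluation.** The density's exponential factor overflows for
  large $\sigma/\tau$ while the normal-tail factor underflows; log-density
  and gradient are therefore evaluated via `pnorm(..., log.p = TRUE)` and a
  log-domain inverse Mills ratio, which is stable for $\sigma/\tau$ well
  beyond $10^3$.
* **Curvature polish.** Near the maximum the likelihood differences between
  successive ascent iterates drop below floating-point resolution (an
  increase of $10^{-11}$ cannot be verified against a log-likelihood of
  magnitude $10^3$–$10^4$) long before the gradient modulus reaches
  $10^{-8}$. The final iterations therefore switch to damped Newton steps on
  the gradient, using the numerical curvature, accepted only while the
  gradient norm decreases. The stationary point is the same; the polish
  merely drives the gradient modulus through its last few orders of
  magnitude. In validation against an independent quasi-Newton optimiser
  the two routes agree to all reported digits.

Samples with fewer than 10 RTs or zero variance are refused, and a cell
whose likelihood maximum lies on the $\sigma \to 0$ boundary (possible for
small pooled samples when the generating $\sigma$ is a few ms) is reported
as `not_converged` rather than silently clamped: the interior-point
convergence criterion has no solution there, and at realistic pooled sizes
(hundreds of RTs per cell) the case does not arise.

```{r fit-example}
x <- rexgauss(1000, mu = 417.56, sigma = 18.72, tau = 227.72, seed = 1)
fit_exgauss(x)
```

## Goodness of fit by parametric bootstrap

Fit quality per cell is summarised by the Kolmogorov–Smirnov statistic
between the pooled sample and its fitted ex-Gaussian, calibrated by
parametric bootstrap: 1000 samples of the same size are drawn from the
fitted distribution and the p-value is the fraction whose KS statistic
exceeds the observed one (ties counted toward the larger p). Larger p means
a better fit. By default every bootstrap KS is computed against the same
fixed fitted parameters; `refit = TRUE` refits each bootstrap sample first
(the Lilliefors-style calibration, conservative because it accounts for the
parameters having been estimated from the data). The fixed-parameter
default matches the procedure the pipeline mirrors, and under it the null
calibration is clean: for data actually drawn from the tested parameters
the p-values are uniform to within binomial error. Reports round p to two
decimals, so a computed 0.004 prints as 0.00.

## Uncertainties from the iso-likelihood surface

In the three-dimensional parameter space, the set of points whose
log-likelihood is 0.5 below the maximum bounds (in the quadratic regime)
the ~68% confidence region. The package samples at least 1000 points of
this surface: directions are drawn uniformly on the sphere after whitening
by the numerical curvature at the MLE — so elongated surfaces are sampled
evenly along all principal axes — and a bisection along each ray finds the
radius where the log-likelihood crosses the target within $10^{-8}$. Rays
that would leave the $\sigma, \tau > 0$ domain before crossing are redrawn;
if the curvature is not negative definite the sampler falls back to raw
magnitude-scaled directions.

The dispersion of the surface is summarised per parameter by its
**half-extent**: the largest absolute deviation of the surface points from
the MLE along that axis. For a quadratic log-likelihood this equals the
tangent extent of the $\Delta\ell = 0.5$ ellipsoid, i.e. exactly the
marginal (profile-likelihood) standard error, so "MLE ± 1 sd" carries the
nominal ~68% coverage and "MLE ± 1.96 sd" the 95% coverage. This choice is
deliberate: the raw per-coordinate standard deviation of points sampled
uniformly on the whitened sphere averages over directions and
underestimates the marginal standard error by $\sqrt{3}$ in three
dimensions (its ±1 interval would cover only ~44%), which would defeat the
1.96 scaling. The half-extent is the one summary that is simultaneously a
per-parameter dispersion of the sampled surface and calibrated as a
confidence interval; empirical coverage at $n = 500$ is verified in the
test suite.

```{r surface-example}
fit <- fit_exgauss(x)
surf <- sample_iso_surface(x, fit, seed = 2)
surface_uncertainties(surf, fit)
```

## The synthetic cohort

No trial-level data are published for the study the pipeline mirrors, so
the package ships a generator that emulates its structure: 50 participants
per country, each seeing all 16 of their country's cells (2 target natures
× 2 roles × 4 primes) at 14 trials per cell — 224 trials per participant,
consistent with 28 test and 28 distractor stimuli per task under repeated
measures. The published per-condition decomposition does not state how the
224 trials split across cells; the balanced 14-per-cell split is the
package's choice and the only one consistent with the design counts.

Clean RTs are drawn cell-wise as normal-plus-exponential sums at the
reference $(\mu, \sigma, \tau)$ of `default_condition_table()`; correctness
is Bernoulli at the cell's reference hit rate. A contaminant fraction
(default 2%) replaces the RT with a uniform draw from
$[80, 250) \cup (1500, 2500]$ ms — outside the trimming window on both
sides, weighted by interval length. The contaminant model is synthetic-only
plumbing to exercise the trimming stage; real anticipations and lapses are
not uniform. Other simplifications: no stimulus-identity effects, no
familiarity or frequency structure, no participant-level random effects
(the pipeline pools across participants, so per-participant shifts are not
identifiable from its output anyway), and prime-sequence timings carried as
metadata only. Passing tests on this generator therefore validate the
estimation machinery — recovery, calibration, coverage — not the
psychological adequacy of the ex-Gaussian for any particular real dataset.

Reproducibility: one master seed; per-participant substreams are derived
deterministically from it, so regenerating any participant's trials does
not depend on generation order. RTs are rounded to 0.001 ms so the CSV
round trip is bit-exact.

## Pipeline defaults and problem sizes

`run_pipeline()` chains the stages per cell and degrades failures to a row
status (`insufficient_data` under 10 pooled RTs, `not_converged`) without
aborting the run. Defaults: 250/1500 ms window, $\varepsilon = 10^{-8}$,
$10^5$ iteration cap, 1000 bootstrap samples, 1024 surface points at
$\Delta\ell = 0.5$, 1.96 scaling. The validation suite sizes its
simulations as: 50 replicates of $n = 1000$ for parameter recovery per
reference row (Monte-Carlo standard error of the mean estimate well under
the ±5–6 ms acceptance bands), and 200 replicates of $n = 500$ for interval
coverage (binomial standard error ≈ 3.3 points at 68%, ≈ 1.5 at 95%).

## Known limitations

* The likelihood treats trimmed samples as complete data — no truncation
  correction — matching the procedure the pipeline mirrors; for windows
  that clip a substantial tail mass the components absorb the bias.
* Boundary maxima at $\sigma \to 0$ are reported, not resolved; a
  shifted-exponential sub-model would be needed to fit them.
* The bootstrap p-value resolution is $1/n_\text{boot}$; with the default
  1000 samples, p-values below 0.001 are reported as 0.
* Surface-based intervals are symmetric by construction (±1.96 sd); they do
  not capture asymmetry of the likelihood in small samples.
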