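---
title: "Multivariate Bayesian inference of difference structure-factor amplitudes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivariate Bayesian inference of difference structure-factor amplitudes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refdelta)
```

## The problem

Several crystallographic techniques — anomalous phasing from Friedel
pairs, time-resolved pump–probe diffraction — depend on the *difference*
between two structure-factor amplitudes of the same reflection,
$\Delta F = F_1 - F_2$.  Because intensities, not amplitudes, are
observed ($I \propto F^2$), and because weak reflections routinely go
negative after background subtraction, estimating $\Delta F$ well is
hard exactly where the signal matters most.

Referencing strategies (inverse-beam geometry, interleaved pump/probe
cycles) record the two observations of a pair in close succession so
that systematic errors are *shared* within a pair.  Standard merging
treats the two observation sets independently and discards that shared
structure.  `refdelta` keeps it: each pair $(I_{1i}, I_{2i})$ is one
draw from a bivariate normal whose correlation carries the
systematic-error covariance.

## The generative model behind the synthetic data

`generate_pairs()` draws, for pair $i$,

$$I_{1i} = F_{1,\mathrm{true}}^2 + s_i + r_{1i}, \qquad
  I_{2i} = F_{2,\mathrm{true}}^2 + s_i + r_{2i},$$

with one shared systematic draw $s_i \sim N(\mu_{\mathrm{sys}},
\sigma_{\mathrm{sys}})$ per pair and independent random errors
$r_{ki} \sim N(0, \sigma_{\mathrm{ran}})$.  The shared-draw reading is
the only one under which $\mathrm{cov}(I_1, I_2) =
\sigma_{\mathrm{sys}}^2$ and referencing helps at all; it is also what
produces the tight diagonal scatter seen in real referenced data.  The
implied moments —
$E[I_k] = F_k^2 + \mu_{\mathrm{sys}}$,
$\mathrm{var}(I_1 - I_2) = 2\sigma_{\mathrm{ran}}^2$ — are asserted by
the test suite at $n = 10^5$.

Draws are consumed from one seeded stream in the fixed order
$(s_1, r_{11}, r_{21}, s_2, \dots)$, so a `(model, seed)` pair is
bitwise reproducible.  Negative observations are never clipped:
handling them is the method's purpose.  The generator emulates the
error structure of corrected, commonly scaled unmerged intensities of a
*single* reflection; it does not emulate a full reflection pool (no
Wilson-distributed amplitudes across resolution shells), so passing
tests say nothing about scaling or correction steps upstream of this
method.

## The two models

**Multivariate.**
$(I_{1i}, I_{2i}) \sim N_2\!\big((F_1^2, F_2^2),\ \Sigma\big)$ with
$\Sigma = \mathrm{diag}(\sigma_1,\sigma_2)\,\Omega\,
\mathrm{diag}(\sigma_1,\sigma_2)$ and
$\Omega = \begin{pmatrix}1&\rho\\\rho&1\end{pmatrix}$.
Priors: $F_1, F_2$ uniform on $(0, 10^8)$ or normal truncated to
$F \ge 0$; $\sigma_1, \sigma_2$ log-normal; $\Omega$ LKJ with shape
$\eta$.

**Univariate baseline.**  The same with the pairing ignored:
$I_{ki} \sim N(F_k^2, \sigma_k)$ independently.  It factorizes, and
equals the multivariate likelihood at $\rho = 0$ (asserted to
$10^{-10}$).

Why the multivariate model wins: the likelihood mean is constrained to
the nonnegative quadrant.  When one set's sample mean is negative, the
constraint binds, and the correlation transfers the correction to the
partner amplitude — conditionally,
$\mu_2 \approx \bar I_2 + \rho\frac{\sigma_2}{\sigma_1}(0 - \bar I_1)$.
The univariate model has no such channel; each strongly negative set
collapses onto a half-normal posterior hugging zero, and $\Delta F$ is
biased toward zero.

Two modelling conventions are not forced by the data contract and are
documented choices here: the likelihood mean is $(F_1^2, F_2^2)$ (the
intensity–amplitude relation, also what the posterior-predictive check
is centred on), and $\Delta F = F_1 - F_2$.  $\Delta F$ is always
computed sample-by-sample from the trace; the median of per-sample
differences is generally not the difference of medians, and a
constructed counterexample in the tests keeps it that way.

## Priors and their defaults

* Amplitudes: `uniform(0, 1e8)` by default — effectively flat over any
  realistic amplitude on a common scale.  The alternative
  `truncated_normal(mu = 0.7, sigma = 7)` is a weakly biased choice
  used in the low-multiplicity study; with `sigma -> Inf` it approaches
  the uniform prior (asserted within $10^{-3}$).
* $\sigma_1, \sigma_2$: log-normal.  The hyperparameters are not pinned
  down by the reference protocol; the defaults `mu_log = 0`,
  `sigma_log = 1` are weakly informative on the unit intensity scale of
  the simulations and are overridable in `prior_config()`.
* Correlation: LKJ with `eta = 1` by default.  For a 2×2 matrix the
  density is $\propto (1-\rho^2)^{\eta-1}$; at $\eta = 1$ this is the
  *uniform* distribution over correlations (the standard LKJ
  convention), which we adopt even though the phrase "reduces to the
  identity distribution" in the source literature could also be read as
  a point mass at the identity matrix.  All prior densities are
  normalized and quadrature-checked to $10^{-6}$.

Out-of-support evaluations return `-Inf` rather than raising, so the
sampler rejects them uniformly; constructors still validate
configuration strictly.

## Sampling

`run_metropolis()` is Metropolis-within-Gibbs with Gaussian proposals,
one coordinate at a time.  The reference protocol — 50 000 iterations,
first 20 000 discarded, two chains pooled after individual burn-in — is
the `chain_config()` default.

* **Transforms.**  $\log\sigma_1$, $\log\sigma_2$ and
  $\operatorname{atanh}\rho$ are sampled unconstrained (with Jacobian
  terms in the target); $F_1, F_2$ stay on the natural scale, negative
  proposals dying through the zero prior mass.  This keeps the
  amplitude posterior's boundary behaviour (half-normal-like mass at 0)
  untouched by any transform artifact.
* **Adaptation.**  Proposal scales are tuned every 200 iterations
  *during burn-in only*, toward a 20–45% acceptance window, then
  frozen — so the recorded chain is a valid fixed-kernel Metropolis
  chain and diminishing-adaptation concerns do not arise.
* **Initialization.**  Method of moments:
  $F_k = \sqrt{\max(\bar I_k, 10^{-6})}$, $\sigma_k$ from sample
  standard deviations, $\rho$ from the sample correlation clipped to
  $(-0.95, 0.95)$.
* **Diagnostics.**  `autocorrelation()` (error on a constant chain, by
  documented choice), `effective_sample_size()` (Geyer
  initial-positive-sequence, capped at the chain length), a warning
  below 1% acceptance, and a between-chain median-agreement warning
  (chain medians spreading beyond half the pooled posterior standard
  deviation).
* **Determinism.**  Per-chain and per-reflection seeds derive from the
  master seed through a fixed integer recurrence, so traces are
  bitwise reproducible and independent of the worker count.

## Summaries

`hdi()` returns the shortest contiguous interval containing
$\lceil 0.95 n \rceil$ sorted samples (ties to the lower start index) —
exact for the sample, matched against a brute-force window scan in the
tests.  For the skewed, boundary-hugging amplitude posteriors the HDI
is the right summary: its lower bound sits at zero where an
equal-tailed interval would not.  Reported widths are
`hdi_high - hdi_low`.

`ppc_ellipses()` converts (by default) 200 evenly strided trace samples
into 95% isodensity ellipses of the implied bivariate normal — centre
$(F_1^2, F_2^2)$, axes from the eigendecomposition of $\Sigma$ with
half-lengths $\sqrt{\chi^2_2(0.95)\,\lambda_k}$ — for overlay on the
observed pairs.

`comparison_table()` runs both models on identical data realizations
over a grid of error models and marks, per variable, which model's
median lands closer to truth (ties go to the narrower HDI).

## Numerical choices

The bivariate log-density uses the closed-form 2×2 expression
($\log\det\Sigma = 2\log\sigma_1 + 2\log\sigma_2 + \log(1-\rho^2)$),
stable as $|\rho| \to 1$ and checked against a dense
inverse/determinant oracle to $10^{-10}$.  Inside the sampler the
likelihood is evaluated from the six sufficient statistics
$(n, \sum I_1, \sum I_2, \sum I_1^2, \sum I_2^2, \sum I_1 I_2)$, so one
posterior evaluation costs $O(1)$ in the number of pairs.  Any
evaluation that would produce `NaN` (overflowing scales, degenerate
correlations) returns `-Inf` and is rejected.

## Problem sizes used in the shipped checks

The test suite exercises the full reference protocol (200 pairs,
50 000/20 000 iterations) with single chains for replicate studies: ten
replicates per generative regime for the five-regime comparison, five
replicates per observation count for the 3–48-pair prior study, and
fifty short-chain (6 000/2 000) low-noise replicates for
interval-coverage calibration.  These sizes give replicate spreads well
inside the assertion tolerances while keeping a full run of the suite
to a few minutes; the acceptance script uses the two-chain reference
protocol throughout.

## Limitations

* One reflection at a time: no joint model across reflections, no
  scale-factor estimation, no resolution-shell pooling of priors.
* Upstream corrections (Lorentz–polarization, scaling) are assumed
  done; only plain columnar text input is supported, and an MTZ/XDS
  converter is an extension point, not a feature.
* The reference study's seeds are unknown, so its tables reproduce in
  distribution, not bitwise.
* Metropolis is robust but not efficient; gradient-based samplers would
  cut chain lengths by an order of magnitude and are out of scope.
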