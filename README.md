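# refdelta

Bayesian estimation of structure-factor amplitudes F₁, F₂ and their
difference ΔF = F₁ − F₂ from **pairwise-referenced** X-ray intensity
observations of a single reflection.

## Why

Difference techniques — anomalous phasing from Friedel mates,
time-resolved pump–probe diffraction — hinge on ΔF, but only intensities
(I ∝ F²) are observed, and weak reflections routinely go negative after
background subtraction.  Referencing strategies record the two
observations of a pair in close succession so systematic errors are
shared within the pair; conventional merging then throws that shared
structure away by treating the two sets independently.

`refdelta` keeps it.  Each referenced pair is modelled as one draw from
a bivariate normal,

    (I1ᵢ, I2ᵢ) ~ N₂( (F₁², F₂²), Σ ),   Σ = diag(σ₁,σ₂) Ω diag(σ₁,σ₂),
    Ω = [[1, ρ], [ρ, 1]],

with uniform (or truncated-normal) priors on the amplitudes, log-normal
priors on σ₁, σ₂ and an LKJ prior on ρ.  Because the likelihood mean is
confined to the nonnegative quadrant, the correlation ρ transfers
information from a strongly negative observation set to its partner —
which is exactly where a univariate (pairing-blind) treatment collapses
to a near-zero half-normal posterior and biases ΔF toward zero.  The
univariate model is included as the baseline.  Posteriors are sampled by
a self-contained random-walk Metropolis sampler (50 000 iterations,
20 000 burn-in, two pooled chains by default) and summarized by
posterior medians with 95% highest-density intervals.

## Worked example

```r
library(refdelta)

# a weak reflection pair driven negative by systematic error
em <- error_model(F1_true = 0.1, F2_true = 0.7, mu_sys = -0.5,
                  sigma_sys = 1.5, sigma_ran = 0.3, n_pairs = 200)
d  <- generate_pairs(em, seed = 42)
d
#> Intensity pair set: 200 referenced pairs
#>   mean(I1) = -0.5623, mean(I2) = -0.05381, mean(I1 - I2) = -0.5085
#>   cor(I1, I2) = 0.955

fit <- fit_pairs(d, "multivariate", chain = chain_config(seed = 1))
summarize_posterior(fit)[c(1, 2, 6), ]
#>   variable      median       hdi_low    hdi_high      width hdi_mass
#> 1       F1  0.06664402  3.292515e-06  0.1875734 0.18757006     0.95
#> 2       F2  0.71359360  6.659481e-01  0.7631107 0.09716255     0.95
#> 6       dF -0.64264967 -7.366685e-01 -0.5303784 0.20629009     0.95

fit_uv <- fit_pairs(d, "univariate", chain = chain_config(seed = 1))
median(fit_uv$samples$dF)
#> [1] -0.07021367
```

Both observation sets have *negative* means, yet the multivariate model
recovers F₂ ≈ 0.71 (truth 0.7) and ΔF ≈ −0.64 (truth −0.6) with a tight
95% HDI, because the near-unity posterior correlation (ρ ≈ 0.96) lets
the constrained F₁ posterior pull the F₂ estimate to the right place.
The univariate baseline on the same data collapses both amplitudes
toward zero and reports ΔF ≈ −0.07 — a tenfold underestimate of the
difference signal.

Further entry points: `read_pairs()` / `fit_groups()` for per-reflection
fits of user data (plain TSV/CSV, optional `h k l` columns, parallel
workers with worker-count-invariant results), `ppc_ellipses()` for
posterior-predictive isodensity ellipses, and `comparison_table()` for
multivariate-vs-univariate studies over a grid of error models.  The
methods vignette (`vignettes/multivariate-amplitude-inference.Rmd`)
documents the model, priors, sampler and design choices.

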