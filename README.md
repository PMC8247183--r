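# ecodiffuse

Hierarchical ecological-diffusion modelling of recolonizing wildlife
populations observed by imperfect aerial surveys — developed around the
recovery of sea otters (*Enhydra lutris*) reintroduced at multiple sites in
a nearshore system, and usable for any population spreading from point
releases across a gridded landscape.

## The model

The expected-abundance intensity λ(s, t) follows logistic **ecological
diffusion** — diffusion with the motility coefficient inside the Laplacian,
so animals accumulate where they move slowly:

    ∂λ/∂t = ∇²[δ(s) λ] + γ λ (1 − λ/K(s))

* **δ(s)** (motility, m²/yr): log-linear in depth, distance to shore,
  slope × depth, shoreline complexity, cumulative swimmable distance to
  towns, and protected-bay / fishery-closure indicators.
* **K(s)** (local density dependence, animals per 400 m cell): log-linear
  in the two management indicators.
* **Initial condition**: a sum of J Gaussian kernels, one per release site,
  contributing exactly θⱼ animals at spatial scale κⱼ.

Counts are linked to λ by an N-mixture observation model: latent abundance
N ~ NB(λ, τ) (heavily overdispersed — rafts), thinned by yearly detection
y ~ Binomial(N, p_t), with detection informed by re-counted "intensive
search unit" groups and an informative beta prior in photographic-survey
years.  The PDE is solved by homogenized sparse finite differences
(harmonic-mean upscaling of δ, implicit diffusion + exact logistic
reaction steps), and the joint posterior — process parameters, detection,
dispersion, and latent abundances — is sampled by Metropolis-within-Gibbs
MCMC.  Derived outputs include asymptotic spread-rate maps
(2√(δ̄γ) km/yr), total-abundance time series, and posterior predictive
checks.

## Worked example

A complete synthetic study — landscape, truth, and all three survey types —
is generated, fitted, and summarised in a few lines:

```r
library(ecodiffuse)

study <- generate_study(seed = 1)
study
#> <eco_study> seed 1: 40 x 40 cells, 734 water; 1403 counts over years {3, 5, 7, 10, 13, 16, 18, 20}

fit <- fit_diffusion(study$surveys, study$landscape, study$epicenters,
                     study$priors,
                     config = list(n_iter = 2500, n_burn = 800,
                                   track_years = 20),
                     seed = 2)
subset(posterior_summary(fit, level = 0.90),
       parameter %in% c("gamma", "beta1", "alpha1", "tau"))
#>    parameter       lower        mean       upper
#> 1      gamma  0.23810122  0.25359431  0.26834746
#> 3      beta1 -2.32116881 -1.53896753 -0.74300308
#> 11    alpha1  2.87949286  8.30996883 16.44495356
#> 13       tau  0.02750694  0.03238693  0.03735929
```

The generating values are γ = 0.29, β₁ = −1.77 (shallow water lowers
motility ≈ six-fold, concentrating animals there), α₁ = 3.16 (the protected
bay supports ≈ 24× the baseline equilibrium density), τ = 0.03.  The 90 %
intervals cover the covariate effects and the dispersion; γ stays near its
informative N(0.25, 0.01²) prior because a desk-scale study carries little
growth-rate information through such overdispersed counts (see the
vignette's limitations section).

Derived quantities come from the same fit:

```r
sm <- posterior_summary(fit)
delta_hat <- motility_field(study$landscape, sm$mean[2:9])
K_hat <- carrying_capacity_field(study$landscape, sm$mean[10:12])
spread_rate_map(homogenize(study$landscape, delta_hat, K_hat, 1/5),
                gamma = sm$mean[1])
#> <eco_spreadrates> km/yr over coarse water: min 0.40, median 0.71, max 1.37

posterior_predictive_check(fit)
#> <eco_ppc> 34 of 1403 observed counts outside their 95% predictive intervals (2.42%)

tail(total_abundance(fit), 1)
#>    year     mean median  lower    upper
#> 20   20 9742.378   8570 3475.9 22946.42
```

Colonisation proceeds at around a kilometre per year on this small domain,
slower in the low-motility shallow and closed areas; virtually all counts
fall inside their 95 % predictive intervals; and the final-year abundance
interval brackets the simulated truth (4 039 animals in this study — the
mean sits high because abundance outside the photographed bay is pure
extrapolation in the final year, and its posterior is wide and
right-skewed).

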