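# nichefate

Population dynamics of normal and leukaemic stem-cell lineages competing for
the bone-marrow niche — and the inference machinery to ask *which kinetic
rates decide the outcome*.

Haematopoietic stem cells (HSCs, species *S*) maintain all blood lineages
through progenitors (*A*) and terminally differentiated cells (*D*).
Leukaemia stem/driving cells (*L*) and their differentiated progeny (*T*)
occupy the same niche, so the two lineages are locked in ecological
competition for a finite resource.  `nichefate` implements two ODE models of
this competition and a behaviour-conditioned ("qualitative") inference
pipeline that maps out the parameter regimes in which the healthy lineage
wins:

* **Model A** — five species sharing a *hard* carrying capacity *K* through
  the linear factor (1 − *Z*/*K*), *Z* = *S*+*A*+*D*+*L*+*T*:

      dS/dt = a1·S·(1 − Z/K) − b1·S
      dA/dt = b1·S + c1·A·(1 − Z/K) − e1·A
      dD/dt = e1·A − f·D
      dL/dt = a2·L·(1 − Z/K) − b2·L
      dT/dt = b2·L − g·T

* **Model B** — explicit stem-cell fates (symmetric renewal λ1/κ1,
  asymmetric renewal λ2/κ2, symmetric differentiation λ3/κ3, loss μ4/ν4,
  progenitor amplification λ5, …) under *soft* exponential feedback from two
  sub-niches, Φ1 = exp(−γ1(S+L)) on stem renewal and Φ2, Φ3 =
  exp(−γ(A+D+T)) on the differentiation fates.  The model is unstable —
  progenitors grow without bound — exactly when λ5 > μ6.

* **Qualitative ABC-SMC** — instead of fitting data, the sampler conditions
  on declared behaviour ("*S*, *A*, *D* viable and *L*, *T* extinct at
  steady state") through a margin distance that is zero exactly on the
  target behaviour, and returns the prior restricted to the parameter region
  that produces it.

* **Posterior PCA** — the *last* principal components (smallest eigenvalues)
  of the weighted posterior are the *stiff* rate combinations the behaviour
  pins down; squared-loading shares say which rates compose them.

The central fitting function is `abc_fit()`, which returns a classed object
with the usual verbs (`print`, `summary`, `coef`, `plot`, `simulate`,
`predict`).

## Worked example

Leukaemia-suppression analysis of model A — 8 free rates with Uniform[0,1]
priors, conditioning on healthy persistence and leukaemic extinction:

```r
library(nichefate)

fit <- abc_fit("modelA", n_particles = 1000, n_generations = 6, seed = 1)
print(fit)
#> Qualitative ABC-SMC fit -- model modelA
#>   8 free parameters, 1000 particles, 6 generation(s) (seed 1)
#>   final tolerance 0, acceptance 0.300, ESS 413.3
#>   target behaviour reproduced by 100.0% of final particles

pca <- pca_posterior(fit)
print(pca)
#> <niche_pca> 8 components, weighted (ESS 413.3)
#>   eigenvalues: 0.0972 0.0834 0.0793 0.0767 0.0635 0.0561 0.0489 0.0183
#>   PC8 (stiffest): b1 75%, a1 15%, b2 5%
#>   PC7 (second stiffest): e1 42%, c1 17%, b2 17%

pc_contribution(pca, "last", c("a1", "b1", "e1"))
#> [1] 90.97568
```

Reading the output: the sampler's tolerance schedule reaches 0, so every
final particle *exactly* reproduces the declared behaviour (the
"100.0%" line).  The stiffest posterior direction (PC8, smallest eigenvalue
0.0183 against ~0.08 for the sloppy directions) is composed almost entirely
of HSC-arm rates — the stem self-renewal/commitment balance (`a1`, `b1`)
plus early differentiation (`e1`) carry ≈91% of it — while leukaemia-arm
rates contribute a few percent.  To suppress leukaemia, it is the healthy
lineage's kinetics that must be controlled; the same analysis for model B
(`abc_fit("modelB", ...)`) names the stem fate balance (λ1, λ3, μ4) and the
progenitor balance (λ5, μ6), with the LSC death rate ν4 the largest
leukaemic contribution.

Everything above is also packaged as named recipes with full provenance
manifests:

```r
run_recipe("modelA_suppression", out_dir = "out_A", seed = 1)   # populations.csv, pca.json, manifest.json, ...
run_recipe("regime_map_B",       out_dir = "out_rm", seed = 1)  # outcome frequencies over prior draws
run_recipe("toy_abc_validation", out_dir = "out_toy", seed = 1) # ABC vs closed-form posterior
```

## Package layout

* `R/models.R` — exact right-hand sides, parameter vectors, CSV round-trip
* `R/simulate.R` — integration to pseudo-steady state, blow-up detection
* `R/classify.R` — outcome labels, behavioural criteria, regime maps
* `R/inference.R` — priors, behavioural distance, rejection ABC, ABC-SMC
* `R/robustness.R` — weighted-posterior PCA, contributions, marginals
* `R/fixtures.R` — samplers, screened regime fixtures, analytic toy problem
* `R/recipes.R` — configuration, named recipes, manifests
* `vignettes/niche-competition.Rmd` — the models, the inference method and
  its design decisions, in detail
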