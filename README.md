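# steppediv

Spatial analysis of plant species diversity in gridded quadrat surveys,
built for the classic grazed-versus-fenced (grazing exclosure) comparison
in steppe vegetation. A survey here is a 5 m × 5 m subplot divided into a
10 × 10 grid of 0.5 m × 0.5 m quadrats, replicated three times per
treatment, with per-quadrat species counts and soil/vegetation covariates.
The package answers the three questions such surveys are designed for, and
ships a synthetic community generator so the whole chain runs and is tested
without field data.

**1. How does diversity accumulate with area?** `sar_curve()` traces
richness, abundance or Shannon diversity over nested square windows
(0.25–25 m²); `fit_sar()` fits the standard model families by least squares
with 95% confidence intervals —

| family | form |
|---|---|
| power (multiplicative / additive) | S = αAᵝ, S = α + Aᵝ |
| exponential | S = α ln A + β |
| logistic | S = β / (1 + exp((δ − log A)/α)) |
| parabolic | S = α ln(A)² + β ln A + δ |

— ranked by residual sum of squares (`compare_sar()`), with
confidence-interval separation tests between treatments (`curves_differ()`)
and a random-placement null model: the closed-form Coleman expectation
E S(a) = Σᵢ (1 − (1 − a/A)^{Nᵢ}) (`expected_sar_coleman()`) and its
seeded randomization envelope (`randomization_sar()`).

**2. How is diversity spatially structured?** `diversity_variogram()`
estimates the semivariance γ(h) = (1/2N(h)) Σ (Z(xᵢ) − Z(xⱼ))² of
per-quadrat diversity per subplot; `fit_variogram()` fits exponential /
spherical / Gaussian models by pair-count-weighted least squares and
reports the nugget C₀, sill C₀ + C, structural proportion C/(C₀+C), and
practical range A₀ (3a for the exponential model).
`spatial_structure_summary()` labels the fenced-minus-grazed sill change.

**3. Environment or space?** `pcnm()` builds spatial eigenvector
predictors from quadrat coordinates, `forward_select()` retains significant
environment and PCNM variables by a permutation F-test (α = 0.05, 999
permutations, double-stopping on the global adjusted R²), and
`partition_variation()` splits the response variance into pure environment
[a], spatially structured environment [b], pure space [c] and residual [d]
on the adjusted-R² scale. `hellinger_transform()` prepares a full species
matrix as a multivariate response.

`simulate_community()` generates the complete grazed/fenced layout:
spatially autocorrelated environmental fields (exponential-covariance
Gaussian random fields), Poisson species counts responding to a shared
soil-water/silt gradient plus species-specific aggregation, and a
palatability-based treatment contrast (more individuals, fewer species
inside the fence). `run_full_analysis()` chains everything into seeded,
byte-reproducible CSV reports.

## Worked example

```r
library(steppediv)

svs <- simulate_community(synth_config(seed = 42))
cv  <- sar_curve(svs$grazed, "richness")
cv
#>       k  area value n_subplots
#>   1     1  0.25  11.1          3
#>   2     2  1     17.4          3
#>   3     3  2.25  20.6          3
#>   4     4  4     22.7          3
#>   ...

fits <- lapply(c("logistic", "power", "exponential"), fit_sar, curve = cv)
compare_sar(fits)
#>   family      n_params    ssr  rank
#> 1 logistic           3  0.487     1
#> 2 exponential        2 13.1       2
#> 3 power              2 23.1       3
```

The logistic model wins by two orders of magnitude in SSR: mean quadrat
richness (11.1 species in 0.25 m²) saturates towards the asymptote β ≈ 26
species as windows approach the full subplot. Its `tidy()` table gives each
parameter with its 95% half-width (e.g. β = 26.2 ± 0.7). The spatial side:

```r
tidy(fit_variogram(diversity_variogram(svs$grazed, "richness"), "exponential"))
#>   model          c0     c  sill  prop     a range    r2
#> 1 exponential     0  6.01  6.01     1 0.423  1.27 0.663
```

a near-zero nugget and a practical range of ~1.3 m: quadrat richness is
spatially autocorrelated at fine, sub-2 m scales, and essentially all of
its variance (prop ≈ 1) is spatially structured. `autoplot()` methods draw
each result (`autoplot(cv, fit = fits[[1]])`, variogram and partition
plots likewise).

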