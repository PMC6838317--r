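# subsidydiet

Quantifying how much free-ranging predators depend on human-provided
food versus wild prey — and what that dependence has to do with the
landscape they are caught in.

The motivating system is the free-ranging domestic cat (*Felis catus*)
on a small subtropical island where endangered endemic mammals (Amami
rabbit, Ryukyu long-haired rat, spiny rat) are taken by cats that are
nevertheless fed, directly or indirectly, by people. Short-term diet is
read from scats; long-term diet from hair stable isotopes; and the
spatial question — do cats caught near forest eat more forest prey? —
from a landscape regression. The package is aimed at wildlife ecologists
and invasive-species managers who have these three data types (or want
to simulate them) and need the whole chain in one reproducible pipeline.

## What it computes

**1. Fecal diet screening.** Frequency of occurrence (FO) and minimum
number of individuals (NI) per prey taxon and predator group, and each
taxon's contribution to the predators' daily consumed biomass,

```
DCB = 3.358 · W^0.813 · 2.86/18      (grams fresh prey; W in grams)
Contribution = 100 · (w_prey · NI / n) / mean(DCB)   (%)
```

with prey heavier than the largest predator's DCB capped at that DCB.
Taxa above a contribution threshold (default 3%) become the sources of
the isotope model. Group contrasts use Fisher's exact test.

**2. Trophic enrichment factors.** Captive diet-switch series (cats held
in a shelter on pet food) are fitted with the asymptotic exponential
`y = A·exp(B·x) + C` by Levenberg–Marquardt least squares; the TEF is
the asymptote C, per isotope.

**3. Bayesian mixing model.** A three-source, two-isotope (δ13C, δ15N)
SIAR-type model: consumer values are normal with mean
`Σ p_k(μ_jk + c_jk)` and variance `Σ p_k²(ω_jk² + τ_jk²) + σ_j²`, a flat
Dirichlet prior on the diet proportions p, and U(0, 20‰) priors on the
residual SDs. Sampling is adaptive random-walk Metropolis on a log-ratio
transform of p; summaries report posterior means and 95% highest-density
regions.

**4. Landscape model.** Buffer (100/200/500 m) land-use coverages and
building density around capture sites are condensed by ML factor
analysis with Promax rotation (parallel analysis confirming two
factors); spatial autocorrelation is absorbed by Moran's eigenvector
maps built from the Delaunay triangulation of the sites; arcsine-sqrt
transformed dependencies are regressed on Factor1, Factor2, weight, sex
and the retained MEMs via all-subsets Gaussian GLMs with AICc ranking
and full model averaging over the ΔAICc < 2 set.

A synthetic-data module (`tokunoshima_scenario()`, `gen_*()`) generates
fecal tables, consumer isotopes, diet-switch series and landscape
mosaics with all of the structure above, so every stage is testable
without field data.

## Worked example

```r
library(subsidydiet)

scenario <- tokunoshima_scenario(seed = 1)   # island-calibrated truths
fecal    <- gen_fecal_table(scenario, mode = "exact")

tab <- contribution_table(fecal$scats, fecal$cats, fecal$taxa,
                          mean_dcb = 379, max_dcb = 629)
select_sources(tab, threshold = 3)
#> # A tibble: 3 × 3
#>   taxon               habitat  contribution
#> 1 Diplothrix legata   forest           7.72
#> 2 Rattus rattus       farmland         6.92
#> 3 Pentalagus furnessi forest           6.71

consumers <- gen_consumer_isotopes(scenario, match_moments = TRUE)
posterior <- run_mixing_mcmc(
  subset(consumers, group %in% c("feral", "stray")),
  default_sources(), mcmc_config(seed = 1))
posterior
#> Bayesian mixing model posterior (feral, stray)
#>   50000 iterations, burn-in 5000, thin 10, seed 1
#>   group source               `mean %` `95% HDR`
#> 1 feral artificial resources     71   66.0-76.4
#> 2 feral farmland animals         11.9 7.0-16.1
#> 3 feral forest animals           17.1 14.3-20.0
#> 4 stray artificial resources     68.9 59.7-79.1
#> 5 stray farmland animals         15.9 7.3-24.4
#> 6 stray forest animals           15.3 9.6-20.3
```

Reading: three prey (two endangered forest mammals and the black rat)
each supply >3% of daily consumed biomass and so enter the isotope
model; the posterior then attributes roughly 70% of both groups' energy
to artificial resources — cats that catch forest wildlife still mostly
eat human food. `autoplot()` methods draw the contribution bars, the
posterior with HDR error bars, TEF fits and averaged-model coefficients;
`tidy()`/`glance()` return the tables. `run_pipeline()` chains all
stages, validates inputs and writes per-stage CSVs plus a JSON summary.

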