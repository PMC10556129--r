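# csiaMix

Compound-specific stable isotope analysis of pottery lipids: biomarker
screening, reference-ellipse classification, and concentration-dependent
Bayesian source mixing.

## What it is for

Organic residues absorbed in archaeological pottery record what the vessels
once processed. `csiaMix` implements the full chain of inference used to
read them, aimed at archaeometry labs comparing ceramic traditions:

1. **Biomarker screening** — aquatic-product criteria (C18 *and* C20
   ω-(o-alkylphenyl)alkanoic acids, or dihydroxy acids), phytanic-acid
   diastereomer ratios (%SRR) with shellfish-like windows on %SRR
   ([20, 47]) and TMTD/phytanic ([0.34, 1.63]), the C32 *n*-alkanol maize
   marker, lauric-acid (palm) and bacteriohopane flags.
2. **Isotope classification** — the offset Δ¹³C₁₈:₀–₁₆:₀ = δ¹³C₁₈:₀ −
   δ¹³C₁₆:₀ and multi-label membership of each sherd in 68 % Gaussian
   confidence ellipses of reference fats in (δ¹³C₁₆:₀, δ¹³C₁₈:₀) space
   (Mahalanobis radius² = χ²₂ quantile).
3. **Mixing model** — for source fractions *f* (of total fatty acids) and
   per-source proxy concentrations *c*, the forward model is the
   concentration-weighted mean δⱼ(f) = Σᵢ fᵢcᵢⱼδᵢⱼ / Σᵢ fᵢcᵢⱼ. Source
   signature uncertainty is marginalized analytically, the prior is flat
   Dirichlet(1), and the posterior over up to four sources given up to
   three δ¹³C proxies is sampled by an adaptive random-walk Metropolis on
   additive-log-ratio coordinates (split-R̂/ESS diagnostics), with an exact
   simplex-grid posterior as an independent oracle. Fractions convert to a
   dry-weight basis via wᵢ ∝ fᵢ/φᵢ, where φᵢ is each source's fatty-acid
   content per dry weight — lipid-poor foods such as maize always gain by
   weight.
4. **Group statistics** — first-principles Mann–Whitney U (tie-corrected,
   exact by enumeration or rank-sum recursion where feasible), Pearson r
   (df = n − 2) and Welch/pooled t, as used for tradition contrasts.
5. **Synthetic data** — a seeded generator (`simulateSherds`,
   `presetScenarios`) producing sherd datasets with known composition
   truth, so the whole pipeline is testable without any external dataset.

Everything is exposed as Bioconductor-style S4: sherd tables are a
`SummarizedExperiment` subclass (`SherdExperiment`), reference fats a
`SourceSet`, posteriors a `MixPosterior`.

## Worked example

```r
library(csiaMix)
pre <- presetScenarios(nSherds = 30L, seed = 1L)
sim <- simulateSherds(pre$guarani_like)   # maize-leaning archetype
sim$sherds
#> SherdExperiment with 30 sherds, 17 compounds observed
#>   traditions: Guarani: 30
#>   sites: 1
#>   d13C proxies per sherd: 2x13, 3x17

pan <- computeBiomarkers(sim$sherds)
summarizeSites(sim$sherds, pan)
#>      site tradition  n aquatic_pct mean_delta
#> 1 GUA-SIM   Guarani 29          10       -3.6
```

29 of 30 sherds clear the 5 µg g⁻¹ lipid-yield threshold; 10 % carry
aquatic biomarkers and the mean Δ¹³C₁₈:₀–₁₆:₀ of −3.6 ‰ is far below the
ruminant-fat range — the isotopic fingerprint of C4-plant (maize) input.
Now model one sherd's two saturated proxies (−26.48 ‰, −30.63 ‰) against a
three-source reference set:

```r
src <- defaultSourceSet()[c("maize", "marine", "ruminant")]
dl  <- d13cValues(sim$sherds)
obs <- data.frame(proxy = c("C16:0", "C18:0"),
                  value = dl[1, c("C16:0", "C18:0")], sd = 0.3)
fit <- runMixing(src, obs, pipelineConfig(seed = 1L))
fit
#> MixPosterior: 12000 draws over 3 sources (seed 1)
#>     source  mean    sd    q2.5   q50 q97.5 rhat  ess
#> 1    maize 0.177 0.104 0.01442 0.169 0.389    1 1200
#> 2   marine 0.198 0.136 0.00668 0.182 0.489    1 1050
#> 3 ruminant 0.624 0.111 0.41733 0.621 0.856    1 1501
#>   converged (max split-Rhat 1.000, min ESS 1050, accept 0.29)

round(faToWeightFractions(colMeans(posteriorSamples(fit)), src), 3)
#>    maize   marine ruminant
#>    0.682    0.137    0.180
```

This sherd is ruminant-dominated on a fatty-acid basis (62 % ± 11), with a
modest maize share (18 %) — but because maize kernels carry ~13× less
fatty acid per gram than animal tissue, that translates to a 68 % maize
share by dry weight. `runPipeline()` chains all stages over a whole CSV
dataset and writes the per-sherd report, site summary, tradition
statistics and a JSON run manifest.

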