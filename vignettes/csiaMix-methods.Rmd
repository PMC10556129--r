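---
title: "From pottery lipids to food sources: methods behind csiaMix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From pottery lipids to food sources: methods behind csiaMix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csiaMix)
```

## The problem

Absorbed lipids in archaeological pottery preserve a chemical memory of what
the vessels once held. Two complementary lines of evidence are used to read
it. First, *biomarker screening*: certain degradation products are
diagnostic of specific resources — ω-(o-alkylphenyl)alkanoic acids (APAAs)
and dihydroxy acids form when unsaturated aquatic oils are heated; the
isoprenoid fatty acids TMTD, pristanic and phytanic acid are enriched in
aquatic tissue, and the SRR diastereomer share of phytanic acid (%SRR)
distinguishes aquatic from terrestrial inputs; a dominant long-chain C32
*n*-alkanol points to maize; abundant lauric acid to palm oil;
bacteriohopanes have been read as fermentation markers. Second,
*compound-specific isotopes*: the δ13C values of palmitic (C16:0), stearic
(C18:0) and, where measurable, oleic acid (C18:1) locate a sherd relative to
reference fats, and the offset Δ13C~18:0–16:0~ = δ13C~18:0~ − δ13C~16:0~ is
a classic classification axis. csiaMix implements both lines, plus a
concentration-dependent Bayesian mixing model that turns the three proxies
into probabilistic source contributions, and a seeded synthetic-data
generator so the whole chain can be validated end to end without any
external dataset.

## Data model

A dataset is a `SherdExperiment`, a `SummarizedExperiment` whose
`"abundance"` assay holds one column per sherd over a fixed compound
vocabulary (`compoundKeys()`), with `NA` meaning *not observed* — absence is
never coerced to zero anywhere downstream. Per-sherd metadata (site,
ceramic tradition, decoration, lipid yield in µg g⁻¹) and the δ13C proxies
with analytical uncertainties live in `colData`. Reference fats are a
`SourceSet`: per source and proxy a signature mean and sd (‰ VPDB), the
proxy's concentration as % of total fatty acids, the total fatty-acid
content per unit dry tissue, and optionally a full 3×3 signature
covariance. Validity methods enforce the invariants (δ13C inside a
[−45, 0] ‰ sanity window that catches unit errors, positive sds,
concentration rows summing to ≤ 100 %, positive-semidefinite covariances).

## Screening rules and their windows

The aquatic flag requires *both* C18 and C20 APAAs, or dihydroxy acids
alone. We read the APAA criterion conjunctively because C18 APAAs on their
own also arise from heated terrestrial plant oils; the rule is a
configuration switch (`aquaticApaaConjunctive`) for users who prefer the
looser reading. Aquatic sherds are sub-classified as shellfish-like when
%SRR falls in [20, 47] and TMTD/phytanic in [0.34, 1.63] (closed
intervals); these windows are descriptive ranges observed in reference
material, not validated decision thresholds, and are therefore
configuration values rather than constants. "Trace" amounts of the maize
alkanol are operationalized as a configurable abundance threshold, with the
flag additionally demanding at least two other even-carbon C28–C36
alkanols. Ratios with absent or zero denominators are reported absent,
never as infinities. Site summaries count only sherds above the lipid-yield
threshold (default 5 µg g⁻¹, the conventional interpretability cut-off).

## Reference ellipses

A reference class is summarized by a Gaussian coverage ellipse in
(δ13C~16:0~, δ13C~18:0~) space: centre at the sample mean, shape from the
unbiased sample covariance, squared Mahalanobis radius at the χ²₂ quantile
of the chosen level (0.68 by default, where the quantile is
−2 log(1 − p) ≈ 2.279). We use the population-coverage contour rather than
a standard-error-of-the-mean ellipse because the regions are used to
classify *individual* sherds against the scatter of reference fats.
Membership is boundary-inclusive and multi-label: reference classes
genuinely overlap and mixed residues plot between them, so no
nearest-class tie-break is imposed. An additive correction (`deltaShift`,
default 0) can shift reference values, e.g. to compensate the modern
fossil-fuel depletion of atmospheric δ13C when comparing archaeological
samples against modern reference fats.

## The mixing model

Let f be the vector of source contributions *as fractions of total fatty
acids* and c~ij~ the concentration of proxy j in source i (% of total fatty
acids). The expected isotope value of proxy j is the concentration-weighted
mean

$$\delta_j(f) = \frac{\sum_i f_i\,c_{ij}\,\delta_{ij}}{\sum_i f_i\,c_{ij}},$$

so a source rich in a proxy dominates that proxy's signal. This is what
makes maize diagnostic: its kernel oil is C16:0-rich but nearly devoid of
C18:0, so mixing maize into any animal fat drags δ13C~16:0~ towards the
enriched C4 value while δ13C~18:0~ stays pinned to the animal fat, and
Δ13C~18:0–16:0~ falls. Evaluating the curve for the default sources shows
the offset decreasing strictly from a maize fraction of 0 up to ≈ 0.85 and
rebounding only as maize's own tiny C18:0 pool finally takes over near a
pure-maize mixture — the prediction therefore holds exactly over the range
where any appreciable animal-fat input is present, and the tests assert
that structure (strict decrease up to the curve minimum, minimum beyond
0.8) rather than a false global monotonicity.

Given f, the mixture mean is linear in the source signatures, so signature
uncertainty marginalizes analytically: with weights
w~ij~ = f~i~c~ij~ / Σ~k~f~k~c~kj~, each observed proxy is Gaussian with
mean Σ~i~w~ij~δ~ij~ and variance
Σ~i~w~ij~²σ~ij~² + sd~obs,j~² + σ~model~². Sources given a full signature
covariance induce cross-proxy covariance Σ~i~w~ij~w~il~C~i~[j,l] and the
proxies are scored jointly. σ~model~ (default 0.5 ‰) is a fixed residual
term absorbing cooking and burial fractionation that the mixing equation
does not model; concentrations are treated as fixed. The prior on f is the
flat Dirichlet(1) — we assert no informative prior knowledge about vessel
contents.

Two independent routes compute the posterior. `gridPosterior` enumerates a
regular simplex lattice (step 0.02, ≤ 4 sources) and normalizes prior ×
likelihood exactly up to discretization — a brute-force oracle.
`runMixing` is a random-walk Metropolis sampler on additive-log-ratio
coordinates with the log-Jacobian Σ log f~i~ included, four chains from
dispersed Dirichlet starts, proposal scale tuned during burn-in to a
20–40 % acceptance rate and frozen afterwards, all post-burn-in draws
retained. Convergence is summarized by split-R̂ (flagged beyond 1.05) and
a Geyer initial-positive-sequence effective sample size; a run whose
posterior is essentially as wide as the prior marginal Beta(1, S−1) is
flagged non-identifiable rather than silently reported. Sherds lacking the
oleic proxy are modelled on two proxies. Everything is reproducible from
the configuration seed.

Fatty-acid fractions understate lipid-poor foods by weight. With φ~i~ the
total fatty-acid content per unit dry tissue,
w~i~ = (f~i~/φ~i~) / Σ~k~(f~k~/φ~k~) converts to a dry-weight basis;
because maize kernels carry an order of magnitude less fatty acid per gram
than animal tissue, its weight share always exceeds its fatty-acid share.

## Group statistics

The tradition contrasts used in residue studies are implemented from first
principles so every number is auditable: Mann–Whitney U from midranks with
the reported statistic min(U₁, U₂); p-values by exhaustive enumeration over
label assignments where feasible (which handles ties exactly), by the
rank-sum counting recursion for tie-free samples up to n₁n₂ = 400, and
otherwise by the tie-corrected, continuity-corrected normal approximation.
Pearson's r uses the t transform with df = n − 2 after dropping incomplete
pairs; the two-sample t defaults to Welch's form. The base-R equivalents
serve as independent cross-checks in the test suite, never as the
implementation.

## What the generator emulates — and what it does not

`simulateSherds` draws per-sherd compositions from a Dirichlet law, draws
one realisation of every source's signatures from their uncertainty law,
forward-mixes them per proxy, adds Gaussian analytical noise (default
0.3 ‰, a typical long-term GC-C-IRMS replicate precision, also the default
sd assigned to δ13C values read without one), and drops the oleic proxy
with probability 0.3 to mimic its frequent unmeasurability. Biomarker
presence is Bernoulli with probabilities tied to the true composition —
aquatic flag probability p₀ + p₁·f~marine~ with defaults (0.05, 0.30),
maize-alkanol probability q₀ + q₁·f~maize~ with defaults (0.01, 0.25) —
conditionally independent of the isotope noise given the composition,
which is the simplest law consistent with using both evidence types
jointly. The two presets encode the study archetypes: `taquara_like`
(Dirichlet α = (0.6, 2.4, 1.5, 1.5); mean marine fraction 0.40, hence an
expected aquatic-screening frequency of 0.05 + 0.30·0.40 = 17 %) and
`guarani_like` (α = (3.0, 0.42, 1.3, 1.28); mean maize fraction 0.50,
mean marine fraction 0.07, expected aquatic frequency 7 %, more
bacteriohopanes). These parameters were fixed at design time from the
screening frequencies the archetypes are meant to emulate.

The generator does *not* simulate chromatographic artefacts, degradation
kinetics, burial alteration, inter-laboratory offsets, or any correlation
between lipid yield and composition. Passing tests therefore demonstrate
that the inference chain is correct *under its own assumptions* — that the
sampler matches the exact oracle, that credible intervals cover truths
generated from the model, that screening flags track the generating law —
not that those assumptions hold for any particular archaeological
assemblage. The shipped reference tables
(`inst/extdata/synthetic_sources.csv`, `synthetic_reference_points.csv`)
are synthetic stand-ins with plausible-range values, labelled as such; real
analyses should substitute measured reference-fat compilations.

## Numerical choices and degenerate inputs

* Problem sizes: the bundled checks run the grid oracle at step 0.02
  (1 326 nodes for three sources), the sampler at 4 × 6 000 retained
  iterations for oracle comparisons and 4 × 1 500 for the 100-replicate
  coverage study, and Monte-Carlo oracles at 10⁵–10⁶ draws — sizes chosen
  to hold MC error well below the tolerances they are compared at.
* Typographic minus signs and per-mille glyphs in input cells are
  normalized to ASCII before parsing; malformed numerics fail naming row
  and column.
* Ellipse fitting refuses fewer than 3 points or (near-)collinear sets;
  `mixingCurve` refuses `nSteps < 1`; the grid oracle refuses more than 4
  sources; a mixture carrying none of an observed proxy has likelihood
  −∞ rather than a crash; a zero standard error in the t statistic reports
  an overflow-safe large value.
* The paper-style report (`writeReport`, `runPipeline`) rounds numerics to
  6 decimals, which defines the round-trip precision of the CSV dialect
  and makes reruns byte-identical for fixed seed.

## Known limitations

Each sherd is modelled independently — no hierarchical pooling across a
site or tradition. Concentrations are fixed, not given uncertainty. The
residual term σ~model~ is a fixed scalar, not estimated. Freshwater and
estuarine fish are isotopically intermediate and the model cannot separate
them from mixtures of its four canonical sources; classification against
their ellipses is reported alongside instead. %SRR is used qualitatively
(window membership), not as a quantitative apportionment axis.
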