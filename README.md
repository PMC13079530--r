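# toxprox

Matched case-control analysis of residential proximity to industrial
point-source emissions.

`toxprox` is for environmental epidemiologists who link facility-level
emission reports (EPA Toxics Release Inventory / RSEI-style extracts:
facility, location, agent, year, toxicity-modeled hazard) to geocoded
case-control cohorts and ask whether living near emitting facilities is
associated with incident disease. It implements the full analysis chain
as a tested, seedable pipeline:

1. **Exposure assessment.** For each agent, a grid of 60 exposure
   definitions — 3 metrics x 4 circular buffers (2, 5, 10, 20 km) x 5
   cumulative reporting-year lags. The metrics per participant *i*,
   buffer *b*, lag *L* (facility-years *S* of the agent within *b* km of
   the residence and reported in `[visit − L, visit − 1]`):
   presence `1{S ≠ ∅}`; count (distinct facilities in *S*); and
   inverse-distance-weighted hazard `Σ_f h_f / max(d_if, 0.1 km)`.
   Exposures are dichotomized (IDW at the median of positive values) and
   filtered to definitions with ≥ 10 exposed cases and ≥ 10 exposed
   controls.
2. **Matching.** Three matched datasets without replacement, k controls
   per case (default 4): greedy nearest-neighbor and exact matching on
   age, sex, race and visit year; optimal matching (exact minimum-cost
   bipartite assignment, compiled) additionally on alcohol, tobacco and
   the Area Deprivation Index (standardized to mean 100, SD 20).
3. **Conditional logistic regression**, fit by direct Newton-Raphson
   maximization of the conditional likelihood
   `ℓ(β) = Σ_s [x_case'β − log Σ_{j∈s} exp(x_j'β)]`, with Wald tests;
   nearest-neighbor/exact models adjust for alcohol, tobacco and ADI.
4. **Consensus inference.** Bonferroni adjustment within each
   (agent, matching method) family; a definition is *overall
   significant* only with adjusted p < 0.01 under **all three** matching
   methods in a consistent direction. Per-agent summary tables
   (percent significant-and-positive of evaluable definitions) and
   volcano exports (`x = ln OR`, `y = −log10 p_adj`) round out the
   outputs.

A synthetic-data generator with known ground-truth odds ratios makes the
whole pipeline verifiable: exposure engine against a brute-force oracle
(bit-identical), optimal matching against exhaustive permutation, the
CLR fitter against closed forms and `survival::clogit`, plus end-to-end
bias, family-wise-error and power studies. See the methods vignette
(`vignettes/toxprox-methods.Rmd`) for the model details and design
decisions.

## Worked example

Simulate a cohort with chromium planted at a true odds ratio of 2 on
facility presence within 10 km (3-year lag), then run the full analysis
for lung cancer:

```r
library(toxprox)

cfg <- simConfig(seed = 1, nCases = 250, nControls = 2250,
                 agents = c("chromium", "benzene"),
                 facilitiesPerAgent = 40L, cancerTypes = "lung",
                 trueLogOR = c("chromium|presence|10|3" = log(2)))
fac <- generateFacilities(cfg)
sim <- generateParticipants(cfg, fac)
res <- analyzeCancer(sim$participants, fac, cancer = "lung", seed = 1)

sum(definitions(res$exposures)$retained)
#> [1] 63      # of 120 grid definitions survive the prevalence filter

subset(res$consensus, overall_significant,
       c(definition_id, or_nn, or_exact, or_optimal, p_adj_optimal))
#>           definition_id or_nn or_exact or_optimal p_adj_optimal
#>  chromium|presence|10|3  2.28     2.48       2.00       0.00220
#>  chromium|presence|10|4  2.25     2.48       1.96       0.00317
#>  chromium|presence|10|5  2.25     2.48       1.94       0.00384

res$agentSummary
#>     agent cancer nearest_neighbor exact optimal
#>  chromium   lung               29     8      26
```

The planted definition is recovered as overall significant in all three
matching analyses (the optimal-matched model estimates OR 2.00, 95% CI
1.42–2.79, adjusted p = 0.0022 — the generating value), the neighboring
lags of the same exposure echo it, and the null agent benzene produces
no significant associations, so it is omitted from the summary table.
Only the chromium row survives: 29% / 8% / 26% of its evaluable
definitions are significant and positive under the three methods.

The same analysis runs from the shell against CSV inputs or a synthetic
configuration in YAML:

```sh
Rscript inst/scripts/toxprox.R run-all --config config.yaml \
        --seed 1 --cancer lung --out results/
```

with subcommands `simulate`, `expose`, `match`, `fit`, `infer` to re-run
individual stages from their persisted inputs.

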