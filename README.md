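# deggnet

Differential gene-gene interaction networks from bulk RNA-Seq.

## What problem this solves

Subgroups of patients within one disease — for example histologically
defined synovial pathotypes in early rheumatoid arthritis, or responders
versus non-responders to a therapy — often differ less in which genes
they express than in how their genes co-vary. `deggnet` implements a
network pipeline for finding those differences and turning them into
predictive models:

1. **Scaffold.** A curated gene-gene interaction network (merged pathway
   repositories, SIF-like input) is restricted to measured genes.
2. **Weighting.** The network is replicated per subgroup; each node is
   weighted by the subgroup's mean log-expression of that gene.
3. **Thresholding.** Nodes below a weight percentile (default the 75th)
   are removed; a percolation scan over the percentile grid profiles the
   giant connected component so the threshold can be chosen where the
   network starts to fragment.
4. **Specific networks.** Edges present in two or more subgroup networks
   are discarded; what remains is each subgroup's specific edge set.
5. **Differential interaction.** Every specific edge (x, y) is tested by
   robust (Huber M-estimator) linear regression

   y = β₀ + β₁ x + γₖ + δₖ x + covariates,

   where k indexes subgroups. The joint Wald test on the δₖ
   (df = #groups − 1, F reference) asks whether the x–y slope differs
   between subgroups; Benjamini–Hochberg adjustment is applied across
   the scanned network.
6. **Response prediction.** For responder/non-responder comparisons,
   significant pairs feed per-pair logistic models

   logit P(good response) = β₀ + β₁ g₁ + β₂ g₂ + β₃ (g₁−ḡ₁)(g₂−ḡ₂) + covariates,

   whose gene-ratio interaction term is evaluated by in-sample ROC/AUC
   with and without the term.
7. **Clusters.** Specific networks are partitioned by greedy modularity
   maximization and annotated by hypergeometric gene-set enrichment,
   reporting the percentage of cluster genes inside each term.

A synthetic-study generator (`simulate_study()`) plants subgroup-specific
slopes and a predictive gene pair so every stage is testable without
external data.

## Worked example

```r
library(deggnet)

fx <- fixture_small()                      # bundled 40-gene toy study
res <- test_edge(fx$expr, fx$annot, c("G0001", "G0002"),
                 covariates = "age")
print(res)
#> edge_test G0002 ~ G0001 (canonical): Wald = 62.905, df = 1, p = 2.749e-08
#>   per-group slopes:
#>       A       B
#>  1.7853 -0.0313
```

The planted relation has slope ≈ 1.8 in subgroup A and ≈ 0 in subgroup
B; the group-by-gene interaction test flags the edge at p ≈ 3e-8.

```r
st <- simulate_study(sim_config(seed = 42))
annot <- select_response_samples(st$annot)       # Good vs None responders
pair <- st$truth$planted_response_pair
m <- fit_ratio_logistic(st$expr, annot, pair[1], pair[2],
                        covariates = "age")
summary(m)
#> Logistic response model for pair G0001 / G0002
#>              Estimate Std. Error z value  Pr(>|z|)
#> (Intercept) -5.558216   3.600340 -1.5438 0.1226361
#> G0001       -0.104610   0.330008 -0.3170 0.7512509
#> G0002        0.498520   0.293602  1.6979 0.0895186 .
#> G0001:G0002  1.164491   0.344133  3.3838 0.0007148 ***
#> age          0.039295   0.018353  2.1410 0.0322748 *
#> AUC with interaction term: 0.831; without: 0.705 (n = 52 Good, 31 None)
```

The planted product-interaction effect is significant (p = 7e-4) and
the gene-ratio term lifts the in-sample AUC from 0.705 to 0.831 — the
with/without-ratio pattern the pipeline is designed to surface.

Full workflows: `run_pathotype(config)` and `run_response(config)` with
a `pipeline_config()`, or the CLI:

```sh
Rscript inst/cli/deggnet.R simulate --seed 1 --out study/
Rscript inst/cli/deggnet.R run-pathotype --expr study/expression.tsv \
  --annot study/annotation.csv --interactions study/interactions.sif \
  --covariates age --out results/
```

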