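# cellmixde

Differential expression across sorted cell subpopulations by a two-stage
empirical-Bayes procedure: a crossed random-effects linear mixed model fitted
by REML to all log-expression values at once, followed by a per-population
two-component zero-mean normal scale mixture fitted by EM to the
gene-by-population effect estimates.

The package is aimed at small sorted-population designs — e.g. four mammary
epithelial subpopulations defined by CD49f/P-Cadherin marker levels with
2–3 replicate arrays each — where per-gene tests are underpowered and
borrowing strength across the transcriptome is essential.

## The model

Stage one fits, to the whole genes x arrays matrix,

```
logExpr[g,a] = mu + CellPop[p(a)] + S[a] + G[g] + GC[g,p(a)] + eps[g,a]
```

with fixed population effects `CellPop`, random array effects
`S ~ N(0, sigma_S^2)`, random gene effects `G ~ N(0, sigma_G^2)`, random
gene-by-population interactions `GC ~ N(0, sigma_G.CP^2)`, and residual
`eps ~ N(0, sigma_e^2)`, estimated by REML (via `lme4`, with
variance-component standard errors from the package's own sparse restricted
log-likelihood). The BLUPs of `GC` — one effect estimate per gene per
population — are the input to stage two, which fits per population

```
f(x) = (1 - pi1) N(x; 0, sigma0^2) + pi1 N(x; 0, sigma1^2),   sigma0 <= sigma1
```

by EM. `pi1` is the proportion of DE genes, `sigma0` the spread of non-DE
effect estimates, `sigma1` that of DE genes. Genes with posterior
probability of the wide component above 0.8 are called DE (signed by the
effect estimate), and the model-based FDR of a call set is the mean of
`1 - posterior` over called genes. Downstream helpers compute
population-exclusive up/down sets, Ward clustering of DE profiles into
`2^3 = 8` pattern groups, and hypergeometric over-representation analysis
with BH correction.

A synthetic-data module (`generate_dataset()`, `reference_config()`)
simulates exactly this generative structure with known ground truth, so
every stage is testable without external data. `read_expression()` ingests
a genes x arrays RPKM TSV plus array metadata (optional `log2(x + 1)`
transform) for real datasets.

## Worked example

Simulate the reference study design (four populations, 3/2/3/3 arrays,
mixture-distributed interaction effects), fit both stages, and call DE
genes:

```r
library(cellmixde)

cfg <- reference_config(n_genes = 1000, gene_cellpop_mode = "mixture", seed = 42)
sim <- generate_dataset(cfg)

fit <- fit_reml(sim$dataset)
fit
#> Crossed random-effects REML fit
#>   converged: TRUE  (restricted logLik -13208.176)
#>   var_sample           0.0572  (SE 0.0307)
#>   var_gene             5.3854  (SE 0.2464)
#>   var_gene_cellpop     0.3937  (SE 0.0125)
#>   var_resid            0.2476  (SE 0.0042)

test_cellpop_effect(fit)
#> Cell-population Wald F = 0.402 on (3, 7) df, p = 0.756

effects <- extract_gene_cellpop_effects(fit)
calls <- lapply(colnames(effects), function(p) {
  x <- setNames(effects[, p], rownames(effects))
  classify_and_fdr(fit_scale_mixture(x), x, threshold = 0.8, population = p)
})
names(calls) <- colnames(effects)
calls[["CD49f_high.Pcad_neg"]]
#> DE calls [CD49f_high.Pcad_neg]: 134 genes at posterior > 0.80 (|effect| > 0.767), FDR = 0.059

overall_fdr(calls)
#> [1] 0.07544288

exclusive_de_sets(calls)
#> Exclusive DE sets (called in exactly one population):
#>   CD49f_neg.Pcad_neg     up:    1  down:    5
#>   CD49f_mid.Pcad_mid     up:   54  down:   50
#>   CD49f_mid.Pcad_high    up:   28  down:   26
#>   CD49f_high.Pcad_neg    up:   28  down:   30
```

Reading the output: the variance components say almost all variation is
between genes (`var_gene`), with a substantial gene-by-population term
(`var_gene_cellpop`) indicating DE genes and a negligible array effect; the
F-test finds no population main effect, as expected for normalized arrays.
Each population's call line reports the posterior-0.8 call count, the
equivalent |effect| cutoff, and the expected fraction of false discoveries
in that set; `overall_fdr()` pools the populations by DE-count weighting.
(At 1,000 genes the BLUPs are noticeably shrunken, so the fitted
`var_gene_cellpop` and per-population `sigma1` sit below the generating
values — expected behaviour, discussed in the methods vignette.)

`run_pipeline()` chains all stages (simulate-or-read, REML, mixtures,
calls, exclusive sets, clustering, enrichment) and writes every artifact
plus a JSON report; reruns with the same config and seed are
byte-identical.

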