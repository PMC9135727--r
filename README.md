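# lncres

Immune-related lncRNA discovery, immune subtyping and prognostic modelling
from bulk tumor expression, with tumor purity as a first-class covariate.

## Why

In bulk tumor RNA-seq the immune compartment occupies the non-tumor
fraction of every sample, so any immune transcript correlates with any
other through variation in tumor purity alone. A lncRNA can therefore look
"immune-related" without regulating anything. `lncres` separates genuine
immune coupling from this artefact and carries the result through to
clinically interpretable endpoints:

1. **lncRES screen.** For each lncRNA, every protein-coding gene is scored
   by the purity-adjusted partial correlation
   `PCC = (R_LG − R_LP·R_GP) / (√(1−R_LP²)·√(1−R_GP²))` and ranked by
   `RS = −log10(p)·sign(PCC)`. Immune pathways are scored on the ranking
   with a Kolmogorov–Smirnov running-sum enrichment statistic ES; the
   analytic two-sided KS tail p with effective size `n = (N−N_I)·N_I/N`
   gives `lncRES = 1−2p` (ES > 0) or `2p−1` (ES < 0). lncRNAs with
   lncRES > 0.995 in any pathway pass.
2. **Immune-cell association.** Each candidate's significantly correlated
   mRNAs are tested against marker sets of 24 immune cell types with an
   upper-tail hypergeometric test on a 2025-gene marker universe; overlaps
   k < 3 are never significant, p < 0.05 otherwise. Final candidates are
   the intersection of both screens.
3. **Subtypes.** Consensus clustering (Monti resampling, k-means inner
   loop) groups samples on the candidate lncRNAs; per-sample immune
   activity is quantified by ssGSEA and compared across subtypes.
4. **Prognosis.** Differential expression between the two prognostically
   most divergent subtypes (rank-sum, p < 0.01, |log2FC| > 1) feeds a
   univariate Cox screen (p < 0.05) and one multivariate Cox fit. The risk
   score `Σ coef·expression`, split at the median, is evaluated by
   Kaplan–Meier / log-rank and IPCW time-dependent AUC at 1/3/5 years, and
   can be applied with frozen coefficients to an external cohort.

A seeded synthetic-cohort generator (`simulate_cohort()`) implants drivers,
purity-confounded decoys, subtypes and risk genes with known ground truth,
so the whole chain is testable offline.

## Worked example

The shipped demonstration cohort (36 samples, 120 mRNAs, 40 lncRNAs, 4
immune pathways, 6 cell types, with ground truth in `truth.json`):

```r
library(lncres)
demo <- system.file("extdata", "demo", package = "lncres")
cfg <- list(expression = file.path(demo, "expression.tsv"),
            annotation = file.path(demo, "annotation.tsv"),
            purity     = file.path(demo, "purity.tsv"),
            pathways   = file.path(demo, "pathways.gmt"),
            markers    = file.path(demo, "markers.gmt"),
            survival   = file.path(demo, "survival.tsv"),
            out_dir    = "demo_run", seed = 5,
            thresholds = list(k_min = 2, k_max = 4, weight_exponent = 0),
            consensus  = list(n_resamples = 200))
res <- run_pipeline(cfg)
res$candidates
#> [1] "LNC0007" "LNC0011" "LNC0039"     # all implanted drivers
print(res$consensus)
#> ConsensusResult
#>   k grid: 2, 3, 4; selected k_opt = 2 (max mean silhouette)
#>  k       pac  cdf_area silhouette
#>  2 0.0000000 0.5190948  0.5903269
#>  3 0.2984127 0.6469747  0.5016074
#>  4 0.1365079 0.7590602  0.4962574
print(res$model)
#> RiskModel: 3 genes, score_mode = log_hr, cutoff = -0.9422
#>   gene    coef     hr
#>  G0024 -0.2323 0.7927
#>  G0106 -0.1507 0.8601
#>  G0115  0.1969 1.2176
```

The three candidates are implanted driver lncRNAs (the cohort was built
with strong effects at this small size); `k_opt = 2` matches the implanted
two subtypes; the fitted risk model stratifies the demo cohort with
log-rank chi-square 4.36 (p = 0.037) and 1/3/5-year AUCs of 0.77 / 0.70 /
0.72. Every table is also written to `out_dir` as TSV, along with a JSON
run log; identical config and seed give byte-identical tables.

The same stages are available as functions (`lncres_table()`,
`screen_immune_lncrnas()`, `associate_cells()`, `consensus_cluster()`,
`score_all()`, `de_screen()`, `univariate_cox_screen()`,
`fit_risk_model()`, `apply_external()`, ...) and as a thin CLI:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts","lncres-cli.R",package="lncres"))') \
  all --config config.yaml
```

with subcommands `simulate`, `lncres`, `associate`, `cluster`, `score`,
`prognosis`, `all`.

## Method notes

See the methods vignette (`vignettes/immune-lncrna-discovery.Rmd`) for the
statistical details and the reasoning behind the defaults: the unweighted
enrichment statistic paired with the analytic KS p-value, Stephens'
small-sample adjustment, silhouette-based consensus model selection,
purity-residualized clustering, and what the synthetic cohorts do and do
not emulate.
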