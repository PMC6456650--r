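# predxpop

Tools for asking a practical question in transcriptome imputation: **how
well do genotype-based gene-expression prediction models transfer across
populations?**

Per-gene prediction models (PredictDB-style SQLite databases of SNP
weights) are typically trained in cohorts of predominantly European
ancestry. When those weights are applied to genotypes from a different
population, differences in allele frequencies and linkage-disequilibrium
patterns between the training and target populations degrade prediction
accuracy. `predxpop` implements the full evaluation pipeline for
quantifying that degradation, plus a synthetic multi-population study
generator so the whole pipeline can be exercised, calibrated and tested
without any external data.

## What it computes

For sample *s* and a gene with model SNPs *k*, predicted expression is the
weighted linear combination of effect-allele dosages

```
ŷ_s = Σ_k  w_k · d_sk ,      d_sk ∈ [0, 2]
```

after harmonizing each VCF variant's REF/ALT orientation to the model's
effect allele. Accuracy for gene *i* in population *j* is the Pearson
correlation *r_ij* between observed and predicted expression (*r*, not
*r²*, so negatively predicted genes count against the model). Genes whose
prediction carries no signal are filtered by a per-gene regression of
observed on predicted expression (two-sided Wald test on the slope,
α = 0.05). Population differences are then assessed with

* a **paired t-test** on per-gene correlations (pairing by gene), for
  two-group comparisons such as pooled-home-continent vs diverged
  population, or one weight database vs another;
* a **random-intercept linear mixed model**, fit from scratch by REML
  (Fisher scoring on the two variance components, fixed effects profiled
  analytically):

  ```
  r_ij = β0 + γ_i + Σ_g β_g · I[j = g] + ε_ij ,
  γ_i ~ N(0, σ²_γ),   ε_ij ~ N(0, σ²)
  ```

  with one contrast β_g per non-reference population and model-based
  Wald tests/CIs per contrast;
* a **repeated-measures ANOVA** of the null β_1 = … = β_{k−1} = 0
  (classical two-way decomposition for balanced complete tables, Wald F
  from the REML fit otherwise).

## Worked example

```r
library(predxpop)

# a 5-population synthetic study: reference + three close populations
# (F_ST 0.01-0.02) + one diverged population (F_ST 0.15), weights trained
# in the reference population only
study <- generate_study(simulation_config(seed = 42), "study")

cfg <- pipeline_config(vcf        = study$paths$vcf,
                       expression = study$paths$expression,
                       population = study$paths$population,
                       weights    = study$paths$weights)
res <- run_pipeline(cfg, "report")

round(colMeans(res$correlations$r, na.rm = TRUE), 3)
#>  POP1  POP2  POP3  POP4  POP5
#> 0.429 0.383 0.373 0.397 0.319

res$lmm$all_populations$fit
#> Random-intercept LMM (REML), reference = POP1
#>   genes: 77  observations: 385
#>   sigma2_gene = 0.0016882  sigma2_resid = 0.0125032
#>              estimate       se     lower     upper
#> (Intercept)  0.428878 0.013576  0.402269  0.455487
#> POP2        -0.045456 0.018021 -0.080777 -0.010134
#> POP3        -0.055426 0.018021 -0.090748 -0.020105
#> POP4        -0.031471 0.018021 -0.066792  0.003851
#> POP5        -0.110000 0.018021 -0.145321 -0.074679

res$lmm$all_populations$anova
#> Repeated-measures ANOVA (balanced_ss)
#>   F(4, 304) = 9.97935, p = 1.337e-07

res$continental_t
#> Paired t-test (pairing by gene)
#>   mean difference = 0.0767254
#>   t(76) = 4.64639, p = 1.392e-05
#>   pairs: 77
```

Reading the output: mean per-gene accuracy is highest in the training
population (POP1, r̄ ≈ 0.43) and lowest in the diverged population (POP5,
r̄ ≈ 0.32). The mixed model puts the POP5 deficit at −0.110 (95% CI
−0.145 to −0.075) relative to the reference, the ANOVA rejects equality
of the five populations, and the gene-paired t-test shows the pooled
non-diverged populations outperform the diverged one by 0.077 on average.
`run_pipeline` also writes all stage outputs (predicted expression +
coverage, per-population correlations, filter statuses, six-category
correlation bins, t-test/LMM/ANOVA tables, run log) as TSV under
`report/`; reruns with identical inputs are bit-identical.

A thin command-line wrapper over the same functions ships at
`inst/cli/predxpop.R` (`simulate`, `run`, … subcommands with `--config`,
`--seed`, `--out`).

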