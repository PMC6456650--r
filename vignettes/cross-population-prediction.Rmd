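---
title: "Methods: evaluating cross-population transfer of expression prediction models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evaluating cross-population transfer of expression prediction models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(predxpop)
```

## The problem

Transcriptome-imputation methods predict a gene's expression from genotype
data alone, as a weighted linear combination of effect-allele dosages over
the SNPs in the gene's cis-window. The weights are estimated by supervised
training in a reference cohort with both genotypes and measured
expression, and are distributed as PredictDB-format SQLite databases. The
training cohorts are predominantly of European ancestry, so a natural
question is how much accuracy is lost when the weights are applied to
genotypes from populations at increasing genetic distance from the
training ancestry. `predxpop` implements the evaluation machinery for
that question end to end, and a synthetic study generator that reproduces
the phenomenon under controlled conditions.

## Prediction and harmonization

Predicted expression is `ŷ_s = Σ_k w_k d_sk` with no intercept and no
scaling. The only accuracy metric downstream is the Pearson correlation
between observed and predicted expression, which is invariant to location
and scale, so an intercept would change nothing and is deliberately
omitted.

Weights are expressed per copy of a designated effect allele while VCF
genotypes count ALT alleles, so every (model SNP, VCF variant) pair is
resolved to one of six harmonization decisions: use the ALT dosage as-is,
flip it (`2 − d`, when the effect allele is the VCF REF), the same two
after strand-complementing the model alleles, drop as strand-ambiguous
(A/T and C/G pairs, only when `drop_ambiguous` is enabled), or drop as a
mismatch. Non-SNV records are dropped as mismatches, never raised as
errors. `drop_ambiguous` defaults to off: within a single study there is
no strand uncertainty, and the flag exists for real cross-platform use.
Model SNPs absent from the genotype data contribute nothing; the
per-gene fraction of usable SNPs is reported as coverage so users can
filter on completeness. A gene with no usable SNP yields an all-zero
prediction and is flagged constant rather than silently dropped.

Missing genotypes are mean-imputed per variant (the variant's mean ALT
dosage over non-missing samples in the file, computed before any sample
subsetting). This preserves sample size, which matters because the
downstream correlations are computed per population on modest group
sizes. Variants are matched by rsid, falling back to a
`chrom:pos:ref:alt` key when the VCF ID column is `.`. Gene identifiers
are matched after stripping Ensembl version suffixes, since expression
matrices and weight databases routinely disagree only in the `.NN`
suffix.

## Scoring and filtering

Accuracy is the Pearson `r` per gene per population — not `r²`, so that
genes whose predictions correlate *negatively* with observation count
against the model rather than being disguised as modest positive
performance. A cell is recorded as missing when either vector is constant
within the group (sample variance below `1e-12`); correlation is
undefined there and such genes are excluded from that group rather than
assigned a value.

The poorly-predicted filter regresses observed on predicted expression
per gene over the pooled samples of all populations and applies a
two-sided Wald test to the slope. Genes with p > α (default α = 0.05) are
labeled `poorly_predicted`; genes with constant predictions are
`excluded_constant`; the rest are `kept`. Pooling all populations is the
primary definition; a per-group sensitivity mode (keep when significant
in at least one group) is available because the choice materially affects
the filtered tables. Because the test is two-sided, genes with
significantly negative slopes are kept — which is why filtered
correlation bins can still contain `r < 0` genes.

Binned summaries use six categories: `r < 0`, then five left-closed
intervals `[0, 0.2), [0.2, 0.4), [0.4, 0.6), [0.6, 0.8), [0.8, 1]`. The
left-closed convention is declared explicitly (`r = 0` falls in
`[0, 0.2)`) because interval notation in such tables is ambiguous at the
boundaries.

## The inferential layer

**Paired t-test.** Two-group comparisons (pooled home-continent vs
diverged population; one weight database vs another on shared genes) use
a paired t-test with pairing on the gene, so between-gene variation in
predictability cancels. Incomplete pairs are dropped with a logged count;
a zero-variance difference vector is a hard error rather than a p-value.

**Random-intercept mixed model.** Population differences across more than
two groups are modeled as

`r_ij = β0 + γ_i + Σ_g β_g I[j = g] + ε_ij`,
`γ_i ~ N(0, σ²_γ)`, `ε_ij ~ N(0, σ²)`,

with population as a categorical fixed effect against a reference
population and a per-gene random intercept absorbing between-gene
variation; the shared intercept induces compound symmetry within genes.
The pipeline fits this model three ways, mirroring the standard analysis
sequence: all populations (reference first), excluding the reference
population (sensitivity to a possibly atypical reference), and the
non-diverged populations only (within-continent differences).

Estimation is REML, implemented in the package rather than delegated:
Fisher scoring on `(σ²_γ, σ²)` with the fixed effects profiled out
analytically at each step. Genes are grouped by missingness pattern, and
every trace and quadratic form in the score and expected information is
accumulated per pattern from closed-form block inverses
`V⁻¹ = (I − φ/(1+mφ) J)/σ²`, so a fit costs O(genes × groups²) per
iteration. Missing cells are handled by the likelihood (each gene
contributes the cells it has — no imputation); a `complete_cases` mode is
provided because whether incomplete genes should be dropped is a
judgment call, and both are supported. Inference is Wald with the normal
reference distribution and model-based standard errors (CI = estimate ±
1.96·SE); no small-sample df correction is applied because the intended
gene counts are in the thousands, and no multiple-testing correction is
applied across the handful of population contrasts.

**Numerical details.** Convergence requires relative change in the
restricted log-likelihood below `1e-10` *and* relative parameter change
below `1e-8` (the likelihood criterion alone can stop with variance
components still ~1e-6 away from the optimum in flat regions), capped at
100 iterations with an error on non-convergence. Steps that would make
`σ²_γ` negative are projected onto the boundary, after which scalar
scoring continues on `σ²` alone; the fit is flagged `boundary`, and a
positive boundary score lets the iteration leave zero again. Steps are
halved whenever they would decrease the objective. Starting values split
the total variance equally between the two components. A table whose OLS
fit is already exact (e.g. all cells equal) returns both variance
components as exactly zero instead of iterating. For balanced complete
tables the profiled GLS fixed effects coincide with ordinary group-mean
contrasts, which the tests assert to 1e-12; agreement of estimates,
standard errors and variance components with an independent REML
implementation (`lme4`, run with tightened optimizer tolerances) is
asserted to 1e-6 across randomized designs.

**Repeated-measures ANOVA.** The null of no population differences is
tested with F = MS_group / MS_error from the classical two-way
decomposition without replication (genes as blocks), df = (k−1),
(k−1)(n−1), whenever the table is balanced and complete. Unbalanced
tables fall back to the Wald F on the k−1 contrasts of the REML fit with
the same denominator df, flagged approximate in the output — the exact
small-sample distribution under unbalancedness has no closed form, and at
the intended scale (thousands of genes, a handful of missing cells) the
approximation is immaterial. A table with zero between-group sum of
squares returns F = 0 exactly, including the degenerate case where the
error sum of squares is also zero.

## The synthetic study generator

The generator emulates the structure of a real cross-population
evaluation: five populations — a reference/training population, three
close relatives, one strongly diverged — genotyped at SNPs in disjoint
per-gene windows, with expression driven by a cis-genetic component and
prediction weights trained in the reference population only.

* **Allele-frequency drift** follows the Balding–Nichols model: given
  ancestral frequency p and divergence F, population frequencies are
  `Beta(p(1−F)/F, (1−p)(1−F)/F)` (mean p, variance F·p(1−p)), clamped to
  [0.01, 0.99] so every variant stays polymorphic and "common" in the
  sense the prediction-model paradigm assumes.
* **LD** comes from a first-order Markov chain along each gene's SNPs:
  haplotypes with stationary frequencies equal to the population's
  drifted frequencies and adjacent-allele correlation `ld_rho`;
  genotypes are sums of two independent haplotypes. Conditional
  probabilities are clamped to [0, 1], which attenuates realized LD when
  adjacent frequencies are very different — one of the mechanisms by
  which divergence degrades tagging.
* **Expression** is `y = g + e` with `g` the causal-dosage combination
  and noise variance `Var(g)(1−h2)/h2`, where `Var(g)` is computed
  empirically in the reference population and the same noise level is
  applied to all populations. Heritability is therefore defined in the
  training population, and target-population heritability moves with the
  drifted genetic variance — as it would in real data.
* **Training** is deliberately simple (marginal per-SNP OLS keeping SNPs
  with slope p < 0.05, or joint OLS), a stand-in for penalized-regression
  training that keeps the weights analytically checkable. By default
  (`tagging_only = TRUE`) the causal SNPs are excluded from the trainable
  set, so the models must rely on LD tagging; this makes cross-population
  decay flow through the hypothesized mechanism — tag-causal LD and
  allele frequencies drifting apart between training and target — rather
  than through direct causal-SNP transfer, and it is the package's chosen
  study condition rather than a tunable claim about any particular
  dataset.

Default conditions, chosen once to mirror a realistic desk-scale study:
5 populations × 60 samples, 80 genes × 6 SNPs (1 causal), ancestral MAF
uniform on [0.1, 0.5], F_ST = (0, 0.01, 0.01, 0.02, 0.15), `ld_rho` =
0.7, h² = 0.3. Determinism is strict: every draw derives from one master
seed with a separate stream per (component, gene), so adding genes does
not perturb earlier genes' draws, and regenerating a study with the same
configuration is byte-identical, SQLite files included.

What the generator does *not* emulate: realistic recombination maps or
demography (bottlenecks, admixture), trans-acting or rare-variant
effects, expression measurement structure (batch, PEER factors, probe
effects), or strand ambiguity across genotyping platforms. Passing tests
on synthetic studies therefore demonstrate that the pipeline's
statistics behave as designed under the stated generative model — not
that any particular real dataset will show effects of the simulated
magnitude.

## Validation included in the test suite

The acceptance tests exercise, at sizes chosen to keep the whole suite
under a few minutes on one CPU: oracle equivalence of the REML fit with
`lme4` over 50 randomized designs (5–50 genes, 2–5 groups, up to 10%
missing cells, tolerance 1e-6); exact balanced closed forms over 100
tables (group-mean contrasts to 1e-12, classical F against the
`stats::aov` error-stratum decomposition to 1e-10); ANOVA type-I error
within [0.035, 0.065] over 2,000 null replicates of 200 genes × 5
groups; recovery of known contrasts (including a −0.07 diverged-
population effect) within 3 Monte-Carlo SEs with >99% ANOVA power over
200 replicates at 1,000 genes; filter calibration on a 500+500
null/heritable mixture at 400 samples; strict monotone decay of
diverged-population accuracy across F_ST ∈ {0.01, 0.05, 0.15} over 20
seeds of the full pipeline; the heritability ceiling (mean per-gene r²
within ±0.05 of h² = 0.4 at 300 genes × 500 samples); and byte-exact
format round trips plus bit-identical pipeline reruns.

## Known limitations

The mixed model assumes homoskedastic, normal gene effects on the raw
correlation scale; correlations are bounded and their sampling variance
depends on the true correlation and the group size, neither of which the
model represents (no Fisher z-transformation is applied, by design — the
raw-r scale is the convention for these comparisons). The unbalanced
ANOVA F is approximate, as flagged. The trainer is not a penalized
regression, so absolute accuracy levels are not comparable to published
databases — only the comparative structure across populations is. The
pipeline takes the observed expression matrix as given; any
normalization or covariate adjustment is upstream of it and is the
user's responsibility.
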