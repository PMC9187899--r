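# sepsisPhenoscope

Phenotype discovery and 28-day survival prediction for intensive-care sepsis
admissions from 35 routine blood tests.

## The scientific problem

Sepsis is a syndrome, not a single disease: admissions that share the
diagnosis differ widely in laboratory presentation and in 28-day mortality.
A recurring finding in critical-care cohorts is that unsupervised clustering
of routine blood tests recovers a small number of laboratory phenotypes —
including coagulopathy-dominated groups with distinctive PTT / PT / INR
profiles and shifted neutrophil/lymphocyte fractions — and that these
phenotypes carry prognostic information beyond standard severity scores.

`sepsisPhenoscope` implements that workflow end to end:

1. **Cohort.** A synthetic MIMIC-like generator (`sampleCohort()`) draws
   admissions from a four-phenotype mixture. Each phenotype specifies
   printed-scale quartiles `(median, q1, q3)` for every blood test, matched
   exactly by two-piece (split) log-normal / normal marginals; a two-piece
   constant hazard over the 28-day horizon (the two coagulopathy phenotypes'
   survival curves cross, the classic case where log-rank and
   Gehan–Breslow–Wilcoxon disagree); heparin-usage rates; and an organ panel
   for severity scoring. Missingness is injected completely at random.
2. **Conditioning.** Complete-case exclusion, shifted min-max normalization
   `x* = (x − 0.99 min)/(max − min)` fitted on the training split only,
   a seeded 7:3 split, and three-mechanism minority up-sampling
   (replication / median synthesis / IQR-scaled jitter) to a 1:1
   death:survivor ratio. Majority records are never altered.
3. **Phenotyping.** K-means (Lloyd, best of 10 k-means++ restarts) with the
   cluster count chosen by an elbow/silhouette compromise, a 3-D PCA
   embedding, and per-feature heterogeneity profiling that reports the
   *higher* of the Kruskal–Wallis and Jonckheere–Terpstra p values
   (exact permutation enumeration at small n, tie-corrected asymptotics
   otherwise).
4. **Survival.** Self-contained Kaplan–Meier curves, Mantel log-rank and
   Gehan–Breslow–Wilcoxon tests, again reported under the conservative
   higher-p rule.
5. **Severity.** SOFA and SIC scores computed from versioned JSON threshold
   tables (`inst/extdata/severity_thresholds.json`), swappable without code
   changes.
6. **Prognosis.** Two bespoke classifiers — the **DCQMFF**
   (double-coefficient quadratic multivariate fitting function), a
   two-headed softmax model whose 33 channels each carry a full 78-term
   quadratic expansion of the 11 organ-function inputs and which provably
   collapses to a single quadratic logit per head (`dcqmffCollapse()`), and
   a seven-layer 1-D **CNN** (channels 1–8–16–16–32–32–16–1, 7809
   parameters, 35 → 23 → 1) — plus logistic, lasso, and random-forest
   baselines and SOFA-as-a-predictor, all evaluated with self-contained
   tie-adjusted ROC/AUC.

Model internals (quadratic expansion, analytic gradients, CNN forward and
backward passes, exact permutation tests, KM/log-rank machinery, ROC) are
implemented directly in the package; standard steps lean on established
libraries (`stats::kmeans`, `cluster::silhouette`, `glmnet`,
`randomForest`, `mclust::adjustedRandIndex`).

## Worked example

A small pipeline run (800 admissions so it finishes in under a minute; the
default configuration simulates 2902):

```r
library(sepsisPhenoscope)

cohort <- sampleCohort(defaultCohortConfig(nPatients = 800, seed = 42))
cohort
#> SepsisCohort: 800 patients x 35 blood tests
#>   28-day survival: 79.0%; events: 168
#>   planted clusters: C1=97, C2=588, C3=17, C4=98

phenotypeSpecs(defaultCohortConfig())[["C3"]]
#> PhenotypeSpec C3: weight 0.028, heparin 0.70,
#>   hazard (0.0300, 0.0030)/day, break day 7

cfg <- pipelineConfig(
  cohortConfig = defaultCohortConfig(nPatients = 800, seed = 42),
  seed = 42, kGrid = 2:6,
  dcqmff = dcqmffConfig(epochs = 150, seed = 42),
  cnn = cnnConfig(epochs = 20, seed = 42))
report <- runPipeline(cfg)
report
#> EvalReport: 452 train / 194 test admissions; K = 3
#>   DCQMFF test AUC 0.547, CNN test AUC 0.513, SOFA AUC 0.463
#>   baselines (test AUC): logistic 0.448, RF 0.358, lasso 0.500

c(report$k_selection$k_elbow, report$k_selection$k_sil)
#> [1] 3 3
unlist(report$cluster_sizes)
#> [1]  55 223 174
report$cluster_survival$p_dual
#> [1] 0.1720657
report$survival_logrank$p
#> [1] 0.01576789
```

Two things about this output are worth reading honestly. At 800 admissions
the elbow/silhouette compromise picks K = 3, not the planted 4 — the
smallest phenotype (C3, 2.8 % mixing weight) contributes only ~17 patients
and is not separable at this size, and min-max normalization compresses the
heavy-tailed coagulation features relative to the percentage features. And
test AUCs hover near 0.5 because in the generator mortality depends on the
blood tests *only through* phenotype membership: the per-admission hazard is
constant within a phenotype, so the Bayes-optimal AUC of any feature-based
classifier is modest, and 194 test admissions leave wide noise bands around
it. The cross-cluster survival split is still detected
(Gehan–Breslow–Wilcoxon p ≈ 0.016; the reported dual p is the conservative
max of the two tests). On cohorts where features separate outcomes
directly, the same classifiers reach AUC ≥ 0.9 — the test suite constructs
such cohorts and verifies this.

## Documentation

* `vignettes/phenotyping-methods.Rmd` — the methods vignette: generator
  construction, normalization and up-sampling, K selection, the dual-test
  reporting rule, DCQMFF mathematics and the collapse identity, CNN
  architecture, and numerical choices.
* Function-level documentation via roxygen comments in `R/`.
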