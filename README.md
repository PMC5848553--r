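# ribotype

Discovery and characterization of ribosomal protein transcript (RPT)
expression patterns in bulk RNA-seq tumor cohorts.

## The problem

The ~80 cytoplasmic ribosomal protein (RP) genes are among the most highly
expressed transcripts in every cell, yet their *relative* stoichiometry is
not constant: tumors and normal tissues carry reproducible, tissue- and
subtype-specific RPT compositions, and subsets of tumors within a cancer
cohort shift the composition of particular transcripts (e.g. high
*RPL8*/*RPL30*, low *RPL3*, high *RPS4X*, high *RPL13*), sometimes driven by
copy-number amplicons and sometimes associated with distinct clinical course.
`ribotype` packages the full analysis used to find such patterns:

1. **Relative expression.** For sample *i* and RP gene *g* with linear RPKM
   `x[i, g]`, the core statistic is the composition
   `r[i, g] = x[i, g] / sum_g x[i, g]`, so each sample lies on the simplex
   (`sum_g r[i, g] = 1`). This removes library size and overall ribosome
   abundance, leaving stoichiometry.
2. **Embedding.** Exact (O(n²)) t-SNE on Euclidean distances between
   compositions: per-sample Gaussian affinities calibrated by bisection so
   every conditional distribution has perplexity `2^H = P`, symmetrized to a
   joint `P`, then gradient descent (learning rate 10, up to 5000 iterations
   or until stabilized, early exaggeration 12×250, momentum 0.5→0.8) on
   `KL(P‖Q)` with a Student-t kernel `Q`. PCA is available for comparison.
3. **Cluster discovery.** Density connectivity on the embedding (radius from
   the kNN-distance elbow; clusters need ≥ 10 samples; the rest is `NOISE`).
4. **Differential patterns.** Per-gene one-way ANOVA volcano tables across
   clusters; Welch cluster-vs-rest contrasts; and cross-cohort co-regulated
   sets: transcripts whose direction of change is consistent (and
   significant at α = 0.01) in *every* cluster sharing an anchor transcript.
5. **Associations.** GISTIC copy-number calls (amp = call > 0, del < 0)
   tested per gene × cluster by chi-squared, Benjamini–Hochberg at 5% FDR,
   and *flagged* only above 90% in-cluster incidence; categorical clinical
   fields by chi-squared (α = 0.01); continuous fields by Welch t or
   Wilcoxon rank-sum after Shapiro-Wilk gating; Kaplan–Meier curves compared
   by log-rank (Mantel–Haenszel) and Gehan–Breslow–Wilcoxon tests.
6. **Classifiers.** Cohort-balanced 60/10/30 splits; binary logistic
   regression reporting the c-statistic, sensitivity and specificity; and a
   feed-forward ReLU network with the full hyperparameter sweep (learning
   rate, batch size, dropout, one or two hidden layers of 0–200 units, L2).
7. **Synthetic cohorts.** A Dirichlet-composition generator with planted
   subclusters (anchor + co-regulated shifts), amplicons, clinical effects
   and exponential survival hazards provides ground truth for every stage.

## Worked example

```r
library(ribotype)

subs <- recurring_patterns(c(0.3, 0.25),
  cnv_amplicon = list(genes = c("RPL8", "RPL30"), call = 1L,
                      incidence = 0.95, log2_effect = 0.25),
  hazard = 2e-3)
co <- generate_cohort(cohort_spec("DEMO", n_tumor = 150,
                                  subclusters = subs, seed = 42))
res <- run_cohort_analysis(co$expression, cnv = co$cnv,
                           phenotype = co$clinical, survival = co$survival,
                           config = pipeline_config(perplexities = c(8, 12),
                                                    iterations = 800, seed = 1))
res
#> Cohort analysis: 150 samples; 3 cluster(s) (perplexity 8 , noise 0 )
#>   CNV associations flagged: 2
#>   log-rank p: 5.48e-09
head(res$volcano[order(res$volcano$p), c("gene", "F", "neg_log10_p", "delta")], 5)
#>     gene        F neg_log10_p       delta
#> 31 RPL30 697.8029    75.03891 0.025984583
#> 7   RPL8 465.6136    63.60638 0.017459724
#> 70 RPS20 273.7030    49.56077 0.017754875
#> 37 RPL36 129.1077    32.36709 0.006515110
#> 9  RPL10 123.7154    31.50603 0.006190664
```

Reading the output: the cohort was generated with two planted tumor
subclusters (a high-*RPL8*/*RPL30* group carrying an 8q-style amplicon and a
raised death hazard, and a low-*RPL3* group). The pipeline finds three
clusters (the two planted ones plus the unshifted bulk), the volcano ranks
exactly the planted transcripts on top (`delta` is the spread in mean
relative expression across clusters), the amplicon genes are the two flagged
CNV associations, and the hazard difference shows up in the log-rank test.

For several cohorts, `run_pan_cancer()` adds the grouped embedding, the
cross-cohort co-regulation report (e.g. anchor *RPL8* up, with *RPL7*
consistently up and *RPL10* consistently down), a tissue-of-origin network
and a tumor-vs-normal logistic model.

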