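# ageswitch

Human tissue expresses an age-related transcriptional program whose linear
trajectory is not lifelong: transcripts that track age steadily through the
third to sixth decades of adulthood largely stop doing so afterwards. This
package implements, end to end and against synthetic data with known truth,
the analysis pipeline needed to detect and characterise such a midlife
"switch" in bulk transcriptome data:

1. **Probe-level quantification** for 25-mer array probes: exact matching
   against a transcriptome, single-match filtering, per-sample GC-content
   adjustment, detection/variance filtering, and Tukey median-polish
   summarisation into a transcript × sample log2 matrix.
2. **Two-window age association**: per-cohort partial Spearman correlation
   of expression with age (residualising both expression and age on aerobic
   capacity and insulin sensitivity), Benjamini–Hochberg FDR, and a
   cross-cohort consistency rule (same sign in every cohort, mean q below a
   threshold) producing the age signature.
3. **Switch classification**: signature transcripts whose window-2
   (post-55 y) correlation keeps sign and magnitude are *Group 1*; those
   whose window-2 correlation is close to zero are *Group 2* (switched
   off). Per-decade coefficients of variation on the linear scale serve as
   a stochasticity control, and low-CV transcripts shared across tissues
   are flagged as housekeeping genes.
4. **Cross-tissue concordance**: sign agreement of the signature in a second
   tissue with an exact binomial test against 0.5.
5. **Connectivity screening**: a bidirectional Kolmogorov–Smirnov running-sum
   score of an up/down query signature against compound reference rankings,
   normalised so perfect constructions attain exactly ±100, with
   hypergeometric compound-class enrichment among hits.
6. **Network and heritability**: permutation-thresholded Spearman
   co-expression networks (FDR < 1%, 10,000 permutations) with degree-based
   hub statistics compared between coding and noncoding biotypes, and
   one-way ANOVA intraclass correlations over monozygotic twin pairs
   contrasting heritability between biotypes.

A first-class synthetic-data module generates every input with planted
truth — trajectory classes (Group 1 / Group 2 / null / housekeeping),
covariate confounding, GC-biased and multi-mapping probes, twin panels with
biotype-specific heritability, compound libraries with planted
mimics/opposers — so that each stage's recovery can be tested quantitatively.

## The statistics in brief

For transcript *g* in cohort *c* with window *W*, the association statistic
is the partial Spearman correlation
ρ<sub>gc</sub> = cor(rank(ε<sub>g</sub>), rank(ε<sub>age</sub>)) computed on
samples with age ∈ W, where ε<sub>g</sub> and ε<sub>age</sub> are the least
squares residuals of expression and age on [1, VO₂max, insulin
sensitivity]. A transcript enters the signature iff sign(ρ<sub>gc</sub>) is
identical across cohorts and mean<sub>c</sub> q<sub>gc</sub> ≤ 0.03 (BH).
Classification: |ρ<sup>w2</sup>| ≤ 0.1 → Group 2; |ρ<sup>w2</sup>| ≥ 0.2
with the window-1 sign → Group 1; otherwise unclassified.

The connectivity score of a query (U, D) against a ranking of n genes is
100·(ES(U) − ES(D))/2 when the two enrichment statistics have opposite
signs and 0 otherwise, where ES is the KS running-sum statistic
a = max<sub>j</sub>(j/t − V(j)/n), b = max<sub>j</sub>(V(j)/n − (j−1)/t),
ES = a if a > b else −b, divided by its maximum attainable magnitude for
(t, n) so that perfect top placement gives exactly +1.

The twin ICC is the one-way ANOVA estimator with k = 2:
ICC = (MSB − MSW)/(MSB + MSW).

## Worked example

```r
library(ageswitch)
report <- run_pipeline(default_run_config(seed = 1, out_dir = "demo_run"))
```

runs the eight-stage demo world (500 transcripts, 80 planted age-related of
which 75% Group 2, three cohorts of 100 for ages 20–55, one cohort of 100
for 55–86, a second tissue sharing 60% of the age genes, a 100-compound
library with 5 planted mimics and 5 opposers, 30 twin pairs with
heritability 0.8 coding / 0.5 noncoding) in about ten seconds and prints
per-stage headlines. With seed 1 it reports:

| stage | headline numbers | meaning |
|---|---|---|
| quantify | median truth correlation **0.953** | probe-summarised expression tracks the planted abundances |
| age_scan | signature size **80**, fraction negative **0.69** | all 80 planted age transcripts recovered; two-thirds decline with age |
| classify | **21** Group 1, **37** Group 2, 22 unclassified; **30** housekeeping | the planted switch and all 30 housekeeping genes are found |
| concordance | fraction **0.85**, p = 1.2e-10 | the second tissue replicates direction far above chance |
| screen | **5** positive and **5** negative hits, top class `pathway_inhibitor` | exactly the planted mimics/opposers score beyond ±90 |
| network | 1913 edges, degree p = **0.82** | coding and noncoding nodes contribute equally to the network |
| heritability | difference **−0.259** [−0.323, −0.200] | noncoding expression is less heritable, recovering the planted gap of −0.3 |

Everything is written under `demo_run/` as TSV/FASTA/JSON, including
`run_report.json` with parameters, input hashes and the numbers above. The
same run is available from the command line:

```sh
Rscript exec/ageswitch run --seed 1 --out-dir demo_run
Rscript exec/ageswitch age-scan --config my_config.json   # any single stage
```

## Documentation

The methods vignette (`vignettes/age-switch-methods.Rmd`) describes the
model, every tunable threshold with its default and rationale, what the
synthetic generator does and does not emulate, and known limitations.
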