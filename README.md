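# tinarray

Transcriptome instability (TIN) scoring from exon-microarray data.

Exon arrays measure every exon of a gene with its own probe set. When a
tumor's splicing machinery is perturbed, individual exons depart from
their gene's overall expression level — skipped where the cohort includes
them, included where the cohort skips them. tinarray quantifies how much
of this *deviating exon usage* each sample accumulates, classifies samples
into instability subtypes, and carries the classification through to
splicing-factor biology and patient survival. It is aimed at cancer
transcriptomics groups analyzing exon-level expression cohorts (the
motivating setting is stage II/III colorectal cancer) and at
methodologists who want a fully simulatable, ground-truthed test bed for
exon-level instability analysis.

## The method

1. **Preprocessing** — normal+exponential background correction per chip
   and inter-chip quantile normalization, then log2.
2. **Gene model & FIRMA scores** — per gene, the additive probe model
   `log2 I[k,s] = c[s] + p[k] + r[k,s]` is fitted by median polish over
   all probes of the gene (no exon term, so exon-level departures stay in
   the residuals). Each exon's score in each sample is its median residual
   divided by a robust per-gene scale (1.4826 x median |r|):
   negative = candidate skipping, positive = candidate inclusion.
3. **TIN profiles** — scores beyond the 1st/99th percentiles of the series
   are counted per sample; counts are expressed as log2 ratios to the
   cohort mean (`rel_skip`, `rel_incl`, `rel_total`) with
   `skew = rel_skip - rel_incl`. Samples with `|skew| > 0.7` are **sTIN**
   (skewed instability); samples with `|rel_total| > 1.0` are **oTIN**
   (overall instability).
4. **Splicing-factor association** — per-gene Pearson correlation of
   expression with `rel_total`, benchmarked against random gene sets of
   equal size and against permutations of `rel_total` across samples;
   hierarchical clustering (Euclidean, complete linkage) of samples on
   splicing-factor expression.
5. **Survival** — Kaplan–Meier curves, log-rank tests and Cox
   proportional-hazards models (Efron ties) for patients stratified by
   TIN status.
6. **Simulation** — a generator with known ground truth (injected
   deviations, coupled splicing factors, hazard contrast) so every stage
   has a parameter-recovery test surface.

See `vignettes/tin-methods.Rmd` for the full model description, parameter
rationale and validation design.

## Worked example

```r
library(tinarray)

sim  <- simulate_tin_study(sim_config(), seed = 1)   # 300 genes x 80 samples
ff   <- firma(sim$intensities, sim$chipdef, bg_correct = FALSE)
prof <- tin_profiles(ff, pseudocount = 0.5)
glance(prof)
#>   n_samples mean_total_count lower_threshold upper_threshold n_sTIN n_oTIN
#> 1        80             48.4           -4.13            1.68     28      8

score_detection_auc(ff, sim$truth$events)
#> [1] 0.9999965
```

The thresholds bracket the central 98% of all FIRMA scores; 8 of 80
samples are called oTIN (the simulation planted 8 TIN-positive samples at
3x the baseline deviation rate), and the absolute scores separate injected
from uninjected (exon, sample) cells essentially perfectly. At this
desk scale each sample has only ~50 flagged exons, so the skew statistic is
noisy and sTIN calls are liberal — on a real array with thousands of
flagged exons per sample the skew noise shrinks accordingly.

```r
assoc <- sf_association(sim$sf_expression, sim$sf_genes, prof, seed = 2)
assoc
#> Splicing-factor association (280 genes, alpha = 0.05)
#>   significant: 280 (100.0%), of which 280 negative / 0 positive
#>   mean r among significant: -0.920
#>   random-set null: p(n significant) < 0.01, p(neg:pos ratio) 0.01
#>   permutation null: p(|median r|) = 0.000999, p(neg excess) = 0.002

sv <- tin_survival(prof, sim$clinical, scheme = "oTIN",
                   covariates = c("stage", "msi", "age", "sex", "location"))
sv
#> TIN survival analysis (scheme: oTIN)
#>   groups: rest n=72, oTIN n=8
#>   log-rank chi-square = 17.752, p = 2.516e-05
#>   univariate HR = 4.75 (95% CI 2.14 to 10.55), p = 0.0001287
#>   multivariate HR = 5.52 (95% CI 2.25 to 13.53), p = 0.0001866
```

Splicing-factor expression is (by simulated design) negatively coupled to
deviation burden: all 280 factors correlate negatively, far beyond what
random gene sets or permuted burdens produce. Patients with oTIN tumors
have a hazard ratio of 4.8 (the simulation's true value is 3.2, within the
interval), independent of stage, MSI, age, sex and location.

`autoplot()` methods display profiles (`autoplot(prof)`), Kaplan–Meier
curves (`autoplot(sv$km)`) and the random-set benchmark
(`autoplot(assoc)`); `tidy()`/`glance()` turn every result into tibbles.

A command-line front end with subcommands `simulate`, `firma`, `tin`,
`sf-assoc`, `cluster`, `survival` and `run-all` is installed under
`exec/tinarray`; real studies enter as plain TSV/CSV files (probe
intensities, a probe→exon→gene chip definition, a splicing-factor gene
list, a clinical table) in the formats documented in `?read_chipdef`,
`?read_intensity_matrix` and `?read_clinical`.

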