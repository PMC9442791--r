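# PDXphos

Downstream quantitative analysis of multi-plex TMT proteomics and
phosphoproteomics for patient-derived xenograft (PDX) cohorts.

## The problem

A PDX tumor proteome measured by LC–MS/MS is a human/mouse mixture, and a
cohort of 20 lines does not fit in one TMT 11-plex: samples are split over
several plexes that share a pooled internal reference channel. Comparing
abundances across plexes, calling subgroup differences, inferring kinase
activities from phosphosites, and correlating basal abundance with drug
response all require a careful, reproducible chain of filtering,
normalization and statistics. PDXphos implements that chain as composable
functions, plus a synthetic-data generator with planted ground truth so
that every stage can be validated without raw MS data.

For features *f* and samples *s* the core operations are:

- **SL**: within each plex, scale every channel so its total observed
  intensity equals the plex mean.
- **IRS**: per feature, scale each plex by
  `geomean(ref_f across plexes) / ref_f(plex)` so reference values agree
  across plexes exactly.
- **TMM**: per column, factor `2^(weighted trimmed mean of
  log2(x_f/ref_f))` (30%/5% M/A trims, inverse-variance weights),
  factors normalized to geometric mean 1.
- **Differential**: one-way ANOVA per feature on log2 values, Tukey–Kramer
  pairwise p, Benjamini–Hochberg q across features (q < 0.05); ranking
  metric `-log10(p) · sign(log2FC)`.
- **ssGSEA**: descending-sorted running sum, increments
  `|v|^0.75 / Σ_set |v|^0.75`, decrements `1/(N − n_set)`; ES = area.
- **Kinase activity**: per sample, minimize
  `Σ_sites (obs_s − mean_{k∈K_s} a_k)²` subject to `0 ≤ a_k ≤ 24`
  (100 bounded multi-start optimizations); the prediction-score cutoff for
  the substrate network maximizes the Matthews correlation coefficient
  against curated annotations.
- **Drug signature**: per screen entry, Spearman correlation of abundance
  with percent viability on matched pairs, sign-flipped to sensitivity;
  median over duplicate entries; top-100 signature; per-sample ssGSEA NES;
  top-50 vs bottom-50 response comparison by Welch t-test.

## Worked example

```r
library(PDXphos)

cfg <- sim_config(seed = 11)        # 20 PDXs, 2 plexes, SHH/G3/G4 planted
res <- run_pipeline(cfg, n_starts = 25)

res$protein
#> AbundanceMatrix: 500 features x 20 samples (2 plex(es), 0 reference channel(s))
#> missing: 0.9%

res$cluster_ari                     # Ward/Euclidean clustering vs truth
#> [1] 1

sig <- subset(res$diff_protein, !untested & q < 0.05)
nrow(sig)                           # differential proteins at q < 0.05
#> [1] 133
head(sig[order(sig$q), c("feature", "F", "p", "q", "log2fc_SHH_vs_G3")], 3)
#>     feature   F        p        q log2fc_SHH_vs_G3
#> 102  P00102 678 6.16e-17 3.08e-14           -1.860
#> 55   P00055 538 4.29e-16 1.07e-13            2.032
#> 145  P00145 510 6.66e-16 1.11e-13            0.194

sum(res$signature %in% res$experiment$truth$drug_associated_proteins)
#> [1] 76                            # planted drug proteins in the top-100

head(res$signature_scores, 3)       # per-sample signature NES (ssGSEA)
#>   sample    es   nes
#> 1  PDX01  18.1  1.27
#> 2  PDX02  33.1  2.05
#> 3  PDX03 -27.9 -1.94
```

The normalized protein matrix recovers the three planted subgroups
perfectly (adjusted Rand index 1); 133 of 500 proteins are called
differential, consistent with the planted 25% shifted fraction plus
group-aligned drug proteins; 76 of the 100 planted drug-associated
proteins land in the top-100 sensitivity signature at the planted
|Spearman| = 0.8 and n = 20.

A command-line wrapper covering each module ships in `inst/cli/pdxphos`:

```sh
Rscript inst/cli/pdxphos simulate --seed 1 --out sim/
Rscript inst/cli/pdxphos pipeline --seed 1 --out results/
Rscript inst/cli/pdxphos enrich --mode ssgsea --matrix m.tsv --gmt sets.gmt --out nes.tsv
```

## Package layout

- `R/synthetic.R` — `sim_config()`, `generate_experiment()`,
  `generate_kinase_sites()`, `generate_drug_table()`
- `R/normalize.R` — filtering, rollup, SL/IRS/TMM, phosphosite
  condensation, outlier QC
- `R/differential.R` — `anova_tukey()`, `bh_adjust()`, `rank_metric()`
- `R/enrichment.R` — `ssgsea_score()`, `gsea_ranked()`, `hypergeom_ora()`
- `R/kinase.R` — `match_curated()`, `optimize_cutoff()`,
  `build_network()`, `score_activities()`
- `R/drugsig.R` — `correlate_response()`, `extract_signature()`,
  `score_signature()`, `compare_extremes()`
- `R/pipeline.R` — `run_pipeline()`, `pdxphos_cli()`
- `vignettes/pdxphos-methods.Rmd` — models, parameters, design choices
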