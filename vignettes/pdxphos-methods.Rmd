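---
title: "PDXphos: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PDXphos: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PDXphos)
```

# The analysis problem

Patient-derived xenograft (PDX) tumor models propagate human tumor cells in
mice, so a PDX proteome measured by mass spectrometry is a mixture of human
tumor and mouse stromal protein. When such cohorts are quantified with
isobaric (TMT) labeling, samples are distributed over several multiplexed
runs ("plexes"), and cross-plex comparison requires a pooled internal
reference channel measured in every plex. PDXphos implements the downstream
quantitative chain for this design:

1. species filtering and protein rollup,
2. three-stage cross-plex normalization (SL → IRS → TMM),
3. phosphopeptide filtering and phosphosite condensation,
4. group-wise differential abundance (one-way ANOVA, Tukey, BH),
5. enrichment scoring (ssGSEA, ranked GSEA, hypergeometric ORA),
6. kinase activity inference on a curated + predicted substrate network,
   with an MCC-optimized prediction-score cutoff,
7. drug-sensitivity correlation signatures.

Every stage is exercised end-to-end on synthetic data with planted ground
truth, so the package is testable without any external download.

# Quantification model and normalization

Reporter intensities are treated as linear-scale abundances; all signal
parameters (batch offsets, group effects, noise) live on the log2 scale.

**Species filtering and rollup.** Only peptides unique to the human
proteome are quantitatively interpretable in a PDX; `filter_human_unique()`
keeps them, and `rollup_proteins()` sums peptide intensities per protein
and channel. Peptides matching more than one master protein are excluded
from rollup; missing values are ignored and an all-missing group stays
missing. Features missing in ≥ 50% of analytic samples are removed
(`filter_missing()`, boundary inclusive); the filter is applied on the
combined multi-plex matrix (the alternative — per plex before combining —
is a caller choice, since the stages are separate functions).

**Sample loading (SL).** Within each plex, every channel (including the
reference) is scaled so its total observed intensity equals the plex mean,
removing pipetting/labeling differences. Post-condition: within-plex column
sums agree to 1e-9 relative tolerance.

**Internal reference standard (IRS).** Per feature, the geometric mean of
its reference-channel values across plexes is the consensus; each plex's
columns are scaled feature-wise by consensus/reference. After IRS a
feature's reference values agree across plexes exactly, and the operation
is idempotent. Features absent from (or zero in) any plex's reference are
dropped with a logged count — they cannot be placed on a common scale.

**Trimmed mean of M-values (TMM).** Residual compositional/scale bias is
removed by a robust column factor: with a reference column chosen as the
one whose upper quartile is closest to the mean upper quartile, each
column's factor is `2^(weighted trimmed mean of log2(column/reference))`,
trimming 30% of M values and 5% of A values on each side and weighting by
the delta-method inverse variance `1/(1/x + 1/ref)`. Factors are
normalized to geometric mean 1 and columns divided by them. The trim
fractions are the standard defaults of the method; the source workflow
names the method without parameters. Note the M statistic here uses raw
column-to-reference ratios (not library-size-normalized ones): after SL the
column totals are already equalized, and the factor is meant to absorb
residual total-scale differences — this is what makes a column multiplied
by 2 recover a factor of ≈ 2.

**Phosphopeptides.** Peptides are retained when they carry at least one
phosphosite, are localization-unambiguous, map to exactly one master
protein, and have an identification score strictly greater than 200 in at
least one plex (evaluated on the best per-plex score supporting the
peptide). Phosphopeptide matrices are normalized by the same SL/IRS/TMM
chain and then condensed to phosphosites: per site and sample, the
arithmetic mean over all peptides containing the site, with
multiply-phosphorylated peptides contributing to each of their sites.
Phosphosites are deliberately *not* normalized to protein abundance, so
phosphoproteins absent from the global proteome remain usable. Site keys
are `ACCESSION_RESPOS` with 1-based positions in the master protein.

**Outlier QC.** The flagging rule (advisory, never auto-excluding) is this
package's operationalization: a sample is flagged when its distance from
the centroid in the first two principal components exceeds `sd_mult = 3`
times the median distance, or its missing fraction exceeds the 0.75
quantile of all samples by more than 0.1 absolute. The study this package
generalizes reported excluding one PDX line for exactly these two symptoms
but gave no rule.

# Differential abundance

Per feature, a one-way fixed-effects ANOVA on log2 abundances (log2 makes
fold-changes additive; the scale is not stated by the source and is
configurable by transforming the input), with Tukey-Kramer adjusted
pairwise p-values (exactly `TukeyHSD`'s unbalanced form, computed from
explicit sums of squares and `ptukey`) and Benjamini-Hochberg across
features applied to the ANOVA p-values — Tukey p's are already
family-corrected within feature. Missing values are complete-case within
feature; a feature lacking two groups with ≥ 2 observations is reported
untested instead of erroring. Significance is called at q < 0.05. The
enrichment ranking metric is `-log10(p) * sign(log2FC)`, with zero
p-values clamped to the smallest positive double.

# Enrichment

`ssgsea_score()` implements the single-sample running-sum statistic:
features sorted by descending value, increments `|v|^alpha / sum|v|^alpha`
at set members (alpha = 0.75, the reference implementation's default),
decrement `1/(N - n_set)` at non-members, ES = the sum of the running sum
(area). Ties in the sort are broken by feature name for determinism. NES
normalization is configurable: division by the mean absolute ES of random
same-size sets (default) or by the ES range across the evaluated
collection. `gsea_ranked()` is the classical weighted KS-style statistic
with gene-label permutation; p-values are two-sided on |ES| with the
`(b+1)/(n_perm+1)` convention, which keeps them uniform under the null and
bounded away from zero. `hypergeom_ora()` is the upper-tail hypergeometric
test, standing in for web-service over-representation tools.

# Kinase activity

The substrate network unions curated links (exact accession/residue/
position matches) with predicted links whose score strictly exceeds a
cutoff; curated wins on duplicates, and kinases undetected in the data can
be filtered out (after cutoff selection, by default). The cutoff is chosen
by Matthews correlation over a threshold grid: predictions with curated
support are positives (TP above, FN at-or-below the threshold), the rest
negatives (FP above, TN at-or-below); MCC is defined 0 when a denominator
factor vanishes; the smallest maximizing threshold is chosen (sensitivity-
favoring tie-break). The grid defaults to the unique observed scores plus
midpoints.

Activity scoring models each site's log2 abundance as the arithmetic mean
of its linked kinases' activities, and per sample minimizes the sum of
squared residuals under box constraints `[0, 24]` — the dynamic range of
log2 reporter intensities — using L-BFGS-B with an analytic gradient from
100 uniform-random restarts ("100 iterations" of the source's scoring tool
is read as its multi-start heuristic). The problem is convex, so the
restarts buy robustness against optimizer edge cases rather than global
search; ties are broken first-found and results are seed-deterministic.
Kinases with no observed linked site are excluded with a warning. With
zero noise and every kinase owning at least one private site the truth is
recovered to 1e-6.

# Drug signatures

Per screen entry, feature abundance is Spearman-correlated with percent
viability on matched pairs (≥ 4 required), flagged samples excludable by
id. Reported values are oriented *to sensitivity* (the negative of the
correlation with viability), so proteins high in sensitive lines score
positive — the source names its signature by sensitivity while correlating
against viability. Entries of the same drug are combined by the per-feature
median; the signature is the top-100 by correlation-to-sensitivity with
lexicographic tie-breaking; per-sample signature NES comes from ssGSEA; and
external-cohort validation compares response between the top-50 and
bottom-50 lines by signature score (or any per-line score, e.g. one
protein's abundance) with an unequal-variance t-test by default (the
pooled form is exposed; the source's environment defaults to Welch).

# The synthetic world

`sim_config()` defaults state the emulated design: 20 samples in two TMT
11-plexes (10 sample channels + 1 pooled reference per plex), subgroups
SHH n=6, G3 n=10, G4 n=4, randomized plex assignment. Stated or
field-realistic parameters, chosen once:

* `plex_effect_sd = 0.5` log2 — batch offsets between plexes.
* `noise_sd = 0.25` log2 — peptide-level measurement noise, a typical
  TMT reporter CV of ~18%.
* `group_effect_size = 2` log2 — subgroup-defining proteins differ
  several-fold between molecular subgroups (MYC programs, lineage
  markers); 25% of non-drug proteins carry a one-group shift.
* `frac_mouse = 0.15`, `frac_shared = 0.05` — stromal contamination;
  shared peptides carry two master proteins and so also exercise the
  multi-master exclusion.
* `missing_rate = 0.05`, completely at random at the peptide-in-sample
  level (the source states no missingness mechanism; MCAR is the testable
  default). Reference channels are pooled and deep, hence always observed.
* phosphosite residues drawn 88.2% S / 11.8% T / 0.05% Y, the composition
  reported for the emulated dataset; kinase activities uniform on [2, 22]
  inside the scoring bounds; each site driven by one kinase (20% by two),
  with round-robin assignment guaranteeing every kinase a private site.
* the drug world: viability is a strictly monotone transform of a
  sensitivity latent with a group-aligned component (`drug_group_shift =
  2` SD toward the G3-like group — drug response tracks a molecular
  subgroup, as for MYC-driven ActD sensitivity); each of the 100 planted
  proteins mixes the latent with its own noise through a Gaussian copula
  (Pearson `2 sin(pi * rho_S / 6)`) so its population |Spearman| with
  viability equals `drug_effect = 0.8`, and `drug_coef = 0.75` log2 per
  latent SD sets the abundance amplitude.

Abundances are emitted on the linear reporter scale; each plex's reference
channel is the *noise-free pooled mean of all samples* (not only the
plex's own) times the plex offset, mirroring a reference pooled from equal
peptide amounts of every line. One RNG stream per component (quantitation,
missingness, phospho, drug screen) is derived from the master seed, so
toggling one component never perturbs another; identical configs give
byte-identical outputs.

What the generator does **not** emulate: spectral interference and ratio
compression, isotope impurities, intensity-dependent missingness,
peptide-specific digestion/ionization biases beyond a static weight, FDR
behavior of the search engine, and co-regulated protein modules beyond the
planted drug/group structure. A green recovery test therefore establishes
correctness of the downstream arithmetic under the stated model, not
robustness to acquisition artifacts.

Because all planted drug proteins share one realized latent per
experiment, single-experiment signature recovery is itself a random
variable with a left tail (observed 0.83–0.99 across seeds at n = 19); the
acceptance check uses the median over five fixed seeds.

# Numerical choices and degenerate inputs

* SL errors on all-zero columns, naming them; IRS drops features with
  missing/zero reference values, with counts in the provenance record.
* TMM trimming is rank-based (ties "first"); an empty post-trim set gives
  factor 1; fewer than two analytic columns is a warned no-op.
* MCC uses the 0-for-0/0 convention; confusion counts are accumulated in
  double to avoid integer overflow.
* Zero p-values are clamped to `.Machine$double.xmin` before the signed
  log metric; `sign(0) = 0`.
* ssGSEA with a set covering all features has an empty decrement pool;
  only increments contribute.
* Activity estimates are clamped to the bounds after optimization to
  remove sub-epsilon excursions; objective ties keep the first solution.
* All file formats are plain text (TSV/GMT/JSON); missing is written `NA`.

# Known limitations

* PSM-level detail is not modeled; peptide identification scores stand in
  for per-plex PSM score maxima.
* The kinase model ignores phosphatases and site-specific kinase affinity;
  sites weight their kinases equally.
* NES definitions differ across GSEA implementations; both normalizations
  offered here are documented but neither reproduces any specific external
  tool's constant factors.
* `detect_outliers` is a screening heuristic; borderline samples need
  human review.
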