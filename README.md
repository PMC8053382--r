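# emoccur

Community-ecology statistics for site-structured ectomycorrhizal (EM)
fungal OTU tables — the kind of dataset produced by ITS metabarcoding of
pooled root samples from a few forest sites.

Surveys of this design ask two questions the usual toolbox answers only
partially: *do the sites host different fungal communities?* (diversity,
dissimilarity, PerMANOVA, Mantel, spatial eigenvectors), and — the harder
one — *which individual fungi are tied to which site?* For the second,
`emoccur` implements a permutation-null **site/fungus occurrence
analysis**:

1. the rarefied table is binarised and collapsed to a **site-level
   matrix** `N(i, j)` = number of site *i*'s samples containing OTU *j*;
2. a **shuffle-sample null** permutes the sample→site assignment (site
   sizes fixed, sample contents intact) 1,000 times;
3. each OTU's (and each site's) specialization is measured by the
   Kullback–Leibler index **d′**,
   `d = Σⱼ p′ⱼ ln(p′ⱼ/qⱼ)` rescaled to [0, 1] by its exact
   marginal-constrained minimum and maximum, and standardized against the
   null: `z = (d′_obs − mean(d′_rand)) / sd(d′_rand)`;
4. each site–OTU pair gets a **two-dimensional occurrence (2DO)** score,
   the analogous z of `N(i, j)` against the null ensemble, with one-tailed
   p-values and Benjamini–Hochberg FDR control across all tested cells.

A synthetic OTU-table generator with planted site specialists
(3 sites × 7 samples, 122-OTU pool, depth 1,038 by default) makes the
whole pipeline testable end to end: type-I error, null-uniformity and
power suites all run against data whose truth is known.

## Worked example

```r
library(emoccur)
spec <- synthetic_spec(seed = 20260925,
                       planted_specialists = plant_specialists(synthetic_spec(),
                                                               strength = 0.9))
ds <- generate_dataset(spec)
ds$table
#> OTU table: 21 samples x 122 OTUs, 21,798 reads total

occ <- occurrence_analysis(ds$table, ds$metadata, n_permutations = 1000, seed = 1)
occurrence_report(occ, alpha = 0.05)
#> Occurrence report (FDR < 0.05, abundant OTUs only):
#>   OTUs: 9 of 20 significant (45%)
#>   sites: 3 of 3 significant
#>   site-OTU cells: 9 of 60 tested significant (15.0%)
```

The nine significant cells are exactly the nine planted specialists; the
first few, with their 2DO scores:

```r
head(subset(occurrence_report(occ)$cells, significant), 3)
#>     site  otu_id n_obs null_mean  null_sd   two_do        p_raw       p_fdr
#> 133   GH OTU_045     7     3.047 1.079795 3.660881 0.0001256750 0.002097972
#> 137  HGL OTU_046     7     3.406 1.105616 3.250677 0.0005756529 0.004934167
#> 141 SHWL OTU_047     7     4.304 1.078307 2.500215 0.0062059013 0.041372675
```

Each row reads: the OTU was found in all 7 of the site's samples
(`n_obs`), the shuffle null expects about 3–4 (`null_mean`), the excess is
2.5–3.7 null standard deviations (`two_do`), significant after FDR
correction. Community-level statistics on the same dataset:

```r
d <- bray_curtis(hellinger_transform(ds$table))
permanova(d, ds$metadata$site, n_permutations = 999, seed = 2)
#> PerMANOVA pseudo-F: statistic = 4.4365, p = 0.001 (Monte-Carlo, 999 permutations)
mantel_test(d, geographic_distance(ds$metadata), n_permutations = 999, seed = 3)
#> Mantel r: statistic = 0.5471, p = 0.001 (Monte-Carlo, 999 permutations)
```

The full stage chain — rarefaction, diversity + ANOVA, accumulation
curves, abundance classes, Venn partition, lineage aggregation,
Bray–Curtis/Sørensen with Mantel/PerMANOVA/PCNM/envfit, occurrence — runs
as one call with TSV outputs and a YAML manifest:

```r
cfg <- pipeline_config(synthetic = synthetic_spec(seed = 1),
                       out_dir = "run1", seed = 1)
run_pipeline(cfg)
```

A thin CLI (`inst/scripts/emoccur-cli.R`) wraps `simulate`, `run` and
`calibrate` for shell use. See `vignettes/occurrence-methods.Rmd` for the
model details, numerical conventions, the design-stage power analysis and
known limitations.

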