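---
title: "Methods: community statistics and the site/fungus occurrence analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community statistics and the site/fungus occurrence analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emoccur)
```

# Scope and data model

`emoccur` implements the statistical workflow of desk-scale ectomycorrhizal
(EM) fungal surveys in which a small number of sites (typically three) are
each represented by a handful of pooled root samples, and the community is
summarised as a sample × OTU table of ITS read counts after clustering and
rarefaction. The canonical orientation everywhere in the package is
**samples as rows**; identifiers are opaque strings. Empty OTU columns —
which arise routinely after rarefaction — are dropped with a logged warning
(a strict mode errors instead), so every validated table satisfies: integer
counts ≥ 0, unique identifiers, no all-zero OTU columns.

Upstream read processing (quality filtering, ITS extraction, chimera
removal, clustering, taxonomic assignment) is out of scope: the package
starts from the clustered table. NMDS embeddings and random-forest variable
importance are likewise delegated to external tools; `env_fit()` consumes
ordination scores from any embedding.

# Rarefaction, diversity and community summaries

Rarefaction (`rarefy_table()`) is a one-shot uniform subsample without
replacement of each sample's reads to a common depth (default 1,038), the
usual single-draw convention of survey papers; repeated draws with different
seeds support stability studies. The exact hypergeometric expectation of
retained richness,

$$E[S_d] = \sum_i \left[1 - \binom{N - n_i}{d}\Big/\binom{N}{d}\right],$$

is exposed as `expected_rarefied_richness()` and serves as the oracle for
the sampler. The same closed form (with occupancies in place of counts)
gives the exact OTU accumulation curve against which the random-ordering
curve of `accumulation_curve()` is checked.

Alpha diversity is richness, Shannon entropy in nats, and Simpson's index
in the complement form $1 - \sum p^2$, which is bounded in $[0, 1)$ and is
the standard companion of Shannon in community ecology reports. Diversity
is computed on the rarefied table by default; whether richness should come
from the rarefied or raw table is genuinely ambiguous in survey practice,
and the rarefied choice keeps all downstream statistics on one object.

Abundance classes use the conventional whole-dataset thresholds: dominant
at ≥ 1 % of all reads, rare below 0.01 %, and an independent "abundant"
flag above 0.1 % marking the subset retained for occurrence testing. The
dominance threshold is applied to pooled relative abundance (not per
sample); this is the reading consistent with tallies like "17 dominant and
80 rare OTUs" in three-site surveys of ~122 OTUs.

# Dissimilarity and spatial/environmental association

The pipeline mirrors the dual reporting common in the field: Hellinger
transformation followed by Bray–Curtis for abundance-based analyses, and
binarisation followed by Sørensen for presence/absence robustness checks
(Sørensen is identical to Bray–Curtis on the binary matrix, and the suite
asserts that identity numerically).

`mantel_test()`, `permanova()` and `env_fit()` are implemented in-package
with the explicit formulas (PerMANOVA partitions
$SS_\mathrm{total} = \frac1n \sum_{i<j} d_{ij}^2$ into between- and
within-group components; the pseudo-F reduces to the classical one-way
ANOVA F for Euclidean distances on one coordinate, which the tests
verify). Three numerical conventions apply throughout:

* Monte-Carlo permutation p-values use $(1 + b)/(1 + m)$, counting the
  observed statistic in the null set, so $p > 0$ always;
* exhaustive enumeration of all $n!$ permutations switches on
  automatically when the permutation space is ≤ 10,000 (and can be forced
  either way); the exhaustive p is the exact fraction of permutations,
  identity included, at or above the observed statistic;
* default Monte-Carlo counts are 999 for Mantel/PerMANOVA/envfit and
  1,000 for the occurrence null, with a caller-supplied seed.

`vegan` stands behind the standard primitives (rarefaction draws,
diversity indices, accumulation permutations, Hellinger, Bray–Curtis) and
is used as an independent cross-check — never as the implementation — for
the permutation tests and PCNM.

`pcnm_vectors()` truncates the geographic distance matrix at the longest
minimum-spanning-tree edge (the conventional default; with three sites the
choice is inert but documented), replaces larger distances by four times
the threshold, double-centres the Gower matrix and returns eigenvectors
with positive eigenvalues. Geographic distances default to plain Euclidean
distance on decimal degrees — the convention such surveys actually use —
with a haversine mode (mean Earth radius 6,371 km) for kilometre units.

# The site/fungus occurrence analysis

This is the package's core contribution. From the binarised table (by
default the rarefied one; a switch allows the raw table, since survey
descriptions leave this ambiguous) the **site-level matrix** counts, for
each site × OTU cell, the number of that site's samples containing the
OTU.

**Null model.** "Shuffle-sample" is interpreted as permuting the
sample→site assignment with site sample-counts fixed while leaving every
sample's OTU content intact — the only reading that is simultaneously
"based on the sample-level matrix" and content-preserving. Every ensemble
member therefore conserves OTU occupancies (column sums) and
`samples_per_site` exactly, which the suite asserts per member.

**d′.** For a focal unit with interaction vector $n$ (total $T$) and
partner availabilities $q_j$ (partner marginal over grand total),

$$d = \sum_j p'_j \ln (p'_j / q_j), \qquad p'_j = n_j / T,$$

normalised to $d' = (d - d_{\min})/(d_{\max} - d_{\min}) \in [0, 1]$ where
the extremes range over integer reallocations of $T$ across partners with
all other rows fixed. Because $d$ is a separable convex function of the
allocation, both extremes are available exactly without enumeration: the
maximum of a convex function over the integer simplex is attained at a
vertex (all interactions on the rarest partner, so
$d_{\max} = \ln(1/\min_j q_j)$), and the minimum is found by the greedy
incremental allocation, which is provably optimal for separable convex
resource allocation. Exhaustive enumeration over all compositions is
retained both as an option and as the test oracle; the suite confirms
agreement on hundreds of random matrices. Degenerate cases are explicit:
a single available partner gives $d' = 0$ by convention, zero-marginal
partners are excluded, zero-total focal units are returned as `NA` with a
warning.

**Standardized scores.** Observed $d'$ (per OTU, and per site on the
transpose) is standardised against the ensemble mean and SD; per-cell
**2DO** scores do the same for the occurrence counts. Cells or focal units
whose null SD is zero are flagged undefined — never silently set to 0.
Raw p-values are upper-tailed by default (the question is which pairs
occur *more* often than chance; a two-tailed flag exists) and come in two
modes: a standard-normal approximation of the z-score (default — it gives
a smooth score-to-p relation), and the empirical rank
$(1 + \#\{N_\mathrm{rand} \ge N_\mathrm{obs}\})/(1 + m)$ used by all
oracle tests. Benjamini–Hochberg FDR is applied jointly across all defined
site–OTU cells, and separately across OTU-level and site-level $d'$
scores; `occurrence_report()` re-applies it within the reported family
when the >0.1 % abundance filter is on, and always reports the number of
cells actually tested, since undefined cells make nominal cell counts
(e.g. 42 OTUs × 3 sites) overstate the family size. Score thresholds that
correspond to FDR ≈ 0.05 are data dependent, so the report derives its own
rather than hard-coding a published one.

# The synthetic generator as the study design

`synthetic_spec()` defaults encode the emulated design: 3 sites × 7
samples, a 122-OTU pool, exactly-rarefied depth 1,038 (a negative-binomial
raw-depth mode exists for rarefaction tests). Base relative abundances are
a ranked geometric series with ratio 0.93 — few dominant, many rare —
reproducing the pooled dominance structure without fitting any real data;
a log-series option ($\propto x^k/k$, default $x = 0.8$) produces the much
longer rare tail in which the majority of the OTU pool occurs in fewer
than three of 21 samples (never-observed pool OTUs count toward that
fraction). Site covariates are means plus per-sample Gaussian jitter,
loosely patterned on a cold-temperate montane range (MAT −4.7 to 0.1 °C,
MAP 374–506 mm); they are synthetic values, not a claim about real soils.

Site affinity multiplies an OTU's sampling probability by
$1 + (S - 1)s$ in its preferred site and $1 - s$ elsewhere; the factor
$S - 1$ makes the site-averaged multiplier 1, so specialization does not
change an OTU's expected abundance class, and $s = 1$ confines the OTU
entirely to its site. What the generator does **not** emulate is
within-site patchiness: real root-tip communities are strongly aggregated
below site level (many moderately-abundant OTUs appear in a single
sample), while multinomial sampling spreads reads evenly across a site's
samples. Passing calibration and power suites therefore demonstrates
correctness of the statistics under site-level structure, not a claim
that the generator reproduces every occupancy feature of real surveys.

## Design-stage power analysis

The planted-specialist design used by the power suites
(`plant_specialists()`) places nine specialists at consecutive geometric
ranks 45–53, preferred sites cycling. The band was fixed by a design-stage
power analysis before the validation suites were written: specialists must
be abundant enough to survive the >0.1 % filter (ranks ≲ 59 at ratio
0.93), yet rare enough that binarised presence still differs between
sites — a ~0.3 % OTU down-weighted by $1 - s = 0.1$ drops to ~0.3 expected
reads per non-preferred sample and so to ~25 % presence, whereas a 1 %
OTU stays near-ubiquitous even when down-weighted tenfold and carries no
presence/absence signal at all. Within that band a pilot sweep gave
per-cell detection (planted cell FDR < 0.05 among abundant cells, normal
p-mode, 1,000 permutations) of ≈ 0.97 at strength 0.9, dropping steeply at
both band edges. Power is essentially zero at strengths ≤ 0.6 — binarised
occurrence is blunt against moderate preferential abundance — so the
monotonicity check across strengths {0.3, 0.6, 0.9} is asserted as
non-decreasing.

## Calibration and the discreteness of empirical p-values

On site-exchangeable null data the shuffle null is exactly the
data-generating symmetry, so empirical per-cell p-values are *valid*:
$P(p \le \alpha) \le \alpha$. They are, however, markedly conservative,
not uniform: the occurrence count per cell takes at most
`samples_per_site + 1` values, ties against the null ensemble are massive,
and the rank p-value piles up at coarse achievable levels. Measured over
100 null datasets (200 permutations each) the pooled rejection rate at
0.05 is about 1 %. The suite therefore asserts validity (rejection below
the binomial upper bound) as the calibration property; an exact-uniformity
check around 5 % cannot hold for this discrete statistic and is retained
in the acceptance suite as a documented expected failure. The
normal-approximation mode smooths this discreteness and is the default for
reporting; PerMANOVA and Mantel p-values, built on continuous statistics,
*are* uniform under the null and are checked against binomial 99 % bounds
over 400 simulated datasets.

# Orchestration and reproducibility

`run_pipeline()` executes the stages in the documented order, writes every
tabular result as TSV, and finishes with a YAML manifest capturing the
config snapshot, the per-stage row/column counts, all warnings (e.g. what
was dropped and why) and the derived seeds. One master seed determines
per-stage seeds via `derive_seeds()`, so a config plus one integer
reproduces the run byte-for-byte; the suite checks checksum equality of
reruns. Failures abort naming the stage. A thin command-line wrapper
(`inst/scripts/emoccur-cli.R`, subcommands `simulate`, `run`, `calibrate`)
exposes the same functions for shell use; the R functions, this vignette
and the scripts are the package's primary interface.

Problem sizes used by the validation suites — 400 null datasets for
permutation-test uniformity (60 OTUs, depth 300: the property is
size-free), 100 datasets × 200 permutations for occurrence calibration at
the full study design, 20 replicates × 1,000 permutations per strength for
power — were chosen once as the smallest designs that give stable binomial
bounds for the properties asserted.

# Known limitations

* The generator's multinomial sampling omits within-site aggregation (see
  above); occupancy-tail realism requires the log-series base model and is
  still weaker than real root-tip data.
* Standardized d′ is undefined for OTUs present in all (or almost all)
  samples, since every shuffle reproduces the same site profile; such OTUs
  are reported as undefined rather than tested.
* Empirical per-cell p-values are conservative by discreteness; use the
  normal mode for ranking and the empirical mode for exactness against
  the ensemble.
* `geographic_distance()`'s degree mode treats coordinates as planar — the
  survey convention, but not a metric distance at continental scales; use
  the haversine mode when kilometres matter.
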