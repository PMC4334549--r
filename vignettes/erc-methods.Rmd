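---
title: "Evolutionary rate covariation: model, statistics, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary rate covariation: model, statistics, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ercnet)
```

# The problem

Genes that work together tend to evolve together: when selective pressure on
a pathway changes, the evolutionary rates of its member genes rise and fall
in tandem across lineages. Evolutionary rate covariation (ERC) quantifies
this as the correlation coefficient, across the branches of a shared species
phylogeny, of two genes' branch-specific relative evolutionary rates. Gene
pairs with ERC near 1 covary strongly and are candidates for shared
function; a random pair is centered near 0.

`ercnet` implements the full analysis stack on top of that signal:

1. placing per-gene branch lengths on a canonical branch coordinate system
   (`species_topology()`, `load_gene_trees()`);
2. normalizing them into relative rates by projection (`normalize_relative_rates()`);
3. the pairwise ERC matrix (`erc_matrix()`);
4. permutation tests for elevated mean ERC in gene groups, with Storey
   q-values and the null proportion η₀ (`permutation_test_group()`,
   `scan_groups()`, `estimate_qvalues()`);
5. guilt-by-association candidate prioritization against a training set
   (`group_erc_scores()`, `best_erc_scores()`, `rank_and_percentile()`,
   `window_candidates()`, `loo_benchmark()`);
6. a disease–disease network from between-group ERC with shared genes
   excluded (`disease_pair_test()`, `build_disease_map()`);
7. a synthetic-data generator that plants pathway-level rate covariation of
   known strength, so every stage above is testable end to end
   (`simulation_config()`, `simulate_rate_matrix()`, `make_benchmark_fixture()`).

Estimating the branch lengths themselves (e.g. from amino-acid alignments
with a maximum-likelihood rate model) is out of scope: the package consumes
newick trees that already carry branch lengths.

# Branch coordinates and the presence mask

All gene trees must be topologically consistent with one reference species
topology. The topology is treated as unrooted and each branch is identified
by the bipartition (split) of the species set it induces; the canonical
branch id is the sorted species list on the side *away* from the
alphabetically first species. This makes branch identity, column order, and
therefore every downstream matrix independent of input file order.

A gene present in only a subset of species contributes a pruned tree.
Pruning merges chains of reference branches into single edges; a merged
edge's length is a sum of non-comparable pieces, so those reference branches
are recorded as **absent** for that gene (the conservative choice), and only
branches that restrict uniquely onto the pruned tree receive values. The
presence mask produced this way propagates unchanged through normalization,
and every pairwise statistic is computed over the branches present in
*both* genes of a pair.

Genes represented in too few species are removed before any statistics
(`filter_min_species()`; default 17, the conventional threshold for a
33-species mammalian set — set it proportionally for other clades).

# Projection normalization

Branch lengths confound divergence time (shared by all genes) with
gene-specific rate. Let $a$ be the genome-average branch-length vector
($a_i$ = mean length of branch $i$ over the genes having it). For a gene $g$
with length vector $b_g$ over its present branches $P_g$, the relative-rate
vector is the residual of the orthogonal projection of $b_g$ onto $a$, with
all inner products restricted to $P_g$:

$$ r_g \;=\; b_g \;-\; \frac{\langle b_g, a\rangle_{P_g}}
                            {\langle a, a\rangle_{P_g}}\, a . $$

This removes the component shared with the genome-wide average — time and
average rate — and leaves signed branch-specific deviations. By
construction $\langle r_g, a\rangle_{P_g} = 0$ (the test suite asserts this
to $10^{-9}$), the residual scales linearly with the gene's lengths, and the
mask is untouched. Raw branch lengths are used by default; `transform =
"sqrt"` or `"log1p"` is available for users who prefer variance
stabilization before projection.

Two numerical notes. Zero-length branches are valid data and are kept.
A gene whose present branches have an all-zero average vector has no defined
projection; it is flagged `non_normalizable` rather than silently passed
through. The average vector is computed once from the full post-filter gene
set and reused for every gene; with realistically many genes, a gene's own
contribution to $a$ is negligible (see the generator section for the regime
where this matters).

# The ERC value and its sampling behavior

ERC is the Pearson correlation of two genes' relative rates over their
shared branches (Spearman is available as an option). An entry is defined
only if the pair shares at least `min_shared` branches (default 10) and both
restricted vectors have nonzero variance; undefined entries stay undefined
— they are never imputed as 0 — and drop out of every downstream mean.

For independent genes on $n$ shared branches, the Fisher transform
$z = \operatorname{atanh}(\mathrm{ERC})$ is approximately normal with
variance $1/(n-3)$. This holds for *unweighted* correlation when the branch
coordinates are comparably scaled. Because the relative-rate residual on
branch $i$ still carries the factor $t_i$ (the branch time), strong
dispersion in branch times acts as an uneven weighting that reduces the
effective number of branches by roughly $\exp(4\,\sigma_t^2)$ for log-normal
times with log-sd $\sigma_t$ — at $\sigma_t = 0.2$ the null z-sd is already
inflated by ~8–11%. The synthetic generator therefore defaults to modest
branch-time dispersion ($\sigma_t = 0.1$), where the $1/(n-3)$ law holds and
the calibration suite can assert it; real phylogenies are more
heterogeneous, and ERC values computed on them have heavier-tailed nulls
than the Fisher law suggests. That is a property of unweighted ERC itself,
not of this implementation, and is the main reason all group-level inference
in this package is permutation-based rather than analytic.

# Group statistics

The mean ERC of a gene group is averaged over its *defined* member pairs.
Significance comes from a permutation null: `n_perm` random gene sets of the
same size (same count of matrix-present genes), drawn without replacement
from all genes in the matrix, with
$p = \#\{\text{null means} \ge \text{observed}\} / n_\text{perm}$
(ties count against the observation). A zero tally is reported censored as
"< 1/n_perm" and imputed at $1/(2\,n_\text{perm})$ wherever a number is
needed (FDR input, sorting). Defaults are 100,000 permutations for a group
scan and 10,000 for disease pairs; the test suite uses 1,000–5,000, which is
ample for the effect sizes it plants.

Across a scan, q-values and the null proportion η₀ are estimated in the
Storey style: $\hat\eta_0(\lambda) = \frac{\#\{p > \lambda\}}{m(1-\lambda)}$
on the grid $\lambda = 0, 0.05, \dots, 0.9$, smoothed with a cubic spline
(df = 3) and read off at the largest $\lambda$; q-values are
$\hat\eta_0\, m\, p_{(i)}/i$ with enforced monotonicity.
Benjamini–Hochberg is available as a fallback mode. On 100-group scans the
smoother has a per-scan standard error near 0.1, so the package's own
calibration checks average η₀ over replicate scans rather than trusting a
single one. Result tables are ordered by p, then descending mean ERC, then
name: censored p-values tie at the floor, and the observed effect size is
the natural deterministic tie-break.

# Prioritization

Given a training set of known disease genes, a candidate's GROUP score is
its mean defined ERC with the training set; the BEST score is the maximum.
GROUP is the default (it is the more stable of the two; BEST is kept behind
an option). Candidates are ranked by descending score, ties sharing the mean
of their occupied ranks, and the reported percentile is the fraction of all
candidates scoring *strictly lower* — rank 1 of 31 is percentile
30/31 ≈ 0.968. Candidates with no defined ERC against the training set
cannot be prioritized: they rank below every defined score and never count
as "scoring lower" for anyone else.

Candidate lists come either from a chromosomal window — all annotated genes
whose interval overlaps the window of total width `window_bp` centered on
the target's midpoint (default 1 Mb; note the source analyses describe both
1 Mb and 10 MB regions, so the width is an explicit argument) — or
scattered uniformly from the matrix (the exome-like setting). The
leave-one-out benchmark drops each group member in turn, scores it against
the remaining members among its window or scattered decoys, and records the
training set's own permutation p alongside, since prioritization quality is
strongly conditional on the training set having an ERC signature in the
first place.

# The synthetic generator

The generator is the package's ground truth. Branch lengths are

$$ b_{g,i} = t_i\, \mu_g\, e^{\sigma d_{g,i}}, \qquad
   d_{g,i} = \sqrt{\rho}\; s_{P(g),i} + \sqrt{1-\rho}\; e_{g,i}, $$

with $t_i$ log-normal branch times, $\mu_g$ log-normal per-gene base rates,
and $s$ (one factor per pathway × branch) and $e$ (per gene × branch)
independent standard normals. Genes in one pathway share the factor $s$, so
their log-deviations correlate at exactly $\rho$ on every branch; genes
outside pathways use $d = e$. Species are dropped per gene with probability
`missing_prob` (default 0.2) and masks are derived by the same
branch-restriction rules the tree loader uses, so the generator and loader
agree exactly (the fixture round-trip test asserts bit-level agreement up to
newick printing precision).

Defaults and why:

* `n_species = 32` → 61 unrooted branches, a mammal-scale tree.
* `n_genes = 500` with one 20-gene pathway. The pathway must be a small
  fraction of the gene universe: the pathway's shared factor contaminates
  the genome-average vector in proportion to its fraction $f$, and
  projection then removes part of the planted signal itself, attenuating
  within-pathway ERC by roughly $(1-f)^2$ relative to $\rho$. At
  $f = 0.2$ the recovered mean ERC at $\rho = 0.5$ is ~0.37; at $f = 0.04$
  it is ~0.47. Real pathways are a tiny fraction of a genome, so the small-$f$
  regime is the realistic one.
* `sigma = 0.3` (moderate branch-specific rate dispersion). The log-normal
  link makes recovered ERC $\approx (e^{\rho\sigma^2}-1)/(e^{\sigma^2}-1)$,
  within 0.01–0.02 of $\rho$ at this $\sigma$.
* `time_sdlog = 0.1` for the reasons in the sampling-behavior section.
* A mandatory seed; every output is a pure function of seed and config.

What the generator does *not* emulate: alignment and estimation noise in
branch lengths, non-stationary topology error, correlated missingness
(real ortholog loss is clade-structured, not i.i.d.), multiple overlapping
pathways per gene, and heavy-tailed branch-time dispersion. Passing the
synthetic suite therefore demonstrates the statistics are implemented
correctly and calibrated in their intended regime — it does not by itself
certify performance on any particular empirical dataset.

Signal disease-groups drawn from a pathway are sampled as a random disjoint
partition whenever they fit inside it. The disease-map test excludes shared
genes by design, so overlapping signal groups would test the drop rule's
leftovers rather than between-group covariation; disjoint groups plant
exactly the feature the map is supposed to find.

# Verification workloads and problem sizes

The package's acceptance-style checks (in `tests/testthat/test-acceptance.R`
and recomputed by `scripts/acceptance.R`) use these sizes, chosen as a
balance of Monte-Carlo error against desk-scale runtime:

* ERC vs. brute-force Pearson on 100 random masked fixtures; permutation p
  vs. exhaustive enumeration on a 6-gene universe (the smallest universe the
  degenerate-null guard admits for 3-gene groups).
* Null calibration: 200 random 5-gene groups on a 300-gene null matrix,
  2,000 permutations each, KS test against uniform at α = 0.01.
* Recovery: within-pathway mean ERC at ρ ∈ {0.3, 0.5}, 200 replicates of a
  20-gene pathway in a 500-gene universe at full species coverage (the
  planted correlation is exact there; masking is exercised by its own
  tests); tolerance ±0.05. η₀ on 20 signal / 80 null group scans, averaged
  over replicate scans, tolerance ±0.1.
* Power: planted ρ = 0.3, 10-gene groups, 500-gene universe, 5,000
  permutations, 100 replicates, requiring p < 0.01 in ≥ 90%.
* Leave-one-out: 10-gene pathway among ~90 decoys per window, 50 replicates
  per ρ; median target percentile ≥ 0.90 at ρ = 0.5, 0.5 ± 0.05 at ρ = 0,
  window vs. scattered medians within 0.05.
* End-to-end: 50 replicates of fixture → trees → rates → ERC → group scan →
  prioritization inputs → disease map, requiring the planted group (p < 0.01)
  and the planted disease edge to be top-ranked in ≥ 90%.

# Known limitations

* Unweighted Pearson ERC inherits branch-time heteroscedasticity; on highly
  heterogeneous trees its null is wider than Fisher's law (use the
  permutation machinery, which is calibrated by construction).
* The projection uses a single shared average vector; in tiny gene universes
  (hundreds of genes with a dominant pathway) the attenuation described
  above becomes material.
* η₀ from 100-group scans is noisy (±0.1); treat single-scan η₀ as
  indicative.
* Exact-name disease grouping only: curating disease nomenclature is the
  user's job, as in the Morbid-Map-style inputs this mirrors.
* Branch-length estimation, codon/dN-dS models, and webserver-style
  interfaces are out of scope.
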