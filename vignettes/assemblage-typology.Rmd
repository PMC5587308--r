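---
title: "Deriving hierarchical typologies of tree species assemblages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving hierarchical typologies of tree species assemblages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(assemblr)
```

## The problem

Forest-inventory programs record the species and basal area of every tree stem
on a large network of plots. Which recurring *assemblages* of tree species do
those plots represent, which species statistically define each assemblage, and
which species dominate it? A defensible answer supports monitoring of community
change and lets species-level projections (for example, climate-envelope
importance-value projections) be translated into community-level impact
screens. `assemblr` implements that full chain: importance values, seeded
hierarchical clustering, indicator-species-based selection of the typology,
species dominance, and dominance-weighted impact aggregation.

## Importance values

For plot $p$ and species $s$, with $BA_{ps}$ the summed basal area and
$N_{ps}$ the stem count,

$$IV_{ps} = 100 \cdot \frac{1}{2}\left(\frac{BA_{ps}}{\sum_{s'} BA_{ps'}} +
\frac{N_{ps}}{\sum_{s'} N_{ps'}}\right),$$

so each plot's row sums to 100. "Abundance" is the per-plot stem count, which
is what a per-stem inventory record supports directly. Per-stem basal area may
be given directly or derived from diameter at breast height as
$\pi(\text{dbh}/200)^2$ m². Before IVs are computed, species recoding rules
(merges of varieties, drops of unreliable generic labels, regional splits by a
plain region-code match — no GIS geometry), plot-flag exclusions (e.g.
`nonstocked`), and the rare-species filter are applied. The rare-species
filter removes species occurring in fewer than `min_plots` distinct plots
(default 250, i.e. roughly 0.2% of a national inventory; the pipeline driver
scales it as 0.2% of the actual plot count). The filter runs exactly once —
it is not iterated after plots empty out — and plots left without records are
dropped rather than kept as zero rows, since an all-zero composition has no
defined Bray-Curtis dissimilarity.

## Seeded hierarchical clustering

A plot-level dissimilarity matrix over $10^5$ plots is out of reach (a
127,000-plot symmetric matrix is ~65 GB), so the hierarchy is built in two
stages:

1. **k-means seeding.** Euclidean Lloyd k-means with a large `k` (20,000 for
   national-scale data; `default_seed_k()` uses about one seed per six plots
   for smaller sets) groups identical or near-identical IV rows. Restarts
   (default 5) draw initial centers from the *distinct* rows, so `k` equal to
   the number of distinct rows reproduces them exactly; clusters emptied
   during iteration are re-seeded from the point farthest from its centroid;
   the restart with the lowest within-cluster sum of squares wins, ties going
   to the earliest restart. The seeding metric is Euclidean even though the
   downstream dissimilarity is Bray-Curtis — the seeds exist only to collapse
   near-duplicates, and the equality tests below confirm the collapse is
   faithful.
2. **Size-weighted UPGMA.** Bray-Curtis dissimilarity
   $d(u,v) = \sum_i |u_i - v_i| / \sum_i (u_i + v_i)$ between seed centroids
   feeds average-linkage agglomeration with the Lance–Williams update seeded
   by the leaf weights $n_i$ (the seed sizes):
   $d(i \cup j, m) = (n_i d(i,m) + n_j d(j,m)) / (n_i + n_j)$. When seeds are
   pure duplicates this yields *identical* merge heights to plain UPGMA on the
   full plot-level matrix — the property the whole memory-reduction device
   rests on, asserted to $10^{-9}$ in the test suite. The linkage is computed
   by `stats::hclust(..., members = sizes)`, whose deterministic tie-breaking
   we adopt (ties do not affect merge heights, only the order in which
   equal-height merges are listed). Inputs above 30,000 leaves are refused
   with a pointer to seeding.

Memberships at any cut level are propagated to plots through the seed map;
cuts are nested across levels by construction. Dendrograms are exported as
Newick for interoperability.

## Selecting the typology

Cut levels from 2 up to 200 (or the number of seeds) are scanned. At each
level, indicator species analysis assigns every species
$\text{IndVal}_s = \max_j A_{sj} B_{sj}$, where specificity $A_{sj}$ is the
species' mean IV in cluster $j$ divided by the sum of its cluster means and
fidelity $B_{sj}$ is the fraction of the cluster's plots containing it.
Significance comes from permuting plot labels:
$p = (1 + \#\{\text{perm } \ge \text{obs}\})/(n_{\text{perm}} + 1)$.

Four indices summarise each level: the sum of significant indicator values,
the number of significant indicator species (each species counted once, at its
best cluster), the mean of significant p-values, and the mean silhouette
width. A level is *eligible* only if every cluster has at least one
significant indicator species. Within the eligible set the indices are
deliberately not combined into a single score; the global best and the local
optima of each index are flagged, and candidates are ranked by how many
indices flag them.

Defaults the method itself leaves open, fixed here: $\alpha = 0.05$ and
$n_{\text{perm}} = 999$ with the add-one correction. No multiple-testing
correction is applied across species, matching standard indicator-species
practice for this selection task.

Silhouette widths are computed at the **seed level with size weights** —
each seed contributes with weight equal to its plot count, own-cluster
distances use the $N_C - 1$ denominator so collapsed duplicate plots (at
distance zero) are counted, and neighbour distances are size-weighted means.
This equals the plot-level silhouette exactly when seeds are pure duplicates
and the classical silhouette when all sizes are 1; plot-level computation is
available by passing unit sizes and a plot-level matrix. A cluster containing
a single *plot* scores 0, as in the classical definition; a singleton *seed*
of size > 1 scores naturally (its own-cluster distance is 0).

## Species dominance

Within each cluster, with IVs rescaled to 0–1,

$$SDI = \frac{MC + MSS + THC}{3},$$

where $MC$ is the species' mean relative IV over **all** plots of the cluster
(zeros included — "across all plots" is read within the cluster, since the
index is computed per cluster; a data-set-wide denominator is exposed as
`mc_all_plots`), $MSS$ is the mean inverse plot richness over the plots where
the species occurs, and $THC$ is the fraction of its occurrence plots where it
both exceeds 0.25 relative IV (strictly) and has the most cover of any species
in the plot (ties qualify — co-dominance counts). The three components are the
three routes to dominance: broad high cover, few companions, or high cover
where present.

Dominant species are those whose SDI meets a percentile cutoff of the SDI
values **pooled over all (species, cluster) records** (a single global
cutoff), default the 90th percentile with 85 and 95 as standard alternatives.
The percentile uses linear interpolation between order statistics
(`quantile()` type 7), a convention that must simply be fixed; records tied at
the cutoff all qualify, and raising the percentile can only shrink the
dominant sets.

## Impact aggregation

Given projected changes in IV ($\Delta IV$) per plot, species and scenario
with per-species reliability grades, a cluster enters the assessment only if
it has at least 100 plots, every dominant species is projected, and more than
half of its dominant species have at least medium reliability. For an
eligible cluster the assemblage impact is the SDI-weighted mean change over
all its plots,

$$\frac{\sum_{p}\sum_{s} SDI_s \, \Delta_{ps}}{n_{\text{plots}} \sum_s SDI_s},$$

a convex combination of the projected changes. Plots missing a projection for
some dominant species raise an error rather than being silently skipped —
eligibility is meant to catch them. The per-plot companion statistic is the
unweighted mean across dominant species, for mapping. Percentages are
reported against the SDI-weighted mean current IV of the dominant species
when a baseline is supplied; since the baseline convention is not canonical,
the raw weighted mean change is always reported alongside.

## The synthetic validation study

The generator plants a known typology so every stage can be validated without
any external database. Its defaults are the package's standard study: 4
assemblage templates, 800 plots, 32 species, plot richness 1–12, log-share
noise 0.35, and a 5% chance a plot borrows one foreign species. Each template
has two exclusive indicator species (occupancy 0.9) and a skewed-share pool of
shared species; basal-area shares are normalised exponentials of Gaussian
log-weights (Dirichlet-like, giving realistic dominance skew), stem counts are
proportional to shares with a floor of one stem, and coordinates are uniform
on the unit square with `region_code` split at $x = 0.5$ for testing regional
recoding. Every plot is guaranteed at least one of its template's indicator
species: a "planted" plot containing none of its template's distinctive
species would carry a truth label with no recoverable signal, which average
linkage then isolates as a singleton outlier — legitimate behaviour on real
data, but noise in a ground-truth recovery study. Projected-change surfaces
are linear trends $b_0 + b_x x + b_y y$ per species and scenario with drawn
reliability grades.

What the generator does *not* emulate: inventory sampling design (subplot
geometry, systematic grids), spatial autocorrelation of composition,
zero-inflated detection error, and regional species turnover beyond the
planted templates. Passing recovery tests therefore demonstrate correctness
of the machinery, not field performance on any particular inventory.

Problem sizes used in the validation suite are chosen to exercise every code
path at desk scale: the recovery study runs 800 plots with ~130 seeds and a
2–10 (tests) or 2–40 (acceptance script) scan at 999 permutations; the
seeding-fidelity check uses 200 plots duplicated from 50 profiles; exhaustive
permutation enumeration runs on instances of up to 8 plots, where the full
arrangement set is computable.

## Numerical conventions and limitations

* All randomness flows from explicit integer seeds; rerunning a pipeline with
  the same configuration writes byte-identical tables.
* Permutation statistics compare with a $10^{-12}$ slack so that
  permutation-invariant species (constant IV) land at $p = 1$ despite
  floating-point reordering.
* Recoding rules must be non-conflicting (no code both source and target);
  this makes the operation order-independent and idempotent.
* Average linkage is monotone, so merge heights never decrease; the memory
  guard, not the algorithm, is what limits leaf counts.
* The seeding approximation is exact only when seeds collapse identical rows;
  with heterogeneous seeds the hierarchy is an approximation whose quality
  the silhouette and recovery diagnostics are there to reveal.
* Eligibility reasons report the *first* failed criterion in the fixed order
  (size, dominance, projection coverage, reliability).
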