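---
title: "Cross-species cell-type mapping: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species cell-type mapping: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `orthocellmap`, the
parameters that matter, the choices made where the design was genuinely
open, and what the synthetic validation does and does not demonstrate.

## The comparison unit: ortho-genes

Cross-species expression comparison needs a common feature space. We use
orthogroups (OGs): sets of genes descended from a single ancestral gene,
as tabulated by orthology inference tools in the `Orthogroups.tsv`
dialect (tab-separated; first column the OG id; one comma-separated gene
list per species). Within a species, all paralogs of an OG are collapsed
by **summing raw counts** (`aggregate_to_orthogenes()`). Summation is
deliberate: it treats the OG as a single ancestral locus whose
expression has been partitioned among duplicates, so OG-level totals are
invariant to lineage-specific expansion. The comparison universe is
restricted to OGs with at least one gene in every analyzed species
(`filter_universal_orthogroups()`); presence-based filtering is the
default, with `min_copies`/`max_copies` exposed for users who want
single-copy stringency instead — whether strict single-copy status
should be required is a judgement call we leave to the user, since
presence-based filtering retains more signal at the cost of summing
paralogs with possibly divergent expression.

Two robustness conventions: genes listed in the orthogroup table but
absent from an expression matrix are dropped with a tally (annotation
version drift is routine and must not abort a run), and OGs with no
present gene are kept as flagged all-zero rows so the matrices of all
species stay aligned on one OG universe.

## From counts to fold-change profiles

Single-cell counts are sparse and depth-confounded, so profile building
proceeds in three steps (`make_metacells()`,
`celltype_geometric_mean()`, `fold_change()`):

1. **Metacells.** Cells of the same type are shuffled (under the run
   seed) and summed in consecutive groups of `metacell_size` (default
   10). Leftover cells are dropped rather than merged so that every
   metacell has identical support; a cell type with fewer cells than the
   group size contributes nothing, with a warning.
2. **Depth-normalized geometric mean.** Each cell is scaled by
   median(total counts)/(its total counts) — "median cell size"
   normalization — and the per-type mean is geometric, computed as
   exp(mean(log(x + ε))) − ε with ε = 0.05, floored at zero. The
   geometric mean is the natural location estimate for log-distributed
   expression and is robust to a few high outlier metacells; the offset
   ε makes it defined at zero, and as ε → 0 it converges to the plain
   geometric mean on positive data. We normalize **cells before
   averaging** (not the averaged profile), since cell size is a per-cell
   quantity; ε defaults to the FC pseudocount so the two regularizers
   share one scale.
3. **Regularized fold change.** FC(o, t) = (μ(o,t) + p)/(median over
   types of μ(o,·) + p) with pseudocount p = 0.05. The median baseline
   makes FC a *cell-type-specificity* measure rather than an abundance
   measure, which is what makes profiles comparable across species with
   different baseline expression; p bounds the FC of weakly expressed
   OGs (an OG at zero everywhere gets FC ≡ 1). The median over an even
   number of types uses the standard midpoint convention.

Activity calls (`binarize_activity()`) mark an OG active when FC
strictly exceeds 1.1 in **any** focal cell type. Both the FC threshold
and the activity rule use strict `>`: 1.1 exactly is inactive.

## KLD similarity and link retention

For each species pair the FC matrices are row-aligned on shared OGs
(`joint_profiles()`), each cell type's FC vector is normalized to a
probability distribution (well-defined because the pseudocount keeps
all entries positive — the package never needs, and does not define, a
zero-handling convention for the divergence), and cell-type pairs are
scored by Kullback–Leibler divergence in nats. Because links between
cell types are undirected, the default is the symmetrized mean of the
two directed divergences; `symmetric = FALSE` gives the directed
variant.

Divergences are inverted to similarities by per-species-pair min–max
scaling, similarity = 1 − KLD/max(KLD). The specific decreasing
inversion is presentational only: the retained link set after
percentile thresholding is provably invariant to any strictly
decreasing transform, and the test suite asserts this invariance
against −KLD, exp(−KLD) and 1/(1+KLD). Thresholding keeps links at or
above the empirical 88th percentile (linear interpolation between
order statistics; ties at the cutoff retained), i.e. the top 12 % most
similar connections. The percentile is computed **within each species
pair** by default, since divergence scales are pair-specific (they
depend on the shared OG set and the two species' FC dispersions);
`global = TRUE` pools all pairs for the other reading.

## Shared markers and intersections

For a linked cell-type pair, a shared orthologous marker is an OG with
FC > 1.1 in the linked type in *both* species and a
Benjamini–Hochberg-adjusted two-sided Wilcoxon rank-sum p-value < 0.05
in *both* species, the test comparing the OG's per-metacell expression
in the focal (ingroup) type against all other metacells. Two
statistical notes:

* The rank-sum (Mann–Whitney) form is used because ingroup and outgroup
  cells have no natural one-to-one pairing, so a signed-rank (paired)
  statistic is undefined in this design. The implementation uses the
  exact null distribution when n·m ≤ 400 and the data are tie-free, and
  the tie-corrected normal approximation with continuity correction
  otherwise; fully tied data return p = 1.
* BH correction is applied within species across all tested OGs at
  FDR 0.05. Thousands of OGs are tested per species, so an uncorrected
  per-OG test would flood the marker sets with false positives.

Marker sets are intersected across species with exact UpSet semantics
(`marker_intersections()`): every OG is counted in exactly the
combination of species sets containing it, so combination sizes sum to
the union size, and the core set is the all-species intersection.
`conserved_deg_orthogroups()` applies the same OG mapping to externally
supplied per-species DEG lists (DEG calling itself is out of scope —
lists are inputs) and keeps OGs with at least one DEG in at least
`min_species` species; a gene counts as a DEG for a species if it
appears in that species' list for any cell type, matching the
any-subcluster reading used for activity calls.

## Parsimony trait evolution

Binary activity vectors over species form a species × OG matrix placed
on a rooted, dated tree (branch lengths in Myr). Ancestral states are
reconstructed by unit-cost maximum parsimony: the bottom-up pass is
Fitch's algorithm, implemented as unit-cost Sankoff so multifurcations
are handled exactly; gains (0→1) and losses (1→0) are weighted equally,
as is standard for presence/absence characters without a model of
asymmetric turnover. Ambiguity is resolved top-down: each node inherits
its parent's state when that state attains the node's minimal cost,
else takes its unique minimal-cost state — an ACCTRAN-style rule that
provably attains the parsimony score (the suite recounts transitions of
every resolved assignment against the Fitch score on 1,000+ random
instances, and cross-checks scores against `phangorn::parsimony` and an
exhaustive enumeration oracle). A root tie (both states optimal) is
broken toward 1 = active and logged, so the bias toward ancestral
presence exists only at exact ties and is auditable. Per edge, gains
and losses are summed over OGs and divided by branch length to give
changes/Myr; zero-length branches yield `NA` with a warning. We use
discrete resolved states rather than marginal state frequencies;
fractional reconstructions would require an extra thresholding
convention before transitions could be counted, and the discrete rule
keeps the per-edge bookkeeping exact (gains + losses over the tree
equal the summed parsimony scores, an identity the tests assert).

One structural caveat, which shaped the validation design: with a
**binary** root, a trait whose single change lies on a root-adjacent
edge has exactly tied root states — no parsimony method can orient that
change — whereas with a basal polytomy (≥ 3 root children) a single
change is always root-identifiable. The recovery studies therefore use
a 9-tip dated tree with a trifurcating root, a realistic shape for
broad metazoan species trees whose deepest split is unresolved. On
binary-root trees users should expect root calls for root-edge changes
to default to "active".

## The synthetic panel: what it emulates, and what it does not

`simulate_panel()` generates, per species: OG-level baseline means
drawn once from a log-normal (shared across species — conserved
baseline expression), expanded into 1 + Poisson(`paralog_rate`) genes
per OG whose expected expression splits the OG total by a symmetric
Dirichlet (so ortho-gene aggregation recovers the OG signal in
expectation — this is the property that makes the generator a fair test
of the aggregation stage), negative-binomial counts
(`nb_dispersion = 2`) with log-normal per-cell size factors
(`depth_variation = 0.3`), and planted structure:

* a conserved module (20 OGs) up-regulated `planted_fold`-fold
  (default 4) in each species' randomly designated phagocyte-like type;
* one lineage-specific identity module per remaining cell type, same
  size and fold, drawn independently per species. Real cell types each
  express a distinct marker program; without such programs all
  non-focal types would share near-uniform FC profiles and would
  pairwise beat the planted pair on divergence, so distinct identity
  programs are a structural requirement of the comparison problem, not
  a convenience;
* a binary trait history on the species tree: Bernoulli(0.5) root
  states, per-edge flip probability `trait_change_prob` (default 0.05).

Defaults are 3 species × 4 cell types × 200 cells per type × 300 OGs —
small enough that the full suite runs in well under a minute per
replicate on one CPU, large enough that rank-sum tests and percentile
thresholds behave asymptotically. The generator is fully reproducible
from one seed and emits plain-text fixtures with a checksum manifest
(`write_fixture_set()`).

What passing on these panels shows: the pipeline's stages compose
correctly, planted homologies are recovered as top links, planted
conserved modules survive the marker/intersection stack, and planted
histories are reconstructed within parsimony's identifiability limits.
What it does **not** show: robustness to features the generator omits —
ambient RNA and doublets, batch effects, cell-type proportion
imbalance, annotation errors, incomplete orthology tables, expression
divergence *within* conserved modules, and gene-tree/species-tree
discordance. Results on real data depend on upstream QC, clustering and
orthology quality, which this package treats as given inputs.

## Parameter summary

| Parameter | Default | Units | Role |
|---|---|---|---|
| `pseudocount` (p) | 0.05 | expression units | FC regularization; also the geometric-mean offset ε |
| `fc_threshold` | 1.1 | dimensionless | strict FC cutoff for markers and activity |
| `percentile` | 88 | percent | per-species-pair similarity cutoff (top 12 % kept) |
| `metacell_size` | 10 | cells | same-type cells summed per metacell |
| `fdr` | 0.05 | — | BH false-discovery-rate for marker tests |
| `planted_fold` | 4 | fold | simulator effect size |
| `trait_change_prob` | 0.05 | per branch | simulator trait flip rate |

All pipeline randomness (metacell shuffling, simulation) flows from the
single `seed` in the configuration objects; two runs with identical
configuration and seed write byte-identical outputs.

## Known limitations

* Summation over paralogs discards within-OG expression divergence; an
  OG whose paralogs subfunctionalized across cell types appears as a
  blended profile.
* KLD is computed on FC-derived distributions over OGs, so it weights
  cell-type-specific OGs heavily; two cell types that differ only in a
  few high-FC programs can look more divergent than biologically
  sensible.
* Parsimony reconstruction ignores branch lengths when inferring
  states (lengths enter only the rate normalization) and cannot orient
  single changes on root-adjacent edges of binary-root trees.
* The percentile threshold guarantees that some links are retained in
  every species pair, including pairs with no genuinely homologous
  types; retained links are candidates for inspection, not homology
  calls.
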