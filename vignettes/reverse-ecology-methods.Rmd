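---
title: "Methods: scope expansion, complementation, overlap and dependency in symbiont communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scope expansion, complementation, overlap and dependency in symbiont communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symbionet)
```

## The system being modelled

Bacteriocytes of sap-feeding insects house an obligate, genome-reduced
symbiont together with varying combinations of facultative symbionts. All
of them draw on nutrients the host secretes into the bacteriocyte. symbionet
treats that cell as **one well-mixed metabolite pool**: the host appears
only as the set of metabolites it provides ("source metabolites"), never as
a reaction network of its own, and metabolites flow freely among all
co-resident bacteria. Each bacterium is reduced to its enzyme content — the
set of EC numbers annotated on its genome — mapped against a local reaction
catalogue into a directed reaction network.

Three modelling assumptions shape everything downstream:

1. **Free flux**: any compound one genome can make is available to every
   other genome and to derived environments.
2. **Qualitative reachability**: a compound is producible or it is not.
   There is no stoichiometry, no flux, no quantity, and therefore no notion
   of a resource being limiting *in amount* — only in *presence*.
3. **Annotation-driven networks**: one EC may map to many catalogue
   reactions and all of them are included; the model inherits both the
   catalogue's and the annotation pipeline's blind spots.

## Network expansion (scope)

`expand_scope(seeds, network)` computes the least fixed point of "if all
substrates of a reaction are present, add its products". Reversible
catalogue records are split into two directed reactions at load time, so
feasibility is purely substrate availability. The fixed point is unique and
independent of the order in which reactions are examined; the
implementation maintains per-reaction unmet-substrate counters and a
worklist, so each reaction fires at most once (near-linear in network
size), but the *contract* is the order-free fixed point and the test suite
holds it to a deliberately naive loop-until-no-change oracle under random
reaction orderings.

Two consequences worth noting:

- A reaction that produces one of its own substrates simply never fires
  unless something else supplies that substrate first; autocatalysis needs
  no special casing under fixed-point semantics.
- Currency cofactors (ATP, NAD+, ...) are **not** auto-seeded. They enter
  the simulation only if the environment file lists them. This is
  deliberate: the dependency scans below specifically probe what happens
  when ATP or NAD+ is withdrawn, which auto-seeding would make impossible.

Growth capacity in an environment is proxied by `assess_growth()`: the
count of a fixed essential-metabolite panel (amino acids, nucleotides,
cofactors) found in the scope.

## Environments

The host-only environment is a flat list of compound ids. The enriched
environment is derived, not curated: `derive_host_obligate_env()` expands
the obligate symbiont's network in the host-only environment and takes the
*entire resulting scope* as the new source set. Taking the whole scope
rather than "only the new compounds" is an equivalent set (seeds are part
of their own scope) and removes any ambiguity. Environment names propagate
into every downstream result object so host-only and enriched outputs
cannot be silently mixed.

The packaged 49-compound host-only environment
(`bacteriocyte_sources_synthetic.txt`) is a synthetic reconstruction
assembled from the tiers described for the whitefly bacteriocyte — ATP,
cofactors and vitamins (NAD+, heme, thiamine, ...), six non-essential amino
acids, sugars, central-carbon intermediates and amino-acid precursors
(ribose-5-phosphate, erythrose-4-phosphate, phosphoenolpyruvate,
homocysteine, branched-chain 2-oxo acids). It is a faithful *shape*, not a
compound-for-compound copy of any published supplement, and analyses of
real genomes should substitute the user's own curated list.

## Complementation and masking

`complementary_metabolites(a, b, env)` implements the three-stage pairwise
model: merge the reaction sets, co-expand in the environment, subtract the
union of the members' individual scopes. `kwise_complementary()` extends
this to $k$ genomes against **all proper non-empty sub-combinations**, so a
triple is only credited with metabolites no pair (and no single) already
reaches. The default search stops at pairs (`kmax = 2` in
`run_pipeline()`), with triples available by configuration — in the
whitefly system triples add nothing, and the combinatorics grow quickly.

Masking (`masking_classify()`) compares a pair's complementary sets between
the host-only and enriched environments. Scopes are monotone in the
environment, but complementary sets are not: enriching the environment can
*remove* a complementary metabolite (one member can now make it alone —
the `host_only` label, "masked") and can in principle also create one. The
test suite pins this non-monotonicity with a constructed example: a lysine
pathway whose terminal diaminopimelate decarboxylase (EC 4.1.1.20) sits in
a different genome than the rest of the chain, plus an obligate genome with
an independent route to the M-DAP intermediate.

Profiles (`build_profile()`) are binary combination x metabolite incidence
matrices with lexicographic column order. `pca_cluster_profiles()` runs
centered, unscaled PCA — the incidence is already on a common 0/1 scale, so
variance scaling would only inflate rare metabolites — with a fixed sign
convention (the largest-magnitude loading of each component is positive),
and average-linkage hierarchical clustering on Euclidean distances. The
distance and linkage are package choices; the cluster count is user-set.
All-identical rows yield a zero-variance warning and all-zero coordinates
rather than an error.

## Seed sets and effective metabolic overlap

`seed_set()` condenses the directed compound graph (an edge
substrate→product for every reaction) into strongly connected components
and returns all compounds in **source components** — components with no
incoming edge from outside. These are the compounds the organism cannot
make from anything else it metabolizes: its topology-predicted exogenous
resources. Components of size > 1 contribute all members, unweighted; no
confidence weighting is applied, because the score below only asks whether
a seed is shared.

`competition_score(row, col, targets)` is the effective metabolic overlap
of the column species *on* the row species: expand `row` in its "optimal"
environment (its own seed set), count producible targets ($T_{opt}$);
remove the seeds shared with `col`'s seed set and recount ($T_{red}$);
report $(T_{opt}-T_{red})/T_{opt}$. The score is asymmetric by design —
the member with the smaller repertoire typically suffers more — and lies
in $[0,1]$. Two edge conventions: $T_{opt}=0$ yields 0, not NaN (a species
that produces nothing cannot be outcompeted in this metric), and the
optimal environment is the row's own seed set only, not the union with the
column's. Scores reproduce the *described* computation; they are not
guaranteed bit-compatible with any particular release of the original
network-comparison tooling, whose internal weighting is unpublished.

`dependency_scan()` leaves the generic optimal environment behind and asks
the sharper in-situ question: within the actual bacteriocyte-like
environment, which single source metabolite, when removed, costs the
organism how many targets? Removal is strictly one-at-a-time — counts are
non-negative by monotonicity, and a source the network never consumes
scores 0. Higher-order removals are out of scope by default; single
removals match the published procedure and keep the scan linear in
environment size.

## Summary statistics

`mean_cross_genus_score()` averages over all **ordered cross-genus
cells**, excluding the diagonal and same-genus cells (duplicate genome
reconstructions of one genus would otherwise contribute near-1 scores and
inflate the mean). On the packaged whitefly table this yields 0.178 → 0.18
at the table's 2-decimal display, over 38 qualifying cells.

`occurrence_association_test()` is a two-sided Welch two-sample t-test of
the ordered cross-genus scores grouped by whether the unordered pair
co-occurs in surveyed hosts. The packaged occurrence flags are
reconstructed from the published table's typographic marking; that
reconstruction does not resolve every grouping ambiguity, so the package
reports the test but treats the published statistic itself as outside
verification scope. Degenerate zero-variance groups return t = 0 (identical
means) or ±Inf (separated constants) rather than erroring.

## Synthetic data: what it does and does not show

The generators plant structure whose ground truth the pipeline must
recover *exactly*:

- `plant_split_pathway()` cuts a linear chain across genomes and returns
  the expected complementary sets both versus single members and versus
  all proper sub-combinations (pairwise recovery and the triple-only
  product beyond the last cut).
- `plant_shared_seeds()` wires each genome's targets to known shared or
  private seeds, giving a closed-form expected score
  $\min(\text{shared}, \text{targets})/\text{targets}$ for every cross
  pair.
- `make_random_universe()` samples substrate/product sets of sizes 1-3
  uniformly, with a configurable reversible fraction, as the substrate for
  oracle testing.

Generators are pure functions of their parameters and seed (the global RNG
stream is saved and restored). Passing these recovery tests demonstrates
the *algorithms* are correct; it says nothing about the fidelity of any
particular reaction catalogue or annotation pipeline on real genomes. The
published per-pair complementary counts for the whitefly system depend on
the (unstated) catalogue release behind their EC mapping, and the package
therefore treats them as packaged reference data covered qualitatively
(orderings, pair symmetry), never as quantities to recompute.

## Numerical and design choices

- **Problem sizes.** The property suites use 100 random universes of up to
  30 compounds and 40 reactions for the expansion oracle, 40 for the
  seed-set oracle, and 50 random split-pathway configurations (chains of
  length 2-9, 2-3 genomes) for complementation recovery — large enough to
  exercise cycles, reversibility and disconnected components, small enough
  that the brute-force oracles stay trivially auditable.
- **Partial ECs** (`1.1.-.-`) prefix-match the catalogue by default, since
  annotation pipelines emit them routinely and dropping them silently
  would understate capability; `strict_ec = TRUE` disables this.
- **Unmapped ECs** are logged, never fatal: genome annotations routinely
  outpace any reaction catalogue.
- **Determinism.** Column orders are lexicographic, report emission is
  byte-stable, PCA signs are pinned, and every run writes a metadata
  sidecar (inputs, md5 checksums, seed, package version).
- **Ties and degenerates.** Empty networks give empty seed sets with a
  warning (not an error); empty environments are an error; an empty merge
  list is an error; `cutree` breaks clustering ties deterministically via
  `hclust`'s ordering.

## Known limitations

- No stoichiometry or flux: common resources need not be limiting, and
  co-produced nutrients may be negligible in amount; interpretation is
  strictly "possible", not "preferred" or "quantitative".
- Single-compartment assumption: transporters and membrane topology are
  invisible.
- The k-wise search is exponential in the combination size; it is intended
  for the handful of co-resident symbionts it was designed around, not for
  large consortia.
- Seed sets are purely topological; a compound both consumed and produced
  inside a cycle with any external production route is never a seed, even
  if the real organism imports it.
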