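---
title: "Optimizing multi-method survey protocols: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimizing multi-method survey protocols: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divopt)
```

## The problem

Ecological communities are sampled with method portfolios: no single method
sees all species, and methods differ enormously in price. `divopt` treats
protocol design as an optimization problem on reference data: given a
multi-method, multi-site inventory intensive enough to be treated as (nearly)
complete, find how many samples of each method a standard protocol should
take so that, at any affordable cost, it either captures the most
α-diversity (inventorying) or distorts β-diversity the least (monitoring).

A deliberate modelling choice makes the three diversity dimensions
commensurable: **everything is branch length on a tree**. Species richness is
branch length on a unit star tree; phylogenetic diversity is branch length on
a phylogeny (or on an ultrametric Linnaean surrogate when no molecular tree
exists); functional diversity is branch length on a neighbor-joining tree
over Gower trait distances. One optimizer therefore serves TD, PD and FD.

## α-diversity and its estimator

`alpha_div(comm, t)` sums the branches of the minimal subtree connecting the
root and all present tips, *including* the root path. Including the root path
is what makes the star-tree equivalence exact (a k-species community on a
unit star tree has α = k) and keeps single-species communities at positive
PD. Communities are incidences: abundances in the sample matrix are collapsed
to presence/absence before any diversity computation, because the
branch-length framework is a richness framework; abundance-weighted variants
are out of scope.

"True" site diversity is the α of all samples pooled — the package does not
estimate asymptotic richness. If a nonparametric estimate is preferred, the
natural injection point is to append pseudo-samples or to rescale the
reported proportions; the optimizers only ever use ratios
`α(sampled)/α(true)`, so any site-specific rescaling cancels out of the
ranking within a site and reweights sites in the average.

Degenerate case: a site whose pooled α is 0 (no species ever observed)
contributes a proportion of 1 — an empty inventory of an empty site is
complete. This can only arise in artificial data.

## β-diversity partition

For two communities with shared spanning branch length A and unique lengths
B and C:

* β_total = (B+C)/(A+B+C) — on a unit star tree this is Jaccard
  dissimilarity;
* β_repl = 2·min(B,C)/(A+B+C) — turnover attributable to replacement;
* β_rich = |B−C|/(A+B+C) — turnover attributable to net gain/loss.

The identity β_total = β_repl + β_rich holds algebraically; the test suite
verifies it to 1e-12 over thousands of random pairs. When both communities
are empty (A+B+C = 0) all three values are defined as 0.

Monitoring bias of an allocation is the expected mean absolute difference
between subsampled and true values, averaged over the three measures and all
site pairs; efficiency is 1 − bias. Averaging (rather than summing) the
three components was chosen so that efficiency stays in [0, 1] and is
directly comparable with the α proportion axis; with a sum the scale would
depend on the number of measures aggregated. The same allocation is applied
at every site, as a field protocol would be.

## Trees

* `star_tree()` builds the TD tree; branch length defaults to 1 (unit
  length), and only the relative scale matters since only ratios of branch
  lengths are used downstream.
* `linnaean_tree()` builds the PD surrogate: one internal node per distinct
  taxon per rank, every root-to-tip path of length `depth` (default 1), and
  equal rank steps `depth/r` (r = rank columns above species). Equal steps
  are the convention for hierarchy surrogates absent any calibration. If the
  coarsest rank holds several taxa they attach to the root by zero-length
  branches to preserve tip depth; supplying a constant top rank avoids this
  and is recommended.
* `neighbor_joining()` delegates the Saitou–Nei agglomeration to `ape::nj`
  (with a closed-form two-taxon case), then clamps negative branch-length
  estimates to zero with a warning — downstream diversity requires
  non-negative lengths, and clamping perturbs path lengths the least — and
  roots the result at its midpoint. Rooting is needed because α includes a
  root path; midpoint rooting is deterministic and independent of label
  order. Any rooting choice slightly shifts PD/FD values of proper subsets
  of species (it moves which branches lie on the root path); since all
  optimizer scores are within-tree ratios against the same rooting, the
  protocol rankings are far less sensitive than raw values, but users
  comparing absolute FD across studies should fix a rooting convention.

## Functional distances

`gower_distance()` implements weighted Gower dissimilarity via
`cluster::daisy`: numeric traits are range-scaled by the observed min/max of
the full table (stable under subsetting pairs), binary/categorical traits
contribute 0/1 mismatches, missing values trigger pairwise trait deletion
with weight renormalization — the conventional treatment for patchy
bibliographic trait compilations. The package errors, rather than guessing,
when a species pair shares no comparable trait. Weights are user input; a
common convention is to weight each column of an n-column block of related
binary traits as 1/n so that the block jointly counts as one trait, and to
regress size-correlated morphological variables on a size measure first
(`residualize()`, ordinary least squares) so that shape differences rather
than size drive the distances.

## The optimizers

**Exhaustive** (`optim_alpha`/`optim_beta`, `mode = "exhaustive"`):
enumerates every allocation n with pool ≤ n ≤ availability (availability of
a method = the minimum across sites, since the protocol must be executable
everywhere), computes each allocation's score, groups by cost, and reports
the best allocation per cost level. Ties are broken toward lexicographically
smallest counts, for determinism. The enumeration is capped (default 10^6
combinations) and errors past the cap, pointing to the nested mode.

**Nested** (`mode = "nested"`): greedy accumulation. At each step the
candidate additions are one extra sample of each method; the method with the
highest expected score gain per cost unit is appended (a method's first
sample carries its fixed cost in the denominator). The output is the full
accumulation sequence — a protocol family in which any prefix is itself a
protocol, which is what field teams with uncertain future budgets need.
Greedy sequences are provably never better than the per-cost exhaustive
optimum; the tests check this dominance on small instances.

**Scoring** uses Monte-Carlo subsampling: uniform draws without replacement
within each (site, method) pool, independent across sites and runs, with
`runs = 1000` by default — enough that the standard error of a proportion is
a few tenths of a percent. When the number of distinct subsets implied by an
allocation is at most `exact_threshold` (default 1000; per site for α,
jointly across sites for β) the expectation is computed exactly by
enumeration instead, which removes Monte-Carlo noise from small instances
entirely and is what makes accumulation-curve monotonicity exact in the test
fixtures.

**Reproducibility**: a single master seed; each candidate allocation draws
from a substream whose seed deterministically folds the allocation's counts
into the master seed. Adding or removing candidate allocations (changing the
budget, constraining a pool) therefore never changes any other allocation's
score — results are stable under search-space edits, and identical seeds
give bit-identical results.

**Constrained starts**: the `pool` argument forces every candidate to
contain a predefined allocation — the tool for extending an existing
protocol while guaranteeing backward comparability. All-or-nothing method
choices (e.g. "acoustic recorders at every site or none") are expressed by
setting availability to one pooled sample per (site, method).

## The survey simulator

`simulate_survey()` generates the structure that makes the optimization
non-trivial, with all parameters fixed at realistic defaults chosen once: 40
species on a Yule tree, 4 sites, 3 methods, 8 samples per (site, method),
lognormal abundances (meanlog 2, sdlog 1 — a typical steep rank-abundance
curve), compositional turnover 0.25 (a quarter of species are single-site
exclusives), and method-biased detection (each species has one primary
method at detection 0.8, 0.1 elsewhere) mirroring the strong method
complementarity of real portfolios (e.g. mist-nets vs acoustic recorders
each seeing different bat families). Detection is Bernoulli per (sample,
species); a detected species is recorded with a zero-truncated Poisson count
of its lognormal abundance, so presence frequencies converge exactly to the
configured detection probabilities. Traits are two Brownian numeric traits
plus one binary and one categorical; taxonomy groups neighbouring tips into
genera of ~3 and families of ~9 species.

What the simulator does **not** emulate: spatial autocorrelation, seasonal
phenology, observer fatigue, abundance-dependent detectability, and
imperfect species identification. Tests passing on simulated data therefore
demonstrate the correctness of the optimization machinery under known
structure, not the field performance of any particular protocol.

`planted_optimum_scenario()` is the analytic benchmark: two equal-cost
methods exclusively detecting complementary clades carrying 3/4 and 1/4 of
the tree length, with detection 1 so that a single sample saturates a clade.
The α-optimal allocation at any budget b ≥ 2 is then known (one sample of
each method, extras broken toward the lexicographically smallest counts:
(1, b−1)), and any optimal allocation must include the large-clade method.
The test suite requires the optimizer to recover it in ≥95 of 100 replicated
data sets.

## Problem sizes and numerical conventions

The test and acceptance fixtures use 12-species, 2-site, 2-method surveys
with 3 samples per (site, method) — small enough for full subset enumeration
(≤ 9 subsets per site and allocation), so every Monte-Carlo result can be
checked against an exact oracle; Monte-Carlo agreement is asserted within 3
standard errors at up to 10,000 runs. Other conventions: ultrametricity is
judged on the range of root-to-tip depths (default tolerance 1e-8); Newick
output carries 12 significant digits so round-trips preserve lengths to
1e-9; distance matrices must be symmetric to 1e-8 with zero diagonals;
proportions are exact rationals under enumeration, so equality tests at
1e-12 are meaningful.

## Limitations

* Incidence-based only; abundance-weighted diversity and kernel-density
  hypervolume FD are not implemented.
* A single scalar cost axis: money, time or person-hours can each play the
  role, but multi-resource constraints are not jointly optimized.
* "True" diversity is the pooled inventory; no asymptotic richness
  estimators are built in.
* The optimizer evaluates the methods present in the reference data;
  it cannot recommend a method never tried there.
* Exhaustive search is exponential in the number of methods; the nested mode
  is the practical path for rich method portfolios, at the usual greedy
  suboptimality risk.
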