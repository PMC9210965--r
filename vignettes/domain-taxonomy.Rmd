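---
title: "Classifying species by protein-domain evidence: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying species by protein-domain evidence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domtax)
```

## The problem

A genome's protein domains — the conserved, independently folding units that
Pfam catalogs — are a phenotype-proximal summary of what an organism can do.
domtax asks how far a classification built purely from domain evidence
agrees with a reference taxonomy, and which way of encoding the domain
evidence agrees best. The package chains three steps: per-species domainome
profiles, pairwise profile distances, and a minimum-spanning-tree
classification scored against the taxonomy.

## Step 1: profiles

Input is a pfam_scan-style hit table per species. Overlapping hits on one
protein are resolved greedily by descending bit score: a hit survives iff
its alignment interval shares no residue with an already-kept hit. Three
choices here were genuinely open and are fixed as follows:

- **Overlap means any shared alignment position.** No tolerance window; one
  shared residue is an overlap. This is the simplest rule that is exactly
  reproducible, and alignment (not envelope) coordinates are used because
  they are the conservative extent of the match.
- **Ties break deterministically** by lexicographically smaller accession,
  then smaller start, so the result is independent of input row order.
  Greedy-by-score is not guaranteed to maximize total bit score over the
  protein — a deliberately simple contract. The tests compare it against an
  exhaustive search for the maximal-total-score non-overlapping subset on
  small instances: the greedy tiling is always valid and maximal, never
  exceeds the optimum, and where the two differ the greedy answer *is* the
  specified behavior.
- **Clan membership is ignored**: all hits are treated uniformly, because
  the polishing rule is defined on scores and coordinates alone.

Surviving hits, ordered N-to-C, form the protein's architecture (accessions
joined with `|`; repeats preserved, so `D1|D1|D2` and `D1|D2` are distinct
keys — domain order and multiplicity both carry signal under the
organization view). Four statistical models summarize a species:
`content` and `organization` are sets (of accessions resp. architectures);
`f_content` and `f_organization` attach occurrence counts. `f_content`
counts every instance, including repeats within one protein — the frequency
models exist precisely to weight multiplicity, so discarding within-protein
repeats would blur the contrast with `content`. Models mixing content and
organization are intentionally not offered.

Assemblies can be pre-filtered by the CheckM-style score
`quality = completeness − 5 × contamination` (percent scale). Removal is
strict: only `quality < 95` is dropped, so a borderline assembly at exactly
95 stays in.

## Step 2: distances

Every distance works from the overlap triple `(a, b, c)`: the two profile
sizes and the shared part. For set models these are cardinalities; for
frequency models, multiset totals with elementwise-minimum sharing — the
canonical multiset generalization, chosen so that identical profiles always
give `c = a = b` and the Jaccard value coincides with the classical
multiset Jaccard (`1 − Σmin/Σmax`).

- **Jaccard**, `1 − c/(a+b−c)`: assumes domain changes are random and
  independent.
- **Poisson**, `sqrt((−ln c/a)(−ln c/b))`: models domain change as a
  Poisson process; each factor is a species' distance to the common
  ancestor and the geometric mean symmetrizes them.
- **Loss-corrected**, `1 − c/min(a,b)`: compares against the smaller
  domainome, so massive lineage-specific gene loss does not masquerade as
  divergence.

Two numerical choices make the implementation total on all valid triples:

- **Poisson clamp.** The raw Poisson expression diverges as `c → 0`, yet
  all three distances are documented to live in `[0, 1]`. The value is
  clamped at 1 and `c = 0` is defined as 1. Clamping respects the stated
  range while preserving the ordering of distances near the boundary;
  rescaling would have distorted every non-boundary value.
- **Empty profiles.** A species with zero surviving hits is retained, not
  dropped. Its distance is 1 to any non-empty profile and 0 to another
  empty one, with a warning. This keeps matrices total and symmetric; real
  datasets should rarely hit the rule.

The test suite verifies the `[0, 1]` range and the identity
`d(x, x) = 0` exhaustively over all integer triples with
`a, b ≤ 20`, and checks `loss_corrected ≤ jaccard` (which follows from
`min(a,b) ≤ a+b−c`) on the same grid.

## Step 3: classification and scoring

The complete distance graph is reduced to a minimum-cost spanning tree by
Prim's algorithm. MSTs are not unique under weight ties, so determinism is
imposed: growth starts at the lexicographically smallest species ID, and
frontier ties break by (weight, in-tree endpoint, new endpoint). The total
weight is tie-invariant and is cross-checked in tests against an
independent MST implementation (igraph) on random matrices up to 50
species.

Clustering tags each node with its taxon at the requested rank, keeps only
edges whose endpoints agree, and takes connected components. Same-taxon
species connected only through a different taxon's node therefore split into
separate groups — that is the disagreement signal. Consequences of this
definition: the partition is independent of any traversal order, and each
species lies in exactly one group. Species missing the rank receive unique
singleton labels so the partition still covers all nodes; dropping them
would silently change `ΣT_i`.

Per taxon *i*, `T_i` counts its species and `S_i` those outside its largest
group (ties for largest are resolved deterministically; `S_i` does not
depend on the choice). Three standards summarize agreement: the arithmetic
percentage `ΣS_i/ΣT_i`, the weighted percentage `mean(S_i/T_i)` over the
`N` taxa actually present (the reference analyses used a fixed 31-taxon
panel; dividing by the observed count generalizes that), and the number of
split taxa. `compare_combinations()` ranks all twelve model combinations on
each standard with ties sharing a rank.

## What the simulator emulates — and what it does not

`simulate_domainomes()` builds a two-level tree: clades (played by phyla)
and species as leaves. A root proteome of `root_n_proteins` proteins
(architecture lengths `1 + Poisson(root_arch_length_mean − 1)`, domains from
an alphabet of `domain_alphabet_size` synthetic accessions) evolves along
each branch with per-protein events whose probabilities are the configured
rates scaled by branch length (capped at 1): loss removes a protein,
duplication copies it, gain adds a random new architecture, and shuffle
permutes a protein's domain order (or swaps a single domain). The shuffle
event is what gives the four statistical models genuinely different
signals: it perturbs organization profiles while leaving multi-domain
content intact.

Defaults were chosen once as a realistic small study: 4 clades × 5 species,
120 root proteins, mean architecture length 2, alphabet 400, event rates
0.01–0.02 per unit branch, and branch lengths 10 (root → clade) versus 0.5
(clade → species), i.e. a 20× between/within divergence ratio that mirrors
phylum-level versus within-phylum separation. A two-level tree rather than
a general birth–death process keeps the ground-truth labels unambiguous —
exactly what the agreement metrics consume.

`write_fixture()` materializes a simulation as pfam_scan-dialect hit files
(synthetic coordinates laid left to right, deterministic bit scores), a
taxonomy TSV, and a quality table deliberately straddling the 95% threshold
(one record exactly at 95, one below). A flag injects overlapping decoy
hits with strictly lower scores, exercising overlap resolution without
changing the ground truth.

What passing the end-to-end tests shows: the pipeline recovers a clean
clade structure perfectly (all metrics zero for all 12 combinations across
10 seeds at the default 20× separation). What it does not show: behavior on
real Pfam length/score distributions, horizontal transfer, contamination,
or the weak and rank-dependent separation of real phyla — the simulator
makes no attempt at those, so real-data conclusions still need real data.

## Problem sizes and runtime choices

The test suite runs the distance-axiom grid exhaustively (9,810 triples),
the Jaccard oracle on 1,000 random profile pairs, 100 random MST instances
up to 50 species, and ten seeded end-to-end simulations at the default
4 × 5 study size; the whole suite completes in well under five minutes on a
single core. Distance matrices are stored dense — even a 2,568-species
study is only ~3.3M pairs of doubles.

## Known limitations

- Greedy overlap polishing is a contract, not an optimum; pathological
  score patterns can tile a protein suboptimally.
- The Poisson clamp discards magnitude information beyond 1; two very
  distant pairs can both saturate at 1.
- The loss-corrected distance is 0 whenever one profile contains the other,
  so it cannot separate nested domainomes of different sizes.
- Weighted percentage gives small taxa the same vote as large ones;
  singleton taxa with one isolated species contribute 0 or 1 in full.
- The simulator has no horizontal transfer, no per-domain rate
  heterogeneity, and no correlation between architecture length and event
  risk.
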