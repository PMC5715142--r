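---
title: "Methods: network pharmacology of multi-compound herbal formulas"
author: "netpharm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network pharmacology of multi-compound herbal formulas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

## The analysis in one paragraph

A multi-compound herbal formula acts on many protein targets at once.  To
relate such a formula to a disease, the package triages its compounds by
predicted pharmacokinetics, links the surviving compounds to their protein
targets, embeds those targets together with the disease's gene set in the
human protein–protein interaction (PPI) network, extracts densely connected
modules, asks which biological processes each module over-represents, and
finally intersects the drug-side and disease-side processes, attributing
each shared process to a disease-etiology category.  Every stage is an
exported function; `runPipeline()` chains them behind one YAML
configuration.

## ADME triage

Compounds enter as a table of precomputed oral bioavailability (OB, in
percent), Caco-2 permeability (a dimensionless cell-monolayer absorption
score) and drug-likeness (DL).  When DL is absent it is computed from a
molecular-descriptor vector $x$ against a reference vector $y$ (the average
molecular properties of approved drugs) with the continuous Tanimoto
coefficient

$$f(x,y) = \frac{x \cdot y}{|x|^2 + |y|^2 - x \cdot y},$$

which for non-negative vectors lies in $[0,1]$ (a Cauchy–Schwarz argument;
the package property-tests it).  Negative descriptor components are
rejected at validation because the bound only holds for non-negative
inputs.  The inclusion rule is

* OB $\geq$ 30 (inclusive),
* Caco-2 $>$ $-0.4$ (strict),
* DL $\geq$ 0.18 (inclusive),

with the boundary semantics deliberately asymmetric: that is how the
thresholds are conventionally stated, and the filter reports, for every
excluded compound, the first criterion it fails (checked in the order OB,
Caco-2, DL).  The filter is idempotent and conserves cardinality; both are
tested.

## Typed networks

`TypedNetwork` is a simple undirected graph whose nodes carry one of five
roles — `compound`, `compound_target`, `disease_target`, `shared_target`
(a compound target that is also a disease gene) or `other_protein` — and
whose edges carry an optional confidence score in $[0,1]$.  Edges are
stored canonically (`node_a < node_b`), deduplicated keeping the maximum
confidence.  Four networks are built:

1. **Disease network** — the PPI subnetwork induced on the disease gene
   list.  Genes with no within-set interaction are dropped, so a 131-gene
   list typically yields a smaller network; only the induced-interaction
   convention reproduces that attrition.
2. **Compound–target network** — bipartite; one edge per distinct
   association pair, no target–target edges (those enter at merge time from
   the PPI layer).
3. **Merged network** — exact node union, roles recomputed (shared targets
   relabelled), plus all confidence-filtered PPI edges among the merged
   protein nodes.  Incremental node/edge counts are reported against *both*
   components via `networkIncrement()`, because "how much did the disease
   side add" and "how much did the drug side add" are different questions
   and published reports are not always explicit about which one they
   answer.
4. **Expanded network** — adds every first PPI neighbor of the merged
   protein nodes plus the filtered PPI edges among the expanded set.  Added
   nodes become `other_protein` unless they match a disease gene, which
   keeps the `disease_target` role: disease genes do turn up among the
   interactome neighbors of compound targets.

PPI edges are kept when their confidence is *strictly* greater than the
cutoff (default 0.4, the conventional medium-confidence level for
STRING-style scores).

## MCODE

`mcode()` is a from-scratch implementation of molecular-complex detection
in three stages.

**Stage 1 (vertex weighting).**  For each vertex $v$, take its closed
neighborhood $N[v]$, find the highest $k$-core of the induced subgraph
(by Batagelj–Zaversnik peeling), and set
$w(v) = k_{\max} \times \text{density of that core}$, with density
$2E/(n(n-1))$.  Vertices with degree below `degree_cutoff` (default 2) get
weight 0.  On all graphs with at most 10 nodes the suite checks these
weights against an independent oracle built on `igraph::coreness()`.

**Stage 2 (complex prediction).**  Seed at the highest-weight unassigned
vertex and grow breadth-first, admitting a neighbor when its weight is at
least `seed_weight * (1 - node_score_cutoff)` (default cutoff 0.2), down to
depth `max_depth` (default 100).  Assigned vertices never join a second
complex, so complexes are node-disjoint.

**Stage 3 (post-processing).**  Complexes lacking a 2-core
(`k_core_filter`) are discarded; `haircut` (default on) keeps the 2-core of
each complex, removing singly connected members; `fluff` (default off) adds
neighbors whose closed-neighborhood density exceeds
`fluff_density_cutoff`, and can make complexes overlap.  The score of a
complex is its density times its member count; ranking is by score, ties
broken lexicographically by seed identifier.  All tie-breaking in the
implementation (seed choice, traversal order, ranking) is lexicographic, so
output is deterministic — a property the suite asserts.

Parameter defaults (degree cutoff 2, node score cutoff 0.2, K-core 2, max
depth 100, haircut on, fluff off) follow the long-standing defaults of the
algorithm's reference implementation, since network-pharmacology studies
rarely print the values they used.  Role labels play no part in
clustering; compound nodes can and do appear inside clusters.

### A structural limitation: bridge merging

The stage-2 admission rule is *relative to the seed weight only*.  In a
graph whose dense regions all have similar density — for example a planted
partition with three equally dense modules — every vertex weight sits
within ~20% of the seed weight, so the breadth-first growth walks across
any single "bridge" edge between two modules and absorbs both into one
complex.  With 3 modules of 10 nodes, within-module edge probability 0.95
and between-module probability 0.02, the expected number of bridges
between a module pair is 2 and the chance of none at all is
$0.98^{100} \approx 0.13$; most runs therefore merge at least two modules.
`recoverPlanted()` makes this measurable: the per-module best-Jaccard match
is about $1/3$ when all three modules collapse into one cluster, and the
suite's recovery experiment reports the mean over 50 seeds, which lands
near 0.5 rather than near 1.  This is a property of the algorithm, not of
the implementation: any method that admits members by a seed-relative score
threshold and grows through neighbors will behave this way when module
densities are homogeneous.  On real interactomes the effect is milder
because density is heterogeneous — bridges usually pass through low-weight
regions that fail the admission threshold.  Users who need planted-partition
style separation should lower `node_score_cutoff` (a stricter admission
band) or use a partition-based community method; we deliberately did not
alter the algorithm to paper over this.

## Over-representation analysis

For a query gene set $q$ (restricted to the annotation universe) and a term
with $K$ annotated genes in a universe of $N$, the raw p-value of an
observed overlap $k$ is the hypergeometric upper tail $P(X \geq k)$,
evaluated with `stats::phyper`; the suite verifies it against direct
enumeration over binomial coefficients for every configuration with
$N \leq 12$.  The EASE variant computes $P(X \geq k-1)$, a deliberately
conservative score popularized by the DAVID service.  The family-wise
correction is Bonferroni, $\min(1, p \cdot m)$; by default $m$ counts only
the terms actually tested for the query (overlap $k \geq 1$) — terms with
zero overlap have $p = 1$ and cannot be rejected, so excluding them from
$m$ does not break the family-wise guarantee, which the suite confirms by
a 1000-replicate null simulation.  The background defaults to the catalog
universe (all annotated genes) because no external background is available
offline; both $m$ and the universe are explicit, configurable choices.

A term is *significant* when its Bonferroni-adjusted p-value is below
`alpha` (default 0.05).  Per side of the analysis (drug networks vs the
disease network), significant terms are unioned across clusters, the two
sides intersected, and each shared term routed to its disease-etiology
category.  The packaged mapping for pregnancy-induced hypertension has four
categories (endothelial cell activation and injury; placental or
trophoblast cell ischemia; hypoxia and oxidative stress; maternal-fetal
immune tolerance disorders); it is editorial domain knowledge shipped as an
editable JSON file, not an algorithmic product.  A term may live in only
one category — duplicates are a validation error — so partition counts
conserve cardinality.  One GO term (positive regulation of angiogenesis,
GO:0045766) is attributed inconsistently in the literature between the
ischemia and immune categories; the packaged file places it under ischemia,
consistent with the 3/7 split of the ten canonical shared processes.

## What the synthetic data emulate — and what they do not

The generators produce every input with known ground truth:

* **Compound tables** with a controllable expected pass rate at the ADME
  thresholds.  Failing compounds fail exactly one criterion (chosen
  uniformly), which exercises the "first failing criterion" report.
* **A planted-partition PPI layer**: dense modules (`p_in`) on a sparse
  background (`p_out`), uniform confidences.  Defaults (30 modules of 20
  genes, `p_in` 0.9, `p_out` 0.01, confidences uniform on [0.2, 1]) give a
  ~600-gene universe whose filtered graph has a few thousand edges.
* **A bipartite compound–target layer** with independent associations;
  density 0.52 over 77 compounds and 432 targets reproduces the scale of a
  published two-herb formula network (509 nodes, ~17k edges).
* **Annotation catalogs** with planted terms.  A planted term of strength
  $s$ includes module genes with probability $\min(1, s\,q_0)$ and others
  with probability $q_0/s$ (baseline $q_0$ = `term_density`, default 0.02);
  at $s \to \infty$ the term set equals its module exactly, and at the
  default validation strength $s = 25$ the expected in-module overlap is
  10 of 20 genes, far above the null, so the power experiment tests
  correctness rather than borderline sensitivity.
* **Disease gene lists** (default 131 genes) whose overlap with compound
  targets is binomial with a controllable expectation.

Uniform confidences, independent associations and homogeneous module
densities are deliberate simplifications: they exercise the thresholds,
counting rules and detection machinery without modeling degree-heavy
interactome topology, correlated annotations, or literature-biased disease
gene lists.  Passing tests on these fixtures therefore demonstrates that
the machinery is correct under its stated model, not that any particular
biological conclusion transfers to real data.

Determinism is a contract: each generator derives one private stream from
the master seed (and restores the caller's RNG state), so a fixed seed
yields byte-identical outputs; the pipeline writes an MD5 manifest and the
suite asserts that two runs from the same configuration agree checksum for
checksum.

## Numerical and degenerate-input choices

* Hypergeometric tails go through `phyper` rather than naive factorial
  ratios, so large catalogs do not overflow.
* The Tanimoto denominator $|x|^2 + |y|^2 - x\cdot y$ is zero only when
  both vectors are zero; that is an error, not a silent `NaN`.
* Density is defined as 0 for graphs with fewer than two nodes; an empty
  cluster result is valid output, and trees yield no clusters because no
  2-core survives the core filter.
* Edge tables reject self-loops and malformed confidences at the row level
  rather than dropping rows silently.
* Problem sizes in the tests and acceptance script (a ~600-gene universe,
  a 2000-gene enrichment universe, 50-seed recovery and 200-seed power
  experiments, a 1000-replicate null) were chosen so the full suite runs in
  about a minute on one CPU while keeping Monte-Carlo standard errors a
  few percent — comfortable margins for the properties being asserted.

## Known limitations

* MCODE's bridge-merging behavior on homogeneous dense regions (above).
* The ADME stage consumes OB and Caco-2 as precomputed numbers; the models
  that produce them are out of scope, as is any structure handling.
* Identifiers are matched exactly and case-sensitively; there is no symbol
  normalization service.
* Only one annotation namespace per catalog is assumed; GO DAG
  propagation, FDR procedures and pathway analysis are out of scope.
* The cluster counts a published analysis reports depend on unrecorded
  algorithm parameters and database snapshots; they are scale references
  here, not reproduction targets.
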