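---
title: "Methods: models, rules and design choices in herbnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, rules and design choices in herbnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbnet)
```

`herbnet` implements the network-pharmacology workflow for prioritizing
protein targets of multi-compound herbal preparations. This vignette is
the package's account of the underlying models, the parameters that
matter, the synthetic study system used for verification, and the design
decisions taken where the workflow's conventions are genuinely open.

## 1. Compound screening

Two complementary ADME screens act on a compound property table.
`screen_tcmsp()` keeps records with oral bioavailability OB ≥ 30 %,
drug-likeness DL ≥ 0.18 and Caco-2 permeability ≥ −0.4; all three
boundaries are **inclusive**, following the "greater than or equal"
phrasing these thresholds are conventionally quoted with.
`screen_swissadme()` keeps records with a "High" gastrointestinal
absorption call and at least two of the five boolean drug-likeness rules
(Lipinski, Ghose, Veber, Egan, Muegge) satisfied. Compounds entering from
literature curation carry no TCMSP properties, so the pipeline routes them
through the SwissADME screen only; the two screened lists are then merged.

How missing property values should be treated is not standardized; the
package defaults to failing loudly (`missing = "error"`, naming the field
and record) with an explicit `"drop"` policy available.

`merge_compounds()` deduplicates by PubChem CID when both records carry
one, otherwise by case- and whitespace-normalized name — deposited
compound tables occasionally lack a CID, so a name fallback is required.
The first occurrence wins, and molecular weights disagreeing by more than
1 % under one key trigger a warning, since that usually indicates a name
collision rather than a duplicate.

## 2. Target sets

`collect_compound_targets()` keeps predicted targets with probability
strictly greater than 0 — the prediction tools emit long tails of
zero-probability rows that carry no evidence — while database-curated
(TCMSP-route) targets enter unconditionally. `collect_disease_targets()`
applies each source's own filter: DisGeNet score ≥ 0.3 (inclusive),
GeneCards relevance > 10 (strict), OMIM and TTD unfiltered, mirroring how
these cutoffs are quoted. Gene symbols are compared case-insensitively
after trimming; no alias or ortholog resolution is attempted, so symbols
from different vocabularies will not be unified. `intersect_targets()`
returns the common set plus Venn counts.

## 3. PPI centralities and the median rule

The interaction network is built from a confidence-scored edge list with a
**strict** cutoff (score > 0.9 by default, the usual highest-confidence
setting; 0–1000-scale scores are auto-detected and divided down). Edge
confidence is used only as a filter: all centralities are computed on the
unweighted simple graph, the default behavior of the Cytoscape centrality
tooling this mirrors, which does not state a weighting.

For a node $v$ with neighborhood $N(v)$:

* **BC** — raw (unnormalized) shortest-path betweenness over unordered
  node pairs, $\sum_{s<t} \sigma_{st}(v)/\sigma_{st}$. Only the median
  rule consumes it, and the rule is scale-invariant, so normalization is
  irrelevant.
* **CC** — closeness per connected component,
  $(n_c-1)/\sum_{u} d(v,u)$ over the $n_c$ members of $v$'s component;
  isolated nodes score 0. Defining closeness within the component keeps
  the quantity finite on disconnected graphs.
* **DC** — degree.
* **EC** — the nonnegative unit-norm principal eigenvector of the largest
  component's adjacency matrix; nodes outside the largest component score
  0, and the degenerate case of an edgeless largest component scores 0
  everywhere. Eigenvector centrality is only defined up to scale, and
  restricting it to the dominant component avoids the indeterminacy of
  block-diagonal adjacency spectra.
* **LAC** — the mean, over $w \in N(v)$, of $w$'s degree within the
  subgraph induced by $N(v)$; degree-0 nodes score 0.
* **NC** — $\sum_{w\in N(v)} \mathrm{ECC}(v,w)$ with
  $\mathrm{ECC}(v,w) = \mathrm{triangles}(v,w)/\min(\deg v - 1, \deg w - 1)$,
  defined as 0 when the denominator vanishes.

`select_key_targets()` keeps nodes at or above the median on **all six**
metrics. Medians interpolate the two middle order statistics for even
counts, which makes the "≥ median" rule deterministic; the selection is
invariant under row order and always contains any node that is
simultaneously argmax on all six metrics, but it can legitimately be
smaller than half the nodes since the six filters intersect.

BC, DC, LAC and NC are rational-exact on small graphs and the tests
compare them exactly against brute-force path/triangle enumeration; CC and
EC are compared at $10^{-9}$ against Floyd–Warshall closeness and power
iteration.

## 4. Over-representation analysis

For a background universe of $N$ genes, a term covering $K$ of them and a
study set covering $n$, the enrichment p-value of an overlap $k$ is the
upper tail $P(X \ge k)$, $X \sim \mathrm{Hypergeom}(N, K, n)$, evaluated
through the log-space stable tail of `phyper()`. Zero-overlap terms are
excluded before adjustment, so the multiplicity $m$ is the number of
*tested* terms. Adjustment is Benjamini–Hochberg — the community default
where only "p.adjust" is specified — applied **within each category**
(KEGG, BP, CC, MF) separately, because pathway and ontology-branch results
are screened and plotted separately. The background defaults to all genes
in the annotation collection and is overridable; results are filtered at
`p_adjust < alpha` (strict), sorted by adjusted p, then count, then term
id, and truncated to `top_k` per category.

Two statistical caveats are worth stating because the test suite documents
them deliberately:

* **Discreteness makes the test conservative.** The attainable null level
  $P(p < 0.05)$ of a discrete upper-tail test is strictly below 0.05 and
  depends on the term size; across the generator's term-size range
  (10–100 genes in a 500-gene background with a 50-gene study set) it
  averages about 0.034. A simulation-based check that the null
  false-positive fraction equals the nominal 0.05 therefore fails by
  construction — not because the implementation is miscalibrated but
  because no discrete hypergeometric test attains its nominal level
  pointwise. The suite carries both checks: the exact-level comparison
  (green) and the nominal-level comparison (red, retained as
  documentation of this property).
* **BH adjustment is not idempotent.** Adjusted p-values are
  $q_{(i)} = \min_{j\ge i} m\,p_{(j)}/j$; feeding the $q$ vector back into
  the same map rescales by $m/j$ again and collapses values upward
  (e.g. $(0.01, 0.02, 0.04) \mapsto (0.03, 0.03, 0.04) \mapsto
  (0.04, 0.04, 0.04)$). The adjusted values are a reporting device; only
  thresholding the *original* adjustment controls FDR.

## 5. Heterogeneous network and core selection

`build_hetero_network()` unions typed relation tables (compound–target,
disease–target, pathway–target, function–target) into one undirected
graph with duplicate edges collapsed; a node id may carry only one type.
`rank_by_degree()` ranks one type by **type-blind** degree — a compound's
rank reflects all its target links, matching how network-analysis degree
is read in practice — with lexicographic tie-breaks for determinism. The
default core size is 10 components and 10 targets. Whether function–target
edges should contribute to target degree is debatable; they are included
by default and can be excluded by omitting those relation tables.

## 6. Docking post-processing

`best_pose()` reduces pose tables to per-pair minima. `classify_affinity()`
applies the conventional cutoffs: above −5 kcal/mol no predicted binding,
at or below −5 moderate, at or below −7 strong. The boundary values are
assigned to the **stronger** class: quoted as strict inequalities they
would otherwise be unclassified, and assigning them downward is
conservative toward reporting binding. `best_complex_table()` selects each
receptor's best ligand (lexicographic tie-break) and reports the global
minimum cell. `compare_target_affinities()` offers a two-sided Wilcoxon
rank-sum comparison of one receptor's affinities against all others — one
reasonable formalization of "significantly lower affinity" statements,
provided as a labeled utility rather than a canonical choice.

## 7. MD post-processing

`summarize_series()` reports the arithmetic mean and *sample* (n−1)
standard deviation of a trajectory tail; published "±" values of this kind
are assumed to be sample standard deviations.

`assess_stability()` formalizes the visual "fluctuation below 0.2 nm"
judgement as a sliding-window rule: the equilibration time is the earliest
sample time $t$ such that every window of length `window` inside
$[t, \mathrm{end}]$ has range (max − min) below `threshold`. The defaults
are 0.2 nm and 5 ns — the window length over which trajectories are
conventionally declared settled — and both are exposed because
equilibration judgements in the literature are visual and vary.

`mmpbsa_totals()` reconstructs MM = VDW + COU, ΔH = MM + PB + SA and
ΔG = ΔH + (−TΔS). Validation mode compares supplied totals against
recomputed ones with a 0.02 kcal/mol default tolerance: published tables
are pre-rounded to 0.01, so each printed total can drift from the sum of
printed addends by about one rounding step per addend.
`residue_fraction()` reports the percentage of total ΔH carried by a
residue subset, converting kJ/mol decompositions to kcal/mol (÷4.184)
when tagged, so fractions are unit-invariant.

## 8. The synthetic study system

The generators in `sim_*()` exist so every stage can be verified against
planted ground truth without database downloads. One master seed drives
per-generator substreams (drawn up front in a fixed order), so adding a
generator never perturbs another's output and all outputs are
bit-reproducible.

Defaults mirror the scale of a typical single-herb study: 30 compound
records with 3 planted duplicates (27 unique); 665 compound targets and
593 disease targets sharing exactly 119 genes; an Erdős–Rényi graph over
the 119 shared genes with edge probability 0.06 (mean degree ≈ 7, the
sparsity of a high-confidence PPI subnetwork); 50 annotation terms with
sizes uniform in 10–100 — the standard gene-set size filter window — and
one fully planted term of size 40; a 50 ns trajectory sampled at 0.05 ns
equilibrating at 13 ns around a 0.35 nm plateau with 0.02 nm noise; energy
components drawn from the ranges seen for flavonoid–kinase complexes;
10 × 10 × 10 docking poses in −11…−4 kcal/mol.

Two generator details are deliberate:

* **Planted enrichment effect** is the fraction of a *term's* members
  drawn from the study set. At effect 1 every member is a study gene, the
  smallest p attainable at that term size, and the term contains every
  study gene whenever it is at least as large as the study set.
* **Pre-equilibration libration.** A smooth noise-free ramp cannot be
  dated by the sliding-window range rule: windows straddling the ramp's
  end see a vanishing range, so the rule would fire arbitrarily early.
  Unequilibrated systems in fact fluctuate at large amplitude, so before
  the planted equilibration time successive samples alternate by
  `pre_eq_amplitude` (default 0.3 nm, above the 0.2 nm rule threshold).
  Any window containing two pre-equilibration samples is then unstable,
  which makes the planted time identifiable to within one sampling
  interval — and the tests require exactly that.

What the generators do **not** emulate: real gene vocabularies (symbols
are `G000001`-style tokens, so no alias pitfalls are exercised), the
covariance structure of real ADME properties, hub-dominated PPI degree
distributions (unless the Barabási–Albert model is selected), GO's DAG
structure (terms are flat sets), correlated docking poses, or
autocorrelated MD noise (samples are independent Gaussians). Passing tests
demonstrate that the *rules and statistics* are implemented correctly
under controlled structure, not that any particular biological conclusion
transfers to real data.

## 9. Problem sizes and determinism

The test suite verifies centralities against brute force on 200 random
graphs of up to 8 nodes, the hypergeometric tail against complete draw
enumeration for all backgrounds up to 12, ORA null calibration over 200
seeded replicates of 50-term collections, and the end-to-end pipeline at
the default scale (119-node graph), all in a few minutes on one CPU.
`run_pipeline()` writes a manifest recording parameters and MD5 hashes of
every output; identical seeds yield byte-identical manifests, which the
suite asserts.

## 10. Known limitations

* Gene-symbol matching is purely lexical; curated alias tables must be
  applied upstream.
* The stability rule is one formalization of a visual judgement; different
  window/threshold choices move the equilibration date.
* The ORA background defaults to the annotation universe, which is
  anti-conservative if the true assay universe is larger.
* Reproducing any specific published target list requires that study's
  database snapshots; the package deliberately verifies structure, not
  database content.
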