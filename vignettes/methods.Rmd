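---
title: "Supervised clustering of formula networks: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised clustering of formula networks: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jamunet)
```

## The model

A formula corpus is a binary K × l incidence matrix: K multi-ingredient
herbal formulas over l plants, each formula carrying a (possibly empty)
set of disease-class labels out of 18 classes (16 from the NCBI disease
taxonomy plus the urinary system and mental/behavioural disorders, which
that taxonomy lacks). The working hypothesis is compositional: formulas
indicated for the same disease class draw on a shared core of plants, so
ingredient similarity carries disease information even before any label
is consulted.

The pipeline has four stages.

**1. Similarity network.** Similarity between two formulas is the
Pearson correlation of their 0/1 ingredient vectors, which for binary
data reduces to the fourfold point correlation (phi coefficient)
computed from the 2 × 2 contingency counts. All K(K−1)/2 pairs are
ranked, the top fraction becomes the edge set, and nodes are the
formulas incident to at least one retained edge. Working with a rank
cutoff rather than a fixed correlation cutoff makes the edge count — and
hence the density of the graph handed to the clusterer — directly
controllable.

**2. Overlapping dense clusters.** Clusters are grown one node at a
time under two constraints: the internal density 2E/(N(N−1)) must stay
at or above `d_in`, and the candidate's cluster property
|E_nk| / (d_k · N_k) — its edge count into the cluster, normalised by
what a density-typical member would have — must reach `cp_in`. The
density constraint keeps clusters cohesive; the periphery constraint
stops growth at natural boundaries (a candidate hanging off the cluster
by a single edge fails it long before the density does). Seeding is
coverage-driven: the highest-weight uncovered node (node weight = summed
common-neighbour counts of its incident edges) seeds the next cluster,
growth runs over the intact graph so already-covered nodes may join
again — this is what produces overlap — and the loop ends when every
node is covered.

**3. Supervised assignment.** The matching score of a cluster is the
largest number of members sharing a single disease class, divided by
cluster size — a purity statistic in (0, 1]. Clusters of at least
`min_report_size` formulas whose score strictly exceeds the matching
threshold and whose dominant class is unique are accepted; each
accepted cluster contributes its highest-frequency plant(s), predicted
to be related to its dominant disease. The stage is "supervised"
because the labels select which clusters are trusted, after clustering
has run unsupervised.

**4. Evaluation.** Predicted (plant, disease-class) pairs are mapped
through an 18-class → 9-efficacy-class table and scored against a
plant–efficacy gold standard: TPR = TP/(TP+FN) per (class, efficacy)
row, and the best row per class when a class maps to two efficacies.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `top_fraction` | 0.007 | fraction of ranked pairs kept as edges; smaller = higher-confidence, sparser network |
| `d_in` | 0.9 | minimum cluster density after every admission |
| `cp_in` | 0.5 | minimum cluster property (periphery) for admission |
| `min_cluster_size` | 3 | two-formula clusters are trivially pure and are discarded |
| `matching_threshold` | 0.6 | strict lower bound on matching score for cluster acceptance |

The defaults are the operating point of the study the package
implements: density 0.9 with cluster property 0.5 produces near-clique
modules, and 0.6 sits where the success-rate curve stops rising steeply
as the threshold drops — raising the threshold to 0.7+ prunes many
correct predictions (the shipped printed prediction list marks exactly
which rows vanish at 0.7), while lowering it below 0.6 admits mixed
clusters.

Threshold comparisons are strict (`>`), matching how thresholded counts
are reported in the reference tables; a cluster scoring exactly 0.6 is
not accepted.

## The synthetic generator

Real corpora of this kind are typically not redistributable, so the
package generates corpora with planted structure: D disease classes,
each owning `signature_size` signature plants (disjoint across classes
by default), each class contributing `formulas_per_class` formulas that
include each signature plant with probability `p_sig` (default 0.8) and
each of `n_background_plants` shared background plants with probability
`p_bg` (default 0.05). The defaults (D = 5, s = 6, B = 50, F = 30)
give a 150 × 80 corpus: large enough that the top-1% network has
non-trivial structure, small enough that the full pipeline runs in
seconds. An optional `multi_label_fraction` attaches a second class
label to a fraction of formulas (labels only), emulating
multi-indication formulas; it defaults to 0 so the planted truth stays
unambiguous.

What the generator emulates: the block-correlation structure the method
exploits (within-class pairs correlate strongly, cross-class pairs
weakly or negatively), label noise through `p_sig < 1`, and background
ingredient sharing through `p_bg > 0`. What it does not emulate: the
heavy-tailed plant-usage distribution of real corpora (every signature
plant is used at the same rate), overlapping plant repertoires between
related diseases (signatures are disjoint unless configured otherwise),
and corpus-scale class imbalance. Passing recovery tests therefore
demonstrates that the machinery is correct and that the method works
when its compositional assumption holds — not that the assumption holds
in any particular real corpus.

At `p_sig = 1, p_bg = 0` every within-class pair has correlation
exactly 1; selecting exactly the within-class pair share of the ranking
reproduces the planted class structure as components, and the pipeline
must recover every planted (plant, class) pair exactly — this is the
package's strongest end-to-end oracle. The stochastic default
(`p_sig = 0.8, p_bg = 0.05`) at top fraction 0.01 and threshold 0.6 is
the standard recovery benchmark; precision stays above 0.9 while recall
reflects the deliberate coverage/reliability trade-off of rank
thresholding.

## Numerical and procedural choices

- **Rounding.** Printed percentages and TPRs use half-away-from-zero
  rounding at two decimals (`round_half_up()`); the top-fraction pair
  count uses round-half-up, which reproduces all three published
  selection sizes (34,454 / 24,610 / 14,766 of 4,921,953). Base R's
  round-half-to-even would not.
- **Constant vectors.** A formula with no (or all) plants has zero
  variance; its correlations are reported as 0 with a warning rather
  than NaN. Such pairs can never enter the top fraction.
- **Tie-breaks.** Every ordering ends in a lexicographic node-id
  comparison: pair ranking (corr desc, then i, j), cluster seeding
  (weight desc, degree desc, id asc), candidate admission (edges-in
  desc, weight-in desc, id asc). Outputs are therefore bit-reproducible
  and independent of edge input order.
- **Dominant-class ties** void a cluster's assignment (a tie carries no
  evidence for either disease); **dominant-plant ties** return all tied
  plants (each is an equally supported candidate relation, and dropping
  arbitrarily would be lossy).
- **Degenerate inputs.** Single-node clusters have density defined as 1;
  the cluster-property criterion degenerates for a singleton and is
  replaced by simple adjacency to the seed. Edgeless graphs yield
  singleton clusters (coverage still holds). Threshold comparisons use
  a 1e-9 slack so that densities that are exactly at threshold in exact
  arithmetic are not rejected by floating-point noise.
- **Clustering-coefficient convention.** Nodes of degree < 2 contribute
  0 to the mean local clustering coefficient (rather than being
  excluded from the average); the diameter of a disconnected graph is
  the maximum over component diameters.

## Design decisions taken where the design was open

- **The overlapping clusterer** is a reconstruction: the original
  density-periphery algorithm is specified by its published properties
  (density- and periphery-constrained growth, overlap, whole-network
  coverage) rather than by pseudocode. This implementation realises
  those properties with coverage-driven seeding over the intact graph.
  Published cluster counts on the original corpus are consequently not
  expected to be reproduced number-for-number, and the tests assert the
  guaranteed properties (density ≥ `d_in`, coverage, determinism,
  subset-freeness) instead.
- **Exclusion stage.** Corpora may contain formulas annotated only to a
  symptom too unspecific to classify (fever, in the reference corpus:
  its disease entry maps to no class). Whether such formulas were
  removed before network construction or only at evaluation is not
  documented; the pipeline exposes `exclude_stage` with default
  `pre_network`, which keeps the network free of label-less nodes.
- **ER baseline** is G(n, m), not G(n, p): matched baselines are
  reported with zero variance in average degree, which forces a fixed
  edge count.
- **BA baseline** grows from a complete seed graph on
  `m_per_node + 1` nodes with `m_per_node = round(m_target/n)` edges
  per arrival; the achieved edge count exceeds `(n − m)·m` by
  `choose(m, 2)` and the residual mismatch against `m_target` is
  attached to the graph rather than silently absorbed.
- **CNN baseline.** The conversion probability u is not part of the
  published description. Since every growth step adds exactly one edge,
  the edge count when the n-th node arrives has expectation n/(1−u);
  the package solves u = 1 − n/m_target in closed form (exact, so no
  search is needed), then tops up with conversions until `m_target`
  edges, reporting pool exhaustion if the target is unreachable.
- **Baseline replicate count** behind the mean ± sd summaries defaults
  to 10 and is configurable; the reference report does not state the
  count it used.
- **Command-line interface.** The package's functions are the primary
  interface; a thin `Rscript` wrapper (`inst/cli/jamunet.R`) exposes
  `simulate`, `run` and `stats` subcommands for shell use.

## Problem sizes used by the test suite

The suite validates against brute-force oracles at sizes where brute
force is exact and fast: Pearson-equivalence on 1000 random binary pairs
(l ≤ 50), network statistics against BFS/counting oracles on random
graphs of ≤ 50 nodes, clusterer invariants on 100 random graphs of 8–30
nodes, baseline comparisons at n = 500, and end-to-end recovery on the
150-formula synthetic default. These sizes were chosen so the whole
suite stays interactive (about a minute) while every property is
exercised far from its trivial regime.

## Known limitations

- The clusterer is quadratic in memory (dense adjacency and
  common-neighbour matrices); corpora beyond ~10⁴ network nodes would
  need a sparse rewrite.
- The matching score treats disease classes as flat and independent;
  hierarchical relations between classes (and between efficacies) are
  ignored.
- A gold standard that is itself partial biases TPR downward: plants
  absent from it are counted as misses, not excluded (the reference
  report is ambiguous on this point; the package takes the conservative
  reading).
- The reconstruction gold standard shipped for testing credits a plant
  with the efficacies of every class it is printed as a Hit for; it is
  consistent with all printed Hit rows but cannot reproduce printed
  Miss rows whose class efficacies overlap a Hit class — it is a test
  fixture, not a scientific claim.
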