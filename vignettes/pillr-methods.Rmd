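---
title: "Replenishing incomplete hierarchical function labels: the model behind pillr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replenishing incomplete hierarchical function labels: the model behind pillr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pillr)
```

## The problem

Protein function annotations live in hierarchies: the MIPS Functional
Catalogue (FunCat) is a tree whose dotted identifiers encode the structure
(`01.03.02` is a child of `01.03`), and the Gene Ontology is a directed
acyclic graph. Under the *true path rule*, annotating a protein with a term
implies every ancestor term. Real annotation corpora are incomplete in a
structured way: what goes missing for a protein are its most specific
(per-protein *leaf*) labels — any missing internal label could be restored
mechanically from an annotated descendant. `pillr` addresses two tasks on
such data:

* **replenishment** — given partially labeled proteins, score every unknown
  (protein, label) entry by how likely the label is genuinely missing;
* **prediction for unlabeled proteins** — transfer labels through an
  interaction network to proteins with no annotations at all.

## Label correlation: ComSim

Let $N(s)$ be the member-protein set of label $s$ and $p(s) = |N(s)|/n$ its
membership probability; $-\log p(s)$ is the label's information content.
Lin's similarity between labels $s$ and $t$ is

$$\mathrm{LinSim}(s,t) = \frac{2\log p_{ca}(s,t)}{\log p(s) + \log p(t)},
\qquad p_{ca}(s,t) = \min_{k \in ca(s,t)} p(k),$$

with $ca(s,t)$ the common proper ancestors of $s$ and $t$. Because a label
is a better subsumer of its own descendants than any of its ancestors,
the shared-ancestor variant HSim replaces $ca(s,t)$ with
$sa(s,t) = ca(s,t) \cup \{s \text{ if } s \text{ is an ancestor of } t\}
\cup \{t \text{ if } t \text{ is an ancestor of } s\}$. HSim dominates
LinSim on ancestor–descendant pairs and equals it on siblings and cousins.

Both are blind to *flat* correlation: strongly co-annotated categories with
no shared ancestor (in yeast FunCat, CELL FATE and CELL TYPE DIFFERENTIATION
co-occur in over 60% of the smaller category's members). The combined
similarity switches to the Jaccard co-annotation coefficient exactly where
the hierarchical signal is uninformative:

$$\mathrm{ComSim}(s,t) = \begin{cases}
\mathrm{HSim}(s,t) & p_{sa}(s,t) \in (0,1)\\
\mathrm{JcdSim}(s,t) = \frac{|N(s) \cap N(t)|}{|N(s) \cup N(t)|} &
\text{otherwise.}
\end{cases}$$

The "otherwise" branch covers pairs with no shared ancestor ($p_{sa} = 0$,
e.g. different FunCat top-level categories) and pairs whose most specific
shared ancestor annotates every protein ($p_{sa} = 1$, e.g. pairs subsumed
only by the GO root). The $K \times K$ matrix of ComSim values is
row-normalized, $C_m(s,t) = \mathrm{ComSim}(s,t) / \sum_t
\mathrm{ComSim}(s,t)$, so each known label distributes one unit of
evidence across candidate labels.

Edge cases are fixed as follows, and exercised in the test suite:
self-similarity is 1 for any label with at least one member and 0 for a
memberless label; if $p(s) \in \{0, 1\}$ the information-content formula is
undefined and the similarity falls back to 0 (no evidence) — the
$p(s) = 1$ case cannot reach the HSim branch anyway because
$p_{sa} \le \min(p(s), p(t))$ forces the Jaccard branch; a Jaccard of two
empty member sets is 0; the logarithm base cancels in the ratio, so natural
logs are used. The row sum in $C_m$ includes the diagonal. Correlations are
always computed from the *training* annotation state (after masking),
never from ground truth — anything else would leak the labels the method is
asked to recover.

## Estimation and propagation

For a partially labeled protein $i$ with label vector $y_i$, the missing
labels are estimated as

$$\tilde y_{ik} = \begin{cases} 1 & y_{ik} = 1\\
y_i^\top C_m(\cdot, k) & y_{ik} = 0,\end{cases}$$

clipped to $[0,1]$ (a protein with many known labels can otherwise
accumulate more than one unit of mass). Unlabeled proteins get zero rows —
they carry nothing to propagate from, and the loss masks them out.

Interacting proteins tend to share function (guilt by association), so the
estimates are smoothed over the interaction network. With $W$ the
row-normalized weight matrix ($\sum_j W_{ij} = 1$, zero diagonal, all-zero
rows for isolated proteins) and $U$ the diagonal indicator of labeled
proteins, the scores $F$ minimize

$$\Psi(F) = \mathrm{tr}\!\left((F - \tilde Y)^\top U (F - \tilde Y)\right)
 + \lambda\, \mathrm{tr}\!\left(F^\top (I - W)^\top (I - W) F\right).$$

This is an unconstrained convex quadratic; setting the gradient
$2U(F - \tilde Y) + 2\lambda (I-W)^\top(I-W) F$ to zero gives the normal
equations $(U + \lambda M)F = U \tilde Y$ with $M = (I-W)^\top (I-W)$,
which `solve_propagation()` solves exactly by sparse Cholesky
factorization — no iterative solver or tolerance is involved at the sizes
this package targets (the factorization is comfortable to a few tens of
thousands of proteins). The relative stationarity residual is reported with
every fit and asserted below $10^{-8}$ in the tests. The system is singular
exactly when some connected network component contains no labeled protein;
this is raised as an error rather than regularized away. Predictions are
deliberately *not* post-processed with the true path rule, so that scores
of different methods remain comparable.

$\lambda > 0$ balances fidelity to the estimates against network
smoothness; the default is $\lambda = 1$, treating both sources as equally
trustworthy. Two further notation conventions: the "first $l$ proteins are
labeled" presentation is implemented as an arbitrary boolean mask (protein
order never matters), and the objective is the trace form above (an
equivalent squared-norm notation for the empirical term appears in some
formulations; the trace form is the operative one).

### Ablation variants

The package exposes the method's own ablations as first-class variants:
`pill_jcd` / `pill_hsim` / `pill_lin` swap the correlation measure;
`pill_fc` uses the estimated $\tilde Y$ directly (no network term);
`pill_gba` propagates the raw annotations (no correlation-based
estimation); `naive` scores every protein with the label-frequency vector,
the standard community baseline.

## Relationship statistics

`relationship_statistics()` quantifies why estimation from close relatives
is reliable: on a closed annotation matrix, the conditional likelihood that
a protein carries $s$ given a relative $r$ is the member-count ratio
$|N(s) \cap N(r)|/|N(r)|$. Along any child–parent–grandparent chain,
closure gives $N(par(s)) \subseteq N(gpar(s))$ and hence
$p(s \mid par(s)) \ge p(s \mid gpar(s))$ *exactly*; the corresponding
uncle inequality $p(s \mid gpar(s)) \ge p(s \mid uncle(s))$ holds in
aggregate but not label-by-label, so it is reported, not asserted. FunCat
top-level categories have no explicit common parent yet are treated as
siblings; the implementation uses a virtual root for sibling/uncle queries
only — it never enters ancestor sets, annotations, or similarity values. In
the DAG case all of par/gpar/uncle are sets and one row is emitted per
(label, relative) pair; a label without a grandparent simply has no such
rows. Zero-valued likelihoods are dropped from distribution summaries
(they encode absent relationships, not small ones).

## The synthetic-data generator

No public corpus exercises incomplete-annotation recovery directly, so the
package ships a generator whose defaults emulate a small curated
interactome (the regime of the yeast co-complex networks on which methods
of this family are benchmarked):

* **Hierarchy** (`generate_hierarchy()`): a rooted tree with per-node child
  counts drawn uniformly; the per-level maxima default to `c(12, 4, 3)` at
  depth 4, giving a *wide top level* of categories with narrower
  specialization below, as in FunCat. `simulate_dataset()` redraws the
  hierarchy sub-seed until the label count lands in 45–80 (about 60
  labels), since uniform child counts are heavy-tailed and a 6-label tree
  is not the same study object as a 60-label one.
* **Annotations** (`generate_annotations()`): each protein receives up to 9
  root-to-node walks (continue probability 0.75 per level), closed under
  the true path rule; the per-protein label count averages about 6, with
  spread, matching curated FunCat corpora (6.5–8 labels/protein). The root
  label is dropped from the matrix: FunCat has no annotated root, and
  keeping one makes every protein pair share an ancestor, which abolishes
  the "no shared ancestor" regime the Jaccard branch exists for. Two
  correlation mechanisms make label sets realistic rather than
  independent: top-level categories are paired, and later walks enter the
  partner category of the protein's first category with probability 0.83,
  *mirroring* its child indices — this produces strongly co-annotated
  label pairs with no shared ancestor, the flat correlation structure
  (CELL FATE / CELL TYPE DIFFERENTIATION style) that motivates ComSim; an
  optional `coherence` parameter (default 0) lets walks instead deepen
  already-annotated branches. With independent uniform walks (both
  mechanisms off), label sets decorrelate, background label-set Jaccard
  between proteins rises toward 0.25, and no similarity measure — flat or
  hierarchical — carries usable signal; no real corpus looks like that.
* **Network** (`generate_network()`): `n_edges` (default 2500, average
  degree ~17) pairs sampled with probability proportional to
  `homophily * Jaccard(label sets) + (1 - homophily) * mean Jaccard`, the
  sampled score becoming the edge weight. The uniform component is scaled
  to the mean Jaccard so the homophily dial mixes two comparable
  distributions; at `homophily = 1` label-disjoint pairs can never be
  joined, at `homophily = 0` edges are label-blind.
* **Masking** (`mask_leaf_labels()`): per protein, `m` removals drawn
  uniformly from the *current* leaf set, which is recomputed after every
  single removal (strictest reading of the dynamic-leaf rule: a label whose
  annotated descendants have all been masked becomes maskable itself). At
  least one label — of any depth — is always retained. Masking repeated
  across runs resamples independently, seeded per run.

What the generator does **not** emulate: false-positive interactions with
structured noise, realistic degree distributions (cliques of co-complex
networks), evidence-code reliability, and obsolete-term churn. Passing the
recovery tests therefore demonstrates correctness of the machinery and the
expected *qualitative* ordering of the variants under homophilous,
correlated data — not a performance claim about any particular organism's
interactome.

## Evaluation

Metrics are computed on an explicit evaluation *scope* (a protein × label
mask): for replenishment, the unknown entries of labeled proteins (masked
entries are the positives, the remaining unknowns the negatives; known
entries are excluded since the estimator fixes them to 1); for the
unlabeled-protein task, every entry of the test proteins.

* **AvgROC** — mean per-label AUC (rank-based, ties at half credit) over
  labels with both classes in scope.
* **1-RankLoss** — one minus the mean per-protein fraction of discordant
  (positive, negative) label pairs.
* **Fmax** — protein-centric maximum F-measure over the threshold grid
  0, 0.01, …, 1: precision averaged over proteins with at least one call,
  recall over all proteins with at least one in-scope positive. The grid
  matches an exhaustive scan over observed score values on small instances
  (asserted in tests).
* **MicroF1 / MacroF1** — need binary calls. The exact binarization rule
  used in the reference experiments is not recoverable, so the default is
  the oracle-r convention common in the weak-label literature (each
  protein's top-r in-scope scores are called positive, r = its true
  positive count in scope), with a fixed-threshold mode (`threshold =`)
  as the alternative. Labels with a single class in scope are dropped from
  label-centric metrics, proteins likewise from protein-centric ones; the
  counts of both are returned.

`run_replenish_experiment()` masks with a fresh seed per repeat, recomputes
correlations from the masked state, fits each variant, and reports mean ±
sample (n−1) standard deviation per (variant, m, metric).
`run_unlabeled_experiment()` splits proteins 70/30, hides the test side
completely, masks the training side at `m = 3`, and evaluates on the test
side only. On that task the correlation-only variant `pill_fc` collapses to
chance on test proteins (they have no labels to correlate from) — the
observation that justifies the network term.

## Problem sizes and reproducibility

The shipped tests and the acceptance script use 300-protein datasets with
about 60 labels, 10 dataset seeds × 5 masking repeats for the recovery
benchmark, 20 random instances for the solver oracle, and hierarchies up to
12 labels for the brute-force similarity oracle — sizes at which every
check runs in seconds while exercising all code paths; the machinery is the
same at corpus scale. All randomness flows through explicit integer seeds:
a dataset, masking, or benchmark table is bit-reproducible from its seed,
and fixture directories carry a JSON manifest of the generating parameters.

## Known limitations

* GO input uses `is_a` edges only; `part_of` and other relations are
  ignored, and cross-ontology reasoning is out of scope.
* The quadratic objective is solved for all labels jointly by one
  factorization; with hundreds of thousands of proteins a per-column
  iterative solver would be preferable.
* ComSim inherits Jaccard's sensitivity to sparsely annotated labels in its
  flat branch; other semantic-similarity families (Resnik, Wang, simGIC)
  are not implemented.
* Scores are not true-path-consistent by construction (no hierarchical
  post-processing), which is intentional for method comparison but means a
  downstream consumer wanting consistent calls should apply their own
  reconciliation.
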