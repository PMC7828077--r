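---
title: "Propagating fold changes through a knowledge graph: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Propagating fold changes through a knowledge graph: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Differential-expression experiments end in a gene list, but the questions
biologists ask are about higher-order concepts: symptoms, anatomical
systems, biological processes, pathways. `walkrank` connects the two by
propagating per-gene fold changes through a typed heterogeneous
biomedical knowledge graph — a network whose ~12 node types (Gene,
Protein, Disease, Symptom, Anatomy, ...) and typed edges encode curated
biomedical relations. The question it answers: *which graph concepts
become systematically more (or less) important in one experimental group
of comparisons than another* — for instance in spaceflight versus
ground-control contrasts of rodent transcriptomes — and *which input
genes drive each of those shifts, along which relational paths*.

# The model

## Gene-restart random walks

For each human Gene node $g$ the package computes the stationary
distribution of a random walk with restart (topic-specific PageRank):

$$p \leftarrow \alpha\, e_g + (1-\alpha)\, W^\top p ,$$

where $W$ is the row-stochastic transition matrix of the graph (uniform
over a node's distinct neighbours, edges traversed in both directions)
and $e_g$ the restart distribution concentrated on $g$. The fixed point
assigns every graph node a visit probability — its relevance to $g$. One
such propagation profile per gene, stacked, gives a genes × nodes
matrix. The jump probability defaults to $\alpha = 0.1$: the walker
diffuses widely (long-range, multi-hop relevance) but is pulled back to
the gene often enough that profiles stay gene-specific.

The solver is plain power iteration (the fixed point is a contraction
with rate $1-\alpha$), converged when the L1 change between iterates
falls below `tol = 1e-10`, with failure after `max_iter = 1000` rounds.
Any transition mass on dangling (neighbourless) nodes is redirected to
the restart distribution so probability is conserved exactly.
`rwr_profile_exact()` solves $(I - (1-\alpha)W^\top)\,p = \alpha e$ by a
dense linear solve; it is exact up to floating point and serves as the
independent oracle for the iterative solver in the test suite (the two
agree to better than $10^{-8}$ in $L_\infty$ on graphs up to a few
hundred nodes).

Two numerical conventions worth noting. Node order is lexicographic in
`node_id`, so vector positions are reproducible across platforms.
Parallel edges between the same node pair are collapsed to one adjacency
for the walk — a pair related in three ways should not receive three
times the transition mass — while the edge types themselves are kept for
path reporting.

## From fold changes to node ranks

Mouse fold-change tables are mapped onto the graph's human Gene nodes
via a homolog table; when several mouse genes map to one human gene the
fold changes are averaged (and the accompanying p-values combined by
their minimum — "any contributing homolog significant"). Within each
study, genes whose fold changes point in opposite directions across the
study's spaceflight comparisons (for example two flight time points)
are dropped: the analysis concerns genes that respond consistently
during spaceflight. By default the Ground-vs-Baseline comparisons are
not examined by this filter (`scope = "space"`); they do not measure a
spaceflight response, and including them (`scope = "all"`) makes the
filter select ground-control noise by sign, which we found distorts the
downstream group contrast. Exact zeros are treated as sign-agnostic.

The propagation profiles of the study's surviving genes are then
normalised in two steps:

1. **z-score per node (column) across the study's genes.** Raw visit
   probabilities carry strong global structure — hubs score high from
   every gene. Column z-scoring asks instead: is this node *more*
   relevant to this gene than to the other genes of the study? Constant
   columns get z = 0. (The alternative `zscore_axis = "gene"`, i.e.
   within-profile standardisation, is available; because ranking is
   monotone within a profile it amounts to ranking the raw profile and
   retains the global-prominence ordering.)
2. **rank within each gene's profile**, most relevant node = $N$ (the
   node count), least = 1, ties averaged. Average ties keep every row
   summing to exactly $N(N+1)/2$ and make results independent of row
   order.

Each comparison is then embedded as one vector over all nodes: the
fold-change-weighted sum of the normalised profiles (equivalently the
dot product of the comparisons × genes FC matrix with the genes × nodes
rank matrix; missing fold changes contribute zero), re-ranked to
$1..N$. Because only the ordering of aggregates matters, the embedding
is invariant under any positive rescaling of the fold changes.

## Group comparison and top nodes

Embedded rank rows from all studies are pooled and split by comparison
label into three groups — Ground vs. Baseline, Space vs. Baseline,
Space vs. Ground. For every node, Welch's unequal-variance t-test
compares its rank sample in each spaceflight group against the
ground-control group (positive t = more important in spaceflight; the
test is two-sided, with direction recovered from the sign of t). Nodes
with zero rank variance in both samples of a contrast are excluded with
a warning rather than assigned p = 1. A "top" node must (i) pass a raw
prescreen p < 0.025 in either spaceflight contrast and (ii) be among the
`ceiling(0.025 × type count)` smallest p-values of its node type in at
least one contrast (ties broken by node id). The ceiling — rather than
floor — keeps at least one candidate per type on small graphs. No
multiple-testing correction is applied; the thresholds act on raw
p-values by design, and users should treat the output as a ranked
shortlist, not as FWER-controlled discoveries.

For display, `adjust_ranks_by_baseline_mean()` centres every node on its
ground-control mean rank (the violin-plot convention); the Welch test is
invariant to this shift, which the tests verify to $10^{-12}$.

## Retracing driver genes and paths

A gene whose fold change correlates with a top node's rank across the
pooled comparisons (Pearson by default; Spearman available) is a
candidate driver of that node. Genes must be present in strictly more
than 20% of the pooled comparisons; correlations with fewer than three
paired observations or degenerate variance are marked unavailable.
Pairs are kept when r > 0.6 *and* the gene's mean fold change agrees in
sign with the node's Welch t. Two conventions here were genuinely open:

* **Which Welch t?** Each node carries one t per contrast; the package
  uses the t of the contrast with the smaller p — the contrast that
  made the node significant.
* **Sign concordance** accepts both +/+ and −/− pairs by default
  (`sign_filter = "concordant"`); restriction to positive pairs only is
  available (`"positive_only"`).

For every kept pair, all simple paths of at most 3 edges between gene
and node are enumerated (undirected traversal; parallel edge types
reported joined by `&`). Pairs with 100 or more such paths are flagged
as overflow and excluded — they are not usefully visualisable. Reported
paths are ordered deterministically by (length, |mean fold change| of
the driver descending, lexicographic node sequence), replacing manual
curation with a reproducible rule. The correlation is computed over the
mapped *and* direction-filtered tables — the genes that actually entered
the embedding — and a gene filtered out of a study counts as absent from
that study's comparisons.

Finally, `score_gene_fc()` places every gene on two axes: **x**, the
Welch t of its fold changes in each spaceflight group against the
ground group, computed per group and averaged (a single available
contrast stands alone); **y**, the advantage of its Stouffer-combined
p-value over the pooled spaceflight groups relative to the combined
ground group, reported as $\log_{10} p_{\text{ground}} - \log_{10}
p_{\text{space}}$ together with both combined values and a boolean. The
exact functional form of such a "more significant than" comparison is a
presentation choice; exporting both p-values keeps it transparent.
P-values are made one-sided in the direction of the gene's overall mean
fold change before combination ($z_i = \Phi^{-1}(1-p_i)$, $Z = \sum z_i
/ \sqrt{k}$), and clamped into $(10^{-15}, 1-10^{-15})$ to keep the
quantile transform finite. At $k = 1$ the combination is the identity,
and it is monotone in every input.

# The synthetic study conditions

`synth_config()` fixes the conditions every test runs under. The graph
has 500 nodes over the 12 types (120 Gene, 100 Protein, 60
BiologicalProcess, 40 Pathway, 30 Compound, 30 SideEffect, 25 Anatomy,
25 Symptom, 20 Disease, 20 CellularComponent, 20 MolecularFunction, 10
PharmacologicalClass), wired per type pair by independent Bernoulli
draws following a biomedical-schema shape (Gene–Protein `encodes`,
Protein–Protein `interacts`, Disease–Symptom `presents`, Disease–Gene
`associates`, ...). Disease–Symptom (0.15) and Disease–Gene (0.05)
densities are set so phenotype-side nodes carry several annotations
each, as they do in curated knowledge graphs; a spanning pass attaches
any stray component to the giant one (`related_to`), so the graph is
always connected. The planted signal is a target Symptom presented by a
hub Disease that is associated with 8 module genes — every module gene
reaches the target in two hops, which the tests verify by path
enumeration.

Three studies of six comparisons each mirror the structure of rodent
spaceflight transcriptome studies: three Ground-vs-Baseline comparisons
(missions typically carry several ground-control arms — basal, vivarium,
ground habitat), two Space-vs-Baseline flight time points, and one
Space-vs-Ground comparison. Fold changes are Gaussian — background
$\mathcal N(0, \sigma)$ with $\sigma = 0.5$, module genes
$\mathcal N(\delta, \sigma)$ with $\delta = 2$ in spaceflight
comparisons only — because Gaussian noise makes the Welch-test behaviour
analytically predictable. Generated p-values are the two-sided normal
tail of $\mathrm{fc}\sqrt{m}/\sigma$ with pseudo sample size $m = 1$,
so null genes have exactly uniform p-values. Five percent of entries
are missing at random; each human gene gets one synthetic mouse homolog
(`mgene_0001`, ...) and 10% get a second, exercising the averaging
rule. Every output is a pure function of the configuration seed, which
the tests check by bitwise comparison.

What the generator does **not** emulate: realistic degree
distributions, the full inventory of curated edge types, correlated
gene modules outside the planted one, platform effects, or anything at
the scale of a production knowledge graph (hundreds of thousands of
nodes) and genome-wide fold-change tables. Passing tests therefore
demonstrate the pipeline's mechanics and calibration at desk scale, not
performance on real data.

# What recovery experiments show — and a known limitation

With the default conditions the planted target node almost always
passes the p < 0.025 prescreen, the null generator ($\delta = 0$)
top-flags it only rarely, and per-type top-set sizes always respect the
ceiling quota — the selection machinery is calibrated. But the sharper
event *"the planted target is the single most significant Symptom"*
occurs in only a minority of seeds (the acceptance script reports the
measured rate, typically 0.2–0.4). The reasons are structural rather
than incidental, and worth understanding before applying the method to
small graphs:

* Re-ranking every comparison and variance-normalising with Welch's t
  makes the node test nearly scale-invariant in effect size: a
  background gene that happens to be sign-consistent across the space
  comparisons (the direction filter guarantees within-study
  consistency, and with three studies about a quarter of survivors are
  consistent across all of them) drives its graph neighbourhood apart
  between groups just as reliably as the genuinely shifted module,
  only at a smaller rank amplitude.
* The target node, being maximally loaded on the module, inherits the
  module genes' *null* fold-change noise in the ground-control group —
  it has the largest ground-rank variance of its type, while partially
  or diffusely loaded neighbours shift almost as far with less
  variance and so reach smaller p.
* With 25 Symptom nodes the per-type quota is one slot per contrast, so
  "most significant of its type" is a near-tie contest within the
  module's own neighbourhood.

At the scale this method is designed for — thousands of nodes per type,
a top-2.5% set containing hundreds of nodes — the neighbourhood of a
real signal lands comfortably inside the top set and exact champion
identity is irrelevant. On small graphs, users should read the top set
(and the traced paths) as identifying a *region* of the graph, not a
single node.

# Parameter reference

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.1 | restart (jump) probability of the walk |
| `tol`, `max_iter` | 1e-10, 1000 | power-iteration L1 tolerance / cap |
| `zscore_axis` | `"node"` | normalisation axis before ranking |
| `prescreen_p` | 0.025 | raw Welch p prescreen threshold |
| `top_frac` | 0.025 | per-type top fraction per contrast |
| `r_threshold` | 0.6 | gene–node correlation cut (strict) |
| `min_presence` | 0.2 | gene presence fraction (strict) |
| `max_edges` | 3 | path length bound (edges) |
| `max_paths` | 100 | overflow bound on path combinations |
| `sign_filter` | `"concordant"` | FC/t sign rule for pairs |
| `correlation` | `"pearson"` | gene–node correlation type |

All of these flow through the `params` block of `run_pipeline()`'s
configuration; the synthetic block accepts every `synth_config()`
argument. Problem sizes used by the test-suite simulations (500-node
graphs, 20 generator seeds, up to 200-node oracle comparisons) were
chosen to exercise every code path at desk scale.

# Reproducibility mechanics

All randomness descends from a single integer seed: the generator
derives per-stage seeds (`seed`, `seed + 1`, `seed + 2`) for graph,
homolog map and fold-change draws, and the pipeline is otherwise
deterministic — two runs with the same configuration produce
byte-identical TSV outputs, which the tests verify by checksum. Each
run writes a manifest (configuration echo, input MD5 hashes, per-stage
record counts) alongside the stage outputs.
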