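# walkrank

Propagating differential gene expression through a heterogeneous
biomedical knowledge graph.

`walkrank` is for computational biologists who have per-comparison
fold-change tables (for example spaceflight vs. ground-control rodent
transcriptomes) and want to know which *concepts* in a typed knowledge
graph — symptoms, anatomical structures, biological processes,
pathways — shift in importance between experimental groups, and which
input genes drive each shift along which relational paths.

## The method

1. **Gene-restart random walks.** For each human Gene node $g$, the
   stationary distribution of a random walk with restart
   (topic-specific PageRank)

   $$p \leftarrow \alpha\,e_g + (1-\alpha)\,W^\top p, \qquad \alpha = 0.1$$

   scores every graph node's relevance to $g$ ($W$ row-stochastic,
   undirected traversal, dangling mass redirected to the restart).

2. **Fold-change embedding.** Mouse fold changes are mapped to human
   Gene nodes via homologs (many-to-one averaged), genes inconsistent
   in sign across a study's spaceflight comparisons are dropped, the
   profile matrix is z-scored per node and ranked per gene (most
   relevant = $N$), and each comparison becomes the rank vector of the
   fold-change-weighted profile sums — one permutation of $1..N$ per
   comparison.

3. **Node significance.** Rank rows are pooled into Ground vs.
   Baseline, Space vs. Baseline, and Space vs. Ground groups. Per node,
   Welch's t-test compares each spaceflight group against the ground
   group; "top" nodes pass a raw p < 0.025 prescreen and sit in the
   most significant 2.5% of their node type in at least one contrast.

4. **Path retracing.** Genes present in >20% of pooled comparisons
   whose fold change correlates (r > 0.6, sign-concordant with the
   node's t) with a top node's rank are linked to it by all simple
   paths of ≤3 edges (pairs with ≥100 paths are dropped as
   unvisualisable). Gene fold changes are also scored across groups
   (averaged Welch t; Stouffer-combined p-values).

A synthetic-data module generates typed 500-node knowledge graphs and
three-study fold-change designs with a planted gene-module → Symptom
signal, so the entire pipeline is testable without any external data.

## Worked example

```r
library(walkrank)

res <- run_pipeline(list(seed = 4, synthetic = list()), "out4",
                    quiet = TRUE)
pipeline_report("out4")
```

```
pipeline run: out4
  500 nodes, 18 pooled comparisons, 74 genes used
  122 nodes prescreened, 20 top
  top Anatomy: anatomy_0016
  top BiologicalProcess: biologicalprocess_0008, biologicalprocess_0033, ...
  top Disease: disease_0007
  top Symptom: symptom_0004
  ...
  planted target symptom_0004 recovered: TRUE
```

Of 500 nodes, 122 pass the raw Welch prescreen and 20 (4.0%) are
top-flagged within their types — here including the planted target
symptom and its hub disease. The target's test results:

```r
dplyr::filter(tidy(res$top_nodes), node_id == "symptom_0004")
#>   node_id      node_type t_svb  p_svb   t_svg  p_svg
#>   symptom_0004 Symptom   4.59  0.00177 4.64   0.00165
```

Positive t ≈ 4.6 in both contrasts: the node ranks systematically
higher in spaceflight comparisons than in ground controls. The traced
paths name the mechanism — module genes reach the target through the
planted hub disease:

```r
head(dplyr::filter(res$paths, node_id == "symptom_0004"), 3)
#>   gene_id   nodes                               edge_types
#>   gene_0081 gene_0081|disease_0007|symptom_0004 associates|presents
#>   gene_0079 gene_0079|disease_0007|symptom_0004 associates|presents
#>   gene_0116 gene_0116|disease_0007|symptom_0004 associates|presents
```

`plot_node_ranks(res$pooled, "symptom_0004")` draws the per-group
violin plot of (ground-centred) ranks; `autoplot(res$top_nodes)` shows
the per-type p-value landscape; `plot_gene_scores(res$gene_scores)`
the gene-level space-vs-ground scatter. Each stage is also exposed as a
composable function (`read_kg()`, `rwr_matrix()`, `map_homologs()`,
`embed_study()`, `compare_groups()`, `select_top_nodes()`,
`trace_paths()`, ...) — see the methods vignette in `vignettes/` for
the model, its assumptions, all tunable parameters, and known
limitations at small graph scale.

A thin command-line wrapper lives at `inst/scripts/walkrank.R`
(`run`, `synth`, `report` subcommands).

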