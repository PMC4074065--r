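# grnfidelity

Two-phase gene regulatory network (GRN) inference from short developmental
time-course expression data, with a fidelity score that fuses data-driven
confidence and Gene-Ontology semantic similarity, SOM-based module
expansion, and a complete synthetic benchmark harness.

## Who this is for

Systems biologists reverse engineering regulatory structure from staged
expression profiles (developmental series, differentiation protocols) where
each gene contributes one short profile — too little data for correlation
networks or Bayesian structure learning to resolve direction and sign — and
who want ranked, experimentally testable edge predictions validated against
a curated interaction database.

## The method

**Phase 1 — scaffold inference.** For every target gene $x$, ensembles of
small regulator subsets are fitted under saturable activation–inhibition
dynamics

$$\frac{dx}{dt} = V_{max}\,\frac{b + \sum a_j u_j^h}{1 + b + \sum a_j u_j^h + \sum c_j v_j^h} - d\,x,$$

and a subset is accepted when the variance-weighted least-squares error is
below 0.75. Sampling 1,000 putative whole networks (one accepted member per
gene) yields per-edge **confidence** (appearance frequency) and sign calls.
Each edge's confidence is fused with the **Jaccard similarity** of the two
genes' GO term sets into the fidelity score

$$Z_k(w) = Zc_k + w\,Zj_k,$$

the weighted sum of the z-scored log-confidence and z-scored Jaccard index
(zero-overlap edges get the sentinel $\min Zj - 1$). Filtering at rising
cutoffs prunes the initial "hairball" into scale-free, hierarchical
networks.

**Phase 2 — module expansion.** Repeated self-organizing-map co-clustering
(random 3×3–50×50 grids) estimates modules of profile-equivalent genes;
every scaffold edge expands to all cross-module gene pairs, the expanded
population is rescored with $Z(w)$, and predictions are prioritized by the
**cluster product** (product of endpoint module sizes — low means
profile-unique).

## Worked example

```r
library(grnfidelity)

# synthetic benchmark: a 20-gene layered activation cascade over 9 stages,
# with a planted 3-gene co-expression module
ds <- make_synthetic_dataset(n_genes = 20, mean_degree = 1.5,
                             activation_fraction = 1, feedback_fraction = 0,
                             attachment_window = 4, module_sizes = 3,
                             noise_sd = 0.02, seed = 1)
cfg <- pipeline_config(seed = 1, k_max = 2, ensemble_cap = 50,
                       attempt_budget = 150, n_networks = 500,
                       som_runs = 50, grid_max = 5,
                       cutoffs = c(0, 1), scaffold_cutoff = 0,
                       phase2_cutoff = 0.5, var_floor = 0.02^2)
p1 <- run_phase1(ds$expression, ds$annotations, cfg)
p1$counts$edges_called
#> [1] 114
ref <- ds$reference[ds$reference$is_true, c("gene_a", "gene_b")]
cv <- evaluate_curves(p1$records, ref, genes = gene_ids(ds$expression))
cv
#> <grn_curves> AUPR 0.203 (baseline 0.084), AUROC 0.686
p2 <- run_phase2(p1, ds$expression, ds$annotations, cfg)
head(p2$prioritized[, c("source", "target", "confidence", "jaccard",
                        "z_w", "cluster_product")], 3)
#>   source target confidence jaccard  z_w cluster_product
#> 1   G004   G020          1     0.6 2.54               9
#> 2   G020   G004          1     0.6 2.54               9
#> 3   G004   G007          1     0.5 2.07               9
```

`evaluate_curves` benchmarks the scored edges (undirected, over all gene
pairs) against the known-interaction reference: the fidelity-ranked edges
reach AUPR 0.20 against a 0.084 random baseline. The Phase 2 table ranks
profile-unique, high-fidelity predictions first — the analogue of the
published top-10 interaction table; both orientations of a within-module
pair are retained as separate directed predictions.
`topology_report(p1$networks[["1"]])` summarizes degree and clustering
structure of any filtered network; `write_sif` / `write_graphml` export for
viewers.

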