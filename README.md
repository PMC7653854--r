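# hspcflow

Integrative single-cell analysis of human bone-marrow hematopoietic
stem/progenitor cells (HSPCs).

Sorted CD34+ marrow cells span a continuum from quiescent stem cells to
lineage-committed progenitors. Given a genes × cells count matrix from
such an experiment (a few hundred full-length scRNA-seq profiles across
the CD38− and CD38+ FACS compartments), hspcflow reconstructs the
cellular hierarchy and asks how gene *regulation*, not just gene
*expression*, changes as lineages commit:

- normalization (log2 CPM), cell QC, and binned-dispersion selection of
  highly variable genes;
- PCA, DBSCAN clustering with an explicit noise class, one-vs-rest
  marker detection, and cell-type assignment by the significance of
  marker/signature overlaps (one-sided Fisher/hypergeometric test);
- cell-cycle phase allocation (G0/G1, S, G2/M) from matched-background
  program scores;
- running-sum gene-set enrichment (GSEA) with phenotype-permutation
  significance for the CD38+ vs CD38− contrast;
- diffusion-map pseudotime, a PAGA-style cluster connectivity graph,
  lineage branch assignment, and spline-based detection of genes dynamic
  along pseudotime;
- **multi-branch differential co-expression**: for a gene set with m
  genes, each lineage branch b contributes a vector of Pearson pair
  correlations ρ_b over its cells, and the set's dispersion index is

  DI = sqrt( (1/p) Σ_pairs (1/B) Σ_branches (ρ_{b,i} − ρ̄_i)² ),

  the root-mean dispersion of branch correlations about the per-pair
  mean (p = m(m−1)/2 pairs, B branches) — 0 when co-expression is
  conserved across branches, large when the regulatory wiring differs.
  Significance comes from permuting branch labels over cells; gene-pair
  edges are classified conserved/altered for network rendering;
- cross-modality projection: lncRNAs are paired with lineage-module
  genes within 50 kb on the same chromosome, and the module memberships
  are tested for directional segregation (Wilcoxon signed-rank on PCA
  loadings) on the principal axes of the mRNA, lncRNA, and
  TF-motif-accessibility (scATAC-derived) PCAs.

A synthetic branching-hematopoiesis generator (`simulate_hspc()`) with
six populations (HSC, MLP, MEP, GMP, ProB, ETP) on the tree
HSC→{MEP, MLP}, MLP→{GMP, ProB, ETP} ships full ground truth — cluster,
branch, latent time, phase, compartment, module membership, genomic
placement, and branch-specific correlation targets — so every stage is
testable end-to-end without external data.

## Worked example

```r
library(hspcflow)

ds   <- simulate_hspc(sim_params(seed = 1))   # 391 cells, six clusters
logm <- normalize_log(ds$counts)
hvg  <- select_hvg(logm)
emb  <- run_pca(scale_clip(logm[hvg$selected, ]), k = 10)

clusters <- dbscan_cluster(emb)
markers  <- cluster_markers(logm, clusters)
universe <- rownames(logm)[rowSums(logm > 0) >= 3]
types    <- assign_celltype(markers,
                            ds$truth$gene_sets[ds$params$cluster_names],
                            universe)
types[, c("cluster", "type", "overlap", "q")]
#>   cluster type overlap            q
#> 1       1  HSC      40 1.058971e-44
#> 2       2  MLP      40 5.978954e-45
#> 3       3  MEP      40 2.072841e-60
#> 4       4  GMP      40 6.035913e-47
#> 5       5 ProB      40 7.820092e-45
#> 6       6  ETP      40 1.755962e-45
```

All six truth populations are recovered and typed: each cluster's
markers overlap their generating signature in all 40 genes, with BH-
adjusted hypergeometric q-values far below any threshold.

Differential co-expression across the three committed branches
(erythro-megakaryocytic, lymphoid, granulo-monocytic; stem cells
excluded):

```r
bl <- setNames(ds$truth$cells$branch, ds$truth$cells$cell_id)
bl[bl == "stem"] <- NA
permute_di(logm, ds$truth$gene_sets$COEXPR_DIFF, bl,
           n_perm = 500, seed = 2)
#> DI = 0.3350, permutation p = 0.001996 (500 permutations)
permute_di(logm, ds$truth$gene_sets$COEXPR_CONS, bl,
           n_perm = 500, seed = 2)
#> DI = 0.0769, permutation p = 0.996 (500 permutations)
```

The set generated with branch-specific co-expression (correlation 0.6
in the erythro-MK branch, 0 elsewhere) shows a large, significant
dispersion index; the set with identical co-expression in every branch
does not.

`run_all(default_config(), out_dir)` executes the eight stages
(simulate, preprocess, cluster_assign, cellcycle, gsea, trajectory,
coexpr, project) in order and writes TSV/GTF/GMT/JSON outputs plus a
run manifest; `inst/scripts/run_pipeline.R` is a thin command-line
wrapper around it. The methods, parameter defaults, and design
decisions are documented in `vignettes/hspcflow-methods.Rmd`.

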