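# fibronet

Tissue-stratified transcriptomic systems biology in R: from two-group
expression matrices to differentially expressed genes (DEGs), scored
protein–protein interaction (PPI) networks, hub/bottleneck/switch (HBS)
centrality classification, over-representation analysis (ORA), and
cross-tissue overlap statistics.

The package is aimed at analysts comparing the transcriptional response of
two tissues (or cohorts) under the same condition — for example epithelial
samples from patients stratified by a genotype — who want to know not just
*which* genes respond in each tissue, but whether the tissues share genes,
pathways, or network regulators, with every step reproducible from a seed.

## The pipeline

1. **Differential expression.** For gene *g* with pooled within-group
   variance *s²_g* on *df* degrees of freedom, the per-gene variance is
   shrunk towards an empirical-Bayes prior (*d₀*, *s₀²*) estimated by
   closed-form moment matching on log *s²_g*:

   *s̃²_g = (d₀·s₀² + df·s²_g) / (d₀ + df)*,
   *t_g = log2FC_g / √( s̃²_g · (1/n₁ + 1/n₂) )*,

   referred to a Student t with *d₀ + df* degrees of freedom. A gene is
   called over/underexpressed when |log2FC| > 0.5 **and**
   Benjamini–Hochberg adjusted *P* < 0.05 (both strict).
2. **Network construction.** Interactions below combined confidence 0.4 are
   discarded; the DEG seed set is expanded by at most 20 first-shell and 5
   second-shell interactors per query (ranked by best qualifying score);
   still-unconnected inputs are re-submitted until no new connections
   appear, and all subnetworks are merged. A separate grow-to-saturation
   mode (≤ 50 first-shell, no second shell) expands a focal set to a fixed
   point and keeps only the edges among the original inputs.
3. **Centrality.** Degree, unnormalised Brandes betweenness, and
   max-rescaled eigenvector centrality. A node is a **Hub** /
   **Bottleneck** / **Switch** when its degree / betweenness / eigenvector
   score is strictly above the network mean, and an **HBS** — a candidate
   key regulator — when it is all three.
4. **Enrichment.** One-sided hypergeometric ORA against GMT gene sets with
   BH FDR, at two tiers: FDR < 0.05 for DEG lists, FDR < 0.001 for HBS
   lists.
5. **Overlap.** Per-direction Venn partitions of the two tissues' DEG sets
   and shared-gene percentages, displayed with truncation (floor) to two
   significant figures — the convention that turns 2/47 = 4.2553% into
   "4.2" and 2/1075 = 0.18604% into "0.18".

A seeded synthetic-data module generates ground-truthed inputs with the
structure the pipeline assumes — two-cohort log2 expression with planted
fold changes, a preferential-attachment interaction network with a planted
hub, annotation sets with a planted enriched term — so everything is
testable end to end without downloads.

## Worked example

```r
library(fibronet)

study <- simulate_study(synthetic_config(seed = 1))   # two tissues, shared truth
rect  <- study$tissues$rectal

degs <- call_degs(fit_group_stats(rect$expression, rect$samples))
glance(degs)
#>   n_genes n_case n_control  d0  s0_2 n_over n_under lfc_cut fdr_cut
#>      1000     16        13 843 0.252     19      31     0.5    0.05

net    <- build_merged_network(study$interactions, degs)
report <- classify_hbs(centrality_report(net))
#> network: 75 nodes, 117 edges; 10 HBS nodes

head(dplyr::arrange(report, dplyr::desc(hbs), dplyr::desc(degree)), 2)
#>   node  degree betweenness eigenvector hub   bottleneck switch hbs
#> 1 G0110     23       1252.       1     TRUE  TRUE       TRUE   TRUE
#> 2 G0715     10        526.       0.218 TRUE  TRUE       TRUE   TRUE

enrich(hbs_nodes(report), study$annotations, rect$expression$gene,
       tier = "hbs")[1, c("term", "k", "K", "n", "N", "p_adj", "significant")]
#>   term k  K  n   N        p_adj significant
#> 1 T001 9 40 10 739 7.622676e-10        TRUE
```

The fitted prior (`d0 = 843`, i.e. near-complete shrinkage, as expected for
homoscedastic noise) is reported alongside the DEG counts; the merged
network keeps every confidence-qualifying edge among the retained nodes;
the planted term `T001` is recovered by the HBS-tier enrichment nine of
whose ten query genes are term members. Cross-tissue overlap:

```r
bron <- study$tissues$bronchial
degs_b <- call_degs(fit_group_stats(bron$expression, bron$samples))
shared_percentages(degs, degs_b)[, c("direction", "n_a", "n_b", "n_shared",
                                     "display_pct_of_a")]
#>   direction n_a n_b n_shared display_pct_of_a
#> 1      over  19  23        4               21
#> 2     under  31  29        6               19
#> 3       all  50  52       10               20
```

The full pipeline — both tissues, networks, centrality, both enrichment
tiers, overlap, saturation network, JSON summary and run log — is one call:

```r
run_pipeline(system.file("extdata", "demo_config.yaml", package = "fibronet"),
             outdir = "demo_out")
```

or from a shell, `Rscript exec/fibronet run --config <yaml> --outdir <dir>`
(subcommands `simulate`, `deg`, `network`, `centrality`, `enrich`,
`saturate` expose the individual stages).

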