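# acidnet

Guide-gene-anchored weighted co-expression network analysis of fruit
acidity for two-genotype RNA-seq studies.

Apple fruit acidity is dominated by malate and strongly structured by the
*Ma* locus: accessions with a functional allele (*Ma_*) accumulate
several-fold more malate at maturity than *mama* homozygotes. Given a
gene-by-sample RPKM matrix, per-sample acidity measurements (malate,
titratable acidity, pH) and a designated guide gene — an ALMT1-like malate
transporter whose own statistics calibrate the selection rules — `acidnet`
identifies trait-associated genes, infers co-expression modules, and ranks
candidate regulators:

- **Trait-associated genes** are the union of differentially expressed
  genes (weighted proportions test on per-sample relative abundances,
  Benjamini–Hochberg FDR < 0.05, RPKM range ≥ 5) and genes expressed
  similarly to the guide (between-group mean difference > 10 RPKM and
  fold change > 1.5 in the guide's direction).
- **Network**: square-root-transformed expression, unsigned soft-threshold
  adjacency `a_ij = |cor(x_i, x_j)|^6`, topological overlap
  `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 − a_ij)`, average-linkage
  clustering with a recursive branch cut (minimum module size 30, eigengene
  merge at dissimilarity 0.25). Per gene: gene significance
  `GS = cor(x_i, malate)`, module membership `MM = cor(x_i, ME)` against
  the module eigengene (first principal component), and total connectivity
  `kTotal = Σ_j a_ij`. Module–trait correlations use the t transform
  (significant at p < 0.001).
- **Guide-calibrated selections**: most-significant acidity genes
  (`|GS| ≥ |GS_guide|`), top-12-|MM| intramodular hubs per significant
  module, and per-genotype kTotal change patterns (major / reverse /
  down-both / up-both).
- **Enrichment**: one-sided hypergeometric tests of annotation terms
  (GO / MapMan-style flat tables) per module and namespace, BH-adjusted.
- **Regulators**: ten Gibbs-sampled Bayesian mixture clusterings,
  consensus tight clusters (≥ 10 genes, top 50), binary sample trees by
  recursive 2-means, per-(candidate, cluster) probabilistic scores
  (node-weighted `−log10 p` of two-sample t-tests), the top-1% rule, and a
  z-test calibration against 96 random control genes.

A seeded synthetic-data generator (`simulate_dataset()`) plants modules, a
malate-like trait, a guide gene and regulators with full ground truth, so
the entire pipeline is validated end-to-end in the test suite.

## Worked example

```r
library(acidnet)

sim <- simulate_dataset(sim_config(seed = 1))   # 604 genes x 29 samples
res <- run_pipeline(sim$expr, sim$traits, sim$annotation,
                    guide_id = sim$truth$guide_id, seed = 1)
res
#> <acid_pipeline> 604 genes; 604 expressed; 112 trait-associated (68 DE, 107 guide-similar)
#>   2 modules (2 significant), 1 MSAGs, 24 hubs, 1 regulator assignments

glance(res$network)
#> # A tibble: 1 x 8
#>   n_genes n_modules n_grey  beta top_module top_module_r n_sig_modules
#>     <int>     <int>  <int> <dbl> <chr>             <dbl>         <int>
#> 1     112         2      4     6 blue              0.869             2

head(tidy(res$network)[order(-tidy(res$network)$abs_gs), ], 3)
#> # A tibble: 3 x 7
#>   gene_id module    gs abs_gs    mm abs_mm ktotal
#>   <chr>   <chr>  <dbl>  <dbl> <dbl>  <dbl>  <dbl>
#> 1 GUIDE_1 blue   0.940  0.940 0.940  0.940   24.6
#> 2 M1_G001 blue   0.887  0.887 0.969  0.969   26.7
#> 3 M1_G025 blue   0.874  0.874 0.891  0.891   19.9

res$ktotal_gs
#> # A tibble: 1 x 4
#>       n     r r_squared        p
#>   <int> <dbl>     <dbl>    <dbl>
#> 1   112 0.682     0.466 1.17e-16
```

Reading these numbers: of 604 simulated genes, 112 are trait-associated
(68 by differential expression, 107 guide-similar, with overlap). The
network groups them into two modules; the guide gene's module ("blue")
attains the strongest eigengene–malate correlation (r = 0.87, p < 0.001).
The guide's gene significance (0.940) becomes the MSAG threshold — here no
other gene exceeds it, so the MSAG set is the guide alone — and the top-12
|MM| genes of each significant module give 24 hubs. Network-wide, more
connected genes tend to have higher |GS| (r² = 0.47). The regulator stage
recovers a planted regulator as the single top-1% (candidate, cluster)
assignment. `autoplot(res$network, "module_trait")` draws the module–trait
heatmap, and `export_network(res$network, 0.10)` exports the TOM-weighted
edge list (weights > 0.10) and a GraphML file for Cytoscape-style viewers.

File-based workflows use `write_dataset()`, `read_expression()`,
`read_traits()` and `read_annotation()`; `run_pipeline(..., out_dir =)`
writes every stage table, the network export and a JSON run manifest.

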