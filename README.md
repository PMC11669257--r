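# soilnet

Soil microbial communities respond to land-use change in two ways that a
count table alone does not reveal: the *processes* that assemble them can
shift between stochastic and deterministic, and the *architecture* of
their co-occurrence networks can gain or lose complexity and stability.
soilnet is an R package for amplicon-derived taxon-by-sample count tables
(with sample groups and a rooted phylogeny) that quantifies both, end to
end, for microbial ecologists comparing treatment groups in field
surveys — for example control plots against plots under photovoltaic
panels or other land-use conversions.

The pipeline implements:

- **Diversity**: rarefaction to even depth, richness and Shannon
  diversity (natural log), weighted UniFrac
  \(\sum_b l_b |p_{Ab}-p_{Bb}|\) (normalized variant by default), PCoA,
  and PERMANOVA (Anderson's pseudo-F, permutation p-value), plus
  Wilcoxon + Benjamini–Hochberg and ANOVA + Tukey HSD group comparisons.
- **Assembly processes**: the beta mean nearest taxon distance
  \(\beta MNTD_{jk} = \frac12[\sum_{i\in j} f_{ij}\min_{i'\in k}d_{ii'} +
  \sum_{i\in k} f_{ik}\min_{i'\in j}d_{ii'}]\), a tip-shuffling null
  model, and the beta nearest taxon index
  \(\beta NTI = (\beta MNTD_{obs}-\mu_{null})/\sigma_{null}\), classified
  by the strict ±2 rule (< −2 homogeneous selection, > +2 heterogeneous
  selection, otherwise stochastic).
- **Networks**: per-group Spearman co-occurrence networks (prevalence ≥
  half the group's samples, |ρ| > 0.6, BH-adjusted p < 0.05), greedy
  modularity modules, degree/weighted degree/betweenness/eigenvector
  metrics with Freeman centralization.
- **Node roles**: within-module connectivity (Zi) and participation
  (Pi), with module hubs (Zi > 2.5, Pi < 0.62), connectors (Zi < 2.5,
  Pi > 0.62), network hubs (both), peripherals otherwise.
- **Stability**: robustness to random removal of 50% of nodes and to
  targeted removal of the five top module hubs (100 replicates,
  extinction by isolation), Welch t-test comparisons, and vulnerability
  as the maximal relative drop in global efficiency
  \(E = \frac{2}{n(n-1)}\sum_{i<j} 1/d_{ij}\) under single-node deletion.
- **Synthetic data**: a generator with planted correlation blocks,
  multi-block hub taxa, a phylogenetically conserved habitat-filtering
  signal and a dispersal lottery, so every stage can be validated against
  known ground truth.

## Worked example

Simulate a three-arm survey (11 control + 16 + 16 treated samples, 300
taxa) in which the treated arms assemble under homogeneous selection,
then run the stages:

```r
library(soilnet)

sim <- simulate_dataset(synth_config(seed = 42))
tab <- rarefy_counts(sim$table, seed = 1)
tab
#> <asv_table> 300 taxa x 43 samples
#> groups: control (11), down (16), mid (16)
#> depth: 20340-20340 reads per sample

head(alpha_diversity(tab), 3)
#> # A tibble: 3 x 4
#>   sample_id  group   richness shannon
#>   <chr>      <chr>      <int>   <dbl>
#> 1 control_01 control      158    3.29
#> 2 control_02 control      180    3.96
#> 3 control_03 control      159    3.30

uf <- weighted_unifrac(tab, sim$tree)
permanova(uf, tab$metadata, n_permutations = 999, seed = 2)
#> PERMANOVA: pseudo-F(2,40) = 47.699, R2 = 0.705, p = 0.001 (999 permutations)

bn <- bnti(tab, sim$tree, n_null = 199, seed = 3, comparisons = "within")
bnti_group_summary(bn)
#> # A tibble: 3 x 7
#>   group   n_pairs mean_bnti stochastic homogeneous_selection ...
#> 1 control      55   -0.0624      0.964                 0
#> 2 down        120   -1.70        0.567                 0.433
#> 3 mid         120   -1.80        0.5                   0.5
```

The PERMANOVA confirms the groups differ in composition (70% of distance
variance explained here), and the betaNTI summary shows the planted
regime shift: control pairs are almost entirely stochastic
(|betaNTI| < 2), while 43–50% of within-group pairs in the treated arms
fall below −2, the signature of homogeneous selection.

Network, roles and stability for one group:

```r
net   <- group_network(tab, "control")     # |rho| > 0.6, BH p < 0.05
part  <- detect_modules(net)
roles <- zi_pi(net, part)
keystone_summary(dplyr::mutate(roles, group = "control"))
#> # A tibble: 1 x 7
#>   group   peripheral connector module_hub network_hub n_nodes keystone
#> 1 control         72         1          1           0      74        2

stability_report(net, roles, seed = 4)
#> <stability_report> random robustness 0.364 +/- 0.003 | targeted 0.878 | vulnerability 0.2519
```

Here the control network keeps 36% of its taxa connected after removing
half its nodes at random, 88% after removing its top hubs, and loses at
most 25% of its global efficiency to any single-node failure.
`run_pipeline(pipeline_config(...))` chains all stages and returns a
JSON-ready summary; `autoplot()` methods and `plot_zi_pi()` /
`plot_robustness()` draw the standard figures.

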