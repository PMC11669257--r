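---
title: "Methods: assembly processes, co-occurrence networks and stability in soilnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assembly processes, co-occurrence networks and stability in soilnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

soilnet implements the post-denoising computational chain of a multi-group
soil-microbiome survey: even-depth rarefaction, alpha and beta diversity,
ordination and PERMANOVA, null-model classification of community assembly
processes, Spearman co-occurrence networks with node-role taxonomy, and
topological stability analysis. This vignette explains each model, the
parameters that matter, the design of the synthetic-data generator, and the
numerical choices, so that results can be interpreted — and the limits of
what the package's own validation shows can be judged.

## The analysis chain

### Diversity and ordination

Counts are rarefied to a common depth (default: the minimum library size)
by per-sample subsampling without replacement. Richness is the number of
detected taxa; the Shannon index is $H = -\sum_i p_i \ln p_i$ with natural
logarithm, the convention of the ecology toolchain this package sits in.
Beta diversity is weighted UniFrac: each branch $b$ of the phylogeny with
length $l_b$ contributes $l_b\,\lvert p_{Ab} - p_{Bb}\rvert$, where
$p_{Xb}$ is the fraction of sample $X$'s reads descending from $b$; the
normalized variant (the default) divides by $\sum_b l_b (p_{Ab}+p_{Bb})$.
Ordination is classical metric scaling of the distance matrix
(double-centred eigendecomposition), and group differences are tested with
PERMANOVA: Anderson's pseudo-F on the partition of squared distances, with
a p-value from free permutation of sample labels,
$p = (\#\{F_{perm} \ge F_{obs}\} + 1)/(n_{perm}+1)$; 999 permutations by
default. Group comparisons of univariate features use the two-sided
Wilcoxon rank-sum test with Benjamini–Hochberg adjustment across features,
or one-way ANOVA with Tukey HSD and a compact letter display for network
metrics (optionally after a log10 transform, zeros offset by half the
smallest positive value and the offset recorded).

### Assembly processes: betaMNTD and betaNTI

The between-sample phylogenetic turnover statistic is the abundance-weighted
beta mean nearest taxon distance,

$$\beta MNTD_{jk} = \tfrac12\Big[\sum_{i \in j} f_{ij}\,
\min_{i' \in k} d_{ii'} \;+\; \sum_{i \in k} f_{ik}\,
\min_{i' \in j} d_{ii'}\Big],$$

with $d$ the patristic distance and $f$ relative abundances. A taxon shared
by both samples has nearest-taxon distance zero. The null model shuffles
taxon labels across all tips of the phylogeny (the "taxa.labels"
convention), recomputing $\beta MNTD$ each time; the beta nearest taxon
index is the z-score
$\beta NTI = (\beta MNTD_{obs} - \mu_{null})/\sigma_{null}$ from 999
shuffles by default. Interpretation uses strict thresholds: values below
−2 indicate homogeneous selection, above +2 heterogeneous selection, and
$\lvert \beta NTI \rvert < 2$ (including the boundaries) stochastic
assembly. Classification fractions are reported per group over
within-group sample pairs by default; both within- and all-pair scopes are
exposed, since published per-group fractions do not always state the
scope. Pairs whose null distribution degenerates ($\sigma_{null}=0$, e.g.
single-taxon tables) are flagged and excluded with a warning.

Implementation note: for one tip-shuffle, only the taxon distance matrix
is permuted, so the per-shuffle cost is one matrix of column minima and
one cross-product; 999 shuffles on a 300-taxon, 43-sample table take a few
seconds.

### Co-occurrence networks

Per group, taxa present in at least `ceiling(0.5 * n)` of the group's
samples are retained (the "at least half of the samples" prevalence rule,
with the ceiling resolving odd counts conservatively), relative abundances
are computed, and all taxon pairs are tested for Spearman correlation with
average-rank ties. P-values come from the t approximation for $n \ge 10$
samples and the exact tie-free distribution otherwise; the BH adjustment
is applied once across all tested pairs of the group. Edges require
$\lvert\rho\rvert > 0.6$ **and** adjusted $p < 0.05$; the sign is kept as
an attribute and the weight is $\lvert\rho\rvert$. Taxa with no retained
edge are excluded from the network.

Modules are found by greedy modularity maximization on the
$\lvert\rho\rvert$ weights — deterministic for a fixed graph, with one
guard: when the detected partition's modularity is not positive (e.g. a
single clique), the trivial one-module partition is reported. Modules
with fewer than 5 nodes are flagged minor but retained. Topology metrics
use unweighted shortest paths for betweenness (correlation magnitude is a
similarity, not a length; an inverse-weight variant would be a different
estimand and is deliberately not the default), eigenvector centrality of
the largest component (zero elsewhere), and Freeman centralization for
both.

### Node roles (Zi/Pi) and keystones

With a module partition fixed, within-module connectivity is the z-score
of a node's link count into its own module relative to that module's nodes
(population standard deviation; a module whose nodes all have identical
within-degree gets Zi = 0), and the participation coefficient is
$P_i = 1 - \sum_t (k_{it}/k_i)^2$ over modules $t$, both on unweighted
counts. Roles use strict thresholds: module hub (Zi > 2.5, Pi < 0.62),
connector (Zi < 2.5, Pi > 0.62), network hub (both exceeded), otherwise
peripheral; values exactly on a boundary are peripheral. Non-peripheral
nodes are collectively "keystone" nodes.

### Stability: robustness and vulnerability

Robustness is the fraction of the original nodes that keep at least one
edge after a perturbation; a species left without partners counts as a
secondary extinction (one pass suffices, since deleting an isolated node
changes no other node's degree). Random removal deletes
$\lfloor 0.5\,n \rfloor$ uniformly chosen nodes per replicate, 100
replicates by default. Targeted removal deletes the five highest-Zi nodes
among module/network hubs; when fewer classified hubs exist, the remaining
removals fall back to the next-highest-Zi nodes — the only reading that
keeps a five-hub removal executable on a network with, say, three module
hubs — and the number of fallback removals is recorded. Replicate vectors
are compared between groups with Welch's two-sided t-test.

Vulnerability is based on global efficiency
$E = \frac{2}{n(n-1)}\sum_{i<j} 1/d_{ij}$ (unweighted distances,
disconnected pairs contributing zero): node $i$'s vulnerability is the
relative efficiency drop $(E - E_i)/E$ when $i$ is deleted, with $E_i$
computed on the remaining $(n-1)$-node graph with its own pair count; the
network's vulnerability is the maximum over nodes. Node values can be
negative when removing a node raises average efficiency.

## The synthetic-data generator

The generator produces datasets with known ground truth at the scale of a
three-arm soil survey: 300 taxa, 43 samples (11 neutral "control", 16 +
16 selective "down"/"mid"), library sizes uniform on 20,000–60,000. Its
purpose is validation: every downstream stage must recover the structure
that was planted.

**Phylogeny and trait.** The tree is two-level: a random backbone of
~75 deep lineages (branch lengths inflated by +0.5) carrying ~4-tip
crowns at 3% of the backbone scale. A continuous trait evolves along it
by Brownian motion. The two-level shape makes the trait strongly
clade-conserved, which is what lets a trait-based habitat filter produce
the clade-confined communities the nearest-taxon index responds to; on a
uniformly random topology the same filter selects taxa scattered across
the tree and the betaNTI signal never materializes at this pool size.

**Abundances.** Base abundances are log-normal (sdlog 1.5), the standard
skewed-abundance assumption. Per sample, each taxon's log-propensity
fluctuates with scale 1.35; counts are multinomial at the drawn depth, so
compositional closure, detection limits and depth heterogeneity are all
present.

**Planted modules and hubs.** Four 15-taxon blocks share per-sample latent
factors with loading $\sqrt{0.9}$, inducing within-block correlation 0.9
of log-propensities. The block factors themselves share a global factor
(pairwise correlation 0.44), and designated hub taxa (one per block,
5-fold abundance) load on the combination of *all* block factors: their
correlation with members of every block clears the 0.6 edge threshold,
and because their edges spread over four modules, their participation
coefficient lands robustly above the 0.62 connector cut. A node whose
edges split over only two modules caps at Pi = 0.5 and can never be a
connector — which is why hubs span all blocks rather than a pair.
Background taxa carry a small negative loading (0.28) on the global
factor: without it, the per-sample propensity total co-varies with the
global factor and compositional closure cancels precisely the hub signal.

**Assembly regimes.** The first group assembles neutrally. Later groups
are under homogeneous selection: propensities are down-weighted by
$\exp(-s\,(z - \theta_g)^2)$ on the standardized trait axis, with optima
$\theta_g$ at evenly spaced quantiles of the trait distribution and
selection strength $s = 200$ by default (Gaussian niche width
$1/\sqrt{2s} = 0.05$ trait SD). Strong selection is deliberate: at
20,000+ reads over 300 taxa, weak selection still leaves nearly every
taxon detectable, samples share essentially all members, and the
tip-shuffle null has nothing to contrast. Two further ingredients give
the selective groups realistic structure: taxa near a group's optimum
share a per-sample environmental factor (loading 2.5, width twice the
niche), so selected communities develop their own co-occurrence edges —
selection both filters and synchronizes; and a dispersal lottery makes
background taxa unavailable in a sample with taxon-heterogeneous rates
(25% persistent core, the rest flickering harder, averaging to the
occupancy parameter, default 0.5). The lottery supplies the
sample-to-sample membership turnover real communities show; without it,
within-group pairs are near-identical and no amount of selection moves
betaNTI below −2.

**What the generator does not emulate.** Sequencing error, chimeras,
taxonomy misassignment, true absolute abundances, and the
phylum-composition structure of real soils are all out of scope; the
taxonomy map is a clade cut provided only so phylum-level aggregation can
be exercised. Passing the recovery tests therefore shows that the
*statistics* behave as designed on data with the assumed structure — not
that real soil data satisfy those assumptions.

## Validation design and problem sizes

The test suite validates three ways. Exact cases: closed-form graphs
(paths, stars, cliques), hand-evaluated formulas, and threshold truth
tables with strict boundaries. Oracle equivalence: betweenness,
eigenvector centrality, global efficiency, Zi/Pi, betaMNTD and the BH
step-up are each checked against independent brute-force implementations
(BFS path counting, dense eigendecomposition, per-node recounts, a
double-loop betaMNTD on path-enumerated patristic distances, a hand
step-up) on dozens of random instances; betaMNTD is additionally
cross-checked against an established phylogenetic-ecology implementation.
Statistical calibration: PERMANOVA type-I error over 500 null datasets,
betaNTI on communities generated by random tip assignment (the fraction
with $\lvert\beta NTI\rvert > 2$ stays below 0.10), and BH-Wilcoxon false
discovery control on null features.

Planted-structure recovery runs on two fixtures. Module/hub recovery uses
a single neutral 60-sample group (occupancy 1): 60 samples keep the
sampling noise of rank correlations at the 0.6 threshold from dominating
block membership, which an 11–16-sample group cannot — with field-sized
groups, planted hubs are usually underpowered into peripherals, a
sampling reality rather than a defect. Recovery requires normalized
mutual information ≥ 0.8 between detected modules and planted blocks
(over planted taxa) and ≥ 80% of planted hubs classified non-peripheral.
Assembly recovery uses the default three-arm fixture and requires that,
pooled over the selective groups' within-group pairs, at least half of
the betaNTI values indicate homogeneous selection, that each selective
group's homogeneous-selection fraction exceeds the control's by a wide
margin, and that the control stays majority-stochastic. The pooled
reading reflects how per-group fractions behave in practice: the two
selective arms straddle the 50% line while their union clears it.

Routine runs use scaled simulation sizes chosen to keep the full
validation cycle short while leaving every estimate well-determined: 199
tip-shuffle replicates for betaNTI in the end-to-end runs (999 remains
the analysis default), 999 PERMANOVA permutations, 100 robustness
replicates. The end-to-end determinism check runs the full pipeline twice
on the default fixture and requires byte-identical summary JSON; all
randomness flows from one master seed fanned out to per-stage seeds
through a fixed-order stream, so any stage can be reproduced in
isolation.

## Numerical choices and degenerate inputs

- Rarefaction refuses depths exceeding any library; the default depth is
  the minimum library size.
- "Present" means count > 0; no detection floor is imposed.
- Spearman p-values for perfect correlations are set to 0 (the t
  approximation is singular there); constant taxa are excluded from
  testing with a warning.
- PCoA reports proportions of variance over positive eigenvalues only.
- Zi in a module with zero degree variance is 0; Pi of an isolated node
  is 0 (such nodes cannot occur in networks built here, which drop
  edgeless taxa).
- Eigenvector centrality fixes the iterative solver's start vector, so
  repeated runs are bit-identical.
- betaNTI pairs with zero null SD are excluded from fractions, with a
  warning.
- An empty per-group network (possible under strong selection with small
  groups) is recorded as such in the pipeline summary rather than
  aborting the run; downstream per-network statistics for that group are
  reported as missing.

## Known limitations

Correlation networks are association networks: edges are not
interactions, and compositionality biases correlations — the generator
itself shows a mild closure-induced coupling among the most dominant
taxa. The role taxonomy depends on the detected partition, so role
counts inherit module-detection instability on weakly modular graphs.
The betaNTI null considers only tip-label exchanges; other community
null models (e.g. fixing row/column sums of presence tables) answer
different questions. Vulnerability as maximal single-node efficiency
drop ignores multi-node failures. Finally, group sizes of 11–16 samples
put hub recovery and edge detection near the power boundary at the 0.6
correlation threshold — an intrinsic property of the design, visible in
the package's own recovery experiments.
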