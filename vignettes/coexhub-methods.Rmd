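---
title: "Methods: weighted coexpression networks and hub-gene screening with coexhub"
author: "coexhub authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted coexpression networks and hub-gene screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexhub)
```

# The analysis

`coexhub` implements the complete chain used to screen hub genes for a
quantitative trait — here, the wax secretion of a scale insect, in
mg/individual — from a bulk RNA-seq FPKM table:

1. **Cleaning.** Genes with zero FPKM in every sample are dropped. For the
   rest, the per-gene median absolute deviation (MAD) is computed and genes
   are kept when they are both within the top 75% by MAD *and* above a MAD
   floor of 0.01.
2. **Sample outliers.** Samples are clustered on Euclidean distance
   $d(x,y)=\sqrt{\sum_i (x_i-y_i)^2}$ over the filtered genes with
   unweighted average linkage (UPGMA); a static cut at a fixed height keeps
   only clusters of at least the replicate count (3), removing degraded or
   contaminated samples.
3. **Network.** The coexpression similarity is the gene-gene Pearson
   correlation. A soft-thresholding power $\beta$ turns it into an
   adjacency, unsigned $a_{ij}=|\mathrm{cor}_{ij}|^{\beta}$ by default.
   $\beta$ is chosen as the lowest power whose signed scale-free fit index
   (the $R^2$ of the log-log regression of connectivity frequency on
   connectivity, signed against positive slopes) reaches a target. The
   network similarity is the topological overlap matrix
   $$\mathrm{TOM}_{ij}=\frac{\ell_{ij}+a_{ij}}
   {\min(k_i,k_j)+1-a_{ij}},\qquad
   \ell_{ij}=\sum_{u\ne i,j}a_{iu}a_{uj},\quad k_i=\sum_{u\ne i}a_{iu}.$$
4. **Modules.** Genes are clustered by average linkage on
   $1-\mathrm{TOM}$ and the tree is cut dynamically (below); modules with
   eigengene dissimilarity $1-\mathrm{cor}(E_I,E_J)$ under 0.15 are merged,
   and modules are named by the canonical color sequence in decreasing
   size, grey holding the unassigned genes.
5. **Module–trait relation.** Each module's eigengene (first principal
   component of its standardized expression, unit variance, sign aligned
   with the mean module profile) is correlated with the trait; the
   two-sided Student asymptotic p-value is
   $t=r\sqrt{n-2}/\sqrt{1-r^2}$ on $n-2$ degrees of freedom. Modules with
   $p<0.05$ are the trait modules. Per gene, GS is the absolute
   gene–trait correlation and MM the gene–eigengene correlation.
6. **Hub screen.** For each trait module the intra-module TOM network is
   exported (Cytoscape edge/node files), unannotated genes are removed,
   the induced subnetwork of the 100 highest-degree nodes is formed
   (stage 1, unweighted degree $C_D(u)=|N_u|$), and on that subnetwork the
   weighted indices are computed (stage 2): weighted degree
   $C_{D,W}(u)=\sum_{v\in N_u}W(u,v)$, eigenvector centrality, and
   betweenness. The top 10% by weighted degree are the hub genes; the
   degree and eigenvector top lists are compared for set agreement.

# Tunable parameters

All tunables live in one validated `pipelineConfig()` object:

| parameter | default | meaning |
|---|---|---|
| `madFraction`, `madFloor` | 0.75, 0.01 | top-MAD retention rule |
| `madScaleConstant` | 1.4826 | MAD scaling; 1.4826 matches R's `mad()` and makes the 0.01 floor commensurate with a standard deviation; set 1 for the raw MAD |
| `cutHeight` | `NA` | static cut height for sample outliers (distance units); `NA` uses the midpoint of the two largest merge heights |
| `minClusterSize` | 3 | replicate count; a valid condition keeps all replicates |
| `powers`, `fitTarget` | 1..20, 0.9 | soft-threshold scan grid and fit target |
| `networkSign` | unsigned | standard tutorial default; signed is one switch |
| `minModuleSize`, `deepSplit`, `mergeCutHeight` | 20, 2, 0.15 | module detection defaults of the reference workflow |
| `moduleAlpha`, `pAdjust` | 0.05, none | plain p < 0.05 selection; optional Benjamini–Hochberg for users who want multiplicity control across modules |
| `exportThreshold` | 0.02 | minimum TOM for an exported edge; deliberately low so the screened networks are near-complete (on a complete network every betweenness is 0, which is also why betweenness is reported but not used for ranking) |
| `topK`, `hubFraction` | 100, 0.10 | two-stage screen sizes |
| `maxGenes` | 25,000 | guard against accidental dense full-transcriptome matrices; raise it deliberately for large runs (quadratic memory, slow) |

# Module detection: the native dynamic cut

The dynamic tree cut is implemented natively rather than ported. Its
contract is recovery of planted modules on synthetic data, not
label-for-label equality with any particular implementation, because the
reference algorithm has many undocumented internal constants. The stages:

* **Adaptive static cut** at `h5 + frac * (max - h5)` over merge heights,
  where `h5` is their 5th percentile and `frac` is 0.98/0.965/0.95/0.92 for
  `deepSplit` 0–3 — deeper splits cut lower.
* **Branch filters.** Branches below `minModuleSize` dissolve. A branch
  must also be markedly tighter inside than outside: its median internal
  topological overlap must be at least twice its median overlap with the
  rest of the network. Overlap *ratios* are used throughout because the
  soft-thresholding power compresses all similarities toward 0; ratios are
  invariant to that compression while absolute thresholds are not.
* **PAM stage.** Each unassigned gene is offered to its nearest module by
  average dissimilarity and accepted only if its overlap exceeds the 0.98
  quantile of the overlaps the rest of the unassigned pool has with that
  module — it must stand out from its surroundings, not merely win a
  nearest-module comparison that something always wins.
* **Eigengene refinement** (in `mergeCloseModules()`, after merging).
  Membership is finally consolidated on the gene–eigengene correlation
  (kME), the one scale the power cannot distort: a gene stays in or joins
  a module only if its kME is significant under the Student test at
  α = 0.01, which is the exact null for a gene fluctuating independently
  of the module. Up to three passes let eigengenes purify if the cut swept
  chance-correlated genes into a module. This mirrors the
  `minKMEtoStay`/reassignment post-processing of the reference workflow.

The α = 0.01 membership level is a deliberate balance at small sample
sizes: stricter levels strand genuine peripheral members in grey, looser
ones admit background genes whose chance correlation over a dozen-odd
samples is substantial.

# The synthetic-data generator

`simulateWaxDataset()` emulates the study design the pipeline targets:
6 conditions × 3 replicates (samples FF/SF/EA/LA/FM/SM 1–3), 2,000 genes,
5 modules of sizes {300, 200, 150, 120, 100}, one outlier sample, 10% of
genes all-zero, 22.5% near-constant, 80% annotation coverage.

The model works on the log scale: module $m$ has a condition-level latent
profile; profiles of different modules are drawn mutually orthonormal (QR
of a centred Gaussian), so planted modules are distinguishable at any
seed; replicates add jitter (sd `0.1 * factorSd`). Gene $g$ in module $m$
with loading $\lambda_g$ has
$\log \mathrm{FPKM} = \mu_g + \lambda_g f_{m,s} + \varepsilon$,
$\varepsilon\sim N(0, 0.10^2)$, baselines $\mu_g \sim N(\log 20, 1)$;
FPKM is the exponential. Choices worth explaining:

* **Loading gap.** Hubs load 0.90–1.0; other members 0.32–0.42. The gap
  makes hub identity unambiguous: at 17 samples, correlation estimates
  carry enough noise that a continuous loading profile lets mid-loading
  members overtake true hubs in weighted degree.
* **Moderate dynamic range** (`factorSd` 0.5, so the strongest genes swing
  about an e-fold per condition). The pipeline correlates raw FPKM — it
  never log-transforms, matching common practice with FPKM tables — and
  Pearson correlation on strongly lognormal data is dominated by shared
  outliers. Keeping the log-variance moderate keeps raw-scale correlations
  close to the planted log-scale ones.
* **Light-tailed background** (log-sd 0.3, typical replicate-level
  variability of an unregulated gene). Heavy-tailed background produces
  shared-argmax pseudo-modules on the raw scale: the ~n/17 genes whose
  maximum lands on the same sample correlate strongly pairwise.
* **Two trait modules** (1 and 3, equal coefficients). With $k$ equal
  trait modules each eigengene–trait correlation is capped at
  $1/\sqrt{k}$; at $n=17$, $k=3$ puts every module at the edge of
  $p<0.05$, whereas $k=2$ (cap $0.707$) gives decisive selection.
* **Planted zero/near-constant fractions** (0.10/0.225) are chosen so the
  default filters remove exactly the planted genes: after removing 200
  zero rows, the top-75% rule keeps `ceiling(0.75 * 1800) = 1350`, the
  number of informative genes.
* **Outlier.** One replicate of the third condition (EA1) is multiplied
  globally by $e^{1.5}\approx 4.5$, which separates it cleanly in the
  Euclidean dendrogram; `suggestCutHeight()` (midpoint of the two largest
  merges) then isolates it.
* **Hubs are always annotated** — hub genes are the conserved, annotatable
  ones — which also makes the 10-hub recovery target well defined.

What the generator does **not** emulate, and hence what passing tests do
not show about real data: count noise (no negative-binomial overdispersion
or library-size effects), transcript-length bias, correlated background
(housekeeping co-variation, batch effects), overlapping or hierarchical
modules, wide FPKM dynamic range, and annotation bias toward highly
expressed genes. Real transcriptomes are harder on every one of these
axes; recovery rates here are upper bounds.

# Numerical choices

* **Ties** are broken deterministically everywhere: MAD ranking by input
  order; module numbering by size then first-member order; node rankings
  by the secondary centrality then lexicographic ID.
* **Eigengene sign** is fixed by non-negative correlation with the mean
  standardized module profile, so MM signs are reproducible across runs
  and platforms.
* **Power iteration** for eigenvector centrality runs on $A + sI$ with
  $s = 0.1\,\max_i k_i$: the shift leaves eigenvectors unchanged but makes
  the leading eigenvalue strictly dominant (bipartite graphs such as stars
  otherwise oscillate). Tolerance $10^{-10}$, cap 10,000 iterations,
  non-convergence is an error. Disconnected networks use the largest
  component, others scored 0, with a warning.
* **Degenerate inputs**: constant genes are an error at the correlation
  stage (the MAD floor makes them impossible in the pipeline); equal
  connectivities give scale-free fit 0 with a warning; an unreached fit
  target falls back to the best-fit power with a warning; empty module
  sets short-circuit the downstream stages.
* **Full-precision text I/O** (`%.17g`) so write/read round trips are
  bitwise and two seeded runs produce byte-identical output files.

# Problem sizes

The package's validation suite runs the full chain on the 2,000-gene
preset (a ~1/50-scale mirror of a full transcriptome run at the same
6 × 3 design), where a complete pipeline pass takes a few seconds; oracle
comparisons (triple-loop TOM, exhaustive betweenness, dense eigensolvers)
use 8–50 genes or ≤ 15 nodes, where brute force is exact and fast. Full
transcriptome tables (≳ 10^5 genes) exceed the default `maxGenes` guard;
they are supported by raising the guard, at quadratic memory cost
(a 100,000-gene TOM is ~80 GB), and are the reason the guard exists.

# Known limitations

* Single-block detection only: no pre-clustering of genes into blocks, so
  the dense-matrix guard is the practical size limit.
* One quantitative trait; the multi-trait generalization is a loop the
  package deliberately does not hide behind its interface.
* Raw p-values by default (as a plain `p < 0.05` rule implies); enable
  `pAdjust = "BH"` when screening many modules.
* The dynamic cut is a native variant: on real data its module boundaries
  will differ in detail from other implementations even when both recover
  the same planted structure.
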