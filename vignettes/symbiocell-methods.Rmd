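---
title: "Methods: single-cell inference for cnidarian-algal symbiosis"
author: "symbiocell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell inference for cnidarian-algal symbiosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Facultatively symbiotic corals can live with or without their intracellular
dinoflagellate symbionts, which makes paired symbiotic/aposymbiotic samples
of the same host genotypes possible. When such samples are profiled by
droplet single-cell RNA-seq against a *concatenated* host + symbiont
reference, every cell's UMI counts split between the two genomes. That
split carries biology: a small minority of gastrodermal cells is dominated
by symbiont reads (the algal-hosting cells), while host-side expression
differences between states concentrate in particular gastrodermal cell
populations rather than in immune cells.

`symbiocell` implements the inference stack this design needs:

1. dual-genome read partitioning and algal-hosting cell classification;
2. standard normalization / variable-gene / PCA / shared-nearest-neighbor
   (SNN) clustering of the host-side counts;
3. per-cell gene-set read-fraction scoring and rank-based (Mann–Whitney U)
   GO enrichment;
4. the per-PC ANOVA "driver gene" procedure: recluster one cell cluster,
   test each principal component for separation by symbiotic state, and
   extract, annotate and DE-cross-reference the top loading genes;
5. marker-trio co-expression scoring;
6. the cross-species differentially-expressed-ortholog (DEO) comparison;
7. small phenotype computations (absorptance from reflectance,
   surface-area-normalized symbiont densities, Kruskal–Wallis contrasts).

Everything is verifiable offline against a synthetic dual-genome generator
with planted ground truth.

# Models and procedures

## Symbiont partition

For cell $i$ the symbiont read fraction is
$f_i = \sum_{g \in \text{symbiont}} c_{ig} / \sum_g c_{ig}$, computed on
the full dual-genome matrix before any host-gene subsetting. A cell is
called *algal-hosting* when $f_i > 0.5$ — strictly over one half, so the
boundary value is not hosting. The hosting cluster is the cluster holding
the most hosting cells (ties break to the lower label and are reported).
Fractions are ratios of integer counts, so they are invariant under
uniform rescaling of a cell's counts, and per-origin fractions sum to 1.

## Embedding and clustering

The host-side pipeline is the field-standard sequence, with each step an
explicit, separately tested function:

* `lognormalize()`: $x_{ig} = \ln(1 + 10^4\, c_{ig} / \sum_g c_{ig})$.
* `select_hvg()`: per-gene variance of the normalized values divided by a
  loess mean–variance trend on log scale; the top genes by this
  standardized variance are kept (ties break by gene id, so selection is
  deterministic). Constant genes rank last.
* `scale_clip()`: per-gene z-scores using the **population** (denominator
  $n$) standard deviation, truncated at $\pm 10$. Zero-variance genes map
  to 0 rather than NaN. The population/sample choice only rescales each
  gene by $\sqrt{n/(n-1)}$ and is irrelevant downstream; it is fixed here
  and covered by tests.
* `run_pca()`: eigendecomposition of the smaller Gram matrix of the
  centered, scaled matrix (equivalent to a truncated SVD). Component signs
  are fixed so each loading column's largest-magnitude entry is positive,
  making the decomposition reproducible. `variance_explained` is the
  proportion of total variance and is non-increasing.
* `snn_cluster()`: exact k-nearest neighbors (default $k = 20$; the
  reference toolchain leaves this parameter unstated, so the default is
  logged) on the first `n_dims` PC scores; neighbor sets include the cell
  itself; edges are reweighted by Jaccard similarity of neighbor sets and
  pruned below $1/15$; communities are found by Leiden with the modularity
  objective at the given resolution (0.55 for the full dataset, 0.25–0.5
  for subsets). Labels are renumbered by decreasing cluster size, and the
  community search runs under a fixed, logged seed.

Cross-sample integration: the reference analysis used CCA anchor
integration; `symbiocell` instead embeds the merged matrix with a joint
PCA. This is sufficient here because every downstream inference
(per-cluster ANOVA, DE) re-embeds per-cluster subsets without integration,
and it avoids re-implementing anchor heuristics none of the bespoke
statistics depend on. The stage is pluggable: any cells × dims embedding
can be passed on to `snn_cluster()`.

`find_markers()` is a Wilcoxon rank-sum test of each gene (cluster vs
rest) restricted to genes whose $|\log_2$ fold change of expm1-mean
expression (pseudocount 1)$| \ge 0.5$, BH-adjusted within the tested set.
The rank-sum statistic uses the normal approximation with tie correction
and no continuity correction; `wilcox.test(exact = FALSE,
correct = FALSE)` reproduces it and serves as the oracle in the tests.

## Gene-set read fractions and MWU GO enrichment

`cell_geneset_fraction()` is the gene-set analogue of the symbiont
fraction: the share of a cell's reads falling in a supplied set (for
example, all genes annotated with immune GO terms of interest), with
strict ">" flagging at 4.5% by default. Fractions are computed on the
host-side matrix by default (the reference analysis subsets to host genes
before this step; the choice is configurable because the quoted
description leaves it open).

`mwu_go_enrichment()` takes one finite score per gene — conventionally the
signed log-p of a state contrast, $-\log_{10}(p)\,\mathrm{sign}(\log_2
\mathrm{FC})$, configurable to the LFC itself — and tests, per term,
whether member genes rank differently from non-members (two-sided
Mann–Whitney U, tie-corrected normal approximation, BH across terms, FDR
0.1). Because only ranks enter, results are invariant to strictly monotone
transforms of the scores. Terms are taken as given (no GO-graph rollup):
the term lists this procedure is used with are supplied explicitly.

## Per-PC state separation (driver genes)

For one cell cluster, `recluster_subset()` re-selects variable genes,
rescales, re-runs PCA (30 dims by default, 20 for small clusters) and
finds subclusters at resolution 0.25–0.5. `pc_state_anova()` then fits a
one-way ANOVA of each of the first 10 PC scores on the two-level state
factor; a PC separates states when $p < 0.05$. Each PC is judged at face
value — no multiplicity correction across the 10 PCs — matching the
reference procedure; the threshold is configurable. The ANOVA uses
per-cell scores, not subcluster means, as the procedure asks whether *the
cells* separate.

`top_loading_genes()` takes the 10 largest-positive and 10
most-negative loading genes per significant PC (ordered by $|loading|$,
gene-id tiebreak; fewer available genes are returned with a warning).
`build_driver_report()` unions drivers over significant PCs (a gene
driving several PCs appears once with all PCs listed), removes genes
without a Pfam domain annotation, joins DE status at adjusted $p < 0.05$,
and tags immune-GO and COG "posttranslational modification, protein
turnover, and chaperones" membership. The report's containment invariants
(DE drivers ⊆ drivers ⊆ Pfam-annotated genes) are tested.

## Differential expression between states

`de_between_states()` is a minimal per-gene negative-binomial Wald test on
raw counts:

* size factors by median-of-ratios, robust to zeros: gene geometric means
  are taken over positive counts, and each cell's factor is the median
  ratio over its positive genes, normalized to geometric mean 1;
* gene-wise dispersion $\alpha_g$ by method of moments on size-factor
  normalized counts, $\hat\alpha_g = \max\{(v_g - m_g\overline{1/s}) /
  m_g^2,\ 10^{-8}\}$, no shrinkage;
* the contrast is $\log_2$ of normalized group means with pseudocount 0.1,
  and the Wald z uses the delta-method variance of the log ratio under
  $\mathrm{Var}(K) = \mu + \alpha\mu^2$;
* BH adjustment across genes; all-zero genes are dropped and counted.

This is deliberately the smallest NB test with the same null as the
heavyweight tools; a test cross-checks it against DESeq2 on the planted
effect cluster (LFC correlation > 0.9 and concordant recovery of the
planted gene set), and `method = "wilcox"` bounds sensitivity to the NB
model. A pseudocount keeps LFCs finite when one group is all zeros.

## Co-expression

`scale_max()` rescales a nonnegative per-cell expression vector to a
maximum of 10 (all-zero vectors pass through, avoiding 0/0); it is
idempotent on its own output. `coexpression_score()` applies it per gene
over a marker set and summarizes joint expression per cell by the
**minimum** across the set — a cell scores high only if it expresses every
member — with the mean emitted alongside as the softer alternative. The
reference analysis only overlays colors; the minimum is this package's
explicit summary of "co-expressed in the same cell", and both summaries
are written so neither is load-bearing.

## Cross-species DEO comparison

DE gene lists from two species are projected through an ortholog table
(`map_orthologs()`; genes without orthogroups are dropped and counted),
partitioned into shared / unique-to-A / unique-to-B orthogroup sets
against a common background (`venn_partition()`, sizes reported), and each
group is tested per GO term with a two-sided Fisher exact test
(`fisher_enrichment()`): hypergeometric enumeration summing all table
probabilities not exceeding the observed one, BH across terms. The
background defaults to all orthogroups in the table — the reference
analysis does not state its background, so it is explicit and
configurable here. The odds ratio is the sample estimate (0.5 continuity
correction on zero cells), not the conditional MLE.

## Phenotype metrics

Absorptance is $A = 1 - R$ per wavelength; $A_{675}$ (the chlorophyll-a
peak) is read at the measured wavelength nearest 675 nm (no
interpolation), and PAR-mean reflectance is the unweighted mean of $R$
over 400–700 nm. Symbiont densities are compared as a plain ratio of
group means (`density_fold_change()`) and by the Kruskal–Wallis rank-sum
test (`rank_sum_compare()`, tie-corrected H, $\chi^2_1$ p-value for two
groups).

# The synthetic generator

`sim_config()` / `generate_dataset()` emulate the study conditions:

* two samples (symbiotic, aposymbiotic), 3,000 cells each by default;
* 2,000 host + 300 symbiont genes; six clusters with equal mixing
  proportions (~500 cells per state per cluster);
* per-gene log-normal baseline abundances, with a disjoint 40-gene marker
  block per cluster up-regulated $2^2$-fold so clusters are separable;
* log-normal library sizes (median 2,500 UMIs, log-sd 0.35) and
  negative-binomial counts with a single global size parameter 2
  (variance $\mu + \mu^2/2$), the standard droplet scRNA-seq noise model;
* an *effect* cluster whose symbiotic-state cells multiply a 40-gene
  immune set by $2^{-1.5}$ and a 10-gene nutrient-cycling marker set by
  $2^{+1.5}$, applied to the mean profile without renormalization so the
  planted fold changes are exact on the mean scale;
* a *null* cluster whose two states are identical in distribution;
* *hosting* cells among the symbiotic-state cells of one cluster: each
  draws a symbiont read share from Beta(70, 30) left-truncated at 0.6 and
  has that share of its expected library reallocated to the symbiont
  genes (a fixed sequencing budget splits between genomes; depth is not
  inflated). An algal-hosting cell is by definition symbiont-dominated,
  so the truncation keeps the planted truth self-consistent and the
  per-cell fractions bimodal — hosting near 0.7, everything else at the
  near-zero background leak (default $10^{-4}$, configurable; background
  symbiont expression in non-hosting cells is not reported by reference
  data, so near-zero is the default);
* flagged doublets (2%), formed by summing two uniformly chosen cells'
  counts — they are flagged, never silently injected, mirroring a
  pipeline that consumes an external doublet caller's calls;
* optional planted low-coverage cells for QC tests.

Identical configurations (including the seed) produce bit-identical
datasets and fixtures on disk.

What the generator does **not** emulate: transcriptome-wide co-expression
structure beyond the planted blocks, ambient RNA, UMI duplication,
batch/genotype effects, or compositional interactions between clusters.
Passing tests therefore demonstrate that the inference machinery recovers
planted signals under idealized NB noise — not that it is robust to every
artifact of real droplet data.

# Numerical choices and degenerate inputs

* QC filtering sweeps the gene filter (detected in ≥ 3 cells) and cell
  filter (200–3,000 detected genes) repeatedly to a fixed point, so the
  operation is idempotent; "expressed/detected" means count ≥ 1, and
  detected-gene windows count host and symbiont genes jointly (filtering
  precedes host-gene subsetting). The gene filter runs first within each
  sweep; the order is configurable.
* Strict inequalities at the 0.5 and 0.045 fraction thresholds ("over").
* Zero-total cells are an error naming the barcode, not a silent NaN.
* Zero-variance genes scale to 0; all-zero vectors pass `scale_max()`
  unchanged; ties break by ascending gene/cell identifier everywhere.
* PCA beyond the achievable rank is an error listing that rank.
* The pipeline derives per-stage seeds from the global seed by a stable
  hash of the stage name, so adding a stage never perturbs earlier ones.

# Problem sizes used in the checks

The packaged checks run the generator at the default scale (2 × 3,000
cells, 2,300 genes) for the ten-seed recovery study and at a reduced scale
(2 × 250–300 cells, ~460 genes) for unit tests; these sizes were chosen so
the planted effects sit comfortably above their detection thresholds
(≥ 150 cells per state in the effect cluster, 40 planted genes at
$|\mathrm{LFC}| = 1.5$) while the whole suite stays quick to run. The
ten-seed loop evaluates state separation on the planted cluster labels —
the quantities it measures are properties of the statistics given a cell
subset — while clustering recovery itself is verified separately
(adjusted Rand index ≥ 0.9 at default scale, ~0.999 in practice).

# Known limitations

* The NB Wald test uses method-of-moments dispersions without shrinkage;
  on very small groups it is noisier than shrinkage-based tools (the
  Wilcoxon alternative is provided).
* Joint PCA in place of anchor integration can leave residual
  sample-level structure in the full-dataset embedding when batch effects
  are strong; per-cluster inferences re-embed and are unaffected.
* Modularity-based community detection on kNN graphs can split large
  diffuse populations at high resolution; the resolution is a scientific
  choice, not an estimated quantity.
* GO term maps are taken as given; no parent-term propagation.
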