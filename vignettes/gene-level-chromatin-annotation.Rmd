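---
title: "Gene-level chromatin annotation with a mixture of HMMs: model, algorithm, and design notes"
author: "geneHMM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-level chromatin annotation with a mixture of HMMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geneHMM)
```

## The problem

Chromatin-state methods annotate the genome position by position from
binarized epigenomic tracks (histone-modification ChIP-seq, DNase
accessibility). Many analyses, however, are gene-centric: one wants a single
label per gene per cell type that summarizes the combinatorial *and* spatial
pattern of marks along the gene body and its flanks. Genes span two orders of
magnitude in length (median around 30 kb), so neither the state at the TSS
nor a length-confounded average of marks over the gene body is a satisfying
summary.

`geneHMM` models the binarized data of each gene (plus 2-kb flanks, in
200-bp bins, oriented 5′→3′) as generated by one of $M$ mixture components,
where each component is itself a fully connected hidden Markov model with
$S$ states and product-Bernoulli emissions over the $E$ marks. The
component posterior given a gene's data is, by construction, constant along
the gene, and the argmax yields one annotation per (gene, cell type).

## Model

Parameters, for components $m = 1..M$, states $s = 1..S$, marks
$e = 1..E$:

* initial probabilities $\tau_{m,s}$ over all $MS$ states
  ($\sum_{m,s}\tau_{m,s} = 1$); the component prior is
  $\pi_m = \sum_s \tau_{m,s}$;
* within-component transitions $\alpha_{ms,ms'}$, plus a per-state *exit*
  probability of ending the gene; each row satisfies
  $\sum_{s'}\alpha_{ms,ms'} + \mathrm{exit}_{m,s} = 1$;
* Bernoulli emission probabilities $\beta_{m,s,e}$; the probability of an
  observation row is $\prod_e \beta_{m,s,e}^{x_e}(1-\beta_{m,s,e})^{1-x_e}$.

The mixture is trained as a *single* HMM of $MS + 1$ states: a dummy state,
emitting only a dummy mark, separates consecutive genes in concatenated
per-(cell type, chromosome) input files. Transitions between states of
different components are structural zeros; the dummy row of the expanded
transition matrix carries the flattened $\tau$, and the dummy column the
exit probabilities. Multiple cell types are handled by concatenation: the
same gene in different cell types is treated as additional training
sequences, giving one common model with cell-type-specific assignments.

## Training

`initialize_model()` draws $\tau$ from a flat Dirichlet over all $MS$
states; sets emissions empirically (genes randomly assigned to components,
bins uniformly to states, then per-state observed mark frequencies, falling
back to the global mark frequency for a state that received no bins —
preferred over a constant 0.5 because it keeps the first E-step from
ranking components by an arbitrary constant); and draws each
within-component transition row from a flat Dirichlet rescaled to 0.95,
reserving 0.05 for the exit. The 0.95/0.05 split is the operative
initialization convention; the exit mass is exposed as `exit_prob` for
users who want a different prior on gene-end transitions.

`em_train()` runs Baum-Welch for a *fixed* number of iterations (default
200) with a fresh, seeded subsample of input files per iteration (default
100 files). There is no convergence threshold: with subsampling the
per-iteration log-likelihoods are computed on different data and are
recorded as-is, flagged non-comparable across iterations, and never used
for early stopping. Parameters that are exactly 0 or 1 at the start of
training are frozen, which preserves the cross-component structural zeros
and the dummy state/mark pinning through every M-step. Accumulators are
combined in a fixed file order, so results do not depend on any future
parallelization of the E-step.

### Numerical scheme

Long concatenated sequences with near-disjoint components underflow and
overflow a textbook implementation: the forward pass can be dominated by
one component and the backward pass by another, so scaling the backward
variables by the *forward* scale factors (the classic recipe) can overflow.
The package therefore:

* rescales forward variables by the per-position sum of forward variables;
* rescales backward variables independently by the per-position sum of
  backward variables;
* floors any scaled variable below $10^{-300}$ at $10^{-300}$, except a
  forward variable whose emission product is exactly zero, which stays
  zero so structural impossibilities remain impossible.

The floor is applied *after* scaling (the convention is not forced by the
algorithm; applying it after scaling keeps the floor's meaning independent
of the sequence's running scale, and it is what the test oracles verify).
Posteriors are renormalized per position. A sequence that is impossible
under the model raises an explicit error rather than dividing by zero. The
recursions are implemented in C++ (via Rcpp) and are checked in the test
suite against two independent references: exhaustive path enumeration on
small instances ($T \le 6$, $MS \le 8$, agreement to $10^{-8}$) and a pure
log-sum-exp forward pass on ~5,000-bin sequences (relative agreement to
$10^{-6}$).

## Assignment

`assign_all()` computes per-position state posteriors per file, sums them
within components, *asserts* (not assumes) that the component posterior is
constant along each gene to $10^{-9}$ — a violation indicates a leak in the
transition mask — and takes the argmax, breaking ties toward the lowest
component index (documented and tested; the choice is arbitrary but must be
fixed for determinism). Per-position state posteriors can be kept, with the
caveat that states are not comparable across components.

## Baselines

* **TSS**: each gene reduced to the single 200-bp bin overlapping its TSS
  (for negative-strand genes, the coordinate `end − 1` under half-open
  conventions), trained as an $M$-component, $S = 1$ mixture.
* **Gene average**: the main pipeline at $S = 1$ — literally the same code
  path, asserted by a test.
* **Collapsed**: the trained multi-state model with each component's states
  merged into one: emissions are state-prior-weighted means
  $\beta_{m',s',e} = \sum_s \pi_{m,s}\beta_{m,s,e}$, the collapsed initial
  probability is $\pi_m$, the self-transition $(x_m - n_m)/x_m$ and exit
  $n_m/x_m$, where $x_m$ counts bins and $n_m$ genes hard-assigned to
  component $m$. Usage counts are aggregated over *all* cell types and
  genes (matching the across-cell-types weighting of the emission
  average), and per-bin states are hard-assigned as the maximum-posterior
  state within the gene's assigned component. The collapsed model is never
  trained further; it isolates the value of spatial modeling from the
  choice of $M$.

## Data conventions

Coordinates are 0-based half-open internally (GTF input is converted on
read). The genomic start is rounded down and the genomic end up to bin
multiples — which realizes "round the TSS in the 5′ direction and the TES
in the 3′ direction" for both strands — then 2-kb flanks are added and the
interval is clamped to the chromosome (clamping at chromosome edges is this
package's choice; dropping edge genes would silently change the universe).
Negative-strand genes are row-reversed so row 1 is always the 5′ flank;
mark columns are never reordered. Overlapping genes are extracted
independently, repeating shared rows. Input files follow the two-header
binarized text dialect with an extra dummy-mark column; a manifest records
gene order and row ranges per file. The default chromosome allow-list is
autosomes plus X (configurable); component labels are 1-based integers.

## Evaluation statistics

All statistics consume hard assignment matrices and are interchangeable
across the main model and baselines:

* **Expression prediction** (leave-one-chromosome-out): per annotation, the
  training-gene median of $\log_{10}(\mathrm{RPKM} + 0.1)$ predicts
  held-out genes; AUROC for expressed (RPKM ≥ 1) vs unexpressed genes uses
  a rank-based (Mann-Whitney) estimator with midrank tie handling — the
  estimator is not dictated by the definition, so the all-pairs count is
  kept as an oracle in the tests. MSE and Pearson r are pooled over folds.
* **Method comparison**: a one-sided binomial test on the number of cell
  types where one method's metric strictly beats the other's; ties count
  for the null (the conservative reading of "how often higher").
* **Mutual information with gene length**: $\log_{10}$ length binned at
  0.05; MI reported in bits (the base is a convention; bits are stated
  explicitly everywhere).
* **Confusion / contingency**: row-stochastic conditional matrices over
  designated replicate pairs and over all other unordered pairs, both
  orientations accumulated (so the underlying joints are symmetric);
  cell-type specificity is $1 - \mathrm{contingency}_{ii} /
  \mathrm{confusion}_{ii}$.
* **Co-assignment enrichment**: observed co-assignment frequencies over
  non-replicate pairs, normalized to sum 1, divided by the independence
  expectation $\pi_i\pi_j$, reported as $\log_2$; never-observed cells are
  reported missing with their counts attached rather than as $-\infty$.
* **Gene-set enrichment**: upper-tail hypergeometric p per cell type;
  fold = mean over cell types of the set proportion assigned to the
  component, divided by the component prior; the Bonferroni multiplier is
  caller-supplied because the correction universe legitimately differs
  between analyses (sets × annotations, optionally × cell types).
* **Random-split comparison**: significant-set counts for the true
  annotation split versus size-matched random splits of the tested genes,
  keeping the minimal expression-ordered annotation subset covering ≥ 75%
  of tested genes.
* **Variance permutation test**: mean within-annotation variance of
  per-cell-type median expression against count-preserving shuffles; the
  p-value counts permutations with a statistic *not exceeding* the
  observed one (non-strict, so a degenerate all-equal input yields p = 1
  rather than 0), and p = 0 is reported as "< 1/n_perm".
* **pLI analysis**: per-annotation high-pLI (≥ 0.9) proportions over
  (gene, cell type) entries; a gene-length-normalized version over 15 bins
  of $\log_{10}$ length on [3, 6] (genes outside 1 kb–1 Mb discarded)
  weighted by the all-gene length density; high-pLI proportion and mean
  pLI across 30 expression bins on $\log_{10}(\mathrm{RPKM}+0.1) \in
  [-1, 2]$; Spearman correlations per cell type.
* **Hyperparameter metrics**: replicate reproducibility (confusion
  diagonal mass) and the mean closest-state Manhattan distance between
  emission vectors within components (undefined at $S = 1$).
* **Assignment distances**: $d(i,j) = 1 - \mathrm{mean}_c\,
  \mathbb{I}(m_{i,c} = m_{j,c})$ on a seeded gene subsample, suitable for
  UPGMA clustering.

## The synthetic-data generator

Every fixture in the package is generated in code; nothing is downloaded.
`sample_ground_truth_model()` draws components with distinct mark
signatures (random active subsets emitted at 0.75–0.95, inactive marks at
0.02–0.10, sticky transitions) and rejection-samples until all component
pairs differ by at least the requested L1 separation between mean
emissions. `simulate_dataset()` lays genes on synthetic chromosomes with
log-normal lengths (median 30 kb, clamped to 2–60 kb — the scale of real
protein-coding genes without the multi-megabase tail), draws one true
component per (gene, cell type) with replicate cell types copying their
partner's label at a configurable concordance (default 0.9, the order of
observed replicate agreement in real epigenomes), simulates the component
HMM over the extended bins, and flips each observation with probability
0.02 (the default noise level of the study conditions). A single integer
seed is split deterministically across all draws, so fixtures are
bit-reproducible. `simulate_covariates()` links expression (per-component
log-normals), pLI (per-gene, from the modal component's high-pLI rate),
and planted gene sets (odds-ratio over-sampling of a target component) to
the true labels.

What the generator does *not* emulate: mark-specific autocorrelation beyond
what the HMM induces, imputation artifacts, copy-number or mappability
structure, and genuinely overlapping genes. Passing recovery tests on these
fixtures therefore demonstrates correctness of the estimation machinery —
not that real epigenomes satisfy the model.

## Problem sizes and defaults

The default fixture is 500 genes × 4 cell types (one replicate pair), 6
marks, $M = 4$ components × $S = 2$ states, separation 2.0, flip noise
0.02 — small enough to train in about two minutes on one core while leaving
component recovery unambiguous. The recovery gates on this fixture
(assignment agreement ≥ 95% up to relabeling, per-parameter emission error
< 0.05) are the package's primary end-to-end checks. The test suite uses a
smaller 90-gene fixture for module-level properties. Defaults elsewhere
mirror the study conventions: bin 200 bp, flank 2 kb, $M = 12$, $S = 3$,
200 EM iterations, 100-file subsamples.

## Known limitations

* Emissions are Bernoulli products only; no Gaussian or negative-binomial
  variants.
* Baum-Welch with a fixed iteration count inherits EM's local-optimum
  sensitivity; different initialization seeds can land on different (label
  permutations of) solutions.
* The per-bin state track is exposed but states are not comparable across
  components and are not used by any evaluation here.
* Flip noise is not modeled during estimation, so recovered emissions
  converge to the noise-attenuated values $\beta(1-2\varepsilon) +
  \varepsilon$; at the default $\varepsilon = 0.02$ this stays within the
  recovery tolerance.
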