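---
title: "Methods: sequence encodings, the stacked autoencoder, and the evaluation protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence encodings, the stacked autoencoder, and the evaluation protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppisae)
```

# The problem and the model

`ppisae` predicts whether two proteins physically interact using nothing
but their amino-acid sequences. The pipeline has three parts: a
fixed-length encoding of each protein, a scaling-and-concatenation step
that turns two protein vectors into one pair input, and a stacked
autoencoder (SAE) classifier. Around these sits a dataset-construction and
cross-validation protocol of the kind used for interaction benchmarks
derived from curated human interactome data.

The central modelling assumption is that interaction propensity leaves a
detectable statistical trace in sequence composition — in the periodicity
of physicochemical properties (captured by autocovariance) or in the local
3-residue vocabulary over a reduced alphabet (captured by conjoint
triads). This is an approximation: interaction is a property of pairs in
structural context, and sequence-level encodings of the two partners
cannot represent binding interfaces explicitly. The method should be read
as learning statistical regularities of interacting pairs under a given
benchmark's sampling scheme, which is also why careful negative-set
construction and redundancy control matter so much (see "Known
limitations").

## Autocovariance encoding

Each residue is mapped to seven physicochemical descriptor values
(hydrophobicity, hydrophilicity, net charge index of side chains,
polarity, polarizability, solvent-accessible surface area, side-chain
volume). The packaged table (`ac_descriptors()`) ships raw values; each
descriptor row is standardized to zero mean and unit variance *across the
20 residues* so descriptors on different scales contribute comparably.
For descriptor $j$, sequence length $n$ and offset $lag$:

$$AC_{lag,j} = \frac{1}{n-lag} \sum_{i=1}^{n-lag}
  (X_{i,j}-\bar X_j)(X_{i+lag,j}-\bar X_j),$$

where $\bar X_j$ is the mean descriptor value over the whole sequence.
The centering term is the sequence *mean*, not the raw sum: only with the
mean does the statistic behave as a covariance, vanish identically on
homopolymers, and stay invariant under sequence reversal — properties the
test suite asserts, alongside equality with a naive double-loop oracle.
With the default `lag_max = 30` (the conventional choice in the AC
lineage; configurable) a protein becomes a 210-vector, so sequences must
be longer than 30 residues. Shorter sequences raise an error naming the
offender rather than silently padding.

## Conjoint-triad encoding

The 20 amino acids are clustered into seven groups by dipole moment and
side-chain volume ({A,G,V}, {I,L,F,P}, {Y,M,T,S}, {H,N,Q,W}, {R,K},
{D,E}, {C}; `ct_groups()`, overridable by a two-column TSV). The sequence
is rewritten in this alphabet and a 3-residue window slides one step at a
time; triad $(a,b,c)$ maps to feature $a + 7(b-1) + 49(c-1)$, the first
position varying fastest, giving a 343-vector whose entries sum to
$n-2$.

The encoding stores **raw window counts**. Whether these counts should be
further normalized per protein before pair assembly is genuinely open in
this method family; the package's decision is to keep counts raw (so the
worked example `MREIVHIQAG` → `3562142411` with its eight unit counts is
exactly reproducible) and to delegate all scaling to the dataset-level
min–max scaler described next. The practical difference is small because
the scaler maps every feature into $[0,1]$ anyway; the main consequence is
that long proteins carry proportionally larger raw counts, which the
min–max map preserves monotonically.

## Pair assembly and scaling

A per-feature min–max scaler is fitted **on training proteins only** and
applied to both members before concatenation (420 or 686 inputs). Values
outside the training range are clipped to $[0,1]$. Two reasons: sigmoid
units saturate outside a bounded input range, and fitting the scaler per
cross-validation fold keeps test information strictly out of training —
the cross-validation driver refits it for every fold. Pairs are encoded in
the order given in the pair file; the classifier is not symmetrized by
default. Training with both orientations as augmentation is possible by
duplicating rows in the pair list, but is not the default because the
benchmarks this protocol mirrors store each pair once in a fixed order.

## The stacked autoencoder

Architecture `[d, h₁, ..., 2]` with logistic sigmoid activations
throughout and a 2-class softmax head. Training proceeds in the classical
two phases:

1. **Greedy layer-wise pretraining.** Each layer's encoder/decoder pair
   $(W^{(1)}, b^{(1)}, W^{(2)}, b^{(2)})$ minimizes mean squared
   reconstruction error of its input through
   $f(W^{(2)} f(W^{(1)}x+b^{(1)})+b^{(2)})$, by mini-batch gradient
   descent with momentum. Decoder weights are *untied* from encoder
   weights and are kept on the layer afterwards only for inspection.
2. **Supervised fine-tuning.** The encoder stack plus softmax head
   minimizes cross-entropy with backpropagation, again with mini-batch
   momentum descent, batch order reshuffled every epoch under the run
   seed.

Plain reconstruction is used in pretraining — no denoising corruption or
sparsity penalty. That is the simplest member of the SAE family and the
natural default when the available evidence does not specify otherwise;
the fine-tuning phase dominates final accuracy at this scale anyway.

Defaults (all exposed via `sae_control()`): learning rate 0.5 for
pretraining and 0.1 for fine-tuning, momentum 0.5, batch size 100, 20
pretraining epochs per layer, 50 fine-tuning epochs. These are standard,
stable settings for sigmoid autoencoders with inputs in $[0,1]$ at this
problem size; the higher pretraining rate is safe because the
reconstruction loss is smooth and bounded, while fine-tuning uses a
smaller rate to avoid destroying pretrained features. The default
architecture is one hidden layer of 400 units for AC input and 700 for CT
— in this method family one medium hidden layer is consistently
sufficient, and `architecture_sweep()` reproduces that observation on the
synthetic benchmark (a 1-unit bottleneck scores measurably worse).

Numerical choices worth recording:

* Weight initialization: uniform on $\pm 4\sqrt{6/(fan_{in}+fan_{out})}$
  (the classical sigmoid scale); softmax head zero-initialized, so an
  untrained model outputs exactly (0.5, 0.5).
* Softmax is computed with row-max subtraction; cross-entropy clamps
  probabilities at 1e-300 before the log. Non-finite epoch losses abort
  with the epoch number.
* Class-label ties at probability exactly 0.5 predict the negative
  (non-interaction) class, a documented, tested convention.
* All randomness (initialization, batch order, splits, sampling) flows
  from integer seeds through one splitting function, making every fit
  bitwise reproducible; model JSON stores 17 significant digits so a
  save/load round trip reproduces predictions bitwise.
* Analytic gradients of both objectives are checked against central
  finite differences (`sae_gradient_check()`); the suite requires
  relative discrepancy below 1e-6 on toy models.

# Dataset construction

`filter_proteins()` applies the usual benchmark hygiene: only the 20
standard residues, minimum length 50 (shorter entries often represent
fragments), and — when compartment labels are required — exactly one
unambiguous subcellular location (annotations containing "potential",
"probable", "maybe", "by similarity", or multiple semicolon-separated
locations are dropped, each removal logged with its rule).

`sample_negatives()` draws unique unordered cross-compartment pairs
uniformly, excluding self-pairs and any supplied positive pair. The
assumption — proteins confined to different compartments do not interact —
is the standard negative-construction heuristic when true non-interactions
are unobservable; its known cost is a compartment-composition confound
discussed under limitations.

`pairwise_identity()` is a global Needleman–Wunsch alignment (BLOSUM62,
affine gaps open 10 / extend 0.5, end gaps penalized) with identity
defined as identical aligned residues over the full alignment length
including gap columns. Arguments are canonically ordered before aligning
so the function is exactly symmetric even when co-optimal alignments
exist. The redundancy filter `remove_redundant()` removes a test pair
when **either** member reaches the identity threshold (default 0.25)
against **any** training protein. The pair-level alternative (both members
redundant) is defensible, but the either-member rule is the conservative
choice for leakage control and is the package's default; the threshold and
alignment parameters are exposed.

`make_folds()` produces stratified folds (global fold sizes differ by at
most one, per-fold class counts within one of the global ratio) —
stratification stabilizes per-fold metrics on balanced data at no cost.
`holdout_split()` is a plain uniform split. Both are deterministic under
seeds.

# The synthetic benchmark

`synth_benchmark()` generates the study conditions used throughout the
tests: a proteome of i.i.d. sequences (uniform residue frequencies,
lengths uniform on 50–150) over six compartments, with `n_pos = n_neg =
1000` labeled pairs by default. The interaction signal is **motif
co-insertion**: with probability `signal_strength`, a positive pair
receives a complementary 12-mer pair (`KWKWKWKWKWKW` into the first
member, `ECECECECECEC` into the second) at uniformly random positions,
never splitting a previously planted motif. These motifs perturb both
triad counts and descriptor autocovariance simultaneously, so both
encodings can detect them; compartment labels are independent of sequence
content, keeping the compartment–label confounder out of the features.

Two structural decisions matter for interpreting results:

* **Pairs form a disjoint matching** — each protein belongs to at most
  one pair (the default proteome of 4,000 proteins supports the 2,000
  default pairs). Real interactomes are the opposite: hub proteins appear
  in many pairs, which lets a classifier partially memorize protein
  identity across cross-validation folds instead of learning sequence
  signal. The generator removes that shortcut by construction, so its
  null calibration is clean: at `signal_strength = 0` nothing
  distinguishes the classes and the pipeline sits at chance accuracy,
  while at full signal the default AC pipeline exceeds 90% mean 10-fold
  CV accuracy (both asserted in the acceptance tests, together with
  monotonicity in between).
* Negative pairs are still cross-compartment (by compartment
  interleaving), exercising the same code path as real negative
  construction.

What the generator does **not** emulate: homology structure (except for
deliberately planted homolog fixtures in the redundancy-filter tests),
hub/degree structure, realistic residue composition, and any biophysics
of binding. Passing the synthetic recovery tests therefore demonstrates
that the implementation can extract a sequence-borne pair signal under a
controlled null — it does not certify accuracy on real interactomes,
whose headline numbers depend on large curated datasets outside this
package's scope.

# Problem sizes and runtime

The test suite trains small models (tens of hidden units, a few epochs)
everywhere except the end-to-end recovery checks, which run the default
2,000-pair benchmark with the default `[420, 400, 2]` architecture
twice (full signal and null). On one CPU core the full suite completes in
a few minutes; `scripts/acceptance.R`, which recomputes the exact
conjoint-triad reference quantities, runs in seconds.

# Known limitations

* Location-based negatives make the negative class systematically easier
  than "random non-interacting pairs"; reported specificity on such
  benchmarks is optimistic.
* Per-protein encodings cannot represent interface complementarity;
  two-protein context enters only through concatenation.
* The identity filter controls sequence redundancy, not network leakage
  (shared hub partners between train and test pairs).
* Only binary classification is supported — no interaction-strength
  regression, no ROC/AUC reporting.
* The descriptor table and cluster map are the conventional ones of the
  AC/CT lineages; correctness of downstream code is anchored by
  dimensional and analytic property tests, not by the specific descriptor
  values, and both tables can be overridden by config files.
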