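# ppisae

Sequence-based prediction of protein–protein interactions (PPIs) with
stacked autoencoders, in R.

Most proteins act through physical interactions, but experimentally mapped
interactomes remain incomplete and noisy. `ppisae` implements a
classification pipeline that decides, from amino-acid sequence alone,
whether a protein pair interacts. It is aimed at computational biologists
who want a transparent, fully reproducible reference implementation of this
family of methods — every stage, from sequence encoding to the neural
classifier's backpropagation, is implemented in the package and covered by
tests, with no machine-learning framework behind it.

## The method

**Encoding.** A protein of length *n* is mapped to a fixed-length vector by
one of two classical schemes:

* *Autocovariance (AC).* Each residue is replaced by seven standardized
  physicochemical descriptor values (hydrophobicity, hydrophilicity, net
  charge index of side chains, polarity, polarizability, solvent-accessible
  surface area, side-chain volume). For descriptor *j* and positional offset
  *lag*,

  AC(lag, j) = 1/(n − lag) · Σᵢ (X[i,j] − X̄ⱼ)(X[i+lag,j] − X̄ⱼ),

  for lag = 1…30, giving 7 × 30 = 210 features per protein regardless of
  length.

* *Conjoint triad (CT).* The 20 amino acids are clustered into seven groups
  by dipole and side-chain volume; the sequence is rewritten in this
  7-letter alphabet and every 3-residue window is counted, giving 7³ = 343
  features. The triad (a, b, c) maps to feature index
  a + 7(b−1) + 49(c−1).

The two members of a pair are min–max scaled (scaler fitted on training
data only) and concatenated: 420 (AC) or 686 (CT) inputs.

**Classifier.** A stacked autoencoder (SAE): each hidden layer is first
pretrained unsupervised to reconstruct its input through an untied decoder
(sigmoid activations, mean-squared reconstruction error), then the whole
encoder stack plus a 2-class softmax head is fine-tuned with
backpropagated cross-entropy, using mini-batch gradient descent with
momentum. The default architecture is one hidden layer of 400 units for AC
input (700 for CT). Analytic gradients are validated against central finite
differences by `sae_gradient_check()`.

**Protocol.** Benchmark-style dataset construction is included: length and
alphabet filtering, negative pairs sampled across subcellular compartments
(proteins confined to different compartments are assumed non-interacting),
hold-out splits, removal of test pairs with ≥25 % global-alignment identity
to training proteins (Needleman–Wunsch, BLOSUM62), and stratified k-fold
cross-validation reporting accuracy, sensitivity, specificity and precision.

A synthetic-data generator (`synth_benchmark()`) plants a tunable
motif-co-occurrence signal into random proteomes so the entire pipeline can
be exercised and calibrated without any external downloads.

## Worked example

```r
library(ppisae)

# a synthetic benchmark: 200 interacting pairs carrying a planted motif
# signal, 200 cross-compartment negatives, one protein per pair
cfg   <- synth_config(n_proteins = 400, n_pos = 100, n_neg = 100, seed = 42)
bench <- synth_benchmark(cfg)

feats <- encode_proteins(bench$proteins, "AC")   # 400 x 210 feature matrix
cv <- cross_validate(bench$pairs, feats, hidden = 100,
                     control = sae_control(batch_size = 20,
                                           pretrain_epochs = 10,
                                           finetune_epochs = 60),
                     k = 5, seed = 42)
print(cv)
#> 5-fold cross-validation, hidden layer(s) [100]
#>      accuracy specificity sensitivity precision
#> mean   0.9800      0.9700      0.9900    0.9723
#> sd     0.0209      0.0447      0.0224    0.0409
```

The classifier recovers the planted interaction signal almost perfectly:
98 % of held-out pairs are labeled correctly, with sensitivity (fraction of
true interactions found) 0.99 and specificity (fraction of non-interactions
recognized) 0.97. Regenerating the benchmark with `signal_strength = 0`
drops accuracy to chance (~0.5), confirming that the model finds signal
exactly when one exists.

The classical worked encoding example is exact:

```r
cluster_sequence("MREIVHIQAG")   # "3562142411"
which(encode_ct("MREIVHIQAG") > 0)
#>   f4  f13  f23  f71  f89 f149 f158 f276
#>    4   13   23   71   89  149  158  276
```

A command-line wrapper with `synth`, `encode`, `build-dataset`, `train`,
`crossval`, `predict` and `evaluate` subcommands is installed at
`inst/scripts/ppisae`; file formats are documented in `FORMATS.md`.

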