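# File formats

All files are plain text. Column order is fixed as documented; all tabular
files are tab-separated unless noted.

## FASTA (input)

Standard multi-record amino-acid FASTA; wrapped lines and lower-case
residues are accepted. The record id is the first whitespace-delimited
token of the header. Sequences must use the 20 standard one-letter codes
(U, X, B, Z, ... are rejected unless reading with `strict = FALSE` for
subsequent filtering).

## Pair list (`pairs.tsv`)

Columns: `idA`, `idB`, `label` (1 = interaction, 0 = non-interaction),
optional `split` (`pretrain` | `holdout` | `nr_test` | `external`).
A header line `idA<TAB>idB<TAB>...` is written on output and auto-detected
on input.

## Localization table (`localization.tsv`)

Columns: `id`, `compartment`. Multiple annotations may be encoded as
semicolon-separated values; such proteins are dropped by
`filter_proteins()` when a unique location is required.

## Descriptor table (`inst/extdata/ac_descriptors.tsv`)

First column `descriptor` (7 rows), then one column per residue
(A C D E F G H I K L M N P Q R S T V W Y). Values are raw; the package
standardizes each row to zero mean / unit variance across residues.

## Cluster map (`inst/extdata/ct_groups.tsv`)

Columns: `residue`, `group` (1..7). Must cover all 20 residues with
exactly seven non-empty groups.

## Feature matrix (`ppisae encode` output)

`#`-prefixed header lines record format name, scheme (AC/CT), lag, matrix
dimensions, scaler provenance, seed and config hash. Then a tab-separated
table: `idA`, `idB`, `label`, followed by 420 (AC) or 686 (CT) feature
columns named `A_<feature>` / `B_<feature>`, at full precision.

## Model file (`model.json`)

Self-describing JSON: `format` ("ppisae-model"), `version`, `layer_sizes`,
`activation`, `seed`, per-layer encoder/decoder weights and biases, softmax
head, encoding `scheme`, `lag_max`, and the fitted min–max `scaler`
(`min`, `range`). Numbers carry 17 significant digits, so a save/load round
trip reproduces predictions bitwise. A `<model>.manifest.json` written by
`ppisae train` records scheme, architecture, epochs, seed, CV accuracy and
a config hash.

## Metrics CSV (`crossval` / `train` output)

Comma-separated: `fold`, `TP`, `TN`, `FP`, `FN`, `accuracy`,
`specificity`, `sensitivity`, `precision`; one row per fold plus `mean` and
`sd` summary rows (summary rows carry metrics only).

## Predictions (`predict` output)

Tab-separated: `idA`, `idB`, `prob_interaction`, `predicted` (0/1, ties at
0.5 resolve to 0), `label` (copied from the input pair list).

## Splits / reports (`build-dataset` output)

`splits.tsv`: pair list with `split` column. `rejected.tsv`: `id`, `rule`
(`nonstandard_residue`, `min_length`, `missing_location`,
`ambiguous_location`, `multiple_locations`). `nr_removed.tsv`: `idA`,
`idB`, `test_id`, `train_id`, `identity` for every pair removed by the
redundancy filter.
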