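#' Apply benchmark-construction filters to a protein set
#'
#' Mirrors the criteria used to assemble sequence-based interaction
#' benchmarks: drop sequences with non-standard residues, sequences shorter
#' than `min_length` (short entries often represent fragments), and — when
#' compartment labels are required — proteins with missing, ambiguous
#' ("potential", "probable", ...) or multiple subcellular locations
#' (semicolon-separated annotations count as multiple).
#'
#' @param proteins A [protein_set()] (built with `strict = FALSE` if it may
#'   contain non-standard residues).
#' @param min_length Minimum sequence length kept (default 50).
#' @param require_unique_location Drop proteins without exactly one
#'   unambiguous compartment (default TRUE).
#' @return List with `kept` (filtered protein set) and `rejected` (data
#'   frame `id`, `rule` logging every removal).
#' @export
filter_proteins <- function(proteins, min_length = 50L,
                            require_unique_location = TRUE) {
  res <- standard_residues()
  ok_alpha <- grepl(paste0("^[", paste(res, collapse = ""), "]+$"),
                    proteins$seq)
  too_short <- nchar(proteins$seq) < min_length
  rej <- data.frame(id = character(0), rule = character(0),
                    stringsAsFactors = FALSE)
  add <- function(rej, mask, rule) {
    if (any(mask)) {
      rbind(rej, data.frame(id = proteins$id[mask], rule = rule,
                            stringsAsFactors = FALSE))
    } else {
      rej
    }
  }
  drop <- !ok_alpha
  rej <- add(rej, !ok_alpha, "nonstandard_residue")
  m <- ok_alpha & too_short
  rej <- add(rej, m, "min_length")
  drop <- drop | too_short
  if (require_unique_location) {
    comp <- proteins$compartment
    missing_loc <- is.na(comp) | !nzchar(comp)
    ambiguous <- !missing_loc &
      grepl("potential|probable|probably|maybe|by similarity", comp,
            ignore.case = TRUE)
    multiple <- !missing_loc & grepl(";", comp, fixed = TRUE)
    m <- !drop & missing_loc
    rej <- add(rej, m, "missing_location")
    m <- !drop & !missing_loc & ambiguous
    rej <- add(rej, m, "ambiguous_location")
    m <- !drop & !missing_loc & !ambiguous & multiple
    rej <- add(rej, m, "multiple_locations")
    drop <- drop | missing_loc | ambiguous | multiple
  }
  kept <- proteins[!drop, , drop = FALSE]
  if (nrow(kept) == 0L) {
    stop("all proteins were filtered out; review min_length/location settings")
  }
  rownames(kept) <- NULL
  list(kept = kept, rejected = rej)
}

# Canonical key of an unordered pair.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Sample non-interacting pairs across subcellular compartments
#'
#' Negative examples are built on the assumption that proteins confined to
#' different compartments do not interact: `n` unique unordered pairs are
#' drawn uniformly at random among all pairs whose members carry different
#' compartment labels, excluding self-pairs and any pair present in
#' `positives`.
#'
#' @param proteins A [protein_set()] with compartment labels.
#' @param n Number of negative pairs requested.
#' @param seed Integer seed.
#' @param positives Optional data frame (`idA`, `idB`) of known interactions
#'   to exclude.
#' @return Data frame `idA`, `idB`, `label` (all 0).
#' @export
sample_negatives <- function(proteins, n, seed = 1L, positives = NULL) {
  comp <- proteins$compartment
  if (any(is.na(comp))) stop("all proteins need a compartment label")
  if (length(unique(comp)) < 2L) {
    stop("need at least two distinct compartments to sample negatives")
  }
  n <- as.integer(n)
  if (n == 0L) {
    return(data.frame(idA = character(0), idB = character(0),
                      label = integer(0), stringsAsFactors = FALSE))
  }
  N <- nrow(proteins)
  tab <- table(comp)
  n_cross <- (N^2 - sum(tab^2)) / 2
  excl <- character(0)
  if (!is.null(positives) && nrow(positives) > 0) {
    key <- pair_key(positives$idA, positives$idB)
    cpA <- comp[match(positives$idA, proteins$id)]
    cpB <- comp[match(positives$idB, proteins$id)]
    excl <- unique(key[!is.na(cpA) & !is.na(cpB) & cpA != cpB])
  }
  avail <- n_cross - length(excl)
  if (n > avail) {
    stop("requested ", n, " negative pairs but only ", avail,
         " distinct cross-compartment pairs are available")
  }
  with_seed(derive_seed(seed, 3L), {
    if (n_cross <= 200000) {
      # enumerate all cross-compartment pairs and sample without replacement
      cmb <- utils::combn(N, 2L)
      cross <- cmb[, comp[cmb[1L, ]] != comp[cmb[2L, ]], drop = FALSE]
      keys <- pair_key(proteins$id[cross[1L, ]], proteins$id[cross[2L, ]])
      keep <- !(keys %in% excl)
      cross <- cross[, keep, drop = FALSE]
      pick <- sample.int(ncol(cross), n)
      ia <- cross[1L, pick]; ib <- cross[2L, pick]
    } else {
      seen <- c(excl)
      ia <- integer(0); ib <- integer(0)
      while (length(ia) < n) {
        need <- n - length(ia)
        ca <- sample.int(N, 2L * need + 10L, replace = TRUE)
        cb <- sample.int(N, 2L * need + 10L, replace = TRUE)
        ok <- ca != cb & comp[ca] != comp[cb]
        ca <- ca[ok]; cb <- cb[ok]
        keys <- pair_key(proteins$id[ca], proteins$id[cb])
        fresh <- !(keys %in% seen) & !duplicated(keys)
        ca <- ca[fresh]; cb <- cb[fresh]; keys <- keys[fresh]
        take <- seq_len(min(need, length(ca)))
        ia <- c(ia, ca[take]); ib <- c(ib, cb[take])
        seen <- c(seen, keys[take])
      }
    }
    data.frame(idA = proteins$id[ia], idB = proteins$id[ib], label = 0L,
               stringsAsFactors = FALSE)
  })
}

#' Pairwise global-alignment sequence identity
#'
#' Needleman-Wunsch global alignment (BLOSUM62, affine gaps: open 10,
#' extend 0.5 by default) of two amino-acid sequences; identity is the
#' number of identical aligned residues divided by the alignment length
#' including gap columns. Symmetric in its arguments.
#'
#' @param seqA,seqB Amino-acid sequences (character scalars).
#' @param gap_opening,gap_extension Affine gap penalties.
#' @param substitution_matrix Name of the substitution matrix (default
#'   "BLOSUM62").
#' @return Identity fraction in [0, 1].
#' @export
#' @examples
#' pairwise_identity("MREIVHIQAG", "MREIVHIQAG")  # 1
pairwise_identity <- function(seqA, seqB, gap_opening = 10,
                              gap_extension = 0.5,
                              substitution_matrix = "BLOSUM62") {
  seqA <- toupper(as.character(seqA)); seqB <- toupper(as.character(seqB))
  if (!nzchar(seqA) || !nzchar(seqB)) stop("empty sequence")
  if (seqA > seqB) {
    # canonical argument order: co-optimal tracebacks can differ between
    # (A,B) and (B,A), so fix the orientation to make the result symmetric
    tmp <- seqA; seqA <- seqB; seqB <- tmp
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seqA), Biostrings::AAString(seqB),
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_opening, gapExtension = gap_extension,
    type = "global")
  # alignedPattern() keeps end-gap columns, unlike pattern()
  aligned <- as.character(Biostrings::alignedPattern(aln))
  Biostrings::nmatch(aln) / nchar(aligned)
}

#' Remove hold-out pairs redundant with the training set
#'
#' A test pair is removed when either member protein has global-alignment
#' identity greater than or equal to `threshold` to any training protein —
#' a conservative rule that prevents evaluation on near-duplicates of
#' training material. Self-comparisons of a protein that appears in both
#' sets trigger removal (identity 1).
#'
#' @param test_pairs Data frame (`idA`, `idB`, ...).
#' @param test_proteins [protein_set()] resolving the test pair ids.
#' @param train_proteins [protein_set()] of training-side proteins.
#' @param threshold Identity threshold (default 0.25).
#' @param ... Passed to [pairwise_identity()].
#' @return List with `kept` (surviving pairs) and `removed` (data frame
#'   `idA`, `idB`, `test_id`, `train_id`, `identity` naming, for each removed
#'   pair, the protein match that triggered removal).
#' @export
remove_redundant <- function(test_pairs, test_proteins, train_proteins,
                             threshold = 0.25, ...) {
  test_ids <- unique(c(test_pairs$idA, test_pairs$idB))
  miss <- setdiff(test_ids, test_proteins$id)
  if (length(miss)) stop("test pair ids without sequences: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  # per-protein verdict cache: first training hit at/above threshold
  hit <- list()
  for (tid in test_ids) {
    s <- test_proteins$seq[match(tid, test_proteins$id)]
    hit[[tid]] <- NULL
    for (k in seq_len(nrow(train_proteins))) {
      idv <- pairwise_identity(s, train_proteins$seq[k], ...)
      if (idv >= threshold) {
        hit[[tid]] <- list(train_id = train_proteins$id[k], identity = idv)
        break
      }
    }
  }
  removed <- data.frame(idA = character(0), idB = character(0),
                        test_id = character(0), train_id = character(0),
                        identity = numeric(0), stringsAsFactors = FALSE)
  keep <- logical(nrow(test_pairs))
  for (i in seq_len(nrow(test_pairs))) {
    hA <- hit[[test_pairs$idA[i]]]
    hB <- hit[[test_pairs$idB[i]]]
    h <- hA %||% hB
    keep[i] <- is.null(h)
    if (!is.null(h)) {
      removed <- rbind(removed, data.frame(
        idA = test_pairs$idA[i], idB = test_pairs$idB[i],
        test_id = if (is.null(hA)) test_pairs$idB[i] else test_pairs$idA[i],
        train_id = h$train_id, identity = h$identity,
        stringsAsFactors = FALSE))
    }
  }
  kept <- test_pairs[keep, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, removed = removed)
}

#' Assign samples to stratified cross-validation folds
#'
#' Random partition into `k` folds whose sizes differ by at most one, with
#' the class ratio of every fold within one sample of the global ratio
#' (stratified by `label`). Deterministic under `seed`.
#'
#' @param labels Integer vector of 0/1 labels (one per sample).
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return Integer vector of fold numbers in 1..k, one per sample.
#' @export
make_folds <- function(labels, k = 10L, seed = 1L) {
  labels <- as.integer(labels)
  k <- as.integer(k)
  n <- length(labels)
  if (k < 2L) stop("k must be at least 2")
  if (k > n) stop("k = ", k, " exceeds the ", n, " available samples")
  with_seed(derive_seed(seed, 4L), {
    fold <- integer(n)
    offset <- 0L
    for (cls in sort(unique(labels))) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      # continue the round-robin across classes so overall fold sizes
      # differ by at most one
      fold[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
      offset <- offset + length(idx)
    }
    fold
  })
}

#' Randomly split samples into a working set and a hold-out set
#'
#' @param samples Data frame of samples (e.g. labeled pairs).
#' @param n_holdout Number of rows withheld for final evaluation.
#' @param seed Integer seed.
#' @return List with `train` and `holdout` data frames; disjoint, exact
#'   sizes, together the input.
#' @export
holdout_split <- function(samples, n_holdout, seed = 1L) {
  n_holdout <- as.integer(n_holdout)
  if (n_holdout <= 0L) stop("n_holdout must be positive")
  if (n_holdout >= nrow(samples)) {
    stop("n_holdout must be smaller than the number of samples")
  }
  with_seed(derive_seed(seed, 5L), {
    idx <- sample.int(nrow(samples), n_holdout)
    list(train = samples[-idx, , drop = FALSE],
         holdout = samples[idx, , drop = FALSE])
  })
}
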