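#' Configuration of the synthetic interaction benchmark
#'
#' The generator emulates the shape of a sequence-based interaction
#' benchmark: a proteome of random sequences with subcellular compartment
#' labels, positive pairs carrying a plantable signal, and cross-compartment
#' negative pairs. The signal mechanism is motif co-insertion: with
#' probability `signal_strength` a positive pair receives a complementary
#' motif pair (`motifs[1]` into the first member, `motifs[2]` into the
#' second), which simultaneously perturbs triad counts and physicochemical
#' autocovariance. Pairs form a disjoint matching over the proteome (each
#' protein belongs to at most one pair), so the planted signal never bleeds
#' into the negatives and no protein is shared between training and test
#' material.
#'
#' @param n_proteins Proteome size (default 4000, enough for the default
#'   2,000 disjoint pairs).
#' @param length_range Min/max sequence length (default c(50, 150); minimum
#'   50 so benchmark length filters pass).
#' @param aa_freq Named 20-vector of residue frequencies summing to 1
#'   (default uniform).
#' @param n_compartments Number of subcellular compartments (default 6,
#'   matching the six localizations of the human benchmark).
#' @param motifs Character vector of two complementary motifs.
#' @param signal_strength Fraction of positive pairs carrying the motif pair,
#'   in [0, 1] (default 1).
#' @param n_pos,n_neg Numbers of positive / negative pairs (default 1000
#'   each).
#' @param seed Master seed; all generator randomness derives from it.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_proteins = 4000L, length_range = c(50L, 150L),
                         aa_freq = NULL, n_compartments = 6L,
                         motifs = c("KWKWKWKWKWKW", "ECECECECECEC"),
                         signal_strength = 1, n_pos = 1000L, n_neg = 1000L,
                         seed = 1L) {
  if (is.null(aa_freq)) {
    aa_freq <- stats::setNames(rep(1 / 20, 20), standard_residues())
  }
  if (!setequal(names(aa_freq), standard_residues())) {
    stop("aa_freq must be named with the 20 standard residues")
  }
  aa_freq <- aa_freq[standard_residues()]
  if (any(aa_freq < 0) || abs(sum(aa_freq) - 1) > 1e-9) {
    stop("aa_freq must be nonnegative and sum to 1")
  }
  stopifnot(length(length_range) == 2, length_range[1] <= length_range[2],
            signal_strength >= 0, signal_strength <= 1,
            n_compartments >= 2, n_proteins >= 0)
  if (signal_strength > 0 && length(motifs) < 2) {
    stop("two complementary motifs are required when signal_strength > 0")
  }
  out <- list(n_proteins = as.integer(n_proteins),
              length_range = as.integer(length_range),
              aa_freq = aa_freq,
              n_compartments = as.integer(n_compartments),
              motifs = toupper(motifs),
              signal_strength = signal_strength,
              n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
              seed = as.integer(seed))
  class(out) <- "synth_config"
  out
}

#' Draw a random proteome with compartment labels
#'
#' Sequences are i.i.d. draws from the configured residue frequencies with
#' lengths uniform in the configured range; compartments are assigned
#' uniformly at random. Deterministic under the config seed.
#'
#' @param cfg A [synth_config()].
#' @return A [protein_set()] with compartments.
#' @export
sample_proteome <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$n_proteins == 0L) {
    return(protein_set(character(0), character(0), character(0)))
  }
  with_seed(derive_seed(cfg$seed, 1L), {
    lens <- sample(seq(cfg$length_range[1], cfg$length_range[2]),
                   cfg$n_proteins, replace = TRUE)
    seqs <- vapply(lens, function(n) {
      paste(sample(standard_residues(), n, replace = TRUE,
                   prob = cfg$aa_freq), collapse = "")
    }, character(1))
    ids <- sprintf("SP%04d", seq_len(cfg$n_proteins))
    comp <- paste0("compartment", sample.int(cfg$n_compartments,
                                             cfg$n_proteins, replace = TRUE))
    protein_set(ids, seqs, comp)
  })
}

# Insert a motif at a random cut point, never splitting an occurrence of
# any motif in `avoid` (keeps previously planted signal intact).
insert_motif <- function(seq, motif, avoid = character(0)) {
  n <- nchar(seq)
  allowed <- rep(TRUE, n + 1L)  # cut points 0..n
  for (m in avoid) {
    hits <- gregexpr(m, seq, fixed = TRUE)[[1]]
    if (hits[1] != -1L) {
      for (s in hits) {
        inside <- seq.int(s, s + nchar(m) - 2L)  # cuts that would split
        allowed[inside + 1L] <- FALSE
      }
    }
  }
  ok <- which(allowed)
  pos <- ok[sample.int(length(ok), 1L)] - 1L
  paste0(substr(seq, 1, pos), motif, substr(seq, pos + 1L, n))
}

# Arrange a protein pool so consecutive entries never share a compartment:
# repeatedly emit a protein from the most-populated remaining compartment
# other than the previous one (always feasible while no compartment holds
# more than half of what remains).
interleave_compartments <- function(idx, comp) {
  remaining <- split(idx, comp[idx])
  out <- integer(0)
  prev <- ""
  while (length(unlist(remaining))) {
    sizes <- vapply(remaining, length, integer(1))
    choices <- names(sizes)[sizes > 0 & names(sizes) != prev]
    if (!length(choices)) {
      stop("cannot form cross-compartment pairs: one compartment dominates ",
           "the negative pool")
    }
    pick <- choices[which.max(sizes[choices])]
    out <- c(out, remaining[[pick]][1L])
    remaining[[pick]] <- remaining[[pick]][-1L]
    prev <- pick
  }
  out
}

#' Plant labeled interaction pairs into a proteome
#'
#' Draws a disjoint random matching: every protein takes part in at most one
#' pair, so classifier performance on the benchmark can only come from
#' sequence content, never from recognizing individual proteins across
#' folds. Negative pairs always join proteins from different compartments.
#' With probability `signal_strength` each positive pair has `motifs[1]`
#' inserted (once) into its first member and `motifs[2]` into its second, at
#' uniformly random positions, creating a learnable co-occurrence signal. At
#' `signal_strength = 0` no sequence is touched and the two classes are
#' statistically exchangeable.
#'
#' @param proteome A [protein_set()] from [sample_proteome()] with at least
#'   `2 * (n_pos + n_neg)` proteins.
#' @param cfg The same [synth_config()].
#' @return List with `proteins` (possibly motif-carrying proteome) and
#'   `pairs` (data frame `idA`, `idB`, `label`, shuffled).
#' @export
plant_interactions <- function(proteome, cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  n <- nrow(proteome)
  need <- 2L * (cfg$n_pos + cfg$n_neg)
  if (need > n) {
    stop("requested ", cfg$n_pos, " positive and ", cfg$n_neg,
         " negative pairs, which needs ", need,
         " distinct proteins, but the proteome has only ", n)
  }
  empty_pairs <- data.frame(idA = character(0), idB = character(0),
                            label = integer(0), stringsAsFactors = FALSE)
  with_seed(derive_seed(cfg$seed, 2L), {
    ord <- sample.int(n)
    pos_idx <- ord[seq_len(2L * cfg$n_pos)]
    neg_idx <- ord[2L * cfg$n_pos + seq_len(2L * cfg$n_neg)]
    positives <- if (cfg$n_pos > 0) {
      data.frame(idA = proteome$id[pos_idx[c(TRUE, FALSE)]],
                 idB = proteome$id[pos_idx[c(FALSE, TRUE)]],
                 label = 1L, stringsAsFactors = FALSE)
    } else {
      empty_pairs
    }
    negatives <- if (cfg$n_neg > 0) {
      arr <- interleave_compartments(neg_idx, proteome$compartment)
      data.frame(idA = proteome$id[arr[c(TRUE, FALSE)]],
                 idB = proteome$id[arr[c(FALSE, TRUE)]],
                 label = 0L, stringsAsFactors = FALSE)
    } else {
      empty_pairs
    }
    if (cfg$signal_strength > 0 && cfg$n_pos > 0) {
      has_a <- has_b <- character(0)
      carry <- stats::runif(cfg$n_pos) < cfg$signal_strength
      for (i in which(carry)) {
        a <- positives$idA[i]; b <- positives$idB[i]
        if (!(a %in% has_a)) {
          j <- match(a, proteome$id)
          proteome$seq[j] <- insert_motif(proteome$seq[j], cfg$motifs[1],
                                          avoid = cfg$motifs)
          has_a <- c(has_a, a)
        }
        if (!(b %in% has_b)) {
          j <- match(b, proteome$id)
          proteome$seq[j] <- insert_motif(proteome$seq[j], cfg$motifs[2],
                                          avoid = cfg$motifs)
          has_b <- c(has_b, b)
        }
      }
    }
    pairs <- rbind(positives, negatives)
    pairs <- pairs[sample.int(nrow(pairs)), , drop = FALSE]
    rownames(pairs) <- NULL
    list(proteins = proteome, pairs = pairs)
  })
}

#' Generate a complete synthetic benchmark
#'
#' Convenience wrapper: [sample_proteome()] then [plant_interactions()].
#'
#' @param cfg A [synth_config()] (default: the package defaults).
#' @return List with `proteins` and `pairs`.
#' @export
#' @examples
#' bench <- synth_benchmark(synth_config(n_proteins = 40, n_pos = 10,
#'                                       n_neg = 10, seed = 7))
#' table(bench$pairs$label)
synth_benchmark <- function(cfg = synth_config()) {
  plant_interactions(sample_proteome(cfg), cfg)
}

#' Write a synthetic benchmark in the package's input formats
#'
#' Emits `proteins.fasta`, `localization.tsv` (id, compartment) and
#' `pairs.tsv` (idA, idB, label) under `dir`, the same formats the dataset
#' builder consumes, so synthetic and real data share one code path.
#'
#' @param bench Output of [synth_benchmark()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synth <- function(bench, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(bench$proteins, file.path(dir, "proteins.fasta"))
  utils::write.table(
    data.frame(id = bench$proteins$id,
               compartment = bench$proteins$compartment),
    file.path(dir, "localization.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  write_pairs(bench$pairs, file.path(dir, "pairs.tsv"))
  invisible(dir)
}
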