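# Independent oracles used across the suite. These deliberately avoid the
# package's vectorized code paths.

# Naive double-loop autocovariance: for each descriptor j and lag,
# AC = 1/(n-lag) * sum_i (X[i,j] - mean_j)(X[i+lag,j] - mean_j).
brute_force_ac <- function(seq, descriptors, lag_max) {
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars)
  out <- numeric(0)
  for (j in seq_len(7)) {
    vals <- descriptors$normalized[j, chars]
    mu <- sum(vals) / n
    for (lag in seq_len(lag_max)) {
      s <- 0
      for (i in seq_len(n - lag)) {
        s <- s + (vals[i] - mu) * (vals[i + lag] - mu)
      }
      out <- c(out, s / (n - lag))
    }
  }
  out
}

# Gotoh global alignment with affine gaps (end gaps penalized), returning
# the optimal score and the identity of one traceback. Written as three
# explicit DP matrices, independent of Biostrings.
gotoh_align <- function(a, b, submat, gap_open = 10, gap_ext = 0.5) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  gp <- function(k) if (k == 0) 0 else -(gap_open + gap_ext * k)
  M <- Ix <- Iy <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) Ix[i, 1] <- gp(i - 1)
  for (j in 2:(m + 1)) Iy[1, j] <- gp(j - 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- submat[A[i - 1], B[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) + s
      Ix[i, j] <- max(M[i - 1, j] - gap_open - gap_ext,
                      Ix[i - 1, j] - gap_ext)
      Iy[i, j] <- max(M[i, j - 1] - gap_open - gap_ext,
                      Iy[i, j - 1] - gap_ext)
    }
  }
  score <- max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
  # traceback of one optimal path for identity
  eq <- function(x, y) abs(x - y) < 1e-9
  state <- which.max(c(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1]))
  i <- n + 1; j <- m + 1
  matches <- 0; len <- 0
  while (i > 1 || j > 1) {
    len <- len + 1
    if (state == 1) {
      if (A[i - 1] == B[j - 1]) matches <- matches + 1
      state <- which.max(c(M[i - 1, j - 1], Ix[i - 1, j - 1],
                           Iy[i - 1, j - 1]))
      i <- i - 1; j <- j - 1
    } else if (state == 2) {
      state <- if (eq(Ix[i, j], M[i - 1, j] - gap_open - gap_ext)) 1L else 2L
      i <- i - 1
    } else {
      state <- if (eq(Iy[i, j], M[i, j - 1] - gap_open - gap_ext)) 1L else 3L
      j <- j - 1
    }
  }
  list(score = score, identity = matches / len)
}

blosum62_matrix <- function() {
  data(BLOSUM62, package = "Biostrings", envir = environment())
  BLOSUM62
}

random_protein <- function(n) {
  paste(sample(ppisae::standard_residues(), n, replace = TRUE), collapse = "")
}

# Tiny deterministic benchmark used by several suites.
small_benchmark <- function(n_proteins = 80, n_pairs = 40, signal = 1,
                            seed = 11) {
  synth_benchmark(synth_config(n_proteins = n_proteins,
                               n_pos = n_pairs / 2, n_neg = n_pairs / 2,
                               signal_strength = signal, seed = seed))
}
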