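#' Autocovariance encoding of a protein sequence
#'
#' Maps a sequence of length n onto a fixed-length vector of
#' lag-autocovariances of its physicochemical profile. For descriptor j with
#' standardized per-residue values X and sequence mean X-bar_j,
#'
#'   AC(lag, j) = 1/(n - lag) * sum_{i=1}^{n-lag}
#'                (X[i,j] - X-bar_j) * (X[i+lag,j] - X-bar_j)
#'
#' for lag = 1..`lag_max`. With seven descriptors and the default
#' `lag_max = 30` the vector has 7 x 30 = 210 entries, independent of
#' sequence length. Entries are ordered descriptor-major:
#' (j=1, lag=1..lag_max), (j=2, ...), ...
#'
#' @param seq Amino-acid sequence (character scalar, standard residues only).
#' @param descriptors A `descriptor_table` from [ac_descriptors()].
#' @param lag_max Maximum lag; the sequence must be longer than this.
#' @return Numeric vector of length `7 * lag_max`, named `<descriptor>_lag<k>`.
#' @export
#' @examples
#' v <- encode_ac("MREIVHIQAGMREIVHIQAGMREIVHIQAGQQ", lag_max = 5)
#' length(v)  # 35
encode_ac <- function(seq, descriptors = ac_descriptors(), lag_max = 30L) {
  seq <- toupper(as.character(seq))
  stopifnot(length(seq) == 1, lag_max >= 1)
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  bad <- setdiff(unique(chars), standard_residues())
  if (length(bad) > 0) {
    stop("non-standard residue(s) ", paste(bad, collapse = ", "),
         " in sequence")
  }
  if (n <= lag_max) {
    stop("sequence of length ", n, " is too short for lag_max = ", lag_max,
         " (need length > lag_max)")
  }
  # n x 7 profile of standardized descriptor values along the sequence
  X <- t(descriptors$normalized[, chars, drop = FALSE])
  Xc <- sweep(X, 2, colMeans(X))
  out <- matrix(0, nrow = 7L, ncol = lag_max)
  for (lag in seq_len(lag_max)) {
    head_i <- seq_len(n - lag)
    out[, lag] <- colSums(Xc[head_i, , drop = FALSE] *
                          Xc[head_i + lag, , drop = FALSE]) / (n - lag)
  }
  v <- as.numeric(t(out))
  names(v) <- paste0(rep(descriptors$names, each = lag_max),
                     "_lag", rep(seq_len(lag_max), times = 7L))
  v
}

#' Replace residues by their conjoint-triad group numbers
#'
#' @param seq Amino-acid sequence.
#' @param groups Cluster map from [ct_groups()].
#' @return A string of digits 1..7, one per residue.
#' @export
#' @examples
#' cluster_sequence("MREIVHIQAG")  # "3562142411"
cluster_sequence <- function(seq, groups = ct_groups()) {
  seq <- toupper(as.character(seq))
  chars <- strsplit(seq, "")[[1]]
  g <- groups[chars]
  if (anyNA(g)) {
    stop("unmapped residue(s): ",
         paste(unique(chars[is.na(g)]), collapse = ", "))
  }
  paste(g, collapse = "")
}

#' Flattened feature index of a cluster triad
#'
#' The 343 three-group words are enumerated with the first position varying
#' fastest: (1,1,1) -> 1, (2,1,1) -> 2, ..., (7,1,1) -> 7, (1,2,1) -> 8, ...,
#' (7,7,7) -> 343. So `index = a + 7*(b-1) + 49*(c-1)` for triad (a, b, c).
#'
#' @param a,b,c Group numbers in 1..7 (vectorized).
#' @return Integer index in 1..343.
#' @export
#' @examples
#' triad_index(3, 5, 6)  # 276
triad_index <- function(a, b, c) {
  a <- as.integer(a); b <- as.integer(b); c <- as.integer(c)
  if (any(c(a, b, c) < 1L) || any(c(a, b, c) > 7L)) {
    stop("triad groups must be in 1..7")
  }
  a + 7L * (b - 1L) + 49L * (c - 1L)
}

#' Conjoint-triad encoding of a protein sequence
#'
#' Slides a 3-residue window along the group-translated sequence one step at
#' a time and counts how often each of the 7^3 = 343 group triads occurs.
#' Counts are raw window counts, so they sum to n - 2 for a length-n
#' sequence; any dataset-level scaling is deferred to [fit_scaler()].
#'
#' @inheritParams cluster_sequence
#' @return Integer vector of length 343 named `f1`..`f343`.
#' @export
#' @examples
#' v <- encode_ct("MREIVHIQAG")
#' which(v > 0)  # triads 356, 562, 621, 214, 142, 424, 241, 411
encode_ct <- function(seq, groups = ct_groups()) {
  digits <- cluster_sequence(seq, groups)
  g <- as.integer(strsplit(digits, "")[[1]])
  n <- length(g)
  if (n < 3L) stop("sequence must have at least 3 residues for CT encoding")
  idx <- triad_index(g[1:(n - 2L)], g[2:(n - 1L)], g[3:n])
  counts <- tabulate(idx, nbins = 343L)
  names(counts) <- paste0("f", 1:343)
  counts
}

#' Fit a per-feature min-max scaler on training feature vectors
#'
#' Sigmoid-activated networks want bounded inputs, so per-protein feature
#' vectors are mapped feature-wise to [0, 1] using minima and maxima observed
#' on the training proteins only. Features that are constant in training map
#' to 0. At application time, values outside the training range are clipped
#' to [0, 1] so no test-set information leaks into the transform.
#'
#' @param x Numeric matrix, rows = training protein feature vectors.
#' @return A `feature_scaler` list with `min` and `range` vectors.
#' @export
fit_scaler <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 1L) stop("cannot fit a scaler on an empty matrix")
  mins <- apply(x, 2, min)
  maxs <- apply(x, 2, max)
  out <- list(min = mins, range = maxs - mins)
  class(out) <- "feature_scaler"
  out
}

#' @rdname fit_scaler
#' @param scaler A fitted `feature_scaler`.
#' @param v Numeric vector or matrix of feature vectors to transform.
#' @return Scaled values in [0, 1].
#' @export
scale_features <- function(scaler, v) {
  if (!inherits(scaler, "feature_scaler")) {
    stop("'scaler' must be a fitted feature_scaler (see fit_scaler)")
  }
  rng <- ifelse(scaler$range == 0, 1, scaler$range)
  if (is.matrix(v)) {
    out <- sweep(sweep(v, 2, scaler$min), 2, rng, "/")
  } else {
    out <- (v - scaler$min) / rng
  }
  pmin(pmax(out, 0), 1)
}

#' Concatenate two scaled protein feature vectors into one pair input
#'
#' Both members are passed through the same training-fitted scaler and
#' concatenated in the order given, yielding the 2 x 210 = 420 (AC) or
#' 2 x 343 = 686 (CT) input the classifier consumes.
#'
#' @param vA,vB Per-protein feature vectors of equal length and scheme.
#' @param scaler A fitted `feature_scaler` (see [fit_scaler()]).
#' @return Numeric vector of length `2 * length(vA)`.
#' @export
encode_pair <- function(vA, vB, scaler) {
  if (length(vA) != length(vB)) {
    stop("pair members have different feature lengths (",
         length(vA), " vs ", length(vB), "); schemes must match")
  }
  if (!inherits(scaler, "feature_scaler")) {
    stop("'scaler' must be a fitted feature_scaler (see fit_scaler)")
  }
  if (length(scaler$min) != length(vA)) {
    stop("scaler was fitted for ", length(scaler$min),
         " features, got vectors of length ", length(vA))
  }
  c(scale_features(scaler, vA), scale_features(scaler, vB))
}

#' Encode every protein of a set under one scheme
#'
#' @param proteins A [protein_set()].
#' @param scheme `"AC"` or `"CT"`.
#' @param descriptors Descriptor table for AC (default [ac_descriptors()]).
#' @param groups Cluster map for CT (default [ct_groups()]).
#' @param lag_max Maximum AC lag (default 30).
#' @return Numeric matrix, one row per protein (rownames = ids), 210 (AC) or
#'   343 (CT) columns.
#' @export
encode_proteins <- function(proteins, scheme = c("AC", "CT"),
                            descriptors = ac_descriptors(),
                            groups = ct_groups(), lag_max = 30L) {
  scheme <- match.arg(scheme)
  enc <- if (scheme == "AC") {
    function(s) encode_ac(s, descriptors, lag_max)
  } else {
    function(s) encode_ct(s, groups)
  }
  rows <- lapply(proteins$seq, enc)
  m <- do.call(rbind, rows)
  rownames(m) <- proteins$id
  m
}

#' Build the pair feature matrix for a set of labeled pairs
#'
#' Looks up each pair member's per-protein encoding, applies the scaler and
#' concatenates. When `scaler` is NULL it is fitted on the proteins occurring
#' in `pairs` (do this only for training pairs; reuse the returned scaler for
#' any evaluation pairs).
#'
#' @param pairs Data frame with columns `idA`, `idB`.
#' @param features Per-protein feature matrix from [encode_proteins()].
#' @param scaler A fitted scaler, or NULL to fit on the proteins of `pairs`.
#' @return List with `x` (pair matrix, one row per pair) and `scaler`.
#' @export
encode_pair_matrix <- function(pairs, features, scaler = NULL) {
  missing_ids <- setdiff(unique(c(pairs$idA, pairs$idB)), rownames(features))
  if (length(missing_ids) > 0) {
    stop("pair ids missing from feature matrix: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  }
  if (is.null(scaler)) {
    used <- unique(c(pairs$idA, pairs$idB))
    scaler <- fit_scaler(features[used, , drop = FALSE])
  }
  a <- scale_features(scaler, features[pairs$idA, , drop = FALSE])
  b <- scale_features(scaler, features[pairs$idB, , drop = FALSE])
  x <- cbind(a, b)
  rownames(x) <- NULL
  colnames(x) <- c(paste0("A_", colnames(features)),
                   paste0("B_", colnames(features)))
  list(x = x, scaler = scaler)
}
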