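#' Physicochemical descriptor table for autocovariance encoding
#'
#' Loads the packaged table of seven physicochemical properties
#' (hydrophobicity, hydrophilicity, net charge index of side chains,
#' polarity, polarizability, solvent-accessible surface area, side-chain
#' volume) for the 20 standard amino acids, and standardizes each property to
#' zero mean and unit variance across the residues via
#' [normalize_descriptors()]. An alternative table with the same layout
#' (first column `descriptor`, then one column per one-letter residue code)
#' can be supplied through `path`.
#'
#' @param path Optional path to a TSV with a custom descriptor table.
#' @return A `descriptor_table` object: a list with elements `names`
#'   (descriptor names), `raw` and `normalized` (7 x 20 matrices with residue
#'   column names).
#' @export
#' @examples
#' t <- ac_descriptors()
#' dim(t$normalized)  # 7 x 20
ac_descriptors <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ac_descriptors.tsv", package = "ppisae")
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  raw <- as.matrix(df[, -1, drop = FALSE])
  rownames(raw) <- df[[1]]
  res <- standard_residues()
  if (!setequal(colnames(raw), res)) {
    stop("descriptor table must have one column per standard residue")
  }
  raw <- raw[, res, drop = FALSE]
  normalize_descriptors(raw)
}

#' Standardize a descriptor matrix across residues
#'
#' Each descriptor (row) is transformed to zero mean and unit standard
#' deviation over the 20 residues, so that properties measured on different
#' scales contribute comparably to the autocovariance sums.
#'
#' @param raw Numeric matrix with 7 rows (descriptors) and 20 columns
#'   (residues, named with one-letter codes).
#' @return A `descriptor_table` list with `names`, `raw` and `normalized`.
#' @export
normalize_descriptors <- function(raw) {
  raw <- as.matrix(raw)
  if (nrow(raw) != 7L || ncol(raw) != 20L) {
    stop("descriptor matrix must be 7 x 20, got ",
         nrow(raw), " x ", ncol(raw))
  }
  if (!all(is.finite(raw))) stop("descriptor values must be finite")
  sds <- apply(raw, 1, stats::sd)
  if (any(sds == 0)) {
    stop("constant descriptor row(s): ",
         paste(rownames(raw)[sds == 0], collapse = ", "),
         " (normalization undefined)")
  }
  normalized <- (raw - rowMeans(raw)) / sds
  out <- list(names = rownames(raw), raw = raw, normalized = normalized)
  class(out) <- "descriptor_table"
  out
}

#' @export
print.descriptor_table <- function(x, ...) {
  cat("Descriptor table:", length(x$names), "physicochemical properties x",
      ncol(x$raw), "residues\n")
  cat(paste0("  ", x$names, collapse = "\n"), "\n")
  invisible(x)
}

#' Seven-group amino-acid clustering for conjoint-triad encoding
#'
#' Loads the packaged classification of the 20 standard amino acids into
#' seven groups by dipole moment and side-chain volume: {A,G,V}, {I,L,F,P},
#' {Y,M,T,S}, {H,N,Q,W}, {R,K}, {D,E}, {C}. A custom two-column TSV
#' (`residue`, `group`) may be supplied.
#'
#' @param path Optional path to a custom cluster map TSV.
#' @return Named integer vector mapping each residue to a group in 1..7.
#' @export
#' @examples
#' m <- ct_groups()
#' m[c("M", "R", "E")]  # 3 5 6
ct_groups <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ct_groups.tsv", package = "ppisae")
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  map <- as.integer(df$group)
  names(map) <- toupper(df$residue)
  if (!setequal(names(map), standard_residues())) {
    stop("cluster map must cover exactly the 20 standard residues")
  }
  if (!setequal(unique(map), 1:7)) {
    stop("cluster map must use exactly seven non-empty groups 1..7")
  }
  map[standard_residues()]
}
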