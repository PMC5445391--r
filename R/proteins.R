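#' Assemble a validated protein table
#'
#' The package's working representation of a protein collection is a plain
#' data frame with columns `id`, `seq` and (optionally) `compartment`.
#' `protein_set()` validates identifiers and sequences: ids must be unique
#' and non-empty, sequences non-empty and, when `strict = TRUE`, drawn from
#' the 20-letter standard amino-acid alphabet (sequences containing U, X, B,
#' Z or other non-standard codes are rejected, as in benchmark construction).
#'
#' @param id Character vector of protein identifiers.
#' @param seq Character vector of amino-acid sequences (case-insensitive).
#' @param compartment Optional character vector of subcellular compartment
#'   labels (`NA` allowed); multiple annotations may be encoded as
#'   semicolon-separated values and are handled by [filter_proteins()].
#' @param strict Reject sequences with non-standard residues (default TRUE).
#' @return A `data.frame` with columns `id`, `seq`, `compartment` and class
#'   `c("protein_set", "data.frame")`.
#' @export
#' @examples
#' protein_set(c("p1", "p2"), c("MREIVHIQAG", "ACDEFGHIKL"))
protein_set <- function(id, seq, compartment = NULL, strict = TRUE) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (length(id) != length(seq)) {
    stop("'id' and 'seq' must have the same length")
  }
  if (anyDuplicated(id)) {
    stop("duplicate protein identifiers: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (any(!nzchar(id))) stop("empty protein identifier")
  if (any(!nzchar(seq))) {
    stop("empty sequence for: ", paste(id[!nzchar(seq)], collapse = ", "))
  }
  if (strict) {
    bad <- !grepl(paste0("^[", paste(standard_residues(), collapse = ""), "]+$"), seq)
    if (any(bad)) {
      stop("non-standard residues in: ", paste(id[bad], collapse = ", "))
    }
  }
  if (is.null(compartment)) {
    compartment <- rep(NA_character_, length(id))
  }
  out <- data.frame(id = id, seq = seq,
                    compartment = as.character(compartment),
                    stringsAsFactors = FALSE)
  class(out) <- c("protein_set", "data.frame")
  out
}

#' Read protein sequences from a FASTA file
#'
#' Reads a (possibly line-wrapped, multi-record) FASTA file of amino-acid
#' sequences. Residues are upper-cased; the record identifier is the first
#' whitespace-delimited token of the header.
#'
#' @param path Path to a FASTA file.
#' @param strict Reject non-standard residues (default TRUE).
#' @return A [protein_set()] data frame (no compartment labels).
#' @export
read_fasta <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  aa <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  protein_set(ids, as.character(aa), strict = strict)
}

#' Write a protein set to FASTA
#'
#' @param proteins A [protein_set()] data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  x <- Biostrings::BStringSet(proteins$seq)
  names(x) <- proteins$id
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read or write a tab-separated protein pair list
#'
#' Pair files are tab-separated with columns `idA`, `idB`, `label`
#' (1 = interaction, 0 = non-interaction) and optionally `split`.
#' A header line is auto-detected on read and always written.
#'
#' @param path File path.
#' @return `read_pairs`: a data frame with columns `idA`, `idB`, `label`
#'   (integer) and `split` if present.
#' @export
read_pairs <- function(path) {
  if (!file.exists(path)) stop("pair file not found: ", path)
  first <- readLines(path, n = 1L)
  has_header <- grepl("^idA\t", first)
  df <- utils::read.table(path, sep = "\t", header = has_header,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  if (!has_header) {
    names(df) <- c("idA", "idB", "label", "split")[seq_len(ncol(df))]
  }
  if (ncol(df) < 3) stop("pair file needs at least 3 columns (idA, idB, label)")
  df$idA <- as.character(df$idA)
  df$idB <- as.character(df$idB)
  df$label <- as.integer(df$label)
  if (any(!df$label %in% c(0L, 1L))) stop("pair labels must be 0 or 1")
  df
}

#' @rdname read_pairs
#' @param pairs Data frame with columns `idA`, `idB`, `label` (and optionally
#'   `split`).
#' @export
write_pairs <- function(pairs, path) {
  keep <- intersect(c("idA", "idB", "label", "split"), names(pairs))
  utils::write.table(pairs[, keep, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a localization annotation table
#'
#' Tab-separated file with columns `id` and `compartment`; joins compartment
#' labels onto an existing protein set.
#'
#' @param proteins A [protein_set()].
#' @param path Path to the TSV.
#' @return The protein set with its `compartment` column filled in.
#' @export
read_localization <- function(proteins, path) {
  if (!file.exists(path)) stop("localization file not found: ", path)
  first <- readLines(path, n = 1L)
  has_header <- grepl("^id\t", first)
  loc <- utils::read.table(path, sep = "\t", header = has_header,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  if (!has_header) names(loc) <- c("id", "compartment")[seq_len(ncol(loc))]
  proteins$compartment <- loc$compartment[match(proteins$id, loc$id)]
  proteins
}
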