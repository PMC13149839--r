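#' Read a FASTA file into a tibble
#'
#' Sequences are uppercased on load (a message is emitted when lowercase
#' residues were present). Duplicate record ids and non-IUPAC characters are
#' rejected.
#'
#' @param path path to a FASTA file.
#' @param type `"dna"` or `"aa"`.
#' @return a tibble with columns `id` (full header line, verbatim) and `seq`.
#' @export
read_fasta <- function(path, type = c("dna", "aa")) {
  type <- match.arg(type)
  set <- if (type == "dna") {
    Biostrings::readBStringSet(path)
  } else {
    Biostrings::readAAStringSet(path)
  }
  ids <- names(set)
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate FASTA ids: %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  seqs <- as.character(set)
  if (any(grepl("[a-z]", seqs))) {
    message("lowercase residues uppercased on load")
    seqs <- toupper(seqs)
  }
  alphabet <- if (type == "dna") "ACGTUNRYSWKMBDHV-" else
    paste0(paste(Biostrings::AA_ALPHABET, collapse = ""))
  for (i in seq_along(seqs)) {
    bad <- regexpr(sprintf("[^%s]", alphabet), seqs[[i]])
    if (bad > 0) {
      abort(sprintf("record '%s': non-IUPAC character '%s' at position %d",
                    ids[[i]], substr(seqs[[i]], bad, bad), bad))
    }
  }
  tibble(id = unname(ids), seq = unname(seqs))
}

#' Write a tibble of sequences to FASTA
#'
#' @param x a data frame with columns `id` and `seq`.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  stopifnot(all(c("id", "seq") %in% names(x)))
  if (anyDuplicated(x$id)) abort("duplicate ids in FASTA output")
  set <- Biostrings::BStringSet(setNames(x$seq, x$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
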