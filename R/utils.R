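# Low-level sequence helpers shared across modules.
#
# All genomic coordinates inside the package are 0-based half-open
# [start, end); 1-based inclusive coordinates appear only in GFF3 output.

DNA_BASES <- c("A", "C", "G", "T")

# canonical recombination signal motifs
RSS_HEPTAMER <- "CACAGTG"
RSS_NONAMER <- "ACAAAAACC"

#' Reverse-complement a DNA string
#'
#' Thin wrapper around [Biostrings::reverseComplement()] operating on plain
#' character vectors.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("CACAGTG")
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Translate DNA to amino acids
#'
#' Translates complete codons of `x` (standard code); a trailing partial
#' codon is dropped. Codons containing N translate to `X`.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of protein sequences (stops as `*`).
#' @export
translate_dna <- function(x) {
  vapply(x, function(s) {
    n <- nchar(s) - nchar(s) %% 3
    if (n == 0) return("")
    if (n <= 600) {
      # table lookup is faster than Biostrings for short fragments
      codons <- substring(s, seq(1, n, 3), seq(3, n, 3))
      aa <- Biostrings::GENETIC_CODE[codons]
      aa[is.na(aa)] <- "X"
      return(paste(aa, collapse = ""))
    }
    as.character(Biostrings::translate(
      Biostrings::DNAString(substr(s, 1, n)),
      if.fuzzy.codon = "solve", no.init.codon = TRUE
    ))
  }, character(1), USE.NAMES = FALSE)
}

# validate a genome-like argument and normalise to list(id, seq)
# accepts: one-row tibble (id, seq), named character length 1,
# unnamed character length 1 (id = "contig"), or DNAString
as_genome <- function(genome) {
  if (is.data.frame(genome)) {
    if (nrow(genome) != 1L || !all(c("id", "seq") %in% names(genome))) {
      abort("`genome` data frame must have one row with columns `id` and `seq`.")
    }
    out <- list(id = genome$id[[1]], seq = toupper(genome$seq[[1]]))
  } else if (methods::is(genome, "DNAString")) {
    out <- list(id = "contig", seq = as.character(genome))
  } else if (is.character(genome) && length(genome) == 1L) {
    out <- list(id = names(genome) %||% "contig", seq = toupper(genome))
  } else {
    abort("`genome` must be a one-row data frame, a string, or a DNAString.")
  }
  bad <- gsub("[ACGTN]", "", out$seq)
  if (nzchar(bad)) {
    abort(sprintf(
      "genome '%s' contains non-DNA characters other than N: %s",
      out$id, paste(unique(strsplit(bad, "")[[1]]), collapse = ", ")
    ))
  }
  if (!nzchar(out$seq)) abort("genome sequence is empty.")
  out
}

# number of mismatches between equal-length strings
str_mismatches <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  sum(ca != cb)
}

# deterministic RNG scope: run `expr` under `seed` without disturbing the
# caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}
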