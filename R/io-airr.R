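# AIRR-style clonotype table IO.
#
# The package's working representation of a repertoire sample is a plain
# tibble with (at least) the AIRR Rearrangement columns
#   repertoire_id, junction, junction_aa, v_call, j_call,
#   duplicate_count, productive
# Multi-gene calls are comma-separated strings ("TRB1V5-2,TRB2V5-2");
# a call containing a comma is an ambiguous call.

AIRR_REQUIRED <- c("junction", "junction_aa", "v_call", "j_call",
                   "duplicate_count", "productive")

validate_airr <- function(x, arg = "sample") {
  missing_cols <- setdiff(AIRR_REQUIRED, names(x))
  if (length(missing_cols)) {
    abort(sprintf("%s is missing required column(s): %s",
                  arg, paste(missing_cols, collapse = ", ")))
  }
  if (!is.numeric(x$duplicate_count) ||
      any(x$duplicate_count != floor(x$duplicate_count)) ||
      any(x$duplicate_count < 1)) {
    bad <- which(!is.finite(x$duplicate_count) | x$duplicate_count < 1 |
                   x$duplicate_count != floor(x$duplicate_count))[1]
    abort(sprintf("%s: duplicate_count must be a positive integer (row %d)",
                  arg, bad %||% NA_integer_))
  }
  invisible(x)
}

#' Read an AIRR-style clonotype TSV
#'
#' @param path path to a tab-separated clonotype table with a header row
#'   carrying at least `junction`, `junction_aa`, `v_call`, `j_call`,
#'   `duplicate_count` and `productive`.
#' @return a tibble; `productive` is logical, `duplicate_count` integer.
#' @export
read_airr <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(AIRR_REQUIRED, names(x))
  if (length(missing_cols)) {
    abort(sprintf("AIRR file '%s' is missing required column(s): %s",
                  path, paste(missing_cols, collapse = ", ")))
  }
  if (is.character(x$productive)) {
    x$productive <- x$productive %in% c("T", "TRUE", "true", "1")
  }
  cnt <- suppressWarnings(as.integer(x$duplicate_count))
  if (anyNA(cnt)) {
    abort(sprintf("AIRR file '%s': non-integer duplicate_count at row %d",
                  path, which(is.na(cnt))[1]))
  }
  x$duplicate_count <- cnt
  validate_airr(x, sprintf("AIRR file '%s'", path))
  x
}

#' Write a clonotype table as AIRR-style TSV
#'
#' @param x clonotype tibble (see [read_airr()] for the required columns).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_airr <- function(x, path) {
  validate_airr(x)
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Convert a MiXCR-style clone export to AIRR columns
#'
#' Maps the MiXCR export dialect (`cloneCount`, `nSeqCDR3`, `aaSeqCDR3`,
#' `allVHitsWithScore`, `allJHitsWithScore`) onto the AIRR columns used
#' throughout the package. Hit lists such as `"TRBV1*00(1200),TRBV2*00(900)"`
#' become comma-separated call sets with scores and allele suffixes removed.
#'
#' @param x data frame in the MiXCR export dialect.
#' @return an AIRR-style tibble.
#' @export
mixcr_to_airr <- function(x) {
  need <- c("cloneCount", "nSeqCDR3", "aaSeqCDR3",
            "allVHitsWithScore", "allJHitsWithScore")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    abort(sprintf("MiXCR table is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  strip_hits <- function(h) {
    vapply(strsplit(h, ","), function(parts) {
      parts <- sub("\\(.*\\)$", "", parts)   # drop scores
      parts <- sub("\\*[0-9]+$", "", parts)  # drop allele suffix
      paste(unique(parts), collapse = ",")
    }, character(1))
  }
  aa <- x$aaSeqCDR3
  tibble(
    junction = x$nSeqCDR3,
    junction_aa = aa,
    v_call = strip_hits(x$allVHitsWithScore),
    j_call = strip_hits(x$allJHitsWithScore),
    duplicate_count = as.integer(round(x$cloneCount)),
    productive = !grepl("[*_]", aa) & nzchar(aa)
  )
}

# number of genes in a (possibly ambiguous) comma-separated call
n_calls <- function(call) lengths(strsplit(call, ","))
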