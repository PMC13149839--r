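# Gene segment functionality classification.
#
# A V gene is functional when its coding region translates without internal
# stops, its length is frame-consistent, an RSS is attached, and its 3' end
# encodes the conserved 2nd-CYS (Cys104) with an open reading into the
# CDR3. A J gene requires an RSS, a stop-free reading and (by default) the
# canonical F/W-G-X-G motif. Failures accumulate in `defect_reasons`.

segment_nt <- function(seg_start, seg_end, seg_strand, genome_seq) {
  s <- substr(genome_seq, seg_start + 1L, seg_end)
  if (seg_strand == "-") revcomp(s) else s
}

# Cys104 bookkeeping: the 2nd-CYS must sit among the last `window` codons
# of the V exon but not be the terminal codon (at least one germline CDR3
# codon must follow, the "open reading into the CDR3").
CYS_WINDOW <- 5L

classify_one <- function(type, aa, rss_n, rss_missing, nt_len,
                         check_j_motif = TRUE) {
  defects <- character(0)
  if (type %in% c("V", "J", "C")) {
    if (nt_len %% 3 != 0) defects <- c(defects, "frameshift")
    internal <- if (type == "V") substr(aa, 1, nchar(aa) - 1L) else aa
    if (grepl("\\*", internal)) defects <- c(defects, "stop_codon")
  }
  if (type %in% c("V", "J") && rss_missing) {
    defects <- c(defects, "missing_rss")
  }
  if (type == "D" && rss_n < 2L) {
    defects <- c(defects, "missing_rss")
  }
  if (type == "V") {
    tail_aa <- substr(aa, max(1L, nchar(aa) - CYS_WINDOW + 1L), nchar(aa))
    cys_pos <- gregexpr("C", tail_aa)[[1]]
    cys_pos <- cys_pos[cys_pos > 0]
    if (!length(cys_pos)) {
      defects <- c(defects, "missing_cys104", "incomplete_cdr3")
    } else if (max(cys_pos) == nchar(tail_aa)) {
      # Cys present but terminal: no germline CDR3 codons follow
      defects <- c(defects, "incomplete_cdr3")
    }
  }
  if (type == "J" && check_j_motif && !grepl("[FW]G.G", aa)) {
    defects <- c(defects, "missing_anchor")
  }
  defects
}

#' Classify gene segment functionality
#'
#' Applies the functionality criteria to every segment draft: absence of
#' stop codons and frameshifts, presence of the required RSS(s), and for V
#' genes the conserved 2nd-CYS (Cys104) near the 3' end with an open
#' reading into the CDR3. J genes are additionally required to carry the
#' F/W-G-X-G anchor motif (disable with `check_j_motif = FALSE`; the
#' criterion is a package convention, stated in the docs).
#'
#' @param segments segment tibble with `segment_type`, `start`, `end`,
#'   `strand`, and the `rss`/`rss_missing` columns from [attach_rss()]
#'   (missing columns are treated as "no RSS attached").
#' @param genome the genome the coordinates refer to.
#' @param check_j_motif require F/W-G-X-G in J translations.
#' @return `segments` with columns `aa` (translation of the coding
#'   interval, segment orientation), `functionality`
#'   (`"functional"`/`"pseudogene"`) and list-column `defect_reasons`.
#' @export
classify_functionality <- function(segments, genome, check_j_motif = TRUE) {
  g <- as_genome(genome)
  if (!nrow(segments)) {
    segments$aa <- character(0)
    segments$functionality <- character(0)
    segments$defect_reasons <- list()
    return(segments)
  }
  if (any(segments$end <= segments$start)) {
    abort("segment without a coding interval (end <= start)")
  }
  has_rss_col <- "rss" %in% names(segments)
  aa <- character(nrow(segments))
  defect_reasons <- vector("list", nrow(segments))
  for (i in seq_len(nrow(segments))) {
    nt <- segment_nt(segments$start[[i]], segments$end[[i]],
                     segments$strand[[i]], g$seq)
    aa[[i]] <- translate_dna(nt)
    rss_n <- if (has_rss_col) nrow(segments$rss[[i]]) else 0L
    rss_missing <- if ("rss_missing" %in% names(segments)) {
      isTRUE(segments$rss_missing[[i]])
    } else {
      segments$segment_type[[i]] %in% c("V", "J") && rss_n == 0L
    }
    defect_reasons[[i]] <- classify_one(
      segments$segment_type[[i]], aa[[i]], rss_n, rss_missing,
      nchar(nt), check_j_motif
    )
  }
  segments$aa <- aa
  segments$defect_reasons <- defect_reasons
  segments$functionality <- ifelse(lengths(defect_reasons) == 0L,
                                   "functional", "pseudogene")
  segments
}
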