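# Six-frame homology scan for coding gene candidates.
#
# A desk-scale protein-vs-translated-genome search: each reference protein
# is aligned locally (BLOSUM62, affine gaps open 11 / extend 1) against all
# six reading-frame translations; all local maxima above the score
# threshold are enumerated by iteratively masking the best hit and
# re-aligning. Scores are raw alignment scores, not E-values.

frame_translations <- function(g) {
  n <- nchar(g$seq)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") g$seq else revcomp(g$seq)
    for (f in 0:2) {
      len <- n - f
      len <- len - len %% 3
      if (len < 3) next
      aa <- translate_dna(substr(s, f + 1L, f + len))
      out[[paste0(strand, f)]] <- list(strand = strand, frame = f, aa = aa)
    }
  }
  out
}

# map an aa interval (1-based inclusive, within a frame translation) back
# to 0-based half-open genome coordinates
aa_to_genome <- function(p1, p2, frame, strand, n) {
  s <- frame + 3L * (p1 - 1L)
  e <- frame + 3L * p2
  if (strand == "+") c(s, e) else c(n - e, n - s)
}

#' Find coding gene candidates by six-frame homology
#'
#' Aligns each reference protein locally against the six reading-frame
#' translations of `genome` and reports every non-overlapping local
#' alignment with score at least `min_score` (raw BLOSUM62 score, affine
#' gap open 11 / extend 1). Within one (strand, frame, reference)
#' combination hits are enumerated best-first with masking, so no two
#' returned candidates overlap on the same strand in the same frame.
#'
#' @param genome genome input (see [scan_rss()]).
#' @param refs reference proteins: a tibble with columns `id`, `chain`
#'   (A/B/G/D or A/D), `type` (V/J/C) and `aa`, e.g. the `refs` element of
#'   [build_fixture_locus()], or a set read from FASTA with
#'   `chain=`/`type=` header tokens via [read_ref_fasta()].
#' @param min_score minimum raw alignment score; either a single number or
#'   a named vector/list with per-type thresholds, e.g.
#'   `c(V = 100, J = 55, C = 100)`.
#' @param max_hits_per_ref safety cap on hits enumerated per reference and
#'   frame.
#' @return a tibble of candidates: `contig`, `segment_type`, `chain`,
#'   `ref_id`, `start`, `end`, `strand`, `frame`, `score`, ordered by
#'   `start`.
#' @export
find_coding_candidates <- function(genome, refs, min_score = 100,
                                   max_hits_per_ref = 200L) {
  g <- as_genome(genome)
  if (is.null(refs) || !nrow(refs)) {
    abort("reference protein set is empty")
  }
  stopifnot(all(c("id", "chain", "type", "aa") %in% names(refs)))
  score_for <- function(type) {
    if (length(min_score) == 1L && is.null(names(min_score))) {
      return(as.numeric(min_score))
    }
    out <- min_score[[type]]
    if (is.null(out) || is.na(out)) abort(
      sprintf("no min_score given for segment type '%s'", type))
    as.numeric(out)
  }
  n <- nchar(g$seq)
  frames <- frame_translations(g)
  rows <- list()
  for (fr in frames) {
    subj_chars <- strsplit(fr$aa, "")[[1]]
    for (r in seq_len(nrow(refs))) {
      ref_aa <- refs$aa[[r]]
      thr <- score_for(refs$type[[r]])
      subj <- paste(subj_chars, collapse = "")
      masked <- subj_chars
      for (k in seq_len(max_hits_per_ref)) {
        pa <- Biostrings::pairwiseAlignment(
          Biostrings::AAString(ref_aa), Biostrings::AAString(subj),
          type = "local", substitutionMatrix = "BLOSUM62",
          gapOpening = 11, gapExtension = 1
        )
        if (Biostrings::score(pa) < thr) break
        sstart <- Biostrings::start(Biostrings::subject(pa))
        send <- Biostrings::end(Biostrings::subject(pa))
        coords <- aa_to_genome(sstart, send, fr$frame, fr$strand, n)
        rows[[length(rows) + 1L]] <- tibble(
          contig = g$id,
          segment_type = refs$type[[r]],
          chain = refs$chain[[r]],
          ref_id = refs$id[[r]],
          start = coords[[1]], end = coords[[2]],
          strand = fr$strand, frame = fr$frame,
          score = Biostrings::score(pa)
        )
        masked[sstart:send] <- "*"   # * scores -4 vs everything
        subj <- paste(masked, collapse = "")
      }
    }
  }
  if (!length(rows)) {
    return(tibble(contig = character(), segment_type = character(),
                  chain = character(), ref_id = character(),
                  start = integer(), end = integer(), strand = character(),
                  frame = integer(), score = numeric()))
  }
  out <- bind_rows(rows)
  # drop lower-scoring candidates overlapping a better one on the same
  # strand and frame (different references can re-find the same locus)
  out <- out |> arrange(desc(score))
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[[i]]) next
    j <- which(keep & seq_len(nrow(out)) > i &
                 out$strand == out$strand[[i]] & out$frame == out$frame[[i]] &
                 out$start < out$end[[i]] & out$end > out$start[[i]])
    keep[j] <- FALSE
  }
  out[keep, , drop = FALSE] |> arrange(start, end)
}

#' Read a reference protein FASTA with chain/type header tokens
#'
#' Headers must carry `chain=<A|B|G|D|A/D>` and `type=<V|J|C>` tokens, e.g.
#' `>vref1 chain=B type=V`.
#'
#' @param path FASTA path.
#' @return a tibble with columns `id`, `chain`, `type`, `aa`.
#' @export
read_ref_fasta <- function(path) {
  x <- read_fasta(path, type = "aa")
  grab <- function(hdr, key) {
    m <- regmatches(hdr, regexpr(sprintf("%s=[^ ]+", key), hdr))
    if (!length(m)) abort(sprintf("reference header lacks %s= token: %s",
                                  key, hdr))
    sub(sprintf("%s=", key), "", m)
  }
  tibble(
    id = vapply(strsplit(x$id, " "), `[[`, character(1), 1L),
    chain = vapply(x$id, grab, character(1), key = "chain",
                   USE.NAMES = FALSE),
    type = vapply(x$id, grab, character(1), key = "type",
                  USE.NAMES = FALSE),
    aa = x$seq
  )
}
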