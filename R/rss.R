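# Recombination signal sequence (RSS) scanning and bookkeeping.
#
# An RSS is heptamer + spacer + nonamer; canonically CACAGTG and ACAAAAACC
# with a 12-bp or 22/23-bp spacer. Hits are reported on both strands.
# A "+" hit reads heptamer -> nonamer left-to-right in genome coordinates,
# so its recombining coding partner lies on its 5' (left) side
# (orientation "coding-5'"); a "-" hit has its heptamer at the right end
# and its partner on the 3' (right) side (orientation "coding-3'").

#' RSS scanning and pairing configuration
#'
#' Defaults follow the canonical 12/23 rule plus the 22-bp V spacers seen in
#' teleost TR loci: V genes pair with a 22/23-spacer RSS, J genes with a
#' 12-spacer RSS, and D genes are flanked by a 12-spacer and a 23-spacer RSS
#' in opposite orientation. The heptamer budget allows one mismatch but the
#' cleavage-critical first three bases (CAC) must be exact; the nonamer
#' budget of two admits variant nonamers such as ACATAAACC.
#'
#' @param spacer_v,spacer_j,spacer_d5,spacer_d3 allowed spacer lengths (nt)
#'   for V RSSs, J RSSs, and the D 5'/3' flanks.
#' @param max_heptamer_mismatch,max_nonamer_mismatch maximum mismatches to
#'   the canonical heptamer/nonamer.
#' @param require_cac if `TRUE`, the first three heptamer bases must equal
#'   CAC exactly.
#' @param max_gap maximum distance (nt) between a coding end and its RSS
#'   heptamer for [attach_rss()].
#' @param max_d_length maximum D gene length (nt) for [detect_d_segments()].
#' @return a list of class `rss_config`.
#' @export
rss_config <- function(spacer_v = c(22L, 23L), spacer_j = 12L,
                       spacer_d5 = 12L, spacer_d3 = 23L,
                       max_heptamer_mismatch = 1L, max_nonamer_mismatch = 2L,
                       require_cac = TRUE, max_gap = 10L,
                       max_d_length = 40L) {
  stopifnot(length(spacer_v) >= 1, max_heptamer_mismatch >= 0,
            max_nonamer_mismatch >= 0, max_gap >= 0, max_d_length >= 1)
  structure(list(
    spacer_v = as.integer(spacer_v), spacer_j = as.integer(spacer_j),
    spacer_d5 = as.integer(spacer_d5), spacer_d3 = as.integer(spacer_d3),
    max_heptamer_mismatch = as.integer(max_heptamer_mismatch),
    max_nonamer_mismatch = as.integer(max_nonamer_mismatch),
    require_cac = isTRUE(require_cac),
    max_gap = as.integer(max_gap),
    max_d_length = as.integer(max_d_length)
  ), class = "rss_config")
}

all_spacers <- function(config) {
  sort(unique(c(config$spacer_v, config$spacer_j,
                config$spacer_d5, config$spacer_d3)))
}

# mismatch count of `motif` at every start offset of `chars`
# (character vector of single bases); N never matches
motif_mismatch_profile <- function(chars, motif) {
  m <- nchar(motif)
  n <- length(chars)
  if (n < m) return(integer(0))
  mb <- strsplit(motif, "")[[1]]
  out <- integer(n - m + 1L)
  for (k in seq_len(m)) {
    out <- out + (chars[k:(n - m + k)] != mb[k])
  }
  out
}

scan_rss_one_strand <- function(chars, config) {
  hm <- motif_mismatch_profile(chars, RSS_HEPTAMER)
  nm <- motif_mismatch_profile(chars, RSS_NONAMER)
  if (config$require_cac) {
    cac <- motif_mismatch_profile(chars, "CAC")
    hm[cac[seq_along(hm)] > 0L] <- NA_integer_
  }
  hits <- list()
  for (sp in all_spacers(config)) {
    # heptamer at 0-based i, nonamer at i + 7 + sp
    i_max <- length(hm) - 1L
    i <- which(!is.na(hm) & hm <= config$max_heptamer_mismatch) - 1L
    i <- i[i + 7L + sp + 9L <= length(chars)]
    if (!length(i)) next
    nmm <- nm[i + 7L + sp + 1L]
    keep <- !is.na(nmm) & nmm <= config$max_nonamer_mismatch
    i <- i[keep]
    if (!length(i)) next
    hits[[length(hits) + 1L]] <- tibble(
      start = i,
      end = i + 16L + sp,
      spacer_length = sp,
      heptamer_mismatches = hm[i + 1L],
      nonamer_mismatches = nm[i + 7L + sp + 1L]
    )
  }
  if (!length(hits)) {
    return(tibble(start = integer(), end = integer(),
                  spacer_length = integer(),
                  heptamer_mismatches = integer(),
                  nonamer_mismatches = integer()))
  }
  bind_rows(hits)
}

#' Scan a genome for recombination signal sequences
#'
#' Finds every position on both strands where the canonical heptamer and
#' nonamer occur within the configured mismatch budgets, separated by one of
#' the allowed spacer lengths. Coordinates are 0-based half-open and span
#' heptamer through nonamer.
#'
#' @param genome a one-row tibble with `id`/`seq` (as from [read_fasta()]),
#'   a character string, or a `DNAString`.
#' @param config an [rss_config()].
#' @return a tibble with one row per hit: `contig`, `start`, `end`,
#'   `strand`, `spacer_length`, `heptamer_seq`, `nonamer_seq`,
#'   `heptamer_mismatches`, `nonamer_mismatches`, `orientation`.
#' @export
scan_rss <- function(genome, config = rss_config()) {
  g <- as_genome(genome)
  n <- nchar(g$seq)
  fwd_chars <- strsplit(g$seq, "")[[1]]
  rev_chars <- strsplit(revcomp(g$seq), "")[[1]]

  fwd <- scan_rss_one_strand(fwd_chars, config)
  fwd$strand <- rep("+", nrow(fwd))

  rev_ <- scan_rss_one_strand(rev_chars, config)
  if (nrow(rev_)) {
    new_start <- n - rev_$end
    rev_$end <- n - rev_$start
    rev_$start <- new_start
  }
  rev_$strand <- rep("-", nrow(rev_))

  hits <- bind_rows(fwd, rev_)
  if (!nrow(hits)) {
    return(tibble(contig = character(), start = integer(), end = integer(),
                  strand = character(), spacer_length = integer(),
                  heptamer_seq = character(), nonamer_seq = character(),
                  heptamer_mismatches = integer(),
                  nonamer_mismatches = integer(),
                  orientation = character()))
  }
  hits <- hits |>
    mutate(
      contig = g$id,
      heptamer_seq = ifelse(
        strand == "+",
        substring(g$seq, start + 1L, start + 7L),
        revcomp(substring(g$seq, end - 6L, end))
      ),
      nonamer_seq = ifelse(
        strand == "+",
        substring(g$seq, end - 8L, end),
        revcomp(substring(g$seq, start + 1L, start + 9L))
      ),
      orientation = ifelse(strand == "+", "coding-5'", "coding-3'")
    ) |>
    select(contig, start, end, strand, spacer_length, heptamer_seq,
           nonamer_seq, heptamer_mismatches, nonamer_mismatches,
           orientation) |>
    arrange(start, end, strand)
  hits
}

# --- attaching hits to gene segment drafts --------------------------------

# which side of the hit its coding partner lies on, in genome coordinates
hit_faces_left <- function(strand) strand == "+"

# allowed spacer set for a draft's RSS given its segment type
spacers_for_type <- function(segment_type, config) {
  switch(segment_type,
    V = config$spacer_v,
    J = config$spacer_j,
    integer(0)
  )
}

#' Attach RSS hits to V and J gene segment drafts
#'
#' A V draft receives the nearest correctly oriented hit whose heptamer
#' starts within `max_gap` nt of the V coding 3' end; a J draft the nearest
#' within `max_gap` of its coding 5' end. "Correctly oriented" means the
#' heptamer faces the coding end on the correct strand: a V's RSS reads
#' heptamer-to-nonamer away from the gene on the gene's own strand, a J's on
#' the opposite strand. Drafts with no eligible hit get `rss_missing = TRUE`.
#'
#' @param drafts segment draft tibble with columns `segment_type`, `start`,
#'   `end`, `strand` (plus anything else, preserved).
#' @param hits RSS hit tibble from [scan_rss()].
#' @param config an [rss_config()]; `config$max_gap` is the adjacency
#'   tolerance.
#' @return `drafts` with list-column `rss` (a 0/1-row hit tibble per draft)
#'   and logical `rss_missing`.
#' @export
attach_rss <- function(drafts, hits, config = rss_config()) {
  if (!nrow(drafts)) {
    drafts$rss <- list()
    drafts$rss_missing <- logical(0)
    return(drafts)
  }
  if ("contig" %in% names(drafts) && "contig" %in% names(hits) &&
      nrow(hits) && length(setdiff(unique(drafts$contig),
                                   unique(hits$contig))) == 0 &&
      length(unique(c(drafts$contig, hits$contig))) > 1) {
    abort("drafts and hits must come from the same contig")
  }
  max_gap <- config$max_gap
  pick <- function(seg_type, seg_start, seg_end, seg_strand) {
    if (!seg_type %in% c("V", "J") || !nrow(hits)) return(NULL)
    spac <- spacers_for_type(seg_type, config)
    # genomic side of the segment where the RSS must sit, and the strand
    # the hit must be on so that its heptamer faces the coding end
    if (seg_type == "V") {
      rss_right <- seg_strand == "+"   # RSS 3' of V in gene orientation
      want_strand <- seg_strand        # reads away from gene on same strand
    } else {
      rss_right <- seg_strand == "-"   # RSS 5' of J in gene orientation
      want_strand <- if (seg_strand == "+") "-" else "+"
    }
    cand <- hits[hits$strand == want_strand &
                   hits$spacer_length %in% spac, , drop = FALSE]
    if (!nrow(cand)) return(NULL)
    gap <- if (rss_right) cand$start - seg_end else seg_start - cand$end
    ok <- gap >= 0 & gap <= max_gap
    if (!any(ok)) return(NULL)
    cand <- cand[ok, , drop = FALSE]
    cand[order(gap[ok], cand$start), , drop = FALSE][1, , drop = FALSE]
  }
  rss_list <- vector("list", nrow(drafts))
  for (i in seq_len(nrow(drafts))) {
    rss_list[i] <- list(pick(drafts$segment_type[[i]], drafts$start[[i]],
                             drafts$end[[i]], drafts$strand[[i]]))
  }
  drafts$rss <- lapply(rss_list, function(h) h %||% hits[0, , drop = FALSE])
  drafts$rss_missing <- drafts$segment_type %in% c("V", "J") &
    vapply(rss_list, is.null, logical(1))
  drafts
}

#' Detect D gene segments from facing RSS pairs
#'
#' A D gene is reported wherever two RSS hits in opposite orientation face
#' each other with an intervening stretch of 1..`max_d_length` nt: the left
#' hit must face right (strand "-", heptamer at its right end) and the right
#' hit must face left (strand "+"). One flank must carry the 12-bp spacer
#' and the other the 23-bp spacer (per `config`); the flank carrying the
#' 5'-type spacer determines the D strand.
#'
#' @param hits RSS hit tibble from [scan_rss()].
#' @param region optional `c(start, end)` (0-based half-open) restricting
#'   the search, e.g. the interval between a V block and a J block.
#' @param config an [rss_config()]; `config$max_d_length` bounds the
#'   D length.
#' @return a segment draft tibble (type "D") with the coding interval
#'   between the facing heptamers and both flanking hits in the `rss`
#'   list-column.
#' @export
detect_d_segments <- function(hits, region = NULL, config = rss_config()) {
  empty <- tibble(contig = character(), segment_type = character(),
                  start = integer(), end = integer(), strand = character(),
                  rss = list())
  if (!nrow(hits)) return(empty)
  if (!is.null(region)) {
    stopifnot(length(region) == 2, region[1] <= region[2])
    hits <- hits[hits$start >= region[1] & hits$end <= region[2], ,
                 drop = FALSE]
  }
  left <- hits[hits$strand == "-", , drop = FALSE]   # faces right
  right <- hits[hits$strand == "+", , drop = FALSE]  # faces left
  out <- list()
  for (i in seq_len(nrow(left))) {
    for (j in seq_len(nrow(right))) {
      core_len <- right$start[[j]] - left$end[[i]]
      if (core_len < 1 || core_len > config$max_d_length) next
      sp <- c(left$spacer_length[[i]], right$spacer_length[[j]])
      if (setequal(sp, c(config$spacer_d5, config$spacer_d3)) &&
          config$spacer_d5 != config$spacer_d3) {
        d_strand <- if (left$spacer_length[[i]] == config$spacer_d5)
          "+" else "-"
      } else next
      out[[length(out) + 1L]] <- tibble(
        contig = left$contig[[i]],
        segment_type = "D",
        start = left$end[[i]],
        end = right$start[[j]],
        strand = d_strand,
        rss = list(bind_rows(left[i, , drop = FALSE],
                             right[j, , drop = FALSE]))
      )
    }
  }
  if (!length(out)) return(empty)
  bind_rows(out) |> arrange(start)
}
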