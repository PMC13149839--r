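# GFF3 output/input for annotated loci.
#
# One feature per gene segment (SO-style types V/D/J/C_gene_segment) with
# its RSSs as child features; coordinates are 1-based inclusive in the
# file and 0-based half-open in memory.

#' Write an annotated locus as GFF3
#'
#' @param locus a `tr_locus` tibble (from [annotate_locus()] or the truth
#'   map of [build_fixture_locus()]).
#' @param path output path.
#' @param contig_length contig length for coordinate validation; defaults
#'   to `attr(locus, "contig_length")`.
#' @return `path`, invisibly.
#' @export
write_locus_gff3 <- function(locus, path, contig_length = NULL) {
  contig_length <- contig_length %||% attr(locus, "contig_length")
  if (!is.null(contig_length) && any(locus$end > contig_length)) {
    abort("segment coordinates outside the contig")
  }
  n <- nrow(locus)
  seg_id <- sprintf("seg%03d", seq_len(n))
  seg <- GenomicRanges::GRanges(
    seqnames = locus$contig,
    ranges = IRanges::IRanges(start = locus$start + 1L, end = locus$end),
    strand = locus$strand
  )
  S4Vectors::mcols(seg) <- S4Vectors::DataFrame(
    type = paste0(locus$segment_type, "_gene_segment"),
    ID = seg_id,
    Name = ifelse(is.na(locus$name), seg_id, locus$name),
    chain = locus$chain,
    functionality = locus$functionality,
    defect_reasons = vapply(locus$defect_reasons %||%
                              rep(list(character(0)), n),
                            function(d) if (length(d))
                              paste(d, collapse = "|") else ".",
                            character(1)),
    subgroup = as.character(locus$subgroup %||% rep(NA, n)),
    group_id = as.character(locus$group_id %||% rep(NA, n)),
    group_kind = locus$group_kind %||% rep(NA_character_, n)
  )
  rss_rows <- list()
  for (i in seq_len(n)) {
    h <- locus$rss[[i]]
    if (is.null(h) || !nrow(h)) next
    h$Parent <- seg_id[[i]]
    rss_rows[[length(rss_rows) + 1L]] <- h
  }
  gr <- seg
  if (length(rss_rows)) {
    h <- bind_rows(rss_rows)
    rss <- GenomicRanges::GRanges(
      seqnames = h$contig,
      ranges = IRanges::IRanges(start = h$start + 1L, end = h$end),
      strand = h$strand
    )
    S4Vectors::mcols(rss) <- S4Vectors::DataFrame(
      type = "recombination_signal_sequence",
      ID = sprintf("rss%03d", seq_len(nrow(h))),
      Name = NA_character_,
      Parent = h$Parent,
      spacer_length = as.character(h$spacer_length),
      heptamer_mismatches = as.character(h$heptamer_mismatches),
      nonamer_mismatches = as.character(h$nonamer_mismatches),
      orientation = h$orientation
    )
    gr <- suppressWarnings(c(seg, rss))
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a locus GFF3 written by [write_locus_gff3()]
#'
#' @param path GFF3 path.
#' @return a `tr_locus` tibble with segments ordered by `start` and RSS
#'   child features re-nested into the `rss` list-column.
#' @export
read_locus_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- as.data.frame(gr)
  md$start0 <- md$start - 1L
  is_seg <- grepl("_gene_segment$", md$type)
  first_chr <- function(x) {
    vapply(x, function(v) if (length(v)) as.character(v)[[1]]
           else NA_character_, character(1))
  }
  if (is.list(md$Parent)) md$Parent <- first_chr(md$Parent)
  seg <- md[is_seg, , drop = FALSE]
  rss <- md[md$type == "recombination_signal_sequence", , drop = FALSE]
  parse_defects <- function(d) {
    lapply(d, function(x) {
      if (is.na(x) || x == ".") character(0) else strsplit(x, "\\|")[[1]]
    })
  }
  out <- tibble(
    contig = as.character(seg$seqnames),
    segment_type = sub("_gene_segment$", "", seg$type),
    chain = seg$chain,
    start = seg$start0,
    end = seg$end,
    strand = as.character(seg$strand),
    functionality = seg$functionality,
    defect_reasons = parse_defects(seg$defect_reasons),
    subgroup = suppressWarnings(as.integer(seg$subgroup)),
    group_id = suppressWarnings(as.integer(seg$group_id)),
    group_kind = seg$group_kind,
    name = seg$Name
  )
  rss_by_parent <- split(seq_len(nrow(rss)), rss$Parent)
  out$rss <- lapply(seg$ID, function(id) {
    ix <- rss_by_parent[[id]]
    if (is.null(ix)) {
      return(tibble(contig = character(), start = integer(),
                    end = integer(), strand = character(),
                    spacer_length = integer(),
                    heptamer_mismatches = integer(),
                    nonamer_mismatches = integer(),
                    orientation = character()))
    }
    h <- rss[ix, , drop = FALSE]
    tibble(
      contig = as.character(h$seqnames),
      start = h$start0, end = h$end,
      strand = as.character(h$strand),
      spacer_length = as.integer(h$spacer_length),
      heptamer_mismatches = as.integer(h$heptamer_mismatches),
      nonamer_mismatches = as.integer(h$nonamer_mismatches),
      orientation = h$orientation
    ) |> arrange(start)
  })
  out <- arrange(out, start, end)
  class(out) <- c("tr_locus", class(out))
  out
}
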