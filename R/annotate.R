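# End-to-end germline locus annotation pipeline.

#' Annotate a TR locus in genomic sequence
#'
#' Runs the full germline annotation pipeline: six-frame homology scan for
#' V/J/C candidates ([find_coding_candidates()]), RSS scanning
#' ([scan_rss()]) and attachment ([attach_rss()]), D-gene detection from
#' facing RSS pairs ([detect_d_segments()]), functionality classification
#' ([classify_functionality()]), V-subgroup clustering
#' ([cluster_subgroups()]), translocon or mini-cluster delineation, and
#' nomenclature ([assign_names()]).
#'
#' @param genome genome input (one-row tibble, string or `DNAString`).
#' @param refs reference protein tibble (`id`, `chain`, `type`, `aa`).
#' @param config an [rss_config()].
#' @param min_score per-type homology score thresholds (see
#'   [find_coding_candidates()]).
#' @param style locus organisation: `"translocon"`, `"minicluster"` or
#'   `"auto"` (mini-clusters when the locus has several C genes, no D genes
#'   and roughly one V per C; translocons otherwise).
#' @param subgroup_threshold identity threshold for V subgroups.
#' @param delta_subgroup see [assign_names()].
#' @param check_j_motif see [classify_functionality()].
#' @return a `tr_locus` tibble: one row per gene segment, ordered by
#'   `start`, with coordinates (0-based half-open), strand, frame,
#'   translation, RSS list-column, functionality, defect reasons, subgroup,
#'   group assignment and name. The RSS hit table is attached as
#'   `attr(, "rss_hits")`, the contig length as `attr(, "contig_length")`.
#' @export
annotate_locus <- function(genome, refs, config = rss_config(),
                           min_score = c(V = 100, J = 55, C = 100),
                           style = c("auto", "translocon", "minicluster"),
                           subgroup_threshold = 0.80,
                           delta_subgroup = NULL,
                           check_j_motif = TRUE) {
  style <- match.arg(style)
  g <- as_genome(genome)

  cand <- find_coding_candidates(g$seq, refs, min_score = min_score)
  cand$contig <- g$id
  hits <- scan_rss(g$seq, config)
  hits$contig <- g$id

  segs <- attach_rss(cand, hits, config)

  # D genes: facing RSS pairs whose core does not overlap a coding candidate
  d <- detect_d_segments(hits, region = NULL, config = config)
  if (nrow(d) && nrow(segs)) {
    overlaps_coding <- vapply(seq_len(nrow(d)), function(i) {
      any(d$start[[i]] < segs$end & d$end[[i]] > segs$start)
    }, logical(1))
    d <- d[!overlaps_coding, , drop = FALSE]
  }
  if (nrow(d)) {
    d$contig <- g$id
    d$chain <- NA_character_
    d$ref_id <- NA_character_
    d$frame <- NA_integer_
    d$score <- NA_real_
    d$rss_missing <- FALSE
    segs <- bind_rows(segs, d)
  }
  segs <- arrange(segs, start, end)

  # D genes inherit the chain of the nearest J gene (they sit in its block)
  if (any(segs$segment_type == "D") && any(segs$segment_type == "J")) {
    jpos <- which(segs$segment_type == "J")
    for (i in which(segs$segment_type == "D" & is.na(segs$chain))) {
      nearest <- jpos[which.min(abs(segs$start[jpos] - segs$start[[i]]))]
      segs$chain[[i]] <- segs$chain[[nearest]]
    }
  }

  segs <- classify_functionality(segs, g$seq, check_j_motif = check_j_motif)
  segs <- cluster_subgroups(segs, threshold = subgroup_threshold)

  if (style == "auto") {
    n_c <- sum(segs$segment_type == "C")
    n_v <- sum(segs$segment_type == "V")
    n_d <- sum(segs$segment_type == "D")
    style <- if (n_d == 0L && n_c >= 3L && n_v <= n_c + 2L)
      "minicluster" else "translocon"
  }
  segs <- if (style == "minicluster") group_miniclusters(segs)
    else delineate_translocons(segs)

  if (is.null(delta_subgroup)) delta_subgroup <- NA
  segs <- assign_names(segs, delta_subgroup = delta_subgroup)

  structure(
    segs,
    rss_hits = hits,
    contig_length = nchar(g$seq),
    class = c("tr_locus", class(segs))
  )
}

#' Summarise an annotated locus
#'
#' @param x a `tr_locus` tibble.
#' @param ... unused.
#' @return a one-row tibble with segment counts by type, functional counts,
#'   number of subgroups and number of groups.
#' @export
glance.tr_locus <- function(x, ...) {
  tibble(
    n_segments = nrow(x),
    n_v = sum(x$segment_type == "V"),
    n_d = sum(x$segment_type == "D"),
    n_j = sum(x$segment_type == "J"),
    n_c = sum(x$segment_type == "C"),
    n_functional = sum(x$functionality == "functional"),
    n_pseudogene = sum(x$functionality == "pseudogene"),
    n_subgroups = dplyr::n_distinct(x$subgroup[!is.na(x$subgroup)]),
    n_groups = dplyr::n_distinct(x$group_id[!is.na(x$group_id)]),
    group_kind = x$group_kind[[1]] %||% NA_character_
  )
}

#' Extract segment sequences from an annotated locus
#'
#' @param locus a `tr_locus` tibble.
#' @param genome the genome it was annotated on.
#' @return a tibble with `name`, `segment_type`, `nt` (gene orientation)
#'   and `aa`.
#' @export
segment_sequences <- function(locus, genome) {
  g <- as_genome(genome)
  tibble(
    name = locus$name,
    segment_type = locus$segment_type,
    nt = vapply(seq_len(nrow(locus)), function(i) {
      segment_nt(locus$start[[i]], locus$end[[i]], locus$strand[[i]], g$seq)
    }, character(1)),
    aa = locus$aa
  )
}
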