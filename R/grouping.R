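# V-gene subgroup clustering and locus-level grouping
# (translocons and mini-clusters).

# pairwise identity between two protein sequences: matches / aligned
# positions with pairwise deletion of gap/ambiguous columns; unequal-length
# inputs are globally aligned first
pairwise_identity <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1
    )
    a <- as.character(Biostrings::alignedPattern(pa))
    b <- as.character(Biostrings::alignedSubject(pa))
  }
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  keep <- !(ca %in% c("-", "X", "?", "*")) & !(cb %in% c("-", "X", "?", "*"))
  if (!any(keep)) return(NA_real_)
  mean(ca[keep] == cb[keep])
}

#' Cluster V genes into subgroups by amino-acid identity
#'
#' Single-linkage clustering of translated V exons: two sequences with
#' pairwise identity strictly greater than `threshold` belong to the same
#' subgroup, and subgroup membership is transitive. Labels are positive
#' integers ordered by the genomic position of each subgroup's 5'-most
#' member. Non-V segments and untranslatable V segments (empty translation)
#' are skipped with a warning and keep `subgroup = NA`.
#'
#' @param segments segment tibble with `segment_type`, `start`, `end`,
#'   `strand` and the `aa` translations from [classify_functionality()].
#' @param threshold identity threshold (fraction); default 0.80.
#' @return `segments` with an integer `subgroup` column.
#' @export
cluster_subgroups <- function(segments, threshold = 0.80) {
  segments$subgroup <- NA_integer_
  is_v <- segments$segment_type == "V"
  if (!any(is_v)) return(segments)
  if (!"aa" %in% names(segments)) {
    abort("segments lack `aa` translations; run classify_functionality() first")
  }
  idx <- which(is_v)
  translatable <- nzchar(segments$aa[idx])
  if (any(!translatable)) {
    warn(sprintf("%d untranslatable V segment(s) skipped in subgroup clustering",
                 sum(!translatable)))
  }
  idx <- idx[translatable]
  if (!length(idx)) return(segments)
  aa <- segments$aa[idx]
  m <- length(idx)
  parent <- seq_len(m)
  find <- function(i) {
    while (parent[[i]] != i) {
      parent[i] <<- parent[[parent[[i]]]]
      i <- parent[[i]]
    }
    i
  }
  if (m > 1) {
    for (i in seq_len(m - 1)) {
      for (j in seq((i + 1), m)) {
        id <- pairwise_identity(aa[[i]], aa[[j]])
        if (!is.na(id) && id > threshold) {
          parent[find(i)] <- find(j)
        }
      }
    }
  }
  comp <- vapply(seq_len(m), find, integer(1))
  # order components by 5'-most member start
  first_start <- tapply(segments$start[idx], comp, min)
  ranks <- rank(first_start, ties.method = "first")
  labels <- setNames(as.integer(ranks), names(first_start))
  segments$subgroup[idx] <- labels[as.character(comp)]
  segments
}

#' Delineate translocons in an ordered locus
#'
#' A translocon runs from its 5'-most V gene to the last gene before the
#' next V-block: a new translocon opens at the first V gene encountered
#' after the current translocon has acquired a C gene. Every segment inside
#' the span belongs to the translocon; segments preceding the first V gene
#' are flagged unassignable (`group_id = NA`) with a warning.
#'
#' @param locus segment tibble ordered (or orderable) by `start`, with
#'   `segment_type`.
#' @return `locus` sorted by `start` with integer `group_id` and
#'   `group_kind = "translocon"`.
#' @export
delineate_translocons <- function(locus) {
  locus <- arrange(locus, start, end)
  n <- nrow(locus)
  gid <- rep(NA_integer_, n)
  current <- 0L
  seen_c <- FALSE
  for (i in seq_len(n)) {
    ty <- locus$segment_type[[i]]
    if (ty == "V" && (current == 0L || seen_c)) {
      current <- current + 1L
      seen_c <- FALSE
    }
    if (current > 0L) gid[[i]] <- current
    if (ty == "C") seen_c <- TRUE
  }
  if (anyNA(gid)) {
    warn(sprintf("%d segment(s) precede the first V gene and are unassignable to a translocon",
                 sum(is.na(gid))))
  }
  locus$group_id <- gid
  locus$group_kind <- "translocon"
  locus
}

#' Summarise translocon extents
#'
#' @param locus output of [delineate_translocons()].
#' @return a tibble with one row per translocon: `group_id`, `start`,
#'   `end`, `n_v`, `n_d`, `n_j`, `n_c`.
#' @export
translocon_table <- function(locus) {
  locus |>
    filter(!is.na(group_id)) |>
    group_by(group_id) |>
    summarise(
      start = min(start), end = max(end),
      n_v = sum(segment_type == "V"), n_d = sum(segment_type == "D"),
      n_j = sum(segment_type == "J"), n_c = sum(segment_type == "C"),
      .groups = "drop"
    )
}

#' Group a locus into V-J-C mini-clusters
#'
#' Walks the locus in transcription order within each run of same-strand
#' segments and chunks it greedily into units opening at each V gene; a
#' unit holding exactly one V, one J and one C is complete, anything else
#' (trailing V-J pairs, units with a missing member) is partial. Clusters
#' are numbered 5' to 3' by genomic position.
#'
#' @param locus segment tibble with `segment_type`, `start`, `end`,
#'   `strand`.
#' @return `locus` sorted by `start` with `group_id`,
#'   `group_kind = "minicluster"` and logical `cluster_complete`.
#' @export
group_miniclusters <- function(locus) {
  locus <- arrange(locus, start, end)
  n <- nrow(locus)
  locus$group_id <- rep(NA_integer_, n)
  locus$group_kind <- rep("minicluster", n)
  locus$cluster_complete <- rep(NA, n)
  if (!n) return(locus)
  runs <- cumsum(c(TRUE, locus$strand[-1] != locus$strand[-n]))
  unit_of <- rep(NA_integer_, n)
  unit_counter <- 0L
  for (r in unique(runs)) {
    idx <- which(runs == r)
    if (locus$strand[[idx[1]]] == "-") idx <- rev(idx)  # transcription order
    open <- FALSE
    for (i in idx) {
      ty <- locus$segment_type[[i]]
      if (ty == "V" || !open) {
        unit_counter <- unit_counter + 1L
        open <- TRUE
      }
      unit_of[[i]] <- unit_counter
      if (ty == "C") open <- FALSE
    }
  }
  # number clusters by genomic position of their leftmost member
  starts <- tapply(locus$start, unit_of, min)
  renum <- setNames(rank(starts, ties.method = "first"), names(starts))
  unit_of <- as.integer(renum[as.character(unit_of)])
  locus$group_id <- unit_of
  for (u in unique(unit_of)) {
    members <- locus$segment_type[unit_of == u]
    complete <- sum(members == "V") == 1L && sum(members == "J") == 1L &&
      sum(members == "C") == 1L
    locus$cluster_complete[unit_of == u] <- complete
  }
  locus
}
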