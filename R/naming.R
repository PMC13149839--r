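# IMGT-style nomenclature for annotated TR loci.
#
# Grammar:
#   beta locus   TRB{translocon}V{subgroup}-{k}  (k: running number within
#                translocon and subgroup, 5'->3'); J/D/C genes are numbered
#                across the whole locus without a translocon digit
#                (TRBJ1..TRBJ23, TRBD1..TRBD3, TRBC1..TRBC3)
#   alpha/delta  TRAV{subgroup}-{k}; the delta-preferential subgroup is
#                marked "/D" (TRAV5/D-1); chain-D segments are TRDJ1/TRDD1/
#                TRDC; single C genes carry no number (TRAC, TRDC)
#   gamma        mini-cluster based: V/J/C of cluster k share the gene
#                number k (TRGV{subgroup}-{k}, TRGJ{k}, TRGC{k}); a missing
#                J/C skips its number; duplicated genes in one cluster get
#                a letter suffix

letter_suffixes <- function(n) {
  if (n <= 26) LETTERS[seq_len(n)] else
    paste0(LETTERS[(seq_len(n) - 1) %/% 26], LETTERS[(seq_len(n) - 1) %% 26 + 1])
}

# append letter suffixes to duplicated names (first occurrence included)
disambiguate <- function(names) {
  for (nm in unique(names[duplicated(names) & !is.na(names)])) {
    idx <- which(!is.na(names) & names == nm)
    names[idx] <- paste0(nm, letter_suffixes(length(idx)))
  }
  names
}

#' Assign IMGT-style names to locus segments
#'
#' Requires subgroup labels (for V genes) and group assignments
#' (translocons or mini-clusters) to be present. Segments whose V subgroup
#' is unassigned are refused a name (`NA`) with a warning. Names are unique
#' within the locus; duplicated genes receive a letter suffix.
#'
#' @param locus segment tibble with `segment_type`, `chain`, `start`,
#'   `subgroup`, `group_id`, `group_kind`.
#' @param chain locus chain context: `"A/D"`, `"B"` or `"G"`. Defaults to
#'   the most common chain label in `locus` (with A and D collapsing to
#'   `"A/D"` when both occur).
#' @param delta_subgroup for `"A/D"` loci: the subgroup marked as
#'   delta-preferential with the `"/D"` designator (`NA` to disable).
#' @return `locus` sorted by `start` with a `name` column.
#' @export
assign_names <- function(locus, chain = NULL, delta_subgroup = NA) {
  locus <- arrange(locus, start, end)
  if (is.null(chain)) {
    chains <- unique(locus$chain)
    chain <- if (all(c("A", "D") %in% chains) || "A/D" %in% chains) "A/D"
      else names(sort(table(locus$chain), decreasing = TRUE))[1]
  }
  n <- nrow(locus)
  name <- rep(NA_character_, n)
  is_v <- locus$segment_type == "V"
  if (any(is_v & is.na(locus$subgroup))) {
    warn(sprintf("naming refused for %d V segment(s) with unassigned subgroup",
                 sum(is_v & is.na(locus$subgroup))))
  }

  if (chain == "B") {
    if (any(is.na(locus$group_id))) {
      warn("segments without translocon assignment are left unnamed")
    }
    # V: translocon digit + subgroup + running number within both
    vidx <- which(is_v & !is.na(locus$subgroup) & !is.na(locus$group_id))
    if (length(vidx)) {
      key <- paste(locus$group_id[vidx], locus$subgroup[vidx])
      k <- stats::ave(seq_along(vidx), key, FUN = seq_along)
      name[vidx] <- sprintf("TRB%dV%d-%d", locus$group_id[vidx],
                            locus$subgroup[vidx], k)
    }
    for (ty in c("D", "J", "C")) {
      idx <- which(locus$segment_type == ty & !is.na(locus$group_id))
      if (length(idx)) name[idx] <- sprintf("TRB%s%d", ty, seq_along(idx))
    }
  } else if (chain == "A/D") {
    sub_token <- function(sub) {
      ifelse(!is.na(delta_subgroup) & sub == delta_subgroup,
             paste0(sub, "/D"), as.character(sub))
    }
    vidx <- which(is_v & !is.na(locus$subgroup))
    if (length(vidx)) {
      k <- stats::ave(seq_along(vidx), locus$subgroup[vidx], FUN = seq_along)
      name[vidx] <- sprintf("TRAV%s-%d", sub_token(locus$subgroup[vidx]), k)
    }
    for (ch in c("A", "D")) {
      for (ty in c("J", "D", "C")) {
        idx <- which(locus$segment_type == ty & locus$chain == ch)
        if (!length(idx)) next
        base <- sprintf("TR%s%s", ch, ty)
        if (ty == "C" && length(idx) == 1L) {
          name[idx] <- base
        } else {
          name[idx] <- sprintf("%s%d", base, seq_along(idx))
        }
      }
    }
  } else if (chain == "G") {
    if (!"group_id" %in% names(locus) || any(is.na(locus$group_id))) {
      warn("segments without mini-cluster assignment are left unnamed")
    }
    vidx <- which(is_v & !is.na(locus$subgroup) & !is.na(locus$group_id))
    if (length(vidx)) {
      name[vidx] <- sprintf("TRGV%d-%d", locus$subgroup[vidx],
                            locus$group_id[vidx])
    }
    for (ty in c("J", "C")) {
      idx <- which(locus$segment_type == ty & !is.na(locus$group_id))
      if (length(idx)) name[idx] <- sprintf("TRG%s%d", ty,
                                            locus$group_id[idx])
    }
  } else {
    abort(sprintf("unknown locus chain context '%s'", chain))
  }

  locus$name <- disambiguate(name)
  locus
}
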