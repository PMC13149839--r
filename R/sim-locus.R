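# Synthetic cod-like TR locus generator.
#
# Emits a genome with planted V/D/J/C genes, RSSs and random intergenic
# sequence, together with the ground-truth locus map, the germline segment
# set used by the V(D)J simulator, and the reference proteins that drive
# the homology scan. Plants are codon-exact: gene ends are held constant
# within a preset so that local alignment recovers the planted intervals
# exactly, while internal codons are mutated to sculpt subgroup structure
# (>80% amino-acid identity within a subgroup, far less between).
#
# Germline junctions are deliberately out of frame: every J carries a 2-nt
# 5' overhang between its RSS and its first codon, and D cores are 14 nt,
# so zero-trim/zero-insertion joints of both the V-J and V-D-J chains are
# non-productive and junctional insertion/deletion is required to restore
# the reading frame.

GEN_CODE <- Biostrings::GENETIC_CODE
# substitution alphabet: no stops (would plant spurious pseudogenes), no
# Cys codons (the 2nd-CYS anchor must stay unique near the V 3' end), no
# Trp (keeps F/W anchors unambiguous)
SAFE_CODONS <- names(GEN_CODE)[!(GEN_CODE %in% c("*", "C", "W"))]

V_N_CODONS <- 96L
V_HEAD <- c("ATG", "GAG", "TCT", "GTG", "CTG")        # codons 1..5, fixed
V_PRE_CYS <- "AGT"                                     # codon 92, fixed
V_CYS <- "TGT"                                         # codon 93: Cys104
V_TAIL <- c("GCT", "ATG", "GAA")                       # codons 94..96
V_CYS_CODON_IDX <- 93L                                 # 1-based codon index

J_HEAD <- c("AAT", "ACT")                              # codons 1..2
J_VAR_IDX <- 3:7                                       # chain-variable codons
J_ANCHOR <- c("TTT", "GGA", "ACA", "GGA")              # F G T G, codons 8..11
J_TAIL <- c("GGC", "ACC", "AAA", "CTG", "GAA")         # codons 12..16
J_LONG_EXTRA <- 7L                                     # extra tail codons
J_OVERHANG <- "GG"                                     # 5' of codon 1
J_ANCHOR_NT_OFFSET <- nchar(J_OVERHANG) + 3L * (8L - 1L)  # = 23

C_N_CODONS <- 150L
D_CORE_LEN <- 14L

random_codons <- function(n) sample(SAFE_CODONS, n, replace = TRUE)

mutate_codons <- function(codons, idx, n_mut) {
  n_mut <- min(n_mut, length(idx))
  if (n_mut < 1) return(codons)
  pos <- sample(idx, n_mut)
  codons[pos] <- sample(SAFE_CODONS, n_mut, replace = TRUE)
  codons
}

make_v_template <- function() {
  c(V_HEAD, random_codons(V_N_CODONS - 10L), V_PRE_CYS, V_CYS, V_TAIL)
}
V_MUTABLE <- 6:91

make_j_template <- function() {
  c(J_HEAD, random_codons(length(J_VAR_IDX)), J_ANCHOR, J_TAIL)
}

make_j_long_template <- function(j_template) {
  c(j_template[1:11], random_codons(J_LONG_EXTRA + 5L))
}

make_c_template <- function() {
  c(V_HEAD, random_codons(C_N_CODONS - 10L), rev(V_HEAD))
}
C_MUTABLE <- 6:(C_N_CODONS - 5L)

rss_string <- function(spacer_length, nonamer = RSS_NONAMER) {
  paste0(RSS_HEPTAMER, random_dna(spacer_length), nonamer)
}

# --- incremental genome builder -------------------------------------------

new_builder <- function(contig = "synthetic_locus") {
  env <- new.env(parent = emptyenv())
  env$contig <- contig
  env$parts <- character(0)
  env$cursor <- 0L
  env$segments <- list()
  env$rss <- list()
  env
}

b_add <- function(b, seq_) {
  s <- b$cursor
  b$parts[[length(b$parts) + 1L]] <- seq_
  b$cursor <- b$cursor + nchar(seq_)
  c(s, b$cursor)
}

b_gap <- function(b, len = NULL) {
  if (is.null(len)) len <- sample(80:160, 1L)
  b_add(b, random_dna(len))
}

record_rss <- function(b, iv, strand, spacer_length, nonamer) {
  b$rss[[length(b$rss) + 1L]] <- tibble(
    contig = b$contig, start = iv[[1]], end = iv[[2]], strand = strand,
    spacer_length = as.integer(spacer_length),
    heptamer_seq = RSS_HEPTAMER, nonamer_seq = nonamer,
    heptamer_mismatches = 0L,
    nonamer_mismatches = str_mismatches(nonamer, RSS_NONAMER),
    orientation = if (strand == "+") "coding-5'" else "coding-3'"
  )
  length(b$rss)
}

record_segment <- function(b, type, chain, iv, strand, nt, rss_idx,
                           subgroup = NA_integer_, pseudo = FALSE,
                           defects = character(0), usable = TRUE) {
  b$segments[[length(b$segments) + 1L]] <- tibble(
    contig = b$contig, segment_type = type, chain = chain,
    start = iv[[1]], end = iv[[2]], strand = strand,
    nt = nt, subgroup = as.integer(subgroup),
    functionality = if (pseudo) "pseudogene" else "functional",
    defect_reasons = list(defects),
    rss_idx = list(rss_idx), usable = usable
  )
}

# V cassette in gene orientation: [exon][RSS]; reversed+complemented when
# planted on the minus strand
plant_v <- function(b, chain, codons, strand, spacer, nonamer = RSS_NONAMER,
                    subgroup = NA, pseudo = FALSE,
                    defects = character(0)) {
  exon <- paste(codons, collapse = "")
  rss <- rss_string(spacer, nonamer)
  if (strand == "+") {
    iv_exon <- b_add(b, exon)
    iv_rss <- b_add(b, rss)
  } else {
    iv_rss <- b_add(b, revcomp(rss))
    iv_exon <- b_add(b, revcomp(exon))
  }
  ri <- record_rss(b, iv_rss, strand, spacer, nonamer)
  record_segment(b, "V", chain, iv_exon, strand, exon, ri,
                 subgroup = subgroup, pseudo = pseudo, defects = defects,
                 usable = !pseudo)
}

# J cassette in gene orientation: [RSS (on opposite strand)][overhang][coding]
plant_j <- function(b, chain, codons, strand, spacer, usable = TRUE) {
  coding <- paste(codons, collapse = "")
  rss <- rss_string(spacer)
  if (strand == "+") {
    iv_rss <- b_add(b, revcomp(rss))
    b_add(b, J_OVERHANG)
    iv_cod <- b_add(b, coding)
    rss_strand <- "-"
  } else {
    iv_cod <- b_add(b, revcomp(coding))
    b_add(b, revcomp(J_OVERHANG))
    iv_rss <- b_add(b, rss)
    rss_strand <- "+"
  }
  ri <- record_rss(b, iv_rss, rss_strand, spacer, RSS_NONAMER)
  record_segment(b, "J", chain, iv_cod, strand, coding, ri, usable = usable)
}

# D cassette in gene orientation: [12-RSS (opposite strand)][core][23-RSS]
plant_d <- function(b, chain, core, strand, config = rss_config()) {
  rss5 <- rss_string(config$spacer_d5)
  rss3 <- rss_string(config$spacer_d3)
  if (strand == "+") {
    iv5 <- b_add(b, revcomp(rss5))
    iv_core <- b_add(b, core)
    iv3 <- b_add(b, rss3)
    r1 <- record_rss(b, iv5, "-", config$spacer_d5, RSS_NONAMER)
    r2 <- record_rss(b, iv3, "+", config$spacer_d3, RSS_NONAMER)
  } else {
    iv3 <- b_add(b, revcomp(rss3))
    iv_core <- b_add(b, revcomp(core))
    iv5 <- b_add(b, rss5)
    r1 <- record_rss(b, iv3, "-", config$spacer_d3, RSS_NONAMER)
    r2 <- record_rss(b, iv5, "+", config$spacer_d5, RSS_NONAMER)
  }
  record_segment(b, "D", chain, iv_core, strand,
                 if (strand == "+") core else core, c(r1, r2))
}

plant_c <- function(b, chain, codons, strand) {
  exon <- paste(codons, collapse = "")
  iv <- b_add(b, if (strand == "+") exon else revcomp(exon))
  record_segment(b, "C", chain, iv, strand, exon, integer(0))
}

# --- preset assembly ------------------------------------------------------

finish_locus <- function(b, style, delta_subgroup = NA) {
  genome <- tibble(id = b$contig, seq = paste(b$parts, collapse = ""))
  rss_tbl <- bind_rows(b$rss)
  truth <- bind_rows(b$segments)
  truth$aa <- translate_dna(truth$nt)
  truth$frame <- 0L
  truth$rss <- lapply(truth$rss_idx, function(ix) {
    if (!length(ix)) rss_tbl[0, , drop = FALSE] else rss_tbl[ix, , drop = FALSE]
  })
  truth$rss_idx <- NULL
  truth <- if (style == "minicluster") group_miniclusters(truth)
    else delineate_translocons(truth)
  truth <- assign_names(truth, delta_subgroup = delta_subgroup)
  attr(truth, "rss_hits") <- rss_tbl
  attr(truth, "contig_length") <- nchar(genome$seq)
  class(truth) <- c("tr_locus", class(truth))
  list(genome = genome, truth = truth)
}

germline_from_truth <- function(truth) {
  is_j <- truth$segment_type == "J"
  tibble(
    id = truth$name,
    chain = truth$chain,
    segment_type = truth$segment_type,
    seq = ifelse(is_j, paste0(J_OVERHANG, truth$nt), truth$nt),
    cys_codon_start = ifelse(truth$segment_type == "V",
                             3L * (V_CYS_CODON_IDX - 1L), NA_integer_),
    anchor_offset = ifelse(is_j, J_ANCHOR_NT_OFFSET, NA_integer_),
    translocon = if ("group_kind" %in% names(truth) &&
                     all(truth$group_kind == "translocon")) {
      truth$group_id
    } else {
      NA_integer_
    },
    functionality = truth$functionality,
    usable = truth$usable
  )
}

refs_row <- function(id, chain, type, codons) {
  tibble(id = id, chain = chain, type = type,
         aa = translate_dna(paste(codons, collapse = "")))
}

build_cod_ad <- function(b, config) {
  v_template <- make_v_template()
  counts <- c(14L, 11L, 10L, 10L, 7L)
  protos <- lapply(seq_along(counts), function(s) {
    mutate_codons(v_template, V_MUTABLE, round(0.35 * length(V_MUTABLE)))
  })
  order_vec <- c(1:5, sample(rep(seq_along(counts), counts - 1L)))
  j_template_a <- make_j_template()
  j_template_d <- make_j_template()
  c_template_a <- make_c_template()
  c_template_d <- make_c_template()
  d_core <- random_dna(D_CORE_LEN)

  seen <- integer(length(counts))
  for (s in order_vec) {
    seen[[s]] <- seen[[s]] + 1L
    codons <- mutate_codons(protos[[s]], V_MUTABLE,
                            round(0.05 * length(V_MUTABLE)))
    pseudo <- s == 1L && seen[[s]] == 9L   # the TRAV1-9-like pseudogene
    if (pseudo) codons[[V_CYS_CODON_IDX]] <- "GGT"
    spacer <- if (s == 5L) 23L else 22L
    nonamer <- if (s == 5L) "ACATAAACC" else RSS_NONAMER
    plant_v(b, "A/D", codons, "+", spacer, nonamer, subgroup = s,
            pseudo = pseudo,
            defects = if (pseudo) c("missing_cys104", "incomplete_cdr3")
              else character(0))
    b_gap(b)
  }
  plant_c(b, "A", c_template_a, "-"); b_gap(b)
  for (k in 1:21) {
    plant_j(b, "A", mutate_codons(j_template_a, J_VAR_IDX, 1L), "-",
            config$spacer_j)
    b_gap(b)
  }
  plant_c(b, "D", c_template_d, "-"); b_gap(b)
  plant_j(b, "D", mutate_codons(j_template_d, J_VAR_IDX, 1L), "-",
          config$spacer_j)
  b_gap(b)
  plant_d(b, "D", d_core, "-", config)

  refs <- bind_rows(
    refs_row("vref_ad", "A/D", "V", v_template),
    refs_row("jref_a", "A", "J", j_template_a),
    refs_row("jref_d", "D", "J", j_template_d),
    refs_row("cref_a", "A", "C", c_template_a),
    refs_row("cref_d", "D", "C", c_template_d)
  )
  list(style = "translocon", delta_subgroup = 5L, refs = refs)
}

build_cod_b <- function(b, config) {
  v_template <- make_v_template()
  n_subgroups <- 9L
  protos <- lapply(seq_len(n_subgroups), function(s) {
    mutate_codons(v_template, V_MUTABLE, round(0.35 * length(V_MUTABLE)))
  })
  patterns <- list(
    c(1, 1, 2, 2, 3, 3, 4, 5, 6, 7),
    c(1, 1, 2, 2, 3, 3, 4, 5, 6, 7),
    c(1, 1, 2, 2, 3, 3, 4, 5, 6, 7, 8, 9, 1, 4)
  )
  j_counts <- c(8L, 7L, 8L)
  j_template <- make_j_template()
  j_long_template <- make_j_long_template(j_template)
  c_template <- make_c_template()

  for (t in 1:3) {
    for (s in patterns[[t]]) {
      codons <- mutate_codons(protos[[s]], V_MUTABLE,
                              round(0.05 * length(V_MUTABLE)))
      spacer <- if (s %% 2L == 1L) 22L else 23L
      plant_v(b, "B", codons, "+", spacer, subgroup = s)
      b_gap(b)
    }
    plant_d(b, "B", random_dna(D_CORE_LEN), "+", config)
    b_gap(b)
    for (k in seq_len(j_counts[[t]])) {
      long <- k == j_counts[[t]]   # terminal J: longer, unused
      codons <- if (long) j_long_template else
        mutate_codons(j_template, J_VAR_IDX, 1L)
      plant_j(b, "B", codons, "+", config$spacer_j, usable = !long)
      b_gap(b)
    }
    plant_c(b, "B", mutate_codons(c_template, C_MUTABLE, 4L), "+")
    b_gap(b, 200L)
  }
  refs <- bind_rows(
    refs_row("vref_b", "B", "V", v_template),
    refs_row("jref_b", "B", "J", j_template),
    refs_row("jref_b_long", "B", "J", j_long_template),
    refs_row("cref_b", "B", "C", c_template)
  )
  list(style = "translocon", delta_subgroup = NA, refs = refs)
}

build_cod_g <- function(b, config) {
  v_proto <- make_v_template()
  j_template <- make_j_template()
  c_template <- make_c_template()
  for (k in 1:6) {
    plant_v(b, "G", mutate_codons(v_proto, V_MUTABLE,
                                  round(0.05 * length(V_MUTABLE))),
            "+", 22L, subgroup = 1L)
    b_gap(b)
    plant_j(b, "G", mutate_codons(j_template, J_VAR_IDX, 1L), "+",
            config$spacer_j)
    b_gap(b)
    plant_c(b, "G", mutate_codons(c_template, C_MUTABLE, 4L), "+")
    b_gap(b, 200L)
  }
  # partial mini-cluster: reverse orientation, no C; V genomically 3' of J
  plant_j(b, "G", mutate_codons(j_template, J_VAR_IDX, 1L), "-",
          config$spacer_j)
  b_gap(b)
  plant_v(b, "G", mutate_codons(v_proto, V_MUTABLE,
                                round(0.05 * length(V_MUTABLE))),
          "-", 22L, subgroup = 1L)
  refs <- bind_rows(
    refs_row("vref_g", "G", "V", v_proto),
    refs_row("jref_g", "G", "J", j_template),
    refs_row("cref_g", "G", "C", c_template)
  )
  list(style = "minicluster", delta_subgroup = NA, refs = refs)
}

#' Build a synthetic cod-like TR locus with ground truth
#'
#' Presets emulate the three locus architectures of the Atlantic cod TR
#' loci:
#' * `cod_AD` — one alpha/delta translocon: 52 forward V genes in five
#'   subgroups (14/11/10/10/7 members; subgroup 5 carries a 23-bp spacer
#'   and the variant nonamer ACATAAACC; the ninth subgroup-1 gene is a
#'   pseudogene lacking Cys104), followed by a reverse alpha C gene,
#'   21 reverse J genes, and a reverse delta C-J-D cassette.
#' * `cod_B` — three consecutive forward translocons with 10/10/14 V genes
#'   (nine subgroups), one D, 8/7/8 J genes (the last J of each translocon
#'   is long and unused) and one C each.
#' * `cod_G` — six complete forward V-J-C mini-clusters plus one partial
#'   reverse V-J cluster lacking its C gene.
#'
#' Deterministic per seed: the same seed yields a byte-identical genome.
#'
#' @param preset `"cod_AD"`, `"cod_B"` or `"cod_G"`.
#' @param seed RNG seed.
#' @param config an [rss_config()] (spacer choices for J and D flanks).
#' @return a list with elements `genome` (one-row tibble `id`/`seq`),
#'   `truth` (`tr_locus` tibble with names, subgroups, groups,
#'   functionality and RSS children), `germline` (segment set for
#'   [simulate_repertoire()]: gene-orientation sequences plus Cys104 / J
#'   anchor positions and translocon ids) and `refs` (reference proteins
#'   for [annotate_locus()]).
#' @export
build_fixture_locus <- function(preset = c("cod_AD", "cod_B", "cod_G"),
                                seed = 1L, config = rss_config()) {
  preset <- match.arg(preset)
  with_seed(seed, {
    b <- new_builder(paste0(tolower(preset), "_locus"))
    b_gap(b, 300L)
    info <- switch(preset,
      cod_AD = build_cod_ad(b, config),
      cod_B = build_cod_b(b, config),
      cod_G = build_cod_g(b, config)
    )
    b_gap(b, 300L)
    loc <- finish_locus(b, info$style, info$delta_subgroup)
    germline <- germline_from_truth(loc$truth)
    list(genome = loc$genome, truth = loc$truth, germline = germline,
         refs = info$refs)
  })
}
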