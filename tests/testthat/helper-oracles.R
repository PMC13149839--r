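# Shared fixtures and independent brute-force oracles for the test suite.
# Oracles are deliberately naive (substring loops, full enumeration) and
# never share code with the implementation paths they check.

# small clonotype tibble builder
clonotbl <- function(counts, aa = NULL, nt = NULL, v = "TRAV1-1",
                     j = "TRAJ1", productive = TRUE) {
  n <- length(counts)
  if (is.null(aa)) aa <- paste0("CASS", LETTERS[seq_len(n)], "F")
  if (is.null(nt)) nt <- vapply(seq_len(n), function(i) {
    paste(rep(c("TGT", "GCA", "AGT", "AGC", "TTT")[
      (i + 0:4) %% 5 + 1], 3)[1:5], collapse = "")
  }, character(1))
  tibble::tibble(
    junction = nt, junction_aa = aa,
    v_call = rep_len(v, n), j_call = rep_len(j, n),
    duplicate_count = as.integer(counts),
    productive = rep_len(productive, n)
  )
}

# random clonotype table for property tests; CDR3s are guaranteed unique
random_clonotbl <- function(n, max_count = 50) {
  i <- seq_len(n)
  aa <- paste0("CASS", LETTERS[(i - 1) %/% 26 + 1],
               LETTERS[(i - 1) %% 26 + 1],
               replicate(n, paste(sample(LETTERS[1:6], 3, TRUE),
                                  collapse = "")), "F")
  nt <- replicate(n, paste(sample(c("A", "C", "G", "T"), 27, TRUE),
                           collapse = ""))
  clonotbl(sample.int(max_count, n, replace = TRUE), aa = aa, nt = nt,
           v = sample(paste0("V", 1:4), n, replace = TRUE))
}

revcomp_chr <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# sliding-window RSS oracle: counts mismatches by explicit substring loops
oracle_scan_rss <- function(seq, spacers = c(12, 22, 23), max_h = 1,
                            max_n = 2, require_cac = TRUE) {
  mism <- function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  scan1 <- function(s, strand, L) {
    out <- list()
    for (sp in spacers) {
      w <- 16 + sp
      for (i in 0:(nchar(s) - w)) {
        hept <- substr(s, i + 1, i + 7)
        nona <- substr(s, i + 8 + sp, i + 16 + sp)
        hm <- mism(hept, "CACAGTG")
        nm <- mism(nona, "ACAAAAACC")
        if (hm > max_h || nm > max_n) next
        if (require_cac && substr(hept, 1, 3) != "CAC") next
        st <- if (strand == "+") i else L - (i + w)
        out[[length(out) + 1]] <- data.frame(
          start = st, end = st + w, strand = strand, spacer_length = sp,
          heptamer_mismatches = hm, nonamer_mismatches = nm
        )
      }
    }
    do.call(rbind, out)
  }
  L <- nchar(seq)
  res <- rbind(scan1(seq, "+", L), scan1(revcomp_chr(seq), "-", L))
  if (is.null(res)) return(res)
  res[order(res$start, res$end, res$strand), , drop = FALSE]
}

# brute-force D50: try every prefix of the sorted counts
oracle_d50 <- function(counts) {
  counts <- sort(counts, decreasing = TRUE)
  total <- sum(counts)
  for (k in seq_along(counts)) {
    if (sum(counts[1:k]) >= total / 2) return(k)
  }
}

oracle_shannon <- function(counts, base = 2) {
  p <- counts / sum(counts)
  -sum(p * log(p) / log(base))
}

# exhaustive concordant/discordant enumeration for tau-b
oracle_tau_b <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      sx <- sign(x[i] - x[j]); sy <- sign(y[i] - y[j])
      if (sx == 0) tx <- tx + 1
      if (sy == 0) ty <- ty + 1
      if (sx * sy > 0) conc <- conc + 1
      if (sx * sy < 0) disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

# closed-form rarefaction expectation (hypergeometric)
oracle_rarefaction_mean <- function(counts, depth) {
  total <- sum(counts)
  sum(1 - choose(total - counts, depth) / choose(total, depth))
}

# translate-and-inspect oracle for V functionality (independent route:
# Biostrings translation on the extracted interval)
oracle_v_defects <- function(nt, has_rss) {
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                           no.init.codon = TRUE))
  defects <- character(0)
  if (nchar(nt) %% 3 != 0) defects <- c(defects, "frameshift")
  if (grepl("\\*", substr(aa, 1, nchar(aa) - 1))) {
    defects <- c(defects, "stop_codon")
  }
  if (!has_rss) defects <- c(defects, "missing_rss")
  tail5 <- substr(aa, nchar(aa) - 4, nchar(aa))
  cys <- gregexpr("C", tail5)[[1]]
  cys <- cys[cys > 0]
  if (!length(cys)) {
    defects <- c(defects, "missing_cys104", "incomplete_cdr3")
  } else if (max(cys) == 5) {
    defects <- c(defects, "incomplete_cdr3")
  }
  defects
}

# cache the fixture loci used across test files (built once per run)
fixture_cache <- new.env(parent = emptyenv())
get_fixture <- function(preset, seed = 7) {
  key <- paste(preset, seed)
  if (is.null(fixture_cache[[key]])) {
    fixture_cache[[key]] <- build_fixture_locus(preset, seed = seed)
  }
  fixture_cache[[key]]
}
get_annotation <- function(preset, seed = 7) {
  key <- paste("ann", preset, seed)
  if (is.null(fixture_cache[[key]])) {
    fx <- get_fixture(preset, seed)
    delta <- if (preset == "cod_AD") 5 else NA
    fixture_cache[[key]] <- annotate_locus(fx$genome, fx$refs,
                                           delta_subgroup = delta)
  }
  fixture_cache[[key]]
}
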