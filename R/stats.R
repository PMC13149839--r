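# Expressed-repertoire statistics.
#
# Every function takes an AIRR-style clonotype tibble (columns `junction`,
# `junction_aa`, `v_call`, `j_call`, `duplicate_count`, `productive`;
# comma-separated multi-gene calls are ambiguous) first and returns a
# tibble, so calls chain with the pipe.

#' Filter clonotypes by read support and productivity
#'
#' Retains clonotypes with at least `min_reads` assigned reads (the
#' default reproduces the "discard receptors with fewer than 5 reads"
#' rule; a clone with exactly 5 reads is kept) and, optionally, only
#' productive clonotypes. Row order is preserved; the filter is
#' idempotent.
#'
#' @param sample clonotype tibble.
#' @param min_reads minimum `duplicate_count` (inclusive).
#' @param productive_only drop non-productive clonotypes.
#' @return the filtered tibble.
#' @export
filter_clonotypes <- function(sample, min_reads = 5L,
                              productive_only = TRUE) {
  stopifnot(min_reads >= 1)
  validate_airr(sample)
  out <- sample[sample$duplicate_count >= min_reads, , drop = FALSE]
  if (productive_only) out <- out[out$productive, , drop = FALSE]
  out
}

#' Rarefaction of unique CDR3s by read depth
#'
#' Subsamples reads without replacement from the read-expanded clonotype
#' multiset and counts unique amino-acid CDR3s, averaged over `n_reps`
#' replicates per depth. At full depth the curve equals the sample's
#' unique count exactly.
#'
#' @param sample clonotype tibble.
#' @param depths read depths to subsample to (each at most the total read
#'   count).
#' @param n_reps subsample replicates per depth.
#' @param seed RNG seed.
#' @param level `"aa"` (unique `junction_aa`) or `"nt"`.
#' @return a `tr_rarefaction` tibble: `depth`, `mean_unique`, `sd_unique`,
#'   `n_reps`.
#' @export
rarefaction <- function(sample, depths, n_reps = 10L, seed = 1L,
                        level = c("aa", "nt")) {
  level <- match.arg(level)
  validate_airr(sample)
  key <- if (level == "aa") sample$junction_aa else sample$junction
  total <- sum(sample$duplicate_count)
  if (any(depths > total)) {
    abort(sprintf("depth %d exceeds total reads (%d)",
                  max(depths), total))
  }
  expanded <- rep.int(match(key, unique(key)), sample$duplicate_count)
  out <- with_seed(seed, {
    purrr::map_dfr(sort(unique(as.integer(depths))), function(d) {
      uniq <- vapply(seq_len(n_reps), function(r) {
        length(unique(expanded[sample.int(total, d)]))
      }, numeric(1))
      tibble(depth = d, mean_unique = mean(uniq), sd_unique = sd(uniq),
             n_reps = n_reps)
    })
  })
  class(out) <- c("tr_rarefaction", class(out))
  out
}

#' D50 repertoire dominance
#'
#' The minimal number of top clonotypes whose reads cover half of the
#' total, with ties in `duplicate_count` broken by amino-acid CDR3
#' lexicographic order for determinism, plus that number as a proportion
#' of unique clonotypes.
#'
#' @param sample clonotype tibble with at least one clonotype.
#' @return a one-row tibble: `d50_count`, `d50_proportion`, `unique`,
#'   `total_reads`.
#' @export
d50 <- function(sample) {
  validate_airr(sample)
  if (!nrow(sample)) abort("d50 needs at least one clonotype")
  ord <- order(-sample$duplicate_count, sample$junction_aa)
  counts <- sample$duplicate_count[ord]
  k <- which(cumsum(counts) >= sum(counts) / 2)[1]
  tibble(d50_count = k, d50_proportion = k / nrow(sample),
         unique = nrow(sample), total_reads = sum(counts))
}

#' Shannon diversity of a repertoire
#'
#' Entropy of the clonotype read-frequency distribution,
#' \eqn{-\sum_i p_i \log_b p_i}.
#'
#' @param sample clonotype tibble.
#' @param base logarithm base (default 2).
#' @return the Shannon index (a number).
#' @export
shannon <- function(sample, base = 2) {
  validate_airr(sample)
  if (!nrow(sample)) abort("shannon needs at least one clonotype")
  p <- sample$duplicate_count / sum(sample$duplicate_count)
  -sum(p * log(p, base = base))
}

#' CDR3 amino-acid length distribution
#'
#' Histogram of CDR3 lengths weighted by unique clonotypes (default) or by
#' reads, plus the mean length.
#'
#' @param sample clonotype tibble with `junction_aa` present.
#' @param weighting `"clonotypes"` or `"reads"`.
#' @return a `tr_cdr3len` tibble (`cdr3_len`, `n`, `prop`) with the mean
#'   (1 decimal) in `attr(, "mean_length")` and exact mean in
#'   `attr(, "mean_length_exact")`.
#' @export
cdr3_length_stats <- function(sample, weighting = c("clonotypes", "reads")) {
  weighting <- match.arg(weighting)
  validate_airr(sample)
  ok <- !is.na(sample$junction_aa) & nzchar(sample$junction_aa)
  if (!any(ok)) abort("no amino-acid CDR3s present")
  len <- nchar(sample$junction_aa[ok])
  w <- if (weighting == "reads") sample$duplicate_count[ok] else
    rep(1L, sum(ok))
  out <- tibble(cdr3_len = len, w = w) |>
    group_by(cdr3_len) |>
    summarise(n = sum(w), .groups = "drop") |>
    mutate(prop = n / sum(n)) |>
    arrange(cdr3_len)
  mean_exact <- sum(len * w) / sum(w)
  attr(out, "mean_length_exact") <- mean_exact
  attr(out, "mean_length") <- round(mean_exact, 1)
  class(out) <- c("tr_cdr3len", class(out))
  out
}

#' V-gene usage
#'
#' Frequency of each germline V gene over clonotypes (or reads) after
#' removing ambiguous calls (those naming more than one gene). The vector
#' covers the full supplied gene universe and sums to 1 (all zero for an
#' empty sample); the dropped-ambiguous fraction is reported as an
#' attribute.
#'
#' @param sample clonotype tibble.
#' @param universe character vector of germline V gene names.
#' @param drop_ambiguous remove clonotypes with ambiguous V calls
#'   (default); if `FALSE`, ambiguous calls are split equally among their
#'   genes.
#' @param weighting `"clonotypes"` or `"reads"`.
#' @return a `tr_usage` tibble (`gene`, `freq`) with
#'   `attr(, "dropped_ambiguous")` = dropped fraction (of clonotypes or
#'   reads, matching `weighting`).
#' @export
v_usage <- function(sample, universe, drop_ambiguous = TRUE,
                    weighting = c("clonotypes", "reads")) {
  weighting <- match.arg(weighting)
  validate_airr(sample)
  stopifnot(length(universe) >= 1)
  calls <- strsplit(sample$v_call, ",")
  unknown <- setdiff(unique(unlist(calls)), universe)
  if (length(unknown)) {
    abort(sprintf("v_call names outside the gene universe: %s",
                  paste(unknown, collapse = ", ")))
  }
  w <- if (weighting == "reads") sample$duplicate_count else
    rep(1L, nrow(sample))
  ambiguous <- lengths(calls) > 1L
  dropped <- if (nrow(sample)) sum(w[ambiguous]) / sum(w) else 0
  freq <- setNames(numeric(length(universe)), universe)
  if (drop_ambiguous) {
    calls <- calls[!ambiguous]
    w <- w[!ambiguous]
  }
  for (i in seq_along(calls)) {
    g <- calls[[i]]
    freq[g] <- freq[g] + w[[i]] / length(g)
  }
  if (sum(freq) > 0) freq <- freq / sum(freq)
  out <- tibble(gene = universe, freq = unname(freq))
  attr(out, "dropped_ambiguous") <- if (drop_ambiguous) dropped else 0
  class(out) <- c("tr_usage", class(out))
  out
}

#' Pairwise correlation of V-gene usage across samples
#'
#' Pearson (or Spearman) correlation of usage vectors for every pair of
#' samples over a shared gene universe, and the mean over distinct pairs.
#' Pairs involving a zero-variance vector are undefined, reported `NA`
#' and excluded from the mean.
#'
#' @param samples named list of clonotype tibbles (one per sample).
#' @param universe shared V gene universe.
#' @param method `"pearson"` or `"spearman"`.
#' @param ... passed to [v_usage()].
#' @return a list: `matrix` (correlation matrix), `mean` (mean off-diagonal
#'   correlation), `usage` (gene-by-sample usage tibble).
#' @export
usage_correlation <- function(samples, universe,
                              method = c("pearson", "spearman"), ...) {
  method <- match.arg(method)
  if (length(samples) < 2) abort("need at least two samples")
  if (is.null(names(samples))) {
    names(samples) <- paste0("sample", seq_along(samples))
  }
  usage <- vapply(samples, function(s) v_usage(s, universe, ...)$freq,
                  numeric(length(universe)))
  rownames(usage) <- universe
  n <- ncol(usage)
  m <- matrix(NA_real_, n, n, dimnames = list(colnames(usage),
                                              colnames(usage)))
  diag(m) <- 1
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (sd(usage[, i]) == 0 || sd(usage[, j]) == 0) next
      m[i, j] <- m[j, i] <- cor(usage[, i], usage[, j], method = method)
    }
  }
  off <- m[upper.tri(m)]
  list(matrix = m, mean = mean(off, na.rm = TRUE),
       usage = as_tibble(usage, rownames = "gene"))
}

# --- Kendall tau-b with exact small-n p-value -----------------------------

kendall_tau_b <- function(x, y) {
  n <- length(x)
  cd <- 0
  tie_x <- 0; tie_y <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      dx <- sign(x[[i]] - x[[j]])
      dy <- sign(y[[i]] - y[[j]])
      cd <- cd + dx * dy
      if (dx == 0) tie_x <- tie_x + 1
      if (dy == 0) tie_y <- tie_y + 1
    }
  }
  n0 <- n * (n - 1) / 2
  denom <- sqrt((n0 - tie_x) * (n0 - tie_y))
  if (denom == 0) return(NA_real_)
  cd / denom
}

kendall_p_value <- function(x, y, tau) {
  n <- length(x)
  if (is.na(tau)) return(NA_real_)
  if (n <= 8) {
    # exact two-sided permutation p over all n! orderings of y
    perms <- permutations_of(n)
    taus <- vapply(perms, function(p) kendall_tau_b(x, y[p]), numeric(1))
    mean(abs(taus) >= abs(tau) - 1e-12)
  } else {
    # normal approximation on the tau-b statistic
    z <- 3 * tau * sqrt(n * (n - 1)) / sqrt(2 * (2 * n + 5))
    2 * pnorm(-abs(z))
  }
}

permutations_of <- function(n) {
  if (n == 1) return(list(1L))
  sub <- permutations_of(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

#' Overlap between two repertoire samples
#'
#' Shared amino-acid CDR3s between two samples of the same chain, with
#' Kendall's tau-b rank correlation of the paired read counts of the
#' shared CDR3s (exact permutation p-value for 8 or fewer shared CDR3s,
#' normal approximation otherwise).
#'
#' @param a,b clonotype tibbles.
#' @param level `"aa"` or `"nt"` CDR3 identity.
#' @return a one-row tibble: `shared`, `union`, `unique_a`, `unique_b`,
#'   `kendall_tau`, `p_value`. The shared CDR3 set is in
#'   `attr(, "shared_cdr3")`.
#' @export
overlap <- function(a, b, level = c("aa", "nt")) {
  level <- match.arg(level)
  validate_airr(a, "a"); validate_airr(b, "b")
  key <- function(s) if (level == "aa") s$junction_aa else s$junction
  counts <- function(s) {
    tibble(k = key(s), n = s$duplicate_count) |>
      group_by(k) |> summarise(n = sum(n), .groups = "drop")
  }
  ca <- counts(a); cb <- counts(b)
  shared <- intersect(ca$k, cb$k)
  tau <- NA_real_; p <- NA_real_
  if (length(shared) >= 2) {
    x <- ca$n[match(shared, ca$k)]
    y <- cb$n[match(shared, cb$k)]
    tau <- kendall_tau_b(x, y)
    p <- kendall_p_value(x, y, tau)
  }
  out <- tibble(
    shared = length(shared),
    union = length(union(ca$k, cb$k)),
    unique_a = nrow(ca), unique_b = nrow(cb),
    kendall_tau = tau, p_value = p
  )
  attr(out, "shared_cdr3") <- shared
  out
}

#' Public and private CDR3 sharing across fish
#'
#' The sharing level of a CDR3 is the number of distinct fish carrying it.
#' Per-sample proportions of CDR3s private to that fish, shared by 2, ...,
#' shared by all are computed over each sample's unique CDR3s and sum
#' to 1.
#'
#' @param samples named list of clonotype tibbles, exactly one per fish
#'   (merge or select technical replicates upstream); names are fish ids.
#' @param level `"aa"` or `"nt"`.
#' @return a `tr_publicness` tibble: `sample_id`, `sharing_level`, `n`,
#'   `prop`. Per-CDR3 levels are in `attr(, "cdr3_levels")`.
#' @export
publicness <- function(samples, level = c("aa", "nt")) {
  level <- match.arg(level)
  if (length(samples) < 2) abort("need at least two fish")
  if (is.null(names(samples)) || anyDuplicated(names(samples))) {
    abort("duplicate or missing fish ids: supply one named sample per fish")
  }
  key <- function(s) unique(if (level == "aa") s$junction_aa else s$junction)
  sets <- lapply(samples, key)
  lev <- table(unlist(lapply(sets, unique)))
  out <- purrr::imap_dfr(sets, function(cdr3s, id) {
    l <- as.integer(lev[cdr3s])
    tibble(sample_id = id, sharing_level = l) |>
      count(sample_id, sharing_level) |>
      mutate(prop = n / length(cdr3s))
  })
  attr(out, "cdr3_levels") <- tibble(cdr3 = names(lev),
                                     sharing_level = as.integer(lev))
  class(out) <- c("tr_publicness", class(out))
  out
}

#' Repertoire-size bounds from partial organ sampling
#'
#' The observed unique count is a lower bound on whole-organ diversity;
#' assuming minimal overlap with the unsampled fraction, the upper bound
#' is `floor(observed / sampling_fraction)`.
#'
#' @param observed_unique observed unique clonotype count.
#' @param sampling_fraction fraction of the organ sampled, in (0, 1].
#' @return a one-row tibble: `lower_bound`, `upper_bound`.
#' @export
repertoire_bounds <- function(observed_unique, sampling_fraction = 0.15) {
  if (sampling_fraction <= 0 || sampling_fraction > 1) {
    abort("sampling_fraction must be in (0, 1]")
  }
  stopifnot(observed_unique >= 0)
  tibble(lower_bound = as.integer(observed_unique),
         upper_bound = as.integer(floor(observed_unique / sampling_fraction)))
}

#' Inter-translocon recombination events
#'
#' Counts clonotypes whose (unambiguously called) V and J genes belong to
#' different translocons. Only clonotypes with single V and J calls can be
#' scored as events; the event fraction is reported both against all
#' clonotypes (the conventional denominator for expressed repertoires)
#' and against the unambiguous subset.
#'
#' @param sample clonotype tibble.
#' @param locus a `tr_locus` (or any tibble with `name` and `group_id`)
#'   providing the translocon id of every V and J gene.
#' @return a list: `summary` (one-row tibble: `n_events`,
#'   `fraction_of_total`, `fraction_of_unambiguous`, `n_total`,
#'   `n_unambiguous`) and `matrix` (V-translocon by J-translocon clonotype
#'   counts).
#' @export
intertranslocon_events <- function(sample, locus) {
  validate_airr(sample)
  tl <- setNames(locus$group_id, locus$name)
  lookup <- function(genes) {
    miss <- setdiff(genes, names(tl))
    if (length(miss)) {
      abort(sprintf("gene(s) missing a translocon id: %s",
                    paste(miss, collapse = ", ")))
    }
    unname(tl[genes])
  }
  unamb <- n_calls(sample$v_call) == 1L & n_calls(sample$j_call) == 1L
  sub <- sample[unamb, , drop = FALSE]
  tv <- if (nrow(sub)) lookup(sub$v_call) else integer(0)
  tj <- if (nrow(sub)) lookup(sub$j_call) else integer(0)
  if (anyNA(tv) || anyNA(tj)) {
    abort("gene(s) missing a translocon id (group_id is NA)")
  }
  events <- tv != tj
  all_t <- sort(unique(locus$group_id[!is.na(locus$group_id)]))
  m <- table(factor(tv, levels = all_t), factor(tj, levels = all_t))
  dimnames(m) <- list(v_translocon = all_t, j_translocon = all_t)
  list(
    summary = tibble(
      n_events = sum(events),
      fraction_of_total = if (nrow(sample)) sum(events) / nrow(sample)
        else NA_real_,
      fraction_of_unambiguous = if (nrow(sub)) mean(events) else NA_real_,
      n_total = nrow(sample), n_unambiguous = nrow(sub)
    ),
    matrix = unclass(m)
  )
}

#' Full diversity report for one sample
#'
#' Convenience wrapper assembling the per-sample diversity statistics into
#' one row: unique nt/aa counts, D50 (count and proportion), Shannon
#' index, functional fraction, mean CDR3 length, and repertoire-size
#' bounds.
#'
#' @param sample clonotype tibble (filter first if desired).
#' @param sampling_fraction organ fraction sampled, for the bounds.
#' @param base Shannon logarithm base.
#' @return a one-row tibble.
#' @export
diversity_report <- function(sample, sampling_fraction = 0.15, base = 2) {
  validate_airr(sample)
  d <- d50(sample)
  bounds <- repertoire_bounds(dplyr::n_distinct(sample$junction_aa),
                              sampling_fraction)
  lens <- cdr3_length_stats(sample)
  tibble(
    unique_nt = dplyr::n_distinct(sample$junction),
    unique_aa = dplyr::n_distinct(sample$junction_aa),
    total_reads = sum(sample$duplicate_count),
    d50_count = d$d50_count,
    d50_proportion = d$d50_proportion,
    shannon = shannon(sample, base = base),
    functional_fraction = mean(sample$productive),
    cdr3_aa_mean = attr(lens, "mean_length"),
    lower_bound = bounds$lower_bound,
    upper_bound = bounds$upper_bound
  )
}
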