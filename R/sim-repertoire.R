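# V(D)J recombination and clonal-expansion simulator.
#
# Junction model: uniform segment choice, geometric exonuclease trimming at
# each coding end, Poisson-many uniform non-templated insertions at each
# junction; VJ joining for alpha/gamma chains, VDJ for beta/delta. The CDR3
# is delimited by the V gene's 2nd-CYS codon and the J gene's F/W anchor
# codon, both inclusive. A rearrangement is productive when the two anchors
# share a reading frame and that reading is stop-free.
#
# Junctional-process parameters (trim geometry, insertion rate) are package
# defaults, documented as such: no species-specific estimates exist for
# cod.

#' Recombination model parameters
#'
#' @param p_trim success parameter of the geometric trim distribution at
#'   every coding end (mean trim `(1-p)/p` nt).
#' @param lambda_ins Poisson mean of non-templated insertions per junction.
#' @param selection_mode `"none"` or `"productive_only"` (redraw until the
#'   rearrangement is productive).
#' @param max_retries bounded retries for trims exceeding segment length or
#'   for the productive-only filter.
#' @return a list of class `recombination_config`.
#' @export
recombination_config <- function(p_trim = 0.4, lambda_ins = 2,
                                 selection_mode = c("none",
                                                    "productive_only"),
                                 max_retries = 200L) {
  stopifnot(p_trim > 0, p_trim <= 1, lambda_ins >= 0)
  selection_mode <- match.arg(selection_mode)
  structure(list(p_trim = p_trim, lambda_ins = lambda_ins,
                 selection_mode = selection_mode,
                 max_retries = as.integer(max_retries)),
            class = "recombination_config")
}

#' Clone-size model parameters
#'
#' Read counts follow a rank-abundance Zipf law: the i-th largest clone
#' receives a share proportional to `i^-exponent`, apportioned so that
#' counts are integers >= 1 summing exactly to `total_reads`. Optional
#' per-read substitution noise (rate per nt within the CDR3) is applied
#' before CDR3 collapse, so low-count artifact clonotypes appear and give
#' the >= 5-read filter something to remove.
#'
#' @param n_clones number of distinct clones.
#' @param exponent Zipf exponent (> 1).
#' @param total_reads total read budget, split across clones.
#' @param error_rate per-nt substitution probability per read.
#' @return a list of class `clone_size_model`.
#' @export
clone_size_model <- function(n_clones = 1000L, exponent = 1.1,
                             total_reads = 50000L, error_rate = 0.001) {
  stopifnot(n_clones >= 1, exponent > 1, total_reads >= n_clones,
            error_rate >= 0, error_rate < 1)
  structure(list(n_clones = as.integer(n_clones), exponent = exponent,
                 total_reads = as.integer(total_reads),
                 error_rate = error_rate),
            class = "clone_size_model")
}

chain_uses_d <- function(chain) chain %in% c("B", "D")

germline_pool <- function(germline, chain, type) {
  sel <- germline$segment_type == type & germline$usable &
    germline$functionality == "functional" &
    (germline$chain == chain |
       (chain %in% c("A", "D") & germline$chain == "A/D"))
  germline[sel, , drop = FALSE]
}

bounded_geom <- function(p, upper, max_retries) {
  for (k in seq_len(max_retries)) {
    x <- rgeom(1L, p)
    if (x <= upper) return(x)
  }
  abort("trim draw exceeded segment length after bounded retries")
}

# plain-vector pools for the inner simulation loop
make_pools <- function(germline, chain, config) {
  vs <- germline_pool(germline, chain, "V")
  js <- germline_pool(germline, chain, "J")
  if (!nrow(vs) || !nrow(js)) {
    abort(sprintf("chain %s not present in germline", chain))
  }
  ds <- if (chain_uses_d(chain)) germline_pool(germline, chain, "D")
    else NULL
  if (chain_uses_d(chain) && !nrow(ds)) {
    abort(sprintf("chain %s requires D segments but none are present",
                  chain))
  }
  list(
    v_id = vs$id, v_seq = vs$seq, v_cys = vs$cys_codon_start,
    j_id = js$id, j_seq = js$seq, j_anchor = js$anchor_offset,
    d_id = ds$id %||% character(0), d_seq = ds$seq %||% character(0)
  )
}

# one rearrangement as a plain list; `pools` from make_pools()
draw_rearrangement <- function(pools, config) {
  for (attempt in seq_len(config$max_retries)) {
    vi <- sample.int(length(pools$v_id), 1L)
    ji <- sample.int(length(pools$j_id), 1L)
    v_seq <- pools$v_seq[[vi]]
    cys_start <- pools$v_cys[[vi]]
    j_seq <- pools$j_seq[[ji]]
    anchor <- pools$j_anchor[[ji]]
    v_len <- nchar(v_seq)
    v_trim <- bounded_geom(config$p_trim, v_len - cys_start - 3L,
                           config$max_retries)
    j_trim <- bounded_geom(config$p_trim, anchor, config$max_retries)
    n1 <- random_dna(rpois(1L, config$lambda_ins))
    if (length(pools$d_id)) {
      di <- sample.int(length(pools$d_id), 1L)
      d_seq <- pools$d_seq[[di]]
      d_len <- nchar(d_seq)
      d5_trim <- bounded_geom(config$p_trim, d_len, config$max_retries)
      d3_trim <- bounded_geom(config$p_trim, d_len - d5_trim,
                              config$max_retries)
      d_part <- substr(d_seq, d5_trim + 1L, d_len - d3_trim)
      n2 <- random_dna(rpois(1L, config$lambda_ins))
      d_call <- pools$d_id[[di]]
    } else {
      d_part <- ""; n2 <- ""; d_call <- NA_character_
      d5_trim <- NA_integer_; d3_trim <- NA_integer_
    }
    v_part <- substr(v_seq, 1L, v_len - v_trim)
    anchor_end <- nchar(v_part) + nchar(n1) + nchar(d_part) + nchar(n2) +
      (anchor - j_trim) + 3L
    cdr3_nt <- substr(paste0(v_part, n1, d_part, n2,
                             substr(j_seq, j_trim + 1L, nchar(j_seq))),
                      cys_start + 1L, anchor_end)
    in_frame <- nchar(cdr3_nt) %% 3L == 0L
    aa <- if (in_frame) translate_dna(cdr3_nt) else NA_character_
    productive <- in_frame && !grepl("\\*", aa)
    if (config$selection_mode == "productive_only" && !productive &&
        attempt < config$max_retries) next
    return(list(v_call = pools$v_id[[vi]], d_call = d_call,
                j_call = pools$j_id[[ji]], junction = cdr3_nt,
                junction_aa = aa, productive = productive,
                v_trim = v_trim, d5_trim = d5_trim, d3_trim = d3_trim,
                j_trim = j_trim, n1 = n1, n2 = n2))
  }
  abort("no productive rearrangement found within the retry budget")
}

#' Simulate a single V(D)J rearrangement
#'
#' Picks V, (D,) J uniformly among usable functional germline segments of
#' the chain, trims each coding end by a geometric draw, inserts
#' Poisson-many uniform nucleotides at each junction, and extracts the CDR3
#' between the V 2nd-CYS and the J F/W anchor (both codons inclusive).
#'
#' @param germline germline segment tibble (the `germline` element of
#'   [build_fixture_locus()]).
#' @param chain `"A"`, `"B"`, `"G"` or `"D"`; `A`/`G` join V-J, `B`/`D`
#'   join V-D-J.
#' @param config a [recombination_config()].
#' @return a one-row tibble: `v_call`, `d_call`, `j_call`, `junction`
#'   (CDR3 nt), `junction_aa` (`NA` when out of frame), `productive`, and
#'   the ground-truth junction record (`v_trim`, `d5_trim`, `d3_trim`,
#'   `j_trim`, `n1`, `n2` inserted strings).
#' @export
recombine_once <- function(germline, chain, config = recombination_config()) {
  pools <- make_pools(germline, chain, config)
  as_tibble(draw_rearrangement(pools, config))
}

# integer apportionment of total_reads over zipf weights, largest first,
# each clone >= 1 read (largest-remainder method; deterministic)
zipf_counts <- function(n_clones, exponent, total_reads) {
  w <- (seq_len(n_clones))^(-exponent)
  share <- total_reads * w / sum(w)
  counts <- floor(share)
  rem <- total_reads - sum(counts)
  if (rem > 0) {
    extra <- order(share - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  # guarantee >= 1 by taking from the largest clone
  zero <- which(counts == 0L)
  if (length(zero)) {
    counts[zero] <- 1L
    counts[[1]] <- counts[[1]] - length(zero)
    if (counts[[1]] < 1L) abort("total_reads too small for n_clones")
  }
  as.integer(counts)
}

#' Simulate a clonotype repertoire with ground truth
#'
#' Draws `n_clones` distinct rearrangements (distinct CDR3 nt), assigns
#' Zipf rank-abundance read counts summing to `total_reads`, applies
#' optional per-read substitution noise within the CDR3 before collapse,
#' and emits an AIRR-style clonotype table. Deterministic per seed.
#'
#' @param germline germline segment tibble.
#' @param chain chain to rearrange.
#' @param config a [recombination_config()].
#' @param clone_model a [clone_size_model()].
#' @param seed RNG seed.
#' @param repertoire_id sample label carried in the output.
#' @return a list: `sample` (AIRR tibble: `repertoire_id`, `junction`,
#'   `junction_aa`, `v_call`, `j_call`, `duplicate_count`, `productive`)
#'   and `truth` (one row per simulated clone with true counts, segment
#'   choices, trims and insertions).
#' @export
simulate_repertoire <- function(germline, chain,
                                config = recombination_config(
                                  selection_mode = "productive_only"),
                                clone_model = clone_size_model(),
                                seed = 1L, repertoire_id = "sim") {
  with_seed(seed, {
    pools <- make_pools(germline, chain, config)
    clones <- vector("list", clone_model$n_clones)
    n_drawn <- 0L
    seen <- new.env(parent = emptyenv(), size = clone_model$n_clones)
    attempts <- 0L
    max_attempts <- 60L * clone_model$n_clones
    while (n_drawn < clone_model$n_clones) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        abort("could not draw the requested number of distinct clonotypes")
      }
      cl <- draw_rearrangement(pools, config)
      if (!is.null(seen[[cl$junction]])) next
      seen[[cl$junction]] <- TRUE
      n_drawn <- n_drawn + 1L
      clones[[n_drawn]] <- cl
    }
    truth <- bind_rows(clones)
    truth$duplicate_count <- zipf_counts(clone_model$n_clones,
                                         clone_model$exponent,
                                         clone_model$total_reads)
    truth$clone_id <- seq_len(nrow(truth))

    # per-read substitution noise within the CDR3, applied pre-collapse
    reads <- truth |>
      select(junction, junction_aa, v_call, j_call, productive,
             duplicate_count)
    if (clone_model$error_rate > 0) {
      extra <- list()
      for (i in seq_len(nrow(reads))) {
        len <- nchar(reads$junction[[i]])
        p_read <- 1 - (1 - clone_model$error_rate)^len
        n_mut <- rbinom(1L, reads$duplicate_count[[i]], p_read)
        if (n_mut == 0L) next
        reads$duplicate_count[[i]] <- reads$duplicate_count[[i]] - n_mut
        for (m in seq_len(n_mut)) {
          nt <- strsplit(reads$junction[[i]], "")[[1]]
          pos <- sample.int(len, 1L)
          nt[[pos]] <- sample(setdiff(DNA_BASES, nt[[pos]]), 1L)
          mutated <- paste(nt, collapse = "")
          in_frame <- nchar(mutated) %% 3L == 0L
          aa <- if (in_frame) translate_dna(mutated) else NA_character_
          extra[[length(extra) + 1L]] <- tibble(
            junction = mutated, junction_aa = aa,
            v_call = reads$v_call[[i]], j_call = reads$j_call[[i]],
            productive = in_frame && !grepl("\\*", aa),
            duplicate_count = 1L
          )
        }
      }
      reads <- bind_rows(reads[reads$duplicate_count > 0L, ], bind_rows(extra))
    }
    sample_tbl <- reads |>
      group_by(junction) |>
      summarise(
        junction_aa = junction_aa[[1]],
        v_call = paste(sort(unique(v_call)), collapse = ","),
        j_call = paste(sort(unique(j_call)), collapse = ","),
        duplicate_count = as.integer(sum(duplicate_count)),
        productive = productive[[1]],
        .groups = "drop"
      ) |>
      arrange(desc(duplicate_count), junction) |>
      mutate(repertoire_id = repertoire_id, .before = 1)
    list(sample = sample_tbl, truth = truth)
  })
}
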