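toy_germline <- function() {
  tibble::tibble(
    id = c("V1", "J1"),
    chain = "A",
    segment_type = c("V", "J"),
    seq = c("ATGGAATCTTGTGCAGTG",   # ...Cys at codon 4
            "TTTGGAACAGGAGAA"),     # F G T G E, anchor at offset 0
    cys_codon_start = c(9L, NA),
    anchor_offset = c(NA, 0L),
    translocon = NA_integer_,
    functionality = "functional",
    usable = TRUE
  )
}

test_that("an engineered in-frame germline joint reproduces the anchored
           concatenation", {
  cfg <- recombination_config(p_trim = 1, lambda_ins = 0)  # no trims/ins
  set.seed(1)
  cl <- recombine_once(toy_germline(), "A", cfg)
  expect_equal(cl$junction, "TGTGCAGTGTTT")  # Cys codon .. F codon
  expect_equal(cl$junction_aa, "CAVF")
  expect_true(cl$productive)
  expect_equal(cl$v_trim, 0L)
  expect_equal(cl$j_trim, 0L)
})

test_that("cod-like germline configurations are non-productive without
           junctional editing, for both the alpha and delta chain", {
  fx <- get_fixture("cod_AD")
  cfg <- recombination_config(p_trim = 1, lambda_ins = 0)
  set.seed(2)
  for (chain in c("A", "D")) {
    for (k in 1:10) {
      cl <- recombine_once(fx$germline, chain, cfg)
      expect_false(cl$productive)
    }
  }
})

test_that("single-nucleotide insertions at the V-J junction restore the
           frame exactly as brute-force enumeration predicts", {
  fx <- get_fixture("cod_AD")
  g <- fx$germline
  v <- g[g$segment_type == "V" & g$functionality == "functional", ][1, ]
  j <- g[g$segment_type == "J" & g$chain == "A", ][1, ]
  productive_oracle <- function(ins) {
    joint <- paste0(v$seq, ins, j$seq)
    cdr3 <- substr(joint, v$cys_codon_start + 1,
                   nchar(v$seq) + nchar(ins) + j$anchor_offset + 3)
    if (nchar(cdr3) %% 3 != 0) return(FALSE)
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(cdr3)))
    !grepl("\\*", aa)
  }
  # the germline joint (no insertion) is out of frame ...
  expect_false(productive_oracle(""))
  # ... and every 1-nt insertion restores the frame (the germline offset
  # is 2 mod 3), so productivity is decided by stop codons alone
  single <- vapply(c("A", "C", "G", "T"), productive_oracle, logical(1))
  in_frame <- vapply(c("A", "C", "G", "T"), function(b) {
    nchar(paste0(substr(v$seq, v$cys_codon_start + 1, nchar(v$seq)),
                 b, substr(j$seq, 1, j$anchor_offset + 3))) %% 3 == 0
  }, logical(1))
  expect_true(all(in_frame))
  expect_true(any(single))
  # two-nt insertions leave the joint out of frame again
  expect_false(productive_oracle("AA"))
})

test_that("the simulator's productive flag agrees with a translate-and-scan
           oracle on every emitted junction", {
  fx <- get_fixture("cod_AD")
  sim <- simulate_repertoire(
    fx$germline, "A",
    config = recombination_config(selection_mode = "none"),
    clone_model = clone_size_model(n_clones = 150, total_reads = 3000,
                                   error_rate = 0),
    seed = 5
  )
  oracle <- vapply(sim$sample$junction, function(nt) {
    if (nchar(nt) %% 3 != 0) return(FALSE)
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt)))
    !grepl("\\*", aa)
  }, logical(1), USE.NAMES = FALSE)
  expect_equal(sim$sample$productive, oracle)
})

test_that("noise-free simulation recovers truth calls by exact matching and
           conserves reads", {
  fx <- get_fixture("cod_AD")
  sim <- simulate_repertoire(
    fx$germline, "A",
    clone_model = clone_size_model(n_clones = 200, total_reads = 5000,
                                   error_rate = 0),
    seed = 6
  )
  expect_equal(sum(sim$sample$duplicate_count), 5000L)
  expect_equal(sum(sim$truth$duplicate_count), 5000L)
  expect_setequal(sim$sample$junction, sim$truth$junction)
  merged <- dplyr::inner_join(sim$sample, sim$truth, by = "junction",
                              suffix = c("", "_truth"))
  expect_equal(nrow(merged), 200L)
  expect_equal(merged$v_call, merged$v_call_truth)
  expect_equal(merged$j_call, merged$j_call_truth)
  expect_equal(merged$duplicate_count, merged$duplicate_count_truth)
})

test_that("identical seeds give identical fixtures and repertoires", {
  a <- build_fixture_locus("cod_G", seed = 11)
  b <- build_fixture_locus("cod_G", seed = 11)
  expect_identical(a$genome$seq, b$genome$seq)
  expect_identical(as.data.frame(a$truth[, c("start", "end", "name")]),
                   as.data.frame(b$truth[, c("start", "end", "name")]))
  c_ <- build_fixture_locus("cod_G", seed = 12)
  expect_false(identical(a$genome$seq, c_$genome$seq))

  s1 <- simulate_repertoire(a$germline, "G",
                            clone_model = clone_size_model(
                              n_clones = 100, total_reads = 2000),
                            seed = 9)
  s2 <- simulate_repertoire(a$germline, "G",
                            clone_model = clone_size_model(
                              n_clones = 100, total_reads = 2000),
                            seed = 9)
  expect_identical(as.data.frame(s1$sample), as.data.frame(s2$sample))
})

test_that("presets without planted defects contain only functional genes", {
  for (preset in c("cod_B", "cod_G")) {
    fx <- get_fixture(preset)
    expect_true(all(fx$truth$functionality == "functional"))
  }
  # cod_AD plants exactly one pseudogene
  ad <- get_fixture("cod_AD")
  expect_equal(sum(ad$truth$functionality == "pseudogene"), 1L)
})

test_that("read-level noise produces low-count artifact clonotypes that the
           read filter removes", {
  fx <- get_fixture("cod_AD")
  sim <- simulate_repertoire(
    fx$germline, "A",
    clone_model = clone_size_model(n_clones = 100, total_reads = 20000,
                                   error_rate = 0.002),
    seed = 10
  )
  expect_gt(nrow(sim$sample), 100)            # artifacts appeared
  expect_equal(sum(sim$sample$duplicate_count), 20000L)  # still conserved
  kept <- filter_clonotypes(sim$sample, min_reads = 5,
                            productive_only = FALSE)
  expect_lt(nrow(kept), nrow(sim$sample))
  artifacts <- dplyr::anti_join(sim$sample, sim$truth, by = "junction")
  expect_true(all(artifacts$duplicate_count <
                    max(sim$sample$duplicate_count)))
})

test_that("impossible requests fail loudly", {
  expect_error(recombine_once(toy_germline(), "B"), "not present")
  tiny <- toy_germline()
  expect_error(
    simulate_repertoire(tiny, "A",
                        config = recombination_config(p_trim = 1,
                                                      lambda_ins = 0),
                        clone_model = clone_size_model(n_clones = 5,
                                                       total_reads = 50,
                                                       error_rate = 0),
                        seed = 1),
    "distinct clonotypes"
  )
})
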