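test_that("a planted canonical RSS is found with exact coordinates", {
  set.seed(42)
  flank <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")
  spacer <- flank(23)
  seq <- paste0(flank(100), "CACAGTG", spacer, "ACAAAAACC", flank(100))
  hits <- scan_rss(seq)
  planted <- hits[hits$start == 100, ]
  expect_equal(nrow(planted), 1L)
  expect_equal(planted$end, 100L + 16L + 23L)
  expect_equal(planted$strand, "+")
  expect_equal(planted$spacer_length, 23L)
  expect_equal(planted$heptamer_mismatches, 0L)
  expect_equal(planted$nonamer_mismatches, 0L)
  expect_equal(planted$orientation, "coding-5'")
})

test_that("hits beyond the mismatch budget are rejected", {
  set.seed(43)
  flank <- paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = "")
  # heptamer with 3 mismatches vs CACAGTG
  seq <- paste0(flank, "CAGTCAG", strrep("A", 12), "ACAAAAACC", flank)
  hits <- scan_rss(seq)
  expect_false(any(hits$start == 80 & hits$strand == "+"))
})

test_that("the ACATAAACC nonamer variant is reported with one mismatch", {
  set.seed(44)
  flank <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  seq <- paste0(flank, "CACAGTG", strrep("G", 23), "ACATAAACC", flank)
  hits <- scan_rss(seq)
  planted <- hits[hits$start == 60 & hits$strand == "+", ]
  expect_equal(nrow(planted), 1L)
  expect_equal(planted$nonamer_mismatches, 1L)
  expect_equal(planted$nonamer_seq, "ACATAAACC")
  expect_equal(planted$spacer_length, 23L)
})

test_that("scanning matches the sliding-window oracle on random sequence", {
  for (s in 1:3) {
    set.seed(s)
    seq <- paste(sample(c("A", "C", "G", "T"), 4000, TRUE), collapse = "")
    # plant one canonical RSS so the fixture is never trivially empty
    seq <- paste0(seq, "CACAGTG", strrep("T", 12), "ACAAAAACC",
                  substr(seq, 1, 500))
    hits <- scan_rss(seq)
    orc <- oracle_scan_rss(seq)
    expect_equal(nrow(hits), nrow(orc))
    expect_equal(hits$start, orc$start)
    expect_equal(hits$end, orc$end)
    expect_equal(hits$strand, orc$strand)
    expect_equal(hits$heptamer_mismatches, orc$heptamer_mismatches)
    expect_equal(hits$nonamer_mismatches, orc$nonamer_mismatches)
  }
})

test_that("scanning the reverse complement mirrors the hit set", {
  fx <- get_fixture("cod_G")
  seq <- fx$genome$seq
  n <- nchar(seq)
  fwd <- scan_rss(seq)
  rev_ <- scan_rss(revcomp(seq))
  mirrored <- data.frame(
    start = n - rev_$end, end = n - rev_$start,
    strand = ifelse(rev_$strand == "+", "-", "+"),
    spacer_length = rev_$spacer_length
  )
  mirrored <- mirrored[order(mirrored$start, mirrored$end,
                             mirrored$strand), ]
  expect_equal(fwd$start, mirrored$start)
  expect_equal(fwd$end, mirrored$end)
  expect_equal(fwd$strand, mirrored$strand)
  expect_equal(fwd$spacer_length, mirrored$spacer_length)
})

test_that("attach_rss links the adjacent correctly oriented hit", {
  drafts <- tibble::tibble(
    contig = "c", segment_type = c("V", "J"),
    start = c(100L, 600L), end = c(500L, 650L), strand = "+"
  )
  hits <- tibble::tibble(
    contig = "c",
    start = c(500L, 560L), end = c(538L, 588L),
    strand = c("+", "-"), spacer_length = c(22L, 12L),
    heptamer_seq = "CACAGTG", nonamer_seq = "ACAAAAACC",
    heptamer_mismatches = 0L, nonamer_mismatches = 0L,
    orientation = c("coding-5'", "coding-3'")
  )
  out <- attach_rss(drafts, hits, rss_config(max_gap = 15))
  expect_false(any(out$rss_missing))
  expect_equal(out$rss[[1]]$start, 500L)  # V: RSS at its coding 3' end
  expect_equal(out$rss[[2]]$end, 588L)    # J: RSS at its coding 5' end
})

test_that("attach_rss flags out-of-range and wrongly oriented hits", {
  v <- tibble::tibble(contig = "c", segment_type = "V",
                      start = 100L, end = 500L, strand = "+")
  far <- tibble::tibble(
    contig = "c", start = 550L, end = 588L, strand = "+",
    spacer_length = 22L, heptamer_seq = "CACAGTG",
    nonamer_seq = "ACAAAAACC", heptamer_mismatches = 0L,
    nonamer_mismatches = 0L, orientation = "coding-5'"
  )
  out <- attach_rss(v, far, rss_config(max_gap = 1))
  expect_true(out$rss_missing)

  # J with a hit on the wrong strand (a J RSS must read away from the
  # gene on the opposite strand)
  j <- tibble::tibble(contig = "c", segment_type = "J",
                      start = 600L, end = 650L, strand = "+")
  wrong <- dplyr::mutate(far, start = 570L, end = 598L, strand = "+")
  out <- attach_rss(j, wrong, rss_config(max_gap = 5))
  expect_true(out$rss_missing)
  out <- attach_rss(j, dplyr::mutate(wrong, strand = "-",
                                     spacer_length = 12L),
                    rss_config(max_gap = 5))
  expect_false(out$rss_missing)
})

test_that("detect_d_segments requires facing flanks and a bounded core", {
  mk_hit <- function(start, end, strand, sp) tibble::tibble(
    contig = "c", start = start, end = end, strand = strand,
    spacer_length = sp, heptamer_seq = "CACAGTG",
    nonamer_seq = "ACAAAAACC", heptamer_mismatches = 0L,
    nonamer_mismatches = 0L,
    orientation = ifelse(strand == "+", "coding-5'", "coding-3'")
  )
  facing <- dplyr::bind_rows(mk_hit(100L, 128L, "-", 12L),
                             mk_hit(140L, 179L, "+", 23L))
  d <- detect_d_segments(facing)
  expect_equal(nrow(d), 1L)
  expect_equal(c(d$start, d$end), c(128L, 140L))  # 12-nt core
  expect_equal(d$strand, "+")
  expect_equal(nrow(d$rss[[1]]), 2L)

  # same orientation: no D
  same <- dplyr::bind_rows(mk_hit(100L, 128L, "+", 12L),
                           mk_hit(140L, 179L, "+", 23L))
  expect_equal(nrow(detect_d_segments(same)), 0L)

  # facing but 500 nt apart: rejected by the length gate
  far <- dplyr::bind_rows(mk_hit(100L, 128L, "-", 12L),
                          mk_hit(628L, 667L, "+", 23L))
  expect_equal(nrow(detect_d_segments(far, config = rss_config(
    max_d_length = 40))), 0L)
})
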