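test_that("the read filter keeps >=5 reads, drops non-productive rows, and
           is idempotent", {
  x <- clonotbl(c(4, 5, 6, 50))
  x$productive[[4]] <- FALSE
  f <- filter_clonotypes(x)
  expect_equal(f$duplicate_count, c(5L, 6L))   # 4 reads out, 5 kept
  expect_identical(filter_clonotypes(f), f)
  expect_equal(nrow(filter_clonotypes(x[0, ])), 0L)
  f2 <- filter_clonotypes(x, productive_only = FALSE)
  expect_equal(f2$duplicate_count, c(5L, 6L, 50L))
})

test_that("rarefaction hits the exact unique count at full depth and tiny
           depths behave analytically", {
  x <- clonotbl(c(1, 1, 1))
  r <- rarefaction(x, depths = c(1, 3), n_reps = 20, seed = 1)
  expect_equal(r$mean_unique[r$depth == 3], 3)   # exhaustive draw
  expect_equal(r$sd_unique[r$depth == 3], 0)
  expect_equal(r$mean_unique[r$depth == 1], 1)   # one read, one clone

  expect_error(rarefaction(x, depths = 10), "exceeds")
})

test_that("rarefaction means match the hypergeometric closed form", {
  x <- clonotbl(c(5, 5))
  n_reps <- 400
  r <- rarefaction(x, depths = 2, n_reps = n_reps, seed = 2)
  expected <- oracle_rarefaction_mean(c(5, 5), 2)
  expect_equal(expected, 2 - 2 * choose(5, 2) / choose(10, 2))  # 1.5556
  se <- r$sd_unique / sqrt(n_reps)
  expect_lt(abs(r$mean_unique - expected), 3 * se)

  # a second toy with three unequal clones
  y <- clonotbl(c(6, 3, 1))
  ry <- rarefaction(y, depths = 4, n_reps = n_reps, seed = 3)
  exp_y <- oracle_rarefaction_mean(c(6, 3, 1), 4)
  expect_lt(abs(ry$mean_unique - exp_y),
            3 * ry$sd_unique / sqrt(n_reps) + 1e-9)
})

test_that("D50 worked examples and brute-force property", {
  expect_equal(d50(clonotbl(rep(10, 10)))$d50_count, 5L)
  expect_equal(d50(clonotbl(rep(10, 10)))$d50_proportion, 0.5)
  expect_equal(d50(clonotbl(c(50, 30, 10, 10)))$d50_count, 1L)
  single <- d50(clonotbl(5))
  expect_equal(single$d50_count, 1L)
  expect_equal(single$d50_proportion, 1)

  set.seed(4)
  for (rep in 1:20) {
    x <- random_clonotbl(sample(2:20, 1))
    expect_equal(d50(x)$d50_count, oracle_d50(x$duplicate_count))
  }
})

test_that("Shannon entropy matches the direct formula", {
  expect_equal(shannon(clonotbl(rep(3, 8))), 3)
  expect_equal(shannon(clonotbl(7)), 0)
  expect_equal(shannon(clonotbl(c(3, 1))), 0.8113, tolerance = 1e-4)
  set.seed(5)
  for (rep in 1:10) {
    x <- random_clonotbl(sample(2:20, 1))
    expect_equal(shannon(x, base = exp(1)),
                 oracle_shannon(x$duplicate_count, base = exp(1)))
  }
  # permutation invariance
  x <- random_clonotbl(12)
  expect_equal(shannon(x), shannon(x[sample(nrow(x)), ]))
})

test_that("CDR3 length statistics report the weighted histogram and mean", {
  x <- clonotbl(c(2, 2), aa = c("CASSLGAQYF", "CASSLGGETQYVFG"))  # 10, 14
  st <- cdr3_length_stats(x)
  expect_equal(attr(st, "mean_length"), 12)
  expect_equal(st$n, c(1, 1))
  st_reads <- cdr3_length_stats(clonotbl(c(3, 1), aa = c("CASSLGAQYF",
                                                         "CASSLGGETQYVFG")),
                                weighting = "reads")
  expect_equal(attr(st_reads, "mean_length"), 11)  # (3*10 + 14)/4
  allsame <- cdr3_length_stats(clonotbl(c(1, 1),
                                        aa = c("CASSLGGETQYVF",
                                               "CASSLGAETQYVF")))
  expect_equal(attr(allsame, "mean_length"), 13)
})

test_that("V usage drops ambiguous calls and tallies like a hand count", {
  x <- clonotbl(c(10, 5, 5, 2), v = c("V1", "V1", "V2", "V1,V2"))
  u <- v_usage(x, universe = c("V1", "V2", "V3"))
  expect_equal(u$freq, c(2 / 3, 1 / 3, 0))
  expect_equal(sum(u$freq), 1)
  expect_equal(attr(u, "dropped_ambiguous"), 1 / 4)

  ur <- v_usage(x, universe = c("V1", "V2", "V3"), weighting = "reads")
  expect_equal(ur$freq, c(15 / 20, 5 / 20, 0))
  expect_equal(attr(ur, "dropped_ambiguous"), 2 / 22)

  one <- v_usage(clonotbl(3, v = "V2"), universe = c("V1", "V2"))
  expect_equal(one$freq, c(0, 1))

  expect_error(v_usage(clonotbl(1, v = "VX"), universe = "V1"), "VX")
})

test_that("usage correlations match the direct formula and handle
           degenerate vectors", {
  # usage here is clonotype-weighted: repeated gene calls shape the vector
  s1 <- clonotbl(c(5, 5, 2), v = c("V1", "V1", "V2"))
  s2 <- clonotbl(c(1, 1, 1), v = c("V1", "V1", "V2"))
  uni <- c("V1", "V2", "V3")
  r <- usage_correlation(list(a = s1, b = s2), uni)
  expect_equal(r$matrix["a", "b"], 1)

  s3 <- clonotbl(c(9, 1), v = c("V1", "V1"))
  s4 <- clonotbl(c(1, 9), v = c("V2", "V2"))
  r2 <- usage_correlation(list(a = s3, b = s4), c("V1", "V2"))
  expect_equal(r2$matrix["a", "b"], -1)

  s5 <- clonotbl(c(2, 3, 7), v = c("V2", "V3", "V3"))
  r3 <- usage_correlation(list(a = s1, b = s4, c = s5), uni)
  ua <- v_usage(s1, uni)$freq; ub <- v_usage(s4, uni)$freq
  uc <- v_usage(s5, uni)$freq
  expect_equal(r3$matrix["a", "c"], cor(ua, uc))
  expect_equal(r3$mean, mean(c(cor(ua, ub), cor(ua, uc), cor(ub, uc))))

  # a zero-variance usage vector leaves its pairs undefined
  flat1 <- clonotbl(c(1, 1), v = c("V1", "V2"))
  skew <- clonotbl(c(1, 1, 1), v = c("V1", "V1", "V2"))
  r4 <- usage_correlation(list(a = flat1, b = skew, c = skew),
                          c("V1", "V2"))
  expect_true(is.na(r4$matrix["a", "b"]))
  expect_equal(r4$mean, 1)  # only the b-c pair is defined
})

test_that("overlap reports sharing and Kendall tau-b with exact small-n
           p-values", {
  x <- clonotbl(c(30, 20, 10, 5, 2))
  same <- overlap(x, x)
  expect_equal(same$shared, 5L)
  expect_equal(same$kendall_tau, 1)

  rev_ <- clonotbl(rev(c(30, 20, 10, 5, 2)),
                   aa = x$junction_aa)
  opp <- overlap(x, rev_)
  expect_equal(opp$kendall_tau, -1)

  # hand-set counts with ties against the enumeration oracle
  a <- clonotbl(c(12, 7, 7, 3, 1))
  b <- clonotbl(c(5, 9, 2, 2, 8), aa = a$junction_aa)
  o <- overlap(a, b)
  expect_equal(o$kendall_tau, oracle_tau_b(a$duplicate_count,
                                           b$duplicate_count))
  # cross-check the tau-b statistic against stats::cor
  expect_equal(o$kendall_tau,
               suppressWarnings(cor(a$duplicate_count, b$duplicate_count,
                                    method = "kendall")))
  expect_true(o$p_value >= 0 && o$p_value <= 1)

  # fewer than two shared CDR3s: tau undefined
  disjoint <- overlap(clonotbl(3, aa = "CAAAF"), clonotbl(3, aa = "CBBBF"))
  expect_equal(disjoint$shared, 0L)
  expect_true(is.na(disjoint$kendall_tau))
})

test_that("the exact small-n p-value agrees with the normal approximation
           in direction and with enumeration on a known case", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(1, 2, 3, 5, 4)
  tau <- codtcr:::kendall_tau_b(x, y)
  p_exact <- codtcr:::kendall_p_value(x, y, tau)
  # 5! = 120 orderings; count those with |tau| >= observed
  perms <- codtcr:::permutations_of(5L)
  taus <- vapply(perms, function(p) codtcr:::kendall_tau_b(x, y[p]),
                 numeric(1))
  expect_equal(p_exact, mean(abs(taus) >= abs(tau) - 1e-12))
})

test_that("publicness partitions each repertoire into sharing levels", {
  f1 <- clonotbl(c(5, 5), aa = c("CAAAF", "CBBBF"))
  f2 <- clonotbl(c(5, 5), aa = c("CCCCF", "CDDDF"))
  p <- publicness(list(fish1 = f1, fish2 = f2))
  expect_true(all(p$sharing_level == 1))
  expect_true(all(p$prop == 1))

  # one CDR3 present in all three fish
  g1 <- clonotbl(c(5, 5, 5), aa = c("CXXXF", "CAAAF", "CBBBF"))
  g2 <- clonotbl(c(5, 5), aa = c("CXXXF", "CCCCF"))
  g3 <- clonotbl(c(5, 5), aa = c("CXXXF", "CDDDF"))
  p3 <- publicness(list(f1 = g1, f2 = g2, f3 = g3))
  lev <- attr(p3, "cdr3_levels")
  expect_equal(lev$sharing_level[lev$cdr3 == "CXXXF"], 3L)
  top <- p3[p3$sample_id == "f1" & p3$sharing_level == 3, ]
  expect_equal(top$prop, 1 / 3)
  sums <- tapply(p3$prop, p3$sample_id, sum)
  expect_true(all(abs(sums - 1) < 1e-12))

  twin <- publicness(list(a = f1, b = f1))
  expect_true(all(twin$sharing_level == 2))

  expect_error(publicness(list(f1, f1)), "fish ids")
})

test_that("repertoire bounds reproduce the worked examples and are
           monotone", {
  expect_equal(repertoire_bounds(4422, 0.15)$upper_bound, 29480L)
  expect_equal(repertoire_bounds(852, 0.15)$upper_bound, 5680L)
  full <- repertoire_bounds(100, 1)
  expect_equal(c(full$lower_bound, full$upper_bound), c(100L, 100L))
  # decreasing the sampled fraction never decreases the upper bound
  fracs <- c(1, 0.5, 0.2, 0.15, 0.05)
  ups <- vapply(fracs, function(f) repertoire_bounds(500, f)$upper_bound,
                integer(1))
  expect_true(all(diff(ups) >= 0))
  expect_error(repertoire_bounds(10, 0), "sampling_fraction")
  expect_error(repertoire_bounds(10, 1.2), "sampling_fraction")
})

test_that("inter-translocon events count unambiguous cross-pairings over
           the full denominator", {
  locus <- tibble::tibble(
    name = c("TRB1V1-1", "TRB2V1-1", "TRBJ1", "TRBJ9"),
    group_id = c(1L, 2L, 1L, 2L)
  )
  x <- clonotbl(c(10, 10, 10, 10),
                v = c("TRB1V1-1", "TRB1V1-1", "TRB2V1-1", "TRB1V1-1"),
                j = c("TRBJ9", "TRBJ1", "TRBJ9", "TRBJ1,TRBJ9"))
  ev <- intertranslocon_events(x, locus)
  expect_equal(ev$summary$n_events, 1L)          # V1(t1) x J9(t2)
  expect_equal(ev$summary$n_unambiguous, 3L)     # ambiguous J excluded
  expect_equal(ev$summary$fraction_of_total, 1 / 4)
  expect_equal(ev$summary$fraction_of_unambiguous, 1 / 3)
  expect_equal(ev$matrix["1", "1"], 1)
  expect_equal(ev$matrix["2", "2"], 1)

  expect_error(intertranslocon_events(
    clonotbl(1, v = "TRBV9-9", j = "TRBJ1"), locus), "TRBV9-9")
})

test_that("statistics on a noise-free simulated sample match the truth
           table", {
  fx <- get_fixture("cod_AD")
  sim <- simulate_repertoire(
    fx$germline, "A",
    clone_model = clone_size_model(n_clones = 120, total_reads = 4000,
                                   error_rate = 0),
    seed = 12
  )
  truth_as_sample <- dplyr::transmute(
    sim$truth, junction, junction_aa, v_call, j_call,
    duplicate_count, productive
  )
  expect_equal(d50(sim$sample)$d50_count,
               d50(truth_as_sample)$d50_count)
  expect_equal(shannon(sim$sample), shannon(truth_as_sample))
  uni <- sort(unique(fx$germline$id[fx$germline$segment_type == "V"]))
  expect_equal(v_usage(sim$sample, uni)$freq,
               v_usage(truth_as_sample, uni)$freq)
})

test_that("the one-row diversity report assembles the component statistics",
{
  x <- clonotbl(c(40, 20, 10, 10, 10, 5, 5))
  rep_ <- diversity_report(x, sampling_fraction = 0.5)
  expect_equal(rep_$unique_aa, 7L)
  expect_equal(rep_$d50_count, d50(x)$d50_count)
  expect_equal(rep_$shannon, shannon(x))
  expect_equal(rep_$upper_bound, 14L)
  expect_equal(rep_$functional_fraction, 1)
})
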