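test_that("self-match scores exactly 3.0 and disjoint peak sets score 0", {
  mz <- c(3000, 4500, 6000, 7500, 9000, 10500)
  int <- c(0.5, 1, 0.8, 0.3, 0.9, 0.6)
  msp <- simple_msp(mz, int, name = "self")
  hit <- score_spectrum(msp_as_peaklist(msp), msp)
  expect_equal(hit$log_score, 3, tolerance = 1e-9)
  expect_equal(c(hit$s_query, hit$s_ref, hit$s_int), c(1, 1, 1))

  disjoint <- peak_list(mz + 1000, int)
  miss <- score_spectrum(disjoint, msp)
  expect_equal(miss$log_score, 0)
  expect_equal(miss$s_query, 0)

  expect_error(score_spectrum(peak_list(numeric(0), numeric(0)), msp),
               "no peaks")
})

test_that("the composite reproduces hand-computed component arithmetic", {
  # ref: 6 peaks; query: 4 peaks of which 3 match; intensities chosen so the
  # matched-pair Pearson correlation is 0.8
  ref_mz <- c(3000, 4000, 5000, 6000, 7000, 8000)
  msp <- simple_msp(ref_mz, rep(1, 6), name = "hand")
  msp$peaks$intensity <- c(1, 2, 3, 1, 1, 1) / 3
  qi <- c(1, 2, 2.6)
  r <- cor(qi, c(1, 2, 3))  # hand-checkable Pearson correlation of 3 pairs
  query <- peak_list(c(3000, 4000, 5000, 12000), c(qi, 3))
  hit <- score_spectrum(query, msp, freq_weight = FALSE)
  expect_equal(hit$s_query, 0.75)          # 3 of 4 query peaks matched
  expect_equal(hit$s_ref, 0.5)             # 3 of 6 reference peaks matched
  expect_equal(hit$s_int, r, tolerance = 1e-9)
  expect_equal(hit$log_score, log10(1000 * 0.75 * 0.5 * r), tolerance = 1e-9)
  # matched intensities engineered for correlation 0.8: the composite is
  # log10(1000 * 0.75 * 0.5 * 0.8) = log10(300) = 2.477
  hit2 <- score_spectrum(peak_list(c(3000, 4000, 5000, 12000),
                                   c(1, 2, 1.8699, 3)), msp,
                         freq_weight = FALSE)
  expect_equal(hit2$s_int, 0.8, tolerance = 1e-4)
  expect_equal(hit2$log_score, 2.477, tolerance = 1e-3)
})

test_that("scores are scale-invariant and clamped to [0, 3]", {
  msp <- simple_msp(c(3000, 4500, 6000, 7500), c(0.4, 1, 0.7, 0.2), name = "s")
  q <- peak_list(c(3000.5, 4499, 6001), c(0.4, 1, 0.7))
  a <- score_spectrum(q, msp)
  b <- score_spectrum(peak_list(q$mz, q$intensity * 417), msp)
  expect_equal(a$log_score, b$log_score, tolerance = 1e-12)
  expect_gte(a$log_score, 0)
  expect_lte(a$log_score, 3)
})

test_that("ranking is sorted, deterministic under ties, and self-first", {
  own <- simple_msp(c(3000, 4500, 6000, 7500, 9000), rep(1, 5), name = "own")
  twin_b <- simple_msp(c(3000, 4500, 6000, 7500, 9000), rep(1, 5), name = "twin_b")
  twin_a <- simple_msp(c(3000, 4500, 6000, 7500, 9000), rep(1, 5), name = "twin_a")
  other <- simple_msp(c(3300, 4800, 6300), rep(1, 3), name = "other")
  lib <- spectral_library(list(own, twin_b, twin_a, other))
  r <- rank_hits(msp_as_peaklist(own), lib)
  expect_equal(r$log_score[1], 3, tolerance = 1e-9)
  # identical entries tie at 3.0 and are ordered lexicographically
  expect_equal(r$entry_name[1:3], c("own", "twin_a", "twin_b")[order(c("own", "twin_a", "twin_b"))])
  expect_true(all(diff(r$log_score) <= 1e-12))
  expect_error(rank_hits(msp_as_peaklist(own), spectral_library(list())), "empty")
})

test_that("a sister species sharing half its peaks ranks below the true one", {
  true_mz <- c(3000, 4000, 5000, 6000, 7000, 8000, 9000, 10000)
  sister_mz <- c(3000, 4000, 5000, 6000, 11000, 12000, 13000, 14000)
  lib <- spectral_library(list(
    simple_msp(true_mz, rep(1, 8), name = "true_species"),
    simple_msp(sister_mz, rep(1, 8), name = "sister_species")))
  q <- peak_list(true_mz, rep(1, 8))
  r <- rank_hits(q, lib)
  expect_equal(r$entry_name[1], "true_species")
  expect_gt(r$log_score[1], r$log_score[2])
})

test_that("the replicate-consensus rubric follows the 2.2 / 3-of-4 rule", {
  fake_hits <- function(scores, entries) {
    lapply(seq_along(scores), function(i)
      data.frame(entry_name = entries[i], log_score = scores[i],
                 s_query = 1, s_ref = 1, s_int = 1, n_matched = 5L))
  }
  ent <- rep("Bacillus safensis_FO36b^T", 4)
  call1 <- consensus_call(fake_hits(c(2.3, 2.3, 2.3, 2.3), ent))
  expect_equal(call1$consensus, "species_level")
  expect_equal(call1$entry, ent[1])

  # all four replicates below threshold -> unidentified / potentially novel
  call2 <- consensus_call(fake_hits(rep(2.03, 4), rep("Bacillus pumilus_DSM 27^T", 4)),
                          genus_threshold = 2.1)
  expect_equal(call2$consensus, "unidentified")

  # 3 of 4 pass -> still species level
  call3 <- consensus_call(fake_hits(c(2.5, 2.5, 2.1, 2.5), ent))
  expect_equal(call3$consensus, "species_level")

  # same scores but disagreeing top entries -> no species consensus
  call4 <- consensus_call(fake_hits(c(2.5, 2.5, 2.5, 2.5),
                                    c("Bacillus a", "Bacillus b",
                                      "Bacillus c", "Bacillus d")),
                          genus_threshold = 2.0)
  expect_equal(call4$consensus, "genus_level")
  expect_equal(call4$entry, "Bacillus")
})

test_that("raising the threshold never converts unidentified into identified", {
  fake <- lapply(c(2.25, 2.21, 2.3, 1.9), function(s)
    data.frame(entry_name = "E sp_X", log_score = s,
               s_query = 1, s_ref = 1, s_int = 1, n_matched = 5L))
  thresholds <- seq(1.8, 3.0, by = 0.1)
  states <- vapply(thresholds, function(th)
    consensus_call(fake, threshold = th)$consensus == "species_level",
    logical(1))
  expect_false(any(diff(states) > 0))  # once lost, never regained
})
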