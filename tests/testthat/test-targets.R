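test_that("duplex scoring follows the penalty rules", {
  set.seed(41)
  mir <- random_seq(21)
  perfect <- revcomp(mir)
  d <- score_duplex(mir, perfect)
  expect_equal(d$expectation, 0)
  expect_true(all(d$states == "match"))

  # G:U at miRNA position 5 (inside the doubled region): 0.5 x 2 = 1.0
  mir_g <- mir
  substr(mir_g, 5, 5) <- "G"
  site <- strsplit(revcomp(mir_g), "")[[1]]
  site[21 - 5 + 1] <- "T"  # G faces U
  d <- score_duplex(mir_g, paste(site, collapse = ""))
  expect_equal(d$expectation, 1.0)
  expect_equal(d$states[5], "GU")

  # mismatch at position 20 (outside the doubled region): 1.0
  site <- strsplit(perfect, "")[[1]]
  site[21 - 20 + 1] <- substr(mir, 20, 20)  # same base: always a mismatch
  d <- score_duplex(mir, paste(site, collapse = ""))
  expect_equal(d$expectation, 1.0)
  expect_equal(d$states[20], "mismatch")

  # mismatch at position 10 (doubled): 2.0
  site <- strsplit(perfect, "")[[1]]
  site[21 - 10 + 1] <- substr(mir, 10, 10)
  d <- score_duplex(mir, paste(site, collapse = ""))
  expect_equal(d$expectation, 2.0)

  expect_error(score_duplex(mir, substr(perfect, 1, 10)), "equal length")
})

test_that("adding a mismatch never decreases the expectation", {
  set.seed(42)
  for (k in 1:50) {
    mir <- random_seq(21)
    site <- strsplit(revcomp(mir), "")[[1]]
    # corrupt a random subset of positions, one at a time
    e_prev <- score_duplex(mir, paste(site, collapse = ""))$expectation
    for (p in sample(21, 5)) {
      site[21 - p + 1] <- substr(mir, p, p)
      e_now <- score_duplex(mir, paste(site, collapse = ""))$expectation
      expect_gte(e_now, e_prev)
      e_prev <- e_now
    }
  }
})

test_that("inhibition is translational only for central mismatches", {
  set.seed(43)
  mir <- random_seq(21)
  perfect <- revcomp(mir)
  expect_equal(classify_inhibition(score_duplex(mir, perfect)), "cleavage")

  site <- strsplit(perfect, "")[[1]]
  site[21 - 10 + 1] <- substr(mir, 10, 10)
  expect_equal(classify_inhibition(score_duplex(mir, paste(site, collapse = ""))),
               "translation")

  # G:U at position 10 is not a mismatch
  mir_g <- mir
  substr(mir_g, 10, 10) <- "G"
  site <- strsplit(revcomp(mir_g), "")[[1]]
  site[21 - 10 + 1] <- "T"
  d <- score_duplex(mir_g, paste(site, collapse = ""))
  expect_equal(d$states[10], "GU")
  expect_equal(classify_inhibition(d), "cleavage")
})

test_that("transcript scanning honours threshold, best-per-transcript and top_n", {
  set.seed(44)
  mir <- random_seq(21)
  site <- revcomp(mir)

  tx <- random_seq(400)
  substr(tx, 200, 220) <- site
  hits <- scan_targets(c(m1 = mir), c(t1 = tx))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$expectation, 0)
  expect_equal(hits$site_start, 200)
  expect_equal(hits$rank, 1L)

  # a site with expectation 3.5 (mismatches at 1, 20, 21 and GU at 14;
  # 1 + 1 + 1 + 0.5) is rejected at the default ceiling 3.0
  mir2 <- random_seq(21)
  substr(mir2, 14, 14) <- "G"
  s2 <- strsplit(revcomp(mir2), "")[[1]]
  for (p in c(1, 20, 21)) s2[21 - p + 1] <- substr(mir2, p, p)
  s2[21 - 14 + 1] <- "T"
  expect_equal(score_duplex(mir2, paste(s2, collapse = ""))$expectation, 3.5)
  tx2 <- random_seq(400)
  substr(tx2, 100, 120) <- paste(s2, collapse = "")
  expect_equal(nrow(scan_targets(c(m = mir2), c(t = tx2))), 0)

  # 60 transcripts with perfect sites: capped at top 50
  txs <- vapply(1:60, function(i) {
    t <- random_seq(120)
    substr(t, 50, 70) <- site
    t
  }, character(1))
  names(txs) <- sprintf("tx%02d", 1:60)
  hits <- scan_targets(c(m1 = mir), txs, top_n = 50)
  expect_equal(nrow(hits), 50)
  expect_equal(hits$rank, 1:50)
  expect_true(all(hits$expectation <= 3.0))
})

test_that("planted sites are recovered with their exact expectations", {
  study <- study_fixture(42)
  truth <- study$transcriptome$truth
  hits <- scan_targets(study$target_mirnas, study$transcriptome$transcripts)
  joined <- dplyr::inner_join(truth, hits, by = c("transcript_id", "mirna_id"),
                              suffix = c("_truth", "_hit"))
  expect_equal(nrow(joined), nrow(truth))
  expect_equal(joined$expectation_hit, joined$expectation_truth,
               tolerance = 1e-12)
  expect_equal(joined$inhibition_hit, joined$inhibition_truth)
  expect_equal(joined$site_start_hit, joined$site_start_truth)
})

test_that("cleavage fractions summarise the inhibition calls", {
  hits <- tibble::tibble(inhibition = c("cleavage", "cleavage", "cleavage",
                                        "translation"))
  s <- summarize_cleavage(hits)
  expect_equal(s$fraction, 0.75)
  expect_equal(s$n_total, 4)
  expect_equal(summarize_cleavage(hits[hits$inhibition == "cleavage", ])$fraction, 1)
  expect_equal(summarize_cleavage(hits[0, ])$fraction, 0)
})
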