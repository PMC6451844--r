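test_that("folding reproduces the canonical toy structures", {
  f <- fold_hairpin("GGGAAACCC")
  expect_equal(f$dot_bracket, "(((...)))")
  expect_equal(f$pair_sum, 9)
  expect_equal(f$score, -9)

  f <- fold_hairpin("AAAAAA")
  expect_equal(nrow(f$pairs), 0)
  expect_equal(f$score, 0)

  expect_error(fold_hairpin("ACGTNACGTA"), "invalid base")
})

test_that("DP optimum equals the exhaustive enumeration oracle", {
  set.seed(31)
  for (k in 1:200) {
    s <- random_seq(sample(5:14, 1))
    expect_equal(fold_hairpin(s)$pair_sum, enum_fold_score(s), info = s)
  }
})

test_that("folding score is symmetric under sequence reversal", {
  # reversing the sequence maps any structure onto one of equal weight
  # (the pair-weight table is symmetric); with G:U wobble permitted this
  # does NOT hold for the reverse complement, where G:U maps to A:C
  set.seed(32)
  for (k in 1:50) {
    s <- random_seq(sample(10:40, 1))
    srev <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    expect_equal(fold_hairpin(s)$pair_sum, fold_hairpin(srev)$pair_sum,
                 info = s)
  }
})

test_that("structures satisfy the pairing invariants", {
  set.seed(33)
  for (k in 1:30) {
    s <- random_seq(sample(20:60, 1))
    f <- fold_hairpin(s)
    p <- f$partner
    # symmetry and single partner
    idx <- which(p > 0)
    expect_true(all(p[p[idx]] == idx))
    # minimum hairpin loop of 3
    if (nrow(f$pairs) > 0) expect_true(all(f$pairs$j - f$pairs$i >= 4))
    # no crossing pairs
    if (nrow(f$pairs) > 1) {
      for (a in seq_len(nrow(f$pairs) - 1)) {
        for (b in (a + 1):nrow(f$pairs)) {
          i1 <- f$pairs$i[a]; j1 <- f$pairs$j[a]
          i2 <- f$pairs$i[b]; j2 <- f$pairs$j[b]
          crossing <- (i1 < i2 && i2 < j1 && j1 < j2) ||
            (i2 < i1 && i1 < j2 && j2 < j1)
          expect_false(crossing)
        }
      }
    }
  }
})

test_that("stem-loop classification accepts planted hairpins and rejects controls", {
  set.seed(34)
  mature <- random_seq(21)
  hairpin <- paste0(mature, random_seq(6), revcomp(mature))
  f <- fold_hairpin(hairpin)
  v <- classify_stem_loop(f, 1, 21)
  expect_true(v$is_stem_loop)
  expect_equal(v$arm, "5p")
  expect_equal(v$mature_paired_fraction, 1.0)

  # the star arm classifies as 3p
  v3 <- classify_stem_loop(f, nchar(hairpin) - 20, 21)
  expect_true(v3$is_stem_loop)
  expect_equal(v3$arm, "3p")

  # mature centred on the terminal loop
  arm <- "GGGGCCCCGGGGCC"
  hp <- paste0(arm, "AAAATTTT", revcomp(arm))
  vloop <- classify_stem_loop(fold_hairpin(hp), 12, 12)
  expect_true(vloop$mature_crosses_loop)
  expect_false(vloop$is_stem_loop)

  # unpairable window: C-rich mature inside an A-homopolymer flank
  flatseq <- paste0(strrep("A", 40), strrep("CCA", 7), strrep("A", 40))
  vflat <- classify_stem_loop(fold_hairpin(flatseq), 41, 21)
  expect_lt(vflat$mature_paired_fraction, 0.6)
  expect_false(vflat$is_stem_loop)
})

test_that("classification is invariant to flank truncation", {
  set.seed(35)
  mature <- random_seq(21)
  core <- paste0(mature, random_seq(6), revcomp(mature))
  for (flank in c(0, 20, 80)) {
    win <- paste0(random_seq(flank), core, random_seq(flank))
    v <- classify_stem_loop(fold_hairpin(win), flank + 1, 21)
    expect_true(v$is_stem_loop, info = paste("flank", flank))
  }
})

test_that("CT files round-trip and report parse errors with line numbers", {
  # toy structure: 9 rows, first row pairs with the last
  f <- fold_hairpin("GGGAAACCC")
  ct <- write_ct(f)
  expect_equal(length(ct), 10)
  row1 <- strsplit(ct[2], "\t")[[1]]
  expect_equal(as.integer(row1[5]), 9)

  # unpaired-only structure
  ct0 <- write_ct(fold_hairpin("AAAAAA"))
  pair_col <- vapply(strsplit(ct0[-1], "\t"), function(x) as.integer(x[5]),
                     integer(1))
  expect_true(all(pair_col == 0))

  # round trips on random folded sequences
  set.seed(36)
  for (k in 1:20) {
    f <- fold_hairpin(random_seq(sample(15:60, 1)))
    back <- read_ct(write_ct(f))
    expect_equal(back$sequence, f$sequence)
    expect_equal(back$partner, f$partner)
    expect_equal(back$dot_bracket, f$dot_bracket)
    expect_equal(back$pair_sum, f$pair_sum)
  }

  # file round trip
  fp <- tempfile(fileext = ".ct")
  f <- fold_hairpin("GGGGAAAACCCCAAAA")
  write_ct(f, fp)
  expect_equal(read_ct(fp)$partner, f$partner)

  bad <- write_ct(f)
  bad[3] <- "oops"
  expect_error(read_ct(bad), "line 3")
})
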