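test_that("miRBase-style headers parse into species and family", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">osa-miR156a-5p", "UGACAGAAGAGAGUGAGCAC",
               ">tae-miR5049-3p", "UAUGGUUUGGAACGGAGGGAGU",
               ">ath-miR172b", "AGAAUCUUGAUGAUGCUGCAU",
               ">weird-header-1", "ACGUACGUACGUACGUACGU"), fa)
  expect_warning(refs <- read_mature_fasta(fa), "skipped 1")
  expect_equal(nrow(refs), 3)
  expect_equal(refs$species, c("osa", "tae", "ath"))
  expect_equal(refs$family, c("miR156", "miR5049", "miR172"))
  # U converted to T
  expect_false(any(grepl("U", refs$sequence)))
  expect_equal(attr(refs, "n_skipped"), 1L)

  expect_equal(mirna_family(c("tae-miR5049-3p", "miR399", "oops")),
               c("miR5049", "miR399", NA))
})

test_that("local alignment matches the trivial arithmetic cases", {
  a <- "TGACAGAAGAGAGTGAGCACA"  # 21-mer
  al <- align_local(a, a)
  expect_equal(al$score, 21)
  expect_equal(al$matches, 21)
  expect_equal(al$identity, 1.0)

  b <- a
  substr(b, 11, 11) <- "C"  # internal substitution (A -> C)
  al <- align_local(a, b)
  expect_equal(al$matches, 20)
  expect_equal(al$mismatches, 1)
  expect_equal(al$identity, 20 / 21)
})

test_that("local alignment equals independent oracles on random pairs", {
  # truly exhaustive path enumeration on very short pairs
  set.seed(101)
  for (k in 1:40) {
    a <- random_seq(sample(4:7, 1))
    b <- random_seq(sample(4:7, 1))
    expect_equal(align_local(a, b)$score, enum_local_score(a, b),
                 info = paste(a, b))
  }
  # Biostrings Smith-Waterman on pairs up to 12 nt
  set.seed(102)
  for (k in 1:200) {
    a <- random_seq(sample(10:12, 1))
    b <- random_seq(sample(10:12, 1))
    expect_equal(align_local(a, b)$score, biostrings_local_score(a, b),
                 info = paste(a, b))
  }
  # a 20-mer against its reverse
  set.seed(103)
  a <- random_seq(20)
  b <- paste(rev(strsplit(a, "")[[1]]), collapse = "")
  expect_equal(align_local(a, b)$score, biostrings_local_score(a, b))
})

test_that("Karlin-Altschul lambda solves the composition equation", {
  ka <- karlin_altschul()
  # bisection oracle for 0.25 e^l + 0.75 e^(-2l) = 1
  f <- function(l) 0.25 * exp(l) + 0.75 * exp(-2 * l) - 1
  lo <- 1e-6; hi <- 10
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  expect_equal(ka$lambda, (lo + hi) / 2, tolerance = 1e-9)
  expect_gt(ka$K, 0)

  # E-value behaviour: monotone in score, linear in n, capped at K*m*n
  e1 <- evalue(20, 21, 1000, ka)
  e2 <- evalue(30, 21, 1000, ka)
  expect_lt(e2, e1)
  expect_equal(evalue(20, 21, 2000, ka), 2 * e1)
  expect_equal(evalue(-5, 21, 1000, ka), ka$K * 21 * 1000)
  expect_lt(evalue(1000, 21, 1000, ka), 1e-300)
})

test_that("homology search applies identity, coverage and E-value filters", {
  refs <- tibble::tibble(
    ref_id = c("osa-miR901a-5p", "osa-miR902a-5p"),
    species = "osa", family = c("miR901", "miR902"),
    sequence = c("TGACAGAAGAGAGTGAGCACA", "ACCGATCTCTTTAAGGCCTGA"),
    length = 21
  )

  # read identical to a reference: retained with identity 1
  uniq <- collapse_reads(rep("TGACAGAAGAGAGTGAGCACA", 3))
  hits <- search_mirna_homologs(uniq, refs)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$identity, 1.0)
  expect_equal(hits$family, "miR901")
  expect_equal(hits$count, 3L)

  # identity exactly 0.90 is NOT retained (strict inequality):
  # 20-mer with 2 substitutions -> 18 matches over 20 columns
  mut <- "TGACAGAAGAGAGTGAGCAC"
  substr(mut, 5, 5) <- "T"
  substr(mut, 15, 15) <- "A"
  hits <- search_mirna_homologs(collapse_reads(mut), refs)
  expect_equal(nrow(hits), 0)

  # random reads against a small reference: empirical null, no hits
  set.seed(104)
  rnd <- vapply(1:200, function(i) random_seq(21), character(1))
  hits <- search_mirna_homologs(collapse_reads(rnd), refs)
  expect_equal(nrow(hits), 0)
})

test_that("retained hits always satisfy the filter predicates", {
  study <- study_fixture(42)
  trimmed <- trim_reads(study$reads$reads, conmir_adapter())
  uniq <- collapse_reads(trimmed)
  refs <- tibble::tibble(ref_id = study$reference$ref_id,
                         species = study$reference$species,
                         family = study$reference$family,
                         sequence = study$reference$sequence,
                         length = nchar(study$reference$sequence))
  hits <- search_mirna_homologs(uniq, refs)
  expect_gt(nrow(hits), 0)
  expect_true(all(hits$identity > 0.90))
  expect_true(all(hits$coverage >= 0.90))
  expect_true(all(hits$e_value <= 1e-4))
  expect_true(all(hits$sequence %in% uniq$sequence))
  # one hit per unique read at most
  expect_lte(nrow(hits), nrow(uniq))
  expect_false(anyDuplicated(hits$sequence) > 0)
})

test_that("family summaries count distinct sequences and families", {
  hits <- tibble::tibble(
    sequence = c("AAAA", "CCCC"), count = c(2L, 1L),
    family = c("miR156", "miR156")
  )
  s <- summarize_families(hits)
  expect_equal(s$n_sequences, 2)
  expect_equal(s$n_families, 1)

  s0 <- summarize_families(hits[0, ])
  expect_equal(s0$n_sequences, 0)
  expect_equal(s0$n_families, 0)

  # error-free synthetic reads recover every planted family
  study <- study_fixture(42)
  reads0 <- sim_reads(study$planted, error_rate = 0, decoy_fraction = 0,
                      seed = 5)
  uniq <- collapse_reads(trim_reads(reads0$reads, conmir_adapter()))
  refs <- study$reference
  hits <- search_mirna_homologs(uniq, refs)
  s <- summarize_families(hits)
  expect_equal(s$n_families, length(unique(study$planted$family)))
  expect_true(all(hits$family %in% study$planted$family))
  # family count never exceeds sequence count
  expect_lte(s$n_families, s$n_sequences)
})
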