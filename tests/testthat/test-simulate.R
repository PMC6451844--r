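test_that("the mature reference generator is seeded and shape-correct", {
  ref <- sim_mature_reference(12, 3, seed = 7)
  expect_equal(nrow(ref), 36)
  expect_equal(length(unique(ref$family)), 12)
  expect_true(all(nchar(ref$sequence) %in% 20:22))
  # cross-species variants stay within 2 substitutions of the canonical
  mm <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, ref$sequence, ref$canonical)
  expect_true(all(mm <= 2))
  expect_equal(mm == 0, ref$n_substitutions == 0, ignore_attr = TRUE)

  # byte-identical under the same seed
  ref2 <- sim_mature_reference(12, 3, seed = 7)
  expect_identical(ref, ref2)
  fa1 <- tempfile(); fa2 <- tempfile()
  write_fasta(setNames(ref$sequence, ref$ref_id), fa1)
  write_fasta(setNames(ref2$sequence, ref2$ref_id), fa2)
  expect_identical(readLines(fa1), readLines(fa2))
})

test_that("planted precursors appear at their recorded loci", {
  ref <- sim_mature_reference(6, 1, seed = 9)
  g <- sim_genome(ref, seed = 9)
  expect_equal(nrow(g$truth), 6)
  for (i in seq_len(nrow(g$truth))) {
    tr <- g$truth[i, ]
    sc <- g$scaffolds[[tr$scaffold]]
    found <- substr(sc, tr$mature_start, tr$mature_end)
    expected <- if (tr$strand == "+") tr$mature_sequence
                else revcomp(tr$mature_sequence)
    expect_equal(found, expected, info = tr$ref_id)
  }
  # strands alternate and some plants sit near a scaffold edge
  expect_true(all(c("+", "-") %in% g$truth$strand))
  expect_true(any(g$truth$near_edge))

  # a near-edge plant yields a truncated upstream flank on extraction
  ne <- g$truth[g$truth$near_edge & g$truth$strand == "+", ][1, ]
  if (!is.na(ne$ref_id)) {
    loci <- find_mature_loci(ne$mature_sequence, g$scaffolds, ne$ref_id)
    loci <- loci[loci$start == ne$mature_start & loci$strand == "+", ]
    cand <- extract_precursors(loci, g$scaffolds)
    expect_equal(cand$upstream_flank, 30)
  }

  expect_error(sim_genome(ref, scaffold_length = 100, seed = 1),
               "too small")
})

test_that("error-free reads collapse back to the planted matures", {
  ref <- sim_mature_reference(8, 1, seed = 13)
  sim <- sim_reads(ref, depth_mean = 20, error_rate = 0, decoy_fraction = 0,
                   seed = 13)
  expect_equal(nrow(sim$reads), nrow(sim$truth))
  trimmed <- trim_reads(sim$reads, conmir_adapter())
  expect_equal(nrow(trimmed), nrow(sim$reads))  # nothing rejected
  uniq <- collapse_reads(trimmed)
  expect_equal(sum(uniq$count), nrow(trimmed))
  # every planted mature that received reads is recovered verbatim
  got <- ref$sequence %in% uniq$sequence
  sequenced <- ref$ref_id %in% sim$truth$ref_id
  expect_equal(got, sequenced)
})

test_that("decoy fraction and GO namespace weights hit their targets", {
  ref <- sim_mature_reference(10, 2, seed = 17)
  sim <- sim_reads(ref, depth_mean = 30, decoy_fraction = 0.3, seed = 17)
  n <- nrow(sim$truth)
  n_decoy <- sum(sim$truth$origin != "mirna")
  # binomial 3-sigma band around 0.3
  p_hat <- n_decoy / n
  expect_lt(abs(p_hat - 0.3), 3 * sqrt(0.3 * 0.7 / n) + 1 / n)

  ann <- sim_go_annotations(paste0("G", 1:50), n_annotations = 1000,
                            namespace_weights = c(0.4, 0.3, 0.3), seed = 17)
  expect_equal(nrow(ann), 1000)
  obs <- table(ann$namespace) / 1000
  expect_lt(abs(obs[["biological process"]] - 0.4), 3 * sqrt(0.4 * 0.6 / 1000))
  expect_lt(abs(obs[["cellular component"]] - 0.3), 3 * sqrt(0.3 * 0.7 / 1000))
  expect_lt(abs(obs[["molecular function"]] - 0.3), 3 * sqrt(0.3 * 0.7 / 1000))
})

test_that("site specifications drive the planted duplex structure", {
  set.seed(61)
  mir <- c(m1 = random_seq(21))
  spec <- tibble::tibble(mirna_id = "m1",
                         states = list(c(`10` = "mismatch")))
  txp <- sim_transcriptome(mir, site_specs = spec, n_decoy_transcripts = 2,
                           seed = 61)
  expect_equal(txp$truth$expectation, 2.0)
  expect_equal(txp$truth$inhibition, "translation")
  hits <- scan_targets(mir, txp$transcripts)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$expectation, 2.0)
  expect_equal(hits$inhibition, "translation")

  # default study conditions: 20 cleavage + 5 translation
  specs <- default_site_specs(mir)
  expect_equal(nrow(specs), 25)
  txp <- sim_transcriptome(mir, site_specs = specs, seed = 62)
  expect_equal(sum(txp$truth$inhibition == "cleavage"), 20)
  expect_equal(sum(txp$truth$inhibition == "translation"), 5)
})

test_that("the full study generator is deterministic", {
  s1 <- sim_smallrna_study(seed = 5)
  s2 <- sim_smallrna_study(seed = 5)
  expect_identical(s1$reads$reads, s2$reads$reads)
  expect_identical(s1$genome$scaffolds, s2$genome$scaffolds)
  expect_identical(s1$transcriptome$transcripts, s2$transcriptome$transcripts)
  expect_identical(s1$go_annotations, s2$go_annotations)
  s3 <- sim_smallrna_study(seed = 6)
  expect_false(identical(s1$reads$reads, s3$reads$reads))
})
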