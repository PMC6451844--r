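test_that("adapter trimming recovers the insert and applies the filters", {
  adapter <- conmir_adapter()
  q40 <- function(n) strrep("I", n)
  insert <- "ACGTACGTACGTACGTACGTA"  # 21 nt

  # full adapter directly after the insert
  reads <- tibble::tibble(id = "r1",
                          sequence = paste0(insert, adapter),
                          quality = q40(nchar(insert) + nchar(adapter)))
  out <- trim_reads(reads, adapter)
  expect_equal(out$sequence, insert)

  # no adapter occurrence: read unchanged
  reads <- tibble::tibble(id = "r1", sequence = strrep("ACGTAC", 4),
                          quality = q40(24))
  out <- trim_reads(reads, adapter)
  expect_equal(out$sequence, strrep("ACGTAC", 4))

  # insert shorter than min_len is rejected
  reads <- tibble::tibble(id = "r1",
                          sequence = paste0("ACGTACGTAC", adapter),
                          quality = q40(10 + nchar(adapter)))
  expect_equal(nrow(trim_reads(reads, adapter, min_len = 16)), 0)

  # one full-length mismatch still trims; terminal overlap must be exact
  mut <- adapter
  substr(mut, 3, 3) <- if (substr(mut, 3, 3) == "A") "C" else "A"
  reads <- tibble::tibble(id = c("full_mm", "overlap"),
                          sequence = c(paste0(insert, mut),
                                       paste0(insert, substr(adapter, 1, 7))),
                          quality = c(q40(nchar(insert) + nchar(mut)),
                                      q40(nchar(insert) + 7)))
  out <- trim_reads(reads, adapter)
  expect_equal(out$sequence, c(insert, insert))

  # more than one ambiguous base is rejected, a single N is kept
  reads <- tibble::tibble(id = c("two_n", "one_n"),
                          sequence = c("ACGTNACGTNACGTACGTACG",
                                       "ACGTNACGTAACGTACGTACG"),
                          quality = c(q40(21), q40(21)))
  out <- trim_reads(reads, adapter)
  expect_equal(out$id, "one_n")

  expect_error(trim_reads(reads, ""), "adapter")
  expect_error(trim_reads(reads, "ACGT"), "adapter")
})

test_that("quality trimming cuts the 3' tail after the last good base", {
  adapter <- conmir_adapter()
  seq <- "ACGTACGTACGTACGTACGTACGT"  # 24 nt
  qual <- paste0(strrep("I", 20), strrep("#", 4))  # Q40 x20 then Q2 x4
  out <- trim_reads(tibble::tibble(id = "r", sequence = seq, quality = qual),
                    adapter, quality_cutoff = 20)
  expect_equal(out$sequence, substr(seq, 1, 20))
  # output is always a prefix of the input insert
  expect_true(startsWith(seq, out$sequence))
})

test_that("collapsing groups identical reads with count conservation", {
  out <- collapse_reads(c("ACGT", "ACGT", "TTTT"))
  expect_equal(out$sequence, c("ACGT", "TTTT"))
  expect_equal(out$count, c(2L, 1L))
  expect_equal(out$uid, c("u1_x2", "u2_x1"))

  expect_equal(nrow(collapse_reads(character(0))), 0)

  # 1000 draws from 10 distinct sequences, counts checked against an
  # independent hash-map tally
  set.seed(11)
  pool <- vapply(1:10, function(i) random_seq(21), character(1))
  draws <- sample(pool, 1000, replace = TRUE)
  out <- collapse_reads(draws)
  expect_equal(nrow(out), 10)
  expect_equal(sum(out$count), 1000)
  tally <- new.env()
  for (s in draws) {
    assign(s, get0(s, envir = tally, ifnotfound = 0L) + 1L, envir = tally)
  }
  for (k in seq_len(nrow(out))) {
    expect_equal(out$count[k], get(out$sequence[k], envir = tally))
  }
  # sorted by descending count, ties lexicographic
  expect_false(is.unsorted(rev(out$count)))

  # idempotence: expanding and re-collapsing reproduces the table
  expanded <- rep(out$sequence, out$count)
  expect_equal(collapse_reads(expanded), out)
})

test_that("read classification uses priority order and both strands", {
  refs <- list(rRNA = "AAACCCGGGTTTAAACCCGGGTTT",
               tRNA = c("GGGTTT", "ACGTACGTACGTACGTAAACCC"))
  uniq <- collapse_reads(c("AAACCCGGGTTT",        # rRNA and tRNA: priority rRNA
                           "ACGTACGTACGT",        # tRNA only
                           "GGGTTTAAACCC",        # revcomp matches rRNA
                           "TGCATGCATGCATGCATGCATG"))  # nothing
  cls <- classify_reads(uniq, refs)
  got <- setNames(cls$class, cls$sequence)
  expect_equal(unname(got["AAACCCGGGTTT"]), "rRNA")
  expect_equal(unname(got["ACGTACGTACGT"]), "tRNA")
  expect_equal(unname(got["GGGTTTAAACCC"]), "rRNA")
  expect_equal(unname(got["TGCATGCATGCATGCATGCATG"]), "unannotated")

  expect_error(classify_reads(uniq, setNames(refs, c("rRNA", "rRNA"))),
               "duplicate")

  prof <- class_profile(cls)
  expect_equal(sum(prof$reads), sum(uniq$count))
  expect_equal(sum(prof$fraction), 1)
})

test_that("FASTQ round-trips through write and read", {
  reads <- tibble::tibble(id = c("a", "b"),
                          sequence = c("ACGTACGTACGTACGTAC", "TTTTACGTACGTACGTA"),
                          quality = c(strrep("D", 18), strrep("D", 17)))
  fp <- tempfile(fileext = ".fastq")
  write_fastq(reads, fp)
  back <- read_smallrna_fastq(fp)
  expect_equal(back$sequence, reads$sequence)
  expect_equal(back$quality, reads$quality)
  expect_equal(back$id, reads$id)
})
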