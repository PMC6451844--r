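# Independent oracles used to validate the dynamic-programming routines.

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Exhaustive maximum pairing score by first-position recursion (no DP
# tables shared with the implementation: the implementation decomposes on
# interval ends with bifurcations, this oracle decomposes on whether the
# first base pairs and with whom).
enum_fold_score <- function(seq, min_loop = 3) {
  chars <- strsplit(toupper(chartr("Uu", "Tt", seq)), "")[[1]]
  wtab <- c(GC = 3, CG = 3, AT = 2, TA = 2, GT = 1, TG = 1)
  w <- function(a, b) {
    v <- wtab[paste0(a, b)]
    if (is.na(v)) 0 else v
  }
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0)
    best <- rec(i + 1, j)                 # first base unpaired
    for (k in (i + min_loop + 1):j) {
      wk <- w(chars[i], chars[k])
      if (wk > 0) {
        left <- if (k - 1 >= i + 1) rec(i + 1, k - 1) else 0
        right <- if (k + 1 <= j) rec(k + 1, j) else 0
        best <- max(best, wk + left + right)
      }
    }
    best
  }
  rec(1, length(chars))
}

# Exhaustive local alignment score by enumerating every alignment path of
# every substring pair (exponential; only for very short sequences).
enum_local_score <- function(a, b, match = 1, mismatch = -2, gap = -3) {
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  n <- length(ac); m <- length(bc)
  ext <- function(i, j) {
    best <- 0  # stop here
    if (i <= n && j <= m) {
      s <- if (ac[i] == bc[j]) match else mismatch
      best <- max(best, s + ext(i + 1, j + 1))
    }
    if (i <= n) best <- max(best, gap + ext(i + 1, j))
    if (j <= m) best <- max(best, gap + ext(i, j + 1))
    best
  }
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      best <- max(best, ext(i, j))
    }
  }
  best
}

# Independent alignment oracle from a separate codebase: Biostrings
# Smith-Waterman with the same +1/-2 and linear gap -3 scoring.
biostrings_local_score <- function(a, b, match = 1, mismatch = -2, gap = 3) {
  mat <- matrix(mismatch, 4, 4,
                dimnames = list(c("A", "C", "G", "T"), c("A", "C", "G", "T")))
  diag(mat) <- match
  s <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                     substitutionMatrix = mat,
                                     gapOpening = 0, gapExtension = gap,
                                     scoreOnly = TRUE)
  max(0, s)
}

# Small complete study used by several integration tests (cached per
# session; generation is seeded and deterministic).
study_fixture <- local({
  cache <- new.env()
  function(seed = 42) {
    key <- as.character(seed)
    if (is.null(cache[[key]])) cache[[key]] <- sim_smallrna_study(seed = seed)
    cache[[key]]
  }
})

table1_path <- function() {
  system.file("extdata", "table1_evidence.tsv", package = "conmir")
}
table2_path <- function() {
  system.file("extdata", "table2_stress_targets.tsv", package = "conmir")
}
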