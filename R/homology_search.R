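#' Parse a miRBase-style mature miRNA FASTA
#'
#' Headers must look like `>osa-miR156a-5p` (species prefix, `miR` plus the
#' family number, optional variant letters and arm suffix). The family is
#' the `miR` prefix plus the leading number; variant letters and `-5p/-3p`
#' arms are stripped. `U` is normalised to `T`. Records whose header does
#' not parse, or whose sequence length falls outside 15-30 nt, are skipped
#' with a warning and counted in the `n_skipped` attribute.
#'
#' @param path FASTA path (or named character vector of sequences).
#' @return Tibble with columns `ref_id`, `species`, `family`, `sequence`,
#'   `length`.
#' @export
read_mature_fasta <- function(path) {
  seqs <- as_seq_vector(path, "mature reference")
  ids <- names(seqs)
  m <- regmatches(ids, regexec("^([A-Za-z]{3,4})-miR(\\d+)[a-z]*(-[35]p)?$",
                               ids))
  ok <- vapply(m, length, integer(1)) == 4
  len <- nchar(seqs)
  ok <- ok & len >= 15 & len <= 30
  if (any(!ok)) {
    warn(sprintf("skipped %d mature reference record(s) with unparseable headers or out-of-range lengths",
                 sum(!ok)))
  }
  out <- tibble(
    ref_id = ids[ok],
    species = vapply(m[ok], `[`, character(1), 2),
    family = paste0("miR", vapply(m[ok], `[`, character(1), 3)),
    sequence = unname(seqs[ok]),
    length = unname(len[ok])
  )
  attr(out, "n_skipped") <- sum(!ok)
  out
}

#' miRNA family from a miRBase-style identifier
#'
#' @param ref_id Character vector like `"osa-miR156a-5p"` or `"miR168-5p"`.
#' @return Character vector of family labels (`"miR156"`), `NA` when the
#'   identifier does not parse.
#' @export
#' @examples
#' mirna_family(c("tae-miR5049-3p", "ath-miR172b", "miR399"))
mirna_family <- function(ref_id) {
  num <- stringr::str_match(ref_id, "(?i)mir-?(\\d+)")[, 2]
  dplyr::if_else(is.na(num), NA_character_, paste0("miR", num))
}

#' Karlin-Altschul parameters for an ungapped scoring scheme
#'
#' Solves for lambda in `sum_ij p_i p_j exp(lambda * s_ij) = 1` under a
#' uniform base composition, and computes K numerically by convolving the
#' lattice score distribution (the classical ladder-epoch series used for
#' ungapped local alignment statistics). H is the relative entropy of the
#' aligned-pair distribution in nats.
#'
#' @param match,mismatch Match and mismatch scores (default +1/-2).
#' @param p Base composition (default uniform).
#' @param max_iter Number of convolution terms for K (default 60).
#' @return List with `lambda`, `K`, `H`.
#' @export
karlin_altschul <- function(match = 1, mismatch = -2, p = rep(0.25, 4),
                            max_iter = 60L) {
  stopifnot(match > 0, mismatch < 0, abs(sum(p) - 1) < 1e-12)
  p_match <- sum(p^2)
  p_mis <- 1 - p_match
  f <- function(l) p_match * exp(l * match) + p_mis * exp(l * mismatch) - 1
  lambda <- uniroot(f, c(1e-8, 20), tol = 1e-12)$root

  scores <- c(match, mismatch)
  probs <- c(p_match, p_mis)
  H <- lambda * sum(scores * probs * exp(lambda * scores))

  # lattice period
  delta <- Reduce(function(a, b) {
    while (b != 0) { t <- b; b <- a %% b; a <- t }
    a
  }, abs(scores))

  # sigma = sum_k (1/k) [ E(e^{lambda S_k}; S_k < 0) + P(S_k >= 0) ]
  lo <- min(scores) * max_iter
  hi <- max(scores) * max_iter
  supp <- lo:hi
  step <- numeric(length(supp))
  step[match(scores, supp)] <- probs
  dist <- numeric(length(supp))
  dist[match(0, supp)] <- 1
  sigma <- 0
  for (k in seq_len(max_iter)) {
    new <- numeric(length(supp))
    nz <- which(dist > 0)
    for (s in scores) {
      shift <- nz + s
      okl <- shift >= 1 & shift <= length(supp)
      pr <- if (s == match) p_match else p_mis
      new[shift[okl]] <- new[shift[okl]] + dist[nz[okl]] * pr
    }
    dist <- new
    vals <- supp
    neg <- vals < 0
    term <- sum(dist[neg] * exp(lambda * vals[neg])) + sum(dist[!neg])
    sigma <- sigma + term / k
  }
  K <- (delta * lambda * exp(-2 * sigma)) / (H * (1 - exp(-lambda * delta)))
  list(lambda = lambda, K = K, H = H)
}

#' E-value of an ungapped/gapped local alignment score
#'
#' `E = K * m * n * exp(-lambda * score)`; for non-positive scores the
#' E-value is capped at `K * m * n` (reported, but such scores can never
#' pass a stringent filter).
#'
#' @param score Alignment score(s).
#' @param m Query length.
#' @param n Total reference (database) length.
#' @param ka Karlin-Altschul parameters from [karlin_altschul()].
#' @return Numeric vector of E-values.
#' @export
evalue <- function(score, m, n, ka = karlin_altschul()) {
  stopifnot(m > 0, n > 0)
  e <- ka$K * m * n * exp(-ka$lambda * pmax(score, 0))
  e
}

#' Smith-Waterman local alignment
#'
#' Optimal local alignment under linear gap penalties with a deterministic
#' traceback: diagonal is preferred over a gap in the subject over a gap in
#' the query, and among equally scoring alignments the one with the
#' smallest subject start (then query start) is returned. `N` never
#' matches.
#'
#' @param query,subject Nucleotide strings.
#' @param match,mismatch,gap Scores (default +1/-2/-3).
#' @return One-row tibble: `score`, `query_start`, `query_end`,
#'   `subject_start`, `subject_end` (1-based inclusive; 0 when no positive
#'   alignment exists), `matches`, `mismatches`, `gaps`, `columns`,
#'   `identity` (= matches / alignment columns).
#' @export
#' @examples
#' align_local("ACGTACGTACGTACGTACGTA", "ACGTACGTACGTACGTACGTA")
align_local <- function(query, subject, match = 1, mismatch = -2, gap = -3) {
  stopifnot(is.character(query), is.character(subject),
            length(query) == 1, length(subject) == 1)
  r <- .sw_align(toupper(chartr("Uu", "Tt", query)),
                 toupper(chartr("Uu", "Tt", subject)),
                 as.integer(match), as.integer(mismatch), as.integer(gap))
  cols <- r$matches + r$mismatches + r$gaps
  tibble(
    score = r$score,
    query_start = r$query_start, query_end = r$query_end,
    subject_start = r$subject_start, subject_end = r$subject_end,
    matches = r$matches, mismatches = r$mismatches, gaps = r$gaps,
    columns = cols,
    identity = if (cols > 0) r$matches / cols else 0
  )
}

#' Homology search of collapsed reads against a mature miRNA reference
#'
#' Aligns every unique read against every mature reference by
#' Smith-Waterman and keeps, per read, the single best hit by lowest
#' E-value, then highest identity, then lexicographic reference id. A hit
#' is retained only when identity is strictly above `min_identity`, the
#' alignment covers at least `min_coverage` of the shorter sequence, and
#' the E-value (computed against the total reference length) is at most
#' `max_evalue`.
#'
#' @param uniques Tibble from [collapse_reads()].
#' @param refs Tibble from [read_mature_fasta()].
#' @param min_identity Identity must be strictly greater (default 0.90).
#' @param max_evalue E-value ceiling (default 1e-4).
#' @param min_coverage Fraction of the shorter sequence that must be inside
#'   the alignment (default 0.90).
#' @param ka Karlin-Altschul parameters (computed once by default).
#' @return Tibble with one row per retained read: read `uid`, `sequence`,
#'   `count`, `ref_id`, `species`, `family`, alignment columns and
#'   `identity`, `coverage`, `score`, `e_value`.
#' @export
search_mirna_homologs <- function(uniques, refs, min_identity = 0.90,
                                  max_evalue = 1e-4, min_coverage = 0.90,
                                  ka = karlin_altschul()) {
  if (nrow(refs) == 0) abort("empty mature reference")
  n_total <- sum(nchar(refs$sequence))
  ref_seqs <- toupper(chartr("Uu", "Tt", refs$sequence))
  ref_len <- nchar(ref_seqs)
  hits <- vector("list", nrow(uniques))
  for (i in seq_len(nrow(uniques))) {
    q <- toupper(chartr("Uu", "Tt", uniques$sequence[i]))
    best <- NULL
    best_j <- 0L
    best_ev <- Inf
    best_id <- -1
    for (j in seq_len(nrow(refs))) {
      al <- .sw_align(q, ref_seqs[j], 1L, -2L, -3L)
      if (al$score <= 0) next
      cols <- al$matches + al$mismatches + al$gaps
      al$identity <- al$matches / cols
      al$columns <- cols
      ev <- evalue(al$score, nchar(q), n_total, ka)
      if (ev < best_ev ||
          (ev == best_ev && al$identity > best_id) ||
          (ev == best_ev && al$identity == best_id &&
           refs$ref_id[j] < refs$ref_id[best_j])) {
        best <- al
        best_j <- j
        best_ev <- ev
        best_id <- al$identity
      }
    }
    if (is.null(best)) next
    j <- best_j
    shorter <- min(nchar(q), ref_len[j])
    span_q <- best$query_end - best$query_start + 1
    span_s <- best$subject_end - best$subject_start + 1
    coverage <- (if (nchar(q) <= ref_len[j]) span_q else span_s) / shorter
    if (best$identity > min_identity && coverage >= min_coverage &&
        best_ev <= max_evalue) {
      hits[[i]] <- dplyr::bind_cols(
        uniques[i, c("uid", "sequence", "count")],
        refs[j, c("ref_id", "species", "family")],
        tibble(score = best$score, query_start = best$query_start,
               query_end = best$query_end,
               subject_start = best$subject_start,
               subject_end = best$subject_end, matches = best$matches,
               mismatches = best$mismatches, gaps = best$gaps,
               columns = best$columns, identity = best$identity,
               coverage = coverage, e_value = best_ev)
      )
    }
  }
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0) {
    out <- tibble(uid = character(), sequence = character(),
                  count = integer(), ref_id = character(),
                  species = character(), family = character(),
                  score = numeric(), query_start = integer(),
                  query_end = integer(), subject_start = integer(),
                  subject_end = integer(), matches = integer(),
                  mismatches = integer(), gaps = integer(),
                  columns = integer(), identity = numeric(),
                  coverage = numeric(), e_value = numeric())
  }
  out
}

#' Summarise homology hits by miRNA family
#'
#' @param hits Tibble from [search_mirna_homologs()].
#' @return List with `n_sequences` (distinct read sequences), `n_families`
#'   (distinct family labels) and `families`, a per-family tibble of
#'   sequence and read counts.
#' @export
summarize_families <- function(hits) {
  if (nrow(hits) == 0) {
    return(list(n_sequences = 0L, n_families = 0L,
                families = tibble(family = character(),
                                  n_sequences = integer(),
                                  total_reads = integer())))
  }
  fam <- hits |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(n_sequences = dplyr::n_distinct(.data$sequence),
                     total_reads = sum(.data$count), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n_sequences), .data$family)
  list(n_sequences = dplyr::n_distinct(hits$sequence),
       n_families = nrow(fam),
       families = fam)
}
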