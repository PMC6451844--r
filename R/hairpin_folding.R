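#' Fold a precursor candidate into its maximum-weight secondary structure
#'
#' Weighted Nussinov dynamic programming: the pairing weight sum (G:C = 3,
#' A:U = 2, G:U = 1) is maximised over pseudoknot-free structures with a
#' minimum hairpin loop of `min_loop` unpaired bases. This is a topological
#' screen for the canonical pre-miRNA stem-loop, not a thermodynamic free
#' energy model; the reported `score` is the negated weight sum so lower
#' means more stably paired. The traceback is deterministic (pairing of the
#' interval ends is preferred over leaving an end unpaired, which is
#' preferred over a bifurcation at the smallest split point), so
#' dot-bracket strings are byte-for-byte reproducible.
#'
#' @param sequence Nucleotide string (A/C/G/T/U, length >= 10).
#' @param min_loop Minimum number of unpaired bases in a hairpin loop
#'   (default 3).
#' @return Object of class `rna_fold`: list with `sequence`, `partner`
#'   (1-based partner index, 0 = unpaired), `pairs` tibble (`i`, `j`,
#'   `weight`), `dot_bracket`, `pair_sum` and `score` (= -`pair_sum`).
#' @export
#' @examples
#' fold_hairpin("GGGAAACCC")$dot_bracket
fold_hairpin <- function(sequence, min_loop = 3L) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  seq_t <- toupper(chartr("Uu", "Tt", sequence))
  if (nchar(seq_t) < min_loop + 2) abort("sequence too short to fold")
  if (grepl("[^ACGT]", seq_t)) abort("invalid base in sequence")
  r <- .nussinov_fold(seq_t, as.integer(min_loop))
  partner <- r$partner
  idx <- which(partner > seq_along(partner))
  bases <- strsplit(seq_t, "")[[1]]
  pair_w <- function(a, b) {
    key <- paste0(a, b)
    c(GC = 3, CG = 3, AT = 2, TA = 2, GT = 1, TG = 1)[key]
  }
  pairs <- tibble(i = idx, j = partner[idx],
                  weight = if (length(idx))
                    unname(pair_w(bases[idx], bases[partner[idx]]))
                  else numeric(0))
  db <- rep(".", length(partner))
  db[pairs$i] <- "("
  db[pairs$j] <- ")"
  structure(list(sequence = sequence,
                 partner = partner,
                 pairs = pairs,
                 dot_bracket = paste(db, collapse = ""),
                 pair_sum = r$score,
                 score = -r$score),
            class = "rna_fold")
}

#' @export
print.rna_fold <- function(x, ...) {
  cat("<rna_fold> ", nchar(x$sequence), " nt, ", nrow(x$pairs),
      " pairs, score ", x$score, "\n", sep = "")
  cat(x$sequence, "\n", x$dot_bracket, "\n", sep = "")
  invisible(x)
}

# Innermost pairs and their hairpin-loop intervals.
hairpin_loops <- function(partner) {
  idx <- which(partner > seq_along(partner))
  loops <- list()
  for (i in idx) {
    j <- partner[i]
    inside <- if (j - i >= 2) (i + 1):(j - 1) else integer(0)
    if (all(partner[inside] == 0)) {
      loops[[length(loops) + 1]] <- c(start = i + 1L, end = j - 1L)
    }
  }
  loops
}

#' Classify whether a folded candidate forms a pre-miRNA stem-loop
#'
#' A candidate is called a stem-loop when (a) every paired base of the
#' mature pairs with a base outside the mature span (the mature sits on one
#' arm and pairs into the star arm), (b) the mature does not straddle a
#' hairpin loop (bases on both sides of a terminal loop; merely touching
#' the loop with a terminal base is tolerated), (c) at least
#' `min_paired_fraction` of mature
#' bases are paired to the dominant arm (the side holding the majority of
#' the mature's partners; stray co-optimal pairings to the opposite side
#' are ignored, as a visual screen would), and (d) the stem-loop element
#' the mature participates
#' in - the region enclosed by the mature's innermost base pair - contains
#' exactly one hairpin loop (so the mature closes a single terminal loop,
#' not a multiloop). Condition (d) is deliberately local: flanking genomic
#' sequence is free to fold into unrelated structure without disqualifying
#' the hairpin, which matters because a maximum-pairing folder pairs random
#' flanks extensively. The arm is `5p` when the mature precedes all of its
#' pairing partners, `3p` when it follows them.
#'
#' @param fold `rna_fold` object from [fold_hairpin()].
#' @param mature_offset 1-based position of the mature within the folded
#'   sequence.
#' @param mature_length Mature length in nt.
#' @param min_paired_fraction Minimum fraction of mature bases that must be
#'   paired (default 0.60).
#' @return One-row tibble: `is_stem_loop`, `arm`, `mature_paired_fraction`,
#'   `mature_crosses_loop`, `n_hairpin_loops`, `score`.
#' @export
classify_stem_loop <- function(fold, mature_offset, mature_length,
                               min_paired_fraction = 0.60) {
  stopifnot(inherits(fold, "rna_fold"))
  partner <- fold$partner
  n <- length(partner)
  span <- mature_offset:(mature_offset + mature_length - 1L)
  if (mature_offset < 1 || max(span) > n)
    abort("mature span outside the folded sequence")

  paired <- span[partner[span] > 0]
  partners_outside <- length(paired) > 0 && !any(partner[paired] %in% span)

  loops <- hairpin_loops(partner)

  # Dominant arm: the side (up- or downstream of the mature) holding the
  # majority of the mature's partners. A maximum-pairing fold occasionally
  # routes one or two terminal mature bases into a co-optimal pairing on
  # the opposite side; a visual stem-loop screen ignores such strays, so
  # the paired fraction and the innermost-pair rule use the dominant side.
  down <- paired[partner[paired] > max(span)]
  up <- paired[partner[paired] < min(span)]
  arm <- if (length(paired) == 0 || length(up) == length(down)) {
    "none"
  } else if (length(down) > length(up)) "5p" else "3p"
  dominant <- if (arm == "5p") down else if (arm == "3p") up else integer(0)
  frac <- length(dominant) / mature_length

  # Stem-loop element of the mature: interval enclosed by its innermost
  # dominant pair. The mature must not reach into a hairpin loop of its own
  # element (loops of unrelated flank hairpins are co-optimal noise).
  n_loops <- 0L
  crosses <- FALSE
  # "crossing" means straddling: mature bases on both sides of the loop.
  # Merely touching the terminal loop with the last base (a frequent
  # lone-pair artifact of maximum pairing) is not disqualifying.
  straddles <- function(lp) {
    lp["start"] <= lp["end"] &&
      span[1] < lp["start"] && span[length(span)] > lp["end"]
  }
  if (length(dominant) > 0) {
    lo <- pmin(dominant, partner[dominant])
    hi <- pmax(dominant, partner[dominant])
    inner <- which.min(hi - lo)
    in_element <- vapply(loops, function(lp) {
      lp["start"] >= lo[inner] && lp["end"] <= hi[inner]
    }, logical(1))
    n_loops <- sum(in_element)
    crosses <- any(vapply(loops[in_element], straddles, logical(1)))
  } else {
    crosses <- any(vapply(loops, straddles, logical(1)))
  }

  verdict <- partners_outside && !crosses &&
    frac >= min_paired_fraction && n_loops == 1L && arm != "none"

  tibble(is_stem_loop = verdict, arm = arm,
         mature_paired_fraction = frac,
         mature_crosses_loop = crosses,
         n_hairpin_loops = as.integer(n_loops),
         score = fold$score)
}

#' Write a secondary structure in connect (CT) format
#'
#' Standard 6-column CT: index, base, previous index, next index, pairing
#' partner (0 = unpaired), index. The header line carries the sequence
#' length, the folding score as an energy-like value, and a name.
#'
#' @param fold `rna_fold` object.
#' @param path Optional output path; when `NULL` the lines are returned.
#' @param name Structure name for the header.
#' @return Character vector of CT lines (invisibly when written to `path`).
#' @export
write_ct <- function(fold, path = NULL, name = "structure") {
  stopifnot(inherits(fold, "rna_fold"))
  bases <- strsplit(fold$sequence, "")[[1]]
  n <- length(bases)
  lines <- c(
    sprintf("%d\tENERGY = %g\t%s", n, fold$score, name),
    sprintf("%d\t%s\t%d\t%d\t%d\t%d",
            seq_len(n), bases, seq_len(n) - 1L,
            c(seq_len(n)[-1], 0L), fold$partner, seq_len(n))
  )
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Read a connect (CT) file back into a secondary structure
#'
#' @param x Path to a CT file, or a character vector of CT lines.
#' @return `rna_fold` object (the pair-weight score is recomputed from the
#'   sequence and pairs).
#' @export
read_ct <- function(x) {
  lines <- if (length(x) == 1 && file.exists(x)) readLines(x) else x
  if (length(lines) < 1) abort("empty CT input")
  n <- suppressWarnings(as.integer(strsplit(lines[1], "\\s+")[[1]][1]))
  if (is.na(n)) abort("CT parse error at line 1: bad header")
  if (length(lines) < n + 1) abort("CT parse error: truncated file")
  bases <- character(n)
  partner <- integer(n)
  for (k in seq_len(n)) {
    f <- strsplit(trimws(lines[k + 1]), "\\s+")[[1]]
    if (length(f) < 6) abort(sprintf("CT parse error at line %d: expected 6 columns", k + 1))
    i <- suppressWarnings(as.integer(f[1]))
    p <- suppressWarnings(as.integer(f[5]))
    if (is.na(i) || i != k || is.na(p))
      abort(sprintf("CT parse error at line %d", k + 1))
    bases[k] <- f[2]
    partner[k] <- p
  }
  seq_u <- paste(bases, collapse = "")
  seq_t <- toupper(chartr("Uu", "Tt", seq_u))
  bt <- strsplit(seq_t, "")[[1]]
  idx <- which(partner > seq_len(n))
  wtab <- c(GC = 3, CG = 3, AT = 2, TA = 2, GT = 1, TG = 1)
  weights <- if (length(idx)) unname(wtab[paste0(bt[idx], bt[partner[idx]])]) else numeric(0)
  db <- rep(".", n)
  db[idx] <- "("
  db[partner[idx]] <- ")"
  pair_sum <- sum(weights, na.rm = TRUE)
  structure(list(sequence = seq_u, partner = partner,
                 pairs = tibble(i = idx, j = partner[idx], weight = weights),
                 dot_bracket = paste(db, collapse = ""),
                 pair_sum = pair_sum, score = -pair_sum),
            class = "rna_fold")
}

#' Fold and classify a table of precursor candidates
#'
#' Folds every candidate not flagged `short` and classifies the stem-loop.
#'
#' @param candidates Tibble from [extract_precursors()].
#' @param min_paired_fraction Passed to [classify_stem_loop()].
#' @param min_loop Passed to [fold_hairpin()].
#' @return `candidates` (short ones dropped) with verdict columns appended
#'   and a `dot_bracket` column; the fold objects are attached as the
#'   `folds` attribute.
#' @export
fold_candidates <- function(candidates, min_paired_fraction = 0.60,
                            min_loop = 3L) {
  cand <- dplyr::filter(candidates, !.data$short)
  folds <- vector("list", nrow(cand))
  verdicts <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    f <- fold_hairpin(cand$sequence[i], min_loop = min_loop)
    folds[[i]] <- f
    verdicts[[i]] <- classify_stem_loop(
      f, cand$mature_offset[i], cand$mature_length[i],
      min_paired_fraction = min_paired_fraction
    ) |>
      dplyr::mutate(dot_bracket = f$dot_bracket)
  }
  out <- dplyr::bind_cols(cand, dplyr::bind_rows(verdicts))
  attr(out, "folds") <- folds
  out
}
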