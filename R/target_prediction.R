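# Pair state of miRNA base vs transcript base when miRNA position k faces
# site position L-k+1: 0 = Watson-Crick match, 1 = G:U wobble, 2 = mismatch.
duplex_state_codes <- function(mirna, site) {
  L <- nchar(mirna)
  if (nchar(site) != L) abort("mirna and site must have equal length")
  m <- strsplit(toupper(chartr("Uu", "Tt", mirna)), "")[[1]]
  s <- rev(strsplit(toupper(chartr("Uu", "Tt", site)), "")[[1]])
  key <- paste0(m, s)
  match_keys <- c("AT", "TA", "GC", "CG")
  gu_keys <- c("GT", "TG")
  ifelse(key %in% match_keys, 0L, ifelse(key %in% gu_keys, 1L, 2L))
}

#' Score a miRNA-target duplex psRNATarget-style
#'
#' The miRNA (5'->3') is paired ungapped against the transcript site
#' (5'->3'), miRNA position k facing site position `L - k + 1`. Penalties:
#' Watson-Crick match 0, G:U wobble 0.5, mismatch 1.0, doubled for miRNA
#' positions in the seed-proximal region (2-13 by default). The expectation
#' is the penalty total; lower means stronger complementarity.
#'
#' @param mirna miRNA sequence, 5'->3'.
#' @param site Transcript site of the same length, 5'->3'.
#' @param double_positions miRNA positions whose penalty is doubled
#'   (default `2:13`).
#' @return Object of class `duplex_score`: list with `expectation`,
#'   `states` (character vector `match`/`GU`/`mismatch` indexed by miRNA
#'   position from the 5' end), `mirna`, `site`.
#' @export
#' @examples
#' score_duplex("ACGTACGTACGTACGTACGTA", revcomp("ACGTACGTACGTACGTACGTA"))
score_duplex <- function(mirna, site, double_positions = 2:13) {
  codes <- duplex_state_codes(mirna, site)
  L <- length(codes)
  pen <- c(0, 0.5, 1)[codes + 1L]
  wgt <- ifelse(seq_len(L) %in% double_positions, 2, 1)
  structure(list(
    expectation = sum(pen * wgt),
    states = c("match", "GU", "mismatch")[codes + 1L],
    mirna = mirna, site = site
  ), class = "duplex_score")
}

#' @export
print.duplex_score <- function(x, ...) {
  cat("<duplex_score> expectation ", x$expectation, "\n", sep = "")
  cat(format_duplex(x), sep = "\n")
  invisible(x)
}

#' Text diagram of a scored duplex
#'
#' Three lines: target site 3'->5' on top, pairing symbols (`|` match,
#' `o` G:U, space mismatch), miRNA 5'->3' below.
#'
#' @param duplex `duplex_score` object.
#' @return Character vector of three lines.
#' @export
format_duplex <- function(duplex) {
  sym <- c(match = "|", GU = "o", mismatch = " ")[duplex$states]
  site_rev <- paste(rev(strsplit(duplex$site, "")[[1]]), collapse = "")
  c(paste0("target 3' ", site_rev, " 5'"),
    paste0("          ", paste(sym, collapse = "")),
    paste0("miRNA  5' ", duplex$mirna, " 3'"))
}

#' Classify the inhibition mode of a target duplex
#'
#' Plant miRNAs direct transcript cleavage when the central region of the
#' duplex is perfectly paired; a mismatch at any central position
#' (miRNA positions 9-11 by default) switches the call to translational
#' inhibition. A G:U wobble is not a mismatch.
#'
#' @param duplex `duplex_score` object (or a `states` character vector).
#' @param central_positions miRNA positions checked (default `9:11`).
#' @return `"cleavage"` or `"translation"`.
#' @export
classify_inhibition <- function(duplex, central_positions = 9:11) {
  states <- if (inherits(duplex, "duplex_score")) duplex$states else duplex
  central <- states[central_positions[central_positions <= length(states)]]
  if (any(central == "mismatch")) "translation" else "cleavage"
}

#' Scan transcripts for miRNA target sites
#'
#' Slides the miRNA over every transcript window (sense strand only). A
#' window is scoreable only when at least `hspsize` miRNA positions pair
#' (match or G:U) - the scored complementarity length. (Requiring the
#' stretch to be consecutive would make a central-mismatch site, the
#' signature of translational inhibition, unreportable at the default
#' hspsize of 18 on a 21-nt miRNA.) Per transcript the best window (lowest
#' expectation, tie broken by smallest start) is kept when its expectation
#' is at most `max_expectation`; hits are sorted by ascending expectation
#' (tie: transcript id) and truncated to `top_n` per miRNA.
#'
#' @param mirnas Named character vector of miRNA sequences (names are
#'   miRNA ids), or a single unnamed sequence.
#' @param transcripts FASTA path, DNAStringSet or named character vector.
#' @param max_expectation Expectation ceiling (default 3.0).
#' @param hspsize Minimum consecutive complementary stretch (default 18).
#' @param top_n Maximum targets reported per miRNA (default 50).
#' @param double_positions,central_positions Passed to [score_duplex()] and
#'   [classify_inhibition()].
#' @return Tibble with `mirna_id`, `transcript_id`, `site_start`,
#'   `site_end` (1-based inclusive), `expectation`, `inhibition`, `rank`,
#'   `states` (compact state string, one character per miRNA position:
#'   `=` match, `o` G:U, `x` mismatch).
#' @export
scan_targets <- function(mirnas, transcripts, max_expectation = 3.0,
                         hspsize = 18L, top_n = 50L,
                         double_positions = 2:13,
                         central_positions = 9:11) {
  if (is.null(names(mirnas))) {
    names(mirnas) <- paste0("mir", seq_along(mirnas))
  }
  txs <- as_seq_vector(transcripts, "transcripts")
  if (length(txs) == 0) abort("empty transcript set")

  # integer-coded transcripts; 5 = unknown base
  enc <- function(s) {
    v <- utf8ToInt(s)
    code <- integer(length(v)) + 5L
    code[v == utf8ToInt("A")] <- 1L
    code[v == utf8ToInt("C")] <- 2L
    code[v == utf8ToInt("G")] <- 3L
    code[v == utf8ToInt("T")] <- 4L
    code
  }
  # state lookup: rows mirna base 1..5, cols site base 1..5
  state_tab <- matrix(2L, 5, 5)
  state_tab[1, 4] <- 0L; state_tab[4, 1] <- 0L
  state_tab[3, 2] <- 0L; state_tab[2, 3] <- 0L
  state_tab[3, 4] <- 1L; state_tab[4, 3] <- 1L

  tx_codes <- lapply(txs, enc)
  out <- vector("list", length(mirnas))
  for (mi in seq_along(mirnas)) {
    mirna <- toupper(chartr("Uu", "Tt", mirnas[[mi]]))
    L <- nchar(mirna)
    mcode <- enc(mirna)
    wgt <- ifelse(seq_len(L) %in% double_positions, 2, 1)
    need <- min(hspsize, L)
    best_rows <- list()
    for (ti in seq_along(tx_codes)) {
      tc <- tx_codes[[ti]]
      n <- length(tc)
      if (n < L) next
      starts <- seq_len(n - L + 1L)
      nw <- length(starts)
      # state matrix L x nw: miRNA position k faces site position L-k+1,
      # i.e. transcript position start + L - k
      pos <- outer(L - seq_len(L), starts, "+")
      st_mat <- matrix(state_tab[cbind(rep(mcode, nw), tc[pos])], nrow = L)
      pen <- matrix(c(0, 0.5, 1)[st_mat + 1L], nrow = L) * wgt
      e_all <- colSums(pen)
      n_paired <- colSums(st_mat != 2L)
      e_all[n_paired < need] <- Inf
      best_s <- which.min(e_all)  # smallest start among ties
      best_e <- e_all[best_s]
      best_states <- st_mat[, best_s]
      if (is.finite(best_e) && best_e <= max_expectation) {
        best_rows[[length(best_rows) + 1]] <- tibble(
          mirna_id = names(mirnas)[mi],
          transcript_id = names(txs)[ti],
          site_start = best_s, site_end = best_s + L - 1L,
          expectation = best_e,
          inhibition = classify_inhibition(
            c("match", "GU", "mismatch")[best_states + 1L],
            central_positions),
          states = paste(c("=", "o", "x")[best_states + 1L], collapse = "")
        )
      }
    }
    hits <- dplyr::bind_rows(best_rows)
    if (nrow(hits) > 0) {
      hits <- hits |>
        dplyr::arrange(.data$expectation, .data$transcript_id) |>
        head(top_n) |>
        dplyr::mutate(rank = dplyr::row_number())
      out[[mi]] <- hits
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble(mirna_id = character(), transcript_id = character(),
                  site_start = integer(), site_end = integer(),
                  expectation = numeric(), inhibition = character(),
                  states = character(), rank = integer())
  }
  dplyr::relocate(res, "rank", .after = "inhibition")
}

#' Cleavage fraction of a target-hit table
#'
#' @param hits Tibble from [scan_targets()].
#' @return List with `fraction` (cleavage hits / total hits; 0 when there
#'   are none), `n_cleavage`, `n_translation`, `n_total`.
#' @export
summarize_cleavage <- function(hits) {
  n_total <- nrow(hits)
  n_cle <- sum(hits$inhibition == "cleavage")
  list(fraction = if (n_total > 0) n_cle / n_total else 0,
       n_cleavage = n_cle,
       n_translation = n_total - n_cle,
       n_total = n_total)
}
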