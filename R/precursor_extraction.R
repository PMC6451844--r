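#' Locate exact genomic matches of a mature miRNA
#'
#' Finds every exact occurrence of the mature sequence on the plus strand
#' and of its reverse complement on the minus strand of a set of genome
#' scaffolds (Biostrings pattern matching). Results are sorted by scaffold,
#' start, strand.
#'
#' @param mature Mature miRNA sequence (>= 15 nt, no `N`).
#' @param scaffolds Genome scaffolds: FASTA path, DNAStringSet or named
#'   character vector.
#' @param mature_id Optional identifier carried into the output.
#' @return Tibble with columns `mature_id`, `scaffold`, `start`, `end`
#'   (1-based inclusive), `strand`.
#' @export
find_mature_loci <- function(mature, scaffolds, mature_id = NA_character_) {
  mature <- toupper(chartr("Uu", "Tt", mature))
  if (nchar(mature) < 15) abort("mature sequence must be >= 15 nt")
  if (grepl("[^ACGT]", mature))
    abort("mature sequence contains ambiguous bases; not searchable")
  seqs <- as_seq_vector(scaffolds, "genome scaffolds")
  if (length(seqs) == 0) abort("empty scaffold set")
  subj <- Biostrings::DNAStringSet(seqs)
  hit_one <- function(pattern, strand) {
    mi <- Biostrings::vmatchPattern(pattern, subj)
    res <- lapply(seq_along(mi), function(k) {
      r <- mi[[k]]
      if (length(r) == 0) return(NULL)
      tibble(scaffold = names(subj)[k],
             start = BiocGenerics::start(r),
             end = BiocGenerics::end(r),
             strand = strand)
    })
    dplyr::bind_rows(res)
  }
  out <- dplyr::bind_rows(hit_one(mature, "+"),
                          hit_one(revcomp(mature), "-"))
  if (nrow(out) == 0) {
    return(tibble(mature_id = character(), scaffold = character(),
                  start = integer(), end = integer(), strand = character()))
  }
  out |>
    dplyr::mutate(mature_id = mature_id, .before = 1) |>
    dplyr::arrange(.data$scaffold, .data$start, .data$strand)
}

#' Extract candidate precursor windows around mature loci
#'
#' For each locus the genomic window `[start - flank, end + flank]` is
#' extracted, clipped at scaffold boundaries (truncation is recorded in the
#' flank columns, never padded). Minus-strand windows are
#' reverse-complemented so the mature always appears in reading orientation
#' at `mature_offset` (1-based within the window). Candidates whose window
#' is shorter than the mature plus 40 nt are flagged `short` and are
#' conventionally excluded from folding.
#'
#' @param loci Tibble from [find_mature_loci()].
#' @param scaffolds Genome scaffolds (FASTA path, DNAStringSet or named
#'   character vector).
#' @param flank Flank length in nt (default 80).
#' @return Tibble with the window sequence, genomic coordinates of the
#'   window, `mature_offset`, `mature_length`, achieved
#'   `upstream_flank`/`downstream_flank` and the `short` flag.
#' @export
extract_precursors <- function(loci, scaffolds, flank = 80L) {
  seqs <- as_seq_vector(scaffolds, "genome scaffolds")
  lens <- nchar(seqs)
  out <- vector("list", nrow(loci))
  for (i in seq_len(nrow(loci))) {
    sc <- loci$scaffold[i]
    if (!sc %in% names(seqs)) abort(paste0("unknown scaffold: ", sc))
    n <- lens[[sc]]
    s <- loci$start[i]; e <- loci$end[i]
    ws <- max(1L, s - flank)
    we <- min(n, e + flank)
    window <- substr(seqs[[sc]], ws, we)
    mlen <- e - s + 1L
    if (loci$strand[i] == "-") {
      window <- revcomp(window)
      up <- we - e
      down <- s - ws
      off <- we - e + 1L
    } else {
      up <- s - ws
      down <- we - e
      off <- s - ws + 1L
    }
    out[[i]] <- tibble(
      mature_id = loci$mature_id[i], scaffold = sc,
      window_start = ws, window_end = we, strand = loci$strand[i],
      sequence = window, mature_offset = off, mature_length = mlen,
      upstream_flank = up, downstream_flank = down,
      short = nchar(window) < mlen + 40L
    )
  }
  dplyr::bind_rows(out)
}

#' Write precursor candidates as FASTA with locus headers
#'
#' Headers follow
#' `>{mature_id}|{scaffold}:{start}-{end}({strand})|offset={mature_offset}`
#' (1-based inclusive coordinates).
#'
#' @param candidates Tibble from [extract_precursors()].
#' @param path Output FASTA path.
#' @return The path, invisibly.
#' @export
write_precursor_fasta <- function(candidates, path) {
  headers <- sprintf("%s|%s:%d-%d(%s)|offset=%d",
                     candidates$mature_id, candidates$scaffold,
                     candidates$window_start, candidates$window_end,
                     candidates$strand, candidates$mature_offset)
  write_fasta(setNames(candidates$sequence, headers), path)
}
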