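#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over character vectors; `U` is treated as
#' `T`, `N` maps to `N`.
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGT", "GGAU"))
revcomp <- function(x) {
  stopifnot(is.character(x))
  vapply(x, function(s) {
    s <- chartr("Uu", "Tt", s)
    paste(rev(strsplit(chartr("ACGTacgtNn", "TGCAtgcaNn", s), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Coerce FASTA path / DNAStringSet / named character to named character.
as_seq_vector <- function(x, what = "sequences") {
  if (inherits(x, "XStringSet")) {
    out <- as.character(x)
    names(out) <- sub("\\s.*$", "", names(x))
    return(toupper(chartr("Uu", "Tt", out)))
  }
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    ss <- Biostrings::readBStringSet(x)
    out <- toupper(chartr("Uu", "Tt", as.character(ss)))
    names(out) <- sub("\\s.*$", "", names(ss))
    return(out)
  }
  if (is.character(x)) {
    return(toupper(chartr("Uu", "Tt", x)))
  }
  abort(paste0("cannot interpret input as ", what,
               " (expected FASTA path, XStringSet or character vector)"))
}

# Write a named character vector as FASTA via Biostrings.
write_fasta <- function(seqs, path) {
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, filepath = path, width = 80L)
  invisible(path)
}

# Normalise gene identifiers: case-insensitive, transcript/version suffix
# (".1", ".2", ...) stripped.
normalize_gene_id <- function(x) {
  toupper(sub("\\.\\d+$", "", trimws(x)))
}
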