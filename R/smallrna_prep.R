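#' Read a small RNA FASTQ file into a tibble
#'
#' Reads phred+33 FASTQ and returns one row per read with the sequence and
#' quality string. Parsing is delegated to Biostrings.
#'
#' @param path Path to a FASTQ file.
#' @return A tibble with columns `id`, `sequence`, `quality`.
#' @export
read_smallrna_fastq <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTQ file not found: ", path))
  ss <- Biostrings::readDNAStringSet(path, format = "fastq",
                                     with.qualities = TRUE)
  tibble(
    id = sub("\\s.*$", "", names(ss)),
    sequence = unname(toupper(as.character(ss))),
    quality = unname(as.character(S4Vectors::mcols(ss)$qualities))
  )
}

# Left-most adapter start within a read (1-based), or 0 if absent.
# Full-length occurrences tolerate <= 1 mismatch; a terminal overlap of the
# adapter prefix at the read 3' end must be exact and >= 6 nt.
find_adapter_start <- function(seq, adapter, max_mismatch = 1L,
                               min_overlap = 6L) {
  n <- nchar(seq)
  alen <- nchar(adapter)
  if (n < min_overlap) return(0L)
  sc <- strsplit(seq, "")[[1]]
  ac <- strsplit(adapter, "")[[1]]
  for (p in seq_len(n)) {
    avail <- n - p + 1L
    if (avail >= alen) {
      mm <- sum(sc[p:(p + alen - 1L)] != ac)
      if (mm <= max_mismatch) return(p)
    } else if (avail >= min_overlap) {
      if (all(sc[p:n] == ac[seq_len(avail)])) return(p)
    }
  }
  0L
}

#' Trim adapters and low-quality tails from small RNA reads
#'
#' Removes the 3' adapter at its best left-most occurrence (full-length
#' occurrences tolerate one mismatch; terminal overlaps of at least 6 nt
#' must be exact), then trims the 3' tail after the last base at or above
#' `quality_cutoff`, and finally rejects reads whose insert length falls
#' outside `[min_len, max_len]` or that contain more than one ambiguous
#' base (`N`).
#'
#' @param reads Tibble from [read_smallrna_fastq()] (columns `id`,
#'   `sequence`, `quality`), or a character vector of sequences (then all
#'   bases are assumed high quality).
#' @param adapter 3' adapter sequence (at least 8 nt).
#' @param quality_cutoff Phred cutoff for 3' quality trimming (default 20).
#' @param min_len,max_len Retained insert length window (default 16-30 nt,
#'   bracketing the 18-24 nt range typical of plant mature miRNAs).
#' @return A tibble of retained reads (`id`, `sequence`, `quality`) with
#'   attributes `n_input` and `n_rejected`.
#' @export
trim_reads <- function(reads, adapter, quality_cutoff = 20L,
                       min_len = 16L, max_len = 30L) {
  if (!is.character(adapter) || length(adapter) != 1 || !nzchar(adapter))
    abort("adapter must be a non-empty string")
  if (nchar(adapter) < 8) abort("adapter must be at least 8 nt long")
  if (min_len > max_len) abort("min_len must be <= max_len")
  if (is.character(reads)) {
    reads <- tibble(id = paste0("r", seq_along(reads)), sequence = reads,
                    quality = strrep("I", nchar(reads)))
  }
  stopifnot(all(c("id", "sequence", "quality") %in% names(reads)))
  adapter <- toupper(adapter)

  n_in <- nrow(reads)
  out_seq <- character(n_in)
  out_qual <- character(n_in)
  keep <- logical(n_in)
  for (i in seq_len(n_in)) {
    s <- reads$sequence[i]
    q <- reads$quality[i]
    p <- find_adapter_start(s, adapter)
    if (p > 0L) {
      s <- substr(s, 1L, p - 1L)
      q <- substr(q, 1L, p - 1L)
    }
    if (nchar(s) > 0L) {
      phred <- utf8ToInt(q) - 33L
      last_ok <- max(c(0L, which(phred >= quality_cutoff)))
      s <- substr(s, 1L, last_ok)
      q <- substr(q, 1L, last_ok)
    }
    len <- nchar(s)
    n_amb <- len - nchar(gsub("N", "", s, fixed = TRUE))
    if (len >= min_len && len <= max_len && n_amb <= 1L) {
      keep[i] <- TRUE
      out_seq[i] <- s
      out_qual[i] <- q
    }
  }
  out <- tibble(id = reads$id[keep], sequence = out_seq[keep],
                quality = out_qual[keep])
  attr(out, "n_input") <- n_in
  attr(out, "n_rejected") <- n_in - nrow(out)
  out
}

#' Collapse identical reads into unique sequences with counts
#'
#' Groups exact-identical sequences and records their occurrence count.
#' The result is sorted by descending count with lexicographic tie-break,
#' and carries miRDeep-style identifiers `u{rank}_x{count}`.
#'
#' @param reads Character vector of sequences, or a tibble with a
#'   `sequence` column.
#' @return Tibble with columns `uid`, `sequence`, `count`, `rank`;
#'   `sum(count)` equals the number of input reads.
#' @export
#' @examples
#' collapse_reads(c("ACGT", "ACGT", "TTTT"))
collapse_reads <- function(reads) {
  seqs <- if (is.data.frame(reads)) reads$sequence else reads
  stopifnot(is.character(seqs))
  if (length(seqs) == 0) {
    return(tibble(uid = character(), sequence = character(),
                  count = integer(), rank = integer()))
  }
  if (any(!nzchar(seqs))) abort("collapse_reads: empty sequences in input")
  tab <- table(seqs)
  out <- tibble(sequence = names(tab), count = as.integer(tab)) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$sequence) |>
    dplyr::mutate(rank = dplyr::row_number(),
                  uid = sprintf("u%d_x%d", .data$rank, .data$count)) |>
    dplyr::select("uid", "sequence", "count", "rank")
  out
}

#' Write collapsed reads as FASTA
#'
#' Headers follow the `>u{rank}_x{count}` convention.
#'
#' @param uniques Tibble from [collapse_reads()].
#' @param path Output FASTA path.
#' @return The path, invisibly.
#' @export
write_collapsed_fasta <- function(uniques, path) {
  write_fasta(setNames(uniques$sequence, uniques$uid), path)
}

#' Classify unique reads into known RNA classes
#'
#' Assigns each unique read to the first class (in the given priority
#' order) whose reference sequences contain the read as an exact substring
#' on either strand; unmatched reads become `"unannotated"`. Reads with an
#' ambiguous base never match.
#'
#' @param uniques Tibble from [collapse_reads()].
#' @param references Ordered named list: class label -> character vector of
#'   reference sequences (or FASTA path). Order defines match priority.
#' @return `uniques` with an added `class` column.
#' @export
classify_reads <- function(uniques, references) {
  stopifnot(is.list(references), length(references) > 0)
  labels <- names(references)
  if (is.null(labels) || any(!nzchar(labels)))
    abort("references must be a named list of class references")
  if (anyDuplicated(labels)) abort("duplicate class labels in references")
  ref_cat <- lapply(references, function(r) {
    paste(as_seq_vector(r), collapse = "|")
  })
  cls <- vapply(uniques$sequence, function(s) {
    if (grepl("N", s, fixed = TRUE)) return("unannotated")
    rc <- revcomp(s)
    for (lab in labels) {
      if (grepl(s, ref_cat[[lab]], fixed = TRUE) ||
          grepl(rc, ref_cat[[lab]], fixed = TRUE)) return(lab)
    }
    "unannotated"
  }, character(1), USE.NAMES = FALSE)
  dplyr::mutate(uniques, class = cls)
}

#' Summarise a read classification into a class profile
#'
#' @param classified Tibble from [classify_reads()] (needs `class` and
#'   `count` columns).
#' @param class_order Optional class display order; defaults to the order
#'   of first appearance with `"unannotated"` last.
#' @return Tibble with columns `class`, `reads`, `fraction`; `reads` sums
#'   to the total collapsed read count.
#' @export
class_profile <- function(classified, class_order = NULL) {
  stopifnot(all(c("class", "count") %in% names(classified)))
  prof <- classified |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(reads = sum(.data$count), .groups = "drop")
  if (is.null(class_order)) {
    class_order <- c(setdiff(unique(classified$class), "unannotated"),
                     "unannotated")
  }
  prof <- prof |>
    dplyr::mutate(class = factor(.data$class, levels = class_order)) |>
    dplyr::arrange(.data$class) |>
    dplyr::mutate(class = as.character(.data$class),
                  fraction = .data$reads / sum(.data$reads))
  prof
}
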