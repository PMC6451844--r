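#' Composition report of identified miRNA sequences
#'
#' Length distribution, per-position base counts and per-length first-base
#' counts. `T` and `U` are treated as one symbol and reported as `U`.
#'
#' @param sequences Character vector of miRNA sequences (non-empty).
#' @return Object of class `composition_report`: list with tibbles
#'   `lengths` (`length`, `n`, `fraction`), `position_bases` (`position`,
#'   `base`, `n`) and `first_base_by_length` (`length`, `base`, `n`), plus
#'   `n_sequences`.
#' @export
composition_report <- function(sequences) {
  if (length(sequences) == 0) abort("no sequences to profile")
  seqs <- toupper(chartr("Tt", "Uu", sequences))
  lens <- nchar(seqs)
  lengths <- tibble(length = lens) |>
    dplyr::count(.data$length, name = "n") |>
    dplyr::mutate(fraction = .data$n / sum(.data$n))
  chars <- strsplit(seqs, "")
  pos_tab <- dplyr::bind_rows(lapply(seq_along(chars), function(i) {
    tibble(position = seq_along(chars[[i]]), base = chars[[i]])
  })) |>
    dplyr::count(.data$position, .data$base, name = "n")
  first <- tibble(length = lens,
                  base = vapply(chars, `[`, character(1), 1)) |>
    dplyr::count(.data$length, .data$base, name = "n")
  structure(list(lengths = lengths, position_bases = pos_tab,
                 first_base_by_length = first,
                 n_sequences = length(seqs)),
            class = "composition_report")
}

#' @export
print.composition_report <- function(x, ...) {
  cat("<composition_report> ", x$n_sequences, " sequences\n", sep = "")
  top <- dplyr::arrange(x$lengths, dplyr::desc(.data$fraction))
  cat("most abundant length: ", top$length[1], " nt (",
      sprintf("%.2f%%", 100 * top$fraction[1]), ")\n", sep = "")
  invisible(x)
}

GO_NAMESPACES <- c("biological process", "molecular function",
                   "cellular component")

#' Cluster GO annotations of a gene set by namespace
#'
#' Counts gene-term matches (the counting unit is the distinct gene-term
#' pair, not the gene) for the given gene set in each of the three GO root
#' namespaces, and tabulates the top terms per namespace.
#'
#' @param annotations Tibble/data frame with columns `gene`, `go_id`,
#'   `namespace`, `term`. Records with a namespace outside the three GO
#'   roots are skipped with a warning.
#' @param genes Character vector of gene ids (matched case-insensitively,
#'   version suffixes stripped).
#' @param top_n Rows per namespace in the term table (default 10).
#' @return Object of class `go_cluster`: list with `namespaces` tibble
#'   (`namespace`, `n_matches`, `fraction`), `top_terms` tibble
#'   (`namespace`, `term`, `go_id`, `n_genes`), `n_matches` and the
#'   `no_matches` flag (fractions are reported as 0 when nothing matches).
#' @export
go_cluster <- function(annotations, genes, top_n = 10L) {
  annotations <- as_tibble(annotations)
  need <- c("gene", "go_id", "namespace", "term")
  if (!all(need %in% names(annotations)))
    abort(paste0("annotations need columns: ", paste(need, collapse = ", ")))
  bad <- !annotations$namespace %in% GO_NAMESPACES
  if (any(bad)) {
    warn(sprintf("skipped %d annotation record(s) with unknown namespace",
                 sum(bad)))
    annotations <- annotations[!bad, ]
  }
  gset <- unique(normalize_gene_id(genes))
  matches <- annotations |>
    dplyr::filter(normalize_gene_id(.data$gene) %in% gset) |>
    dplyr::distinct(.data$gene, .data$go_id, .keep_all = TRUE)
  n_matches <- nrow(matches)
  ns <- matches |>
    dplyr::count(.data$namespace, name = "n_matches") |>
    dplyr::right_join(tibble(namespace = GO_NAMESPACES), by = "namespace") |>
    dplyr::mutate(n_matches = dplyr::coalesce(.data$n_matches, 0L),
                  fraction = if (!!n_matches > 0) .data$n_matches / !!n_matches
                             else 0) |>
    dplyr::arrange(match(.data$namespace, GO_NAMESPACES))
  top <- matches |>
    dplyr::count(.data$namespace, .data$term, .data$go_id, name = "n_genes") |>
    dplyr::group_by(.data$namespace) |>
    dplyr::arrange(dplyr::desc(.data$n_genes), .data$term, .by_group = TRUE) |>
    dplyr::slice_head(n = top_n) |>
    dplyr::ungroup()
  structure(list(namespaces = ns, top_terms = top,
                 n_matches = n_matches, no_matches = n_matches == 0),
            class = "go_cluster")
}

#' @export
print.go_cluster <- function(x, ...) {
  cat("<go_cluster> ", x$n_matches, " gene-term matches\n", sep = "")
  print(x$namespaces)
  invisible(x)
}
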