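#' Tidy a folded secondary structure
#'
#' One row per base pair with its weight.
#'
#' @param x `rna_fold` object.
#' @param ... Unused.
#' @return Tibble with columns `i`, `j`, `weight`.
#' @export
tidy.rna_fold <- function(x, ...) {
  x$pairs
}

#' One-row summary of a folded secondary structure
#'
#' @param x `rna_fold` object.
#' @param ... Unused.
#' @return Tibble with `length`, `n_pairs`, `paired_fraction`, `pair_sum`,
#'   `score`.
#' @export
glance.rna_fold <- function(x, ...) {
  n <- length(x$partner)
  tibble(length = n, n_pairs = nrow(x$pairs),
         paired_fraction = if (n > 0) sum(x$partner > 0) / n else 0,
         pair_sum = x$pair_sum, score = x$score)
}

#' Tidy a pipeline run into stage counts
#'
#' @param x `conmir_run` object.
#' @param ... Unused.
#' @return Tibble with `stage`, `records`.
#' @export
tidy.conmir_run <- function(x, ...) {
  cnt <- x$manifest$stage_counts
  tibble(stage = names(cnt), records = unlist(cnt, use.names = FALSE))
}

#' One-row summary of a pipeline run
#'
#' @param x `conmir_run` object.
#' @param ... Unused.
#' @return Tibble with the headline numbers of the run: unique reads,
#'   homology hits, families, stem-loops, targets, cleavage fraction.
#' @export
glance.conmir_run <- function(x, ...) {
  tibble(
    n_unique_reads = nrow(x$uniques),
    n_hits = nrow(x$hits),
    n_families = x$families$n_families,
    n_candidates = nrow(x$candidates),
    n_stem_loops = if (nrow(x$verdicts) > 0) sum(x$verdicts$is_stem_loop) else 0L,
    n_targets = nrow(x$targets),
    cleavage_fraction = x$cleavage$fraction
  )
}
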