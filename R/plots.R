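#' Plot the length distribution of identified miRNAs
#'
#' @param report `composition_report` object.
#' @return A ggplot.
#' @export
plot_length_distribution <- function(report) {
  stopifnot(inherits(report, "composition_report"))
  ggplot2::ggplot(report$lengths,
                  ggplot2::aes(x = factor(.data$length), y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = "read length (nt)", y = "fraction of miRNAs",
                  title = "Length distribution of identified miRNAs") +
    ggplot2::theme_minimal()
}

#' Plot first-nucleotide bias by miRNA length
#'
#' @param report `composition_report` object.
#' @return A ggplot.
#' @export
plot_first_base <- function(report) {
  stopifnot(inherits(report, "composition_report"))
  ggplot2::ggplot(report$first_base_by_length,
                  ggplot2::aes(x = factor(.data$length), y = .data$n,
                               fill = .data$base)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = "miRNA length (nt)", y = "sequences",
                  fill = "first base",
                  title = "First-nucleotide bias by length") +
    ggplot2::theme_minimal()
}

#' Plot positional nucleotide bias
#'
#' @param report `composition_report` object.
#' @return A ggplot.
#' @export
plot_position_bias <- function(report) {
  stopifnot(inherits(report, "composition_report"))
  ggplot2::ggplot(report$position_bases,
                  ggplot2::aes(x = factor(.data$position), y = .data$n,
                               fill = .data$base)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = "position (5' to 3')", y = "sequences", fill = "base",
                  title = "Positional nucleotide bias") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.composition_report <- function(object, ...) {
  plot_length_distribution(object)
}

#' Plot the species-conservation histogram of stress-responsive families
#'
#' @param evidence Tibble from [read_evidence_table()].
#' @param conditions Conditions to show (default both).
#' @return A ggplot.
#' @export
plot_conservation <- function(evidence, conditions = c("salt", "drought")) {
  dat <- dplyr::bind_rows(lapply(conditions, function(cc) {
    dplyr::mutate(conservation_histogram(evidence, cc), condition = cc)
  }))
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$n_species),
                                    y = .data$n_families,
                                    fill = .data$condition)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "number of supporting species", y = "miRNA families",
                  fill = "stress",
                  title = "Conservation of stress-responsive miRNA families") +
    ggplot2::theme_minimal()
}

#' Plot GO namespace clustering of target genes
#'
#' @param cluster `go_cluster` object.
#' @return A ggplot of the top terms per namespace.
#' @export
plot_go_clusters <- function(cluster) {
  stopifnot(inherits(cluster, "go_cluster"))
  ggplot2::ggplot(cluster$top_terms,
                  ggplot2::aes(x = stats::reorder(.data$term, .data$n_genes),
                               y = .data$n_genes)) +
    ggplot2::geom_col(fill = "darkgreen") +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~namespace, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "genes",
                  title = "GO classification of predicted target genes") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.go_cluster <- function(object, ...) {
  plot_go_clusters(object)
}
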