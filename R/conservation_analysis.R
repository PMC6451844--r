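#' Read a species-by-condition stress-evidence table
#'
#' The TSV has a `family` column followed by `<species>_<condition>`
#' columns (condition `salt` or `drought`); cells may be `1`, `0`, blank
#' (no evidence) or a check mark transcribed as `1`. The result is a
#' lossless long boolean tibble.
#'
#' @param path TSV path.
#' @return Tibble of class `evidence_table` with columns `family`,
#'   `species`, `condition`, `evidence` (logical).
#' @export
read_evidence_table <- function(path) {
  if (!file.exists(path)) abort(paste0("evidence table not found: ", path))
  wide <- readr::read_tsv(path, col_types = readr::cols(
    family = readr::col_character(), .default = readr::col_character()))
  if (nrow(wide) == 0) abort("empty evidence table")
  if (!"family" %in% names(wide)) abort("evidence table needs a 'family' column")
  if (anyDuplicated(wide$family)) abort("duplicate family rows in evidence table")
  long <- wide |>
    tidyr::pivot_longer(-"family", names_to = "column", values_to = "cell") |>
    tidyr::separate_wider_regex("column",
      patterns = c(species = ".*", "_", condition = "salt|drought")) |>
    dplyr::mutate(evidence = !is.na(.data$cell) &
                    trimws(.data$cell) %in% c("1", "√", "x1", "TRUE")) |>
    dplyr::select("family", "species", "condition", "evidence")
  empty <- long |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(any = any(.data$evidence), .groups = "drop")
  if (any(!empty$any))
    abort(paste0("evidence table has all-empty rows: ",
                 paste(empty$family[!empty$any], collapse = ", ")))
  structure(long, class = c("evidence_table", class(long)))
}

#' Write an evidence table back to wide TSV
#'
#' @param evidence Long tibble from [read_evidence_table()].
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_evidence_table <- function(evidence, path) {
  wide <- evidence |>
    dplyr::mutate(column = paste0(.data$species, "_", .data$condition),
                  cell = as.integer(.data$evidence)) |>
    dplyr::select("family", "column", "cell") |>
    tidyr::pivot_wider(names_from = "column", values_from = "cell")
  readr::write_tsv(wide, path)
  invisible(path)
}

check_condition <- function(evidence, condition) {
  known <- unique(evidence$condition)
  if (!condition %in% known)
    abort(paste0("unknown condition '", condition, "' (table has: ",
                 paste(known, collapse = ", "), ")"))
}

#' Families with evidence for a stress condition
#'
#' A family counts as responsive to a condition when at least one species
#' carries evidence for it.
#'
#' @param evidence Tibble from [read_evidence_table()].
#' @param condition `"salt"` or `"drought"` (must exist in the table).
#' @return Sorted character vector of family labels.
#' @export
condition_families <- function(evidence, condition) {
  check_condition(evidence, condition)
  fams <- evidence |>
    dplyr::filter(.data$condition == !!condition, .data$evidence) |>
    dplyr::pull("family")
  sort(unique(fams))
}

#' Families with evidence for both of two conditions
#'
#' @param evidence Tibble from [read_evidence_table()].
#' @param cond_a,cond_b Condition labels.
#' @return Sorted character vector (intersection of the two family sets).
#' @export
condition_intersection <- function(evidence, cond_a, cond_b) {
  intersect(condition_families(evidence, cond_a),
            condition_families(evidence, cond_b))
}

#' Conservation histogram of a stress condition
#'
#' Counts, for each number of supporting species, how many families are
#' supported by exactly that many species; unsupported families are
#' excluded, so the counts sum to the size of the condition's family set.
#'
#' @param evidence Tibble from [read_evidence_table()].
#' @param condition Condition label.
#' @return Tibble with columns `n_species`, `n_families`.
#' @export
conservation_histogram <- function(evidence, condition) {
  check_condition(evidence, condition)
  evidence |>
    dplyr::filter(.data$condition == !!condition) |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(n_species = sum(.data$evidence), .groups = "drop") |>
    dplyr::filter(.data$n_species > 0) |>
    dplyr::count(.data$n_species, name = "n_families") |>
    dplyr::arrange(.data$n_species)
}

#' Read a stress-target record table
#'
#' One row per (miRNA, target gene) with its drought/salt association
#' (cells `1`/check = associated, `0`/`x`/blank = not) and the annotated
#' protein product. Every record must be associated with at least one
#' condition.
#'
#' @param path TSV path with columns `family`, `mirna_name`, `drought`,
#'   `salt`, `target_gene_id`, `product`.
#' @return Tibble with `drought`/`salt` as logicals.
#' @export
read_stress_targets <- function(path) {
  if (!file.exists(path)) abort(paste0("stress-target table not found: ", path))
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  need <- c("family", "mirna_name", "drought", "salt", "target_gene_id", "product")
  if (!all(need %in% names(tab)))
    abort(paste0("stress-target table needs columns: ", paste(need, collapse = ", ")))
  as_flag <- function(x) !is.na(x) & trimws(x) %in% c("1", "√", "TRUE")
  out <- tab |>
    dplyr::mutate(drought = as_flag(.data$drought), salt = as_flag(.data$salt))
  if (any(!out$drought & !out$salt))
    abort("stress-target records must have at least one of drought/salt")
  out
}

#' Intersect predicted targets with a stress-gene list
#'
#' Keeps target hits whose gene is in the stress-gene list (gene ids are
#' matched case-insensitively with version suffixes stripped) and annotates
#' each with its miRNA family's salt/drought status from the evidence
#' table.
#'
#' @param hits Tibble from [scan_targets()] (`mirna_id`, `transcript_id`).
#' @param stress_genes Character vector of stress-related gene ids.
#' @param evidence Optional tibble from [read_evidence_table()] supplying
#'   the salt/drought status; families absent from the table get `FALSE`.
#' @return Tibble of stress-target records: `family`, `mirna_name`,
#'   `drought`, `salt`, `target_gene_id`.
#' @export
stress_gene_overlap <- function(hits, stress_genes, evidence = NULL) {
  stress_norm <- normalize_gene_id(stress_genes)
  out <- hits |>
    dplyr::filter(normalize_gene_id(.data$transcript_id) %in% stress_norm) |>
    dplyr::transmute(family = mirna_family(.data$mirna_id),
                     mirna_name = .data$mirna_id,
                     target_gene_id = .data$transcript_id)
  if (!is.null(evidence)) {
    status <- evidence |>
      dplyr::group_by(.data$family, .data$condition) |>
      dplyr::summarise(any = any(.data$evidence), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "condition", values_from = "any",
                         values_fill = FALSE)
    out <- out |>
      dplyr::left_join(status, by = "family") |>
      dplyr::mutate(dplyr::across(dplyr::any_of(c("salt", "drought")),
                                  ~ !is.na(.x) & .x))
  } else {
    out$salt <- FALSE
    out$drought <- FALSE
  }
  dplyr::relocate(out, "family", "mirna_name", dplyr::any_of(c("drought", "salt")),
                  "target_gene_id")
}
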