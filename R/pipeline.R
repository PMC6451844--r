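#' Default pipeline parameters
#'
#' All thresholds of the discovery pipeline with their defaults: adapter
#' and trimming settings, the >90% identity / E-value <= 1e-4 homology
#' filters, the 80-nt precursor flank, the psRNATarget-style expectation
#' ceiling 3.0 with hspsize 18 and top 50 targets, and the stem-loop
#' classification threshold.
#'
#' @return Named list of parameters.
#' @export
default_params <- function() {
  list(adapter = conmir_adapter(), quality_cutoff = 20, min_len = 16,
       max_len = 30, min_identity = 0.90, max_evalue = 1e-4,
       min_coverage = 0.90, flank = 80, max_expectation = 3.0,
       hspsize = 18, top_n = 50, min_paired_fraction = 0.60, min_loop = 3,
       seed = 1)
}

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(paste0("config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config$params <- utils::modifyList(default_params(),
                                     config$params %||% list())
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_input <- function(path, stage, what) {
  if (is.null(path) || !file.exists(path))
    abort(sprintf("stage '%s': missing input %s: %s", stage, what,
                  path %||% "<unset>"))
  path
}

stage_warn_empty <- function(n, stage) {
  if (n == 0) warn(sprintf("stage '%s' produced zero records; downstream stages still run", stage))
  n
}

#' Run the conserved-miRNA discovery pipeline end-to-end
#'
#' Executes, in order: read preparation (trim + collapse), known-RNA
#' classification, homology search against the mature reference, precursor
#' extraction from genome scaffolds, stem-loop folding and classification,
#' target prediction on the transcriptome, stress-conservation analysis,
#' and composition/GO reporting. All stage outputs are written under
#' `config$out_dir` together with `manifest.json` recording the verbatim
#' configuration, its hash and per-stage record counts. Reruns with the
#' same configuration produce byte-identical output trees.
#'
#' @param config Configuration list or YAML path with input paths
#'   (`reads_fastq`, `mature_fa`, `genome_fa`, `transcripts_fa`, `go_tsv`,
#'   `stress_genes_txt`, `evidence_tsv`, `class_refs`), `out_dir`, and an
#'   optional `params` list overriding [default_params()].
#' @return Object of class `conmir_run` (invisibly): list with the stage
#'   tables and the manifest.
#' @export
run_pipeline <- function(config) {
  config <- read_run_config(config)
  pr <- config$params
  out_dir <- config$out_dir %||% abort("config needs an out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  o <- function(...) file.path(out_dir, ...)
  counts <- list()

  # 1. prep ----------------------------------------------------------------
  reads <- read_smallrna_fastq(check_input(config$reads_fastq, "prep", "FASTQ"))
  trimmed <- trim_reads(reads, adapter = pr$adapter,
                        quality_cutoff = pr$quality_cutoff,
                        min_len = pr$min_len, max_len = pr$max_len)
  uniques <- collapse_reads(trimmed)
  write_collapsed_fasta(uniques, o("collapsed.fasta"))
  counts$prep <- stage_warn_empty(nrow(uniques), "prep")

  # 2. classify ------------------------------------------------------------
  # the mature reference doubles as the miRNA class, ahead of the others
  class_refs <- c(list(miRNA = check_input(config$mature_fa, "classify",
                                           "mature reference FASTA")),
                  config$class_refs %||% toy_class_references())
  classified <- classify_reads(uniques, class_refs)
  profile <- class_profile(classified,
                           class_order = c(names(class_refs), "unannotated"))
  readr::write_tsv(profile, o("class_profile.tsv"))
  counts$classify <- stage_warn_empty(nrow(profile), "classify")

  # 3. search --------------------------------------------------------------
  refs <- read_mature_fasta(check_input(config$mature_fa, "search",
                                        "mature reference FASTA"))
  hits <- search_mirna_homologs(uniques, refs,
                                min_identity = pr$min_identity,
                                max_evalue = pr$max_evalue,
                                min_coverage = pr$min_coverage)
  readr::write_tsv(hits, o("hits.tsv"))
  fam <- summarize_families(hits)
  readr::write_tsv(fam$families, o("family_summary.tsv"))
  counts$search <- stage_warn_empty(nrow(hits), "search")

  # 4. extract -------------------------------------------------------------
  genome <- as_seq_vector(check_input(config$genome_fa, "extract",
                                      "genome FASTA"))
  mature_set <- hits |>
    dplyr::distinct(.data$sequence, .keep_all = TRUE)
  loci <- dplyr::bind_rows(lapply(seq_len(nrow(mature_set)), function(i) {
    find_mature_loci(mature_set$sequence[i], genome,
                     mature_id = mature_set$ref_id[i])
  }))
  candidates <- if (nrow(loci) > 0) {
    extract_precursors(loci, genome, flank = pr$flank)
  } else {
    extract_precursors(loci[0, ], genome, flank = pr$flank)
  }
  if (nrow(candidates) > 0) write_precursor_fasta(candidates, o("precursors.fa"))
  readr::write_tsv(candidates, o("precursors.tsv"))
  counts$extract <- stage_warn_empty(nrow(candidates), "extract")

  # 5. fold ----------------------------------------------------------------
  verdicts <- if (nrow(candidates) > 0) {
    fold_candidates(candidates, min_paired_fraction = pr$min_paired_fraction,
                    min_loop = pr$min_loop)
  } else {
    tibble()
  }
  if (nrow(verdicts) > 0) {
    folds <- attr(verdicts, "folds")
    ct_dir <- o("ct")
    dir.create(ct_dir, showWarnings = FALSE)
    db_lines <- character(0)
    for (i in seq_len(nrow(verdicts))) {
      nm <- sprintf("%s_%s_%d", verdicts$mature_id[i], verdicts$scaffold[i],
                    verdicts$window_start[i])
      write_ct(folds[[i]], file.path(ct_dir, paste0(nm, ".ct")), name = nm)
      db_lines <- c(db_lines, paste0(">", nm), folds[[i]]$sequence,
                    folds[[i]]$dot_bracket)
    }
    writeLines(db_lines, o("structures.db"))
    readr::write_tsv(dplyr::select(verdicts, -"sequence"), o("verdicts.tsv"))
  } else {
    readr::write_tsv(tibble(), o("verdicts.tsv"))
  }
  counts$fold <- stage_warn_empty(nrow(verdicts), "fold")

  # 6. targets -------------------------------------------------------------
  transcripts <- as_seq_vector(check_input(config$transcripts_fa, "targets",
                                           "transcript FASTA"))
  mirna_set <- setNames(mature_set$sequence, mature_set$ref_id)
  targets <- scan_targets(mirna_set, transcripts,
                          max_expectation = pr$max_expectation,
                          hspsize = pr$hspsize, top_n = pr$top_n)
  readr::write_tsv(targets, o("targets.tsv"))
  cleavage <- summarize_cleavage(targets)
  counts$targets <- stage_warn_empty(nrow(targets), "targets")

  # 7. conservation --------------------------------------------------------
  evidence <- read_evidence_table(check_input(config$evidence_tsv,
                                              "conservation", "evidence TSV"))
  stress_genes <- readLines(check_input(config$stress_genes_txt,
                                        "conservation", "stress-gene list"))
  overlap <- stress_gene_overlap(targets, stress_genes, evidence)
  readr::write_tsv(overlap, o("stress_overlap.tsv"))
  cons <- list(
    salt = length(condition_families(evidence, "salt")),
    drought = length(condition_families(evidence, "drought")),
    both = length(condition_intersection(evidence, "salt", "drought")),
    stress_target_records = nrow(overlap),
    cleavage_fraction = cleavage$fraction
  )
  jsonlite::write_json(cons, o("conservation_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  counts$conservation <- stage_warn_empty(nrow(overlap), "conservation")

  # 8. reports -------------------------------------------------------------
  comp <- composition_report(hits$sequence %||% character(0))
  readr::write_tsv(comp$lengths, o("lengths.tsv"))
  readr::write_tsv(comp$position_bases, o("position_bias.tsv"))
  readr::write_tsv(comp$first_base_by_length, o("first_base.tsv"))
  go_tab <- readr::read_tsv(check_input(config$go_tsv, "reports", "GO TSV"),
                            col_types = readr::cols(.default = readr::col_character()))
  gc <- go_cluster(go_tab, unique(targets$transcript_id))
  readr::write_tsv(gc$namespaces, o("go_clusters.tsv"))
  readr::write_tsv(gc$top_terms, o("go_top_terms.tsv"))
  counts$reports <- nrow(comp$lengths)

  # manifest ---------------------------------------------------------------
  cfg_path <- o("config.yaml")
  yaml::write_yaml(config, cfg_path)
  manifest <- list(
    package = "conmir",
    version = as.character(utils::packageVersion("conmir")),
    config = config,
    config_md5 = unname(tools::md5sum(cfg_path)),
    stage_counts = counts
  )
  jsonlite::write_json(manifest, o("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  res <- list(uniques = uniques, profile = profile, hits = hits,
              families = fam, candidates = candidates, verdicts = verdicts,
              targets = targets, cleavage = cleavage, evidence = evidence,
              stress_overlap = overlap, conservation = cons,
              composition = comp, go = gc, manifest = manifest,
              out_dir = out_dir)
  class(res) <- "conmir_run"
  invisible(res)
}

#' @export
print.conmir_run <- function(x, ...) {
  cat("<conmir_run> output:", x$out_dir, "\n")
  cnt <- x$manifest$stage_counts
  for (nm in names(cnt)) cat(sprintf("  %-12s %d\n", nm, cnt[[nm]]))
  invisible(x)
}

#' Hash every file of a pipeline output tree
#'
#' Convenience for determinism checks: md5 of every file under a run's
#' output directory, keyed by relative path.
#'
#' @param dir Output directory of a pipeline run.
#' @return Named character vector of md5 hashes.
#' @export
hash_output_tree <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  h <- tools::md5sum(files)
  names(h) <- sub(paste0("^", dir, "/?"), "", files)
  h
}
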