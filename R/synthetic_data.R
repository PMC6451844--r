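# Seeded synthetic-data generators. Every generator is deterministic under
# its seed argument (RNG state is scoped with withr) and returns complete
# ground-truth tables alongside the data, so pipeline recovery can be
# asserted exactly.

rand_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

substitute_bases <- function(seq, k) {
  if (k == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(length(chars), k)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

#' Default 3' sequencing adapter
#'
#' The TruSeq small RNA 3' adapter used as the simulation and trimming
#' default.
#'
#' @return Adapter sequence string.
#' @export
conmir_adapter <- function() "TGGAATTCTCGGGTGCCAAGG"

#' Simulate a mature miRNA reference across species
#'
#' Draws one canonical 20-22 nt mature per family and derives per-species
#' variants carrying at most `max_substitutions` substitutions (so the
#' >90% identity filter is exercised by near-identical cross-species
#' homologs). Identifiers are miRBase-style (`spa-miR101a-5p`).
#'
#' @param n_families Number of miRNA families (>= 1).
#' @param n_species Number of species.
#' @param seed Integer seed.
#' @param max_substitutions Maximum substitutions of a species variant
#'   relative to the family canonical (default 2).
#' @return Tibble with `ref_id`, `species`, `family`, `sequence`,
#'   `canonical`, `n_substitutions`.
#' @export
sim_mature_reference <- function(n_families = 12, n_species = 3, seed = 1,
                                 max_substitutions = 2) {
  stopifnot(n_families >= 1, n_species >= 1)
  withr::local_seed(seed)
  rows <- list()
  for (f in seq_len(n_families)) {
    len <- sample(20:22, 1)
    canon <- rand_bases(len)
    fam <- paste0("miR", 100 + f)
    for (s in seq_len(n_species)) {
      k <- if (s == 1) 0L else sample(0:max_substitutions, 1)
      rows[[length(rows) + 1]] <- tibble(
        ref_id = sprintf("sp%s-%s%s-5p", letters[s], fam, "a"),
        species = paste0("sp", letters[s]),
        family = fam,
        sequence = substitute_bases(canon, k),
        canonical = canon,
        n_substitutions = k
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Plant hairpin precursors in a synthetic genome
#'
#' Each mature is embedded as `mature + loop + star`, where the star is the
#' reverse complement of the mature carrying `star_mismatches`
#' substitutions. Insertions alternate between the plus and minus strand
#' and round-robin across scaffolds; the first precursor on every
#' even-numbered scaffold is deliberately placed 30 nt from the scaffold
#' start so flank truncation is exercised.
#'
#' @param matures Tibble with `ref_id`, `family`, `sequence` (one planting
#'   per row).
#' @param n_scaffolds Number of scaffolds.
#' @param scaffold_length Length of each scaffold in nt.
#' @param loop_len Loop length between mature and star (default 8).
#' @param star_mismatches Substitutions in the star arm (default 0: a
#'   perfect hairpin).
#' @param seed Integer seed.
#' @return List with `scaffolds` (named character) and `truth`, a tibble of
#'   planted loci (`ref_id`, `family`, `mature_sequence`, `scaffold`,
#'   `mature_start`, `mature_end`, `strand`, `precursor_start`,
#'   `precursor_end`, `near_edge`, `star_mismatches`).
#' @export
sim_genome <- function(matures, n_scaffolds = 4, scaffold_length = 8000,
                       loop_len = 8, star_mismatches = 0, seed = 1) {
  max_prec <- max(nchar(matures$sequence)) * 2 + loop_len
  if (scaffold_length < 2 * (80 + max_prec))
    abort("scaffold_length too small for planted precursors plus flanks")
  withr::local_seed(seed)
  scaffolds <- vapply(seq_len(n_scaffolds), function(i) rand_bases(scaffold_length),
                      character(1))
  names(scaffolds) <- sprintf("scaffold%02d", seq_len(n_scaffolds))
  cursor <- rep(200L, n_scaffolds)
  edge_used <- rep(FALSE, n_scaffolds)
  truth <- list()
  for (i in seq_len(nrow(matures))) {
    m <- matures$sequence[i]
    L <- nchar(m)
    loop <- rand_bases(loop_len)
    star <- substitute_bases(revcomp(m), star_mismatches)
    prec <- paste0(m, loop, star)
    plen <- nchar(prec)
    sc <- (i - 1L) %% n_scaffolds + 1L
    strand <- if (i %% 2L == 1L) "+" else "-"
    near_edge <- sc %% 2L == 0L && !edge_used[sc]
    if (near_edge) {
      pos <- 31L
      edge_used[sc] <- TRUE
    } else {
      pos <- cursor[sc] + sample(0:40, 1)
      cursor[sc] <- pos + plen + 170L
    }
    if (pos + plen - 1L > scaffold_length - 10L)
      abort("scaffold capacity exceeded; increase scaffold_length or n_scaffolds")
    planted <- if (strand == "+") prec else revcomp(prec)
    substr(scaffolds[sc], pos, pos + plen - 1L) <- planted
    if (strand == "+") {
      ms <- pos; me <- pos + L - 1L
    } else {
      ms <- pos + plen - L; me <- pos + plen - 1L
    }
    truth[[i]] <- tibble(
      ref_id = matures$ref_id[i], family = matures$family[i],
      mature_sequence = m, scaffold = names(scaffolds)[sc],
      mature_start = ms, mature_end = me, strand = strand,
      precursor_start = pos, precursor_end = pos + plen - 1L,
      near_edge = near_edge, star_mismatches = star_mismatches
    )
  }
  list(scaffolds = scaffolds, truth = dplyr::bind_rows(truth))
}

toy_class_references <- function() {
  ext <- function(f) system.file("extdata", f, package = "conmir")
  list(rRNA = ext("toy_rrna.fa"), tRNA = ext("toy_trna.fa"),
       snoRNA = ext("toy_snorna.fa"))
}

#' Simulate adaptered small RNA reads with decoys
#'
#' Per mature, the read count follows a negative-binomial depth model
#' (heterogeneous miRNA abundance); each read is the mature (with a 1-nt 3'
#' jitter in a fraction of reads) followed by the 3' adapter, truncated to
#' `read_length`, with substitution errors at `error_rate` and constant
#' Q35 qualities. Decoy reads are a mix of random 18-24-mers and fragments
#' of the packaged toy rRNA/tRNA references, making up `decoy_fraction` of
#' all reads.
#'
#' @param matures Tibble with `ref_id`, `sequence`.
#' @param depth_mean,depth_dispersion Negative-binomial mean and dispersion
#'   (defaults 50 and 5).
#' @param adapter 3' adapter (default [conmir_adapter()]).
#' @param error_rate Per-base substitution error rate (must be <= 0.05).
#' @param decoy_fraction Fraction of all reads that are decoys.
#' @param read_length Sequencer read length (default 50).
#' @param seed Integer seed.
#' @return List with `reads` (tibble `id`, `sequence`, `quality`) and
#'   `truth` (tibble `read_id`, `origin`, `ref_id`).
#' @export
sim_reads <- function(matures, depth_mean = 50, depth_dispersion = 5,
                      adapter = conmir_adapter(), error_rate = 0.001,
                      decoy_fraction = 0.3, read_length = 50, seed = 1) {
  stopifnot(error_rate >= 0, error_rate <= 0.05,
            decoy_fraction >= 0, decoy_fraction < 1)
  withr::local_seed(seed)
  qual35 <- strrep(intToUtf8(35 + 33), read_length)

  make_read <- function(insert) {
    full <- paste0(insert, adapter)
    if (nchar(full) < read_length)
      full <- paste0(full, rand_bases(read_length - nchar(full)))
    full <- substr(full, 1, read_length)
    if (error_rate > 0) {
      chars <- strsplit(full, "")[[1]]
      err <- which(runif(length(chars)) < error_rate)
      for (p in err)
        chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
      full <- paste(chars, collapse = "")
    }
    full
  }

  seqs <- character(0); origins <- character(0); refs <- character(0)
  for (i in seq_len(nrow(matures))) {
    n_i <- rnbinom(1, size = depth_dispersion, mu = depth_mean)
    if (n_i == 0) next
    m <- matures$sequence[i]
    for (r in seq_len(n_i)) {
      jitter <- sample(c(0L, -1L, 1L), 1, prob = c(0.8, 0.1, 0.1))
      insert <- if (jitter == -1L) substr(m, 1, nchar(m) - 1)
                else if (jitter == 1L) paste0(m, rand_bases(1))
                else m
      seqs <- c(seqs, make_read(insert))
    }
    origins <- c(origins, rep("mirna", n_i))
    refs <- c(refs, rep(matures$ref_id[i], n_i))
  }
  n_mirna <- length(seqs)
  n_decoy <- round(n_mirna * decoy_fraction / (1 - decoy_fraction))
  if (n_decoy > 0) {
    class_refs <- toy_class_references()
    pools <- lapply(class_refs[c("rRNA", "tRNA")], as_seq_vector)
    for (d in seq_len(n_decoy)) {
      kind <- sample(c("random", "rRNA", "tRNA"), 1,
                     prob = c(0.5, 0.25, 0.25))
      insert <- if (kind == "random") {
        rand_bases(sample(18:24, 1))
      } else {
        src <- sample(pools[[kind]], 1)
        len <- sample(18:24, 1)
        start <- sample(nchar(src) - len + 1, 1)
        substr(src, start, start + len - 1)
      }
      seqs <- c(seqs, make_read(insert))
      origins <- c(origins, kind)
      refs <- c(refs, NA_character_)
    }
  }
  ids <- sprintf("read%06d", seq_along(seqs))
  list(
    reads = tibble(id = ids, sequence = seqs,
                   quality = rep(qual35, length(seqs))),
    truth = tibble(read_id = ids, origin = origins, ref_id = refs)
  )
}

#' Write simulated reads as FASTQ (phred+33)
#'
#' @param reads Tibble with `id`, `sequence`, `quality`.
#' @param path Output FASTQ path.
#' @return The path, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(reads$sequence, reads$id)),
    Biostrings::PhredQuality(reads$quality))
  Biostrings::writeQualityScaledXStringSet(x, filepath = path)
  invisible(path)
}

# penalty arithmetic of a site spec, independent of score_duplex
spec_expectation <- function(states, L, double_positions = 2:13) {
  if (length(states) == 0) return(0)
  pos <- as.integer(names(states))
  pen <- c(GU = 0.5, mismatch = 1)[states]
  sum(pen * ifelse(pos %in% double_positions, 2, 1))
}

spec_inhibition <- function(states, central_positions = 9:11) {
  pos <- as.integer(names(states))
  if (any(states == "mismatch" & pos %in% central_positions)) "translation"
  else "cleavage"
}

#' Default planted target-site specifications
#'
#' Builds `n_cleavage` cleavage-type and `n_translation` translation-type
#' site specifications over the given miRNAs (cycled). Cleavage specs keep
#' the central region (positions 9-11) perfectly paired and stay at or
#' below expectation 3; translation specs place one mismatch centrally.
#' Wobble positions are only used where the miRNA base admits a G:U pair.
#'
#' @param mirnas Named character vector (id -> sequence).
#' @param n_cleavage,n_translation Numbers of planted sites (defaults 20
#'   and 5).
#' @return Tibble with `mirna_id` and a `states` list-column (named
#'   character vectors, miRNA position -> `"GU"`/`"mismatch"`).
#' @export
default_site_specs <- function(mirnas, n_cleavage = 20, n_translation = 5) {
  ids <- names(mirnas)
  gu_ok <- function(seq, pos) substr(seq, pos, pos) %in% c("G", "T", "U")
  menus <- list(
    function(seq, L) c(),                                    # perfect
    function(seq, L) c(stats::setNames("mismatch", L - 1)),  # 3' mismatch
    function(seq, L) {
      p <- which(vapply(15:min(L, 16), function(k) gu_ok(seq, k), logical(1)))
      if (length(p)) stats::setNames("GU", 14 + p[1])
      else stats::setNames("mismatch", L)
    },
    function(seq, L) stats::setNames(c("mismatch", "mismatch"), c(1, L))
  )
  rows <- list()
  for (k in seq_len(n_cleavage)) {
    id <- ids[(k - 1) %% length(ids) + 1]
    seq <- toupper(chartr("Uu", "Tt", mirnas[[id]]))
    L <- nchar(seq)
    states <- menus[[(k - 1) %% length(menus) + 1]](seq, L)
    rows[[length(rows) + 1]] <- tibble(mirna_id = id, states = list(states))
  }
  central <- c(9, 10, 11)
  for (k in seq_len(n_translation)) {
    id <- ids[(k - 1) %% length(ids) + 1]
    pos <- central[(k - 1) %% 3 + 1]
    rows[[length(rows) + 1]] <- tibble(
      mirna_id = id, states = list(stats::setNames("mismatch", pos)))
  }
  dplyr::bind_rows(rows)
}

#' Simulate a transcriptome with planted miRNA target sites
#'
#' Each site specification becomes one transcript with exactly the
#' requested mismatch/wobble structure embedded at a random position, so
#' the duplex scorer must recover the specified expectation exactly.
#' Additional decoy transcripts carry no planted site.
#'
#' @param mirnas Named character vector (id -> sequence).
#' @param site_specs Tibble from [default_site_specs()] (the default).
#' @param n_decoy_transcripts Transcripts without sites (default 10).
#' @param transcript_length Transcript length in nt (default 500).
#' @param seed Integer seed.
#' @return List with `transcripts` (named character) and `truth` (tibble
#'   `transcript_id`, `mirna_id`, `site_start`, `site_end`, `expectation`,
#'   `inhibition`).
#' @export
sim_transcriptome <- function(mirnas, site_specs = default_site_specs(mirnas),
                              n_decoy_transcripts = 10,
                              transcript_length = 500, seed = 1) {
  withr::local_seed(seed)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  txs <- character(0)
  truth <- list()
  for (k in seq_len(nrow(site_specs))) {
    id <- site_specs$mirna_id[k]
    states <- site_specs$states[[k]]
    mir <- toupper(chartr("Uu", "Tt", mirnas[[id]]))
    L <- nchar(mir)
    site <- strsplit(revcomp(mir), "")[[1]]  # perfect complement, 5'->3'
    if (length(states)) {
      pos <- as.integer(names(states))
      for (q in seq_along(pos)) {
        p <- pos[q]
        mb <- substr(mir, p, p)
        sp <- L - p + 1  # site index facing miRNA position p
        if (states[q] == "GU") {
          if (mb == "G") site[sp] <- "T"
          else if (mb == "T") site[sp] <- "G"
          else abort(sprintf("G:U not possible at miRNA position %d (base %s)", p, mb))
        } else {
          site[sp] <- mb  # same base never pairs: guaranteed mismatch
        }
      }
    }
    site <- paste(site, collapse = "")
    bg <- rand_bases(transcript_length)
    at <- sample(transcript_length - L - 1, 1)
    substr(bg, at, at + L - 1) <- site
    tx_id <- sprintf("TX%04d", k)
    txs[tx_id] <- bg
    truth[[k]] <- tibble(
      transcript_id = tx_id, mirna_id = id,
      site_start = at, site_end = at + L - 1L,
      expectation = spec_expectation(states, L),
      inhibition = spec_inhibition(states)
    )
  }
  for (d in seq_len(n_decoy_transcripts)) {
    txs[sprintf("DECOY%04d", d)] <- rand_bases(transcript_length)
  }
  list(transcripts = txs, truth = dplyr::bind_rows(truth))
}

#' Simulate a GO annotation table
#'
#' Gene-term annotations drawn with fixed namespace proportions; term
#' vocabulary is a small synthetic pool per namespace.
#'
#' @param genes Character vector of gene ids to annotate.
#' @param n_annotations Number of annotation records (default 1000).
#' @param namespace_weights Probabilities of the three GO roots in the
#'   order biological process, cellular component, molecular function.
#' @param seed Integer seed.
#' @return Tibble with `gene`, `go_id`, `namespace`, `term`.
#' @export
sim_go_annotations <- function(genes, n_annotations = 1000,
                               namespace_weights = c(0.4, 0.3, 0.3),
                               seed = 1) {
  stopifnot(length(namespace_weights) == 3,
            abs(sum(namespace_weights) - 1) < 1e-9)
  withr::local_seed(seed)
  ns <- c("biological process", "cellular component", "molecular function")
  terms <- list(
    `biological process` = c("response to stress", "signal transduction",
      "photosynthesis", "protein phosphorylation", "lipid metabolic process",
      "transcription regulation", "cell wall organization", "transport"),
    `cellular component` = c("nucleus", "chloroplast", "plasma membrane",
      "cytosol", "mitochondrion", "ribosome", "vacuole", "cell wall"),
    `molecular function` = c("ATP binding", "DNA binding",
      "protein kinase activity", "transferase activity", "hydrolase activity",
      "metal ion binding", "oxidoreductase activity", "RNA binding")
  )
  picked_ns <- sample(ns, n_annotations, replace = TRUE,
                      prob = namespace_weights)
  out <- tibble(
    gene = sample(genes, n_annotations, replace = TRUE),
    namespace = picked_ns,
    term = vapply(picked_ns, function(n) sample(terms[[n]], 1), character(1))
  )
  vocab <- unlist(terms, use.names = FALSE)
  out$go_id <- sprintf("GO:%07d", match(out$term, vocab))
  dplyr::select(out, "gene", "go_id", "namespace", "term")
}

#' Simulate a complete small RNA study with ground truth
#'
#' One-stop generator: mature reference, genome with planted precursors,
#' adaptered reads with decoys, transcriptome with planted target sites,
#' GO annotations and a stress-gene list, all deterministic under `seed`.
#' Thirty of the 36 reference matures (12 families x 3 species, every
#' family represented) are planted and sequenced; the remainder exist only
#' in the reference.
#'
#' @param seed Integer seed.
#' @param n_families,n_species Reference shape (defaults 12 and 3).
#' @param n_planted Number of matures planted and sequenced (default 30).
#' @param depth_mean,depth_dispersion,error_rate,decoy_fraction Passed to
#'   [sim_reads()].
#' @param star_mismatches Passed to [sim_genome()].
#' @return List with `reference`, `planted`, `genome` (scaffolds + truth),
#'   `reads` (reads + truth), `transcriptome` (transcripts + truth),
#'   `go_annotations`, `stress_genes`, and the target miRNA set used for
#'   scanning (`target_mirnas`).
#' @export
sim_smallrna_study <- function(seed = 1, n_families = 12, n_species = 3,
                               n_planted = 30, depth_mean = 50,
                               depth_dispersion = 5, error_rate = 0.001,
                               decoy_fraction = 0.3, star_mismatches = 0) {
  reference <- sim_mature_reference(n_families, n_species, seed = seed)
  withr::local_seed(seed + 1L)
  first <- reference |> dplyr::filter(.data$species == "spa")
  rest <- reference |> dplyr::filter(.data$species != "spa")
  n_extra <- max(0, n_planted - nrow(first))
  planted <- dplyr::bind_rows(first, rest[sample(nrow(rest), n_extra), ]) |>
    dplyr::slice_head(n = n_planted)
  genome <- sim_genome(planted, star_mismatches = star_mismatches,
                       seed = seed + 2L)
  reads <- sim_reads(planted, depth_mean = depth_mean,
                     depth_dispersion = depth_dispersion,
                     error_rate = error_rate,
                     decoy_fraction = decoy_fraction, seed = seed + 3L)
  target_mirnas <- setNames(planted$sequence, planted$ref_id)[1:5]
  transcriptome <- sim_transcriptome(target_mirnas, seed = seed + 4L)
  tx_ids <- names(transcriptome$transcripts)
  go_annotations <- sim_go_annotations(tx_ids, seed = seed + 5L)
  withr::local_seed(seed + 6L)
  with_sites <- transcriptome$truth$transcript_id
  stress_genes <- sort(sample(with_sites, ceiling(length(with_sites) / 3)))
  list(reference = reference, planted = planted, genome = genome,
       reads = reads, transcriptome = transcriptome,
       go_annotations = go_annotations, stress_genes = stress_genes,
       target_mirnas = target_mirnas)
}

#' Write all simulated study inputs to a directory
#'
#' Emits the FASTQ/FASTA/TSV inputs consumed by [run_pipeline()] plus
#' `truth/*.tsv`, and returns a ready-to-run pipeline configuration list.
#'
#' @param study List from [sim_smallrna_study()].
#' @param dir Output directory (created if needed).
#' @return Pipeline configuration list (paths filled in), invisibly.
#' @export
write_study_inputs <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  write_fastq(study$reads$reads, p("reads.fastq"))
  write_fasta(setNames(study$reference$sequence, study$reference$ref_id),
              p("mature.fa"))
  write_fasta(study$genome$scaffolds, p("genome.fa"))
  write_fasta(study$transcriptome$transcripts, p("transcripts.fa"))
  readr::write_tsv(study$go_annotations, p("go_annotations.tsv"))
  writeLines(study$stress_genes, p("stress_genes.txt"))
  file.copy(system.file("extdata", "table1_evidence.tsv", package = "conmir"),
            p("evidence.tsv"), overwrite = TRUE)
  readr::write_tsv(study$genome$truth, p("truth", "planted_precursors.tsv"))
  readr::write_tsv(study$reads$truth, p("truth", "read_origins.tsv"))
  readr::write_tsv(study$transcriptome$truth, p("truth", "planted_sites.tsv"))
  cfg <- list(
    reads_fastq = p("reads.fastq"),
    mature_fa = p("mature.fa"),
    genome_fa = p("genome.fa"),
    transcripts_fa = p("transcripts.fa"),
    go_tsv = p("go_annotations.tsv"),
    stress_genes_txt = p("stress_genes.txt"),
    evidence_tsv = p("evidence.tsv"),
    class_refs = toy_class_references()
  )
  invisible(cfg)
}
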