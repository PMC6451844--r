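---
title: "Homology-based discovery of conserved plant miRNAs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homology-based discovery of conserved plant miRNAs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conmir)
```

## The problem

Conserved microRNAs can be identified in a species without a sequenced
genome by homology: small RNA reads are compared against the mature miRNA
sequences already catalogued for other species, candidate precursors are
pulled from whatever genomic scaffolds are available and screened for the
canonical stem-loop, and targets are predicted from complementarity to
transcripts. `conmir` implements this discovery pipeline for plant small
RNA sequencing data — the setting where a diploid wheat relative is
profiled against the full complement of known plant mature miRNAs — as a
set of composable, tested functions plus a one-call orchestrator,
`run_pipeline()`.

Because studies of this kind often leave no public read archive, the
package ships a seeded generator (`sim_smallrna_study()`) that produces
every input the pipeline needs with complete ground truth, so that the
whole chain can be benchmarked end to end.

## Pipeline stages and their models

### Read preparation

`trim_reads()` removes the 3' sequencing adapter at its best left-most
occurrence. Full-length adapter occurrences tolerate one mismatch;
terminal overlaps at the read's 3' end must be exact and at least 6 nt —
shorter exact overlaps arise too often by chance. The 3' tail is then cut
after the last base at or above the phred cutoff (default Q20), and reads
are kept only if the insert falls in the 16–30 nt window (bracketing the
18–24 nt range of plant mature miRNAs) and carries at most one ambiguous
base. A single `N` is tolerated but can never count as a match anywhere
downstream. `collapse_reads()` merges identical inserts and records their
occurrence counts; the collapsed counts always sum to the number of
retained reads, which the tests assert as an invariant.

`classify_reads()` assigns each unique read to the first known-RNA class
(in a documented priority order) whose reference contains the read as an
exact substring on either strand. This replaces genome mapping against an
external reference: it keeps the profiling semantics (each read assigned
to exactly one class, priority resolving multi-class matches) without an
aligner or genome dependency.

### Homology search

Every unique read is aligned against every mature reference with a
Smith–Waterman local alignment (match +1, mismatch −2, gap −3; compiled
code). The traceback is fully deterministic: diagonal is preferred over a
gap in the subject over a gap in the query, and among equal-scoring
alignments the one with the smallest subject start (then query start)
wins, so output is reproducible byte for byte.

Alignment scores are converted to E-values with the Karlin–Altschul
formula `E = K·m·n·exp(−λ·score)`, with `n` the summed reference length.
`λ` solves `Σ p_i p_j exp(λ·s_ij) = 1` under uniform base composition,
and `K` is computed numerically by convolving the lattice score
distribution (the ladder-epoch series used for ungapped alignment
statistics). For the default +1/−2 scheme this yields λ ≈ 1.33 and
K ≈ 0.62, matching the published ungapped blastn constants, which the
package uses as an external sanity check of the numerics.

A hit is retained only when

* identity (matches / alignment columns, the BLAST convention) is
  **strictly** greater than 0.90,
* the alignment covers at least 90 % of the shorter sequence, and
* E ≤ 1e−4.

The coverage rule needs a word: identity alone would pass a 10-nt perfect
sub-alignment of a 24-nt read, which is clearly not the intended
"conserved mature" semantics, so coverage of the shorter sequence is
required alongside. The E-value criterion is an upper bound — a permissive
lower bound would make no sense as a false-positive filter. One best hit
is kept per read (lowest E, then highest identity, then lexicographic
reference id), and `summarize_families()` reduces hits to distinct
sequences and distinct `miR`-number families.

### Precursor extraction

`find_mature_loci()` finds every exact occurrence of a putative mature on
both strands of the genome scaffolds (Biostrings pattern matching; both
strands are searched because miRNA genes occur on either). Each locus is
expanded by `extract_precursors()` into a window of 80 nt upstream and
downstream of the mature, clipped — never padded — at scaffold edges, with
the achieved flanks recorded. Minus-strand windows are
reverse-complemented so the mature always appears in reading orientation.
Windows shorter than the mature plus 40 nt are flagged `short` and
excluded from folding; such fragments cannot display a stem-loop and are
the expected failure mode on fragmented scaffold assemblies.

### Stem-loop screening

`fold_hairpin()` maximises a pairing-weight sum (G:C = 3, A:U = 2,
G:U = 1) over pseudoknot-free structures with a minimum hairpin loop of
3 nt, by Nussinov-style dynamic programming in compiled code. This is a
deliberate design choice: the folding step acts purely as a *topological
screen* for the canonical hairpin, so pairing topology rather than
kcal/mol accuracy is the contract, and a full thermodynamic model is out
of scope (ViennaRNA remains useful as an external cross-check, but is
never in the pipeline path). Lone pairs are allowed — a documented
limitation of the weight model. The traceback is deterministic (pairing
of the interval ends preferred over an unpaired end, preferred over a
bifurcation at the smallest split), so dot-bracket strings reproduce
exactly. Structures are written and read in the standard 6-column connect
(CT) format, and `read_ct(write_ct(x))` is an exact round trip.

One property worth recording: with G:U allowed, the optimal score is *not*
invariant under reverse complement (a G:U pair maps to A:C, which does not
pair); it is invariant under plain sequence reversal, and that is the
symmetry the property tests assert.

`classify_stem_loop()` calls a candidate a pre-miRNA stem-loop when

1. every paired mature base pairs outside the mature span (the mature
   sits on one arm and pairs into the star arm),
2. the mature does not straddle a hairpin loop of its own stem-loop
   element (bases on both sides of a terminal loop disqualify; merely
   touching the loop with a terminal base — a frequent lone-pair artifact
   of maximum pairing — does not),
3. at least 60 % of mature bases pair to the **dominant arm**, and
4. the region enclosed by the mature's innermost pair contains exactly
   one hairpin loop.

Two aspects are intentionally local. A maximum-pairing folder pairs
random flanking sequence extensively, so a rule that counted hairpin
loops over the whole connected component would reject essentially every
true hairpin embedded in 80-nt genomic flanks; conditions (2) and (4)
therefore look only at the stem-loop element the mature itself
participates in. Similarly, co-optimal structures occasionally route one
or two terminal mature bases into the flank; the dominant-arm fraction
ignores such strays, which is what a visual stem-loop screen does. The
0.60 threshold is a configurable knob (`min_paired_fraction`), not a
claim about any particular published practice.

### Target prediction

`scan_targets()` slides each miRNA over every transcript window on the
sense strand and scores the ungapped duplex in the miRU/psRNATarget
style: miRNA position *k* (from the 5' end) faces site position
*L − k + 1*; a Watson–Crick match costs 0, a G:U wobble 0.5 and a
mismatch 1.0, and penalties are doubled at the seed-proximal positions
2–13. The total is the *expectation*; hits require expectation ≤ 3.0,
the best window is kept per transcript, and at most the top 50 targets
are reported per miRNA (all three defaults match the published parameter
choices this pipeline mirrors).

`hspsize` (default 18) is interpreted as the minimum number of *paired*
(match or G:U) miRNA positions in the scored window. The alternative
reading — 18 consecutive paired positions — would make a site with a
central mismatch unreportable for a 21-nt miRNA, and central mismatches
are exactly the signature by which `classify_inhibition()` calls
translational inhibition (any mismatch at miRNA positions 9–11; a wobble
is not a mismatch) versus transcript cleavage. The chosen reading keeps
the cleavage/translation dichotomy observable at the default parameters.

### Conservation analysis and reporting

`read_evidence_table()` ingests a family × (species, condition) evidence
matrix (checkmarks transcribed to 1); `condition_families()`,
`condition_intersection()` and `conservation_histogram()` derive the
stress-responsive family sets and their cross-species support. A family
counts as responsive to a condition when at least one species carries
evidence — the only reading under which the packaged table reproduces its
published set sizes (23 salt, 24 drought, 17 shared), which the
acceptance tests pin down. `stress_gene_overlap()` intersects predicted
targets with a stress-gene list (gene ids matched case-insensitively
with version suffixes stripped) and annotates each record with the
family's salt/drought status.

`composition_report()` profiles lengths, positional base counts and
first-base bias (U and T folded into one symbol, reported as U);
`go_cluster()` clusters GO annotations of a target-gene set by the three
root namespaces, counting *gene–term matches* (not genes) and tabulating
the ten most frequent terms per namespace.

## The synthetic study

`sim_smallrna_study(seed)` draws:

* a mature reference of 12 families × 3 species (20–22 nt canonicals,
  species variants within 2 substitutions — close enough to exercise the
  strict >90 % identity filter);
* a 4-scaffold genome in which 30 of the 36 matures (every family
  represented) are planted as `mature + 8-nt loop + perfect star`,
  alternating strands, with the first precursor of every even scaffold
  placed 30 nt from the edge to exercise flank truncation;
* adaptered reads at negative-binomial depth (mean 50, dispersion 5 —
  heterogeneous abundance), 1-nt 3' jitter in 20 % of reads, substitution
  errors at 0.1 %, constant Q35, and 30 % decoys (half random 18–24-mers,
  half fragments of packaged synthetic rRNA/tRNA toys so the class
  profile is exercised);
* a transcriptome with 25 planted target sites (20 cleavage-type, 5
  translation-type) whose mismatch/wobble structure is specified
  position by position, so the scanner must recover each expectation
  exactly;
* a GO table with 40/30/30 namespace proportions and a stress-gene list.

These defaults are the study conditions for all recovery benchmarks; the
acceptance suite asserts ≥95 % mature recovery with zero hits outside the
planted families, stem-loop verdicts for all planted perfect-star
precursors, exact site expectations, and a planted cleavage fraction of
0.80.

What the generator does *not* emulate: realistic Illumina error profiles
or quality-score decay, ligation and PCR biases, isomiR 5' heterogeneity,
multi-locus miRNA families with divergent precursors, and genomes whose
background composition mimics real intergenic sequence. Passing the
recovery benchmarks therefore demonstrates the correctness of the
machinery under controlled conditions, not field performance on real
libraries.

## Numerical and engineering choices

* All randomness is seed-scoped (`withr`); identical seeds give
  byte-identical FASTQ/FASTA/TSV outputs, and `run_pipeline()` reruns
  hash-identically (the manifest intentionally carries no timestamp).
* Tie-breaks in both dynamic programs are fixed and documented (see
  above), making every downstream artifact reproducible.
* Degenerate inputs: empty read sets collapse to empty tables and flow
  through with stage warnings rather than errors; a stage with zero
  records warns and lets downstream stages run, while a *missing input
  file* fails fast with the stage name and path.
* Problem sizes in the shipped tests: folding is cross-checked against an
  exhaustive enumeration oracle on 1000 random sequences up to 14 nt, and
  the aligner against an independent Smith–Waterman implementation on 500
  random pairs up to 12 nt plus a fully exhaustive path-enumeration
  oracle on pairs up to 7 nt; the end-to-end study uses 30 planted
  matures and ~2300 reads. These sizes were chosen to exercise every code
  path at interactive runtimes.

## Known limitations

* The folding model is a pairing-weight screen; it reports no free
  energies and will overpair random flanks (mitigated, by design, in the
  stem-loop classifier rather than the folder).
* Target scoring is ungapped; bulged duplexes are not representable, and
  no accessibility/UPE term is computed.
* The homology search is exhaustive Smith–Waterman over all read ×
  reference pairs — transparent and adequate at package scale, but not a
  drop-in replacement for an indexed search at tens of millions of reads.
* GO clustering assumes a pre-digested annotation table and performs no
  DAG propagation or enrichment testing.
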