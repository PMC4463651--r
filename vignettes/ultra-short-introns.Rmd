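---
title: "Detecting and validating ultra-short pre-mRNA introns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and validating ultra-short pre-mRNA introns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(usintrons)
```

## The problem

Human intron lengths are bimodal: a narrow mode of short introns peaking
near 85 nt and a broad mode of long introns near 2 kb. Below about 65 nt
two populations mix: a small set of genuine, evolutionarily conserved
**ultra-short introns** (<= 65 nt) and a larger set of **false introns** —
artifactual gaps produced when automated annotation pipelines over-fit
transcript-to-genome alignments to the GT–AG rule. The false population
betrays itself in the ratio of non-GT–AG to GT–AG introns, which is high
below the threshold and collapses above it.

Genuine ultra-short introns matter because they sit at or below the
physical footprint of the spliceosomal A complex (which occupies roughly
79–125 nt of RNA), so their splicing cannot proceed by the textbook
mechanism without steric conflict. Establishing that specific ultra-short
introns are real and spliced therefore requires an evidence chain:
length-distribution thresholding, cross-species conservation, direct
splice-junction read support, and the functional argument that retention
would destroy the host protein (frameshift and/or nonsense-mediated decay).
This package implements that chain as testable components plus a seeded
synthetic-data generator that produces every input with known ground
truth.

## Pipeline overview

1. **Intron extraction** (`read_genome()`, `read_annotation()`,
   `extract_introns()`): introns are the gaps between consecutive exons,
   reported on the transcript strand with 1-based ordinals in
   transcription order. Coordinates are 0-based half-open internally;
   GFF3 is converted on read, BED12 is native. Region calls (`CDS`,
   `UTR5`, `UTR3`) follow the CDS interval; a gap abutting a CDS boundary
   counts as CDS when an adjacent exonic base is coding, because the
   retained intron would interrupt codons. `N` at a terminal dinucleotide
   makes an intron noncanonical — the conservative reading under
   ambiguity.

2. **Length distribution** (`build_histogram()`, `ratio_curve()`,
   `detect_threshold()`, `classify_length()`): counts per length for
   canonical (GT–AG) versus noncanonical introns up to 949 nt (the
   conventional plotting domain for the short mode), the per-length
   noncanonical/canonical ratio (masked, never infinite, where the
   denominator is zero), and a changepoint detector for the ultra-short
   threshold. Lengths <= 65 are `ultra_short`, 66–85 `short`.

3. **Conservation screen** (`filter_hits()`, `intersect_searches()`,
   `select_ultra_short()`): tabular local-alignment hits from two
   searches — concatenated flanking exons against a transcriptome, and
   intron-plus-flanks against genomes — are filtered at alignment length
   > 55, bit score > 99, E-value <= 1e-19, identity >= 96% (the printed
   comparison directions are honored exactly: the first two exclusive,
   the last two inclusive), and intersected: an intron is conserved only
   if the same (transcript, intron, species) triple survives in both
   searches. Candidates from partial transcripts (no annotated UTR) are
   dropped — an apparent intron in a truncated transcript may be a
   truncation artifact. A `mapping_error_filter()` discards transcripts
   whose best self-species hit aligns with indels, the operational
   meaning of "erroneously mapped with insertion/deletion"; no numeric
   rule beyond gap presence is defined, so gap presence in the best hit
   is used.

4. **Junction evidence** (`build_junction_index()`, `match_reads()`):
   exon-only fragments across each junction (flank `F` per side,
   truncated when an exon is shorter) are matched against short reads.
   A read supports a junction only if it (or its reverse complement)
   aligns ungapped with at most `max_mismatches` substitutions and covers
   at least `min_anchor` nt on **both** sides of the breakpoint — an
   unspliced genomic read can never do this. Defaults: `F = read_length -
   min_anchor`, `min_anchor = 8`, `max_mismatches = 1`, and one read
   suffices for a spliced call (`min_reads = 1`); matching is ungapped
   because the fragments are short. Junctions spliced in all samples are
   `ubiquitous`, in some `tissue_specific`, otherwise `none`.

5. **Retention consequences** (`retention_report()`, `nmd_classify()`):
   for each intron the retained mRNA is built (all other introns
   spliced), the frame effect classified (UTR introns cannot shift
   frame; CDS introns preserve frame iff length is a multiple of three),
   and the first in-frame stop that is not the annotated native stop is
   the PTC. The CDS convention here includes the stop codon, so the
   native stop occupies the last three CDS bases. An mRNA is an NMD
   target iff a PTC lies more than `boundary` nt upstream of the 3'-most
   remaining exon–exon junction; the conventional rule spans 50–55 nt,
   the default is the permissive 50 and `boundary` is constrained to
   [50, 55] (monotone: a target at 55 is a target at 50). A retention
   with no PTC returns a clean "not a target", not an error.

6. **Splice signals** (`train_pwm()`, `ss_score()`,
   `u1_duplex_energy()`, `find_branch_sites()`, `percentile_score()`,
   `flag_inefficient()`): position-weight matrices are trained on site
   collections (>= 20 aligned sites, pseudocount so every entry is
   positive); the percent score rescales the summed column frequencies
   between the worst and best possible sums, so the consensus scores 100
   and the anti-consensus 0, with `N` contributing the column minimum.
   Donor strength is additionally summarized as the free energy of the
   donor:U1 snRNA duplex. Branch sites match the human consensus
   (C/T)T N A(C/T) within the last 40 nt of the intron excluding the
   final 3 nt (the acceptor AG itself is not a branch candidate; no
   published window exists, so this convention is exposed as arguments).
   Raw scores become mid-rank percentiles against reference collections,
   and a donor or acceptor is flagged inefficient only when *every*
   percentile in its pair is below 0.1 or NA. Windows default to 9 nt
   donors (3 exonic + 6 intronic) and 16 nt acceptors (14 intronic + 2
   exonic), configurable at training time.

7. **Sequence features** (`base_composition()`, `find_g_runs()`,
   `ise_scan()`, `gcontent_by_class()`): exact base composition with all
   tied maxima reported and `N` tallied separately; maximal G-runs of
   length >= 3 (G-triplets or longer, reported once at full extent);
   scanning for the 11-nt G-rich intronic splicing enhancer
   `CAGGGGCTGGG` at Levenshtein distance <= 2 ("highly homologous" has
   no published cutoff; two edits preserves both G-triplets in most
   cases); and mean G fraction per length class (mean, not median, is
   used; the choice is ours).

8. **Evidence integration** (`evidence_table1()`, `confirm_evidence()`,
   `summarize_evidence()`): the packaged 22-row evidence matrix for the
   conserved human ultra-short introns (SN1–SN22) with three
   confirmation channels — RT–PCR of the endogenous transcript,
   mRNA-Seq junction evidence, and individually sequenced archive
   records. `RM` (record removed) and `UC` (unclear) are explicit states
   that never count as positive; an intron is confirmed when at least
   one channel is positive. The 100%-splice-frequency tally counts only
   introns with multiple aligned transcripts: a 1/1 frequency carries no
   information about constitutive splicing. The >= 75% bucket includes an
   exact 75% (6/8) record by design.

## The threshold detector

The visible signature of the threshold is that the
noncanonical/canonical ratio "drops markedly" at 65 nt. The obvious
estimator — the difference of windowed means of the per-length ratio —
was implemented first and measured on the cohorts used for acceptance
(200 genes, 50 seeded replicates) — and proved unreliable. The reason
is structural, not a tuning issue: below the threshold canonical introns
are rare (0–2 per length at this cohort size), so per-length ratios are
dominated by single-count noise, and window-aggregated ratios explode
wherever the canonical denominator vanishes. Bounded-fraction variants
inherit a systematic low bias because the canonical density rises with
length.

The detector shipped instead works on the quantity that actually steps
at the threshold: the **noncanonical count rate**, which is roughly flat
below the contamination edge and near zero above it. `detect_threshold()`
maximizes the two-segment profile Poisson log-likelihood of the
noncanonical counts (one rate on `1..T`, another on `T+1..max_length`)
over the search range (default 40–120 nt). Its argmax is exactly
invariant under uniform scaling of the counts, ties break toward the
smaller `T` (a changeless curve returns the lower end of the range, the
documented degenerate result), and the acceptance suite verifies that it
recovers the planted 65 nt within 2 nt in at least 95% of 50 seeded
replicates at the default generator settings. The ratio curve itself remains available for
reporting and plotting (`ratio_curve()`, `plot_length_distribution()`).

## The synthetic-data generator

`sim_config()` fixes the study conditions; `make_genome()`,
`make_transcripts()`, `make_reads()` and `make_hit_tables()` derive
their RNG streams from one root seed (offsets 0–3), so each generator is
reproducible in isolation and `simulate_all()` is byte-identical under a
fixed seed.

* **Intron lengths**: a log-normal mixture with a short mode at median
  85 nt (sdlog 0.25) and a long mode at median 2000 nt (sdlog 0.5),
  weight 0.6 on the short mode — the shape of the real bimodal
  distribution. Genes carry 4–10 background introns (human genes average
  about eight).
* **False introns**: with probability 0.15 a background slot becomes a
  non-GT–AG decoy with length uniform on 20–65 nt — contamination exists
  only below the planted threshold, which is what the detector must find.
* **Planted ultra-short introns**: ten canonical introns at lengths
  37–65 nt (mirroring the validated lengths) distributed across genes,
  G-biased at fraction 0.40 versus 0.25 for longer introns (the
  G-content gradient), and carrying an embedded `CAGGGGCTGGG` at rate
  0.25.
* **Orthologs**: each intron's two query types are diverged per species
  at 97% identity for planted introns and 85% for background ones.
  Substitutions are placed at evenly spaced, jittered positions,
  emulating steady divergence; with i.i.d. placement the identity of the
  *optimal local alignment* of a diverged pair fluctuates around the
  nominal value, which would make planted-identity recovery a matter of
  placement luck rather than a generator property. Only introns up to
  120 nt receive hits — the screen targets short-intron candidates, and
  orthologs of multi-kb introns are irrelevant to it.
* **Isoforms and reads**: each isoform retains or splices every intron
  independently at its splice frequency (default 0.9); reads of 50 nt at
  coverage 20 with substitution rate 0.005 start uniformly and carry
  their origin (isoform, position) in the read id.

What the generator does **not** emulate: real human sequence content
(composition beyond G-bias, repeats, paralogy), alignment gaps in
orthologs, indel sequencing errors, coverage biases, U12-type introns,
and any RT–PCR chemistry (its outcome enters only as an evidence flag).
Passing the planted-recovery tests therefore demonstrates that the
screen's logic is correct under its stated assumptions, not that its
thresholds are optimal for real archives.

## Numerical choices and conventions

* **Alignment statistics**: `local_align()` delegates the optimal local
  alignment to `Biostrings::pairwiseAlignment` and computes bit score
  `(lambda*S - ln K)/ln 2` and E-value `m*n*2^-bitscore` with the
  published ungapped DNA Karlin–Altschul constants for +1/−2 scoring
  (lambda = 1.28, K = 0.46). These E-values gate a filter at desk scale;
  they are a documented approximation, configurable, and no acceptance
  value depends on their absolute scale.
* **U1 duplex energy**: nearest-neighbour Watson–Crick stack free
  energies (kcal/mol, 37 °C) from the standard RNA set; any stack
  containing a G·U wobble receives a single flat −0.5 kcal/mol.
  Mismatches form no pair and contribute nothing. The absolute scale is
  a simplification; the package asserts only orderings (the consensus
  donor `CAGGTAAGT` is the unique minimum over all 4^9 donors —
  verified by enumeration in the tests — and every single mutant is
  strictly weaker).
* **Percentiles**: mid-rank convention, reported as fractions in [0, 1];
  the inefficiency cutoff "< 0.1" is applied to those fractions.
* **Minus-strand conventions**: intron numbers count from the
  transcript's 5' end on either strand (how the upstream annotation
  numbered minus-strand introns is not documented; transcription order
  is assumed), and strand symmetry is enforced by a property test.
* **Degenerate inputs**: single-exon transcripts yield no introns;
  zero-canonical lengths are masked in the ratio, not imputed;
  `aligned_hits = 0` makes the splice frequency NA with a warning;
  junctions with a zero-length flanking exon are skipped with a warning.

## Problem sizes

The test-suite defaults are chosen for a single CPU: threshold-recovery
cohorts use 200 genes x 50 seeds (length sampling only, no sequence
assembly); the end-to-end planted-recovery test runs the full
genome/hit-table/screen chain at 20 genes x 20 seeds; the U1 enumeration
covers all 262,144 donor 9-mers once. The evidence-matrix and
retention-fact computations are instantaneous (22 rows).

## Known limitations

* The conservation screen consumes hit tables; it does not wrap a real
  BLAST, and the desk-scale `local_align()` stands in only so the screen
  is testable end to end.
* The junction matcher is ungapped and single-junction; it is not a
  spliced-read aligner.
* Splice-site strength uses trained PWMs, duplex energies and branch
  consensus matches; published maximum-entropy or comparative scoring
  models are out of scope, so absolute score values are not comparable
  to tools built on them — the decision rule (percentile pairs, all-weak
  flag) is preserved instead.
* Genome-scale candidate counts from any particular annotation release
  are version-dependent and are not reproduced; the evidence matrix for
  the 22 conserved ultra-short introns and the retention facts are
  packaged as fixtures instead.
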