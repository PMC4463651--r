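# usintrons

Detection and validation of evolutionarily conserved **ultra-short
pre-mRNA introns** (≤ 65 nt) — an R package for transcriptomics.

## The problem

Human intron lengths are bimodal: a narrow mode of short introns peaking
near 85 nt and a broad mode near 2 kb. Below ~65 nt, annotated "introns"
are a mixture of rare genuine ultra-short introns and artifactual gaps
produced when transcript-to-genome alignment over-fits the GT–AG rule.
Genuine ultra-short introns are mechanistically puzzling — they are
shorter than the footprint of the spliceosomal A complex — so claiming
one is real requires an evidence chain. This package implements that
chain end to end:

1. **Intron extraction** from genome FASTA + GFF3/BED12 annotation, with
   GT–AG classification and CDS/UTR region calls;
2. **Length-distribution analysis**: per-length canonical vs noncanonical
   counts, the noncanonical/canonical ratio curve, and a changepoint
   detector for the ultra-short threshold (a two-segment Poisson
   likelihood on the noncanonical counts, which step at the
   contamination edge);
3. **Conservation screen** over BLAST-style tabular hits from two
   searches (flanking exons vs transcriptome; intron + flanks vs
   genome), filtered at alignment length > 55, bit score > 99, E-value
   ≤ 1e-19, identity ≥ 96%, and intersected on (transcript, intron,
   species);
4. **Splice-junction read evidence**: exon-only junction fragments and an
   anchored, ungapped read matcher (a read must span the breakpoint with
   ≥ 8 nt on both sides);
5. **Retention consequences**: reading-frame effect, premature
   termination codon (PTC) scan, and the NMD junction-distance rule
   (PTC > 50–55 nt upstream of the 3'-most exon–exon junction);
6. **Splice-signal scoring**: Shapiro–Senapathy-style PWM percent scores,
   donor:U1 snRNA duplex free energy, branch-site consensus
   (C/T)TNA(C/T) search, mid-rank percentiles against reference site
   sets, and the "all values < 0.1 or NA" inefficiency flag;
7. **Sequence features**: base composition, maximal G-runs, and
   edit-distance scanning for the 11-nt G-rich intronic splicing
   enhancer `CAGGGGCTGGG`;
8. **Evidence integration**: a packaged 22-row evidence matrix for the
   conserved human ultra-short introns (SN1–SN22) and the
   at-least-one-positive-channel confirmation rule;
9. A **seeded synthetic-data generator** producing genomes with planted
   ultra-short introns and false-intron decoys, isoforms, reads and
   ortholog hit tables, with full ground truth.

See the methods vignette (`vignettes/ultra-short-introns.Rmd`) for the
models, conventions and design decisions.

## Worked example

Evidence integration over the packaged matrix of the 22 conserved
ultra-short introns:

```r
library(usintrons)
summarize_evidence(evidence_table1())
#> confirmation_report: 22 candidate introns
#>   confirmed (>=1 positive channel): 15
#>   RT-PCR spliced: 9 | mRNA-Seq junction evidence: 12 | individually sequenced: 8
#>   site: 20 CDS / 2 UTR; 17 host proteins in categories I/II
#>   splice frequency among multi-transcript introns: 4 at 100%, 3 at >=75%
```

Fifteen of the 22 candidates are confirmed by at least one of the three
channels; retention analysis over the per-intron facts classifies 15 as
possible NMD targets:

```r
facts <- load_nmd_facts()
sum(nmd_from_facts(facts, boundary = 50)$nmd_target)
#> [1] 15
```

Threshold detection and the full discovery chain on synthetic data with
a planted 65-nt threshold and ten planted conserved ultra-short introns:

```r
cfg <- sim_config(seed = 7)
coh <- sample_intron_cohort(sim_config(seed = 7, n_genes = 200))
detect_threshold(build_histogram(coh))
#> [1] 65

sim <- make_genome(cfg)
ht  <- make_hit_tables(sim)
res <- discover_ultra_short(sim$models, sim$genome, ht$tx_hits, ht$gn_hits)
res$selected[, c("transcript_id", "intron_number", "length", "region")]
#>    transcript_id intron_number length region
#> 1          TX001             6     37    CDS
#> 2          TX002             5     43    CDS
#> ...
#> 10         TX010             3     65    CDS
```

All ten planted introns are recovered; none of the planted non-GT–AG
decoys survive (they are eliminated by the GT–AG rule before the
conservation screen).

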