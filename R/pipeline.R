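# End-to-end discovery pipeline: extract introns, apply the GT-AG rule,
# screen both hit tables, intersect, and select conserved ultra-short
# introns from complete transcripts.

#' Discover conserved ultra-short introns
#'
#' Chains the discovery stages: [extract_introns()] over all models,
#' elimination of non-GT-AG introns ([classify_termini()]),
#' [filter_hits()] on the transcriptome- and genome-search hit tables,
#' [intersect_searches()], and [select_ultra_short()].
#'
#' @param models named list of [transcript_model] objects.
#' @param genome genome [Biostrings::DNAStringSet].
#' @param tx_hits,gn_hits hit data.frames (see [read_hits()]).
#' @param threshold ultra-short upper bound (nt), default 65.
#' @param thresholds a [screen_thresholds()] object.
#' @return list with `introns` (all extracted), `canonical` (GT-AG
#'   subset), `conserved_keys`, and `selected` (the conserved
#'   ultra-short introns from complete transcripts).
#' @export
discover_ultra_short <- function(models, genome, tx_hits, gn_hits,
                                 threshold = 65,
                                 thresholds = screen_thresholds()) {
  introns <- extract_introns(models, genome)
  canonical <- introns[classify_termini(introns) == "canonical", ,
                       drop = FALSE]
  ck <- intron_key(canonical$transcript_id, canonical$intron_number)
  keep_canonical <- function(h) {
    h[intron_key(h$transcript_id, h$intron_number) %in% ck, , drop = FALSE]
  }
  tx_f <- filter_hits(keep_canonical(tx_hits), thresholds)
  gn_f <- filter_hits(keep_canonical(gn_hits), thresholds)
  conserved <- intersect_searches(tx_f, gn_f)
  selected <- select_ultra_short(conserved, canonical, models, threshold)
  list(introns = introns, canonical = canonical,
       conserved_keys = conserved, selected = selected)
}
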