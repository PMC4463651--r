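# evidence_integration: the per-intron evidence matrix for the conserved
# ultra-short introns and its summary report. Evidence channels: RT-PCR
# of the endogenous transcript (Spliced / Expressed / No-Exp / No-PCR /
# n/a), splice-junction support in mRNA-Seq (Yes/No), and individually
# sequenced transcripts in the nucleotide archives (Yes / No / RM
# [record removed] / UC [unclear description]). An intron is confirmed
# when at least one of the three channels is positive.

RTPCR_LEVELS <- c("Spliced", "Expressed", "No-Exp", "No-PCR", "n/a")
INDIV_LEVELS <- c("Yes", "No", "RM", "UC")

#' Read and validate an evidence matrix
#'
#' The TSV carries one row per candidate intron with columns `sn`
#' (serial), `length`, `transcript_id`, `intron_number`, `total_introns`,
#' `region` (`CDS`/`UTR5`), `in_second_db` (presence in a second
#' transcript database), `protein_category` (I-VII), `spliced_hits`,
#' `aligned_hits`, `rtpcr`, `rnaseq`, `indiv_seq`, and optionally
#' `gene`. Invariants checked: unique serials, `spliced_hits <=
#' aligned_hits`, `intron_number <= total_introns`, valid channel levels.
#'
#' @param path path to the TSV.
#' @return validated data.frame of evidence records.
#' @export
read_evidence <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   check.names = FALSE, na.strings = NULL)
  need <- c("sn", "length", "transcript_id", "intron_number",
            "total_introns", "region", "in_second_db", "protein_category",
            "spliced_hits", "aligned_hits", "rtpcr", "rnaseq", "indiv_seq")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("evidence matrix missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sn)) stop("duplicate serial numbers in evidence matrix")
  stopifnot(
    all(df$spliced_hits >= 0), all(df$spliced_hits <= df$aligned_hits),
    all(df$intron_number <= df$total_introns),
    all(df$region %in% c("CDS", "UTR5", "UTR3")),
    all(df$rtpcr %in% RTPCR_LEVELS),
    all(df$rnaseq %in% c("Yes", "No")),
    all(df$indiv_seq %in% INDIV_LEVELS),
    all(df$protein_category %in% c("I", "II", "III", "IV", "V", "VI", "VII"))
  )
  df
}

#' The packaged evidence matrix for the 22 conserved ultra-short introns
#'
#' Loads the curated 22-row evidence matrix for the conserved human
#' ultra-short introns (serials SN1-SN22): lengths 37-65 nt, host
#' transcript/locus ids, CDS/UTR site, protein similarity category,
#' per-intron splice frequency (spliced/aligned transcript counts), and
#' the three confirmation channels.
#'
#' @return validated data.frame of 22 evidence records.
#' @export
evidence_table1 <- function() {
  read_evidence(system.file("extdata", "ultra_short_evidence.tsv",
                            package = "usintrons", mustWork = TRUE))
}

#' Per-intron splice frequency
#'
#' The fraction of aligned transcripts that are spliced at the intron:
#' `spliced_hits / aligned_hits`. Undefined (`NA`, with a warning) when
#' no transcript aligns.
#'
#' @param spliced_hits,aligned_hits non-negative integer vectors.
#' @return numeric vector of fractions.
#' @export
intron_frequency <- function(spliced_hits, aligned_hits) {
  stopifnot(all(spliced_hits >= 0), all(aligned_hits >= 0),
            all(spliced_hits <= aligned_hits | aligned_hits == 0))
  if (any(aligned_hits == 0)) {
    warning("aligned_hits = 0: frequency undefined, reported as NA")
  }
  ifelse(aligned_hits == 0, NA_real_, spliced_hits / aligned_hits)
}

#' Confirmation call from the three evidence channels
#'
#' An intron is confirmed iff RT-PCR observed splicing (`Spliced`), OR
#' mRNA-Seq junction evidence is positive (`Yes`), OR an individually
#' sequenced transcript exists (`Yes`). `RM` (removed record) and `UC`
#' (unclear) are explicit states that do NOT count as positive, nor do
#' `Expressed`/`No-Exp`/`No-PCR`/`n/a` on the RT-PCR channel. Monotone:
#' upgrading any channel to positive never withdraws a confirmation.
#'
#' @param records evidence data.frame (see [read_evidence()]).
#' @return logical vector, one per record.
#' @export
confirm_evidence <- function(records) {
  records$rtpcr == "Spliced" | records$rnaseq == "Yes" |
    records$indiv_seq == "Yes"
}

#' Summarize an evidence matrix
#'
#' Direct tabulation of the confirmation rule and the headline counts.
#' `n_freq_100pct` counts introns spliced in 100% of aligned transcripts
#' among introns with multiple aligned transcripts (`aligned_hits >= 2`):
#' with a single aligned transcript a 1/1 frequency carries no
#' information about constitutive splicing, so singletons are excluded
#' from that bucket. `n_freq_ge75pct` is the analogous >=75% bucket
#' (excluding the 100% ones).
#'
#' @param records evidence data.frame (see [read_evidence()]).
#' @return an object of class `confirmation_report`: list with
#'   `records` (the input plus `frequency` and `confirmed` columns) and
#'   `counts` (named integer vector: `n_records`, `n_confirmed`,
#'   `n_rtpcr_spliced`, `n_rnaseq_yes`, `n_indiv_yes`, `n_cds`, `n_utr`,
#'   `n_cat_I_II`, `n_freq_100pct`, `n_freq_ge75pct`).
#' @export
summarize_evidence <- function(records) {
  if (anyDuplicated(records$sn)) stop("duplicate serial numbers")
  records$frequency <- intron_frequency(records$spliced_hits,
                                        records$aligned_hits)
  records$confirmed <- confirm_evidence(records)
  multi <- records$aligned_hits >= 2
  counts <- c(
    n_records = nrow(records),
    n_confirmed = sum(records$confirmed),
    n_rtpcr_spliced = sum(records$rtpcr == "Spliced"),
    n_rnaseq_yes = sum(records$rnaseq == "Yes"),
    n_indiv_yes = sum(records$indiv_seq == "Yes"),
    n_cds = sum(records$region == "CDS"),
    n_utr = sum(records$region %in% c("UTR5", "UTR3")),
    n_cat_I_II = sum(records$protein_category %in% c("I", "II")),
    n_freq_100pct = sum(multi & records$frequency == 1, na.rm = TRUE),
    n_freq_ge75pct = sum(multi & records$frequency >= 0.75 &
                           records$frequency < 1, na.rm = TRUE)
  )
  structure(list(records = records, counts = counts),
            class = "confirmation_report")
}

#' @export
print.confirmation_report <- function(x, ...) {
  c_ <- x$counts
  cat("confirmation_report:", c_["n_records"], "candidate introns\n")
  cat("  confirmed (>=1 positive channel):", c_["n_confirmed"], "\n")
  cat("  RT-PCR spliced:", c_["n_rtpcr_spliced"],
      "| mRNA-Seq junction evidence:", c_["n_rnaseq_yes"],
      "| individually sequenced:", c_["n_indiv_yes"], "\n")
  cat("  site: ", c_["n_cds"], " CDS / ", c_["n_utr"], " UTR; ",
      c_["n_cat_I_II"], " host proteins in categories I/II\n", sep = "")
  cat("  splice frequency among multi-transcript introns: ",
      c_["n_freq_100pct"], " at 100%, ", c_["n_freq_ge75pct"],
      " at >=75%\n", sep = "")
  invisible(x)
}

#' Write a confirmation report
#'
#' Writes the per-record table (TSV) and the summary counts (TSV) into a
#' directory.
#'
#' @param report a `confirmation_report` from [summarize_evidence()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_confirmation_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(report$records, file.path(dir, "evidence_records.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(count = names(report$counts),
                         value = as.integer(report$counts)),
              file.path(dir, "evidence_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
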