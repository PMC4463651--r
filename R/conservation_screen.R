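# conservation_screen: filtering of tabular local-alignment hits, the
# mapping-error pre-filter, intersection of the transcriptome- and
# genome-targeted searches, and final ultra-short candidate selection.
#
# Hit tables are BLAST outfmt-6-like TSVs with an appended species column:
# qseqid (transcript|intronN), sseqid, species, length, bitscore, evalue,
# pident, gaps.

#' Conservation screen thresholds
#'
#' The published screen keeps a hit when alignment length > 55 (exclusive),
#' bit score > 99 (exclusive), E-value <= 1e-19 (inclusive) and identity
#' >= 96% (inclusive). The printed comparison directions are honored
#' exactly; all four are configurable.
#'
#' @param min_aln_length_exclusive alignment length must exceed this (nt).
#' @param min_bit_score_exclusive bit score must exceed this (bits).
#' @param max_e_value_inclusive E-value at most this.
#' @param min_identity_inclusive percent identity at least this.
#' @return an object of class `screen_thresholds`.
#' @export
screen_thresholds <- function(min_aln_length_exclusive = 55,
                              min_bit_score_exclusive = 99,
                              max_e_value_inclusive = 1e-19,
                              min_identity_inclusive = 96) {
  stopifnot(min_aln_length_exclusive > 0, min_bit_score_exclusive > 0,
            max_e_value_inclusive > 0, min_identity_inclusive > 0)
  structure(list(min_aln_length_exclusive = min_aln_length_exclusive,
                 min_bit_score_exclusive = min_bit_score_exclusive,
                 max_e_value_inclusive = max_e_value_inclusive,
                 min_identity_inclusive = min_identity_inclusive),
            class = "screen_thresholds")
}

#' Read an alignment hit table
#'
#' Reads a tab-separated hit table in the outfmt-6 dialect used throughout
#' the package: columns `qseqid` (format `transcript|intronN`), `sseqid`,
#' `species`, `length`, `bitscore`, `evalue`, `pident`, `gaps`, with a
#' header line. Species names are trimmed and lower-cased on read so later
#' comparisons are deterministic.
#'
#' @param path path to the TSV.
#' @return a data.frame of hits with `transcript_id` and `intron_number`
#'   split out of `qseqid`.
#' @export
read_hits <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("qseqid", "sseqid", "species", "length", "bitscore",
            "evalue", "pident", "gaps")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("hit table missing column(s): ",
                         paste(miss, collapse = ", "))
  key <- split_intron_key(df$qseqid)
  df$transcript_id <- key$transcript_id
  df$intron_number <- key$intron_number
  df$species <- tolower(trimws(df$species))
  validate_hits(df)
  df
}

validate_hits <- function(hits) {
  stopifnot(all(hits$length >= 1), all(hits$evalue >= 0),
            all(hits$pident >= 0 & hits$pident <= 100))
  invisible(hits)
}

#' Mapping-error pre-filter
#'
#' Transcripts whose exons were erroneously mapped to the genome with
#' insertions/deletions (over-fitting to the GT-AG rule during automated
#' annotation) betray themselves in an exon-query-vs-transcriptome search:
#' the best same-species hit aligns with gaps. A transcript is discarded
#' when its best self-species hit (lowest E-value; ties by higher bit
#' score) has `gaps > 0`.
#'
#' @param hits exon-vs-transcriptome hit data.frame (see [read_hits()]).
#' @param self_species species name of the query organism.
#' @return character vector of transcript_ids to discard.
#' @export
mapping_error_filter <- function(hits, self_species = "homo_sapiens") {
  self_species <- tolower(trimws(self_species))
  self <- hits[hits$species == self_species, , drop = FALSE]
  if (nrow(self) == 0L) return(character())
  discard <- vapply(split(self, self$transcript_id), function(h) {
    best <- h[order(h$evalue, -h$bitscore), , drop = FALSE][1L, ]
    best$gaps > 0
  }, logical(1))
  names(discard)[discard]
}

#' Filter hits under the screen thresholds
#'
#' Retains exactly the hits with `length > min_aln_length_exclusive`,
#' `bitscore > min_bit_score_exclusive`, `evalue <= max_e_value_inclusive`
#' and `pident >= min_identity_inclusive`. Idempotent, and monotone in
#' every threshold.
#'
#' @param hits hit data.frame (see [read_hits()]).
#' @param thresholds a [screen_thresholds()] object.
#' @return the surviving subset of `hits`.
#' @export
filter_hits <- function(hits, thresholds = screen_thresholds()) {
  stopifnot(inherits(thresholds, "screen_thresholds"))
  keep <- hits$length > thresholds$min_aln_length_exclusive &
    hits$bitscore > thresholds$min_bit_score_exclusive &
    hits$evalue <= thresholds$max_e_value_inclusive &
    hits$pident >= thresholds$min_identity_inclusive
  hits[keep, , drop = FALSE]
}

#' Intersect the transcriptome- and genome-targeted searches
#'
#' An intron is conserved when at least one species has a surviving hit
#' for that (transcript, intron number) key in BOTH searches. Symmetric in
#' its two arguments.
#'
#' @param transcriptome_hits,genome_hits already-filtered hit data.frames.
#' @return data.frame of conserved keys (`transcript_id`,
#'   `intron_number`).
#' @export
intersect_searches <- function(transcriptome_hits, genome_hits) {
  trip <- function(h) {
    unique(paste(h$transcript_id, h$intron_number, h$species, sep = "\r"))
  }
  shared <- intersect(trip(transcriptome_hits), trip(genome_hits))
  if (length(shared) == 0L) {
    return(data.frame(transcript_id = character(),
                      intron_number = integer()))
  }
  parts <- do.call(rbind, strsplit(shared, "\r", fixed = TRUE))
  out <- unique(data.frame(transcript_id = parts[, 1],
                           intron_number = as.integer(parts[, 2]),
                           stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out[order(out$transcript_id, out$intron_number), , drop = FALSE]
}

#' Smith-Waterman local alignment with BLAST-style statistics
#'
#' Optimal local alignment (via [Biostrings::pairwiseAlignment]) with a
#' simple match/mismatch score and affine gaps, summarized the way a
#' tabular BLAST hit is: `bitscore = (lambda * S - ln K) / ln 2` and
#' `evalue = m * n * 2^-bitscore`, identity over aligned columns, and the
#' number of gap columns. The default Karlin-Altschul constants are the
#' published ungapped DNA values for +1/-2 scoring; they gate a filter
#' here, not a database search, and are configurable.
#'
#' If no alignment of positive score exists the hit is empty: length 0,
#' bit score 0, identity 0, `evalue = m * n`.
#'
#' @param query,subject DNA sequences (character scalars over A/C/G/T/N).
#' @param match,mismatch match reward and mismatch penalty.
#' @param gap_open,gap_extend non-negative affine gap penalties.
#' @param lambda,K Karlin-Altschul parameters.
#' @param qseqid,sseqid,species optional identifiers copied into the hit.
#' @return a one-row data.frame: `qseqid`, `sseqid`, `species`, `length`,
#'   `bitscore`, `evalue`, `pident`, `gaps`, `score`.
#' @export
local_align <- function(query, subject, match = 1, mismatch = -2,
                        gap_open = 5, gap_extend = 2,
                        lambda = 1.28, K = 0.46,
                        qseqid = "query", sseqid = "subject",
                        species = "unknown") {
  stopifnot(nzchar(query), nzchar(subject))
  m <- nchar(query); n <- nchar(subject)
  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE
  )
  pa <- Biostrings::pairwiseAlignment(
    pattern = query, subject = subject, type = "local",
    substitutionMatrix = sub_mat,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  s <- Biostrings::score(pa)
  if (s <= 0) {
    bit <- 0
    return(data.frame(qseqid = qseqid, sseqid = sseqid, species = species,
                      length = 0L, bitscore = 0, evalue = m * n,
                      pident = 0, gaps = 0L, score = 0,
                      stringsAsFactors = FALSE))
  }
  ind <- Biostrings::nindel(pa)
  gap_cols <- sum(ind@insertion[, "WidthSum"]) + sum(ind@deletion[, "WidthSum"])
  # aligned columns incl. gap columns
  aln_len <- Biostrings::nmatch(pa) + Biostrings::nmismatch(pa) + gap_cols
  ident <- 100 * Biostrings::nmatch(pa) / aln_len
  bit <- (lambda * s - log(K)) / log(2)
  data.frame(qseqid = qseqid, sseqid = sseqid, species = species,
             length = aln_len, bitscore = bit,
             evalue = m * n * 2^(-bit),
             pident = ident, gaps = as.integer(gap_cols), score = s,
             stringsAsFactors = FALSE)
}

#' Select conserved ultra-short introns
#'
#' Keeps conserved introns of length <= `threshold` whose host transcript
#' is complete (not flagged partial: a conserved "intron" inside a partial
#' transcript lacking a UTR may simply be a truncation artifact).
#'
#' @param conserved_keys data.frame from [intersect_searches()].
#' @param introns intron data.frame from [extract_introns()].
#' @param models named list of [transcript_model] objects.
#' @param threshold ultra-short upper bound (nt), default 65.
#' @return the selected subset of `introns`.
#' @export
select_ultra_short <- function(conserved_keys, introns, models,
                               threshold = 65) {
  if (nrow(conserved_keys) == 0L) return(introns[0L, , drop = FALSE])
  ik <- intron_key(introns$transcript_id, introns$intron_number)
  ck <- intron_key(conserved_keys$transcript_id, conserved_keys$intron_number)
  missing_keys <- setdiff(ck, ik)
  if (length(missing_keys)) {
    stop("conserved key(s) without matching intron: ",
         paste(missing_keys, collapse = ", "))
  }
  sel <- introns[ik %in% ck & introns$length <= threshold, , drop = FALSE]
  if (nrow(sel) == 0L) return(sel)
  partial <- vapply(sel$transcript_id, function(tid) {
    mod <- models[[tid]]
    if (is.null(mod)) stop("no transcript model for ", tid)
    mod$partial_flag
  }, logical(1))
  out <- sel[!partial, , drop = FALSE]
  rownames(out) <- NULL
  out
}
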