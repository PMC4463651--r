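# junction_evidence: splice-junction fragment indexes and read support.
#
# A junction fragment is exon-only sequence across a splice junction: the
# last F nt of the upstream exon concatenated with the first F nt of the
# downstream exon, in transcript orientation. A short read supports the
# junction only if it aligns (ungapped, read or its reverse complement)
# within the fragment crossing the breakpoint with at least `min_anchor`
# nt on both sides -- a genomic (unspliced) read cannot do this.

#' Build a splice-junction fragment index
#'
#' One fragment per intron. Flanks shorter than `flank` (the adjacent
#' exon runs out) are truncated and recorded; junctions with a zero-length
#' flanking exon are skipped with a warning.
#'
#' @param introns intron data.frame from [extract_introns()].
#' @param models named list of [transcript_model] objects.
#' @param genome genome [Biostrings::DNAStringSet].
#' @param flank nt of exonic sequence per side (>= 8).
#' @return data.frame with `junction_id`, `transcript_id`,
#'   `intron_number`, `sequence`, `breakpoint` (0-based offset of the
#'   junction in `sequence` = realized upstream flank), `flank_up`,
#'   `flank_down`, `truncated`.
#' @export
build_junction_index <- function(introns, models, genome, flank = 42) {
  stopifnot(flank >= 8)
  rows <- vector("list", nrow(introns))
  for (i in seq_len(nrow(introns))) {
    tid <- introns$transcript_id[i]
    num <- introns$intron_number[i]
    mod <- models[[tid]]
    if (is.null(mod)) stop("no transcript model for ", tid)
    chrom <- as.character(genome[[mod$seq_id]])
    n_ex <- nrow(mod$exons)
    # genomic index of the gap: transcription order num maps to genomic gap
    gi <- if (mod$strand == "+") num else (n_ex - num)
    up_ex <- mod$exons[gi, ]        # genomic-left exon
    dn_ex <- mod$exons[gi + 1L, ]
    left_len <- min(flank, up_ex[2] - up_ex[1])
    right_len <- min(flank, dn_ex[2] - dn_ex[1])
    if (left_len == 0L || right_len == 0L) {
      warning("zero-length flanking exon at ", intron_key(tid, num),
              "; junction skipped")
      next
    }
    left <- substr0(chrom, up_ex[2] - left_len, up_ex[2])
    right <- substr0(chrom, dn_ex[1], dn_ex[1] + right_len)
    frag <- paste0(left, right)
    if (mod$strand == "-") {
      frag <- revcomp(frag)
      bp <- right_len  # genomic-right flank becomes upstream after revcomp
      fu <- right_len; fd <- left_len
    } else {
      bp <- left_len
      fu <- left_len; fd <- right_len
    }
    rows[[i]] <- data.frame(
      junction_id = intron_key(tid, num),
      transcript_id = tid, intron_number = num,
      sequence = frag, breakpoint = bp,
      flank_up = fu, flank_down = fd,
      truncated = (fu < flank || fd < flank),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no junctions to index")
  rownames(out) <- NULL
  out
}

#' Write a junction index as FASTA
#'
#' Record ids are `transcript|intronN|flankF` with `F` the realized
#' upstream flank (= breakpoint offset).
#'
#' @param index data.frame from [build_junction_index()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_junction_index <- function(index, path) {
  seqs <- Biostrings::DNAStringSet(index$sequence)
  names(seqs) <- paste0(index$junction_id, "|flank", index$breakpoint)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

# ungapped best placement of `read` inside `frag`; returns TRUE when some
# placement has <= max_mismatches and covers >= min_anchor nt on both
# sides of breakpoint bp (0-based offset into frag).
matches_junction <- function(read, frag, bp, min_anchor, max_mismatches) {
  lr <- nchar(read); lf <- nchar(frag)
  if (lr > lf) return(FALSE)
  rv <- utf8ToInt(read)
  fv <- utf8ToInt(frag)
  for (off in 0:(lf - lr)) {
    left_cov <- bp - off            # nt of read left of breakpoint
    right_cov <- (off + lr) - bp
    if (left_cov < min_anchor || right_cov < min_anchor) next
    mm <- sum(rv != fv[(off + 1L):(off + lr)])
    if (mm <= max_mismatches) return(TRUE)
  }
  FALSE
}

#' Match short reads against a junction index
#'
#' A read supports a junction iff it (or its reverse complement) aligns
#' ungapped within the fragment with at most `max_mismatches`
#' substitutions and covers at least `min_anchor` nt on both sides of the
#' breakpoint. Counts are aggregated per junction for one sample.
#'
#' @param reads a character vector of read sequences, a
#'   [Biostrings::DNAStringSet], or a path to a FASTQ file (plain or
#'   gzipped).
#' @param index data.frame from [build_junction_index()].
#' @param sample_id sample label recorded in the output.
#' @param min_anchor minimum nt on each side of the breakpoint (>= 5).
#' @param max_mismatches maximum substitutions, default 1.
#' @param min_reads reads required to call the junction spliced, default 1.
#' @return data.frame with `junction_id`, `sample_id`, `read_count`,
#'   `spliced_call`.
#' @export
match_reads <- function(reads, index, sample_id, min_anchor = 8,
                        max_mismatches = 1, min_reads = 1) {
  stopifnot(min_anchor >= 5)
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- Biostrings::readDNAStringSet(reads, format = "fastq")
  }
  reads <- as.character(reads)
  counts <- integer(nrow(index))
  if (length(reads) > 0L) {
    reads_rc <- revcomp(reads)
    for (j in seq_len(nrow(index))) {
      frag <- index$sequence[j]
      bp <- index$breakpoint[j]
      n <- 0L
      for (k in seq_along(reads)) {
        if (matches_junction(reads[k], frag, bp, min_anchor, max_mismatches) ||
            matches_junction(reads_rc[k], frag, bp, min_anchor,
                             max_mismatches)) {
          n <- n + 1L
        }
      }
      counts[j] <- n
    }
  }
  data.frame(junction_id = index$junction_id, sample_id = sample_id,
             read_count = counts, spliced_call = counts >= min_reads,
             stringsAsFactors = FALSE)
}

#' Summarize junction support across samples
#'
#' Labels each junction `ubiquitous` (spliced call in every sample),
#' `tissue_specific` (in at least one but not all), or `none`.
#'
#' @param supports row-bound [match_reads()] results over samples.
#' @return data.frame with `junction_id`, `n_samples`, `n_spliced`,
#'   `pattern`.
#' @export
summarize_support <- function(supports) {
  out <- do.call(rbind, lapply(split(supports, supports$junction_id),
                               function(s) {
    n <- length(unique(s$sample_id))
    k <- sum(s$spliced_call)
    data.frame(
      junction_id = s$junction_id[1L], n_samples = n, n_spliced = k,
      pattern = if (k == 0L) "none" else if (k == n) "ubiquitous"
                else "tissue_specific",
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}
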