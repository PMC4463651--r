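# genome_io: genome FASTA reading, transcript models from GFF3/BED12,
# intron extraction with GT-AG classification and CDS/UTR region calls.
#
# All coordinates inside the package are 0-based half-open on the genome;
# GFF3's 1-based inclusive coordinates are converted on read, BED12 is
# native. Intron numbering follows transcription order (5'->3' of the
# mRNA) on either strand.

#' Read a genome FASTA file
#'
#' Reads a (multi-)FASTA file of genome sequences. Residues are upper-cased
#' and RNA `U` is converted to `T`; only `A`, `C`, `G`, `T`, `N` are
#' permitted.
#'
#' @param path path to a FASTA file (wrapped or unwrapped).
#' @return a named [Biostrings::DNAStringSet], one entry per record.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgtacgu"), fa)
#' read_genome(fa)
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty FASTA file: ", path)
  # FASTA ids: first whitespace-delimited token
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- chartr("u", "t", toupper(as.character(raw)))
  seqs <- chartr("U", "T", seqs)
  if (any(grepl("[^ACGTN]", seqs))) {
    bad <- ids[grepl("[^ACGTN]", seqs)]
    stop("non-nucleotide symbols in record(s): ", paste(bad, collapse = ", "))
  }
  if (any(!nzchar(seqs))) stop("empty sequence record in ", path)
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Construct a transcript model
#'
#' A transcript model holds ordered exon intervals on a genome sequence,
#' an optional CDS interval, and a strand. Exons are 0-based half-open
#' genomic intervals, sorted ascending on the genome regardless of strand.
#'
#' @param transcript_id,gene_id,seq_id character identifiers.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column matrix (start, end) of 0-based half-open
#'   intervals, ascending and non-overlapping.
#' @param cds optional length-2 numeric `c(start, end)`, 0-based half-open,
#'   contained in the union of exons.
#' @param partial_flag `TRUE` when the transcript lacks an annotated UTR
#'   (e.g. the CDS spans the full exonic extent). Defaults to that rule
#'   when a CDS is present, otherwise `FALSE`.
#' @return an object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, seq_id, strand, exons,
                             cds = NULL, partial_flag = NULL) {
  stopifnot_scalar_string(transcript_id, "transcript_id")
  stopifnot_scalar_string(seq_id, "seq_id")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  exons <- matrix(as.numeric(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) < 1L) stop("transcript ", transcript_id, " has zero exons")
  if (any(exons[, 2] <= exons[, 1])) {
    stop("transcript ", transcript_id, ": empty or inverted exon interval")
  }
  if (is.unsorted(exons[, 1], strictly = TRUE) && nrow(exons) > 1L) {
    exons <- exons[order(exons[, 1]), , drop = FALSE]
  }
  if (nrow(exons) > 1L && any(exons[-1L, 1] < exons[-nrow(exons), 2])) {
    stop("transcript ", transcript_id, ": overlapping exons")
  }
  if (!is.null(cds)) {
    cds <- as.numeric(cds)
    if (length(cds) != 2L || cds[2] <= cds[1]) {
      stop("transcript ", transcript_id, ": cds must be c(start, end)")
    }
    span <- c(exons[1L, 1], exons[nrow(exons), 2])
    if (cds[1] < span[1] || cds[2] > span[2]) {
      stop("transcript ", transcript_id, ": cds outside exonic extent")
    }
  }
  if (is.null(partial_flag)) {
    partial_flag <- !is.null(cds) &&
      cds[1] <= exons[1L, 1] && cds[2] >= exons[nrow(exons), 2]
  }
  structure(
    list(transcript_id = transcript_id, gene_id = gene_id %||% transcript_id,
         seq_id = seq_id, strand = strand, exons = exons, cds = cds,
         partial_flag = isTRUE(partial_flag)),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("transcript_model", x$transcript_id, "on", x$seq_id, x$strand,
      "with", nrow(x$exons), "exon(s)",
      if (!is.null(x$cds)) sprintf("cds [%d,%d)", x$cds[1], x$cds[2]) else "noncoding",
      if (x$partial_flag) "(partial)" else "", "\n")
  invisible(x)
}

#' Read transcript models from GFF3 or BED12
#'
#' GFF3 files must carry `mRNA`/`transcript` features with `exon` (and
#' optionally `CDS`) children linked by `Parent`. BED12 blocks become
#' exons and the thick interval becomes the CDS. A transcript is flagged
#' partial when it has a CDS but no UTR (the CDS covers the full exonic
#' extent) or when the source marks it `partial=true`.
#'
#' @param path path to a `.gff3`/`.gff` or `.bed` file.
#' @param format `"auto"` (by extension), `"gff3"` or `"bed12"`.
#' @return a named list of [transcript_model] objects.
#' @export
read_annotation <- function(path, format = c("auto", "gff3", "bed12")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed12" else "gff3"
  }
  if (format == "gff3") read_annotation_gff3(path) else read_annotation_bed12(path)
}

read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)
  tx_idx <- which(type %in% c("mRNA", "transcript"))
  if (length(tx_idx) == 0L) stop("no mRNA/transcript features in ", path)
  models <- list()
  parent_of <- function(i) {
    p <- meta$Parent[[i]]
    if (length(p) == 0L) NA_character_ else as.character(p[[1L]])
  }
  parents <- vapply(seq_along(gr), parent_of, character(1))
  for (i in tx_idx) {
    tid <- as.character(meta$ID[i])
    kids <- which(!is.na(parents) & parents == tid)
    ex <- kids[type[kids] == "exon"]
    if (length(ex) == 0L) stop("transcript ", tid, " has zero exons")
    exons <- cbind(GenomicRanges::start(gr)[ex] - 1L, GenomicRanges::end(gr)[ex])
    exons <- exons[order(exons[, 1]), , drop = FALSE]
    cds_kids <- kids[type[kids] == "CDS"]
    cds <- NULL
    if (length(cds_kids) > 0L) {
      cds <- c(min(GenomicRanges::start(gr)[cds_kids]) - 1L,
               max(GenomicRanges::end(gr)[cds_kids]))
    }
    partial <- NULL
    if (!is.null(meta$partial)) {
      p <- meta$partial[i]
      if (!is.na(p) && tolower(as.character(p)) %in% c("true", "1", "yes")) {
        partial <- TRUE
      }
    }
    models[[tid]] <- transcript_model(
      transcript_id = tid,
      gene_id = if (!is.na(parents[i])) parents[i] else tid,
      seq_id = as.character(GenomicRanges::seqnames(gr))[i],
      strand = as.character(GenomicRanges::strand(gr))[i],
      exons = exons, cds = cds, partial_flag = partial
    )
  }
  models
}

read_annotation_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  meta <- S4Vectors::mcols(gr)
  if (is.null(meta$blocks)) stop("BED file lacks block (BED12) columns: ", path)
  models <- list()
  for (i in seq_along(gr)) {
    chrom_start0 <- GenomicRanges::start(gr)[i] - 1L
    blocks <- meta$blocks[[i]]  # 1-based, relative to chromStart
    starts0 <- chrom_start0 + IRanges::start(blocks) - 1L
    exons <- cbind(starts0, starts0 + IRanges::width(blocks))
    tid <- as.character(meta$name[i] %||% paste0("tx", i))
    cds <- NULL
    if (!is.null(meta$thick)) {
      th <- meta$thick[i]
      ts0 <- IRanges::start(th) - 1L
      te0 <- IRanges::end(th)
      if (te0 > ts0) cds <- c(ts0, te0)
    }
    models[[tid]] <- transcript_model(
      transcript_id = tid, gene_id = tid,
      seq_id = as.character(GenomicRanges::seqnames(gr))[i],
      strand = as.character(GenomicRanges::strand(gr))[i],
      exons = exons, cds = cds
    )
  }
  models
}

# region of an intronic gap [gs, ge) relative to the model's CDS.
# A gap abutting the CDS boundary is CDS when any adjacent exonic base is
# coding (the retained intron would interrupt codons).
gap_region <- function(gs, ge, cds, strand) {
  if (is.null(cds)) return("noncoding")
  left_coding <- (gs - 1) >= cds[1] && (gs - 1) < cds[2]
  right_coding <- ge >= cds[1] && ge < cds[2]
  if (left_coding || right_coding) return("CDS")
  if (ge <= cds[1]) return(if (strand == "+") "UTR5" else "UTR3")
  if (gs >= cds[2]) return(if (strand == "+") "UTR3" else "UTR5")
  "CDS"
}

#' Extract introns from transcript models
#'
#' Produces one intron per gap between consecutive exons. Sequences are on
#' the transcript strand (reverse-complemented for minus-strand models) and
#' intron numbers count from the transcript's 5' end. The region call is
#' `CDS` when an exonic base adjacent to either junction is coding,
#' `UTR5`/`UTR3` by position relative to the CDS in transcript
#' orientation, and `noncoding` for models without a CDS.
#'
#' @param models a [transcript_model] or list of them.
#' @param genome a [Biostrings::DNAStringSet] as returned by
#'   [read_genome()] (or a single named sequence).
#' @return a data.frame with one row per intron: `transcript_id`,
#'   `intron_number`, `seq_id`, `strand`, `start`, `end` (0-based
#'   half-open genomic), `length`, `sequence`, `donor_dinuc`,
#'   `acceptor_dinuc`, `region`.
#' @export
extract_introns <- function(models, genome) {
  if (inherits(models, "transcript_model")) models <- list(models)
  rows <- lapply(models, extract_introns_one, genome = genome)
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(
      transcript_id = character(), intron_number = integer(),
      seq_id = character(), strand = character(),
      start = numeric(), end = numeric(), length = integer(),
      sequence = character(), donor_dinuc = character(),
      acceptor_dinuc = character(), region = character(),
      stringsAsFactors = FALSE
    )
  }
  rownames(out) <- NULL
  out
}

extract_introns_one <- function(model, genome) {
  stopifnot(inherits(model, "transcript_model"))
  if (!model$seq_id %in% names(genome)) {
    stop("genome lacks sequence ", model$seq_id)
  }
  chrom <- as.character(genome[[model$seq_id]])
  n_ex <- nrow(model$exons)
  if (model$exons[n_ex, 2] > nchar(chrom)) {
    stop("transcript ", model$transcript_id, " extends past end of ",
         model$seq_id)
  }
  if (n_ex < 2L) return(NULL)
  gs <- model$exons[-n_ex, 2]
  ge <- model$exons[-1L, 1]
  if (any(ge <= gs)) {
    stop("transcript ", model$transcript_id, ": touching or overlapping exons")
  }
  n_int <- n_ex - 1L
  seqs <- vapply(seq_len(n_int), function(i) substr0(chrom, gs[i], ge[i]),
                 character(1))
  if (model$strand == "-") seqs <- revcomp(seqs)
  # transcription order: genomic left-to-right on +, right-to-left on -
  ord <- if (model$strand == "+") seq_len(n_int) else rev(seq_len(n_int))
  region <- vapply(seq_len(n_int), function(i) {
    gap_region(gs[i], ge[i], model$cds, model$strand)
  }, character(1))
  data.frame(
    transcript_id = model$transcript_id,
    intron_number = order(ord),  # rank in transcription order
    seq_id = model$seq_id,
    strand = model$strand,
    start = gs, end = ge,
    length = as.integer(ge - gs),
    sequence = seqs,
    donor_dinuc = substr(seqs, 1L, 2L),
    acceptor_dinuc = substr(seqs, nchar(seqs) - 1L, nchar(seqs)),
    region = region,
    stringsAsFactors = FALSE
  )
}

#' Classify intron termini under the GT-AG rule
#'
#' An intron is `canonical` iff its first two bases are `GT` and its last
#' two are `AG` on the transcript strand. `N` at terminal positions is
#' noncanonical (conservative under ambiguity).
#'
#' @param introns intron data.frame from [extract_introns()], or a
#'   character vector of intron sequences.
#' @return character vector, `"canonical"` or `"noncanonical"`.
#' @export
classify_termini <- function(introns) {
  seqs <- if (is.data.frame(introns)) introns$sequence else introns
  if (any(nchar(seqs) < 4L)) {
    stop("intron shorter than 4 nt cannot be classified")
  }
  donor <- substr(seqs, 1L, 2L)
  acceptor <- substr(seqs, nchar(seqs) - 1L, nchar(seqs))
  ifelse(donor == "GT" & acceptor == "AG", "canonical", "noncanonical")
}

#' Write introns as BED6
#'
#' One line per intron; `name` is `transcript_id|intron_number` and
#' `score` is the intron length.
#'
#' @param introns intron data.frame from [extract_introns()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_introns_bed <- function(introns, path) {
  bed <- data.frame(
    chrom = introns$seq_id,
    start = format(introns$start, scientific = FALSE, trim = TRUE),
    end = format(introns$end, scientific = FALSE, trim = TRUE),
    name = intron_key(introns$transcript_id, introns$intron_number),
    score = introns$length,
    strand = introns$strand
  )
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write intron sequences as FASTA
#'
#' @inheritParams write_introns_bed
#' @return `path`, invisibly.
#' @export
write_introns_fasta <- function(introns, path) {
  seqs <- Biostrings::DNAStringSet(introns$sequence)
  names(seqs) <- intron_key(introns$transcript_id, introns$intron_number)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Spliced (mature) transcript sequence of a model
#'
#' Concatenates the exon sequences in transcript orientation; used for
#' round-trip checks and by the read simulator.
#'
#' @inheritParams extract_introns
#' @param model a single [transcript_model].
#' @return a character scalar.
#' @export
spliced_sequence <- function(model, genome) {
  chrom <- as.character(genome[[model$seq_id]])
  parts <- vapply(seq_len(nrow(model$exons)), function(i) {
    substr0(chrom, model$exons[i, 1], model$exons[i, 2])
  }, character(1))
  s <- paste(parts, collapse = "")
  if (model$strand == "-") s <- revcomp(s)
  s
}
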