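# Deterministic toy genes built in code: interleaves exon and intron
# sequences (transcript orientation), lays them onto a padded chromosome
# on either strand, and maps a CDS given in spliced-transcript
# coordinates back to a genomic interval.

toy_gene <- function(exon_seqs, intron_seqs = character(0), strand = "+",
                     cds_spliced = NULL, transcript_id = "toy1",
                     pad = 10, seq_id = "chrT") {
  stopifnot(length(exon_seqs) == length(intron_seqs) + 1L)
  n_seg <- 2L * length(intron_seqs) + 1L
  segs <- character(n_seg)
  is_exon <- rep(c(TRUE, FALSE), length.out = n_seg)
  segs[is_exon] <- exon_seqs
  segs[!is_exon] <- intron_seqs
  gene_tx <- paste(segs, collapse = "")
  total <- nchar(gene_tx)
  gene_genomic <- if (strand == "-") {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(gene_tx)))
  } else gene_tx
  chrom <- paste0(strrep("T", pad), gene_genomic, strrep("T", pad))
  seg_len <- nchar(segs)
  cum <- cumsum(seg_len)
  seg_start_tx <- cum - seg_len
  gene_start <- pad
  if (strand == "+") {
    g_start <- gene_start + seg_start_tx
    g_end <- gene_start + cum
  } else {
    g_start <- gene_start + total - cum
    g_end <- gene_start + total - seg_start_tx
  }
  exons <- cbind(g_start[is_exon], g_end[is_exon])
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  cds <- NULL
  if (!is.null(cds_spliced)) {
    # map a spliced-transcript offset to its genomic base
    ex_tx_len <- nchar(exon_seqs)
    cum_ex <- cumsum(ex_tx_len)
    map_g <- function(p) {
      k <- which(p < cum_ex)[1]
      within <- p - (cum_ex[k] - ex_tx_len[k])
      if (strand == "+") {
        ex_sorted <- exons[k, ]
        ex_sorted[1] + within
      } else {
        ex_sorted <- exons[nrow(exons) - k + 1L, ]
        ex_sorted[2] - 1 - within
      }
    }
    a <- map_g(cds_spliced[1])
    b <- map_g(cds_spliced[2] - 1L)
    cds <- if (strand == "+") c(a, b + 1) else c(b, a + 1)
  }
  genome <- Biostrings::DNAStringSet(chrom)
  names(genome) <- seq_id
  model <- transcript_model(
    transcript_id = transcript_id, gene_id = paste0(transcript_id, "_g"),
    seq_id = seq_id, strand = strand, exons = exons, cds = cds,
    partial_flag = FALSE
  )
  list(genome = genome, model = model, spliced = gene_tx_spliced(exon_seqs))
}

gene_tx_spliced <- function(exon_seqs) paste(exon_seqs, collapse = "")

# a small deterministic hit table for filter tests
toy_hits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(
      qseqid = r$qseqid %||% "tx1|1",
      sseqid = r$sseqid %||% "subj",
      species = r$species %||% "pan_troglodytes",
      length = r$length %||% 60,
      bitscore = r$bitscore %||% 120,
      evalue = r$evalue %||% 1e-25,
      pident = r$pident %||% 97,
      gaps = r$gaps %||% 0L,
      transcript_id = sub("\\|.*", "", r$qseqid %||% "tx1|1"),
      intron_number = as.integer(sub(".*\\|", "", r$qseqid %||% "tx1|1")),
      stringsAsFactors = FALSE
    )
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

intron_keys_of <- function(df) paste0(df$transcript_id, "|", df$intron_number)

# deterministic donor training set: consensus CAGGTAAGT with positionwise
# variation so column extrema are unique
donor_training_set <- function(n = 100) {
  set.seed(99)
  cons <- strsplit("CAGGTAAGT", "")[[1]]
  vapply(seq_len(n), function(i) {
    s <- cons
    flip <- runif(9) < 0.15
    s[flip] <- vapply(which(flip), function(j) {
      sample(setdiff(c("A", "C", "G", "T"), cons[j]), 1)
    }, character(1))
    paste(s, collapse = "")
  }, character(1))
}
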