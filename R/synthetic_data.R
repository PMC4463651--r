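# synthetic_data: seeded generators for every input the pipeline needs --
# genomes with planted ultra-short introns and false-intron decoys,
# transcript isoform sets with per-intron splice frequencies,
# junction-spanning short reads, and ortholog hit tables -- all with a
# ground-truth table for parameter-recovery tests.
#
# Seed derivation: make_genome uses `seed`, make_transcripts `seed + 1`,
# make_reads `seed + 2`, make_hit_tables `seed + 3`, so modules can be
# exercised in isolation yet a full simulate_all() run is reproducible
# byte for byte.

#' Simulation configuration
#'
#' Defaults emulate the shape of the real data: a bimodal intron-length
#' mixture (log-normal short mode, median 85 nt; log-normal long mode,
#' median 2000 nt), a contaminating population of non-GT-AG "false
#' introns" injected only below the planted ultra-short threshold, a
#' G-content gradient from long to ultra-short introns, occasional
#' insertion of the 11-nt G-rich ISE into planted ultra-short introns,
#' and ortholog divergence controlled per intron class.
#'
#' @param seed integer root seed.
#' @param n_genes number of genes (one transcript each).
#' @param introns_per_gene integer `c(min, max)` background introns per
#'   gene.
#' @param exon_length integer `c(min, max)` exon length (nt).
#' @param short_mode_meanlog,short_mode_sdlog,long_mode_meanlog,
#'   long_mode_sdlog,short_mode_weight log-normal mixture of true intron
#'   lengths.
#' @param planted_lengths lengths (nt) of the planted conserved
#'   ultra-short introns, one per planting, distributed over genes.
#' @param false_intron_rate fraction of background intron slots replaced
#'   by non-GT-AG false introns.
#' @param false_length_range integer `c(min, max)` false-intron lengths;
#'   the maximum must not exceed `planted_threshold` (false introns occur
#'   only below the threshold).
#' @param planted_threshold the ultra-short threshold being planted (nt).
#' @param g_fraction_ultra_short,g_fraction_short,g_fraction_long G
#'   fraction of true intron bodies per length class.
#' @param ise_insertion_rate probability a planted ultra-short intron
#'   carries an embedded `CAGGGGCTGGG`.
#' @param splice_frequency default per-intron probability that an
#'   isoform splices the intron.
#' @param ortholog_identity,background_identity percent identity of
#'   simulated orthologs for planted (conserved) and background introns.
#' @param species species names for the ortholog tables.
#' @param read_length,coverage,error_rate short-read simulation
#'   parameters.
#' @param n_transcripts isoforms sampled per gene.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_genes = 20,
                       introns_per_gene = c(4, 10),
                       exon_length = c(80, 200),
                       short_mode_meanlog = log(85),
                       short_mode_sdlog = 0.25,
                       long_mode_meanlog = log(2000),
                       long_mode_sdlog = 0.5,
                       short_mode_weight = 0.6,
                       planted_lengths = c(37, 43, 47, 49, 54, 56,
                                           61, 62, 63, 65),
                       false_intron_rate = 0.15,
                       false_length_range = c(20, 65),
                       planted_threshold = 65,
                       g_fraction_ultra_short = 0.40,
                       g_fraction_short = 0.25,
                       g_fraction_long = 0.25,
                       ise_insertion_rate = 0.25,
                       splice_frequency = 0.9,
                       ortholog_identity = 97,
                       background_identity = 85,
                       species = c("pan_troglodytes", "macaca_mulatta"),
                       read_length = 50,
                       coverage = 20,
                       error_rate = 0.005,
                       n_transcripts = 10) {
  stopifnot(seed == round(seed), n_genes >= 1,
            false_intron_rate >= 0, false_intron_rate <= 1,
            ise_insertion_rate >= 0, ise_insertion_rate <= 1,
            splice_frequency >= 0, splice_frequency <= 1,
            error_rate >= 0, error_rate <= 1,
            false_length_range[2] <= planted_threshold,
            false_length_range[1] >= 6,
            all(planted_lengths >= 6),
            exon_length[1] > 70)
  structure(as.list(environment()), class = "sim_config")
}

# sample the per-gene intron layout (lengths, termini, planted flags);
# consumes RNG -- callers seed.
sample_gene_plan <- function(config) {
  g_class_of <- function(len) {
    cls <- classify_length(len, config$planted_threshold)
    switch(cls,
           ultra_short = config$g_fraction_ultra_short,
           short = config$g_fraction_short,
           config$g_fraction_long)
  }
  plans <- lapply(seq_len(config$n_genes), function(g) {
    n_int <- sample(config$introns_per_gene[1]:config$introns_per_gene[2], 1)
    is_false <- runif(n_int) < config$false_intron_rate
    len <- integer(n_int)
    for (i in seq_len(n_int)) {
      if (is_false[i]) {
        len[i] <- sample(config$false_length_range[1]:
                           config$false_length_range[2], 1)
      } else {
        mode_short <- runif(1) < config$short_mode_weight
        l <- if (mode_short) {
          rlnorm(1, config$short_mode_meanlog, config$short_mode_sdlog)
        } else {
          rlnorm(1, config$long_mode_meanlog, config$long_mode_sdlog)
        }
        len[i] <- max(20L, min(6000L, as.integer(round(l))))
      }
    }
    data.frame(
      gene = g, length = len, canonical = !is_false, is_false = is_false,
      is_planted = FALSE, has_ise = FALSE,
      g_fraction = vapply(len, g_class_of, numeric(1)),
      stringsAsFactors = FALSE
    )
  })
  # distribute planted conserved ultra-short introns over genes
  for (i in seq_along(config$planted_lengths)) {
    g <- ((i - 1L) %% config$n_genes) + 1L
    len <- config$planted_lengths[i]
    row <- data.frame(
      gene = g, length = len, canonical = TRUE, is_false = FALSE,
      is_planted = TRUE,
      has_ise = (runif(1) < config$ise_insertion_rate) && len >= 19,
      g_fraction = config$g_fraction_ultra_short,
      stringsAsFactors = FALSE
    )
    at <- sample(nrow(plans[[g]]) + 1L, 1)
    plans[[g]] <- rbind(
      if (at > 1L) plans[[g]][seq_len(at - 1L), ], row,
      if (at <= nrow(plans[[g]])) plans[[g]][at:nrow(plans[[g]]), ]
    )
  }
  plans
}

#' Sample an intron cohort (lengths and termini only)
#'
#' The length/termini layer of [make_genome()]: the per-intron truth of a
#' simulated genome without building any sequence. Useful for
#' distribution-level tests (threshold recovery) at scale.
#'
#' @param config a [sim_config()].
#' @return data.frame with `gene`, `length`, `canonical`, `is_false`,
#'   `is_planted`.
#' @export
sample_intron_cohort <- function(config) {
  set.seed(config$seed)
  plan <- do.call(rbind, sample_gene_plan(config))
  rownames(plan) <- NULL
  plan[c("gene", "length", "canonical", "is_false", "is_planted")]
}

# one intron body: terminal dinucleotides per canonical status, G-biased
# body, optional embedded ISE
make_intron_seq <- function(len, canonical, g_fraction, has_ise) {
  pg <- g_fraction
  po <- (1 - pg) / 3
  body <- random_dna(len - 4L, prob = c(po, po, pg, po))
  s <- if (canonical) {
    paste0("GT", body, "AG")
  } else {
    paste0(sample(c("CT", "AT", "GA"), 1), body,
           sample(c("AC", "GC", "TT"), 1))
  }
  if (has_ise && len >= nchar(ISE_MOTIF) + 8L) {
    at <- 3L + sample(len - nchar(ISE_MOTIF) - 4L, 1)  # keep termini intact
    substr(s, at, at + nchar(ISE_MOTIF) - 1L) <- ISE_MOTIF
  }
  s
}

#' Generate a synthetic genome with planted ultra-short introns
#'
#' Builds one chromosome carrying `n_genes` genes (one transcript each,
#' random strand) whose introns follow the configured bimodal length
#' mixture; non-GT-AG false introns are injected only below the planted
#' threshold; planted conserved ultra-short introns are canonical,
#' G-biased and optionally carry the ISE motif. Each transcript has 5'
#' and 3' UTRs (so `partial_flag` is `FALSE`), an ATG at the CDS start
#' and a stop codon at the CDS end.
#'
#' @param config a [sim_config()].
#' @return list with `genome` ([Biostrings::DNAStringSet], one
#'   chromosome `chrS`), `models` (named list of [transcript_model]),
#'   `truth` (data.frame: `transcript_id`, `intron_number`, `length`,
#'   `canonical`, `is_false`, `is_planted`, `has_ise`, `g_fraction`),
#'   and `config`.
#' @export
make_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  plans <- sample_gene_plan(config)
  spacer_len <- 50L
  u5 <- 30L
  chrom_parts <- character(0)
  cursor <- 0L
  models <- list()
  truth_rows <- list()
  for (g in seq_len(config$n_genes)) {
    plan <- plans[[g]]
    n_int <- nrow(plan)
    tid <- sprintf("TX%03d", g)
    gid <- sprintf("GENE%03d", g)
    strand <- sample(c("+", "-"), 1)
    exon_lens <- sample(config$exon_length[1]:config$exon_length[2],
                        n_int + 1L, replace = TRUE)
    intron_seqs <- vapply(seq_len(n_int), function(i) {
      make_intron_seq(plan$length[i], plan$canonical[i],
                      plan$g_fraction[i], plan$has_ise[i])
    }, character(1))
    exon_seqs <- vapply(exon_lens, random_dna, character(1))
    # interleave exon1, intron1, exon2, ... in transcript orientation
    seg_seq <- character(2L * n_int + 1L)
    seg_exon <- logical(2L * n_int + 1L)
    seg_seq[seq(1L, 2L * n_int + 1L, by = 2L)] <- exon_seqs
    seg_exon[seq(1L, 2L * n_int + 1L, by = 2L)] <- TRUE
    if (n_int > 0L) seg_seq[seq(2L, 2L * n_int, by = 2L)] <- intron_seqs
    seg_len <- nchar(seg_seq)
    cum <- cumsum(seg_len)
    total <- cum[length(cum)]
    gene_seq <- paste(seg_seq, collapse = "")
    # CDS in transcript-oriented gene coordinates (spans introns)
    exonic_total <- sum(exon_lens)
    u3 <- 30L + (exonic_total - u5 - 30L) %% 3L
    a <- u5                      # CDS start offset, first exon
    b <- total - u3              # CDS end offset (within last exon)
    substr(gene_seq, a + 1L, a + 3L) <- "ATG"
    substr(gene_seq, b - 2L, b) <- "TAA"
    if (strand == "-") {
      genomic_gene <- revcomp(gene_seq)
    } else {
      genomic_gene <- gene_seq
    }
    spacer <- random_dna(spacer_len)
    chrom_parts <- c(chrom_parts, spacer, genomic_gene)
    gene_start <- cursor + spacer_len
    cursor <- gene_start + total
    # segment k occupies tx-oriented [cum[k]-seg_len[k], cum[k])
    seg_start <- cum - seg_len
    if (strand == "+") {
      g_start <- gene_start + seg_start
      g_end <- gene_start + cum
    } else {
      g_start <- gene_start + total - cum
      g_end <- gene_start + total - seg_start
    }
    exons <- cbind(g_start[seg_exon], g_end[seg_exon])
    exons <- exons[order(exons[, 1]), , drop = FALSE]
    cds <- if (strand == "+") {
      c(gene_start + a, gene_start + b)
    } else {
      c(gene_start + total - b, gene_start + total - a)
    }
    models[[tid]] <- transcript_model(
      transcript_id = tid, gene_id = gid, seq_id = "chrS",
      strand = strand, exons = exons, cds = cds, partial_flag = FALSE
    )
    truth_rows[[g]] <- data.frame(
      transcript_id = tid, intron_number = seq_len(n_int),
      length = plan$length, canonical = plan$canonical,
      is_false = plan$is_false, is_planted = plan$is_planted,
      has_ise = plan$has_ise, g_fraction = plan$g_fraction,
      stringsAsFactors = FALSE
    )
  }
  genome <- Biostrings::DNAStringSet(paste(chrom_parts, collapse = ""))
  names(genome) <- "chrS"
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  list(genome = genome, models = models, truth = truth, config = config)
}

#' Sample transcript isoforms with per-intron splice frequencies
#'
#' Each sampled isoform independently splices or retains every intron of
#' its gene at the intron's splice frequency; realized spliced/aligned
#' counts are recorded per intron.
#'
#' @param sim output of [make_genome()].
#' @param frequencies per-intron splice probabilities: a scalar, or a
#'   named vector keyed by `transcript|intronN`; defaults to the
#'   config's `splice_frequency`.
#' @param n_transcripts isoforms per gene; defaults to the config's.
#' @return list with `isoforms` (data.frame: `isoform_id`,
#'   `transcript_id`, `sequence`, `retained` comma-joined intron
#'   numbers) and `counts` (data.frame: `transcript_id`,
#'   `intron_number`, `spliced_hits`, `aligned_hits`).
#' @export
make_transcripts <- function(sim, frequencies = NULL, n_transcripts = NULL) {
  config <- sim$config
  set.seed(config$seed + 1L)
  n_tx <- n_transcripts %||% config$n_transcripts
  freq_of <- function(key) {
    if (is.null(frequencies)) return(config$splice_frequency)
    if (length(frequencies) == 1L && is.null(names(frequencies))) {
      return(frequencies)
    }
    unname(frequencies[key])
  }
  iso_rows <- list()
  count_rows <- list()
  for (tid in names(sim$models)) {
    mod <- sim$models[[tid]]
    introns <- extract_introns(mod, sim$genome)
    n_int <- nrow(introns)
    mrna <- spliced_sequence(mod, sim$genome)
    # exon-exon junction offsets in the fully spliced mRNA
    w <- mod$exons[, 2] - mod$exons[, 1]
    cum_plus <- cumsum(w)[-length(w)]
    junc <- if (n_int == 0L) integer(0)
            else if (mod$strand == "+") cum_plus
            else sum(w) - rev(cum_plus)
    spliced_n <- integer(n_int)
    for (k in seq_len(n_tx)) {
      keys <- intron_key(tid, seq_len(n_int))
      p <- vapply(keys, freq_of, numeric(1))
      spliced <- runif(n_int) < p
      spliced_n <- spliced_n + spliced
      retained_idx <- which(!spliced)
      # insert retained introns 3'-first so earlier offsets stay valid
      iso_seq <- mrna
      for (ri in rev(order(junc[retained_idx]))) {
        i <- retained_idx[ri]
        j <- junc[i]
        iso_seq <- paste0(substr(iso_seq, 1L, j),
                          introns$sequence[introns$intron_number == i],
                          substr(iso_seq, j + 1L, nchar(iso_seq)))
      }
      iso_rows[[length(iso_rows) + 1L]] <- data.frame(
        isoform_id = sprintf("%s.iso%02d", tid, k),
        transcript_id = tid, sequence = iso_seq,
        retained = paste(retained_idx, collapse = ","),
        stringsAsFactors = FALSE
      )
    }
    if (n_int > 0L) {
      count_rows[[length(count_rows) + 1L]] <- data.frame(
        transcript_id = tid, intron_number = seq_len(n_int),
        spliced_hits = spliced_n, aligned_hits = n_tx,
        stringsAsFactors = FALSE
      )
    }
  }
  list(isoforms = do.call(rbind, iso_rows),
       counts = do.call(rbind, count_rows))
}

#' Simulate short reads from isoforms
#'
#' Uniform start positions, substitution errors at `error_rate`; read ids
#' encode the isoform and 0-based start position
#' (`isoform_id:start:serial`) for truth-based testing.
#'
#' @param isoforms `isoforms` data.frame from [make_transcripts()].
#' @param config a [sim_config()] supplying `read_length`, `coverage`,
#'   `error_rate` and the seed.
#' @return data.frame with `read_id` and `sequence`.
#' @export
make_reads <- function(isoforms, config) {
  set.seed(config$seed + 2L)
  rl <- config$read_length
  rows <- list()
  for (i in seq_len(nrow(isoforms))) {
    s <- isoforms$sequence[i]
    len <- nchar(s)
    if (len < rl) next
    n_reads <- ceiling(config$coverage * len / rl)
    starts0 <- sample(0:(len - rl), n_reads, replace = TRUE)
    for (k in seq_len(n_reads)) {
      r <- substr0(s, starts0[k], starts0[k] + rl)
      n_err <- rbinom(1, rl, config$error_rate)
      if (n_err > 0L) {
        pos <- sample(rl, n_err)
        for (p in pos) {
          old <- substr(r, p, p)
          substr(r, p, p) <- sample(setdiff(DNA_BASES, old), 1)
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = sprintf("%s:%d:%d", isoforms$isoform_id[i], starts0[k], k),
        sequence = r, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(read_id = character(), sequence = character())
  }
  out
}

#' Write reads as FASTQ
#'
#' @param reads data.frame from [make_reads()].
#' @param path output path; a `.gz` suffix gzip-compresses.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (nrow(reads) > 0L) {
    qual <- strrep("I", nchar(reads$sequence))
    writeLines(paste0("@", reads$read_id, "\n", reads$sequence, "\n+\n",
                      qual), con)
  }
  invisible(path)
}

# exact-count substitutions at (jittered) evenly spaced positions --
# emulates steady divergence so the optimal local alignment's identity
# tracks the configured value tightly
mutate_sequence <- function(seq, identity_pct) {
  len <- nchar(seq)
  n_mut <- round(len * (100 - identity_pct) / 100)
  if (n_mut < 1L) return(seq)
  pos <- round((seq_len(n_mut) - 0.5) * len / n_mut) +
    sample(-1:1, n_mut, replace = TRUE)
  pos <- pmin(pmax(pos, 1L), len)
  pos <- unique(pos)
  for (p in pos) {
    old <- substr(seq, p, p)
    substr(seq, p, p) <- sample(setdiff(DNA_BASES, old), 1)
  }
  seq
}

#' Generate ortholog hit tables for both conservation searches
#'
#' For every intron, builds the two query types the dual screen uses --
#' concatenated flanking exons (transcriptome search) and intron plus
#' flanking exons (genome search) -- generates a diverged ortholog per
#' species at the configured identity (planted introns:
#' `ortholog_identity`; everything else: `background_identity`), aligns
#' query against ortholog with [local_align()], and returns both hit
#' tables.
#'
#' @param sim output of [make_genome()].
#' @param flank nt of exonic flank per side, default 60.
#' @param max_intron_length only introns up to this length (nt) get
#'   ortholog hits (the conservation screen targets short-intron
#'   candidates; orthologs of multi-kb introns are irrelevant to it and
#'   expensive to align). Default 120.
#' @return list with `tx_hits` and `gn_hits` data.frames in the package
#'   hit-table dialect (see [read_hits()]).
#' @export
make_hit_tables <- function(sim, flank = 60, max_intron_length = 120) {
  config <- sim$config
  set.seed(config$seed + 3L)
  introns <- extract_introns(sim$models, sim$genome)
  introns <- introns[introns$length <= max_intron_length, , drop = FALSE]
  key_truth <- intron_key(sim$truth$transcript_id, sim$truth$intron_number)
  tx_rows <- list(); gn_rows <- list()
  for (i in seq_len(nrow(introns))) {
    tid <- introns$transcript_id[i]
    num <- introns$intron_number[i]
    key <- intron_key(tid, num)
    mod <- sim$models[[tid]]
    chrom <- as.character(sim$genome[[mod$seq_id]])
    n_ex <- nrow(mod$exons)
    gi <- if (mod$strand == "+") num else (n_ex - num)
    up_ex <- mod$exons[gi, ]; dn_ex <- mod$exons[gi + 1L, ]
    fl <- min(flank, up_ex[2] - up_ex[1])
    fr <- min(flank, dn_ex[2] - dn_ex[1])
    left <- substr0(chrom, up_ex[2] - fl, up_ex[2])
    right <- substr0(chrom, dn_ex[1], dn_ex[1] + fr)
    gap <- substr0(chrom, up_ex[2], dn_ex[1])
    tx_query <- paste0(left, right)
    gn_query <- paste0(left, gap, right)
    if (mod$strand == "-") {
      tx_query <- revcomp(tx_query)
      gn_query <- revcomp(gn_query)
    }
    planted <- sim$truth$is_planted[key_truth == key]
    ident <- if (isTRUE(planted[1])) config$ortholog_identity
             else config$background_identity
    for (sp in config$species) {
      subj_tx <- mutate_sequence(tx_query, ident)
      subj_gn <- mutate_sequence(gn_query, ident)
      tx_rows[[length(tx_rows) + 1L]] <- local_align(
        tx_query, subj_tx, qseqid = key,
        sseqid = paste0(sp, "_mrna"), species = sp
      )
      gn_rows[[length(gn_rows) + 1L]] <- local_align(
        gn_query, subj_gn, qseqid = key,
        sseqid = paste0(sp, "_genome"), species = sp
      )
    }
  }
  finish <- function(rows) {
    df <- do.call(rbind, rows)
    keysplit <- split_intron_key(df$qseqid)
    df$transcript_id <- keysplit$transcript_id
    df$intron_number <- keysplit$intron_number
    df
  }
  list(tx_hits = finish(tx_rows), gn_hits = finish(gn_rows))
}

#' Write transcript models as GFF3
#'
#' Emits gene, mRNA, exon and per-exon CDS features with `ID`/`Parent`
#' links, 1-based inclusive coordinates.
#'
#' @param models named list of [transcript_model] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  fmt <- function(seqid, type, s0, e0, strand, attrs) {
    sprintf("%s\tusintrons\t%s\t%d\t%d\t.\t%s\t.\t%s",
            seqid, type, s0 + 1L, e0, strand, attrs)
  }
  for (mod in models) {
    span <- c(mod$exons[1, 1], mod$exons[nrow(mod$exons), 2])
    lines <- c(
      lines,
      fmt(mod$seq_id, "gene", span[1], span[2], mod$strand,
          paste0("ID=", mod$gene_id)),
      fmt(mod$seq_id, "mRNA", span[1], span[2], mod$strand,
          paste0("ID=", mod$transcript_id, ";Parent=", mod$gene_id))
    )
    for (i in seq_len(nrow(mod$exons))) {
      lines <- c(lines, fmt(mod$seq_id, "exon", mod$exons[i, 1],
                            mod$exons[i, 2], mod$strand,
                            paste0("Parent=", mod$transcript_id)))
      if (!is.null(mod$cds)) {
        cs <- max(mod$exons[i, 1], mod$cds[1])
        ce <- min(mod$exons[i, 2], mod$cds[2])
        if (ce > cs) {
          lines <- c(lines, fmt(mod$seq_id, "CDS", cs, ce, mod$strand,
                                paste0("Parent=", mod$transcript_id)))
        }
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Run the full simulation and write every pipeline input
#'
#' Generates the genome, annotation, isoforms, reads and hit tables for
#' one configuration and writes them to a directory: `genome.fa`,
#' `models.gff3`, `reads_s1.fastq.gz`, `tx_hits.tsv`, `gn_hits.tsv`,
#' `truth.tsv`, `isoform_counts.tsv`.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a named list of the written paths plus the in-memory
#'   `sim` object.
#' @export
simulate_all <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- make_genome(config)
  p <- function(f) file.path(out_dir, f)
  Biostrings::writeXStringSet(sim$genome, p("genome.fa"))
  write_gff3(sim$models, p("models.gff3"))
  tx <- make_transcripts(sim)
  reads <- make_reads(tx$isoforms, config)
  write_fastq(reads, p("reads_s1.fastq.gz"))
  hits <- make_hit_tables(sim)
  keep <- c("qseqid", "sseqid", "species", "length", "bitscore", "evalue",
            "pident", "gaps")
  write.table(hits$tx_hits[keep], p("tx_hits.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(hits$gn_hits[keep], p("gn_hits.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$truth, p("truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(tx$counts, p("isoform_counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(list(sim = sim, dir = out_dir,
                 paths = vapply(c("genome.fa", "models.gff3",
                                  "reads_s1.fastq.gz", "tx_hits.tsv",
                                  "gn_hits.tsv", "truth.tsv",
                                  "isoform_counts.tsv"), p, character(1))))
}
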