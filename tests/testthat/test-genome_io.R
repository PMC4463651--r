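test_that("read_genome normalizes case and RNA alphabet and rejects bad input", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1 some description", "acgt", ">chr2", "ACGU"), fa)
  g <- read_genome(fa)
  expect_equal(names(g), c("chr1", "chr2"))
  expect_equal(as.character(g[["chr1"]]), "ACGT")
  expect_equal(as.character(g[["chr2"]]), "ACGT")

  dup <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">a", "GGGG"), dup)
  expect_error(read_genome(dup), "duplicate")

  bad <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACXT"), bad)
  expect_error(read_genome(bad), "non-nucleotide")

  empty <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(0), empty)
  expect_error(read_genome(empty), "empty")
})

test_that("extract_introns computes gaps, strand and regions correctly", {
  # plus strand: exons [0,10), [53,63) -> one intron [10,53), 43 nt
  chrom <- paste0(strrep("A", 10), "GT", strrep("C", 39), "AG", strrep("A", 10))
  genome <- Biostrings::DNAStringSet(chrom); names(genome) <- "c"
  mod <- transcript_model("t1", "g1", "c", "+",
                          exons = rbind(c(0, 10), c(53, 63)))
  ii <- extract_introns(mod, genome)
  expect_equal(nrow(ii), 1L)
  expect_equal(ii$start, 10)
  expect_equal(ii$end, 53)
  expect_equal(ii$length, 43L)
  expect_equal(ii$donor_dinuc, "GT")
  expect_equal(ii$acceptor_dinuc, "AG")
  expect_equal(ii$region, "noncoding")

  # minus strand: genomic gap CT...AC reverse-complements to GT...AG
  chrom2 <- paste0(strrep("A", 10), "CT", strrep("C", 6), "AC", strrep("A", 10))
  genome2 <- Biostrings::DNAStringSet(chrom2); names(genome2) <- "c"
  mod2 <- transcript_model("t2", "g2", "c", "-",
                           exons = rbind(c(0, 10), c(20, 30)))
  ii2 <- extract_introns(mod2, genome2)
  expect_equal(substr(ii2$sequence, 1, 2), "GT")
  expect_equal(substr(ii2$sequence, 9, 10), "AG")

  # single exon: no junctions
  mod3 <- transcript_model("t3", "g3", "c", "+", exons = rbind(c(0, 10)))
  expect_equal(nrow(extract_introns(mod3, genome2)), 0L)
})

test_that("minus-strand intron numbering counts from the transcript 5' end", {
  g <- toy_gene(exon_seqs = c("AAAAAAAA", "CCCCCCCC", "GGGGGGGG"),
                intron_seqs = c("GTAAAAAG", "GTCCCCCCCCAG"),
                strand = "-")
  ii <- extract_introns(g$model, g$genome)
  ii <- ii[order(ii$intron_number), ]
  # intron 1 (5'-most in transcript) is the genomically rightmost gap
  expect_equal(ii$length, c(8L, 12L))
  expect_equal(ii$sequence[1], "GTAAAAAG")
  expect_equal(ii$sequence[2], "GTCCCCCCCCAG")
  expect_true(ii$start[1] > ii$start[2])
})

test_that("region assignment distinguishes CDS, UTR5 and UTR3 on both strands", {
  for (strand in c("+", "-")) {
    # exons of 12 nt; spliced = 36 nt; CDS spliced [9, 30): intron 1 sits
    # at spliced offset 12 (inside CDS), intron 2 at 24 (inside CDS)
    g <- toy_gene(exon_seqs = c("AAATTTGGGATG", "AAACCCGGGTTT",
                                "AAATAAGGGCCC"),
                  intron_seqs = c("GTAAAG", "GTCCAG"),
                  strand = strand, cds_spliced = c(9, 30))
    ii <- extract_introns(g$model, g$genome)
    expect_equal(ii$region, c("CDS", "CDS"))
    # CDS spliced [14, 23): intron 1 (offset 12) is 5' of it, intron 2
    # (offset 24) is 3' of it
    g2 <- toy_gene(exon_seqs = c("AAATTTGGGATG", "AAACCCGGGTTT",
                                 "AAATAAGGGCCC"),
                   intron_seqs = c("GTAAAG", "GTCCAG"),
                   strand = strand, cds_spliced = c(14, 23))
    ii2 <- extract_introns(g2$model, g2$genome)
    ii2 <- ii2[order(ii2$intron_number), ]
    expect_equal(ii2$region, c("UTR5", "UTR3"))
  }
})

test_that("classify_termini applies the GT-AG rule to both ends", {
  expect_equal(classify_termini("GTAAGTCCAG"), "canonical")
  expect_equal(classify_termini("ATAAGTCCAC"), "noncanonical")
  expect_equal(classify_termini("GTAAGTCCAC"), "noncanonical")
  expect_equal(classify_termini("ATAAGTCCAG"), "noncanonical")
  expect_equal(classify_termini("GTNNAG"), "canonical")
  expect_equal(classify_termini("NTAAAG"), "noncanonical")
  expect_error(classify_termini("GTA"), "4 nt")
})

test_that("round trip: splicing extracted introns out of the genomic span
           reproduces the spliced transcript on both strands", {
  set.seed(42)
  sim <- make_genome(sim_config(seed = 42, n_genes = 4))
  for (tid in names(sim$models)) {
    mod <- sim$models[[tid]]
    ii <- extract_introns(mod, sim$genome)
    chrom <- as.character(sim$genome[[mod$seq_id]])
    span <- substr(chrom, mod$exons[1, 1] + 1, mod$exons[nrow(mod$exons), 2])
    respliced <- span
    ii_g <- ii[order(-ii$start), ]  # remove genomically right-to-left
    for (k in seq_len(nrow(ii_g))) {
      rel_s <- ii_g$start[k] - mod$exons[1, 1]
      rel_e <- ii_g$end[k] - mod$exons[1, 1]
      respliced <- paste0(substr(respliced, 1, rel_s),
                          substr(respliced, rel_e + 1, nchar(respliced)))
    }
    if (mod$strand == "-") {
      respliced <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(respliced)))
    }
    expect_identical(respliced, spliced_sequence(mod, sim$genome))
    # length bookkeeping: intron + exon lengths = genomic span
    expect_equal(sum(ii$length) + sum(mod$exons[, 2] - mod$exons[, 1]),
                 unname(mod$exons[nrow(mod$exons), 2] - mod$exons[1, 1]))
  }
})

test_that("strand symmetry: a model on the reverse-complemented genome with
           flipped strand yields identical intron sequences and numbers", {
  exons <- c("AAACCCGGGTTT", "CCCAAATTTGGG")
  intr <- "GTAAACCCAG"
  fw <- toy_gene(exons, intr, strand = "+")
  rv <- toy_gene(exons, intr, strand = "-")
  ifw <- extract_introns(fw$model, fw$genome)
  irv <- extract_introns(rv$model, rv$genome)
  expect_equal(ifw$sequence, irv$sequence)
  expect_equal(ifw$intron_number, irv$intron_number)
})

test_that("GFF3 written by the package round-trips through read_annotation", {
  sim <- make_genome(sim_config(seed = 5, n_genes = 3))
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(sim$models, gff)
  models2 <- read_annotation(gff)
  expect_setequal(names(models2), names(sim$models))
  for (tid in names(sim$models)) {
    a <- sim$models[[tid]]; b <- models2[[tid]]
    expect_equal(unname(b$exons), unname(a$exons))
    expect_equal(unname(b$cds), unname(a$cds))
    expect_equal(b$strand, a$strand)
    expect_false(b$partial_flag)
  }
  # intron extraction agrees between original and round-tripped models
  i1 <- extract_introns(sim$models, sim$genome)
  i2 <- extract_introns(models2, sim$genome)
  i2 <- i2[match(paste(i1$transcript_id, i1$intron_number),
                 paste(i2$transcript_id, i2$intron_number)), ]
  expect_equal(i2$sequence, i1$sequence)
})

test_that("BED12 blocks expand to exons and the thick interval to a CDS", {
  bed <- withr::local_tempfile(fileext = ".bed")
  # 3 blocks on [100, 400); thick [120, 380)
  writeLines(paste(c("chr1", 100, 400, "txA", 0, "+", 120, 380, "0",
                     3, "50,60,70,", "0,150,230,"), collapse = "\t"), bed)
  models <- read_annotation(bed)
  m <- models[["txA"]]
  expect_equal(nrow(m$exons), 3L)
  expect_equal(unname(m$exons),
               unname(cbind(c(100, 250, 330), c(150, 310, 400))))
  expect_equal(unname(m$cds), c(120, 380))
  expect_false(m$partial_flag)
})

test_that("a transcript with CDS spanning the full exonic extent is partial", {
  m <- transcript_model("t", "g", "c", "+", exons = rbind(c(0, 30), c(40, 70)),
                        cds = c(0, 70))
  expect_true(m$partial_flag)
  m2 <- transcript_model("t", "g", "c", "+",
                         exons = rbind(c(0, 30), c(40, 70)), cds = c(5, 65))
  expect_false(m2$partial_flag)
})

test_that("transcript_model validates exon and cds geometry", {
  expect_error(transcript_model("t", "g", "c", "+",
                                exons = matrix(numeric(0), ncol = 2)),
               "zero exons")
  expect_error(transcript_model("t", "g", "c", "+",
                                exons = rbind(c(0, 10), c(5, 20))),
               "overlapping")
  expect_error(transcript_model("t", "g", "c", "+", exons = rbind(c(0, 10)),
                                cds = c(5, 20)), "cds")
})

test_that("intron BED6 and FASTA writers emit the documented formats", {
  g <- toy_gene(c("AAAACCCC", "GGGGTTTT"), "GTAAAG", strand = "+",
                transcript_id = "txZ")
  ii <- extract_introns(g$model, g$genome)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_introns_bed(ii, bed)
  fields <- strsplit(readLines(bed), "\t")[[1]]
  expect_equal(fields[4], "txZ|1")
  expect_equal(as.integer(fields[5]), ii$length)
  fa <- withr::local_tempfile(fileext = ".fa")
  write_introns_fasta(ii, fa)
  seqs <- Biostrings::readDNAStringSet(fa)
  expect_equal(names(seqs), "txZ|1")
  expect_equal(as.character(seqs[[1]]), "GTAAAG")
})
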