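test_that("filter_hits honors the printed comparison directions exactly", {
  hits <- toy_hits(
    list(qseqid = "t|1", length = 60, bitscore = 120, evalue = 1e-25, pident = 97),
    list(qseqid = "t|2", length = 60, bitscore = 120, evalue = 1e-25, pident = 95),
    list(qseqid = "t|3", length = 55, bitscore = 120, evalue = 1e-25, pident = 99),
    list(qseqid = "t|4", length = 60, bitscore = 99,  evalue = 1e-25, pident = 99),
    list(qseqid = "t|5", length = 60, bitscore = 120, evalue = 1e-19, pident = 96),
    list(qseqid = "t|6", length = 60, bitscore = 120, evalue = 2e-19, pident = 99)
  )
  kept <- filter_hits(hits)
  # >55 and >99 are exclusive; <=1e-19 and >=96 are inclusive
  expect_setequal(kept$qseqid, c("t|1", "t|5"))
})

test_that("filter_hits is idempotent and monotone in every threshold", {
  set.seed(31)
  hits <- do.call(rbind, lapply(1:200, function(i) toy_hits(list(
    qseqid = sprintf("t%d|%d", i %% 20, i %% 5 + 1),
    length = sample(40:150, 1), bitscore = runif(1, 50, 300),
    evalue = 10^runif(1, -40, -5), pident = runif(1, 80, 100)
  ))))
  th <- screen_thresholds()
  once <- filter_hits(hits, th)
  expect_identical(filter_hits(once, th), once)
  relaxed <- list(
    screen_thresholds(min_aln_length_exclusive = 30),
    screen_thresholds(min_bit_score_exclusive = 50),
    screen_thresholds(max_e_value_inclusive = 1e-10),
    screen_thresholds(min_identity_inclusive = 90)
  )
  for (r in relaxed) {
    expect_true(all(rownames(once) %in% rownames(filter_hits(hits, r))))
  }
})

test_that("mapping_error_filter discards transcripts whose best self-species
           hit aligns with gaps", {
  hits <- rbind(
    toy_hits(list(qseqid = "clean|1", species = "homo_sapiens",
                  evalue = 1e-30, gaps = 0L)),
    toy_hits(list(qseqid = "gapped|1", species = "homo_sapiens",
                  evalue = 1e-30, gaps = 2L)),
    # best (lowest-E) self hit is clean; a worse gapped hit must not matter
    toy_hits(list(qseqid = "mixed|1", species = "homo_sapiens",
                  evalue = 1e-30, gaps = 0L)),
    toy_hits(list(qseqid = "mixed|1", species = "homo_sapiens",
                  evalue = 1e-5, gaps = 3L)),
    # other-species hits are ignored entirely
    toy_hits(list(qseqid = "foreign|1", species = "pan_troglodytes",
                  evalue = 1e-40, gaps = 5L))
  )
  discarded <- mapping_error_filter(hits, self_species = "Homo_sapiens")
  expect_equal(discarded, "gapped")
})

test_that("intersect_searches requires the same intron key and species on
           both sides, and is symmetric", {
  tx <- rbind(
    toy_hits(list(qseqid = "a|1", species = "pan_troglodytes")),
    toy_hits(list(qseqid = "b|2", species = "pan_troglodytes")),
    toy_hits(list(qseqid = "c|3", species = "macaca_mulatta"))
  )
  gn <- rbind(
    toy_hits(list(qseqid = "a|1", species = "pan_troglodytes")),
    toy_hits(list(qseqid = "b|2", species = "macaca_mulatta")),
    toy_hits(list(qseqid = "c|3", species = "macaca_mulatta"))
  )
  ab <- intersect_searches(tx, gn)
  expect_equal(intron_keys <- paste(ab$transcript_id, ab$intron_number),
               c("a 1", "c 3"))
  ba <- intersect_searches(gn, tx)
  expect_equal(ab, ba)
  empty <- intersect_searches(tx, tx[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("local_align reports BLAST-style statistics on known cases", {
  s60 <- strrep("ACGTGTCAAT", 6)
  self <- local_align(s60, s60)
  expect_equal(self$score, 60)
  expect_equal(self$pident, 100)
  expect_equal(self$gaps, 0L)
  expect_equal(self$length, 60L)
  # no positive-scoring letter pairing at all
  none <- local_align("AAAA", "CCCC")
  expect_equal(none$score, 0)
  expect_equal(none$length, 0L)
  expect_equal(none$bitscore, 0)
  # two substitutions in a 60-mer: identity 58/60
  mut <- s60
  substr(mut, 10, 10) <- "C"; substr(mut, 40, 40) <- "G"
  two <- local_align(s60, mut)
  expect_equal(two$pident, 100 * 58 / 60, tolerance = 1e-6)
  # bit score / E-value transforms
  expect_equal(two$bitscore, (1.28 * two$score - log(0.46)) / log(2),
               tolerance = 1e-9)
  expect_equal(two$evalue, 3600 * 2^(-two$bitscore), tolerance = 1e-9)
})

test_that("local_align equals the independent DP oracle on short sequences", {
  set.seed(77)
  for (rep in 1:25) {
    a <- random_seq(sample(4:12, 1))
    b <- random_seq(sample(4:12, 1))
    got <- local_align(a, b)
    expect_equal(got$score, sw_oracle_score(a, b),
                 info = paste(a, b))
  }
  # and with different scoring parameters
  for (rep in 1:10) {
    a <- random_seq(10); b <- random_seq(12)
    got <- local_align(a, b, match = 2, mismatch = -3,
                       gap_open = 4, gap_extend = 1)
    expect_equal(got$score,
                 sw_oracle_score(a, b, match = 2, mismatch = -3,
                                 gap_open = 4, gap_extend = 1),
                 info = paste(a, b))
  }
})

test_that("select_ultra_short keeps conserved short introns of complete
           transcripts only", {
  introns <- data.frame(
    transcript_id = c("full", "part", "full"),
    intron_number = c(1L, 1L, 2L),
    length = c(65L, 37L, 70L),
    stringsAsFactors = FALSE
  )
  models <- list(
    full = transcript_model("full", "g", "c", "+",
                            exons = rbind(c(0, 100), c(165, 260), c(330, 430)),
                            cds = c(10, 420)),
    part = transcript_model("part", "g", "c", "+",
                            exons = rbind(c(0, 100), c(137, 237)),
                            cds = c(0, 237))
  )
  expect_true(models$part$partial_flag)
  keys <- data.frame(transcript_id = c("full", "part", "full"),
                     intron_number = c(1L, 1L, 2L))
  sel <- select_ultra_short(keys, introns, models, threshold = 65)
  expect_equal(nrow(sel), 1L)
  expect_equal(sel$transcript_id, "full")
  expect_equal(sel$intron_number, 1L)
  # conserved key without a matching intron is a consistency error
  bad <- data.frame(transcript_id = "ghost", intron_number = 9L)
  expect_error(select_ultra_short(bad, introns, models), "ghost")
})

test_that("hit tables round-trip through the TSV dialect", {
  sim <- make_genome(sim_config(seed = 21, n_genes = 3))
  ht <- make_hit_tables(sim)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  keep <- c("qseqid", "sseqid", "species", "length", "bitscore", "evalue",
            "pident", "gaps")
  write.table(ht$tx_hits[keep], tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  back <- read_hits(tsv)
  expect_equal(nrow(back), nrow(ht$tx_hits))
  expect_equal(back$pident, ht$tx_hits$pident, tolerance = 1e-6)
  expect_equal(back$transcript_id, ht$tx_hits$transcript_id)
})

test_that("planted 97%-identity orthologs pass the screen and 90% orthologs
           are excluded", {
  cfg_hi <- sim_config(seed = 51, n_genes = 6, ortholog_identity = 97)
  sim <- make_genome(cfg_hi)
  ht <- make_hit_tables(sim)
  res <- discover_ultra_short(sim$models, sim$genome, ht$tx_hits, ht$gn_hits)
  planted <- sim$truth[sim$truth$is_planted, ]
  pk <- intron_keys_of(planted)
  expect_true(all(pk %in% intron_keys_of(res$selected)))

  cfg_lo <- sim_config(seed = 51, n_genes = 6, ortholog_identity = 90)
  sim2 <- make_genome(cfg_lo)
  ht2 <- make_hit_tables(sim2)
  res2 <- discover_ultra_short(sim2$models, sim2$genome,
                               ht2$tx_hits, ht2$gn_hits)
  expect_equal(nrow(res2$selected), 0L)
})
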