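test_that("train_pwm estimates column frequencies and validates its input", {
  pwm <- train_pwm(rep("CAGGTAAGT", 100), kind = "donor")
  expect_equal(pwm$window, 9L)
  expect_true(all(pwm$freq["C", 1] > 99))
  expect_true(all(pwm$freq > 0))
  expect_equal(colSums(pwm$freq), rep(100, 9), tolerance = 1e-9)
  set.seed(2)
  unif <- vapply(1:400, function(i) random_seq(6), character(1))
  pwm_u <- train_pwm(unif, kind = "acceptor")
  expect_true(all(abs(pwm_u$freq - 25) < 8))
  expect_error(train_pwm(rep("CAGGTAAGT", 19), "donor"), "20")
  expect_error(train_pwm(c(rep("CAGGTAAGT", 30), "CAG"), "donor"), "ragged")
})

test_that("ss_score spans [0, 100] from anti-consensus to consensus and
           matches a hand summation", {
  pwm <- train_pwm(donor_training_set(), kind = "donor")
  consensus <- paste(c("A", "C", "G", "T")[apply(pwm$freq, 2, which.max)],
                     collapse = "")
  anti <- paste(c("A", "C", "G", "T")[apply(pwm$freq, 2, which.min)],
                collapse = "")
  expect_equal(ss_score(consensus, pwm), 100)
  expect_equal(ss_score(anti, pwm), 0)
  # spreadsheet-style oracle: sum the looked-up column percentages
  site <- "CAGGTAAGT"
  bases <- strsplit(site, "")[[1]]
  t_raw <- sum(vapply(1:9, function(j) pwm$freq[bases[j], j], numeric(1)))
  t_min <- sum(apply(pwm$freq, 2, min))
  t_max <- sum(apply(pwm$freq, 2, max))
  expect_equal(ss_score(site, pwm), 100 * (t_raw - t_min) / (t_max - t_min))
  # N contributes the column minimum
  site_n <- "NAGGTAAGT"
  t_n <- t_raw - unname(pwm$freq["C", 1]) + min(pwm$freq[, 1])
  expect_equal(ss_score(site_n, pwm), 100 * (t_n - t_min) / (t_max - t_min))
  expect_error(ss_score("CAGG", pwm), "window")
})

test_that("ss_score is monotone under base upgrades", {
  pwm <- train_pwm(donor_training_set(), kind = "donor")
  set.seed(4)
  for (i in 1:30) {
    site <- strsplit(random_seq(9), "")[[1]]
    j <- sample(9, 1)
    alt <- sample(c("A", "C", "G", "T"), 1)
    if (pwm$freq[alt, j] >= pwm$freq[site[j], j]) {
      upgraded <- site; upgraded[j] <- alt
      expect_gte(ss_score(paste(upgraded, collapse = ""), pwm),
                 ss_score(paste(site, collapse = ""), pwm))
    }
  }
})

test_that("u1_duplex_energy: consensus donor attains the enumerated minimum,
           unpaired 9-mers score 0, single mutants are strictly weaker", {
  cons <- "CAGGTAAGT"
  e_cons <- u1_duplex_energy(cons)
  expect_lt(e_cons, -15)
  # no paired position at all (avoiding wobble G-U pairs too)
  expect_equal(u1_duplex_energy("ACAAACCAA"), 0)
  # every single-base mutant is strictly weaker (higher energy)
  for (j in 1:9) {
    for (b in setdiff(c("A", "C", "G", "T"), substr(cons, j, j))) {
      mut <- cons
      substr(mut, j, j) <- b
      expect_gt(u1_duplex_energy(mut), e_cons)
    }
  }
  expect_error(u1_duplex_energy("CAGGTAAG"), "9 nt")
  expect_error(u1_duplex_energy("CAGGTAANT"), "A/C/G/T")
})

test_that("find_branch_sites matches the (C/T)TNA(C/T) consensus including
           overlaps, against the direct-scan oracle", {
  h <- find_branch_sites("GGGCTGACGGG")
  expect_equal(h$offset, 3L)
  expect_equal(h$motif, "CTGAC")
  expect_equal(nrow(find_branch_sites("GGGGGGGG")), 0L)
  h2 <- find_branch_sites("TTAATTTAC")
  expect_equal(h2$offset, c(0L, 4L))
  expect_equal(h2$motif, c("TTAAT", "TTTAC"))
  set.seed(6)
  for (i in 1:25) {
    s <- random_seq(sample(10:60, 1), prob = c(0.2, 0.25, 0.15, 0.4))
    expect_equal(find_branch_sites(s)$offset, branch_scan_oracle(s),
                 info = s)
  }
  # window and 3'-exclusion restrict the scanned region
  s <- paste0("CTGAC", strrep("G", 20), "CTGAC")
  expect_equal(find_branch_sites(s)$offset, c(0L, 25L))
  expect_equal(find_branch_sites(s, window = 10, exclude_last = 0)$offset, 25L)
  expect_equal(nrow(find_branch_sites(s, window = 10, exclude_last = 3)), 0L)
})

test_that("percentile_score uses the mid-rank convention and recovers the
           empirical CDF", {
  ref <- c(1, 2, 3, 4, 5)
  expect_equal(percentile_score(0, ref), 0)
  expect_equal(percentile_score(10, ref), 1)
  expect_equal(percentile_score(3, ref), 0.5)
  set.seed(7)
  ref2 <- sample(1:20, 50, replace = TRUE)
  for (x in c(0, 5, 10, 21)) {
    expect_equal(percentile_score(x, ref2),
                 (sum(ref2 < x) + 0.5 * sum(ref2 == x)) / 50)
  }
})

test_that("flag_inefficient requires every value in the pair/triplet to be
           below the cutoff or NA", {
  expect_true(flag_inefficient(c(0.05, 0.08)))
  expect_false(flag_inefficient(c(0.05, 0.30)))
  expect_true(flag_inefficient(c(NA, NA)))
  expect_true(flag_inefficient(c(0.05, NA)))
  expect_false(flag_inefficient(c(0.10, 0.05)))  # 0.1 is not < 0.1
  expect_equal(flag_inefficient(list(c(0.01, 0.02), c(0.5, 0.01))),
               c(TRUE, FALSE))
})

test_that("strong donors rank high and random donors rank mid against a
           reference score distribution", {
  pwm <- train_pwm(donor_training_set(), kind = "donor")
  set.seed(11)
  ref_sites <- vapply(1:500, function(i) random_seq(9), character(1))
  ref <- ss_score(ref_sites, pwm)
  strong <- donor_training_set(60)
  rand <- vapply(1:60, function(i) random_seq(9), character(1))
  p_strong <- vapply(ss_score(strong, pwm), percentile_score, numeric(1),
                     reference = ref)
  p_rand <- vapply(ss_score(rand, pwm), percentile_score, numeric(1),
                   reference = ref)
  expect_gt(mean(p_strong), 0.9)
  expect_lt(abs(mean(p_rand) - 0.5), 0.1)
})

test_that("score_splice_signals produces calibrated per-intron rows on a
           synthetic genome", {
  sim <- make_genome(sim_config(seed = 17, n_genes = 4))
  introns <- extract_introns(sim$models, sim$genome)
  introns <- introns[classify_termini(introns) == "canonical" &
                       introns$length >= 20, ][1:6, ]
  sites <- extract_splice_sites(introns, sim$models, sim$genome)
  donor_pwm <- train_pwm(donor_training_set(), "donor")
  set.seed(23)
  acc_sites <- vapply(1:100, function(i) {
    paste0(random_seq(12, prob = c(0.1, 0.3, 0.1, 0.5)), "AGGT")
  }, character(1))
  acceptor_pwm <- train_pwm(acc_sites, "acceptor")
  branch_pwm <- train_pwm(vapply(1:50, function(i) {
    paste0(sample(c("C", "T"), 1), "T", sample(c("A", "C", "G", "T"), 1),
           "A", sample(c("C", "T"), 1))
  }, character(1)), "branch")
  donor_ref <- ss_score(vapply(1:200, function(i) random_seq(9),
                               character(1)), donor_pwm)
  dg_ref <- vapply(1:200, function(i) u1_duplex_energy(random_seq(9)),
                   numeric(1))
  acc_ref <- ss_score(vapply(1:200, function(i) random_seq(16),
                             character(1)), acceptor_pwm)
  br_ref <- ss_score(vapply(1:200, function(i) random_seq(5),
                            character(1)), branch_pwm)
  out <- score_splice_signals(sites, donor_pwm, acceptor_pwm, branch_pwm,
                              donor_ref, dg_ref, acc_ref, br_ref)
  expect_equal(nrow(out), 6L)
  expect_true(all(out$donor_ss >= 0 & out$donor_ss <= 100, na.rm = TRUE))
  pct <- unlist(out[c("donor_ss_pct", "donor_dg_pct", "acceptor_ss_pct",
                      "branch_pct")])
  expect_true(all(pct >= 0 & pct <= 1, na.rm = TRUE))
  expect_type(out$donor_inefficient, "logical")
  # every canonical donor site starts GT right of the exonic 3 nt
  expect_true(all(substr(sites$donor_site, 4, 5) == "GT", na.rm = TRUE))
  expect_true(all(substr(sites$acceptor_site, 13, 14) == "AG", na.rm = TRUE))
})
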