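# Independent oracles used across the suite. Each re-derives a result by
# the most direct method available (DP, enumeration, regex, tabulation),
# deliberately sharing no code with the implementation under test.

# Smith-Waterman optimal local alignment score, affine gaps, 3-state DP.
# gap_open/gap_extend are positive penalties; opening a gap of length 1
# costs gap_open + gap_extend (Biostrings convention).
sw_oracle_score <- function(a, b, match = 1, mismatch = -2,
                            gap_open = 5, gap_extend = 2) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  M <- matrix(0, n + 1, m + 1)      # ending in a match/mismatch
  X <- matrix(-Inf, n + 1, m + 1)   # gap in b (consume a)
  Y <- matrix(-Inf, n + 1, m + 1)   # gap in a (consume b)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (av[i - 1] == bv[j - 1]) match else mismatch
      M[i, j] <- max(0, M[i - 1, j - 1], X[i - 1, j - 1],
                     Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                     X[i - 1, j] - gap_extend)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                     Y[i, j - 1] - gap_extend)
      best <- max(best, M[i, j], X[i, j], Y[i, j])
    }
  }
  best
}

# plain Levenshtein distance DP
edit_distance_oracle <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  d <- matrix(0L, n + 1, m + 1)
  d[, 1] <- 0:n; d[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                             d[i, j] + (av[i] != bv[j]))
    }
  }
  d[n + 1, m + 1]
}

# all (possibly overlapping) branch consensus matches by direct
# position-by-position comparison; 0-based offsets
branch_scan_oracle <- function(seq) {
  v <- strsplit(seq, "")[[1]]
  n <- length(v)
  offs <- integer(0)
  if (n >= 5) {
    for (i in 1:(n - 4)) {
      if (v[i] %in% c("C", "T") && v[i + 1] == "T" &&
          v[i + 3] == "A" && v[i + 4] %in% c("C", "T")) {
        offs <- c(offs, i - 1L)
      }
    }
  }
  offs
}

# maximal G runs by direct scan; data.frame(offset 0-based, length)
g_runs_oracle <- function(seq, min_run = 3) {
  v <- strsplit(seq, "")[[1]]
  n <- length(v)
  out <- data.frame(offset = integer(), length = integer())
  i <- 1L
  while (i <= n) {
    if (v[i] == "G") {
      j <- i
      while (j < n && v[j + 1] == "G") j <- j + 1L
      if (j - i + 1L >= min_run) {
        out <- rbind(out, data.frame(offset = i - 1L, length = j - i + 1L))
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

# vectorized enumeration of the U1 duplex energy over a matrix of 9-mer
# base indices (1=A,2=C,3=G,4=U); independent of u1_duplex_energy()
u1_energy_enumerate <- function(base_mat, model = u1_energy_model()) {
  template <- c("G", "U", "C", "C", "A", "U", "U", "C", "A")
  rna <- c("A", "C", "G", "U")
  # pair type code per donor base (rows) x template base: 0 none, 1 wc, 2 wobble
  ptab <- matrix(0L, 4, 4, dimnames = list(rna, rna))
  ptab["A", "U"] <- 1L; ptab["U", "A"] <- 1L
  ptab["G", "C"] <- 1L; ptab["C", "G"] <- 1L
  ptab["G", "U"] <- 2L; ptab["U", "G"] <- 2L
  ptype <- sapply(1:9, function(i) ptab[cbind(base_mat[, i], match(template[i], rna))])
  wc <- model$wc_stack
  dg <- numeric(nrow(base_mat))
  for (i in 1:8) {
    both <- ptype[, i] > 0L & ptype[, i + 1L] > 0L
    bothwc <- both & ptype[, i] == 1L & ptype[, i + 1L] == 1L
    key <- paste0(rna[base_mat[, i]], rna[base_mat[, i + 1L]])
    dg[bothwc] <- dg[bothwc] + unname(wc[key[bothwc]])
    dg[both & !bothwc] <- dg[both & !bothwc] + model$wobble_stack
  }
  dg
}

random_seq <- function(n, prob = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}
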