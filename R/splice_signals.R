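# splice_signals: position-weight-matrix scoring of donor and acceptor
# sites (Shapiro-Senapathy style percent scores), U1 snRNA duplex free
# energy for donors, branch-site consensus search, percentile calibration
# against reference site collections, and the all-weak inefficiency flag.
#
# Windows (configurable at training time): donor = 3 exonic + 6 intronic
# nt around the 5' splice site (9 nt, positions -3..+6); acceptor = last
# 14 intronic + first 2 exonic nt around the 3' splice site (16 nt).

#' Train a splice-site position weight matrix
#'
#' Column base frequencies (as percentages) from a collection of aligned
#' site sequences, with a pseudocount so every entry is positive.
#'
#' @param sites character vector of site sequences, all the same length;
#'   at least 20 are required.
#' @param kind `"donor"`, `"acceptor"` or `"branch"`.
#' @param pseudocount small positive count added per base per column.
#' @return an object of class `pwm_model`: list with `kind`, `window`
#'   (site width), `freq` (4 x window percentage matrix, rows A/C/G/T).
#' @export
train_pwm <- function(sites, kind = c("donor", "acceptor", "branch"),
                      pseudocount = 0.25) {
  kind <- match.arg(kind)
  stopifnot(pseudocount > 0)
  if (length(sites) < 20L) stop("at least 20 sites required to train a PWM")
  w <- unique(nchar(sites))
  if (length(w) != 1L) stop("ragged site lengths: ",
                            paste(w, collapse = ", "))
  mat <- do.call(rbind, strsplit(toupper(sites), ""))
  freq <- vapply(seq_len(w), function(j) {
    counts <- table(factor(mat[, j], levels = DNA_BASES)) + pseudocount
    100 * as.numeric(counts) / sum(counts)
  }, numeric(4))
  rownames(freq) <- DNA_BASES
  structure(list(kind = kind, window = w, freq = freq),
            class = "pwm_model")
}

#' @export
print.pwm_model <- function(x, ...) {
  cat("pwm_model (", x$kind, "), window ", x$window, " nt\n", sep = "")
  consensus <- paste(DNA_BASES[apply(x$freq, 2, which.max)], collapse = "")
  cat("consensus:", consensus, "\n")
  invisible(x)
}

#' Shapiro-Senapathy-style percent score of a splice site
#'
#' Sums the per-position base frequency percentages and rescales between
#' the worst and best possible sums: `100 * (t - t_min) / (t_max -
#' t_min)` with `t_min`/`t_max` the sums of the column-wise minima/maxima.
#' The consensus sequence scores 100 and the anti-consensus 0. An `N`
#' contributes its column's minimum.
#'
#' @param site character vector of site sequences, each of the PWM's
#'   window length.
#' @param pwm a `pwm_model` from [train_pwm()].
#' @return numeric vector of scores in `[0, 100]`.
#' @export
ss_score <- function(site, pwm) {
  stopifnot(inherits(pwm, "pwm_model"))
  if (any(nchar(site) != pwm$window)) {
    stop("site length must equal PWM window (", pwm$window, " nt)")
  }
  col_min <- apply(pwm$freq, 2, min)
  col_max <- apply(pwm$freq, 2, max)
  t_min <- sum(col_min); t_max <- sum(col_max)
  vapply(toupper(site), function(s) {
    bases <- strsplit(s, "")[[1]]
    t <- sum(vapply(seq_along(bases), function(j) {
      b <- bases[j]
      if (b == "N") col_min[j] else {
        if (!b %in% DNA_BASES) stop("invalid base '", b, "' in site")
        pwm$freq[b, j]
      }
    }, numeric(1)))
    100 * (t - t_min) / (t_max - t_min)
  }, numeric(1), USE.NAMES = FALSE)
}

# U1 snRNA 5'-end template opposite donor positions -3..+6, written
# 3'->5' so element i pairs with donor base i. The perfect complement is
# the consensus donor CAG|GTAAGT.
U1_TEMPLATE <- c("G", "U", "C", "C", "A", "U", "U", "C", "A")

#' Default nearest-neighbor energy model for the U1:donor duplex
#'
#' Watson-Crick stack free energies (kcal/mol at 37 C) from the standard
#' RNA nearest-neighbor set, keyed by the donor-strand dinucleotide of
#' two adjacent base pairs; any stack involving a G-U wobble pair gets a
#' single flat value. Absolute energies from this table are a documented
#' simplification -- the package only relies on their ordering.
#'
#' @param wobble_stack free energy (kcal/mol) of a stack containing at
#'   least one G-U wobble pair.
#' @return list with `wc_stack` (named numeric, donor-strand
#'   dinucleotides) and `wobble_stack`.
#' @export
u1_energy_model <- function(wobble_stack = -0.5) {
  wc <- c(AA = -0.93, UU = -0.93, AU = -1.10, UA = -1.33,
          CU = -2.08, AG = -2.08, CA = -2.11, UG = -2.11,
          GU = -2.24, AC = -2.24, GA = -2.35, UC = -2.35,
          CG = -2.36, GG = -3.26, CC = -3.26, GC = -3.42)
  list(wc_stack = wc, wobble_stack = wobble_stack)
}

# pair type of donor RNA base x against template base t:
# "wc", "wobble", or NA (mismatch)
u1_pair_type <- function(x, t) {
  wc <- (x == "A" && t == "U") || (x == "U" && t == "A") ||
    (x == "G" && t == "C") || (x == "C" && t == "G")
  if (wc) return("wc")
  if ((x == "G" && t == "U") || (x == "U" && t == "G")) return("wobble")
  NA_character_
}

#' Free energy of the donor:U1 snRNA duplex
#'
#' Pairs the donor 9-mer (positions -3..+6 around the 5' splice site,
#' DNA alphabet) against the U1 snRNA 5'-end template and sums
#' nearest-neighbor stack energies over adjacent paired positions.
#' Mismatched positions form no pair and contribute nothing. More
#' negative = stronger; the perfect complement (the consensus donor
#' `CAGGTAAGT`) attains the minimum.
#'
#' @param donor_site 9-nt character scalar over A/C/G/T.
#' @param energy_model energy table from [u1_energy_model()].
#' @return free energy in kcal/mol (0 when nothing pairs).
#' @export
u1_duplex_energy <- function(donor_site, energy_model = u1_energy_model()) {
  if (nchar(donor_site) != 9L) stop("donor site must be 9 nt")
  bases <- strsplit(chartr("Tt", "Uu", toupper(donor_site)), "")[[1]]
  if (!all(bases %in% c("A", "C", "G", "U"))) {
    stop("donor site must be over A/C/G/T")
  }
  ptype <- vapply(seq_len(9L), function(i) {
    u1_pair_type(bases[i], U1_TEMPLATE[i])
  }, character(1))
  dg <- 0
  for (i in 1:8) {
    if (is.na(ptype[i]) || is.na(ptype[i + 1L])) next
    if (ptype[i] == "wc" && ptype[i + 1L] == "wc") {
      dg <- dg + energy_model$wc_stack[paste0(bases[i], bases[i + 1L])]
    } else {
      dg <- dg + energy_model$wobble_stack
    }
  }
  unname(dg)
}

#' Find branch-site consensus matches
#'
#' Scans a window at the 3' end of an intron for the human branch-site
#' consensus `(C/T)T N A (C/T)` (the branched A at pattern position 4).
#' Overlapping matches are all reported, 5' to 3'.
#'
#' @param intron_seq intron sequence (character scalar).
#' @param window nt scanned, counted from the 3' end; default the whole
#'   sequence. Must not exceed the intron length.
#' @param exclude_last nt at the extreme 3' end excluded from the scan
#'   (the acceptor AG and its polypyrimidine run are not branch
#'   candidates); default 0.
#' @return data.frame with `offset` (0-based, relative to the intron 5'
#'   end) and `motif` (the matched 5-mer).
#' @export
find_branch_sites <- function(intron_seq, window = NULL, exclude_last = 0) {
  len <- nchar(intron_seq)
  window <- window %||% len
  if (window > len) stop("window exceeds intron length")
  region_start <- max(0L, len - exclude_last - window)  # 0-based
  region_end <- len - exclude_last
  hits <- list()
  if (region_end - region_start >= 5L) {
    region <- substr0(intron_seq, region_start, region_end)
    m <- gregexpr("(?=[CT]T[ACGT]A[CT])", region, perl = TRUE)[[1]]
    if (m[1] != -1L) {
      offs <- region_start + as.integer(m) - 1L
      hits <- data.frame(
        offset = offs,
        motif = substr(rep(intron_seq, length(offs)), offs + 1L, offs + 5L),
        stringsAsFactors = FALSE
      )
      return(hits)
    }
  }
  data.frame(offset = integer(), motif = character(),
             stringsAsFactors = FALSE)
}

#' Percentile of a raw score against a reference collection
#'
#' Mid-rank convention: the fraction of reference values strictly below
#' the raw score plus half the ties, as a fraction in `[0, 1]`.
#'
#' @param raw numeric scalar (or vector) of raw scores.
#' @param reference numeric vector of reference raw scores (non-empty).
#' @return numeric in `[0, 1]`.
#' @export
percentile_score <- function(raw, reference) {
  if (length(reference) == 0L) stop("reference collection is empty")
  vapply(raw, function(x) {
    (sum(reference < x) + 0.5 * sum(reference == x)) / length(reference)
  }, numeric(1))
}

#' Flag inefficient splice signals
#'
#' A signal (a donor's or acceptor's pair/triplet of percentile values)
#' is inefficient iff EVERY value is below `cutoff` or `NA`; one value at
#' or above the cutoff rescues the signal.
#'
#' @param percentiles numeric vector of percentile values in `[0, 1]`
#'   (`NA` allowed), or a list of such vectors.
#' @param cutoff inefficiency cutoff, default 0.1.
#' @return logical (one per vector).
#' @export
flag_inefficient <- function(percentiles, cutoff = 0.1) {
  if (!is.list(percentiles)) percentiles <- list(percentiles)
  vapply(percentiles, function(p) {
    all(is.na(p) | p < cutoff)
  }, logical(1))
}

#' Extract donor and acceptor site sequences for introns
#'
#' Donor: last 3 exonic nt + first 6 intronic nt (9-mer); acceptor: last
#' 14 intronic nt + first 2 exonic nt (16-mer); both on the transcript
#' strand. Introns whose flanking exon or body is too short for a window
#' get `NA` for that site.
#'
#' @param introns intron data.frame from [extract_introns()].
#' @param models named list of [transcript_model] objects.
#' @param genome genome [Biostrings::DNAStringSet].
#' @param donor_exonic,donor_intronic,acceptor_intronic,acceptor_exonic
#'   window composition in nt.
#' @return `introns` with added `donor_site` and `acceptor_site` columns.
#' @export
extract_splice_sites <- function(introns, models, genome,
                                 donor_exonic = 3, donor_intronic = 6,
                                 acceptor_intronic = 14,
                                 acceptor_exonic = 2) {
  donor <- character(nrow(introns))
  acceptor <- character(nrow(introns))
  for (i in seq_len(nrow(introns))) {
    mod <- models[[introns$transcript_id[i]]]
    chrom <- as.character(genome[[mod$seq_id]])
    s <- introns$start[i]; e <- introns$end[i]
    len <- e - s
    if (mod$strand == "+") {
      d <- if (s >= donor_exonic && len >= donor_intronic) {
        substr0(chrom, s - donor_exonic, s + donor_intronic)
      } else NA_character_
      a <- if (len >= acceptor_intronic &&
               e + acceptor_exonic <= nchar(chrom)) {
        substr0(chrom, e - acceptor_intronic, e + acceptor_exonic)
      } else NA_character_
    } else {
      d <- if (e + donor_exonic <= nchar(chrom) && len >= donor_intronic) {
        revcomp(substr0(chrom, e - donor_intronic, e + donor_exonic))
      } else NA_character_
      a <- if (len >= acceptor_intronic && s >= acceptor_exonic) {
        revcomp(substr0(chrom, s - acceptor_exonic, s + acceptor_intronic))
      } else NA_character_
    }
    donor[i] <- d; acceptor[i] <- a
  }
  introns$donor_site <- donor
  introns$acceptor_site <- acceptor
  introns
}

#' Score splice signals for a set of introns
#'
#' For each intron: donor S&S score and U1 duplex energy, acceptor S&S
#' score and best branch-site score (best [ss_score()] over consensus
#' matches in the 3'-end window; `NA` when the window has no consensus
#' match), percentiles of each against reference collections, and the
#' per-signal inefficiency flags (donor pair: S&S and delta-G
#' percentiles; acceptor pair: S&S and branch percentiles).
#'
#' @param introns output of [extract_splice_sites()] (must carry
#'   `donor_site`, `acceptor_site`, `sequence`).
#' @param donor_pwm,acceptor_pwm,branch_pwm `pwm_model`s (branch window
#'   5 nt).
#' @param donor_ref,donor_dg_ref,acceptor_ref,branch_ref numeric
#'   reference score collections for percentile calibration (raw S&S for
#'   donor/acceptor/branch; raw delta-G, sign-flipped internally so that
#'   stronger = higher percentile, for `donor_dg_ref`).
#' @param branch_window,branch_exclude branch search window from the 3'
#'   end and excluded terminal nt; defaults 40 and 3.
#' @param cutoff inefficiency cutoff on percentiles, default 0.1.
#' @return data.frame, one row per intron, with raw scores, percentiles
#'   and `donor_inefficient` / `acceptor_inefficient` flags.
#' @export
score_splice_signals <- function(introns, donor_pwm, acceptor_pwm,
                                 branch_pwm, donor_ref, donor_dg_ref,
                                 acceptor_ref, branch_ref,
                                 branch_window = 40, branch_exclude = 3,
                                 cutoff = 0.1) {
  n <- nrow(introns)
  out <- data.frame(
    junction_id = intron_key(introns$transcript_id, introns$intron_number),
    donor_ss = NA_real_, donor_dg = NA_real_,
    acceptor_ss = NA_real_, branch_ss = NA_real_,
    donor_ss_pct = NA_real_, donor_dg_pct = NA_real_,
    acceptor_ss_pct = NA_real_, branch_pct = NA_real_,
    donor_inefficient = NA, acceptor_inefficient = NA,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    ds <- introns$donor_site[i]
    as_ <- introns$acceptor_site[i]
    seq <- introns$sequence[i]
    if (!is.na(ds)) {
      out$donor_ss[i] <- ss_score(ds, donor_pwm)
      out$donor_dg[i] <- u1_duplex_energy(ds)
      out$donor_ss_pct[i] <- percentile_score(out$donor_ss[i], donor_ref)
      # delta-G: more negative = stronger, so rank on -dg
      out$donor_dg_pct[i] <- percentile_score(-out$donor_dg[i],
                                              -donor_dg_ref)
    }
    if (!is.na(as_)) {
      out$acceptor_ss[i] <- ss_score(as_, acceptor_pwm)
      out$acceptor_ss_pct[i] <- percentile_score(out$acceptor_ss[i],
                                                 acceptor_ref)
    }
    bw <- min(branch_window, nchar(seq))
    bh <- find_branch_sites(seq, window = bw, exclude_last = branch_exclude)
    if (nrow(bh) > 0L) {
      out$branch_ss[i] <- max(ss_score(bh$motif, branch_pwm))
      out$branch_pct[i] <- percentile_score(out$branch_ss[i], branch_ref)
    }
    out$donor_inefficient[i] <-
      flag_inefficient(c(out$donor_ss_pct[i], out$donor_dg_pct[i]), cutoff)
    out$acceptor_inefficient[i] <-
      flag_inefficient(c(out$acceptor_ss_pct[i], out$branch_pct[i]), cutoff)
  }
  out
}
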