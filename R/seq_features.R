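# seq_features: base composition, G-runs, intronic-splicing-enhancer
# (ISE) similarity scanning, and G-content by length class. Ultra-short
# introns are frequently G-rich, carry G-triplets, and a subset contains
# (near-)copies of the 11-nt G-rich ISE CAGGGGCTGGG.

ISE_MOTIF <- "CAGGGGCTGGG"

#' Base composition of a sequence
#'
#' Exact A/C/G/T counts and fractions; `N`s are excluded from the counted
#' total and tallied separately. All tied most-frequent bases are
#' reported.
#'
#' @param seq DNA sequence (character scalar over A/C/G/T/N).
#' @return list with `counts` (named integer), `fractions` (named
#'   numeric, over counted bases), `most_frequent` (character vector of
#'   tied maxima), `n_count` (number of `N`s), `length`.
#' @export
base_composition <- function(seq) {
  stopifnot(nzchar(seq))
  bases <- strsplit(toupper(seq), "")[[1]]
  if (!all(bases %in% c(DNA_BASES, "N"))) stop("invalid symbol in sequence")
  counts <- table(factor(bases, levels = DNA_BASES))
  counts <- setNames(as.integer(counts), DNA_BASES)
  total <- sum(counts)
  fractions <- if (total > 0) counts / total else setNames(rep(NA_real_, 4),
                                                           DNA_BASES)
  mx <- max(counts)
  list(counts = counts, fractions = fractions,
       most_frequent = DNA_BASES[counts == mx],
       n_count = sum(bases == "N"), length = length(bases))
}

#' Find maximal G-runs
#'
#' Maximal (non-overlapping, reported once at full extent) runs of `G`
#' of length at least `min_run`.
#'
#' @param seq DNA sequence (character scalar).
#' @param min_run minimum run length (>= 2), default 3 (G-triplets).
#' @return data.frame with `offset` (0-based) and `length`.
#' @export
find_g_runs <- function(seq, min_run = 3) {
  stopifnot(min_run >= 2)
  r <- rle(strsplit(toupper(seq), "")[[1]] == "G")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths  # 0-based
  keep <- r$values & r$lengths >= min_run
  data.frame(offset = starts[keep], length = r$lengths[keep])
}

#' Scan for ISE-like motifs by edit distance
#'
#' Finds windows of a sequence within `max_edits`
#' (substitutions/insertions/deletions, unit costs) of an ISE motif,
#' reporting the minimal distance per non-overlapping best window: all
#' windows of length within `max_edits` of the motif length are scored
#' with Levenshtein distance, then hits are selected greedily by
#' (distance, offset) skipping overlaps.
#'
#' @param seq DNA sequence (character scalar), at least as long as the
#'   motif.
#' @param motif the enhancer motif; default the 11-nt G-rich ISE
#'   `CAGGGGCTGGG`.
#' @param max_edits maximum edit distance, default 2.
#' @return data.frame with `offset` (0-based), `length` (window length),
#'   `distance`.
#' @export
ise_scan <- function(seq, motif = ISE_MOTIF, max_edits = 2) {
  seq <- toupper(seq); motif <- toupper(motif)
  m <- nchar(motif); n <- nchar(seq)
  if (m > n) stop("motif longer than sequence")
  cand <- list()
  widths <- max(1L, m - max_edits):(m + max_edits)
  for (w in widths) {
    if (w > n) next
    starts0 <- 0:(n - w)
    wins <- substr(rep(seq, length(starts0)), starts0 + 1L, starts0 + w)
    d <- as.integer(adist(wins, motif))
    ok <- d <= max_edits
    if (any(ok)) {
      cand[[length(cand) + 1L]] <- data.frame(
        offset = starts0[ok], length = w, distance = d[ok]
      )
    }
  }
  if (length(cand) == 0L) {
    return(data.frame(offset = integer(), length = integer(),
                      distance = integer()))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$distance, cand$offset, cand$length), , drop = FALSE]
  taken <- logical(0)
  picked <- integer(0)
  covered <- rep(FALSE, n)
  for (i in seq_len(nrow(cand))) {
    span <- (cand$offset[i] + 1L):(cand$offset[i] + cand$length[i])
    if (any(covered[span])) next
    covered[span] <- TRUE
    picked <- c(picked, i)
  }
  out <- cand[picked, , drop = FALSE]
  out <- out[order(out$offset), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mean G fraction by intron length class
#'
#' Classifies introns by [classify_length()] and reports the mean G
#' fraction and n per class. Empty classes are omitted with a warning.
#'
#' @param introns intron data.frame from [extract_introns()] (needs
#'   `length` and `sequence`).
#' @param threshold,short_max length-class bounds, see
#'   [classify_length()].
#' @return data.frame with `class`, `n`, `mean_g_fraction`.
#' @export
gcontent_by_class <- function(introns, threshold = 65, short_max = 85) {
  stopifnot(nrow(introns) >= 1)
  cls <- classify_length(introns$length, threshold, short_max)
  gfrac <- vapply(introns$sequence, function(s) {
    base_composition(s)$fractions[["G"]]
  }, numeric(1), USE.NAMES = FALSE)
  out <- do.call(rbind, lapply(c("ultra_short", "short", "other"),
                               function(k) {
    idx <- cls == k
    if (!any(idx)) return(NULL)
    data.frame(class = k, n = sum(idx), mean_g_fraction = mean(gfrac[idx]),
               stringsAsFactors = FALSE)
  }))
  present <- unique(cls)
  absent <- setdiff(c("ultra_short", "short", "other"), present)
  if (length(absent)) {
    warning("empty length class(es) omitted: ", paste(absent, collapse = ", "))
  }
  rownames(out) <- NULL
  out
}

#' Per-intron sequence feature table
#'
#' Composition, G-runs and ISE hits for each intron, one row per intron.
#'
#' @param introns intron data.frame from [extract_introns()].
#' @param motif,max_edits see [ise_scan()].
#' @param min_run see [find_g_runs()].
#' @return data.frame with `junction_id`, per-base fractions,
#'   `most_frequent` (comma-joined on ties), `n_g_runs`,
#'   `longest_g_run`, `n_ise_hits`, `best_ise_distance`.
#' @export
feature_table <- function(introns, motif = ISE_MOTIF, max_edits = 2,
                          min_run = 3) {
  rows <- lapply(seq_len(nrow(introns)), function(i) {
    s <- introns$sequence[i]
    comp <- base_composition(s)
    runs <- find_g_runs(s, min_run)
    ise <- if (nchar(s) >= nchar(motif)) ise_scan(s, motif, max_edits)
           else data.frame(distance = integer())
    data.frame(
      junction_id = intron_key(introns$transcript_id[i],
                               introns$intron_number[i]),
      frac_a = comp$fractions[["A"]], frac_c = comp$fractions[["C"]],
      frac_g = comp$fractions[["G"]], frac_t = comp$fractions[["T"]],
      most_frequent = paste(comp$most_frequent, collapse = ","),
      n_g_runs = nrow(runs),
      longest_g_run = if (nrow(runs)) max(runs$length) else 0L,
      n_ise_hits = nrow(ise),
      best_ise_distance = if (nrow(ise)) min(ise$distance) else NA_integer_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
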