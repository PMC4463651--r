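# orf_nmd: consequence of retaining one intron in its mRNA -- reading
# frame effect, premature termination codon (PTC) discovery by in-frame
# translation scan, and the NMD junction-distance rule.
#
# Convention: a model's CDS interval includes the stop codon, so the
# native stop occupies the last three CDS bases. The NMD rule: an mRNA is
# a likely nonsense-mediated-decay target when it carries a PTC more than
# `boundary` nt (50-55) upstream of the 3'-most exon-exon junction.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Reading-frame effect of retaining an intron
#'
#' UTR introns cannot shift the frame (`not_applicable_UTR`); a CDS intron
#' whose length is a multiple of three is `frame_preserving`; any other
#' CDS intron causes a `frameshift`.
#'
#' @param intron_length intron length(s), nt.
#' @param region `"CDS"`, `"UTR5"` or `"UTR3"` (vectorized).
#' @return character vector in `{"frame_preserving", "frameshift",
#'   "not_applicable_UTR"}`.
#' @export
frame_effect <- function(intron_length, region) {
  stopifnot(all(intron_length >= 1))
  ifelse(region %in% c("UTR5", "UTR3"), "not_applicable_UTR",
         ifelse(intron_length %% 3 == 0, "frame_preserving", "frameshift"))
}

# transcript-strand offset (0-based, spliced coordinates) of genomic base
# gpos within the model's exons
genomic_to_transcript <- function(model, gpos) {
  ex <- model$exons
  w <- ex[, 2] - ex[, 1]
  hit <- which(gpos >= ex[, 1] & gpos < ex[, 2])
  if (length(hit) != 1L) {
    stop("position ", gpos, " is not exonic in ", model$transcript_id)
  }
  off_plus <- sum(w[seq_len(hit - 1L)]) + (gpos - ex[hit, 1])
  if (model$strand == "+") off_plus else sum(w) - 1 - off_plus
}

#' Build the retention model for one intron
#'
#' Splices every intron except the target, producing the retained mRNA in
#' transcript orientation, the start-codon offset, the offsets of the
#' remaining exon-exon junctions, the retained intron's span, and the
#' native stop-codon offset mapped through the retention.
#'
#' @param model a [transcript_model] with a CDS (required for PTC
#'   scanning; models without CDS are allowed, `cds_start` is then `NA`).
#' @param genome genome [Biostrings::DNAStringSet].
#' @param intron_number 1-based intron ordinal in transcription order.
#' @return an object of class `retention_model`: list with
#'   `retained_mrna`, `cds_start`, `native_stop_offset`,
#'   `junction_offsets`, `intron_span` (`c(start, end)`, 0-based
#'   half-open), `target_region`, `intron_length`, `transcript_id`,
#'   `intron_number`.
#' @export
build_retention_model <- function(model, genome, intron_number) {
  introns <- extract_introns(model, genome)
  n_int <- nrow(introns)
  if (intron_number < 1L || intron_number > n_int) {
    stop("transcript ", model$transcript_id, " has no intron ", intron_number)
  }
  target <- introns[introns$intron_number == intron_number, ]
  mrna <- spliced_sequence(model, genome)
  w <- model$exons[, 2] - model$exons[, 1]
  # junction offsets in spliced coordinates, transcript order
  cum_plus <- cumsum(w)[-length(w)]
  junctions_spliced <- if (model$strand == "+") cum_plus
                       else sum(w) - rev(cum_plus)
  # junction i (transcript order) sits at junctions_spliced[i]
  j_t <- junctions_spliced[intron_number]
  len <- target$length
  retained <- paste0(substr(mrna, 1L, j_t), target$sequence,
                     substr(mrna, j_t + 1L, nchar(mrna)))
  other <- junctions_spliced[-intron_number]
  junction_offsets <- sort(ifelse(other > j_t, other + len, other))
  cds_start <- NA_integer_
  native_stop <- NA_integer_
  if (!is.null(model$cds)) {
    g_start <- if (model$strand == "+") model$cds[1] else model$cds[2] - 1
    g_last <- if (model$strand == "+") model$cds[2] - 1 else model$cds[1]
    cds_start <- genomic_to_transcript(model, g_start)
    cds_last <- genomic_to_transcript(model, g_last)
    native_stop <- cds_last - 2
    if (j_t <= cds_start) cds_start <- cds_start + len
    if (j_t <= native_stop) native_stop <- native_stop + len
  }
  structure(
    list(retained_mrna = retained, cds_start = cds_start,
         native_stop_offset = native_stop,
         junction_offsets = junction_offsets,
         intron_span = c(j_t, j_t + len),
         target_region = target$region, intron_length = len,
         transcript_id = model$transcript_id,
         intron_number = intron_number),
    class = "retention_model"
  )
}

#' Scan a retention model for a premature termination codon
#'
#' Translates in frame from the start codon and reports the first stop
#' codon that is not the annotated native stop. A stop inside the retained
#' intron's span is flagged `in_intron_stop`.
#'
#' @param rmodel a `retention_model` from [build_retention_model()].
#' @return list with `ptc_offset` (0-based offset of the PTC's first
#'   base, or `NA`), `in_intron_stop` (logical).
#' @export
scan_ptc <- function(rmodel) {
  stopifnot(inherits(rmodel, "retention_model"))
  if (is.na(rmodel$cds_start)) {
    return(list(ptc_offset = NA_integer_, in_intron_stop = FALSE))
  }
  s <- rmodel$retained_mrna
  cs <- rmodel$cds_start
  if (nchar(s) < cs + 3) stop("retained mRNA too short for CDS start")
  if (substr(s, cs + 1L, cs + 3L) != "ATG") {
    warning("no ATG at annotated CDS start of ", rmodel$transcript_id,
            "; scanning anyway")
  }
  for (off in seq(cs, nchar(s) - 3, by = 3)) {
    codon <- substr(s, off + 1L, off + 3L)
    if (codon %in% STOP_CODONS) {
      if (!is.na(rmodel$native_stop_offset) &&
          off == rmodel$native_stop_offset) {
        return(list(ptc_offset = NA_integer_, in_intron_stop = FALSE))
      }
      in_intron <- off >= rmodel$intron_span[1] &&
        off < rmodel$intron_span[2]
      return(list(ptc_offset = as.integer(off), in_intron_stop = in_intron))
    }
  }
  list(ptc_offset = NA_integer_, in_intron_stop = FALSE)
}

#' NMD junction-distance rule
#'
#' An mRNA is called an NMD target iff a PTC exists, at least one
#' exon-exon junction lies downstream of it, and the 3'-most junction is
#' more than `boundary` nt downstream of the PTC. Monotone in `boundary`:
#' a target at 55 is a target at 50.
#'
#' @param ptc_offset 0-based PTC offset, or `NA`/`NULL` when no PTC.
#' @param junction_offsets offsets of exon-exon junctions in the retained
#'   mRNA.
#' @param boundary distance rule in nt, in `[50, 55]`; default 50 (the
#'   permissive end of the conventional 50-55 nt rule).
#' @return logical.
#' @export
nmd_classify <- function(ptc_offset, junction_offsets, boundary = 50) {
  stopifnot(boundary >= 50, boundary <= 55)
  if (is.null(ptc_offset) || length(ptc_offset) == 0L || is.na(ptc_offset)) {
    return(FALSE)
  }
  if (length(junction_offsets) == 0L) return(FALSE)
  last_j <- max(junction_offsets)
  (last_j > ptc_offset) && (last_j - ptc_offset > boundary)
}

#' Retention consequences for a set of introns
#'
#' For each intron, builds the retention model (all other introns
#' spliced), applies [frame_effect()], [scan_ptc()] and [nmd_classify()],
#' and tabulates summary counts. Records with inconsistent annotation are
#' reported as errors in the table and the run continues.
#'
#' @param introns intron data.frame from [extract_introns()].
#' @param models named list of [transcript_model] objects.
#' @param genome genome [Biostrings::DNAStringSet].
#' @param boundary NMD distance rule, see [nmd_classify()].
#' @return list with `per_intron` (data.frame: `transcript_id`,
#'   `intron_number`, `region`, `frame_effect`, `in_intron_stop`,
#'   `ptc_offset`, `distance_to_last_junction`, `nmd_target`, `error`)
#'   and `summary` (named counts: `n_cds`, `n_utr`, `n_frame_preserving`,
#'   `n_frameshift`, `n_nmd_target`).
#' @export
retention_report <- function(introns, models, genome, boundary = 50) {
  rows <- lapply(seq_len(nrow(introns)), function(i) {
    tid <- introns$transcript_id[i]
    num <- introns$intron_number[i]
    base <- data.frame(
      transcript_id = tid, intron_number = num,
      region = introns$region[i],
      frame_effect = frame_effect(introns$length[i], introns$region[i]),
      in_intron_stop = NA, ptc_offset = NA_integer_,
      distance_to_last_junction = NA_integer_, nmd_target = FALSE,
      error = NA_character_, stringsAsFactors = FALSE
    )
    res <- tryCatch({
      mod <- models[[tid]]
      if (is.null(mod)) stop("no transcript model for ", tid)
      rm_ <- build_retention_model(mod, genome, num)
      ptc <- scan_ptc(rm_)
      base$in_intron_stop <- ptc$in_intron_stop
      base$ptc_offset <- ptc$ptc_offset
      if (!is.na(ptc$ptc_offset) && length(rm_$junction_offsets) > 0L) {
        base$distance_to_last_junction <-
          as.integer(max(rm_$junction_offsets) - ptc$ptc_offset)
      }
      base$nmd_target <- nmd_classify(ptc$ptc_offset, rm_$junction_offsets,
                                      boundary)
      base
    }, error = function(e) {
      base$error <- conditionMessage(e)
      base
    })
    res
  })
  per_intron <- do.call(rbind, rows)
  rownames(per_intron) <- NULL
  summary <- c(
    n_cds = sum(per_intron$region == "CDS"),
    n_utr = sum(per_intron$region %in% c("UTR5", "UTR3")),
    n_frame_preserving = sum(per_intron$frame_effect == "frame_preserving"),
    n_frameshift = sum(per_intron$frame_effect == "frameshift"),
    n_nmd_target = sum(per_intron$nmd_target)
  )
  list(per_intron = per_intron, summary = summary)
}

#' Load the per-intron retention facts for the 22 conserved ultra-short
#' introns
#'
#' A packaged fixture encoding, for each of the 22 conserved human
#' ultra-short introns (SN1-SN22), the facts that determine its NMD
#' status on retention: host region (CDS/UTR), intron length, whether the
#' retained intron itself carries an in-frame stop, and the position
#' class of the resulting PTC relative to the 3'-most exon-exon junction
#' (`upstream_far`, `downstream_of_last_junction`, or `no_ptc`).
#'
#' @param path optional path to an alternative TSV with the same columns.
#' @return data.frame with columns `sn`, `length`, `region`,
#'   `in_intron_stop`, `ptc_class`.
#' @export
load_nmd_facts <- function(path = NULL) {
  path <- path %||% system.file("extdata", "nmd_stated_facts.tsv",
                                package = "usintrons", mustWork = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sn", "length", "region", "in_intron_stop", "ptc_class")
  if (!all(need %in% names(df))) {
    stop("facts fixture missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  stopifnot(!anyDuplicated(df$sn),
            all(df$ptc_class %in% c("upstream_far",
                                    "downstream_of_last_junction",
                                    "no_ptc")))
  df
}

#' Apply the NMD rule to encoded per-intron facts
#'
#' Converts each intron's PTC position class into representative
#' (PTC offset, junction offsets) coordinates and runs [nmd_classify()],
#' so the classification is produced by the rule itself, not read off the
#' fixture.
#'
#' @param facts data.frame from [load_nmd_facts()].
#' @param boundary NMD distance rule, see [nmd_classify()].
#' @return `facts` with an added logical `nmd_target` column.
#' @export
nmd_from_facts <- function(facts, boundary = 50) {
  facts$nmd_target <- vapply(seq_len(nrow(facts)), function(i) {
    cls <- facts$ptc_class[i]
    if (cls == "no_ptc") {
      nmd_classify(NA_integer_, c(100, 400), boundary)
    } else if (cls == "downstream_of_last_junction") {
      # PTC past the 3'-most junction
      nmd_classify(500L, c(100, 400), boundary)
    } else {
      # PTC well upstream (beyond any boundary in [50, 55]) of the
      # 3'-most junction
      nmd_classify(300L, c(100, 400), boundary)
    }
  }, logical(1))
  facts
}
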