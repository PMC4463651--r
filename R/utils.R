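# Internal helpers shared across modules. Coordinates are 0-based,
# half-open everywhere inside the package; conversion to/from 1-based
# formats happens only at I/O boundaries.

`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

# substring by 0-based half-open interval
substr0 <- function(x, start0, end0) substr(x, start0 + 1L, end0)

# random DNA with per-base probabilities; vector of one string
random_dna <- function(n, prob = rep(0.25, 4)) {
  paste(sample(DNA_BASES, n, replace = TRUE, prob = prob), collapse = "")
}

# split "transcript|intronN" keys used in BED names and hit tables
split_intron_key <- function(key) {
  parts <- strsplit(key, "|", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    stop("malformed intron key (expected 'transcript|intronNumber'): ",
         paste(key[bad], collapse = ", "))
  }
  data.frame(
    transcript_id = vapply(parts, `[`, character(1), 1L),
    intron_number = as.integer(vapply(parts, `[`, character(1), 2L)),
    stringsAsFactors = FALSE
  )
}

intron_key <- function(transcript_id, intron_number) {
  paste0(transcript_id, "|", intron_number)
}

stopifnot_scalar_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    stop(what, " must be a non-empty string")
  }
}
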