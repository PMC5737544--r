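#' Construct a 3'-UTR reference object
#'
#' Holds the UTR sequence together with its coordinate conventions. All
#' coordinates in the package are 0-based with half-open intervals
#' `[start, end)`, so a deletion of length L starting at `start` removes
#' reference bases `start .. start+L-1` and BED output needs no shifting.
#'
#' @param name reference (amplicon) name, used as the SAM/FASTA record name.
#' @param sequence DNA string over A/C/G/T; lower case and U are normalized.
#' @param polya_site 0-based position of the cleavage/polyadenylation site
#'   (one past the last transcribed base), or `NULL` when unknown.
#' @param polya_signal half-open 6-nt interval `c(start, end)` of the polyA
#'   signal hexamer, or `NULL`. Supply manually when no canonical AATAAA is
#'   found (see [find_polya_signal()]).
#' @param stop_codon_end 0-based position where the 3'-UTR begins; 0 for a
#'   UTR-only reference.
#' @return An object of class `utr_reference`: a list with fields `name`,
#'   `sequence`, `length`, `polya_site`, `polya_signal`, `stop_codon_end`.
#' @export
utr_reference <- function(name, sequence, polya_site = NULL,
                          polya_signal = NULL, stop_codon_end = 0L) {
  sequence <- normalize_sequence(sequence)
  len <- nchar(sequence)
  if (!is.null(polya_site)) {
    polya_site <- as.integer(polya_site)
    if (polya_site < 0L || polya_site > len)
      stop("polya_site must lie in [0, length]")
  }
  if (!is.null(polya_signal)) {
    polya_signal <- as.integer(polya_signal)
    if (length(polya_signal) != 2L || polya_signal[2] - polya_signal[1] != 6L)
      stop("polya_signal must be a half-open interval of width 6")
    if (polya_signal[1] < 0L || polya_signal[2] > len)
      stop("polya_signal must lie within the reference")
  }
  structure(
    list(name = as.character(name), sequence = sequence, length = len,
         polya_site = polya_site, polya_signal = polya_signal,
         stop_codon_end = as.integer(stop_codon_end)),
    class = "utr_reference")
}

# Uppercase, U->T, then reject anything outside A/C/G/T naming the first
# offending 0-based position.
normalize_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- chartr("u", "t", sequence)
  s <- toupper(s)
  s <- chartr("U", "T", s)
  bad <- regexpr("[^ACGT]", s)
  if (bad != -1L)
    stop(sprintf("invalid character '%s' at position %d (0-based); only A/C/G/T/U allowed",
                 substr(s, bad, bad), as.integer(bad) - 1L))
  s
}

#' @export
print.utr_reference <- function(x, ...) {
  cat(sprintf("utr_reference '%s': %d nt", x$name, x$length))
  if (!is.null(x$polya_site)) cat(sprintf(", polyA site %d", x$polya_site))
  if (!is.null(x$polya_signal))
    cat(sprintf(", polyA signal [%d,%d)", x$polya_signal[1], x$polya_signal[2]))
  cat("\n")
  invisible(x)
}

#' Load a 3'-UTR reference from FASTA
#'
#' Reads a single-record FASTA (or a named record from a multi-record file),
#' normalizes it (uppercase, RNA U to DNA T) and validates the alphabet.
#'
#' @param path FASTA file.
#' @param record record name to select when the file holds several.
#' @param ... passed to [utr_reference()] (`polya_site`, `polya_signal`,
#'   `stop_codon_end`).
#' @return A [utr_reference()] object.
#' @export
load_reference <- function(path, record = NULL, ...) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA: ", path)
  if (is.null(record)) {
    if (length(set) > 1L)
      stop("FASTA has ", length(set), " records; select one with 'record='")
    idx <- 1L
  } else {
    # FASTA descriptions may carry comments after the name
    ids <- sub("\\s.*$", "", names(set))
    idx <- match(record, ids)
    if (is.na(idx)) stop("record '", record, "' not found in ", path)
  }
  utr_reference(name = sub("\\s.*$", "", names(set)[idx]),
                sequence = as.character(set[[idx]]), ...)
}

#' Write a reference to FASTA
#'
#' @param ref a [utr_reference()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(ref, path) {
  x <- Biostrings::DNAStringSet(stats::setNames(ref$sequence, ref$name))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Locate the canonical polyA signal hexamer
#'
#' Searches for AATAAA (the DNA form of AAUAAA) whose six bases lie entirely
#' within 10-35 nt upstream of the cleavage/polyA site: hexamer start `s`
#' must satisfy `polya_site - 35 <= s` and `s + 6 <= polya_site - 10`. When
#' several hexamers qualify the 5'-most is returned, which keeps the distal
#' guide cut as far upstream of the signal as possible. When none is found
#' the caller must supply the signal position manually (config key
#' `polya_signal`); no alternative-signal prediction is attempted.
#'
#' @param ref a [utr_reference()].
#' @param polya_site 0-based cleavage site; defaults to the one stored in
#'   `ref`.
#' @param strict if `TRUE`, a `polya_site` closer than 35 nt to the 5' end is
#'   an error; otherwise the search window is truncated at position 0.
#' @return Integer vector `c(start, end)` (half-open) or `NULL` if absent.
#' @export
find_polya_signal <- function(ref, polya_site = ref$polya_site, strict = FALSE) {
  if (is.null(polya_site)) stop("polya_site is required")
  polya_site <- as.integer(polya_site)
  if (polya_site > ref$length) stop("polya_site beyond reference end")
  if (polya_site < 35L && strict)
    stop("polya_site < 35: upstream search window extends past the reference start")
  lo <- max(0L, polya_site - 35L)
  hi <- polya_site - 10L - 6L  # latest allowed hexamer start
  if (hi < lo) return(NULL)
  m <- Biostrings::matchPattern("AATAAA", Biostrings::DNAString(ref$sequence))
  starts0 <- Biostrings::start(m) - 1L
  ok <- starts0 >= lo & starts0 <= hi
  if (!any(ok)) return(NULL)
  s <- min(starts0[ok])
  c(start = s, end = s + 6L)
}
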