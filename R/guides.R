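#' Enumerate all SpCas9 guide sites in a 3'-UTR
#'
#' Scans both strands for 20-nt protospacers immediately followed (5'->3' on
#' their own strand) by an NGG PAM, the SpCas9 requirement. On the reference
#' (+) strand a site is `[s, s+20)` protospacer + `[s+20, s+23)` PAM with G at
#' s+21 and s+22; on the (-) strand the PAM appears as CCN at `[q, q+3)` on
#' the reference with the protospacer at `[q+3, q+23)`. The blunt Cas9 cut
#' falls between protospacer positions 17 and 18 (3 bp 5' of the PAM), so
#' `cut_position` is `s+17` on + and `q+6` on -; it is the 0-based reference
#' coordinate of the first base 3' of the cut on the + strand, suitable
#' directly as a half-open deletion endpoint.
#'
#' No uniqueness, GC or synthesis filters are applied: every NGG site yields
#' exactly one guide.
#'
#' @param ref a [utr_reference()].
#' @return data.frame with one row per site, columns `protospacer` (5'->3' on
#'   its own strand), `strand` (+/-), `proto_start`, `proto_end`, `pam_start`,
#'   `pam_end` (0-based half-open reference coordinates), `cut_position`;
#'   sorted by `cut_position` then strand. Zero rows if the sequence is too
#'   short or has no PAM.
#' @export
enumerate_guides <- function(ref) {
  s <- ref$sequence
  L <- ref$length
  empty <- data.frame(protospacer = character(), strand = character(),
                      proto_start = integer(), proto_end = integer(),
                      pam_start = integer(), pam_end = integer(),
                      cut_position = integer(), stringsAsFactors = FALSE)
  if (L < 23L) return(empty)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  starts <- 0:(L - 23L)                      # candidate protospacer starts, 0-based
  plus <- starts[ch[starts + 22L] == "G" & ch[starts + 23L] == "G"]
  minus <- starts[ch[starts + 1L] == "C" & ch[starts + 2L] == "C"]
  rows <- list(empty)
  if (length(plus)) {
    rows$plus <- data.frame(
      protospacer = substring(s, plus + 1L, plus + 20L),
      strand = "+",
      proto_start = plus, proto_end = plus + 20L,
      pam_start = plus + 20L, pam_end = plus + 23L,
      cut_position = plus + 17L, stringsAsFactors = FALSE)
  }
  if (length(minus)) {
    rows$minus <- data.frame(
      protospacer = revcomp(substring(s, minus + 4L, minus + 23L)),
      strand = "-",
      proto_start = minus + 3L, proto_end = minus + 23L,
      pam_start = minus, pam_end = minus + 3L,
      cut_position = minus + 6L, stringsAsFactors = FALSE)
  }
  g <- do.call(rbind, rows)
  g <- g[order(g$cut_position, g$strand), , drop = FALSE]
  rownames(g) <- NULL
  g
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Design a dual-guide excision pair for a 3'-UTR
#'
#' Picks the two guides whose simultaneous cuts excise as much of the UTR as
#' possible without touching the coding sequence or the polyA signal: the
#' proximal guide is on the antisense strand with its PAM entirely within the
#' 3'-UTR (at or after `stop_codon_end`) and the smallest qualifying cut
#' position; the distal guide is on the sense strand with its PAM entirely
#' 5' of the polyA signal and the largest cut position. The expected deletion
#' is the half-open interval between the two blunt cuts.
#'
#' @param ref a [utr_reference()] with a known `polya_signal`.
#' @param guides guide table from [enumerate_guides()].
#' @return list with `proximal` and `distal` (single-row guide data.frames)
#'   and `expected_deletion = c(start, end)`.
#' @export
design_dual_pair <- function(ref, guides) {
  if (is.null(ref$polya_signal))
    stop("polya_signal unknown: run find_polya_signal() or supply it manually")
  sce <- ref$stop_codon_end
  prox_ok <- guides$strand == "-" &
    guides$pam_start >= sce &
    guides$cut_position >= sce
  if (!any(prox_ok))
    stop("no valid proximal guide: no antisense-strand site with PAM inside the 3'-UTR")
  dist_ok <- guides$strand == "+" &
    guides$pam_end <= ref$polya_signal[1]
  if (!any(dist_ok))
    stop("no valid distal guide: no sense-strand site with PAM upstream of the polyA signal")
  proximal <- guides[prox_ok, , drop = FALSE]
  proximal <- proximal[which.min(proximal$cut_position), , drop = FALSE]
  distal <- guides[dist_ok, , drop = FALSE]
  distal <- distal[which.max(distal$cut_position), , drop = FALSE]
  if (proximal$cut_position >= distal$cut_position)
    stop("no valid distal guide: all sense-strand cuts lie at or before the proximal cut")
  del <- c(start = proximal$cut_position, end = distal$cut_position)
  if (del["start"] < sce || del["end"] > ref$polya_signal[1])
    stop("internal error: expected deletion violates placement constraints")
  list(proximal = proximal, distal = distal, expected_deletion = del)
}

#' Write a guide table to TSV
#'
#' @param guides data.frame from [enumerate_guides()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_guides <- function(guides, path) {
  utils::write.table(guides, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
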