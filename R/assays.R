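#' Reporter 3'-UTR effect
#'
#' Effect of a 3'-UTR on reporter mRNA level: per-replicate GFP signal
#' normalized by the LNGFR reference transgene, divided by the mean
#' normalized GFP of the empty (no-UTR) reporter. Values below 1 mean the
#' UTR lowers reporter mRNA.
#'
#' @param test data.frame with columns `target_level` (GFP) and
#'   `reference_level` (LNGFR), one row per replicate.
#' @param empty same layout for the empty-reporter replicates.
#' @return list `effect` (per test replicate), `mean`, `sd`.
#' @export
reporter_effect <- function(test, empty) {
  tn <- normalized_level(test)
  en <- normalized_level(empty)
  eff <- tn / mean(en)
  list(effect = eff, mean = mean(eff), sd = stats::sd(eff))
}

normalized_level <- function(d) {
  stopifnot(all(c("target_level", "reference_level") %in% names(d)),
            nrow(d) >= 1L)
  if (any(d$reference_level <= 0)) stop("reference_level must be > 0")
  if (any(d$target_level < 0)) stop("target_level must be >= 0")
  d$target_level / d$reference_level
}

#' mRNA decay: fraction remaining after the chase
#'
#' 4sU pulse-chase readout: normalized target RNA at 4 h divided by
#' normalized target RNA at 0 h, each normalized to GAPDH at its own
#' timepoint. Below 1 = the transcript decays faster than the reference
#' gene; above 1 = more stable.
#'
#' @param t0,t4 data.frames with `target_level` and `reference_level`
#'   (GAPDH) per replicate; replicates are paired by row when the tables
#'   have equal rows, otherwise each t4 replicate is divided by the mean t0
#'   normalized level.
#' @return list `fraction` (per replicate), `mean`, `sd`.
#' @export
decay_fraction <- function(t0, t4) {
  n0 <- normalized_level(t0)
  n4 <- normalized_level(t4)
  if (any(n0 == 0)) stop("zero normalized level at t0")
  frac <- if (length(n0) == length(n4)) n4 / n0 else n4 / mean(n0)
  list(fraction = frac, mean = mean(frac), sd = stats::sd(frac))
}

#' New transcription after a 4sU pulse
#'
#' Newly synthesized target RNA captured during a 20-min 4sU pulse,
#' normalized to GAPDH, relative to the mean normalized pulse signal of
#' wild-type cells. The conventional presentation as a percent reduction is
#' `100 * (1 - ratio)` (a ratio of 0.18 is an 82% reduction in
#' transcription).
#'
#' @param targeted data.frame with `target_level`, `reference_level` per
#'   replicate for the edited cells.
#' @param wildtype same layout for wild-type cells.
#' @return list `ratio` (per targeted replicate), `reduction_percent`,
#'   `mean`, `sd`.
#' @export
new_transcription_ratio <- function(targeted, wildtype) {
  tn <- normalized_level(targeted)
  wt <- mean(normalized_level(wildtype))
  if (wt == 0) stop("zero wild-type mean normalized level")
  ratio <- tn / wt
  list(ratio = ratio, reduction_percent = 100 * (1 - ratio),
       mean = mean(ratio), sd = stats::sd(ratio))
}

#' Enhancer activity of a candidate sequence
#'
#' Transcriptional output per integrated reporter copy: normalized GFP mRNA
#' divided by normalized GFP DNA, both normalized by the same reference
#' gene. With a minimal-promoter-only control the fold change over the
#' control's mean activity is also reported.
#'
#' @param mrna data.frame with `target_level` (GFP mRNA) and
#'   `reference_level` per replicate.
#' @param dna same layout for GFP DNA; paired with `mrna` by row.
#' @param control optional list as returned by this function (or numeric
#'   activities) for the minimal-promoter-only control.
#' @return list `activity` (per replicate), `mean`, `sd`, and `fold_change`
#'   when a control is supplied.
#' @export
enhancer_activity <- function(mrna, dna, control = NULL) {
  m <- normalized_level(mrna)
  d <- normalized_level(dna)
  if (any(d == 0)) stop("zero normalized DNA level")
  if (length(m) != length(d)) stop("mRNA and DNA replicates must be paired")
  act <- m / d
  out <- list(activity = act, mean = mean(act), sd = stats::sd(act))
  if (!is.null(control)) {
    ctrl <- if (is.list(control)) control$activity else control
    out$fold_change <- mean(act) / mean(ctrl)
  }
  out
}
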