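#' Distinct deletions involving a position
#'
#' A deletion involves a position when the position lies inside its deleted
#' half-open interval `[start, start + length)` — i.e. the base was actually
#' removed; undeleted bases adjacent to the junction do not count.
#'
#' @param dels distinct-deletion data.frame.
#' @param position 0-based reference position.
#' @return the subset of `dels` involving the position.
#' @export
deletions_at <- function(dels, position) {
  dels[dels$start <= position & position < dels$start + dels$length, ,
       drop = FALSE]
}

#' Bootstrap percentile confidence interval for a median
#'
#' Standard nonparametric bootstrap: B resamples with replacement of the
#' same size, medians of each, percentile interval at the requested level.
#'
#' @param values numeric observations (the resampling unit; here, one value
#'   per distinct deletion).
#' @param B number of bootstrap resamples; `B = 0` skips the interval
#'   (returns NA bounds).
#' @param level confidence level.
#' @param seed optional RNG seed for reproducibility.
#' @return named list `median`, `ci_low`, `ci_high`.
#' @export
bootstrap_median_ci <- function(values, B = 10000L, level = 0.95,
                                seed = NULL) {
  stopifnot(length(values) >= 1L, level > 0, level < 1)
  if (!is.null(seed)) set.seed(seed)
  med <- stats::median(values)
  if (B <= 0L) return(list(median = med, ci_low = NA_real_, ci_high = NA_real_))
  n <- length(values)
  res <- matrix(values[sample.int(n, n * B, replace = TRUE)], nrow = n)
  meds <- apply(res, 2L, stats::median)
  qs <- stats::quantile(meds, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 7)
  list(median = med, ci_low = qs[1], ci_high = qs[2])
}

#' Position-wise Mann-Whitney test
#'
#' Compares the distribution of r for deletions involving a position against
#' r for all other retained distinct deletions, two-sided. The p-value is
#' exact (enumeration) when the smaller group has at most 8 values and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity correction is used.
#'
#' @param values_at r values of deletions involving the position.
#' @param values_elsewhere r values of all other retained deletions.
#' @return two-sided p-value, or `NA` when either group is empty (the
#'   position is then not analyzed).
#' @export
position_test <- function(values_at, values_elsewhere) {
  if (!length(values_at) || !length(values_elsewhere)) return(NA_real_)
  mw_test(values_at, values_elsewhere)
}

#' Build the per-nucleotide activity map
#'
#' For every reference position: the number of retained distinct deletions
#' whose deleted interval contains it; positions with fewer than
#' `min_deletions` are not analyzed. Analyzed positions get the median r of
#' those deletions (and the median normalized r for reporting), a bootstrap
#' percentile CI for the median of r, and a two-sided Mann-Whitney p-value
#' against all other retained deletions. Bonferroni correction uses the
#' family of analyzed positions only (tests never performed are not part of
#' the family); `significant` means the corrected p is at or below `alpha`.
#' Runs of adjacent significant positions are merged into intervals.
#'
#' @param dels retained deletions with `r` and `normalized_r` from
#'   [compute_ratios()].
#' @param ref a [utr_reference()] (or an integer reference length).
#' @param alpha family-wise significance level.
#' @param B bootstrap resamples per position (`0` skips CIs).
#' @param seed RNG seed for the bootstrap stream.
#' @param min_deletions minimum distinct deletions for a position to be
#'   analyzed.
#' @return list with `positions` (data.frame `position`, `n_deletions`,
#'   `analyzed`, `median_r`, `median_normalized_r`, `ci_low`, `ci_high`,
#'   `p_value`, `p_bonferroni`, `significant`), `significant_intervals`
#'   (data.frame `start`, `end`, half-open), `n_analyzed`, and `alpha`.
#' @export
build_map <- function(dels, ref, alpha = 0.05, B = 1000L, seed = NULL,
                      min_deletions = 4L) {
  L <- if (inherits(ref, "utr_reference")) ref$length else as.integer(ref)
  stopifnot(alpha > 0, alpha < 1)
  pos <- 0:(L - 1L)
  out <- data.frame(position = pos, n_deletions = 0L, analyzed = FALSE,
                    median_r = NA_real_, median_normalized_r = NA_real_,
                    ci_low = NA_real_, ci_high = NA_real_,
                    p_value = NA_real_, p_bonferroni = NA_real_,
                    significant = FALSE)
  if (nrow(dels)) {
    ir <- IRanges::IRanges(start = dels$start + 1L, width = dels$length)
    cov <- IRanges::coverage(ir, width = L)
    out$n_deletions <- as.integer(cov)
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = pos + 1L, width = 1L), ir)
    at <- split(S4Vectors::subjectHits(hits),
                factor(S4Vectors::queryHits(hits), levels = seq_len(L)))
  }
  out$analyzed <- out$n_deletions >= min_deletions & out$n_deletions < nrow(dels)
  n_analyzed <- sum(out$analyzed)
  if (n_analyzed == 0L) {
    warning("no positions with >= ", min_deletions, " distinct deletions")
    return(list(positions = out,
                significant_intervals = data.frame(start = integer(),
                                                   end = integer()),
                n_analyzed = 0L, alpha = alpha))
  }
  if (!is.null(seed)) set.seed(seed)
  for (i in which(out$analyzed)) {
    idx <- at[[i]]
    r_at <- dels$r[idx]
    r_else <- dels$r[-idx]
    bs <- bootstrap_median_ci(r_at, B = B)
    out$median_r[i] <- bs$median
    out$median_normalized_r[i] <- stats::median(dels$normalized_r[idx])
    out$ci_low[i] <- bs$ci_low
    out$ci_high[i] <- bs$ci_high
    out$p_value[i] <- position_test(r_at, r_else)
  }
  out$p_bonferroni <- pmin(1, out$p_value * n_analyzed)
  out$significant <- !is.na(out$p_bonferroni) & out$p_bonferroni <= alpha
  sig <- out$position[out$significant]
  si <- if (length(sig)) {
    red <- IRanges::reduce(IRanges::IRanges(start = sig + 1L, width = 1L))
    data.frame(start = IRanges::start(red) - 1L, end = IRanges::end(red))
  } else data.frame(start = integer(), end = integer())
  list(positions = out, significant_intervals = si,
       n_analyzed = n_analyzed, alpha = alpha)
}

#' Plot the activity track of a position map
#'
#' Median normalized r per analyzed position with its (normalized) bootstrap
#' band; significant positions highlighted.
#'
#' @param map result of [build_map()].
#' @param reference_ratio used to put the CI (computed on r) on the
#'   normalized scale; 1 leaves it on the r scale.
#' @param ... passed to [plot()].
#' @return invisibly, the plotted data.frame.
#' @export
plot_position_map <- function(map, reference_ratio = 1, ...) {
  p <- map$positions[map$positions$analyzed, , drop = FALSE]
  if (!nrow(p)) stop("no analyzed positions to plot")
  graphics::plot(p$position, p$median_normalized_r, type = "n",
                 xlab = "3'-UTR position (nt)",
                 ylab = "median normalized r", ...)
  if (!all(is.na(p$ci_low)))
    graphics::segments(p$position, p$ci_low / reference_ratio,
                       p$position, p$ci_high / reference_ratio,
                       col = "grey70")
  graphics::points(p$position, p$median_normalized_r, pch = 16, cex = 0.4,
                   col = ifelse(p$significant, "red", "black"))
  graphics::abline(h = 1, lty = 2)
  invisible(p)
}
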