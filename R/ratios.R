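#' Group fragment calls into distinct deletions
#'
#' All fragments sharing the same (start, length) deleted interval form one
#' "distinct deletion" allele, with fragment counts accumulated per library.
#' Alleles observed only in the RNA library get `dna_count` 0; they carry no
#' ratio and are flagged (`rna_only`) rather than assigned an infinite r.
#'
#' @param fragments row-bound [call_fragments()] output for the DNA and RNA
#'   libraries.
#' @return data.frame `start`, `length`, `dna_count`, `rna_count`,
#'   `rna_only`, sorted by `start` then `length`.
#' @export
group_distinct <- function(fragments) {
  del <- fragments[fragments$status == "deletion", , drop = FALSE]
  if (!nrow(del))
    return(data.frame(start = integer(), length = integer(),
                      dna_count = integer(), rna_count = integer(),
                      rna_only = logical()))
  key <- paste(del$start, del$length)
  dna <- tapply(del$library == "DNA", key, sum)
  rna <- tapply(del$library == "RNA", key, sum)
  sk <- strsplit(names(dna), " ", fixed = TRUE)
  out <- data.frame(start = as.integer(vapply(sk, `[`, "", 1L)),
                    length = as.integer(vapply(sk, `[`, "", 2L)),
                    dna_count = as.integer(dna),
                    rna_count = as.integer(rna))
  out$rna_only <- out$dna_count == 0L
  out <- out[order(out$start, out$length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-library fragment totals and reference counts
#'
#' @param fragments row-bound [call_fragments()] output.
#' @return data.frame `library`, `total_fragments`, `reference_fragments`.
#' @export
library_summary <- function(fragments) {
  libs <- c("DNA", "RNA")
  data.frame(
    library = libs,
    total_fragments = vapply(libs, function(l)
      sum(fragments$library == l), integer(1)),
    reference_fragments = vapply(libs, function(l)
      sum(fragments$library == l & fragments$status == "reference"),
      integer(1)),
    row.names = NULL)
}

#' Apply the abundance and length filters to distinct deletions
#'
#' A distinct deletion is kept only if it is sufficiently frequent to yield a
#' reliable ratio and its length lies in the analyzable window. In the
#' default `per-library` mode a deletion with `count/total <= min_per_1e7 *
#' 1e-7` in either library is eliminated (the boundary itself is
#' eliminated). The `absolute` mode instead requires the fixed per-library
#' minima (`min_rna` RNA and `min_dna` DNA fragments).
#'
#' @param dels [group_distinct()] output.
#' @param summary [library_summary()] output (for the per-library totals).
#' @param min_per_1e7 elimination threshold in reads per 1e7 reads.
#' @param min_len,max_len analyzable deletion-length window in nt.
#' @param mode `"per-library"` or `"absolute"`.
#' @param min_rna,min_dna absolute-mode minimum fragment counts.
#' @return the retained subset of `dels`.
#' @export
filter_abundance <- function(dels, summary, min_per_1e7 = 6.5,
                             min_len = 3L, max_len = 29L,
                             mode = c("per-library", "absolute"),
                             min_rna = 8L, min_dna = 16L) {
  mode <- match.arg(mode)
  if (!nrow(dels)) return(dels)
  tot <- stats::setNames(summary$total_fragments, summary$library)
  if (any(tot <= 0)) stop("library totals must be positive")
  keep_len <- dels$length >= min_len & dels$length <= max_len
  if (mode == "per-library") {
    thr <- min_per_1e7 / 1e7
    keep <- dels$dna_count / tot[["DNA"]] > thr &
            dels$rna_count / tot[["RNA"]] > thr
  } else {
    keep <- dels$dna_count >= min_dna & dels$rna_count >= min_rna
  }
  out <- dels[keep & keep_len, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compute RNA/DNA count ratios
#'
#' Adds to each retained distinct deletion its count ratio
#' `r = rna_count / dna_count` and `normalized_r = r / reference_ratio`,
#' where the reference ratio is the same RNA/DNA ratio over fragments with
#' no qualifying deletion. Also computes the pooled `total_r`
#' (sum of RNA counts / sum of DNA counts over retained deletions); in a
#' well-behaved screen this is close to the reference ratio.
#'
#' @param dels retained deletions from [filter_abundance()].
#' @param summary [library_summary()] output.
#' @return list with `deletions` (plus `r`, `normalized_r` columns) and
#'   `summary` (plus `reference_ratio`, `total_r`).
#' @export
compute_ratios <- function(dels, summary) {
  ref <- stats::setNames(summary$reference_fragments, summary$library)
  if (ref[["DNA"]] == 0L)
    stop("reference_ratio undefined: zero DNA reference fragments")
  reference_ratio <- ref[["RNA"]] / ref[["DNA"]]
  if (nrow(dels) && any(dels$dna_count < 1L))
    stop("retained deletions must have dna_count >= 1")
  dels$r <- dels$rna_count / dels$dna_count
  dels$normalized_r <- dels$r / reference_ratio
  summary$reference_ratio <- reference_ratio
  summary$total_r <- if (nrow(dels)) sum(dels$rna_count) / sum(dels$dna_count)
                     else NA_real_
  list(deletions = dels, summary = summary)
}

# Mann-Whitney engine shared by the pilot and position tests: exact by
# enumeration when both groups are small and untied, else normal
# approximation with tie and continuity correction.
mw_test <- function(x, y, exact_max = 8L) {
  no_ties <- !anyDuplicated(c(x, y))
  use_exact <- min(length(x), length(y)) <= exact_max && no_ties
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = use_exact,
                       correct = TRUE)$p.value)
}

#' Pilot three-class deletion analysis around a single element
#'
#' Classifies distinct deletions relative to a candidate cis-element
#' interval: deletions fully inside the element (`dElem`), deletions that
#' strictly contain the whole element plus flanking sequence (`dElemPlus`),
#' and control deletions disjoint from the element (`dC`). Deletions
#' straddling exactly one element boundary belong to no class and are
#' excluded. Within each class the `top_n` most abundant deletions (by DNA
#' fragment count) are selected, their ratios normalized to the no-deletion
#' reference ratio, and each element class is compared with the control
#' class by a two-sided Mann-Whitney U-test.
#'
#' @param dels deletions with `r` from [compute_ratios()].
#' @param reference_ratio no-deletion RNA/DNA ratio.
#' @param element half-open interval `c(start, end)` of the element.
#' @param top_n deletions per class entering the comparison.
#' @return list with `classes` (the input plus `class` and `selected`
#'   columns), `ratios` (named list of selected normalized ratios per
#'   class), and `p_values` (`elem_vs_control`, `elem_plus_vs_control`).
#' @export
pilot_class_analysis <- function(dels, reference_ratio, element, top_n = 9L) {
  es <- element[1]; ee <- element[2]
  dend <- dels$start + dels$length
  cls <- rep(NA_character_, nrow(dels))
  cls[dels$start >= es & dend <= ee] <- "dElem"
  cls[dels$start < es & dend > ee] <- "dElemPlus"
  cls[dend <= es | dels$start >= ee] <- "dC"
  dels$class <- cls
  sizes <- vapply(c("dElem", "dElemPlus", "dC"),
                  function(k) sum(cls == k, na.rm = TRUE), integer(1))
  if (any(sizes < 3L))
    stop("too few deletions per class: ",
         paste(names(sizes), sizes, sep = "=", collapse = ", "))
  dels$selected <- FALSE
  ratios <- list()
  for (k in names(sizes)) {
    idx <- which(cls == k)
    idx <- idx[order(-dels$dna_count[idx])]
    idx <- idx[seq_len(min(top_n, length(idx)))]
    dels$selected[idx] <- TRUE
    ratios[[k]] <- dels$r[idx] / reference_ratio
  }
  list(classes = dels, ratios = ratios,
       p_values = c(
         elem_vs_control = mw_test(ratios$dElem, ratios$dC, exact_max = 49L),
         elem_plus_vs_control = mw_test(ratios$dElemPlus, ratios$dC,
                                        exact_max = 49L)))
}
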