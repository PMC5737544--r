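#' Generate a synthetic AT-rich 3'-UTR reference
#'
#' Random sequence emulating an AT-rich chemokine 3'-UTR of the scale used in
#' tiling screens (default 781 nt, 42% GC, which yields on the order of 64 SpCas9 sites on a typical draw), with a canonical AATAAA polyA
#' signal planted so that its hexamer lies fully within 10-35 nt upstream of
#' the cleavage site (taken to be the reference end). The sequence is marked
#' synthetic via its record name.
#'
#' @param length reference length in nt.
#' @param gc GC fraction of the random background.
#' @param seed RNG seed.
#' @param name record name.
#' @return a [utr_reference()] with `polya_site = length` and the planted
#'   `polya_signal` annotated.
#' @export
make_synthetic_utr <- function(length = 781L, gc = 0.42, seed = 1L,
                               name = "synthetic_utr") {
  stopifnot(length >= 60L, gc > 0, gc < 1)
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  ch <- sample(names(p), length, replace = TRUE, prob = p)
  # plant the signal at the 5' edge of the admissible window so it is the
  # hexamer find_polya_signal() reports even if chance creates another
  sig_start <- length - 35L
  ch[(sig_start + 1L):(sig_start + 6L)] <- c("A", "A", "T", "A", "A", "A")
  utr_reference(name = name, sequence = paste(ch, collapse = ""),
                polya_site = length,
                polya_signal = c(sig_start, sig_start + 6L))
}

#' Define the ground-truth regulatory effect profile
#'
#' Each region carries a multiplicative effect on RNA abundance for any
#' deletion allele whose deleted interval overlaps it: a multiplier above 1
#' models removal of a destabilizing element (deleting it raises the RNA/DNA
#' ratio), below 1 removal of a transcription-promoting element.
#'
#' @param regions data.frame with columns `start`, `end` (0-based half-open)
#'   and `multiplier` (> 0); regions must not overlap. Zero rows = neutral
#'   profile.
#' @param baseline_ratio RNA/DNA ratio of the intact allele.
#' @return object of class `effect_profile`.
#' @export
effect_profile <- function(regions = data.frame(start = integer(),
                                                end = integer(),
                                                multiplier = numeric()),
                           baseline_ratio = 0.5) {
  stopifnot(all(c("start", "end", "multiplier") %in% names(regions)),
            baseline_ratio > 0)
  if (nrow(regions)) {
    if (any(regions$multiplier <= 0)) stop("multipliers must be > 0")
    if (any(regions$end <= regions$start)) stop("empty effect region")
    o <- order(regions$start)
    if (any(regions$start[o][-1] < regions$end[o][-nrow(regions)]))
      stop("effect regions must not overlap")
  }
  structure(list(regions = regions, baseline_ratio = baseline_ratio),
            class = "effect_profile")
}

# product of multipliers of regions overlapped by [start, start+length)
effect_multiplier <- function(profile, start, length) {
  if (!nrow(profile$regions)) return(rep(1, base::length(start)))
  end <- start + length
  vapply(seq_along(start), function(i) {
    hit <- profile$regions$start < end[i] & start[i] < profile$regions$end
    prod(profile$regions$multiplier[hit])
  }, numeric(1))
}

#' Default deletion-length distribution
#'
#' Support 1..40 nt with mode 5 and geometric decay beyond it. Covers the
#' 3-29 nt analysis window and deliberately includes the 1-2 nt and >= 30 nt
#' tails that the read filters must reject.
#'
#' @param decay geometric decay rate beyond the mode.
#' @return numeric vector of length 40 summing to 1; element L is P(length = L).
#' @export
deletion_length_probs <- function(decay = 0.85) {
  p <- c(seq_len(5) / 5, decay^seq_len(35))
  p / sum(p)
}

#' Simulate the deletion-allele population of a screen
#'
#' Draws a reproducible set of deletion alleles around the Cas9 cut sites.
#' Each draw is a single-cut allele (length from `length_probs`, placed so
#' the deleted interval contains or abuts the cut) or, with probability
#' `dual_cut_prob`, a dual-cut allele spanning two cut positions no more
#' than 35 nt apart. Duplicated (start, length) draws merge into one allele.
#' DNA frequencies come from exponential weights renormalized to
#' `1 - intact_fraction`; the intact allele carries `intact_fraction`. Each
#' allele's RNA relative abundance is its DNA frequency times the intact
#' baseline ratio times the product of effect multipliers of the ground-truth
#' regions its deletion overlaps.
#'
#' @param ref a [utr_reference()].
#' @param guides guide table from [enumerate_guides()]; one allele batch is
#'   drawn per distinct cut position.
#' @param profile an [effect_profile()].
#' @param n_per_cut allele draws per cut site; the default gives a
#'   deletion spectrum on the order of a thousand distinct analyzable
#'   (3-29 nt) alleles over a ~781-nt UTR with ~64 cut sites, the scale a
#'   saturating tiling screen produces.
#' @param dual_cut_prob probability a draw spans two cut sites.
#' @param intact_fraction DNA fraction of the unedited allele, in (0, 1].
#' @param length_probs deletion-length distribution over 1..length(length_probs).
#' @param depths named vector `c(dna =, rna =)` fragment depths recorded for
#'   downstream read/count simulation.
#' @param read_length read length in nt.
#' @param error_rate per-base substitution error probability.
#' @param seed RNG seed; identical seeds give identical truth.
#' @return object of class `screen_truth`: list with `alleles` (data.frame
#'   `start`, `length`, `intact`, `dna_freq`, `rna_rel`), the generator
#'   settings, and the profile.
#' @export
simulate_alleles <- function(ref, guides, profile = effect_profile(),
                             n_per_cut = 24L, dual_cut_prob = 0.15,
                             intact_fraction = 0.3,
                             length_probs = deletion_length_probs(),
                             depths = c(dna = 2e5, rna = 112500),
                             read_length = 150L, error_rate = 1e-3,
                             seed = 1L) {
  if (intact_fraction <= 0 || intact_fraction > 1)
    stop("intact_fraction must be in (0, 1]")
  cuts <- sort(unique(guides$cut_position))
  if (!length(cuts)) stop("no guide cut sites")
  set.seed(seed)
  maxlen <- length(length_probs)
  alleles <- data.frame(start = integer(), length = integer(),
                        weight = numeric())
  if (intact_fraction < 1) {
    recs <- list()
    for (cut in cuts) {
      for (k in seq_len(n_per_cut)) {
        partner <- cuts[cuts != cut & abs(cuts - cut) <= 35L]
        if (!length(partner) && length(cuts) > 1L) {
          other <- cuts[cuts != cut]
          partner <- other[which.min(abs(other - cut))]
        }
        if (length(partner) && stats::runif(1) < dual_cut_prob) {
          c2 <- if (length(partner) == 1L) partner else sample(partner, 1L)
          st <- min(cut, c2); len <- abs(c2 - cut)
        } else {
          len <- sample.int(maxlen, 1L, prob = length_probs)
          st <- cut - sample.int(len + 1L, 1L) + 1L  # start in [cut-len, cut]
          st <- max(0L, min(st, ref$length - len))
        }
        recs[[length(recs) + 1L]] <- c(st, len)
      }
    }
    m <- do.call(rbind, recs)
    w <- stats::rexp(nrow(m))
    key <- paste(m[, 1], m[, 2])
    agg <- rowsum(w, key)
    sk <- strsplit(rownames(agg), " ", fixed = TRUE)
    alleles <- data.frame(start = as.integer(vapply(sk, `[`, "", 1L)),
                          length = as.integer(vapply(sk, `[`, "", 2L)),
                          weight = agg[, 1])
    alleles <- alleles[order(alleles$start, alleles$length), ]
  }
  n_del <- nrow(alleles)
  dna_freq <- if (n_del) alleles$weight / sum(alleles$weight) * (1 - intact_fraction)
              else numeric()
  out <- data.frame(
    start = c(alleles$start, NA_integer_),
    length = c(alleles$length, NA_integer_),
    intact = c(rep(FALSE, n_del), TRUE),
    dna_freq = c(dna_freq, intact_fraction))
  mult <- c(if (n_del) effect_multiplier(profile, alleles$start, alleles$length),
            1)
  out$rna_rel <- out$dna_freq * profile$baseline_ratio * mult
  rownames(out) <- NULL
  structure(list(alleles = out, ref_name = ref$name, ref_length = ref$length,
                 profile = profile, depths = depths,
                 read_length = as.integer(read_length),
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "screen_truth")
}

#' @export
print.screen_truth <- function(x, ...) {
  cat(sprintf("screen_truth: %d deletion alleles + intact (%.0f%% DNA), seed %d\n",
              sum(!x$alleles$intact), 100 * x$alleles$dna_freq[x$alleles$intact],
              x$seed))
  invisible(x)
}

#' Simulate fragment counts directly from the allele truth
#'
#' Multinomial sampling of per-allele fragment counts in each library (DNA by
#' allele frequency, RNA by relative abundance), bypassing read emission and
#' alignment. The result has the same shape as [group_distinct()] plus
#' [library_summary()] output, so the ratio and position-map stages consume
#' it directly. Used for statistical calibration at depths where emitting
#' reads would be pointless; fragment classification is taken as perfect.
#'
#' @param truth a `screen_truth` from [simulate_alleles()].
#' @param depths named vector `c(dna =, rna =)`; defaults to the truth's.
#' @param seed RNG seed (defaults to `truth$seed + 1`).
#' @return list with `deletions` (data.frame `start`, `length`, `dna_count`,
#'   `rna_count`) and `summary` (per-library totals and reference counts).
#' @export
simulate_counts <- function(truth, depths = truth$depths,
                            seed = truth$seed + 1L) {
  set.seed(seed)
  al <- truth$alleles
  dna <- as.vector(stats::rmultinom(1, depths[["dna"]], al$dna_freq))
  rna <- as.vector(stats::rmultinom(1, depths[["rna"]], al$rna_rel / sum(al$rna_rel)))
  del <- !al$intact
  list(
    deletions = data.frame(start = al$start[del], length = al$length[del],
                           dna_count = dna[del], rna_count = rna[del]),
    summary = data.frame(
      library = c("DNA", "RNA"),
      total_fragments = c(sum(dna), sum(rna)),
      reference_fragments = c(sum(dna[al$intact]), sum(rna[al$intact]))))
}

# reference sequence with one deletion applied; NA start = intact
allele_sequence <- function(ref, start, length) {
  if (is.na(start)) return(ref$sequence)
  paste0(substr(ref$sequence, 1L, start),
         substr(ref$sequence, start + length + 1L, ref$length))
}

#' Simulate paired-end amplicon reads for both libraries
#'
#' Emits, per library, a truth-aligned SAM (CIGAR carries a D operation at
#' the allele's deletion for any read spanning the junction) plus paired
#' FASTQ, so the pipeline runs with no external aligner while the FASTQ
#' preserves the option of using one. Fragments are drawn from the allele
#' frequencies (DNA) or renormalized RNA abundances (RNA); fragment length is
#' Normal(300, 30) truncated to `[read_length, allele length]`, fragment
#' start uniform. Sequencing errors are substitutions only, applied after the
#' alignment is determined (end-to-end alignment tolerates mismatches).
#' Alleles shorter than the read length trigger a re-draw, which is counted.
#'
#' @param truth a `screen_truth`.
#' @param ref the [utr_reference()] the truth was built from.
#' @param dir output directory (created if needed).
#' @param depths fragment depths, default the truth's.
#' @param seed RNG seed (defaults to `truth$seed`).
#' @param mean_fragment,sd_fragment fragment-length distribution.
#' @param junk_deletion_rate optional rate at which a 1-2 nt spurious
#'   deletion is injected into a read's alignment, to exercise the
#'   sequencing-error length filter. Default 0.
#' @return list with per-library file paths (`dna_sam`, `rna_sam`,
#'   `dna_fastq1`, ... ), `fragments` (per-fragment truth: library, qname,
#'   allele row index, allele-space start, fragment length) and `n_redraws`.
#' @export
simulate_reads <- function(truth, ref, dir, depths = truth$depths,
                           seed = truth$seed, mean_fragment = 300,
                           sd_fragment = 30, junk_deletion_rate = 0) {
  stopifnot(ref$name == truth$ref_name, ref$length == truth$ref_length)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  al <- truth$alleles
  aseq <- vapply(seq_len(nrow(al)),
                 function(i) allele_sequence(ref, al$start[i], al$length[i]),
                 character(1))
  alen <- nchar(aseq)
  rl <- truth$read_length
  paths <- list()
  frags <- list()
  n_redraws <- 0L
  for (lib in c("dna", "rna")) {
    n <- as.integer(depths[[lib]])
    stopifnot(n >= 1L)
    prob <- if (lib == "dna") al$dna_freq else al$rna_rel / sum(al$rna_rel)
    idx <- sample.int(nrow(al), n, replace = TRUE, prob = prob)
    short <- alen[idx] < rl
    while (any(short)) {        # redraw fragments from too-short alleles
      n_redraws <- n_redraws + sum(short)
      idx[short] <- sample.int(nrow(al), sum(short), replace = TRUE, prob = prob)
      short <- alen[idx] < rl
    }
    flen <- pmin(pmax(round(stats::rnorm(n, mean_fragment, sd_fragment)), rl),
                 alen[idx])
    f <- floor(stats::runif(n) * (alen[idx] - flen + 1))  # 0-based allele coord
    qname <- sprintf("%s_frag%07d", lib, seq_len(n))
    r1 <- substr(aseq[idx], f + 1L, f + rl)
    r2f <- substr(aseq[idx], f + flen - rl + 1L, f + flen)  # fwd orientation
    r1 <- add_substitution_errors(r1, truth$error_rate)
    r2f <- add_substitution_errors(r2f, truth$error_rate)
    a1 <- mate_alignment(f, rl, al$start[idx], al$length[idx])
    a2 <- mate_alignment(f + flen - rl, rl, al$start[idx], al$length[idx])
    if (junk_deletion_rate > 0) {
      j1 <- inject_junk_deletions(a1$cigar, rl, junk_deletion_rate)
      a1$cigar <- j1$cigar; r1 <- trim_junk(r1, j1$trim)
      j2 <- inject_junk_deletions(a2$cigar, rl, junk_deletion_rate)
      a2$cigar <- j2$cigar; r2f <- trim_junk(r2f, j2$trim)
    }
    qual1 <- strrep("I", nchar(r1)); qual2 <- strrep("I", nchar(r2f))
    tlen <- a2$pos + a2$ref_len - a1$pos
    hdr <- c("@HD\tVN:1.6\tSO:queryname",
             sprintf("@SQ\tSN:%s\tLN:%d", ref$name, ref$length))
    recs <- character(2L * n)
    recs[seq(1L, by = 2L, length.out = n)] <- paste(
      qname, 99L, ref$name, a1$pos + 1L, 60L, a1$cigar, "=", a2$pos + 1L,
      tlen, r1, qual1, sep = "\t")
    recs[seq(2L, by = 2L, length.out = n)] <- paste(
      qname, 147L, ref$name, a2$pos + 1L, 60L, a2$cigar, "=", a1$pos + 1L,
      -tlen, r2f, qual2, sep = "\t")
    sam <- file.path(dir, paste0(lib, ".sam"))
    writeLines(c(hdr, recs), sam)
    fq1 <- file.path(dir, paste0(lib, "_1.fastq"))
    fq2 <- file.path(dir, paste0(lib, "_2.fastq"))
    writeLines(as.vector(rbind(paste0("@", qname, "/1"), r1, "+", qual1)), fq1)
    writeLines(as.vector(rbind(paste0("@", qname, "/2"), revcomp(r2f), "+",
                               qual2)), fq2)
    paths[[paste0(lib, "_sam")]] <- sam
    paths[[paste0(lib, "_fastq1")]] <- fq1
    paths[[paste0(lib, "_fastq2")]] <- fq2
    frags[[lib]] <- data.frame(library = toupper(lib), qname = qname,
                               allele = idx, frag_start = f, frag_len = flen)
  }
  truth_tsv <- file.path(dir, "truth_alleles.tsv")
  utils::write.table(al, truth_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  c(paths, list(truth_tsv = truth_tsv, fragments = do.call(rbind, frags),
                n_redraws = n_redraws))
}

# reference pos (0-based) and CIGAR for a read covering allele coords
# [a, a+rl) of an allele with one deletion (ds, dl); NA ds = intact
mate_alignment <- function(a, rl, ds, dl) {
  n <- length(a)
  pos <- integer(n); cigar <- character(n); ref_len <- integer(n)
  intact <- is.na(ds)
  left_of <- !intact & (a + rl <= ds)
  right_of <- !intact & (a >= ds)
  spans <- !intact & !left_of & !right_of
  pos[intact | left_of] <- a[intact | left_of]
  pos[right_of] <- a[right_of] + dl[right_of]
  pos[spans] <- a[spans]
  cigar[!spans] <- paste0(rl, "M")
  ref_len[!spans] <- rl
  if (any(spans)) {
    left <- ds[spans] - a[spans]
    cigar[spans] <- paste0(left, "M", dl[spans], "D", rl - left, "M")
    ref_len[spans] <- rl + dl[spans]
  }
  list(pos = pos, cigar = cigar, ref_len = ref_len)
}

add_substitution_errors <- function(reads, rate) {
  if (rate <= 0) return(reads)
  rl <- nchar(reads)
  k <- stats::rbinom(length(reads), rl, rate)
  hit <- which(k > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    p <- sample.int(rl[i], k[i])
    for (j in p) {
      old <- substr(reads[i], j, j)
      substr(reads[i], j, j) <- sample(setdiff(bases, old), 1L)
    }
  }
  reads
}

# Optional error mode: replace a read's trailing match block "xM" with
# "(x-1-len)M lenD ..." is complex; instead split the M block in two around a
# 1-2 nt D, trimming the read so aligned read bases stay consistent.
inject_junk_deletions <- function(cigar, rl, rate) {
  hit <- which(stats::runif(length(cigar)) < rate & grepl("^\\d+M$", cigar))
  trim <- integer(length(cigar))
  for (i in hit) {
    m <- as.integer(sub("M$", "", cigar[i]))
    len <- sample(1:2, 1L)
    at <- sample(seq(10L, m - 10L), 1L)    # away from read ends
    cigar[i] <- paste0(at, "M", len, "D", m - at - len, "M")
    trim[i] <- len
  }
  list(cigar = cigar, trim = trim)
}

trim_junk <- function(reads, trim) {
  hit <- which(trim > 0L)
  if (length(hit))
    reads[hit] <- substr(reads[hit], 1L, nchar(reads[hit]) - trim[hit])
  reads
}
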