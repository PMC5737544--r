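# shared fixtures and independent oracles, built in code at test time

random_dna <- function(n, gc = 0.4) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

revcomp_chr <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

# independent NGG-site counter: perl lookahead regex on both strands
guide_regex_count <- function(seq) {
  n_strand <- function(s) {
    m <- gregexpr("(?=[ACGT]{21}GG)", s, perl = TRUE)[[1]]
    sum(m > 0)
  }
  n_strand(seq) + n_strand(revcomp_chr(seq))
}

# brute-force two-sided Mann-Whitney p by enumeration of all rank
# assignments (assumes no ties)
mw_enum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  stopifnot(!anyDuplicated(c(x, y)))
  u_obs <- sum(outer(x, y, ">"))
  subsets <- utils::combn(N, n1)
  ranks_all <- seq_len(N)
  u_all <- colSums(matrix(ranks_all[subsets], nrow = n1)) - n1 * (n1 + 1) / 2
  pl <- mean(u_all <= u_obs)
  pu <- mean(u_all >= u_obs)
  min(1, 2 * min(pl, pu))
}

# write a SAM file from parallel vectors; pos is 0-based here
write_test_sam <- function(path, ref_name, ref_len, qname, flag, pos, cigar,
                           seq = NULL) {
  if (is.null(seq)) seq <- strrep("A", cigar_read_len(cigar))
  qual <- strrep("I", nchar(seq))
  lines <- c(sprintf("@SQ\tSN:%s\tLN:%d", ref_name, ref_len),
             paste(qname, flag, ref_name, pos + 1L, 60L, cigar, "*", 0L, 0L,
                   seq, qual, sep = "\t"))
  writeLines(lines, path)
  path
}

cigar_read_len <- function(cigar) {
  vapply(cigar, function(cg) {
    m <- gregexpr("\\d+[MIS=X]", cg)[[1]]
    sum(as.integer(sub("[MIS=X]", "", regmatches(cg, list(m))[[1]])))
  }, integer(1), USE.NAMES = FALSE)
}

# small screen fixture shared by ratio/map tests
demo_screen <- function(seed = 5L, depths = c(dna = 3e4, rna = 3e4),
                        profile = effect_profile()) {
  ref <- make_synthetic_utr(seed = 3L)
  guides <- enumerate_guides(ref)
  truth <- simulate_alleles(ref, guides, profile, depths = depths, seed = seed)
  cnt <- simulate_counts(truth)
  list(ref = ref, guides = guides, truth = truth, counts = cnt)
}
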