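frag_row <- function(lib, status, start = NA, length = NA, n = 1) {
  data.frame(fragment_id = sprintf("%s_%s_%d_%d_%d", lib, status,
                                   ifelse(is.na(start), 0, start),
                                   ifelse(is.na(length), 0, length),
                                   seq_len(n)),
             library = lib, status = status, start = start, length = length,
             reason = NA_character_)
}

test_that("fragments group into distinct deletions by (start, length)", {
  frags <- rbind(frag_row("DNA", "deletion", 40, 5, 3),
                 frag_row("RNA", "deletion", 40, 5, 2),
                 frag_row("DNA", "deletion", 41, 5, 1),
                 frag_row("RNA", "deletion", 60, 4, 2),
                 frag_row("DNA", "reference", n = 10),
                 frag_row("RNA", "reference", n = 5))
  dels <- group_distinct(frags)
  expect_equal(nrow(dels), 3L)
  d40 <- dels[dels$start == 40 & dels$length == 5, ]
  expect_equal(d40$dna_count, 3L)
  expect_equal(d40$rna_count, 2L)
  expect_equal(nrow(dels[dels$start == 41, ]), 1L)  # distinct key
  rna_only <- dels[dels$start == 60, ]
  expect_true(rna_only$rna_only)
  expect_equal(rna_only$dna_count, 0L)

  summ <- library_summary(frags)
  expect_equal(summ$total_fragments, c(14L, 9L))
  expect_equal(summ$reference_fragments, c(10L, 5L))
})

test_that("abundance filter eliminates at the boundary, per library", {
  summ <- data.frame(library = c("DNA", "RNA"),
                     total_fragments = c(1e7, 1e7),
                     reference_fragments = c(5e6, 5e6))
  dels <- data.frame(start = c(10, 20, 30, 40), length = rep(5L, 4),
                     dna_count = c(16L, 100L, 7L, 100L),
                     rna_count = c(100L, 6L, 100L, 7L),
                     rna_only = FALSE)
  kept <- filter_abundance(dels, summ)
  # 16/1e7 > 6.5e-7 passes DNA; 6/1e7 and 7/1e7 <= or > ?
  expect_true(10 %in% kept$start)    # 16 DNA, 100 RNA: both above
  expect_false(20 %in% kept$start)   # 6 RNA <= 6.5 eliminated
  expect_true(40 %in% kept$start)    # 7 RNA > 6.5 retained

  # exactly 6.5 per 1e7 (65 of 1e8) is eliminated: boundary is inclusive
  summ2 <- data.frame(library = c("DNA", "RNA"),
                      total_fragments = c(1e8, 1e8),
                      reference_fragments = c(5e6, 5e6))
  d2 <- data.frame(start = 10, length = 5L, dna_count = 65L, rna_count = 1000L,
                   rna_only = FALSE)
  expect_equal(nrow(filter_abundance(d2, summ2)), 0L)
  d3 <- data.frame(start = 10, length = 5L, dna_count = 66L, rna_count = 1000L,
                   rna_only = FALSE)
  expect_equal(nrow(filter_abundance(d3, summ2)), 1L)

  # length window 3-29 is enforced here too
  d4 <- data.frame(start = c(1, 2, 3, 4), length = c(2L, 3L, 29L, 30L),
                   dna_count = 1000L, rna_count = 1000L, rna_only = FALSE)
  expect_equal(filter_abundance(d4, summ)$length, c(3L, 29L))

  # absolute mode uses the fixed per-library minima
  d5 <- data.frame(start = c(1, 2), length = 5L,
                   dna_count = c(16L, 15L), rna_count = c(8L, 100L),
                   rna_only = FALSE)
  expect_equal(filter_abundance(d5, summ, mode = "absolute")$start, 1)
})

test_that("abundance filter is monotone in counts", {
  summ <- data.frame(library = c("DNA", "RNA"),
                     total_fragments = c(1e6, 1e6),
                     reference_fragments = c(5e5, 5e5))
  set.seed(8)
  for (i in 1:50) {
    d <- data.frame(start = 10, length = 10L,
                    dna_count = sample(0:5, 1), rna_count = sample(0:5, 1),
                    rna_only = FALSE)
    kept_before <- nrow(filter_abundance(d, summ)) == 1L
    d2 <- d; d2$dna_count <- d2$dna_count + sample(1:10, 1)
    d2$rna_count <- d2$rna_count + sample(1:10, 1)
    kept_after <- nrow(filter_abundance(d2, summ)) == 1L
    expect_true(!kept_before || kept_after)
  }
})

test_that("count ratios and normalization follow r = RNA/DNA", {
  summ <- data.frame(library = c("DNA", "RNA"),
                     total_fragments = c(100L, 100L),
                     reference_fragments = c(40L, 20L))
  dels <- data.frame(start = c(10, 20, 30), length = 5L,
                     dna_count = c(20L, 20L, 10L),
                     rna_count = c(10L, 0L, 5L), rna_only = FALSE)
  rq <- compute_ratios(dels, summ)
  expect_equal(rq$deletions$r, c(0.5, 0, 0.5))
  expect_equal(rq$summary$reference_ratio[1], 0.5)
  expect_equal(rq$deletions$normalized_r, c(1, 0, 1))
  expect_equal(rq$summary$total_r[1], 15 / 50)

  summ0 <- summ; summ0$reference_fragments <- c(0L, 20L)
  expect_error(compute_ratios(dels, summ0), "reference_ratio undefined")
})

test_that("total_r and reference_ratio are stable under equal subsampling", {
  sc <- demo_screen(seed = 43, depths = c(dna = 8e4, rna = 8e4))
  full <- compute_ratios(
    filter_abundance(sc$counts$deletions, sc$counts$summary),
    sc$counts$summary)
  half <- simulate_counts(sc$truth, depths = c(dna = 4e4, rna = 4e4),
                          seed = 101)
  sub <- compute_ratios(filter_abundance(half$deletions, half$summary),
                        half$summary)
  expect_equal(sub$summary$reference_ratio[1], full$summary$reference_ratio[1],
               tolerance = 0.05)
  expect_equal(sub$summary$total_r[1], full$summary$total_r[1],
               tolerance = 0.05)
})

test_that("pilot classification assigns the three deletion classes", {
  element <- c(100, 120)
  dels <- data.frame(
    start = c(102, 105, 110, 95, 90, 85, 10, 30, 50, 98),
    length = c(5L, 8L, 9L, 30L, 35L, 40L, 10L, 10L, 10L, 5L),
    dna_count = 100L, rna_count = 50L, rna_only = FALSE)
  dels$r <- dels$rna_count / dels$dna_count
  out <- pilot_class_analysis(dels, reference_ratio = 0.5, element,
                              top_n = 3L)
  cls <- out$classes$class
  expect_equal(cls[1:3], rep("dElem", 3))      # fully inside
  expect_equal(cls[4:6], rep("dElemPlus", 3))  # strictly contain the element
  expect_equal(cls[7:9], rep("dC", 3))         # disjoint
  expect_true(is.na(cls[10]))                  # straddles one boundary: excluded
  expect_equal(sum(!is.na(cls)) + sum(is.na(cls)), nrow(dels))
})

test_that("pilot comparison reproduces the exact Mann-Whitney result", {
  # 9 element ratios all above all 9 control ratios: the extreme arrangement
  element <- c(100, 120)
  n <- 9L
  dels <- data.frame(
    start = c(rep(102, n), rep(95, n), rep(10, n)),
    length = c(seq(3, 11), seq(30, 38), seq(3, 11)),
    dna_count = rep(1000L, 3 * n),
    rna_count = c(2000L + 17L * seq_len(n), 2100L + 13L * seq_len(n),
                  100L + 11L * seq_len(n)),
    rna_only = FALSE)
  dels$r <- dels$rna_count / dels$dna_count
  out <- pilot_class_analysis(dels, reference_ratio = 1, element, top_n = 9L)
  expect_equal(unname(out$p_values["elem_vs_control"]), 2 / choose(18, 9))
  expect_equal(unname(out$p_values["elem_plus_vs_control"]), 2 / choose(18, 9))
  # and matches the enumeration oracle on the same data
  expect_equal(unname(out$p_values["elem_vs_control"]),
               mw_enum_p(out$ratios$dElem, out$ratios$dC))
})

test_that("pilot analysis errors when a class is underpopulated", {
  dels <- data.frame(start = c(102, 10, 30, 50), length = c(5L, 10L, 5L, 5L),
                     dna_count = 10L, rna_count = 5L, rna_only = FALSE)
  dels$r <- 0.5
  expect_error(pilot_class_analysis(dels, 0.5, c(100, 120)),
               "dElem=1.*dElemPlus=0.*dC=3")
})

test_that("pilot p-values are uniform under the null", {
  set.seed(71)
  reps <- 400
  p <- numeric(reps)
  for (i in seq_len(reps)) {
    dels <- data.frame(
      start = c(rep(102, 9), rep(95, 9), rep(10, 9)),
      length = c(seq(3, 11), seq(30, 38), seq(3, 11)),
      dna_count = 100L, rna_count = 50L, rna_only = FALSE)
    dels$r <- rlnorm(27)           # all classes from one distribution
    p[i] <- pilot_class_analysis(dels, 1, c(100, 120))$p_values[[1]]
  }
  rej <- mean(p <= 0.05)
  # binomial check at alpha = 0.05 (exact test is slightly conservative)
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / reps) + 0.01)
})
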