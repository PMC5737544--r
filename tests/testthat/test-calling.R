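test_that("CIGAR walking yields deletion coordinates and read-end offsets", {
  ex <- extract_deletions("40M5D110M", 0)
  expect_equal(nrow(ex$calls), 1L)
  expect_equal(ex$calls$start, 40L)
  expect_equal(ex$calls$length, 5L)
  expect_equal(ex$calls$off_left, 40L)
  expect_equal(ex$calls$off_right, 110L)
  expect_equal(ex$ref_span, c(0L, 155L))

  expect_equal(nrow(extract_deletions("150M", 7)$calls), 0L)
  expect_equal(extract_deletions("150M", 7)$ref_span, c(7L, 157L))

  # two deletions: second start advances past the first D's ref consumption
  ex2 <- extract_deletions("30M3D50M4D67M", 0)
  expect_equal(ex2$calls$start, c(30L, 83L))
  expect_equal(ex2$calls$length, c(3L, 4L))
  expect_equal(ex2$calls$off_left, c(30L, 80L))
  expect_equal(ex2$calls$off_right, c(117L, 67L))

  # insertions and soft clips advance the read only
  ex3 <- extract_deletions("5S35M5D110M", 10)
  expect_equal(ex3$calls$start, 45L)
  expect_equal(ex3$calls$off_left, 40L)
  # N behaves as D (subject to the usual length filters downstream)
  ex4 <- extract_deletions("40M5N110M", 0)
  expect_equal(ex4$calls$start, 40L)
  # hard clips / padding are unsupported
  expect_null(extract_deletions("5H145M", 0))
})

test_that("CIGAR walk agrees with GenomicAlignments on random alignments", {
  skip_if_not_installed("GenomicAlignments")
  set.seed(19)
  for (i in 1:50) {
    nblocks <- sample(1:3, 1)
    m <- sample(10:60, nblocks + 1, replace = TRUE)
    d <- sample(1:40, nblocks, replace = TRUE)
    cigar <- paste0(paste0(m[-length(m)], "M", d, "D", collapse = ""),
                    m[length(m)], "M")
    pos <- sample(0:100, 1)
    ex <- extract_deletions(cigar, pos)
    ir <- GenomicAlignments::cigarRangesAlongReferenceSpace(
      cigar, ops = "D", pos = pos + 1L)[[1]]
    expect_equal(ex$calls$start, IRanges::start(ir) - 1L)
    expect_equal(ex$calls$length, IRanges::width(ir))
    expect_equal(
      diff(ex$ref_span),
      GenomicAlignments::cigarWidthAlongReferenceSpace(cigar))
  }
})

test_that("read filters implement the screen's discard rules", {
  pass <- data.frame(start = 100, length = 5, off_left = 40, off_right = 110)
  expect_equal(filter_read(pass)$status, "deletion")

  # 1-2 nt deletions are sequencing errors: dropped, read kept as reference
  err <- data.frame(start = 100, length = 2, off_left = 40, off_right = 110)
  expect_equal(filter_read(err)$status, "reference")

  edge <- data.frame(start = 100, length = 5, off_left = 4, off_right = 141)
  res <- filter_read(edge)
  expect_equal(res$status, "discarded")
  expect_equal(res$reason, "edge-proximal")

  multi <- data.frame(start = c(100, 120), length = c(5, 6),
                      off_left = c(40, 80), off_right = c(110, 70))
  expect_equal(filter_read(multi)$reason, "multi-deletion")

  long <- data.frame(start = 100, length = 30, off_left = 40, off_right = 110)
  expect_equal(filter_read(long)$reason, "length->=30")
  ok29 <- data.frame(start = 100, length = 29, off_left = 40, off_right = 110)
  expect_equal(filter_read(ok29)$status, "deletion")

  # an error-length deletion plus a real one: real one survives alone
  mix <- data.frame(start = c(100, 120), length = c(2, 6),
                    off_left = c(40, 80), off_right = c(110, 70))
  res <- filter_read(mix)
  expect_equal(res$status, "deletion")
  expect_equal(res$call$start, 120)
})

test_that("mate reconciliation follows the fragment rule table", {
  del <- function(s, l) list(status = "deletion",
                             call = data.frame(start = s, length = l),
                             reason = NA_character_)
  refr <- list(status = "reference", call = NULL, reason = NA_character_)
  disc <- list(status = "discarded", call = NULL, reason = "edge-proximal")

  # deletion + reference mate whose span misses the deletion: deletion stands
  r <- reconcile_mates(del(40, 5), refr, span1 = c(0, 155), span2 = c(100, 250))
  expect_equal(r$status, "deletion")
  expect_equal(r$call$start, 40)

  # reference mate covering the deleted interval without a D: conflict
  r2 <- reconcile_mates(del(40, 5), refr, span1 = c(0, 155), span2 = c(10, 160))
  expect_equal(r2$reason, "mate-conflict")

  # agreeing deletion mates count once
  r3 <- reconcile_mates(del(40, 5), del(40, 5), c(0, 155), c(20, 175))
  expect_equal(r3$status, "deletion")

  # disagreeing deletion mates cannot come from one molecule
  r4 <- reconcile_mates(del(40, 5), del(60, 4), c(0, 155), c(20, 175))
  expect_equal(r4$reason, "mate-conflict")

  expect_equal(reconcile_mates(refr, refr, c(0, 150), c(100, 250))$status,
               "reference")
  expect_equal(reconcile_mates(disc, del(40, 5), c(0, 155), c(0, 155))$reason,
               "edge-proximal")
  expect_equal(reconcile_mates("unmapped", "unmapped")$reason, "unmapped")
  expect_equal(reconcile_mates("unmapped", del(40, 5), NULL, c(0, 155))$status,
               "deletion")
})

test_that("fragment calling classifies a constructed SAM correctly", {
  sam <- tempfile(fileext = ".sam")
  qn <- c("f1", "f1", "f2", "f2", "f3", "f3", "f4", "f4", "f5", "f5")
  cg <- c("150M", "150M",                 # reference pair
          "40M5D110M", "150M",            # deletion + non-covering reference
          "40M5D110M", "40M5D110M",       # agreeing deletion pair
          "4M5D146M", "150M",             # edge-proximal junction
          "30M3D50M4D67M", "150M")        # multiple deletions
  pos <- c(0, 200, 0, 300, 0, 0, 0, 300, 0, 300)
  write_test_sam(sam, "utr", 781L, qn, rep(c(99L, 147L), 5), pos, cg,
                 seq = strrep("A", cigar_read_len(cg)))
  fc <- call_fragments(sam, "DNA")
  fc <- fc[order(fc$fragment_id), ]
  expect_equal(fc$status,
               c("reference", "deletion", "deletion", "discarded", "discarded"))
  expect_equal(fc$start[2:3], c(40L, 40L))
  expect_equal(fc$reason[4:5], c("edge-proximal", "multi-deletion"))
  # counting conservation
  expect_equal(nrow(fc), 5L)
  expect_equal(sum(attr(fc, "discard_counts")), 2L)
})

test_that("error-free simulated fragments are recovered or dropped for the predicted reason", {
  ref <- make_synthetic_utr(seed = 3)
  g <- enumerate_guides(ref)
  tr <- simulate_alleles(ref, g, error_rate = 0, seed = 37)
  out <- simulate_reads(tr, ref, file.path(tempdir(), "sim_oracle"),
                        depths = c(dna = 500, rna = 500))
  fc <- call_fragments(out$dna_sam, "DNA")
  frags <- out$fragments[out$fragments$library == "DNA", ]
  al <- tr$alleles
  rl <- tr$read_length
  ok <- 0L
  for (i in seq_len(nrow(frags))) {
    a <- al[frags$allele[i], ]
    row <- fc[fc$fragment_id == frags$qname[i], ]
    if (a$intact) { expect_equal(row$status, "reference"); next }
    # oracle: where does the junction fall in each mate?
    f <- frags$frag_start[i]; fl <- frags$frag_len[i]
    off1 <- a$start - f                    # junction offset in mate 1
    off2 <- a$start - (f + fl - rl)        # in mate 2 (forward orientation)
    seen1 <- off1 > 0 && off1 < rl
    seen2 <- off2 > 0 && off2 < rl
    near_edge <- function(o) o < 8 || rl - o < 8
    if (!seen1 && !seen2) {
      expect_equal(row$status, "reference")
    } else if (a$length <= 2) {
      expect_equal(row$status, "reference")
    } else if (a$length >= 30) {
      # which reason wins depends on which mate is hit; both are valid drops
      expect_equal(row$status, "discarded")
      expect_true(row$reason %in% c("length->=30", "edge-proximal"))
    } else if ((seen1 && near_edge(off1)) || (seen2 && near_edge(off2))) {
      expect_equal(row$status, "discarded")
      expect_equal(row$reason, "edge-proximal")
    } else {
      expect_equal(row$status, "deletion")
      expect_equal(row$start, a$start)
      expect_equal(row$length, a$length)
      ok <- ok + 1L
    }
  }
  expect_gt(ok, 50L)  # the check exercised real recoveries
})
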