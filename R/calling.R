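#' Extract deletion calls from one alignment
#'
#' Walks a SAM CIGAR string and returns one call per deletion operation, in
#' reference order. M/=/X advance reference and read, I and S advance the
#' read only, D advances the reference only. N is treated as D (amplicon
#' alignments should not contain true splices, but STAR can emit N; the
#' length filters then apply normally). H and P are unsupported: the record
#' must be discarded by the caller.
#'
#' @param cigar CIGAR string.
#' @param pos 0-based reference position of the first aligned base.
#' @return `NULL` when the CIGAR contains an unsupported operation, otherwise
#'   a list with `calls` (data.frame `start`, `length`, `off_left`,
#'   `off_right`: 0-based reference start of the deleted bases, deletion
#'   length, and read bases between each read end and the junction) and
#'   `ref_span = c(start, end)`, the half-open reference interval the
#'   alignment covers.
#' @export
extract_deletions <- function(cigar, pos) {
  m <- gregexpr("\\d+|[A-Z=]", cigar)[[1]]
  tok <- regmatches(cigar, list(m))[[1]]
  lens <- as.integer(tok[c(TRUE, FALSE)])
  ops <- tok[c(FALSE, TRUE)]
  if (any(ops %in% c("H", "P"))) return(NULL)
  if (!all(ops %in% c("M", "=", "X", "I", "S", "D", "N")))
    stop("malformed CIGAR: ", cigar)
  read_len <- sum(lens[ops %in% c("M", "=", "X", "I", "S")])
  ref_cur <- as.integer(pos)
  read_cur <- 0L
  starts <- integer(); dlens <- integer(); offl <- integer()
  for (i in seq_along(ops)) {
    op <- ops[i]; len <- lens[i]
    if (op %in% c("D", "N")) {
      starts <- c(starts, ref_cur)
      dlens <- c(dlens, len)
      offl <- c(offl, read_cur)
      ref_cur <- ref_cur + len
    } else if (op %in% c("M", "=", "X")) {
      ref_cur <- ref_cur + len
      read_cur <- read_cur + len
    } else {                      # I or S
      read_cur <- read_cur + len
    }
  }
  list(calls = data.frame(start = starts, length = dlens,
                          off_left = offl, off_right = read_len - offl),
       ref_span = c(as.integer(pos), ref_cur))
}

#' Apply the read-level deletion filters
#'
#' Classifies one mate's deletion calls. Deletions of length 1-2 nt are
#' removed first and the read kept (they are treated as sequencing errors,
#' not evidence of an allele). Of the remaining calls: more than one means
#' the read is discarded (`multi-deletion`); a junction closer than
#' `edge_distance` read bases to either read end is discarded
#' (`edge-proximal`), since alignment uncertainty near read ends is high; a
#' deletion of `max_discard_len` nt or longer is discarded (`length->=30`).
#' A read with no surviving call is a reference read.
#'
#' @param calls data.frame from [extract_deletions()] (`$calls`).
#' @param edge_distance minimum read bases between a junction and either
#'   read end.
#' @param error_max_len deletions of up to this length are dropped as
#'   sequencing errors (read retained).
#' @param max_discard_len deletions at least this long are discarded.
#' @return list with `status` in `reference`/`deletion`/`discarded`, `call`
#'   (single-row data.frame when status is `deletion`) and `reason` (when
#'   discarded).
#' @export
filter_read <- function(calls, edge_distance = 8L, error_max_len = 2L,
                        max_discard_len = 30L) {
  keep <- calls[calls$length > error_max_len, , drop = FALSE]
  if (nrow(keep) == 0L)
    return(list(status = "reference", call = NULL, reason = NA_character_))
  if (nrow(keep) > 1L)
    return(list(status = "discarded", call = NULL, reason = "multi-deletion"))
  if (keep$off_left < edge_distance || keep$off_right < edge_distance)
    return(list(status = "discarded", call = NULL, reason = "edge-proximal"))
  if (keep$length >= max_discard_len)
    return(list(status = "discarded", call = NULL, reason = "length->=30"))
  list(status = "deletion", call = keep, reason = NA_character_)
}

#' Reconcile the two mates of a fragment
#'
#' A fragment's two mates must describe the same molecule. Both reference:
#' reference fragment. One mate reports a deletion and the other is a
#' reference read whose aligned span does not contain the deleted interval:
#' the deletion stands (the reference mate simply did not reach the
#' junction; unmapped or uncovered regions are assumed to have no
#' deletions). A reference mate whose span does contain the deleted interval
#' contradicts the deletion mate: `mate-conflict`. Two deletion mates must
#' agree exactly on (start, length) — the allele is then counted once per
#' fragment — otherwise `mate-conflict`. A discarded mate discards the
#' fragment with its reason; two unmapped mates give `unmapped`. A single
#' mapped mate is taken at face value.
#'
#' @param res1,res2 per-mate results from [filter_read()], or the string
#'   `"unmapped"` / `NULL` for an unmapped mate.
#' @param span1,span2 half-open reference spans of the mates (from
#'   [extract_deletions()]), `NULL` when unmapped.
#' @return list `status`, `call`, `reason` as in [filter_read()].
#' @export
reconcile_mates <- function(res1, res2, span1 = NULL, span2 = NULL) {
  unmapped1 <- is.null(res1) || identical(res1, "unmapped")
  unmapped2 <- is.null(res2) || identical(res2, "unmapped")
  if (unmapped1 && unmapped2)
    return(list(status = "discarded", call = NULL, reason = "unmapped"))
  if (unmapped1) return(reconcile_mates(res2, "unmapped", span2, NULL))
  if (unmapped2) {
    if (res1$status == "discarded") return(res1)
    return(res1)
  }
  if (res1$status == "discarded") return(res1)
  if (res2$status == "discarded") return(res2)
  s1 <- res1$status; s2 <- res2$status
  if (s1 == "reference" && s2 == "reference")
    return(list(status = "reference", call = NULL, reason = NA_character_))
  if (s1 == "deletion" && s2 == "deletion") {
    if (res1$call$start == res2$call$start &&
        res1$call$length == res2$call$length)
      return(list(status = "deletion", call = res1$call, reason = NA_character_))
    return(list(status = "discarded", call = NULL, reason = "mate-conflict"))
  }
  # one deletion, one reference
  del <- if (s1 == "deletion") res1 else res2
  ref_span <- if (s1 == "deletion") span2 else span1
  d <- del$call
  if (!is.null(ref_span) &&
      d$start >= ref_span[1] && d$start + d$length <= ref_span[2])
    return(list(status = "discarded", call = NULL, reason = "mate-conflict"))
  list(status = "deletion", call = d, reason = NA_character_)
}

#' Read alignment records from a SAM file
#'
#' Uses Rsamtools (text SAM is converted to a temporary BAM first).
#' Secondary and supplementary alignments are dropped.
#'
#' @param path SAM file.
#' @return data.frame `qname`, `flag`, `rname`, `pos` (1-based, NA when
#'   unmapped), `cigar`; attribute `header_targets` holds the named
#'   reference-length vector from the header.
#' @export
read_sam <- function(path) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar"))
  x <- Rsamtools::scanBam(bam, param = param)[[1]]
  df <- data.frame(qname = x$qname, flag = x$flag,
                   rname = as.character(x$rname), pos = x$pos,
                   cigar = x$cigar, stringsAsFactors = FALSE)
  df <- df[bitwAnd(df$flag, 0x900L) == 0L, , drop = FALSE]  # primary only
  attr(df, "header_targets") <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  df
}

#' Call per-fragment deletions from an aligned library
#'
#' Runs [extract_deletions()] + [filter_read()] on every primary alignment
#' and [reconcile_mates()] per read pair (pairing by query name).
#'
#' @param sam path to a SAM file, or a data.frame from [read_sam()].
#' @param library library label, `"DNA"` or `"RNA"`.
#' @param edge_distance,error_max_len,max_discard_len see [filter_read()].
#' @return data.frame with one row per fragment: `fragment_id`, `library`,
#'   `status`, `start`, `length` (NA unless status is `deletion`), `reason`
#'   (NA unless discarded). The discard-reason tally is attached as
#'   attribute `discard_counts`.
#' @export
call_fragments <- function(sam, library = c("DNA", "RNA"), edge_distance = 8L,
                           error_max_len = 2L, max_discard_len = 30L) {
  library <- match.arg(library)
  recs <- if (is.character(sam)) read_sam(sam) else sam
  n <- nrow(recs)
  if (n == 0L) {
    out <- data.frame(fragment_id = character(), library = character(),
                      status = character(), start = integer(),
                      length = integer(), reason = character())
    attr(out, "discard_counts") <- table(character())
    return(out)
  }
  status <- character(n); reason <- rep(NA_character_, n)
  start <- rep(NA_integer_, n); len <- rep(NA_integer_, n)
  span_s <- rep(NA_integer_, n); span_e <- rep(NA_integer_, n)
  unmapped <- bitwAnd(recs$flag, 0x4L) != 0L | is.na(recs$pos) |
    is.na(recs$cigar) | recs$cigar == "*"
  # fast path: all-match CIGARs are reference reads with a trivial span
  plain <- !unmapped & grepl("^\\d+M$", recs$cigar)
  status[unmapped] <- "unmapped"
  status[plain] <- "reference"
  span_s[plain] <- recs$pos[plain] - 1L
  span_e[plain] <- span_s[plain] + as.integer(sub("M$", "", recs$cigar[plain]))
  for (i in which(!unmapped & !plain)) {
    ex <- extract_deletions(recs$cigar[i], recs$pos[i] - 1L)
    if (is.null(ex)) {
      status[i] <- "discarded"; reason[i] <- "unsupported-cigar"
      next
    }
    fr <- filter_read(ex$calls, edge_distance, error_max_len, max_discard_len)
    status[i] <- fr$status
    span_s[i] <- ex$ref_span[1]; span_e[i] <- ex$ref_span[2]
    if (fr$status == "deletion") {
      start[i] <- fr$call$start; len[i] <- fr$call$length
      reason[i] <- NA_character_
    } else if (fr$status == "discarded") reason[i] <- fr$reason
  }
  grp <- split(seq_len(n), recs$qname)
  out_status <- character(length(grp)); out_reason <- rep(NA_character_, length(grp))
  out_start <- rep(NA_integer_, length(grp)); out_len <- rep(NA_integer_, length(grp))
  mate_result <- function(i) {
    if (status[i] == "unmapped") return("unmapped")
    if (status[i] == "discarded")
      return(list(status = "discarded", call = NULL, reason = reason[i]))
    if (status[i] == "reference")
      return(list(status = "reference", call = NULL, reason = NA_character_))
    list(status = "deletion",
         call = data.frame(start = start[i], length = len[i]),
         reason = NA_character_)
  }
  mate_span <- function(i) {
    if (is.na(span_s[i])) NULL else c(span_s[i], span_e[i])
  }
  for (k in seq_along(grp)) {
    idx <- grp[[k]]
    rec <- if (length(idx) == 1L) {
      r <- mate_result(idx)
      if (identical(r, "unmapped"))
        list(status = "discarded", call = NULL, reason = "unmapped") else r
    } else {
      reconcile_mates(mate_result(idx[1]), mate_result(idx[2]),
                      mate_span(idx[1]), mate_span(idx[2]))
    }
    out_status[k] <- rec$status
    out_reason[k] <- rec$reason
    if (rec$status == "deletion") {
      out_start[k] <- rec$call$start; out_len[k] <- rec$call$length
    }
  }
  out <- data.frame(fragment_id = names(grp), library = library,
                    status = out_status, start = out_start, length = out_len,
                    reason = out_reason, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "discard_counts") <- table(out$reason[out$status == "discarded"])
  out
}
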