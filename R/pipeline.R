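#' Build a validated run configuration
#'
#' All numeric thresholds of the screen analysis in one place, defaulting to
#' the values used throughout the package: read-edge distance 8 nt,
#' analyzable deletion lengths 3-29 nt, abundance cutoff 6.5 reads per 1e7
#' reads (with per-library absolute minima 8 RNA / 16 DNA in the alternative
#' mode), at least 4 distinct deletions per analyzed position, alpha 0.05.
#' An optional YAML file overrides the defaults; explicit arguments override
#' the file. The `alignment` block is documentation echoed to the run log
#' for users aligning FASTQ externally (end-to-end, max 20 mismatches, min
#' 40 matched bases, no multi-mapping); the pipeline itself consumes SAM.
#'
#' @param path optional YAML config file.
#' @param ... named overrides of individual keys.
#' @return named list of validated settings, class `run_config`.
#' @export
read_run_config <- function(path = NULL, ...) {
  cfg <- list(
    reference = NULL, record = NULL,
    polya_site = NULL, polya_signal = NULL, stop_codon_end = 0L,
    edge_distance = 8L, error_max_len = 2L,
    min_len = 3L, max_len = 29L,
    abundance_per_1e7 = 6.5, abundance_mode = "per-library",
    min_rna = 8L, min_dna = 16L,
    alpha = 0.05, bootstrap_B = 1000L,
    min_deletions_per_position = 4L,
    seed = 1L,
    simulator = list(depths = c(dna = 2e5, rna = 112500),
                     read_length = 150L, error_rate = 1e-3,
                     n_per_cut = 8L, dual_cut_prob = 0.15,
                     intact_fraction = 0.3, baseline_ratio = 0.5),
    alignment = list(mode = "end-to-end", max_mismatches = 20L,
                     min_matched_bases = 40L, multimappers = "disallowed"))
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  cfg <- utils::modifyList(cfg, list(...))
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  if (!(cfg$alpha > 0 && cfg$alpha < 1)) stop("alpha must be in (0, 1)")
  if (cfg$min_len > cfg$max_len) stop("min_len must be <= max_len")
  for (key in c("edge_distance", "min_len", "max_len", "abundance_per_1e7",
                "min_deletions_per_position", "min_rna", "min_dna"))
    if (cfg[[key]] <= 0) stop(key, " must be positive")
  if (!cfg$abundance_mode %in% c("per-library", "absolute"))
    stop("abundance_mode must be 'per-library' or 'absolute'")
  invisible(cfg)
}

#' Run the full screen analysis
#'
#' SAM in, activity map out: calls per-fragment deletions in the DNA and
#' RNA libraries, groups distinct deletions, applies the abundance and
#' length filters, computes RNA/DNA ratios, builds the per-nucleotide map,
#' and writes every table plus a run log to `out_dir`. Outputs are
#' deterministic given inputs, config and seed.
#'
#' @param config a [read_run_config()] result.
#' @param ref a [utr_reference()] (or NULL to load `config$reference`).
#' @param dna_sam,rna_sam aligned paired-end SAM files for the genomic-DNA
#'   and cDNA libraries.
#' @param out_dir output directory.
#' @return invisibly, a list with the in-memory results (`fragments`,
#'   `deletions`, `summary`, `map`) and output `paths`.
#' @export
run_pipeline <- function(config, ref = NULL, dna_sam, rna_sam, out_dir) {
  if (is.null(ref)) {
    if (is.null(config$reference)) stop("no reference given")
    ref <- load_reference(config$reference, record = config$record,
                          polya_site = config$polya_site,
                          polya_signal = config$polya_signal,
                          stop_codon_end = config$stop_codon_end)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character()
  say <- function(...) log <<- c(log, sprintf(...))
  say("reference name=%s length=%d", ref$name, ref$length)
  say("thresholds edge=%d len=[%d,%d] abundance=%.2f/1e7 mode=%s minpos=%d alpha=%g seed=%d B=%d",
      config$edge_distance, config$min_len, config$max_len,
      config$abundance_per_1e7, config$abundance_mode,
      config$min_deletions_per_position, config$alpha, config$seed,
      config$bootstrap_B)
  frags <- list()
  for (lib in c("DNA", "RNA")) {
    sam <- if (lib == "DNA") dna_sam else rna_sam
    recs <- read_sam(sam)
    tg <- attr(recs, "header_targets")
    if (!(ref$name %in% names(tg)) || tg[[ref$name]] != ref$length)
      stop("SAM header of ", sam, " does not match reference '", ref$name,
           "' (", ref$length, " nt)")
    fc <- call_fragments(recs, library = lib,
                         edge_distance = config$edge_distance,
                         error_max_len = config$error_max_len)
    dc <- attr(fc, "discard_counts")
    say("stage=call library=%s fragments=%d reference=%d deletion=%d discarded=%d [%s]",
        lib, nrow(fc), sum(fc$status == "reference"),
        sum(fc$status == "deletion"), sum(fc$status == "discarded"),
        paste(names(dc), as.integer(dc), sep = ":", collapse = " "))
    frags[[lib]] <- fc
  }
  fragments <- do.call(rbind, frags)
  rownames(fragments) <- NULL
  dels <- group_distinct(fragments)
  summ <- library_summary(fragments)
  kept <- filter_abundance(dels, summ, min_per_1e7 = config$abundance_per_1e7,
                           min_len = config$min_len, max_len = config$max_len,
                           mode = config$abundance_mode,
                           min_rna = config$min_rna, min_dna = config$min_dna)
  say("stage=quantify distinct=%d retained=%d", nrow(dels), nrow(kept))
  rq <- compute_ratios(kept, summ)
  say("stage=quantify reference_ratio=%.6g total_r=%.6g",
      rq$summary$reference_ratio[1], rq$summary$total_r[1])
  map <- build_map(rq$deletions, ref, alpha = config$alpha,
                   B = config$bootstrap_B, seed = config$seed,
                   min_deletions = config$min_deletions_per_position)
  say("stage=map analyzed=%d significant_positions=%d intervals=%d",
      map$n_analyzed, sum(map$positions$significant),
      nrow(map$significant_intervals))
  paths <- list(
    fragments = file.path(out_dir, "fragments.tsv"),
    deletions = file.path(out_dir, "distinct_deletions.tsv"),
    summary = file.path(out_dir, "library_summary.tsv"),
    position_map = file.path(out_dir, "position_map.tsv"),
    significant_bed = file.path(out_dir, "significant_intervals.bed"),
    log = file.path(out_dir, "run_log.txt"))
  wt <- function(d, p) utils::write.table(
    d, p, sep = "\t", quote = FALSE, row.names = FALSE)
  wt(fragments, paths$fragments)
  wt(rq$deletions, paths$deletions)
  wt(rq$summary, paths$summary)
  wt(format_map_tsv(map$positions), paths$position_map)
  write_significant_bed(map$significant_intervals, ref, paths$significant_bed)
  writeLines(log, paths$log)
  invisible(list(fragments = fragments, deletions = rq$deletions,
                 summary = rq$summary, map = map, paths = paths))
}

# fixed-precision numeric formatting so identical runs are byte-identical
format_map_tsv <- function(positions) {
  num <- vapply(positions, is.double, logical(1))
  positions[num] <- lapply(positions[num], function(x)
    ifelse(is.na(x), "NA", formatC(x, digits = 8, format = "g")))
  positions
}

write_significant_bed <- function(intervals, ref, path) {
  if (!nrow(intervals)) {
    file.create(path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = ref$name,
    ranges = IRanges::IRanges(start = intervals$start + 1L,
                              end = intervals$end))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
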