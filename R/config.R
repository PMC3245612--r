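#' Pipeline run configuration
#'
#' Builds the configuration object consumed by every pipeline stage. The
#' defaults are the published algorithm constants: 25-bp read segments with
#' the final segment absorbing any remainder, at most 2 mismatches per
#' segment, a multi-mapping bound of M = 2 placements, 13-bp minimum anchors
#' with at most 2 mismatches for fusion-spanning reads, a 100,000-bp minimum
#' separation for same-chromosome fusions (anything closer on the same
#' strand is treated as read-through transcription, not a fusion), 22-bp
#' flanks giving 44-bp spliced fusion contigs that junction-crossing
#' segments must overlap by at least 3 bp, a 23-mer repeat filter, and a
#' 600-bp coverage window (300 bp per side).
#'
#' @param segment_length Segment size reads are split into (bp).
#' @param max_segment_mismatches Mismatch bound per segment alignment (0-3).
#' @param max_read_mismatches Mismatch bound for whole-read gap-free
#'   alignment; reads exceeding it everywhere become IUM.
#' @param multimap_bound_M Maximum number of placements a read (or segment)
#'   may have; more and it is discarded as repetitive.
#' @param min_anchor Minimum aligned bases required on both sides of a
#'   fusion point for a spanning read.
#' @param max_anchor_mismatches Mismatch bound for a spanning read.
#' @param min_intra_distance Minimum same-chromosome, same-strand breakpoint
#'   separation for a fusion (bp); smaller separations are read-through.
#' @param flank_length Bases extracted on each side of a candidate
#'   breakpoint; the spliced fusion contig is `2 * flank_length` bp.
#' @param min_contig_overlap Minimum bases by which a segment must cross the
#'   contig junction, on both sides.
#' @param repeat_kmer Length of the junction-flanking words used by the
#'   repeat filter.
#' @param window_half Half-width of the coverage window around a fusion (bp
#'   per side).
#' @param max_intron_length Largest same-strand genomic gap stitched as an
#'   intron. The default equals `min_intra_distance` so that same-strand
#'   gaps partition cleanly into introns (including read-through events)
#'   below the cutoff and fusions at or above it.
#' @param max_indel Largest genomic offset stitched as an indel (bp).
#' @param min_covered_fraction Minimum fraction of covered bases required on
#'   each side of the coverage window.
#' @param support_preset One of `"breast"`, `"vcap"`, `"uhr_paired"`,
#'   `"uhr_single"`, `"custom"`; see [support_filter()].
#' @param min_spanning,min_pairs,min_sum Thresholds used when
#'   `support_preset = "custom"`: keep if (spanning >= min_spanning AND
#'   pairs >= min_pairs) OR spanning + pairs >= min_sum.
#' @param inner_dist_mean,inner_dist_sd Expected inner mate distance and its
#'   standard deviation (bp), used for mate-based breakpoint narrowing and
#'   supporting-pair distance bounds.
#' @param index_k k-mer size of the genome index. The default 8 keeps the
#'   pigeonhole completeness guarantee for 25-bp segments at 2 mismatches
#'   (`(max_mismatches + 1) * k <= segment_length`).
#' @param collapse_radius Junction-jitter collapse: a candidate whose two
#'   breakpoints both lie within this many bases of another candidate with
#'   the same chromosomes and strands but strictly more spanning reads is
#'   treated as a base-call-error echo of that junction and absorbed by
#'   it. Genuine alternative fusion points (different exon boundaries) are
#'   far outside this radius. 0 disables.
#' @param penalty_intron,penalty_indel,penalty_fusion Alignment penalties;
#'   default-locked to -2 / -4 / -4.
#' @param max_hits_per_contig_segment Cap on contig placements per segment.
#' @return A list of class `fs_config`.
#' @export
run_config <- function(segment_length = 25L,
                       max_segment_mismatches = 2L,
                       max_read_mismatches = 2L,
                       multimap_bound_M = 2L,
                       min_anchor = 13L,
                       max_anchor_mismatches = 2L,
                       min_intra_distance = 100000L,
                       flank_length = 22L,
                       min_contig_overlap = 3L,
                       repeat_kmer = 23L,
                       window_half = 300L,
                       max_intron_length = 100000L,
                       max_indel = 3L,
                       min_covered_fraction = 0.5,
                       support_preset = "breast",
                       min_spanning = 0L,
                       min_pairs = 0L,
                       min_sum = 0L,
                       inner_dist_mean = 200L,
                       inner_dist_sd = 30L,
                       index_k = 8L,
                       collapse_radius = 5L,
                       penalty_intron = -2L,
                       penalty_indel = -4L,
                       penalty_fusion = -4L,
                       max_hits_per_contig_segment = 16L) {
  cfg <- list(
    segment_length = as.integer(segment_length),
    max_segment_mismatches = as.integer(max_segment_mismatches),
    max_read_mismatches = as.integer(max_read_mismatches),
    multimap_bound_M = as.integer(multimap_bound_M),
    min_anchor = as.integer(min_anchor),
    max_anchor_mismatches = as.integer(max_anchor_mismatches),
    min_intra_distance = as.integer(min_intra_distance),
    flank_length = as.integer(flank_length),
    min_contig_overlap = as.integer(min_contig_overlap),
    repeat_kmer = as.integer(repeat_kmer),
    window_half = as.integer(window_half),
    max_intron_length = as.integer(max_intron_length),
    max_indel = as.integer(max_indel),
    min_covered_fraction = as.numeric(min_covered_fraction),
    support_preset = as.character(support_preset),
    min_spanning = as.integer(min_spanning),
    min_pairs = as.integer(min_pairs),
    min_sum = as.integer(min_sum),
    inner_dist_mean = as.integer(inner_dist_mean),
    inner_dist_sd = as.integer(inner_dist_sd),
    index_k = as.integer(index_k),
    collapse_radius = as.integer(collapse_radius),
    penalty_intron = as.integer(penalty_intron),
    penalty_indel = as.integer(penalty_indel),
    penalty_fusion = as.integer(penalty_fusion),
    max_hits_per_contig_segment = as.integer(max_hits_per_contig_segment)
  )
  validate_config(cfg)
  structure(cfg, class = "fs_config")
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) fs_config_error(msg)
  chk(cfg$segment_length >= 1L, "segment_length must be >= 1")
  chk(cfg$max_segment_mismatches >= 0L && cfg$max_segment_mismatches <= 3L,
      "max_segment_mismatches must be in 0..3")
  chk(cfg$min_contig_overlap < cfg$segment_length,
      "min_contig_overlap must be smaller than segment_length")
  chk(cfg$window_half > 0L, "window_half must be positive")
  chk(cfg$flank_length >= cfg$min_contig_overlap,
      "flank_length must be at least min_contig_overlap")
  chk(cfg$min_anchor >= 1L, "min_anchor must be >= 1")
  chk(cfg$min_intra_distance >= 0L, "min_intra_distance must be >= 0")
  chk(cfg$inner_dist_mean >= 0L, "inner_dist_mean must be >= 0")
  chk(cfg$inner_dist_sd >= 0L, "inner_dist_sd must be >= 0")
  chk(cfg$index_k >= 1L && cfg$index_k <= 31L, "index_k must be in 1..31")
  chk((cfg$max_segment_mismatches + 1L) * cfg$index_k <= cfg$segment_length,
      "segment alignment is only guaranteed complete when (max_segment_mismatches + 1) * index_k <= segment_length; lower index_k")
  chk(cfg$support_preset %in%
        c("breast", "vcap", "uhr_paired", "uhr_single", "custom"),
      sprintf("unknown support preset '%s'", cfg$support_preset))
  invisible(cfg)
}

#' Read a run configuration from a flat key-value file
#'
#' Accepts lines of the form `key: value` or `key = value`; blank lines and
#' `#` comments are ignored. Keys must be arguments of [run_config()];
#' unknown keys are a configuration error.
#'
#' @param path Path to the configuration file.
#' @param base Configuration the file overrides (defaults to
#'   `run_config()`).
#' @return An `fs_config` object.
#' @export
read_run_config <- function(path, base = run_config()) {
  if (!file.exists(path)) fs_input_error(sprintf("config file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- unclass(base)
  for (i in seq_along(lines)) {
    m <- regmatches(lines[i], regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*[:=]\\s*(.+)$", lines[i]))[[1]]
    if (length(m) != 3L)
      fs_config_error(sprintf("cannot parse config line %d: '%s'", i, lines[i]))
    key <- m[2]; val <- trimws(m[3])
    if (!key %in% names(out))
      fs_config_error(sprintf("unknown config key '%s' (line %d)", key, i))
    out[[key]] <- if (is.character(out[[key]])) val
      else if (is.integer(out[[key]])) as.integer(round(as.numeric(val)))
      else as.numeric(val)
    if (!is.character(out[[key]]) && is.na(out[[key]]))
      fs_config_error(sprintf("non-numeric value for config key '%s'", key))
  }
  do.call(run_config, out)
}

#' Per-dataset read-support presets
#'
#' Returns the decision rule of each built-in support preset as a predicate
#' over spanning-read and supporting-pair counts:
#' * `breast` — at least 2 supporting pairs AND spanning + pairs >= 5;
#' * `vcap` — spanning + pairs >= 10;
#' * `uhr_paired` — (3 spanning AND 2 pairs) OR spanning + pairs >= 10;
#' * `uhr_single` — at least 2 spanning reads.
#'
#' @param name Preset name.
#' @return A function `(spanning, pairs) -> logical`.
#' @export
support_preset_rule <- function(name) {
  switch(name,
    breast     = function(spanning, pairs) pairs >= 2L & (spanning + pairs) >= 5L,
    vcap       = function(spanning, pairs) (spanning + pairs) >= 10L,
    uhr_paired = function(spanning, pairs)
      (spanning >= 3L & pairs >= 2L) | (spanning + pairs) >= 10L,
    uhr_single = function(spanning, pairs) spanning >= 2L,
    fs_config_error(sprintf("unknown support preset '%s'", name))
  )
}
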