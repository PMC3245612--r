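# False-positive filter cascade: anchor length, multi-mapping, genomic
# distance class, read support, junction-word repeats, gene annotation and
# the 600-bp coverage window.

#' Anchor filter for fusion-spanning reads
#'
#' A read mapping across a fusion point must have at least `min_anchor`
#' bases aligned on both sides of the junction and at most
#' `max_anchor_mismatches` mismatches in total.
#'
#' @param alignment An [fs_alignment()] containing a fusion event.
#' @param config An [run_config()].
#' @return TRUE when the alignment qualifies as spanning evidence.
#' @export
anchor_filter <- function(alignment, config = run_config()) {
  fus <- which(alignment$joins$type == "fusion")
  if (length(fus) != 1L)
    fs_input_error("anchor_filter requires an alignment with one fusion event")
  sides <- fusion_side_bases(alignment)
  min(sides) >= config$min_anchor &&
    alignment$mismatches <= config$max_anchor_mismatches
}

fusion_side_bases <- function(alignment) {
  fus <- which(alignment$joins$type == "fusion")
  b <- alignment$blocks
  left <- sum(b$read_end[seq_len(fus)] - b$read_start[seq_len(fus)])
  right <- sum(b$read_end[-seq_len(fus)] - b$read_start[-seq_len(fus)])
  c(left = left, right = right)
}

#' Multi-mapping filter
#'
#' Reads (or segments) with more than `multimap_bound_M` placements are
#' discarded as repetitive; up to M placements are all considered.
#'
#' @param hit_count Number of placements.
#' @param config An [run_config()].
#' @return TRUE to keep.
#' @export
multimap_filter <- function(hit_count, config = run_config())
  hit_count <= config$multimap_bound_M

#' Classify a candidate by its genomic geometry
#'
#' Different chromosomes are inter-chromosomal fusions; the same chromosome
#' qualifies as intra-chromosomal when the breakpoints are at least
#' `min_intra_distance` apart or on opposite strands (inversions). A
#' same-chromosome, same-strand pair below the distance threshold is
#' rejected as likely read-through transcription.
#'
#' @param candidate An [fusion_candidate()].
#' @param config An [run_config()].
#' @return `"inter"`, `"intra"` or `"rejected"`.
#' @export
classify_candidate <- function(candidate, config = run_config()) {
  cls <- classify_candidate_sides(candidate$left, candidate$right, config)
  if (cls == "inversion") "intra" else cls
}

# --- support counting --------------------------------------------------------

# Tabular views of the selected alignments used by support counting and
# coverage profiling. gapfree: one row per selected gap-free (single-block)
# alignment; fusion: one row per selected fusion-spanning alignment.
support_tables <- function(gapfree, fusion) {
  list(gapfree = gapfree, fusion = fusion)
}

# side membership helpers: is a gap-free block on the transcribed side of a
# breakpoint, and how far does its outer end reach from the junction?
on_side <- function(blocks, side, which_side, maxspan) {
  pos <- as.integer(side[["pos"]])
  ok_chrom <- blocks$chrom == side[["chrom"]]
  towards <- (which_side == "left") == (side[["strand"]] == "+")
  if (towards) {
    # transcribed side occupies coordinates <= pos
    dist <- pos - blocks$start + 1L
    ok <- ok_chrom & blocks$end - 1L <= pos & dist <= maxspan
  } else {
    dist <- blocks$end - pos
    ok <- ok_chrom & blocks$start >= pos & dist <= maxspan
  }
  list(ok = ok, dist = ifelse(ok, dist, NA_integer_))
}

# inter-base boundary coordinate of a breakpoint side (junction lies
# between column c-1 and c of the side's chromosome)
boundary_coord <- function(side, which_side) {
  pos <- as.integer(side[["pos"]])
  if (which_side == "left") {
    if (side[["strand"]] == "+") pos + 1L else pos
  } else {
    if (side[["strand"]] == "+") pos else pos + 1L
  }
}

#' Count read support for a fusion candidate
#'
#' Spanning reads are selected alignments whose fusion event matches the
#' candidate exactly and pass the anchor rule. Supporting pairs are read
#' pairs whose two ends map consistently to the two sides in the
#' fusion-implied orientation within fragment-length bounds (a pair
#' containing a spanning read counts in both tallies). Contradicting reads
#' are gap-free alignments crossing either breakpoint boundary by at least
#' `min_anchor` bases on both sides.
#'
#' @param candidate An [fusion_candidate()].
#' @param selected Either a list of selected [fs_alignment()]s or the
#'   internal precomputed tables (as built by the pipeline).
#' @param reads Optional data.frame from [read_fastq()] (pairing
#'   information); NULL for single-end evidence.
#' @param config An [run_config()].
#' @return List with `spanning_reads`, `supporting_pairs`,
#'   `contradicting_reads` and `dist_sum` (summed end-to-junction
#'   distances over supporting pairs, or spanning-read left-anchor sizes
#'   for single-end data).
#' @export
count_support <- function(candidate, selected, reads = NULL,
                          config = run_config()) {
  tabs <- if (is.list(selected) && !is.null(selected$gapfree)) selected
          else tables_from_alignments(selected, reads, config)
  gf <- tabs$gapfree; fu <- tabs$fusion
  maxspan <- config$inner_dist_mean + 4L * config$inner_dist_sd +
    2L * max(c(gf$end - gf$start, 1L))

  span_rows <- fu[fu$key == candidate$key & fu$anchor_ok, , drop = FALSE]
  spanning <- nrow(span_rows)

  # contradicting: gap-free reads crossing either boundary
  bl <- boundary_coord(candidate$left, "left")
  br <- boundary_coord(candidate$right, "right")
  contra <- sum((gf$chrom == candidate$left[["chrom"]] &
                   gf$start <= bl - config$min_anchor &
                   gf$end >= bl + config$min_anchor) |
                (gf$chrom == candidate$right[["chrom"]] &
                   gf$start <= br - config$min_anchor &
                   gf$end >= br + config$min_anchor))

  pairs <- 0L; dist_sum <- 0
  paired <- !is.null(gf$pair_id) && any(!is.na(gf$pair_id))
  if (paired) {
    onL <- on_side(gf, candidate$left, "left", maxspan)
    onR <- on_side(gf, candidate$right, "right", maxspan)
    sL <- candidate$left[["strand"]]; sR <- candidate$right[["strand"]]
    flip <- function(s) ifelse(s == "+", "-", "+")
    # both-ends-gap-free pairs, consistent with one fragment orientation
    cand_ids <- unique(c(gf$pair_id[onL$ok], gf$pair_id[onR$ok]))
    cand_ids <- cand_ids[!is.na(cand_ids)]
    sup_ids <- integer(0)
    for (pid in cand_ids) {
      rows <- which(gf$pair_id == pid)
      if (length(rows) != 2L) next
      for (perm in list(rows, rev(rows))) {
        i <- perm[1]; j <- perm[2]
        if (isTRUE(onL$ok[i]) && isTRUE(onR$ok[j]) &&
            ((gf$strand[i] == sL && gf$strand[j] == flip(sR)) ||
             (gf$strand[i] == flip(sL) && gf$strand[j] == sR)) &&
            onL$dist[i] + onR$dist[j] <= maxspan) {
          sup_ids <- c(sup_ids, pid)
          dist_sum <- dist_sum + onL$dist[i] + onR$dist[j]
          break
        }
      }
    }
    # pairs in which one end itself spans the fusion
    span_pids <- span_rows$pair_id[!is.na(span_rows$pair_id)]
    for (pid in setdiff(unique(span_pids), sup_ids)) {
      rows <- which(gf$pair_id == pid)
      ok <- FALSE; d <- 0
      for (i in rows) {
        if (isTRUE(onL$ok[i])) { ok <- TRUE; d <- onL$dist[i]; break }
        if (isTRUE(onR$ok[i])) { ok <- TRUE; d <- onR$dist[i]; break }
      }
      if (ok) { sup_ids <- c(sup_ids, pid); dist_sum <- dist_sum + d }
    }
    pairs <- length(unique(sup_ids))
  } else {
    # single-end: distances of spanning-read starts to the junction
    dist_sum <- sum(span_rows$left_bases)
  }
  list(spanning_reads = as.integer(spanning),
       supporting_pairs = as.integer(pairs),
       contradicting_reads = as.integer(contra),
       dist_sum = as.numeric(dist_sum))
}

# Build support tables from a plain list of selected alignments (the
# pipeline builds them vectorised instead).
tables_from_alignments <- function(alignments, reads, config) {
  gf <- list(); fu <- list()
  for (al in alignments) {
    pid <- NA_integer_
    if (!is.null(reads)) {
      i <- match(al$read_id, reads$id)
      if (!is.na(i)) pid <- reads$pair_id[i]
    }
    if (is.null(al$fusion)) {
      if (nrow(al$blocks) == 1L)
        gf[[length(gf) + 1L]] <- data.frame(
          read_id = al$read_id, chrom = al$blocks$chrom,
          start = al$blocks$start, end = al$blocks$end,
          strand = al$blocks$strand, pair_id = pid,
          stringsAsFactors = FALSE)
    } else {
      sides <- fusion_side_bases(al)
      fu[[length(fu) + 1L]] <- data.frame(
        read_id = al$read_id, key = al$fusion$key,
        left_bases = sides[["left"]], right_bases = sides[["right"]],
        anchor_ok = anchor_filter(al, config), pair_id = pid,
        stringsAsFactors = FALSE)
    }
  }
  empty_gf <- data.frame(read_id = character(), chrom = character(),
                         start = integer(), end = integer(),
                         strand = character(), pair_id = integer(),
                         stringsAsFactors = FALSE)
  empty_fu <- data.frame(read_id = character(), key = character(),
                         left_bases = integer(), right_bases = integer(),
                         anchor_ok = logical(), pair_id = integer(),
                         stringsAsFactors = FALSE)
  support_tables(if (length(gf)) do.call(rbind, gf) else empty_gf,
                 if (length(fu)) do.call(rbind, fu) else empty_fu)
}

#' Read-support filter
#'
#' Applies one of the per-dataset support presets (see
#' [support_preset_rule()]) or the custom rule
#' `(spanning >= min_spanning AND pairs >= min_pairs) OR
#' spanning + pairs >= min_sum`.
#'
#' @param support Result of [count_support()] (or any list with
#'   `spanning_reads` and `supporting_pairs`).
#' @param config An [run_config()].
#' @return TRUE to keep the candidate.
#' @export
support_filter <- function(support, config = run_config()) {
  s <- support$spanning_reads; p <- support$supporting_pairs
  if (config$support_preset == "custom")
    return((s >= config$min_spanning && p >= config$min_pairs) ||
             (s + p) >= config$min_sum)
  support_preset_rule(config$support_preset)(s, p)
}

#' Junction-word repeat filter
#'
#' Extracts the `repeat_kmer`-base word ending at the left breakpoint and
#' the one starting at the right breakpoint (transcript orientation),
#' enumerates every exact genomic placement of each (both strands), and
#' eliminates the candidate when any placement of one word lies within
#' `min_intra_distance` (100 kb) of any placement of the other on the same
#' chromosome — the signature of a repeat-induced artifact.
#'
#' @param index A genome [build_index()].
#' @param genome The matching [fs_genome()].
#' @param candidate An [fusion_candidate()].
#' @param config An [run_config()].
#' @return TRUE to keep, FALSE to eliminate.
#' @export
repeat_filter <- function(index, genome, candidate, config = run_config()) {
  k <- config$repeat_kmer
  lw <- side_flank_left(genome, candidate$left, k)
  rw <- side_flank_right(genome, candidate$right, k)
  if (is.null(lw) || is.null(rw)) {
    warning(sprintf("candidate %s: breakpoint closer than %d bp to a chromosome end; repeat filter passes trivially",
                    candidate$key, k))
    return(TRUE)
  }
  hits <- align_exactish(index, c(lw, rw), max_mismatches = 0L,
                         max_hits = Inf)
  hl <- hits[hits$query == 1L, , drop = FALSE]
  hr <- hits[hits$query == 2L, , drop = FALSE]
  for (c in intersect(unique(hl$chrom), unique(hr$chrom))) {
    a <- hl$start[hl$chrom == c]; b <- hr$start[hr$chrom == c]
    if (min(abs(outer(a, b, "-"))) <= config$min_intra_distance)
      return(FALSE)
  }
  TRUE
}

#' Gene-annotation filter
#'
#' Keeps a candidate only when at least one breakpoint lies within an
#' annotated gene interval.
#'
#' @param candidate An [fusion_candidate()].
#' @param annotation An `fs_annotation` data.frame from [read_bed()].
#' @return TRUE to keep.
#' @export
annotation_filter <- function(candidate, annotation) {
  inside <- function(side) {
    pos <- as.integer(side[["pos"]])
    any(annotation$chrom == side[["chrom"]] &
          annotation$start <= pos & pos < annotation$end)
  }
  inside(candidate$left) || inside(candidate$right)
}

#' Per-base depth profile around a fusion
#'
#' Computes per-base read depth over the `window_half`-bp window on each
#' side of the breakpoint (transcript orientation; positions off the
#' chromosome end count as depth 0).
#'
#' @param candidate An [fusion_candidate()].
#' @param blocks data.frame of all selected-alignment blocks (`chrom`,
#'   `start`, `end`).
#' @param config An [run_config()].
#' @return List with numeric vectors `ldepth` and `rdepth` of length
#'   `window_half`.
#' @export
depth_profile <- function(candidate, blocks, config = run_config()) {
  wh <- config$window_half
  win <- function(side, which_side) {
    pos <- as.integer(side[["pos"]])
    towards <- (which_side == "left") == (side[["strand"]] == "+")
    if (towards) c(pos - wh + 1L, pos) else c(pos, pos + wh - 1L)
  }
  depth_in <- function(side, rng) {
    d <- numeric(rng[2] - rng[1] + 1L)
    b <- blocks[blocks$chrom == side[["chrom"]] & blocks$start <= rng[2] &
                  blocks$end > rng[1], , drop = FALSE]
    for (i in seq_len(nrow(b))) {
      lo <- max(b$start[i], rng[1]); hi <- min(b$end[i] - 1L, rng[2])
      idx <- (lo - rng[1] + 1L):(hi - rng[1] + 1L)
      d[idx] <- d[idx] + 1
    }
    d
  }
  list(ldepth = depth_in(candidate$left, win(candidate$left, "left")),
       rdepth = depth_in(candidate$right, win(candidate$right, "right")))
}

#' Coverage-window filter
#'
#' True fusions are covered by reads across a wide window around the
#' junction; artifacts are covered only narrowly or on one side. Rejects a
#' candidate when the covered fraction of either side of the 600-bp window
#' falls below `min_covered_fraction`.
#'
#' @param profile A [depth_profile()] result.
#' @param config An [run_config()].
#' @return TRUE to keep.
#' @export
coverage_window_filter <- function(profile, config = run_config()) {
  mean(profile$ldepth > 0) >= config$min_covered_fraction &&
    mean(profile$rdepth > 0) >= config$min_covered_fraction
}
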