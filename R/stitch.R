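# Stitching per-segment placements into full-read alignments, scoring and
# per-read selection.

#' Construct a full-read alignment
#'
#' @param read_id Read identifier.
#' @param seq Read sequence as sequenced.
#' @param blocks data.frame of aligned blocks in read order: `chrom`,
#'   `start`, `end` (0-based half-open), `strand`, `read_start`,
#'   `read_end`.
#' @param joins data.frame (`type`, `length`) with one row per junction
#'   between consecutive blocks; types `intron`, `deletion`, `insertion`,
#'   `fusion`.
#' @param fusion NULL, or list `(left, right, key)` naming the breakpoint
#'   sides (in the read's orientation) and the canonical candidate key.
#' @param mismatches Total mismatch count.
#' @param config An [run_config()] (penalty constants).
#' @return List of class `fs_alignment` with a `penalty` field.
#' @export
fs_alignment <- function(read_id, seq, blocks, joins = empty_joins(),
                         fusion = NULL, mismatches = 0L,
                         config = run_config()) {
  al <- structure(list(read_id = read_id, seq = seq, blocks = blocks,
                       joins = joins, fusion = fusion,
                       mismatches = as.integer(mismatches), penalty = 0L),
                  class = "fs_alignment")
  al$penalty <- score_alignment(al, config)
  al
}

empty_joins <- function()
  data.frame(type = character(), length = integer(), stringsAsFactors = FALSE)

#' Penalty of a full alignment
#'
#' Gap-free alignments score 0; each spanned intron costs -2, each indel
#' -4, each fusion -4 (defaults; configurable). Higher (less negative) is
#' better.
#'
#' @param alignment An [fs_alignment()].
#' @param config An [run_config()].
#' @return Integer penalty.
#' @export
score_alignment <- function(alignment, config = run_config()) {
  ty <- alignment$joins$type
  as.integer(sum(ty == "intron") * config$penalty_intron +
             sum(ty %in% c("deletion", "insertion")) * config$penalty_indel +
             sum(ty == "fusion") * config$penalty_fusion)
}

#' Select the best alignment for one read
#'
#' Orders candidates by penalty (least negative first), then by fewest
#' mismatches, then by the (chrom, start, strand) of the first block so
#' that exact ties resolve deterministically. A gap-free alignment with
#' three mismatches therefore beats a fusion alignment with one mismatch;
#' between a fusion and a deletion at equal penalty, the fewer mismatches
#' win.
#'
#' @param alignments List of [fs_alignment()] for one read (may be empty).
#' @param config An [run_config()].
#' @return The chosen alignment, or NULL for an empty list.
#' @export
select_best <- function(alignments, config = run_config()) {
  if (length(alignments) == 0L) return(NULL)
  pen <- vapply(alignments, `[[`, integer(1), "penalty")
  mm <- vapply(alignments, `[[`, integer(1), "mismatches")
  ch <- vapply(alignments, function(a) a$blocks$chrom[1], "")
  st <- vapply(alignments, function(a) a$blocks$start[1], numeric(1))
  sd <- vapply(alignments, function(a) a$blocks$strand[1], "")
  alignments[[order(-pen, mm, ch, st, sd)[1]]]
}

# A placement is one segment's contribution to a chain: one genomic block,
# or a contig hit's two blocks with an internal fusion join.
genome_placement <- function(hit, rs, re) {
  len <- re - rs
  list(blocks = data.frame(chrom = hit$chrom, start = hit$start,
                           end = hit$start + len, strand = hit$strand,
                           read_start = rs, read_end = re,
                           stringsAsFactors = FALSE),
       joins = empty_joins(), fusion = NULL, mismatches = hit$mismatches)
}

contig_placement <- function(chit, seg_off) {
  b <- chit$blocks
  list(blocks = data.frame(chrom = b$chrom, start = b$start, end = b$end,
                           strand = b$strand,
                           read_start = b$seg_start + seg_off,
                           read_end = b$seg_end + seg_off,
                           stringsAsFactors = FALSE),
       joins = data.frame(type = "fusion", length = 0L,
                          stringsAsFactors = FALSE),
       fusion = list(left = chit$left, right = chit$right, key = chit$key),
       mismatches = chit$mismatches)
}

# How two consecutive blocks connect; NULL if they cannot.
connect_blocks <- function(prev, nxt, candidate_keys, fusion_allowed, config) {
  if (prev$chrom == nxt$chrom && prev$strand == nxt$strand) {
    gap <- if (prev$strand == "+") nxt$start - prev$end else prev$start - nxt$end
    if (gap == 0L) return(list(kind = "merge"))
    if (gap >= 1L && gap <= config$max_indel)
      return(list(kind = "join", type = "deletion", length = gap))
    if (gap > config$max_indel && gap <= config$max_intron_length)
      return(list(kind = "join", type = "intron", length = gap))
    if (gap < 0L && -gap <= config$max_indel)
      return(list(kind = "join", type = "insertion", length = -gap))
  }
  if (!fusion_allowed) return(NULL)
  pl <- if (prev$strand == "+") prev$end - 1L else prev$start
  pr <- if (nxt$strand == "+") nxt$start else nxt$end - 1L
  left <- side_vec(prev$chrom, pl, prev$strand)
  right <- side_vec(nxt$chrom, pr, nxt$strand)
  key <- min(cand_key(left, right),
             cand_key(flip_side(right), flip_side(left)))
  if (!key %in% candidate_keys) return(NULL)
  list(kind = "fusion", left = left, right = right, key = key)
}

# Append a placement to a partial chain state; NULL if incompatible.
extend_chain <- function(state, placement, candidate_keys, config) {
  blocks <- state$blocks; joins <- state$joins
  fusion <- state$fusion; mism <- state$mismatches
  pb <- placement$blocks
  for (i in seq_len(nrow(pb))) {
    nxt <- pb[i, , drop = FALSE]
    if (i > 1L) {
      # internal fusion join of a contig placement
      if (!is.null(fusion)) return(NULL)
      fusion <- placement$fusion
      joins <- rbind(joins, data.frame(type = "fusion", length = 0L,
                                       stringsAsFactors = FALSE))
      blocks <- rbind(blocks, nxt)
      next
    }
    if (is.null(blocks)) { blocks <- nxt; next }
    prev <- blocks[nrow(blocks), , drop = FALSE]
    cn <- connect_blocks(prev, nxt, candidate_keys, is.null(fusion), config)
    if (is.null(cn)) return(NULL)
    if (cn$kind == "merge") {
      if (prev$strand == "+") blocks$end[nrow(blocks)] <- nxt$end
      else blocks$start[nrow(blocks)] <- nxt$start
      blocks$read_end[nrow(blocks)] <- nxt$read_end
    } else if (cn$kind == "join") {
      if (cn$type == "insertion") {
        d <- cn$length
        if (nxt$read_end - nxt$read_start <= d) return(NULL)
        nxt$read_start <- nxt$read_start + d
        if (nxt$strand == "+") nxt$start <- nxt$start + d
        else nxt$end <- nxt$end - d
      }
      joins <- rbind(joins, data.frame(type = cn$type, length = cn$length,
                                       stringsAsFactors = FALSE))
      blocks <- rbind(blocks, nxt)
    } else { # fusion between segment placements (junction at segment edge)
      fusion <- list(left = cn$left, right = cn$right, key = cn$key)
      joins <- rbind(joins, data.frame(type = "fusion", length = 0L,
                                       stringsAsFactors = FALSE))
      blocks <- rbind(blocks, nxt)
    }
  }
  list(blocks = blocks, joins = joins, fusion = fusion,
       mismatches = mism + placement$mismatches)
}

#' Stitch segment placements into full-read alignments
#'
#' Chains one placement per segment left-to-right across the read. Two
#' consecutive placements connect when they are coordinate-adjacent on the
#' same chromosome and strand (contiguous), separated by a genomic gap of
#' at most `max_indel` (deletion) or up to `max_intron_length` (intron),
#' overlap by at most `max_indel` (insertion), or form a junction matching
#' a known fusion candidate — directly, or through a spliced-contig hit.
#' At most one fusion per read: chains that would need two are rejected.
#' Only chains covering every segment (the entire read) are returned.
#'
#' @param read_id,seq Read identity and sequence.
#' @param seg_hits List per segment of genomic placement data.frames
#'   (`chrom`, `start`, `strand`, `mismatches`); over-multi-mapped
#'   segments should be passed as empty.
#' @param contig_hits List per segment of contig hits (elements of
#'   [map_segments_to_contigs()] output).
#' @param seg_ranges Read offsets per segment (`segment_ranges()`).
#' @param candidate_keys Character vector of canonical candidate keys.
#' @param config An [run_config()].
#' @return List of [fs_alignment()] objects.
#' @export
stitch_segments <- function(read_id, seq, seg_hits, contig_hits, seg_ranges,
                            candidate_keys, config = run_config()) {
  n <- nrow(seg_ranges)
  options <- vector("list", n)
  for (s in seq_len(n)) {
    opts <- list()
    h <- seg_hits[[s]]
    if (!is.null(h) && nrow(h) > 0L && nrow(h) <= config$multimap_bound_M) {
      for (r in seq_len(nrow(h)))
        opts[[length(opts) + 1L]] <-
          genome_placement(h[r, ], seg_ranges$start[s], seg_ranges$end[s])
    }
    ch <- contig_hits[[s]]
    if (!is.null(ch))
      for (x in ch)
        opts[[length(opts) + 1L]] <- contig_placement(x, seg_ranges$start[s])
    if (length(opts) == 0L) return(list())
    options[[s]] <- opts
  }
  states <- list(list(blocks = NULL, joins = empty_joins(), fusion = NULL,
                      mismatches = 0L))
  for (s in seq_len(n)) {
    nxt_states <- list()
    for (st in states) for (opt in options[[s]]) {
      ext <- extend_chain(st, opt, candidate_keys, config)
      if (!is.null(ext)) nxt_states[[length(nxt_states) + 1L]] <- ext
    }
    if (length(nxt_states) == 0L) return(list())
    states <- nxt_states
  }
  lapply(states, function(st)
    fs_alignment(read_id, seq, st$blocks, st$joins, st$fusion,
                 st$mismatches, config))
}
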