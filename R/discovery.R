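# Candidate fusion discovery: discordant segment patterns, base-pair
# breakpoint refinement, spliced fusion contigs and contig re-mapping.

ACGT <- c("A", "C", "G", "T")

side_vec <- function(chrom, pos, strand)
  c(chrom = chrom, pos = as.integer(pos), strand = strand)

flip_side <- function(side)
  side_vec(side[["chrom"]], as.integer(side[["pos"]]),
           if (side[["strand"]] == "+") "-" else "+")

cand_key <- function(left, right)
  sprintf("%s:%s:%s|%s:%s:%s", left[["chrom"]], left[["pos"]], left[["strand"]],
          right[["chrom"]], right[["pos"]], right[["strand"]])

#' Construct a fusion candidate
#'
#' A candidate is an ordered breakpoint pair: `pos` of the left side is the
#' last transcribed base before the junction, `pos` of the right side the
#' first after it (both 0-based). The same physical event read from the
#' opposite transcript strand appears with both sides flipped and swapped;
#' a canonical form (the lexicographically smaller of the two encodings)
#' identifies the event regardless of read orientation.
#'
#' @param chromL,posL,strandL Left side (last transcribed base).
#' @param chromR,posR,strandR Right side (first transcribed base).
#' @param config An [run_config()] (distance threshold for classification).
#' @return List of class `fs_candidate` with `left`, `right`, `class`
#'   (`"inter"`, `"intra"`, `"inversion"` or `"rejected"`), and canonical
#'   `key`.
#' @export
fusion_candidate <- function(chromL, posL, strandL, chromR, posR, strandR,
                             config = run_config()) {
  left <- side_vec(chromL, posL, strandL)
  right <- side_vec(chromR, posR, strandR)
  k1 <- cand_key(left, right)
  k2 <- cand_key(flip_side(right), flip_side(left))
  if (k2 < k1) {
    tmp <- left; left <- flip_side(right); right <- flip_side(tmp)
  }
  structure(list(left = left, right = right,
                 class = classify_candidate_sides(left, right, config),
                 key = min(k1, k2)),
            class = "fs_candidate")
}

classify_candidate_sides <- function(left, right, config) {
  if (left[["chrom"]] != right[["chrom"]]) return("inter")
  if (left[["strand"]] != right[["strand"]]) return("inversion")
  if (abs(as.integer(left[["pos"]]) - as.integer(right[["pos"]])) >=
      config$min_intra_distance) "intra" else "rejected"
}

# n transcript bases just after a left-side last base (downstream across
# the junction flank on the left chromosome); NULL when off the chromosome.
transcript_ext_after <- function(genome, chrom, pos, strand, n) {
  if (n == 0L) return(character(0))
  len <- chrom_length(genome, chrom)
  if (strand == "+") {
    if (pos + 1L + n > len) return(NULL)
    s <- genome_sub(genome, chrom, pos + 1L, pos + 1L + n)
  } else {
    if (pos - n < 0L) return(NULL)
    s <- revcomp(genome_sub(genome, chrom, pos - n, pos))
  }
  strsplit(s, "", fixed = TRUE)[[1]]
}

# n transcript bases just before a right-side first base.
transcript_pre_before <- function(genome, chrom, pos, strand, n) {
  if (n == 0L) return(character(0))
  len <- chrom_length(genome, chrom)
  if (strand == "+") {
    if (pos - n < 0L) return(NULL)
    s <- genome_sub(genome, chrom, pos - n, pos)
  } else {
    if (pos + 1L + n > len) return(NULL)
    s <- revcomp(genome_sub(genome, chrom, pos + 1L, pos + 1L + n))
  }
  strsplit(s, "", fixed = TRUE)[[1]]
}

#' Detect discordant segment-alignment patterns
#'
#' Scans the per-segment placements of one IUM read for anchor pairs whose
#' placements lie on different chromosomes, on the same chromosome at a
#' distance of at least `min_intra_distance`, or on the same chromosome
#' with opposite strands (inversions). Anchors must occur in read order and
#' every segment strictly between the two anchors must be unmapped (a
#' multi-mapped in-between segment also disqualifies no pattern, it is
#' simply not an anchor). Each retained placement combination is one
#' pattern; with the multi-map bound M per segment this is at most M x M
#' patterns per anchor pair.
#'
#' @param seg_hits List (one entry per segment, in read order) of placement
#'   data.frames with columns `chrom`, `start`, `strand`, `mismatches`. A
#'   segment with more than `multimap_bound_M` rows is treated as unusable.
#' @param seg_ranges data.frame of 0-based read offsets (`start`, `end`)
#'   per segment, as from `segment_ranges()`.
#' @param config An [run_config()].
#' @return List of patterns: each holds `left_segment`, `right_segment`
#'   (indices), `left_hit`, `right_hit` (single-row data.frames) and
#'   `middle` = c(start, end) read offsets of the unexplained bases.
#' @export
detect_fusion_pattern <- function(seg_hits, seg_ranges, config = run_config()) {
  M <- config$multimap_bound_M
  usable <- vapply(seg_hits, function(h) !is.null(h) && nrow(h) >= 1L &&
                     nrow(h) <= M, logical(1))
  n <- length(seg_hits)
  out <- list()
  for (i in seq_len(n)) {
    if (!usable[i]) next
    for (j in seq_len(n)) {
      if (j <= i || !usable[j]) next
      if (j > i + 1L && any(usable[(i + 1L):(j - 1L)])) next
      hi <- seg_hits[[i]]; hj <- seg_hits[[j]]
      for (a in seq_len(nrow(hi))) for (b in seq_len(nrow(hj))) {
        hl <- hi[a, , drop = FALSE]; hr <- hj[b, , drop = FALSE]
        leni <- seg_ranges$end[i] - seg_ranges$start[i]
        lenj <- seg_ranges$end[j] - seg_ranges$start[j]
        pl <- anchor_last_pos(hl, leni)
        pr <- anchor_first_pos(hr, lenj)
        discordant <- hl$chrom != hr$chrom ||
          hl$strand != hr$strand ||
          abs(pl - pr) >= config$min_intra_distance
        if (!discordant) next
        out[[length(out) + 1L]] <- list(
          left_segment = i, right_segment = j,
          left_hit = hl, right_hit = hr,
          middle = c(seg_ranges$end[i], seg_ranges$start[j]))
      }
    }
  }
  out
}

# genome position of the last read base of a placed segment, in transcript
# orientation ('+': right end of block; '-': left end)
anchor_last_pos <- function(hit, seg_len)
  if (hit$strand == "+") hit$start + seg_len - 1L else hit$start

# genome position of the first read base of a placed segment
anchor_first_pos <- function(hit, seg_len)
  if (hit$strand == "+") hit$start else hit$start + seg_len - 1L

#' Refine a fusion point to base-pair precision
#'
#' Given the two anchor placements and the unexplained middle subsequence,
#' tries every split `s = 0..m` of the middle: the first `s` bases are
#' compared with the `s` transcript bases immediately following the left
#' anchor, the remaining `m - s` with those immediately preceding the right
#' anchor. The split with the fewest total mismatches wins; ties break to
#' the smallest split (leftmost breakpoint in transcript order). N bases
#' never match.
#'
#' @param genome An [fs_genome()].
#' @param left_anchor List `(chrom, strand, last_pos)`: genome position
#'   (0-based) of the last aligned read base of the left anchor.
#' @param right_anchor List `(chrom, strand, first_pos)` for the right
#'   anchor's first aligned read base.
#' @param middle_sequence The unexplained read bases between the anchors
#'   (may be empty).
#' @param config An [run_config()].
#' @return List with `candidate` (an [fusion_candidate()]), `split` and
#'   `mismatches`, or NULL when a flank runs off a chromosome end.
#' @export
refine_fusion_point <- function(genome, left_anchor, right_anchor,
                                middle_sequence, config = run_config()) {
  m <- nchar(middle_sequence)
  s_best <- 0L; mm_best <- 0L
  if (m > 0L) {
    lext <- transcript_ext_after(genome, left_anchor$chrom,
                                 left_anchor$last_pos, left_anchor$strand, m)
    rpre <- transcript_pre_before(genome, right_anchor$chrom,
                                  right_anchor$first_pos, right_anchor$strand, m)
    if (is.null(lext) || is.null(rpre)) return(NULL)
    mid <- strsplit(toupper(middle_sequence), "", fixed = TRUE)[[1]]
    mm_pair <- function(a, b) (a != b) | !(a %in% ACGT) | !(b %in% ACGT)
    p <- c(0L, cumsum(mm_pair(mid, lext)))       # prefix vs left extension
    sfx <- c(0L, cumsum(mm_pair(mid, rpre)))     # prefix sums vs right flank
    total <- p + (sfx[m + 1L] - sfx)             # index s+1 <-> split s
    s_best <- which.min(total) - 1L              # which.min takes first min
    mm_best <- total[s_best + 1L]
  }
  dl <- if (left_anchor$strand == "+") s_best else -s_best
  dr <- if (right_anchor$strand == "+") -(m - s_best) else (m - s_best)
  cand <- fusion_candidate(left_anchor$chrom, left_anchor$last_pos + dl,
                           left_anchor$strand,
                           right_anchor$chrom, right_anchor$first_pos + dr,
                           right_anchor$strand, config)
  list(candidate = cand, split = s_best, mismatches = as.integer(mm_best))
}

#' Build the spliced fusion contig for a candidate
#'
#' Extracts `flank_length` bases immediately flanking each side of the
#' breakpoint — in transcript orientation, reverse-complementing as needed —
#' and concatenates them. With the default 22-bp flanks this yields the
#' 44-bp spliced fusion contig against which junction-crossing segments are
#' re-mapped.
#'
#' @param genome An [fs_genome()].
#' @param candidate An [fusion_candidate()].
#' @param flank_length Flank size (bp).
#' @return List of class `fs_contig` with `sequence`, `junction_offset`
#'   (= `flank_length`) and `candidate`, or NULL (with a warning) when a
#'   flank runs off a chromosome end.
#' @export
build_fusion_contig <- function(genome, candidate, flank_length = 22L) {
  lf <- side_flank_left(genome, candidate$left, flank_length)
  rf <- side_flank_right(genome, candidate$right, flank_length)
  if (is.null(lf) || is.null(rf)) {
    warning(sprintf("candidate %s: breakpoint closer than %d bp to a chromosome end; dropped",
                    candidate$key, flank_length))
    return(NULL)
  }
  structure(list(sequence = paste0(lf, rf), junction_offset = flank_length,
                 candidate = candidate),
            class = "fs_contig")
}

# flank of n transcript bases ENDING at (and including) the left breakpoint
side_flank_left <- function(genome, side, n) {
  pos <- as.integer(side[["pos"]]); chrom <- side[["chrom"]]
  len <- chrom_length(genome, chrom)
  if (side[["strand"]] == "+") {
    if (pos + 1L - n < 0L) return(NULL)
    genome_sub(genome, chrom, pos + 1L - n, pos + 1L)
  } else {
    if (pos + n > len) return(NULL)
    revcomp(genome_sub(genome, chrom, pos, pos + n))
  }
}

# flank of n transcript bases STARTING at (and including) the right breakpoint
side_flank_right <- function(genome, side, n) {
  pos <- as.integer(side[["pos"]]); chrom <- side[["chrom"]]
  len <- chrom_length(genome, chrom)
  if (side[["strand"]] == "+") {
    if (pos + n > len) return(NULL)
    genome_sub(genome, chrom, pos, pos + n)
  } else {
    if (pos + 1L - n < 0L) return(NULL)
    revcomp(genome_sub(genome, chrom, pos + 1L - n, pos + 1L))
  }
}

#' Re-map segments against spliced fusion contigs
#'
#' Aligns segment sequences against the contig set with the same k-mer
#' machinery used for the genome. A hit is retained only when it crosses
#' the contig junction by at least `min_contig_overlap` bases on both
#' sides; retained hits are translated back into a pair of genomic blocks.
#' A reverse-strand contig hit is the same segment read from the opposite
#' transcript strand and is translated against the flipped candidate.
#'
#' @param contigs List of [build_fusion_contig()] results.
#' @param segments Character vector of segment sequences.
#' @param config An [run_config()].
#' @return List of retained hits: each holds `query` (index into
#'   `segments`), `blocks` (2-row data.frame: chrom, start, end, strand,
#'   seg_start, seg_end — segment-relative read offsets), `left`, `right`
#'   (breakpoint sides in the orientation of this hit), `key` (canonical
#'   candidate key) and `mismatches`.
#' @export
map_segments_to_contigs <- function(contigs, segments, config = run_config()) {
  if (length(contigs) == 0L || length(segments) == 0L) return(list())
  seqs <- vapply(contigs, `[[`, "", "sequence")
  names(seqs) <- sprintf("C%06d", seq_along(contigs))
  cgenome <- fs_genome(seqs)
  k <- min(config$index_k, min(nchar(seqs)))
  cindex <- build_index(cgenome, k)
  hits <- align_exactish(cindex, segments, config$max_segment_mismatches,
                         max_hits = config$max_hits_per_contig_segment)
  out <- list()
  fl <- config$flank_length
  for (r in seq_len(nrow(hits))) {
    h <- hits[r, ]
    ci <- match(h$chrom, names(seqs))
    contig <- contigs[[ci]]
    len <- nchar(segments[h$query])
    a <- h$start
    left <- contig$candidate$left; right <- contig$candidate$right
    if (h$strand == "-") {
      a <- nchar(contig$sequence) - a - len
      tmp <- left
      left <- flip_side(right); right <- flip_side(tmp)
    }
    len_l <- fl - a
    len_r <- len - len_l
    if (len_l < config$min_contig_overlap || len_r < config$min_contig_overlap)
      next
    lb <- side_block_left(left, len_l)
    rb <- side_block_right(right, len_r)
    blocks <- data.frame(
      chrom = c(lb[["chrom"]], rb[["chrom"]]),
      start = as.integer(c(lb[["start"]], rb[["start"]])),
      end = as.integer(c(lb[["end"]], rb[["end"]])),
      strand = c(left[["strand"]], right[["strand"]]),
      seg_start = c(0L, len_l),
      seg_end = c(len_l, len),
      stringsAsFactors = FALSE)
    out[[length(out) + 1L]] <- list(
      query = h$query, blocks = blocks, left = left, right = right,
      key = contig$candidate$key, mismatches = h$mismatches)
  }
  out
}

# genomic block of the n transcript bases ending at a left breakpoint
side_block_left <- function(side, n) {
  pos <- as.integer(side[["pos"]])
  if (side[["strand"]] == "+")
    c(chrom = side[["chrom"]], start = pos + 1L - n, end = pos + 1L)
  else
    c(chrom = side[["chrom"]], start = pos, end = pos + n)
}

# genomic block of the n transcript bases starting at a right breakpoint
side_block_right <- function(side, n) {
  pos <- as.integer(side[["pos"]])
  if (side[["strand"]] == "+")
    c(chrom = side[["chrom"]], start = pos, end = pos + n)
  else
    c(chrom = side[["chrom"]], start = pos + 1L - n, end = pos + 1L)
}

#' Narrow the breakpoint search window using a mapped mate
#'
#' When exactly one end of a pair maps uniquely and gap-free, the fusion
#' point implied by the other end is expected within the inner mate
#' distance +- its standard deviation of the mapped partner, measured in
#' the partner's fragment orientation: downstream of a forward partner's
#' left coordinate, upstream of a reverse partner's right coordinate. The
#' window is clipped to the chromosome.
#'
#' @param partner List `(chrom, start, end, strand)` of the mapped mate's
#'   gap-free block (0-based half-open).
#' @param inner Expected inner mate distance (bp).
#' @param sd Its standard deviation (bp).
#' @param chrom_len Length of the partner's chromosome.
#' @return List `(chrom, low, high)`, an inclusive 0-based range.
#' @export
narrow_by_mate <- function(partner, inner, sd, chrom_len) {
  if (partner$strand == "+") {
    lo <- partner$start + inner - sd
    hi <- partner$start + inner + sd
  } else {
    lo <- (partner$end - 1L) - inner - sd
    hi <- (partner$end - 1L) - inner + sd
  }
  lo <- max(0L, min(lo, chrom_len - 1L))
  hi <- max(0L, min(hi, chrom_len - 1L))
  list(chrom = partner$chrom, low = as.integer(lo), high = as.integer(hi))
}
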