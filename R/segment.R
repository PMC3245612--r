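#' Split a read into segments
#'
#' Reads are split into consecutive pieces of `segment_length` bases, the
#' final segment absorbing any remainder so that it is between
#' `segment_length` and `2 * segment_length - 1` bases long; an 80-bp read
#' at the default 25 splits into 25 + 25 + 30. Reads shorter than
#' `segment_length` yield a single segment.
#'
#' @param sequence Read sequence.
#' @param segment_length Segment size (bp).
#' @return Character vector of segment subsequences whose concatenation
#'   reproduces the input.
#' @export
split_read <- function(sequence, segment_length = 25L) {
  L <- nchar(sequence)
  if (L == 0L) fs_input_error("cannot split an empty sequence")
  if (segment_length < 1L) fs_config_error("segment_length must be >= 1")
  n <- max(1L, L %/% segment_length)
  starts <- (seq_len(n) - 1L) * segment_length + 1L
  ends <- c(starts[-1L] - 1L, L)
  substring(sequence, starts, ends)
}

# 0-based read offsets of each segment: data.frame(start, end)
segment_ranges <- function(read_len, segment_length) {
  n <- max(1L, read_len %/% segment_length)
  start <- (seq_len(n) - 1L) * segment_length
  end <- c(start[-1L], read_len)
  data.frame(start = start, end = end)
}

#' Build a k-mer index over a genome
#'
#' Exhaustive forward-strand hash index; k-mers containing N are skipped and
#' reverse-strand queries are resolved at query time. The index is the
#' package's stand-in for an external short-read aligner.
#'
#' @param genome An [fs_genome()].
#' @param k k-mer size (1..31); must not exceed the shortest chromosome.
#' @return An object of class `fs_index`.
#' @export
build_index <- function(genome, k = 8L) {
  k <- as.integer(k)
  lens <- nchar(genome$chromosomes)
  if (k > min(lens))
    fs_input_error(sprintf("k = %d exceeds shortest chromosome (%d bp)",
                           k, min(lens)))
  ptr <- .fs_index_build(names(genome$chromosomes),
                         unname(genome$chromosomes), k)
  structure(list(ptr = ptr, k = k,
                 chromosomes = names(genome$chromosomes),
                 lengths = stats::setNames(lens, names(genome$chromosomes))),
            class = "fs_index")
}

#' @export
print.fs_index <- function(x, ...) {
  info <- .fs_index_info(x$ptr)
  cat(sprintf("fs_index: k = %d over %d chromosome(s), %s distinct k-mers\n",
              info$k, length(info$chromosomes),
              format(info$n_kmers, big.mark = ",")))
  invisible(x)
}

#' Gap-free alignment of queries with bounded mismatches
#'
#' Seed-and-extend search over both strands: seeds are error-free k-mers of
#' the query at offsets 0, k, 2k, ... and the final offset, so the hit set
#' is complete whenever `(max_mismatches + 1) * k <= nchar(query)`
#' (pigeonhole). Reverse-strand hits are placements of the reverse
#' complement reported on forward coordinates. Results are ordered by
#' (chromosome name, position, strand) and truncated to `max_hits + 1` rows
#' per query so a caller can detect "more than max_hits" without
#' enumerating every placement. Genome N bases never match.
#'
#' @param index An [build_index()] result.
#' @param queries Character vector of query sequences.
#' @param max_mismatches Mismatch bound.
#' @param max_hits Per-query hit cap (`Inf` for all hits).
#' @return data.frame with columns `query` (index into `queries`), `chrom`,
#'   `start` (0-based), `strand`, `mismatches`.
#' @export
align_exactish <- function(index, queries, max_mismatches = 2L,
                           max_hits = Inf) {
  cap <- if (is.finite(max_hits)) as.integer(max_hits) else -1L
  hits <- .fs_align_batch(index$ptr, as.character(queries),
                          as.integer(max_mismatches), cap)
  data.frame(query = hits$query,
             chrom = index$chromosomes[hits$chrom_idx],
             start = as.integer(hits$start),
             strand = hits$strand,
             mismatches = hits$mismatches,
             stringsAsFactors = FALSE)
}

#' End-to-end gap-free placements of whole reads
#'
#' Reads with at least one end-to-end gap-free placement within the
#' mismatch bound are "mapped"; reads with none are initially unmapped
#' (IUM) and enter fusion discovery. Reads with more than
#' `multimap_bound_M` placements are discarded as repetitive.
#'
#' @param index An [build_index()] result.
#' @param reads Character vector of read sequences.
#' @param config An [run_config()].
#' @return List with `hits` (data.frame as [align_exactish()]) and
#'   `status`, a character vector per read: `"mapped"`, `"ium"` or
#'   `"multimapped"`.
#' @export
align_whole_reads <- function(index, reads, config = run_config()) {
  hits <- align_exactish(index, reads, config$max_read_mismatches,
                         max_hits = config$multimap_bound_M)
  counts <- tabulate(hits$query, nbins = length(reads))
  status <- ifelse(counts == 0L, "ium",
                   ifelse(counts > config$multimap_bound_M, "multimapped",
                          "mapped"))
  hits <- hits[status[hits$query] == "mapped", , drop = FALSE]
  list(hits = hits, status = status)
}
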