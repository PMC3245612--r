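#' Genome container
#'
#' A genome is an ordered, named set of uppercase chromosome sequences over
#' the alphabet A/C/G/T/N. All coordinates in the package are 0-based
#' half-open against these strings; conversion to 1-based happens only when
#' writing SAM.
#'
#' @param chromosomes Named character vector of nucleotide sequences.
#' @return An object of class `fs_genome`.
#' @export
fs_genome <- function(chromosomes) {
  nm <- names(chromosomes)
  if (is.null(nm) || any(!nzchar(nm)))
    fs_input_error("all chromosomes must be named")
  if (anyDuplicated(nm))
    fs_input_error(sprintf("duplicate chromosome name: %s",
                           nm[duplicated(nm)][1]))
  seqs <- chartr("u", "U", toupper(chromosomes))
  seqs <- chartr("U", "T", seqs)
  seqs <- gsub("[^ACGTN]", "N", seqs)
  if (any(!nzchar(seqs)))
    fs_input_error(sprintf("empty sequence for chromosome '%s'",
                           nm[!nzchar(seqs)][1]))
  structure(list(chromosomes = stats::setNames(as.character(seqs), nm)),
            class = "fs_genome")
}

#' @export
print.fs_genome <- function(x, ...) {
  cat(sprintf("fs_genome: %d chromosome(s), %s bp total\n",
              length(x$chromosomes),
              format(sum(nchar(x$chromosomes)), big.mark = ",")))
  invisible(x)
}

chrom_length <- function(genome, chrom) nchar(genome$chromosomes[[chrom]])

genome_sub <- function(genome, chrom, start, end) {
  # 0-based half-open
  substr(genome$chromosomes[[chrom]], start + 1L, end)
}

#' Reverse-complement nucleotide strings
#'
#' @param x Character vector of sequences (A/C/G/T/N; anything else maps
#'   to N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) .fs_revcomp(toupper(x))

#' Read a FASTA genome
#'
#' One genome entry per FASTA record; sequences are uppercased, U is mapped
#' to T and any other non-ACGT character to N. Duplicate record names or
#' empty sequences are hard errors.
#'
#' @param path FASTA file.
#' @return An [fs_genome()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) fs_input_error(sprintf("FASTA not found: %s", path))
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e)
                    fs_input_error(sprintf("malformed FASTA %s: %s", path,
                                           conditionMessage(e))))
  if (length(set) == 0L) fs_input_error(sprintf("no records in FASTA %s", path))
  nm <- sub("\\s.*$", "", names(set))
  fs_genome(stats::setNames(as.character(set), nm))
}

#' Write a genome as FASTA
#' @param genome An [fs_genome()].
#' @param path Output file.
#' @param width Line wrap width.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(genome$chromosomes)) {
    s <- genome$chromosomes[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(c(paste0(">", nm), substring(s, starts,
                                            pmin(starts + width - 1L, nchar(s)))),
               con)
  }
  invisible(path)
}

#' Read RNA-seq reads from FASTQ
#'
#' Parses single-end or paired-end FASTQ. Qualities are validated (their
#' length must equal the sequence length) and then ignored. Paired files
#' are matched by position; unequal record counts or mismatched id stems
#' (after stripping a trailing `/1`, `/2`, `.1`, `.2`, `_1` or `_2`) are
#' errors.
#'
#' @param path FASTQ file (mate 1 when paired).
#' @param paired_path Optional FASTQ file of mate 2.
#' @return A data.frame with columns `id`, `sequence`, `mate`
#'   (`"none"`, `"first"` or `"second"`) and `pair_id` (NA when single-end).
#' @export
read_fastq <- function(path, paired_path = NULL) {
  first <- parse_fastq_one(path)
  if (is.null(paired_path)) {
    return(data.frame(id = first$id, sequence = first$sequence,
                      mate = "none", pair_id = NA_integer_,
                      stringsAsFactors = FALSE))
  }
  second <- parse_fastq_one(paired_path)
  if (nrow(first) != nrow(second))
    fs_input_error(sprintf(
      "paired FASTQ record counts differ: %d in %s vs %d in %s",
      nrow(first), path, nrow(second), paired_path))
  stem <- function(id) sub("[/._][12]$", "", id)
  bad <- which(stem(first$id) != stem(second$id))
  if (length(bad))
    fs_input_error(sprintf("mate id mismatch at record %d: '%s' vs '%s'",
                           bad[1], first$id[bad[1]], second$id[bad[1]]))
  n <- nrow(first)
  data.frame(
    id = c(first$id, second$id),
    sequence = c(first$sequence, second$sequence),
    mate = rep(c("first", "second"), each = n),
    pair_id = rep(seq_len(n), 2L),
    stringsAsFactors = FALSE)
}

parse_fastq_one <- function(path) {
  if (!file.exists(path)) fs_input_error(sprintf("FASTQ not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4L != 0L)
    fs_input_error(sprintf("FASTQ %s: line count %d is not a multiple of 4",
                           path, length(lines)))
  n <- length(lines) %/% 4L
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seqs <- toupper(lines[seq(2L, by = 4L, length.out = n)])
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(substr(hdr, 1L, 1L) != "@")
  if (length(bad))
    fs_input_error(sprintf("FASTQ %s line %d: header does not start with '@'",
                           path, (bad[1] - 1L) * 4L + 1L))
  bad <- which(substr(plus, 1L, 1L) != "+")
  if (length(bad))
    fs_input_error(sprintf("FASTQ %s line %d: separator does not start with '+'",
                           path, (bad[1] - 1L) * 4L + 3L))
  bad <- which(nchar(seqs) != nchar(qual))
  if (length(bad))
    fs_input_error(sprintf(
      "FASTQ %s record %d: sequence length %d != quality length %d",
      path, bad[1], nchar(seqs[bad[1]]), nchar(qual[bad[1]])))
  data.frame(id = sub("\\s.*$", "", substring(hdr, 2L)),
             sequence = seqs, stringsAsFactors = FALSE)
}

#' Read gene annotation from BED
#'
#' Requires BED4+ (a gene name in column 4). Intervals are kept verbatim as
#' 0-based half-open. A strand column (6) is honoured when present; unknown
#' strand symbols are treated as unstranded (`"*"`).
#'
#' @param path BED file.
#' @return A data.frame of class `fs_annotation` with columns `chrom`,
#'   `start`, `end`, `name`, `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) fs_input_error(sprintf("BED not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0L) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), strand = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("fs_annotation", "data.frame")
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < 4L))
    fs_input_error(sprintf("BED %s line %d: gene name (column 4) required",
                           path, which(ncols < 4L)[1]))
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 3L)))
  name <- vapply(parts, `[[`, "", 4L)
  if (anyNA(start) || anyNA(end))
    fs_input_error(sprintf("BED %s: non-numeric interval bounds", path))
  bad <- which(start >= end)
  if (length(bad))
    fs_input_error(sprintf("BED %s line %d: start %d >= end %d",
                           path, bad[1], start[bad[1]], end[bad[1]]))
  strand <- ifelse(ncols >= 6L, vapply(parts, function(p) p[6L], ""), "*")
  strand[!strand %in% c("+", "-")] <- "*"
  out <- data.frame(chrom = chrom, start = start, end = end, name = name,
                    strand = strand, stringsAsFactors = FALSE)
  class(out) <- c("fs_annotation", "data.frame")
  out
}

#' Write annotation intervals as BED6
#' @param annotation An `fs_annotation` data.frame.
#' @param path Output file.
#' @export
write_bed <- function(annotation, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", annotation$chrom,
                   annotation$start, annotation$end, annotation$name,
                   ifelse(annotation$strand %in% c("+", "-"),
                          annotation$strand, "."))
  writeLines(lines, path)
  invisible(path)
}

# ---- modified SAM dialect ---------------------------------------------------

#' Write selected alignments in the modified SAM dialect
#'
#' Standard SAM (1-based POS, `N` for introns, `D`/`I` for indels) with one
#' extension: a fusion-spanning read is emitted as two records — one per
#' side of the junction, the other side's bases soft-clipped — sharing the
#' QNAME and each carrying
#' `XF:Z:<chromL>:<posL>:<strandL>|<chromR>:<posR>:<strandR>` (1-based
#' breakpoint coordinates: last transcribed base of the left side, first of
#' the right side) and `XP:i:<bases on this side>`. `NM:i` holds the
#' whole-read mismatch count.
#'
#' @param alignments List of full alignments (as produced by the stitcher /
#'   selector).
#' @param genome The [fs_genome()] the alignments refer to.
#' @param path Output SAM file.
#' @export
write_fusion_sam <- function(alignments, genome, path) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(genome$chromosomes),
                      nchar(genome$chromosomes)),
              "@PG\tID:fusescan\tPN:fusescan")
  recs <- unlist(lapply(alignments, sam_records_one), use.names = FALSE)
  writeLines(c(header, recs), path)
  invisible(path)
}

sam_records_one <- function(al) {
  fus <- which(al$joins$type == "fusion")
  if (length(fus) > 1L)
    stop("alignment with more than one fusion event cannot be written")
  L <- nchar(al$seq)
  if (length(fus) == 0L)
    return(sam_record_side(al, seq_len(nrow(al$blocks)), NULL, L))
  left_blocks <- seq_len(fus)
  right_blocks <- seq(fus + 1L, nrow(al$blocks))
  xf <- sprintf("XF:Z:%s:%d:%s|%s:%d:%s",
                al$fusion$left["chrom"], as.integer(al$fusion$left["pos"]) + 1L,
                al$fusion$left["strand"],
                al$fusion$right["chrom"], as.integer(al$fusion$right["pos"]) + 1L,
                al$fusion$right["strand"])
  c(sam_record_side(al, left_blocks, xf, L),
    sam_record_side(al, right_blocks, xf, L))
}

# Emit one SAM line for a run of blocks (one side of a fusion, or the whole
# alignment). Blocks within the run share chrom and strand.
sam_record_side <- function(al, idx, xf, read_len) {
  b <- al$blocks[idx, , drop = FALSE]
  j <- if (nrow(b) > 1L) al$joins[idx[-length(idx)], , drop = FALSE] else NULL
  strand <- b$strand[1]
  r0 <- min(b$read_start); r1 <- max(b$read_end)
  # CIGAR in genome-forward order
  ord <- order(b$start)
  b <- b[ord, , drop = FALSE]
  if (!is.null(j) && strand == "-") j <- j[rev(seq_len(nrow(j))), , drop = FALSE]
  ops <- character(0)
  for (i in seq_len(nrow(b))) {
    if (i > 1L) {
      gap <- b$start[i] - b$end[i - 1L]
      ty <- j$type[i - 1L]
      if (ty == "intron") ops <- c(ops, sprintf("%dN", gap))
      else if (ty == "deletion") ops <- c(ops, sprintf("%dD", gap))
      else if (ty == "insertion") ops <- c(ops, sprintf("%dI", j$length[i - 1L]))
    }
    ops <- c(ops, sprintf("%dM", b$end[i] - b$start[i]))
  }
  pre <- r0; post <- read_len - r1
  if (strand == "-") { tmp <- pre; pre <- post; post <- tmp }
  cig <- paste0(if (pre > 0L) sprintf("%dS", pre) else "",
                paste(ops, collapse = ""),
                if (post > 0L) sprintf("%dS", post) else "")
  seq_out <- if (strand == "-") revcomp(al$seq) else al$seq
  tags <- c(sprintf("NM:i:%d", al$mismatches),
            if (!is.null(xf)) c(xf, sprintf("XP:i:%d", r1 - r0)))
  paste(al$read_id, if (strand == "-") 16L else 0L, b$chrom[1],
        min(b$start) + 1L, 255L, cig, "*", 0L, 0L, seq_out, "*",
        paste(tags, collapse = "\t"), sep = "\t")
}
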