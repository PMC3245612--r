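# Independent reference implementations (pure R, brute force) and fixture
# builders used across the suite. These stay deliberately separate from the
# package's own code paths.

rand_genome <- function(lens, seed = 1) {
  set.seed(seed)
  fs_genome(vapply(stats::setNames(lens, names(lens)), function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    ""))
}

rc <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

# exhaustive gap-free scan over every offset and strand
oracle_align <- function(genome, query, max_mm) {
  out <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") query else rc(query)
    qc <- strsplit(q, "")[[1]]
    L <- length(qc)
    for (nm in names(genome$chromosomes)) {
      gc <- strsplit(genome$chromosomes[[nm]], "")[[1]]
      n <- length(gc)
      if (n < L) next
      mm <- integer(n - L + 1L)
      for (j in seq_len(L)) {
        gj <- gc[j:(n - L + j)]
        mm <- mm + as.integer(gj != qc[j] | gj == "N" | !qc[j] %in% c("A", "C", "G", "T"))
      }
      hit <- which(mm <= max_mm)
      if (length(hit))
        out[[length(out) + 1L]] <- data.frame(
          chrom = nm, start = hit - 1L, strand = strand,
          mismatches = mm[hit], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      strand = character(), mismatches = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start, res$strand), , drop = FALSE]
}

# exhaustive split enumeration for breakpoint refinement
oracle_refine <- function(genome, left, right, middle) {
  m <- nchar(middle)
  count_mm <- function(a, b) {
    if (nchar(a) == 0L) return(0L)
    ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
    sum(ac != bc | !ac %in% c("A", "C", "G", "T") | !bc %in% c("A", "C", "G", "T"))
  }
  sub0 <- function(chrom, s, e) substr(genome$chromosomes[[chrom]], s + 1L, e)
  lext <- if (left$strand == "+") sub0(left$chrom, left$last_pos + 1L, left$last_pos + 1L + m)
          else rc(sub0(left$chrom, left$last_pos - m, left$last_pos))
  rpre <- if (right$strand == "+") sub0(right$chrom, right$first_pos - m, right$first_pos)
          else rc(sub0(right$chrom, right$first_pos + 1L, right$first_pos + 1L + m))
  best <- NULL
  for (s in 0:m) {
    mm <- count_mm(substr(middle, 1L, s), substr(lext, 1L, s)) +
      count_mm(substr(middle, s + 1L, m), substr(rpre, s + 1L, m))
    if (is.null(best) || mm < best$mm) best <- list(s = s, mm = mm)
  }
  best
}

# brute-force repeat check: exact placements of both junction words via the
# oracle aligner, any same-chromosome pair within `dist` eliminates
oracle_repeat <- function(genome, lword, rword, dist) {
  hl <- oracle_align(genome, lword, 0L)
  hr <- oracle_align(genome, rword, 0L)
  for (cc in intersect(unique(hl$chrom), unique(hr$chrom))) {
    a <- hl$start[hl$chrom == cc]; b <- hr$start[hr$chrom == cc]
    if (length(a) && length(b) && min(abs(outer(a, b, "-"))) <= dist)
      return(FALSE)
  }
  TRUE
}

# junction-flanking words of a candidate, computed directly from the genome
# (independent of the package's flank helpers)
oracle_words <- function(genome, cand, k = 23L) {
  sub1 <- function(chrom, s, e) substr(genome$chromosomes[[chrom]], s, e)
  lpos <- as.integer(cand$left[["pos"]]); lchr <- cand$left[["chrom"]]
  rpos <- as.integer(cand$right[["pos"]]); rchr <- cand$right[["chrom"]]
  lw <- if (cand$left[["strand"]] == "+") sub1(lchr, lpos - k + 2L, lpos + 1L)
        else rc(sub1(lchr, lpos + 1L, lpos + k))
  rw <- if (cand$right[["strand"]] == "+") sub1(rchr, rpos + 1L, rpos + k)
        else rc(sub1(rchr, rpos - k + 2L, rpos + 1L))
  c(lw, rw)
}

# read bases straddling a planted junction: n transcript bases on each side
middle_from_event <- function(genome, ev, n) {
  sub1 <- function(chrom, s, e) substr(genome$chromosomes[[chrom]], s, e)
  left <- if (ev$strand_l == "+") sub1(ev$chrom_l, ev$pos_l - n + 2L, ev$pos_l + 1L)
          else rc(sub1(ev$chrom_l, ev$pos_l + 1L, ev$pos_l + n))
  right <- if (ev$strand_r == "+") sub1(ev$chrom_r, ev$pos_r + 1L, ev$pos_r + n)
           else rc(sub1(ev$chrom_r, ev$pos_r - n + 2L, ev$pos_r + 1L))
  paste0(left, right)
}

# plain two-pass reference for coverage statistics
oracle_coverage_stats <- function(depth) {
  count <- 0L
  for (d in depth) if (d > 0) count <- count + 1L
  avg <- sum(depth) / length(depth)
  gap <- 0L; run <- 0L
  for (d in depth) {
    if (d == 0) { run <- run + 1L; gap <- max(gap, run) } else run <- 0L
  }
  if (avg > 0) {
    acc <- 0
    for (d in depth) acc <- acc + ((avg - d) / avg)^2
    der <- sqrt(acc / length(depth))
  } else der <- 1.0
  list(count = count, avg = avg, gap = gap, der = der)
}

# a tiny two-chromosome world with one planted inter-chromosomal fusion at
# known coordinates; used by io/stitch tests that need a coherent genome
make_fusion_world <- function(seed = 7, chrom_len = 3000L) {
  g <- rand_genome(c(chrA = chrom_len, chrB = chrom_len), seed)
  list(genome = g,
       cand = fusion_candidate("chrA", 1500L, "+", "chrB", 900L, "+"))
}
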