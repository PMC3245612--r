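# Discordant-pattern detection, breakpoint refinement, spliced fusion
# contigs, contig re-mapping and mate-based narrowing.

seg_ranges_75 <- data.frame(start = c(0L, 25L, 50L), end = c(25L, 50L, 75L))

hit_df <- function(chrom, start, strand = "+", mm = 0L)
  data.frame(chrom = chrom, start = start, strand = strand,
             mismatches = mm, stringsAsFactors = FALSE)

test_that("detect_fusion_pattern finds cross-chromosome anchors with an unmapped middle", {
  cfg <- run_config()
  sh <- list(hit_df("chrA", 1000L), NULL, hit_df("chrB", 5000L))
  pats <- detect_fusion_pattern(sh, seg_ranges_75, cfg)
  expect_length(pats, 1L)
  expect_equal(pats[[1]]$middle, c(25L, 50L))
  expect_equal(pats[[1]]$left_segment, 1L)
  expect_equal(pats[[1]]$right_segment, 3L)
})

test_that("collinear segments yield no pattern; opposite strands yield an inversion pattern", {
  cfg <- run_config()
  collinear <- list(hit_df("chrA", 1000L), hit_df("chrA", 1025L),
                    hit_df("chrA", 1050L))
  expect_length(detect_fusion_pattern(collinear, seg_ranges_75, cfg), 0L)

  inv <- list(hit_df("chrA", 1000L, "+"), NULL, hit_df("chrA", 3000L, "-"))
  pats <- detect_fusion_pattern(inv, seg_ranges_75, cfg)
  expect_length(pats, 1L)
  expect_equal(pats[[1]]$right_hit$strand, "-")
})

test_that("same-chromosome patterns require the 100-kb separation", {
  cfg <- run_config()
  near <- list(hit_df("chrA", 1000L), NULL, hit_df("chrA", 90000L))
  expect_length(detect_fusion_pattern(near, seg_ranges_75, cfg), 0L)
  far <- list(hit_df("chrA", 1000L), NULL, hit_df("chrA", 201000L))
  expect_length(detect_fusion_pattern(far, seg_ranges_75, cfg), 1L)
})

test_that("multi-hit anchors enumerate the cross-product within the M bound", {
  cfg <- run_config()
  sh <- list(hit_df(c("chrA", "chrC"), c(1000L, 2000L)), NULL,
             hit_df(c("chrB", "chrD"), c(5000L, 6000L)))
  expect_length(detect_fusion_pattern(sh, seg_ranges_75, cfg), 4L)
  over <- list(hit_df(rep("chrA", 3), c(1L, 100L, 200L)), NULL,
               hit_df("chrB", 5000L))
  expect_length(detect_fusion_pattern(over, seg_ranges_75, cfg), 0L)
})

test_that("refine_fusion_point recovers a constructed split exactly", {
  g <- rand_genome(c(chrA = 4000L, chrB = 4000L), seed = 31)
  ca <- g$chromosomes[["chrA"]]; cb <- g$chromosomes[["chrB"]]
  # junction: last left base at chrA pos 2011 (0-based), right starts at
  # chrB 1013; middle = 12 left bases + 13 right bases
  middle <- paste0(substr(ca, 2001, 2012), substr(cb, 1014, 1026))
  left <- list(chrom = "chrA", strand = "+", last_pos = 1999L)
  right <- list(chrom = "chrB", strand = "+", first_pos = 1026L)
  ref <- refine_fusion_point(g, left, right, middle)
  expect_equal(ref$split, 12L)
  expect_equal(ref$mismatches, 0L)
  expect_equal(unname(ref$candidate$left["pos"]), "2011")
  expect_equal(unname(ref$candidate$right["pos"]), "1013")

  # one substitution in the left part: same split, 1 mismatch
  mid2 <- middle
  substr(mid2, 5, 5) <- if (substr(mid2, 5, 5) == "A") "G" else "A"
  ref2 <- refine_fusion_point(g, left, right, mid2)
  expect_equal(ref2$split, 12L)
  expect_equal(ref2$mismatches, 1L)
})

test_that("refine_fusion_point equals exhaustive split enumeration (middles <= 60)", {
  g <- rand_genome(c(chrA = 4000L, chrB = 4000L), seed = 32)
  set.seed(33)
  for (i in 1:40) {
    m <- sample(0:60, 1)
    sl <- sample(c("+", "-"), 1); sr <- sample(c("+", "-"), 1)
    left <- list(chrom = "chrA", strand = sl,
                 last_pos = sample(1000:3000, 1))
    right <- list(chrom = "chrB", strand = sr,
                  first_pos = sample(1000:3000, 1))
    middle <- paste(sample(c("A", "C", "G", "T"), m, TRUE), collapse = "")
    got <- refine_fusion_point(g, left, right, middle)
    want <- oracle_refine(g, left, right, middle)
    expect_equal(got$split, want$s, info = paste("case", i))
    expect_equal(got$mismatches, want$mm, info = paste("case", i))
  }
})

test_that("refinement ties break to the smallest split", {
  g <- fs_genome(c(chrA = strrep("A", 200), chrB = strrep("A", 200)))
  left <- list(chrom = "chrA", strand = "+", last_pos = 99L)
  right <- list(chrom = "chrB", strand = "+", first_pos = 100L)
  ref <- refine_fusion_point(g, left, right, "AAAA")
  expect_equal(ref$split, 0L)  # all five splits are 0-mismatch ties
  expect_equal(oracle_refine(g, left, right, "AAAA")$s, 0L)
})

test_that("build_fusion_contig extracts transcript-oriented flanks", {
  w <- make_fusion_world()
  g <- w$genome
  ctg <- build_fusion_contig(g, w$cand, 22L)
  expect_equal(nchar(ctg$sequence), 44L)
  expect_equal(ctg$junction_offset, 22L)
  expect_equal(substr(ctg$sequence, 1, 22),
               substr(g$chromosomes[["chrA"]], 1480, 1501))
  expect_equal(substr(ctg$sequence, 23, 44),
               substr(g$chromosomes[["chrB"]], 901, 922))

  expect_equal(nchar(build_fusion_contig(g, w$cand, 10L)$sequence), 20L)

  # inversion: right half is the reverse complement of the forward strand
  # (coordinates chosen so canonicalization keeps this orientation)
  inv <- fusion_candidate("chrA", 1000500L, "+", "chrA", 1500L, "-",
                          run_config())
  expect_equal(unname(inv$right[["strand"]]), "-")
  gi <- rand_genome(c(chrA = 1001100L), seed = 41)
  ctg_i <- build_fusion_contig(gi, inv, 22L)
  expect_equal(substr(ctg_i$sequence, 23, 44),
               rc(substr(gi$chromosomes[["chrA"]], 1480, 1501)))

  near_edge <- fusion_candidate("chrA", 5L, "+", "chrB", 900L, "+")
  expect_warning(out <- build_fusion_contig(g, near_edge, 22L), "dropped")
  expect_null(out)
})

test_that("contig hits must span the junction by min_contig_overlap on both sides", {
  w <- make_fusion_world()
  g <- w$genome
  cfg <- run_config()
  ctg <- build_fusion_contig(g, w$cand, cfg$flank_length)
  # segments crossing by exactly 3, by 2, and not at all
  cross3 <- substr(ctg$sequence, 22L - 21L + 1L + 19L, 25L)   # 20 left + 3 right
  cross3 <- substr(ctg$sequence, 3, 25)                        # 20|3 of the 44-mer
  cross2 <- substr(ctg$sequence, 2, 24)                        # 21|2
  onesided <- substr(ctg$sequence, 1, 20)                      # all left
  hits <- map_segments_to_contigs(list(ctg), c(cross3, cross2, onesided), cfg)
  expect_equal(vapply(hits, `[[`, 0, "query"), 1)
  h <- hits[[1]]
  expect_equal(h$blocks$chrom, c("chrA", "chrB"))
  # translated blocks reproduce the genomic sequence of the segment
  left_seq <- substr(g$chromosomes[["chrA"]], h$blocks$start[1] + 1L,
                     h$blocks$end[1])
  right_seq <- substr(g$chromosomes[["chrB"]], h$blocks$start[2] + 1L,
                      h$blocks$end[2])
  expect_equal(paste0(left_seq, right_seq), cross3)
})

test_that("reverse-strand contig hits translate against the flipped candidate", {
  w <- make_fusion_world()
  g <- w$genome
  cfg <- run_config()
  ctg <- build_fusion_contig(g, w$cand, cfg$flank_length)
  seg <- rc(substr(ctg$sequence, 11, 35))  # crosses 12|13, reverse strand
  hits <- map_segments_to_contigs(list(ctg), seg, cfg)
  expect_length(hits, 1L)
  h <- hits[[1]]
  # flipped orientation: first block is the right side on '-'
  expect_equal(h$blocks$chrom, c("chrB", "chrA"))
  expect_equal(h$blocks$strand, c("-", "-"))
  expect_equal(h$key, w$cand$key)
  # blocks still reproduce the segment when read in transcript order
  b1 <- rc(substr(g$chromosomes[["chrB"]], h$blocks$start[1] + 1L, h$blocks$end[1]))
  b2 <- rc(substr(g$chromosomes[["chrA"]], h$blocks$start[2] + 1L, h$blocks$end[2]))
  expect_equal(paste0(b1, b2), seg)
})

test_that("narrow_by_mate computes the inner-distance window", {
  win <- narrow_by_mate(list(chrom = "chrA", start = 10000L, end = 10050L,
                             strand = "+"), 200L, 30L, 1000000L)
  expect_equal(c(win$low, win$high), c(10170L, 10230L))

  point <- narrow_by_mate(list(chrom = "chrA", start = 10000L, end = 10050L,
                               strand = "+"), 200L, 0L, 1000000L)
  expect_equal(point$low, point$high)

  clipped <- narrow_by_mate(list(chrom = "chrA", start = 500L, end = 550L,
                                 strand = "-"), 600L, 50L, 1000000L)
  expect_equal(c(clipped$low, clipped$high), c(0L, 0L))

  rev <- narrow_by_mate(list(chrom = "chrA", start = 10000L, end = 10050L,
                             strand = "-"), 200L, 30L, 1000000L)
  expect_equal(c(rev$low, rev$high), c(10049L - 230L, 10049L - 170L))
})

test_that("candidates canonicalize flipped orientations to one key", {
  a <- fusion_candidate("chrA", 500L, "+", "chrB", 900L, "+")
  b <- fusion_candidate("chrB", 900L, "-", "chrA", 500L, "-")
  expect_equal(a$key, b$key)
  expect_equal(a$class, "inter")
  inv <- fusion_candidate("chrA", 500L, "+", "chrA", 200500L, "-")
  expect_equal(inv$class, "inversion")
})
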