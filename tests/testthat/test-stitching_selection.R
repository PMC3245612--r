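# Stitching of segment placements, penalties and per-read selection.

mk_hits <- function(...) {
  rows <- list(...)
  lapply(rows, function(r) {
    if (is.null(r)) return(NULL)
    data.frame(chrom = r[[1]], start = as.integer(r[[2]]),
               strand = if (length(r) > 2) r[[3]] else "+",
               mismatches = if (length(r) > 3) as.integer(r[[4]]) else 0L,
               stringsAsFactors = FALSE)
  })
}

sr3 <- data.frame(start = c(0L, 25L, 50L), end = c(25L, 50L, 75L))

test_that("collinear adjacent segments stitch into one gap-free alignment", {
  cfg <- run_config()
  als <- stitch_segments("r", strrep("A", 75),
                         mk_hits(list("chrA", 1000), list("chrA", 1025),
                                 list("chrA", 1050)),
                         vector("list", 3), sr3, character(0), cfg)
  expect_length(als, 1L)
  expect_equal(nrow(als[[1]]$blocks), 1L)
  expect_equal(als[[1]]$blocks$start, 1000L)
  expect_equal(als[[1]]$blocks$end, 1075L)
  expect_equal(als[[1]]$penalty, 0L)
})

test_that("an intron-sized gap stitches with penalty -2, a small gap as a deletion", {
  cfg <- run_config()
  als <- stitch_segments("r", strrep("A", 75),
                         mk_hits(list("chrA", 1000), list("chrA", 1025),
                                 list("chrA", 1550)),
                         vector("list", 3), sr3, character(0), cfg)
  expect_length(als, 1L)
  expect_equal(als[[1]]$joins$type, "intron")
  expect_equal(als[[1]]$joins$length, 500L)
  expect_equal(als[[1]]$penalty, -2L)

  del <- stitch_segments("r", strrep("A", 75),
                         mk_hits(list("chrA", 1000), list("chrA", 1027),
                                 list("chrA", 1052)),
                         vector("list", 3), sr3, character(0), cfg)
  expect_equal(del[[1]]$joins$type, "deletion")
  expect_equal(del[[1]]$penalty, -4L)
})

test_that("minus-strand chains stitch with descending coordinates", {
  cfg <- run_config()
  als <- stitch_segments("r", strrep("A", 75),
                         mk_hits(list("chrA", 1050, "-"), list("chrA", 1025, "-"),
                                 list("chrA", 1000, "-")),
                         vector("list", 3), sr3, character(0), cfg)
  expect_length(als, 1L)
  expect_equal(als[[1]]$blocks$start, 1000L)
  expect_equal(als[[1]]$blocks$strand, "-")
  expect_equal(als[[1]]$penalty, 0L)
})

test_that("a discordant junction stitches as a fusion only when a candidate matches", {
  cfg <- run_config()
  cand <- fusion_candidate("chrA", 1049L, "+", "chrB", 5000L, "+")
  hits <- mk_hits(list("chrA", 1000), list("chrA", 1025), list("chrB", 5000))
  none <- stitch_segments("r", strrep("A", 75), hits, vector("list", 3),
                          sr3, character(0), cfg)
  expect_length(none, 0L)
  als <- stitch_segments("r", strrep("A", 75), hits, vector("list", 3),
                         sr3, cand$key, cfg)
  expect_length(als, 1L)
  expect_equal(als[[1]]$joins$type, "fusion")
  expect_equal(als[[1]]$fusion$key, cand$key)
  expect_equal(als[[1]]$penalty, -4L)
})

test_that("chains needing two fusions are rejected", {
  cfg <- run_config()
  k1 <- fusion_candidate("chrA", 1024L, "+", "chrB", 5000L, "+")$key
  k2 <- fusion_candidate("chrB", 5024L, "+", "chrC", 100L, "+")$key
  hits <- mk_hits(list("chrA", 1000), list("chrB", 5000), list("chrC", 100))
  als <- stitch_segments("r", strrep("A", 75), hits, vector("list", 3),
                         sr3, c(k1, k2), cfg)
  expect_length(als, 0L)
})

test_that("score_alignment applies the -2/-4/-4 penalties additively", {
  cfg <- run_config()
  mk <- function(types)
    list(joins = data.frame(type = types,
                            length = rep(1L, length(types)),
                            stringsAsFactors = FALSE))
  expect_equal(score_alignment(mk(character(0)), cfg), 0L)
  expect_equal(score_alignment(mk("intron"), cfg), -2L)
  expect_equal(score_alignment(mk("deletion"), cfg), -4L)
  expect_equal(score_alignment(mk("insertion"), cfg), -4L)
  expect_equal(score_alignment(mk("fusion"), cfg), -4L)
  expect_equal(score_alignment(mk(c("intron", "fusion")), cfg), -6L)
})

mk_al <- function(penalty_joins, mm, chrom = "chrA", start = 0L) {
  al <- fs_alignment("r", strrep("A", 50),
    data.frame(chrom = chrom, start = start, end = start + 50L, strand = "+",
               read_start = 0L, read_end = 50L, stringsAsFactors = FALSE),
    joins = if (length(penalty_joins))
      data.frame(type = penalty_joins, length = 1L, stringsAsFactors = FALSE)
    else empty_joins_for_test(),
    mismatches = mm)
  al
}

empty_joins_for_test <- function()
  data.frame(type = character(), length = integer(), stringsAsFactors = FALSE)

test_that("select_best prefers penalty, then mismatches, then coordinates", {
  cfg <- run_config()
  gapfree3 <- mk_al(character(0), 3L)
  fusion1 <- mk_al("fusion", 1L)
  expect_identical(select_best(list(fusion1, gapfree3), cfg), gapfree3)

  fusion0 <- mk_al("fusion", 0L)
  deletion2 <- mk_al("deletion", 2L)
  expect_identical(select_best(list(deletion2, fusion0), cfg), fusion0)

  expect_null(select_best(list(), cfg))

  # total order: permuting the input never changes the winner
  a <- mk_al(character(0), 1L, start = 500L)
  b <- mk_al(character(0), 1L, start = 100L)
  c3 <- mk_al("intron", 0L, start = 1L)
  pool <- list(a, b, c3)
  set.seed(9)
  for (i in 1:10) {
    perm <- sample(pool)
    expect_identical(select_best(perm, cfg), b)
  }
})

test_that("emitted alignments cover the whole read: block lengths + insertions", {
  cfg <- run_config()
  cases <- list(
    mk_hits(list("chrA", 1000), list("chrA", 1025), list("chrA", 1050)),
    mk_hits(list("chrA", 1000), list("chrA", 1025), list("chrA", 1550)),
    mk_hits(list("chrA", 1000), list("chrA", 1027), list("chrA", 1052)))
  for (hits in cases) {
    for (al in stitch_segments("r", strrep("A", 75), hits,
                               vector("list", 3), sr3, character(0), cfg)) {
      covered <- sum(al$blocks$read_end - al$blocks$read_start) +
        sum(al$joins$length[al$joins$type == "insertion"])
      expect_equal(covered, 75L)
      expect_equal(sum(al$blocks$end - al$blocks$start) +
                     sum(al$joins$length[al$joins$type == "insertion"]), 75L)
    }
  }
})
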