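# The false-positive filter cascade.

fusion_al <- function(left_bases, right_bases, mm,
                      cand = fusion_candidate("chrA", 999L, "+", "chrB",
                                              5000L, "+")) {
  fs_alignment("r", strrep("A", left_bases + right_bases),
    data.frame(chrom = c("chrA", "chrB"),
               start = c(1000L - left_bases, 5000L),
               end = c(1000L, 5000L + right_bases), strand = "+",
               read_start = c(0L, left_bases),
               read_end = c(left_bases, left_bases + right_bases),
               stringsAsFactors = FALSE),
    joins = data.frame(type = "fusion", length = 0L, stringsAsFactors = FALSE),
    fusion = list(left = cand$left, right = cand$right, key = cand$key),
    mismatches = mm)
}

test_that("anchor_filter enforces 13 bases per side and <= 2 mismatches", {
  cfg <- run_config()
  expect_true(anchor_filter(fusion_al(13L, 37L, 0L), cfg))
  expect_false(anchor_filter(fusion_al(12L, 38L, 0L), cfg))
  expect_false(anchor_filter(fusion_al(25L, 25L, 3L), cfg))
  expect_true(anchor_filter(fusion_al(25L, 25L, 2L), cfg))
})

test_that("multimap_filter applies the M = 2 bound", {
  cfg <- run_config()
  expect_true(multimap_filter(1L, cfg))
  expect_true(multimap_filter(2L, cfg))
  expect_false(multimap_filter(3L, cfg))
})

test_that("classify_candidate applies the 100-kb same-chromosome rule", {
  cfg <- run_config()
  expect_equal(classify_candidate(
    fusion_candidate("chrA", 1000L, "+", "chrB", 2000L, "+"), cfg), "inter")
  expect_equal(classify_candidate(
    fusion_candidate("chrA", 1000L, "+", "chrA", 101000L, "+"), cfg), "intra")
  expect_equal(classify_candidate(
    fusion_candidate("chrA", 1000L, "+", "chrA", 90000L, "+"), cfg),
    "rejected")
  expect_equal(classify_candidate(
    fusion_candidate("chrA", 1000L, "+", "chrA", 90000L, "-"), cfg), "intra")
})

test_that("support_filter reproduces the four per-dataset presets", {
  with_preset <- function(p) run_config(support_preset = p)
  sup <- function(s, p) list(spanning_reads = s, supporting_pairs = p)
  expect_true(support_filter(sup(3L, 2L), with_preset("breast")))
  expect_false(support_filter(sup(2L, 2L), with_preset("breast")))
  expect_false(support_filter(sup(4L, 1L), with_preset("breast")))
  expect_true(support_filter(sup(0L, 10L), with_preset("vcap")))
  expect_false(support_filter(sup(4L, 5L), with_preset("vcap")))
  expect_true(support_filter(sup(3L, 2L), with_preset("uhr_paired")))
  expect_true(support_filter(sup(1L, 9L), with_preset("uhr_paired")))
  expect_false(support_filter(sup(2L, 2L), with_preset("uhr_paired")))
  expect_true(support_filter(sup(2L, 0L), with_preset("uhr_single")))
  expect_false(support_filter(sup(1L, 0L), with_preset("uhr_single")))
  custom <- run_config(support_preset = "custom", min_spanning = 1L,
                       min_pairs = 3L, min_sum = 8L)
  expect_true(support_filter(sup(1L, 3L), custom))
  expect_true(support_filter(sup(8L, 0L), custom))
  expect_false(support_filter(sup(2L, 2L), custom))
  expect_error(support_preset_rule("nope"), "unknown")
})

test_that("count_support tallies spanning reads, pairs and contradictions", {
  cfg <- run_config()
  cand <- fusion_candidate("chrA", 999L, "+", "chrB", 5000L, "+")
  reads <- data.frame(id = c("p1", "p1", "p2", "p2", "c1", "s1"),
                      sequence = strrep("A", 50),
                      mate = c("first", "second", "first", "second",
                               "none", "none"),
                      pair_id = c(1L, 1L, 2L, 2L, NA, NA),
                      stringsAsFactors = FALSE)
  gap_al <- function(id, chrom, start, strand)
    fs_alignment(id, strrep("A", 50),
      data.frame(chrom = chrom, start = start, end = start + 50L,
                 strand = strand, read_start = 0L, read_end = 50L,
                 stringsAsFactors = FALSE))
  selected <- list(
    gap_al("p1", "chrA", 900L, "+"),    # left side, towards junction
    gap_al("p1", "chrB", 5100L, "-"),   # right side, back towards junction
    gap_al("p2", "chrA", 850L, "+"),    # left side, further out
    gap_al("p2", "chrB", 5150L, "-"),
    gap_al("c1", "chrA", 975L, "+"),    # crosses the left breakpoint: contradicts
    fusion_al(25L, 25L, 0L, cand))      # spanning read s1
  sup <- count_support(cand, selected, reads, cfg)
  expect_equal(sup$spanning_reads, 1L)
  expect_equal(sup$supporting_pairs, 2L)
  expect_equal(sup$contradicting_reads, 1L)

  none <- count_support(cand, list(), reads, cfg)
  expect_equal(unlist(none[1:3], use.names = FALSE), c(0, 0, 0))
})

test_that("repeat_filter eliminates junction words that co-occur within 100 kb", {
  set.seed(51)
  g <- rand_genome(c(chrA = 150000L, chrB = 50000L), seed = 51)
  cfg <- run_config()
  idx <- build_index(g, cfg$index_k)
  # unique words on different chromosomes: keep
  cand <- fusion_candidate("chrA", 1000L, "+", "chrB", 30000L, "+")
  expect_true(repeat_filter(idx, g, cand, cfg))
  expect_true(oracle_repeat(g, oracle_words(g, cand)[1],
                            oracle_words(g, cand)[2], 100000L))

  # plant the left word 90 kb downstream of the right word's locus
  word <- substr(g$chromosomes[["chrA"]], 1000L - 22L + 1L, 1001L)
  s <- g$chromosomes[["chrA"]]
  substr(s, 120001L, 120023L) <- word
  g2 <- fs_genome(stats::setNames(c(s, g$chromosomes[["chrB"]]),
                                  c("chrA", "chrB")))
  cand2 <- fusion_candidate("chrA", 1000L, "+", "chrA", 30000L + 100000L + 2000L,
                            "+", cfg)
  # right word locus chrA:132000..; left word now also at chrA:120000 -> within 100 kb
  idx2 <- build_index(g2, cfg$index_k)
  expect_false(repeat_filter(idx2, g2, cand2, cfg))
  expect_false(oracle_repeat(g2, oracle_words(g2, cand2)[1],
                             oracle_words(g2, cand2)[2],
                             100000L))
})

test_that("repeat_filter agrees with the brute-force scan on random candidates", {
  g <- rand_genome(c(chrA = 40000L, chrB = 30000L), seed = 52)
  cfg <- run_config(min_intra_distance = 5000L)
  idx <- build_index(g, cfg$index_k)
  set.seed(53)
  for (i in 1:10) {
    cand <- fusion_candidate("chrA", sample(2000:38000, 1), "+",
                             "chrB", sample(2000:28000, 1),
                             sample(c("+", "-"), 1), cfg)
    got <- repeat_filter(idx, g, cand, cfg)
    want <- oracle_repeat(g, oracle_words(g, cand)[1],
                          oracle_words(g, cand)[2],
                          cfg$min_intra_distance)
    expect_equal(got, want, info = paste("case", i))
  }
})

test_that("annotation_filter requires a gene on at least one side", {
  ann <- structure(data.frame(chrom = "chrA", start = 900L, end = 1100L,
                              name = "GENE1", strand = "+",
                              stringsAsFactors = FALSE),
                   class = c("fs_annotation", "data.frame"))
  inside <- fusion_candidate("chrA", 1000L, "+", "chrB", 5000L, "+")
  outside <- fusion_candidate("chrA", 5000L, "+", "chrB", 5000L, "+")
  expect_true(annotation_filter(inside, ann))
  expect_false(annotation_filter(outside, ann))
  empty <- ann[0, ]
  expect_false(annotation_filter(inside, empty))
})

test_that("coverage_window_filter rejects narrow and one-sided coverage", {
  cfg <- run_config()
  full <- list(ldepth = rep(5, 300), rdepth = rep(7, 300))
  expect_true(coverage_window_filter(full, cfg))
  narrow <- list(ldepth = c(rep(0, 260), rep(5, 40)),
                 rdepth = c(rep(5, 40), rep(0, 260)))
  expect_false(coverage_window_filter(narrow, cfg))
  onesided <- list(ldepth = rep(5, 300), rdepth = rep(0, 300))
  expect_false(coverage_window_filter(onesided, cfg))
})

test_that("depth_profile counts per-base depth on each side", {
  cfg <- run_config(window_half = 10L)
  cand <- fusion_candidate("chrA", 999L, "+", "chrB", 5000L, "+")
  blocks <- data.frame(chrom = c("chrA", "chrA", "chrB"),
                       start = c(985L, 995L, 5003L),
                       end = c(1000L, 1000L, 5020L),
                       stringsAsFactors = FALSE)
  prof <- depth_profile(cand, blocks, cfg)
  # left window: chrA 990..999 -> depth 1 for 990..994, 2 for 995..999
  expect_equal(prof$ldepth, c(rep(1, 5), rep(2, 5)))
  # right window: chrB 5000..5009 -> zero until 5003
  expect_equal(prof$rdepth, c(0, 0, 0, rep(1, 7)))
})
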