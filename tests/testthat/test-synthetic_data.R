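# The deterministic simulator.

small_spec <- function(seed = 5, ...) {
  simulation_spec(seed = seed, chrom_length = 250000L, genes_per_chrom = 6L,
                  n_inter = 1L, n_intra = 1L, n_inversion = 0L,
                  n_read_through = 0L, n_repeat_artifact = 0L,
                  n_intron_genes = 1L, coverage_depth = 4, ...)
}

test_that("identical seeds give byte-identical datasets", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  run_simulate(small_spec(), d1)
  run_simulate(small_spec(), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  run_simulate(small_spec(seed = 6), d2)
  expect_false(identical(readLines(file.path(d1, "genome.fa")),
                         readLines(file.path(d2, "genome.fa"))))
})

test_that("planted events respect the distance invariants", {
  ds <- make_genome(small_spec())
  ev <- ds$events
  intra <- ev[ev$type == "intra", ]
  expect_true(all(abs(intra$pos_l - intra$pos_r) >= 100000L))

  expect_error(simulation_spec(planted_events = list(
    list(type = "intra", chrom_l = "chr1", pos_l = 1000L, strand_l = "+",
         chrom_r = "chr1", pos_r = 100999L, strand_r = "+"))), "intra")

  expect_error(simulation_spec(planted_events = list(
    list(type = "read_through", chrom_l = "chr1", pos_l = 1000L,
         strand_l = "+", chrom_r = "chr1", pos_r = 201000L,
         strand_r = "+"))), "read_through")
})

test_that("fused transcripts concatenate donor and acceptor at the junction", {
  ds <- make_genome(small_spec())
  tx <- make_fused_transcripts(ds, small_spec())
  ev <- ds$events
  g <- ds$genome
  for (i in seq_len(nrow(ev))) {
    t <- tx[[sprintf("FUS%02d", i)]]
    half <- nchar(t) / 2
    donor_last <- substr(t, half, half)
    accep_first <- substr(t, half + 1, half + 1)
    expect_equal(donor_last, substr(g$chromosomes[[ev$chrom_l[i]]],
                                    ev$pos_l[i] + 1L, ev$pos_l[i] + 1L))
    expect_equal(accep_first, substr(g$chromosomes[[ev$chrom_r[i]]],
                                     ev$pos_r[i] + 1L, ev$pos_r[i] + 1L))
  }
})

test_that("inversion transcripts use the reverse complement of the forward strand", {
  spec <- simulation_spec(seed = 9, chrom_length = 400000L,
                          genes_per_chrom = 8L, n_inter = 0L, n_intra = 0L,
                          n_inversion = 1L, n_read_through = 0L,
                          n_repeat_artifact = 0L, n_intron_genes = 0L)
  ds <- make_genome(spec)
  tx <- make_fused_transcripts(ds, spec)
  ev <- ds$events[1, ]
  expect_equal(ev$strand_r, "-")
  t <- tx[["FUS01"]]
  right_part <- substr(t, nchar(t) / 2 + 1, nchar(t))
  genomic <- substr(ds$genome$chromosomes[[ev$chrom_r]],
                    ev$pos_r + 1L - nchar(right_part) + 1L, ev$pos_r + 1L)
  expect_equal(right_part, rc(genomic))
})

test_that("error-free reads are exact transcript substrings with stated pair geometry", {
  spec <- small_spec(error_rate = 0, fragment_length_sd = 0L)
  ds <- simulate_dataset(spec)
  first <- ds$reads[ds$reads$mate == "first", ]
  second <- ds$reads[ds$reads$mate == "second", ]
  expect_equal(nrow(first), nrow(second))
  org <- ds$origins
  expect_equal(nrow(org), nrow(first))
  set.seed(1)
  for (i in sample(nrow(first), 25L)) {
    o <- org[org$id == first$id[i], ]
    t <- ds$transcripts[[o$transcript]]
    frag <- substr(t, o$start + 1L, o$start + o$frag_len)
    if (!o$forward) frag <- rc(frag)
    expect_equal(first$sequence[i], substr(frag, 1, 50))
    expect_equal(second$sequence[i],
                 rc(substr(frag, o$frag_len - 49L, o$frag_len)))
    # inner mate distance = fragment - 2 * read length
    expect_equal(o$frag_len - 100L, spec$fragment_length_mean - 100L)
  }
})

test_that("the repeat artifact duplicates the junction word near the partner locus", {
  spec <- simulation_spec(seed = 11, chrom_length = 300000L,
                          genes_per_chrom = 6L, n_inter = 1L, n_intra = 0L,
                          n_inversion = 0L, n_read_through = 1L,
                          n_repeat_artifact = 1L, n_intron_genes = 0L)
  ds <- make_genome(spec)
  ev <- ds$events[ds$events$type == "repeat_artifact", ]
  word <- substr(ds$genome$chromosomes[[ev$chrom_l]],
                 ev$pos_l + 1L - 39L, ev$pos_l + 1L)
  hits <- oracle_align(ds$genome, word, 0L)
  expect_gte(nrow(hits), 2L)
  copy <- hits[hits$chrom == ev$chrom_r, ]
  expect_true(any(abs(copy$start - ev$pos_r) <= 100000L))

  rt <- ds$events[ds$events$type == "read_through", ]
  expect_false(rt$reportable)
  expect_true(abs(rt$pos_l - rt$pos_r) < 100000L)
  expect_false(ev$reportable)
})

test_that("junctions are free of 1-bp microhomology", {
  ds <- make_genome(simulation_spec(seed = 13))
  g <- ds$genome
  for (i in seq_len(nrow(ds$events))) {
    ev <- ds$events[i, ]
    ref <- refine_fusion_point(
      g,
      list(chrom = ev$chrom_l, strand = ev$strand_l,
           last_pos = if (ev$strand_l == "+") ev$pos_l - 10L else ev$pos_l + 10L),
      list(chrom = ev$chrom_r, strand = ev$strand_r,
           first_pos = if (ev$strand_r == "+") ev$pos_r + 10L else ev$pos_r - 10L),
      middle_from_event(g, ev, 10L))
    expect_equal(unname(ref$candidate$key), ev$key, label = ev$key)
    expect_equal(ref$mismatches, 0L)
  }
})
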