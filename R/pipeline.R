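# Two-phase pipeline: (1) find candidate fusions and align reads across
# them; (2) filter false fusions and rank the survivors.

REFINE_SLACK <- 6L  # anchor bases handed back to breakpoint refinement

#' Run the full fusion-discovery pipeline
#'
#' Executes whole-read alignment, IUM segment mapping, discordant-pattern
#' detection, breakpoint refinement, spliced-contig re-mapping, stitching,
#' per-read alignment selection, the filter cascade and ranking; writes
#' the modified-SAM alignment file, a candidate table, the ranked fusion
#' table and a per-stage candidate-count log.
#'
#' @param genome_path FASTA reference.
#' @param reads_paths Character vector of one (single-end) or two
#'   (paired-end) FASTQ files.
#' @param annotation_path BED4+ gene annotation.
#' @param config An [run_config()].
#' @param outdir Output directory (created if missing).
#' @return A list of class `fs_result` with `report` (ranked fusions),
#'   `candidates`, `stage_counts`, `n_reads` and the paths written.
#' @export
run_discover <- function(genome_path, reads_paths, annotation_path,
                         config = run_config(), outdir = ".") {
  genome <- read_fasta(genome_path)
  annotation <- read_bed(annotation_path)
  reads <- if (length(reads_paths) >= 2L)
    read_fastq(reads_paths[1], reads_paths[2]) else read_fastq(reads_paths[1])
  res <- discover_core(genome, reads, annotation, config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  res$paths <- write_pipeline_outputs(res, genome, outdir)
  res
}

#' Run discovery on in-memory objects
#'
#' The computational core of [run_discover()], usable without file I/O.
#'
#' @param genome An [fs_genome()].
#' @param reads data.frame as returned by [read_fastq()].
#' @param annotation An `fs_annotation` data.frame.
#' @param config An [run_config()].
#' @return A list of class `fs_result`.
#' @export
discover_core <- function(genome, reads, annotation, config = run_config()) {
  index <- build_index(genome, config$index_k)
  lens <- nchar(reads$sequence)

  ## phase 1a: whole-read gap-free alignment
  wr <- align_whole_reads(index, reads$sequence, config)
  h <- wr$hits
  ord <- order(h$query, h$mismatches, h$chrom, h$start, h$strand)
  h <- h[ord, , drop = FALSE]
  best <- h[!duplicated(h$query), , drop = FALSE]
  mapped_best <- data.frame(read_idx = best$query, chrom = best$chrom,
                            start = best$start,
                            end = best$start + lens[best$query],
                            strand = best$strand,
                            mismatches = best$mismatches,
                            stringsAsFactors = FALSE)

  ## phase 1b: segment alignment of IUM reads
  ium <- which(wr$status == "ium")
  segs <- ium_segments(reads, ium, lens, config)
  seg_hits_all <- if (nrow(segs)) {
    align_exactish(index, segs$seq, config$max_segment_mismatches,
                   max_hits = config$multimap_bound_M)
  } else {
    align_exactish(index, character(0), 0L, 1L)
  }
  hit_rows <- split(seq_len(nrow(seg_hits_all)), seg_hits_all$query)

  ## phase 1c: discordant patterns -> refined candidates
  candidates <- list()
  for (ri in unique(segs$read)) {
    rows <- which(segs$read == ri)
    sr <- data.frame(start = segs$start[rows], end = segs$end[rows])
    sh <- lapply(rows, function(r) {
      idx <- hit_rows[[as.character(r)]]
      if (is.null(idx)) NULL
      else seg_hits_all[idx, c("chrom", "start", "strand", "mismatches"),
                        drop = FALSE]
    })
    pats <- detect_fusion_pattern(sh, sr, config)
    for (p in pats) {
      ref <- refine_pattern(genome, reads$sequence[ri], p, sr, config)
      if (is.null(ref)) next
      cand <- ref$candidate
      if (cand$class == "rejected") next
      if (!cand$key %in% names(candidates)) candidates[[cand$key]] <- cand
    }
  }
  ## phase 1c': paired-end rescue — reads whose junction lies inside a
  ## segment have only one mapped anchor; the uniquely mapped partner read
  ## narrows where the unmapped tail must align on the other side
  if (any(reads$mate != "none") && nrow(segs)) {
    rescued <- rescue_candidates_by_mate(genome, index, reads, wr,
                                         mapped_best, segs, hit_rows,
                                         seg_hits_all, config)
    for (cand in rescued)
      if (!cand$key %in% names(candidates)) candidates[[cand$key]] <- cand
  }
  n_refined <- length(candidates)

  ## phase 1d: spliced fusion contigs + segment re-mapping
  contigs <- list()
  for (cand in candidates) {
    ctg <- withCallingHandlers(
      build_fusion_contig(genome, cand, config$flank_length),
      warning = function(w) invokeRestart("muffleWarning"))
    if (!is.null(ctg)) contigs[[cand$key]] <- ctg
  }
  candidates <- candidates[names(contigs)]
  chits <- map_segments_to_contigs(unname(contigs), segs$seq, config)
  chit_by_row <- split(chits, vapply(chits, `[[`, 0, "query"))

  ## phase 1e: stitching and per-read selection
  stitched <- list()
  for (ri in unique(segs$read)) {
    rows <- which(segs$read == ri)
    sr <- data.frame(start = segs$start[rows], end = segs$end[rows])
    sh <- lapply(rows, function(r) {
      idx <- hit_rows[[as.character(r)]]
      if (is.null(idx)) NULL
      else seg_hits_all[idx, c("chrom", "start", "strand", "mismatches"),
                        drop = FALSE]
    })
    ch <- lapply(rows, function(r) chit_by_row[[as.character(r)]])
    als <- stitch_segments(reads$id[ri], reads$sequence[ri], sh, ch, sr,
                           names(candidates), config)
    bestal <- select_best(als, config)
    if (!is.null(bestal)) stitched[[length(stitched) + 1L]] <-
      c(bestal, list(read_idx = ri))
  }

  ## phase 2: support, filters, ranking
  tabs <- build_tables(mapped_best, stitched, reads, config)
  blocks <- tabs$blocks
  support <- lapply(candidates, count_support, selected = tabs,
                    reads = reads, config = config)

  ## absorb base-call-error echoes of stronger junctions
  keep <- collapse_junction_echoes(candidates, support,
                                   config$collapse_radius)
  candidates <- candidates[keep]
  support <- support[keep]

  keys <- names(candidates)
  pass_anchor <- vapply(keys, function(k)
    support[[k]]$spanning_reads >= 1L, logical(1))
  pass_multimap <- pass_anchor  # read-level bound applied during alignment
  pass_classify <- pass_multimap & vapply(keys, function(k)
    classify_candidate(candidates[[k]], config) != "rejected", logical(1))
  pass_support <- pass_classify & vapply(keys, function(k)
    support_filter(support[[k]], config), logical(1))
  pass_repeat <- pass_support
  for (k in keys[pass_support]) {
    pass_repeat[k] <- withCallingHandlers(
      repeat_filter(index, genome, candidates[[k]], config),
      warning = function(w) invokeRestart("muffleWarning"))
  }
  pass_annot <- pass_repeat & vapply(keys, function(k)
    annotation_filter(candidates[[k]], annotation), logical(1))
  profiles <- list()
  pass_cov <- pass_annot
  for (k in keys[pass_annot]) {
    profiles[[k]] <- depth_profile(candidates[[k]], blocks, config)
    pass_cov[k] <- coverage_window_filter(profiles[[k]], config)
  }

  stage_counts <- data.frame(
    stage = c("refined_candidates", "contigs_built", "anchor", "multimap",
              "classify", "support", "repeat", "annotation", "coverage"),
    count = c(n_refined, length(candidates), sum(pass_anchor),
              sum(pass_multimap), sum(pass_classify), sum(pass_support),
              sum(pass_repeat), sum(pass_annot), sum(pass_cov)))

  paired <- any(reads$mate != "none")
  report <- make_report(candidates, support, profiles, keys[pass_cov],
                        annotation, paired, config)

  cand_tab <- candidate_table(candidates, support, pass_anchor,
                              pass_classify, pass_support, pass_repeat,
                              pass_annot, pass_cov)

  structure(list(report = report, candidates = cand_tab,
                 stage_counts = stage_counts,
                 mapped_best = mapped_best, stitched = stitched,
                 tables = tabs, reads = reads,
                 n_reads = nrow(reads), status = wr$status,
                 config = config),
            class = "fs_result")
}

# Sequencing errors on the base adjacent to a junction shift refinement by
# the same offset on both sides, creating low-support echo candidates a few
# bases from the true junction. A candidate is absorbed when another
# candidate with identical chromosomes and strands lies within `radius`
# bases on both sides and has strictly more spanning reads (ties keep
# both). Returns the keys to keep.
collapse_junction_echoes <- function(candidates, support, radius) {
  keys <- names(candidates)
  if (radius <= 0L || length(keys) < 2L) return(keys)
  span <- vapply(keys, function(k) support[[k]]$spanning_reads, integer(1))
  keep <- rep(TRUE, length(keys))
  for (i in seq_along(keys)) {
    ci <- candidates[[i]]
    for (j in seq_along(keys)) {
      if (i == j) next
      cj <- candidates[[j]]
      if (ci$left[["chrom"]] != cj$left[["chrom"]] ||
          ci$right[["chrom"]] != cj$right[["chrom"]] ||
          ci$left[["strand"]] != cj$left[["strand"]] ||
          ci$right[["strand"]] != cj$right[["strand"]]) next
      if (abs(as.integer(ci$left[["pos"]]) - as.integer(cj$left[["pos"]])) <= radius &&
          abs(as.integer(ci$right[["pos"]]) - as.integer(cj$right[["pos"]])) <= radius &&
          span[j] > span[i]) {
        keep[i] <- FALSE
        break
      }
    }
  }
  keys[keep]
}

ium_segments <- function(reads, ium, lens, config) {
  if (length(ium) == 0L)
    return(data.frame(read = integer(), seg = integer(), start = integer(),
                      end = integer(), seq = character(),
                      stringsAsFactors = FALSE))
  out <- lapply(ium, function(ri) {
    sr <- segment_ranges(lens[ri], config$segment_length)
    data.frame(read = ri, seg = seq_len(nrow(sr)), start = sr$start,
               end = sr$end,
               seq = substring(reads$sequence[ri], sr$start + 1L, sr$end),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Translate one discordant pattern into a refined candidate: trim the inner
# ends of both anchors by up to REFINE_SLACK bases (a segment can absorb a
# few junction-crossing bases as mismatches) and refine over the expanded
# middle.
refine_pattern <- function(genome, seq, pat, sr, config) {
  i <- pat$left_segment; j <- pat$right_segment
  a0 <- sr$start[i]; a1 <- sr$end[i]
  b0 <- sr$start[j]; b1 <- sr$end[j]
  t <- min(REFINE_SLACK, a1 - a0 - 1L, b1 - b0 - 1L)
  hl <- pat$left_hit; hr <- pat$right_hit
  leni <- a1 - a0; lenj <- b1 - b0
  left_last <- if (hl$strand == "+") hl$start + leni - t - 1L else hl$start + t
  right_first <- if (hr$strand == "+") hr$start + t
                 else hr$start + lenj - t - 1L
  middle <- substr(seq, a1 - t + 1L, b0 + t)
  refine_fusion_point(genome,
                      list(chrom = hl$chrom, strand = hl$strand,
                           last_pos = left_last),
                      list(chrom = hr$chrom, strand = hr$strand,
                           first_pos = right_first),
                      middle, config)
}

RESCUE_TAIL <- 16L  # tail word length: (1 + 1) * index_k for 1-mismatch seeds

# Paired-end candidate rescue (mate-narrowed tail search). For an IUM read
# whose usable segment placements form a prefix (or suffix) of the read
# with the rest unmapped, and whose partner has a unique gap-free
# alignment, the read's terminal 16-mer on the unmapped end is aligned
# genome-wide with <= 1 mismatch; placements falling inside the
# fragment-implied window around the partner become the second anchor and
# the junction is refined as usual.
rescue_candidates_by_mate <- function(genome, index, reads, wr, mapped_best,
                                      segs, hit_rows, seg_hits_all, config) {
  hitcount <- tabulate(wr$hits$query, nbins = nrow(reads))
  mb_row <- rep(NA_integer_, nrow(reads))
  mb_row[mapped_best$read_idx] <- seq_len(nrow(mapped_best))
  # partner read index: same pair_id, other mate
  partner <- rep(NA_integer_, nrow(reads))
  paired_rows <- which(reads$mate != "none")
  if (length(paired_rows)) {
    split_by_pair <- split(paired_rows, reads$pair_id[paired_rows])
    for (p in split_by_pair)
      if (length(p) == 2L) { partner[p[1]] <- p[2]; partner[p[2]] <- p[1] }
  }
  tails <- character(0)
  meta <- list()
  M <- config$multimap_bound_M
  for (ri in unique(segs$read)) {
    pr <- partner[ri]
    if (is.na(pr) || wr$status[pr] != "mapped" || hitcount[pr] != 1L) next
    rows <- which(segs$read == ri)
    n <- length(rows)
    cnt <- vapply(rows, function(r) {
      idx <- hit_rows[[as.character(r)]]
      if (is.null(idx)) 0L else length(idx)
    }, 0L)
    usable <- cnt >= 1L & cnt <= M
    if (!any(usable) || all(usable)) next
    L <- nchar(reads$sequence[ri])
    if (L < RESCUE_TAIL + config$min_anchor) next
    runs <- rle(usable)
    if (length(runs$lengths) != 2L) next  # need mapped|unmapped split
    if (runs$values[1]) {
      anchor_seg <- runs$lengths[1]         # last usable segment
      side <- "suffix"
      tail_seq <- substr(reads$sequence[ri], L - RESCUE_TAIL + 1L, L)
    } else {
      anchor_seg <- runs$lengths[1] + 1L    # first usable segment
      side <- "prefix"
      tail_seq <- substr(reads$sequence[ri], 1L, RESCUE_TAIL)
    }
    tails <- c(tails, tail_seq)
    meta[[length(meta) + 1L]] <- list(ri = ri, rows = rows,
                                      anchor_seg = anchor_seg, side = side,
                                      partner_row = mb_row[pr])
  }
  if (length(tails) == 0L) return(list())
  th <- align_exactish(index, tails, 1L, max_hits = 8L)
  out <- list()
  for (qi in unique(th$query)) {
    m <- meta[[qi]]
    pb <- mapped_best[m$partner_row, ]
    L <- nchar(reads$sequence[m$ri])
    W <- config$inner_dist_mean + 4L * config$inner_dist_sd + 2L * L
    hits <- th[th$query == qi & th$chrom == pb$chrom &
                 th$start + RESCUE_TAIL > pb$start - W &
                 th$start < pb$end + W, , drop = FALSE]
    if (nrow(hits) == 0L || nrow(hits) > M) next
    arow <- m$rows[m$anchor_seg]
    a0 <- segs$start[arow]; a1 <- segs$end[arow]
    aidx <- hit_rows[[as.character(arow)]]
    for (r in seq_len(nrow(hits))) {
      g <- as.list(hits[r, ])
      for (ai in aidx) {
        ah <- as.list(seg_hits_all[ai, ])
        cand <- rescue_refine(genome, reads$sequence[m$ri], m$side,
                              a0, a1, ah, g, L, config)
        if (!is.null(cand) && cand$class != "rejected")
          out[[cand$key]] <- cand
      }
    }
  }
  out
}

rescue_refine <- function(genome, seq, side, a0, a1, anchor_hit, tail_hit,
                          L, config) {
  t1 <- min(REFINE_SLACK, a1 - a0 - 1L)
  t2 <- min(REFINE_SLACK, RESCUE_TAIL - 1L)
  leni <- a1 - a0
  if (side == "suffix") {
    left_last <- if (anchor_hit$strand == "+")
      anchor_hit$start + leni - t1 - 1L else anchor_hit$start + t1
    right_first <- if (tail_hit$strand == "+")
      tail_hit$start + t2 else tail_hit$start + RESCUE_TAIL - t2 - 1L
    left <- list(chrom = anchor_hit$chrom, strand = anchor_hit$strand,
                 last_pos = left_last)
    right <- list(chrom = tail_hit$chrom, strand = tail_hit$strand,
                  first_pos = right_first)
    middle <- substr(seq, a1 - t1 + 1L, L - RESCUE_TAIL + t2)
  } else {
    left_last <- if (tail_hit$strand == "+")
      tail_hit$start + RESCUE_TAIL - t2 - 1L else tail_hit$start + t2
    right_first <- if (anchor_hit$strand == "+")
      anchor_hit$start + t1 else anchor_hit$start + leni - t1 - 1L
    left <- list(chrom = tail_hit$chrom, strand = tail_hit$strand,
                 last_pos = left_last)
    right <- list(chrom = anchor_hit$chrom, strand = anchor_hit$strand,
                  first_pos = right_first)
    middle <- substr(seq, RESCUE_TAIL - t2 + 1L, a0 + t1)
  }
  if (nchar(middle) < 1L) return(NULL)
  discordant <- left$chrom != right$chrom || left$strand != right$strand ||
    abs(left$last_pos - right$first_pos) >= config$min_intra_distance
  if (!discordant) return(NULL)
  ref <- refine_fusion_point(genome, left, right, middle, config)
  if (is.null(ref)) NULL else ref$candidate
}

build_tables <- function(mapped_best, stitched, reads, config) {
  gf_list <- list()
  if (nrow(mapped_best))
    gf_list[[1]] <- data.frame(read_id = reads$id[mapped_best$read_idx],
                               chrom = mapped_best$chrom,
                               start = mapped_best$start,
                               end = mapped_best$end,
                               strand = mapped_best$strand,
                               pair_id = reads$pair_id[mapped_best$read_idx],
                               stringsAsFactors = FALSE)
  fu_list <- list()
  blk_list <- list(mapped_best[, c("chrom", "start", "end")])
  for (al in stitched) {
    blk_list[[length(blk_list) + 1L]] <- al$blocks[, c("chrom", "start", "end")]
    if (is.null(al$fusion)) {
      if (nrow(al$blocks) == 1L)
        gf_list[[length(gf_list) + 1L]] <- data.frame(
          read_id = al$read_id, chrom = al$blocks$chrom,
          start = al$blocks$start, end = al$blocks$end,
          strand = al$blocks$strand, pair_id = reads$pair_id[al$read_idx],
          stringsAsFactors = FALSE)
    } else {
      sides <- fusion_side_bases(al)
      fu_list[[length(fu_list) + 1L]] <- data.frame(
        read_id = al$read_id, key = al$fusion$key,
        left_bases = sides[["left"]], right_bases = sides[["right"]],
        anchor_ok = anchor_filter(al, config),
        pair_id = reads$pair_id[al$read_idx], stringsAsFactors = FALSE)
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
  tabs <- support_tables(
    if (length(gf_list)) do.call(rbind, gf_list) else empty_gf,
    if (length(fu_list)) do.call(rbind, fu_list) else empty_fu)
  tabs$blocks <- do.call(rbind, blk_list)
  tabs
}

genes_at <- function(side, annotation) {
  pos <- as.integer(side[["pos"]])
  hit <- annotation$name[annotation$chrom == side[["chrom"]] &
                           annotation$start <= pos & pos < annotation$end]
  if (length(hit)) paste(unique(hit), collapse = ",") else "-"
}

make_report <- function(candidates, support, profiles, keep_keys, annotation,
                        paired, config) {
  rows <- lapply(keep_keys, function(k) {
    cand <- candidates[[k]]; sup <- support[[k]]
    ls <- coverage_stats(profiles[[k]]$ldepth)
    rs <- coverage_stats(profiles[[k]]$rdepth)
    evidence <- if (paired) sup$supporting_pairs else sup$spanning_reads
    rate <- evidence / max(1L, sup$contradicting_reads)
    comp <- list(lcount = ls$count, rcount = rs$count, lavg = ls$avg,
                 ravg = rs$avg, lgap = ls$gap, rgap = rs$gap,
                 lder = ls$der, rder = rs$der, rate = rate,
                 dist = sup$dist_sum)
    data.frame(gene_left = genes_at(cand$left, annotation),
               gene_right = genes_at(cand$right, annotation),
               chrom_left = cand$left[["chrom"]],
               pos_left = as.integer(cand$left[["pos"]]),
               strand_left = cand$left[["strand"]],
               chrom_right = cand$right[["chrom"]],
               pos_right = as.integer(cand$right[["pos"]]),
               strand_right = cand$right[["strand"]],
               class = cand$class,
               spanning_reads = sup$spanning_reads,
               supporting_pairs = sup$supporting_pairs,
               contradicting_reads = sup$contradicting_reads,
               lcount = ls$count, rcount = rs$count,
               lavg = ls$avg, ravg = rs$avg, lgap = ls$gap, rgap = rs$gap,
               lder = ls$der, rder = rs$der, rate = rate,
               dist = sup$dist_sum,
               score = fusion_score(comp, config),
               key = k, stringsAsFactors = FALSE)
  })
  empty <- data.frame(gene_left = character(), gene_right = character(),
                      chrom_left = character(), pos_left = integer(),
                      strand_left = character(), chrom_right = character(),
                      pos_right = integer(), strand_right = character(),
                      class = character(), spanning_reads = integer(),
                      supporting_pairs = integer(),
                      contradicting_reads = integer(), lcount = integer(),
                      rcount = integer(), lavg = numeric(), ravg = numeric(),
                      lgap = integer(), rgap = integer(), lder = numeric(),
                      rder = numeric(), rate = numeric(), dist = numeric(),
                      score = numeric(), key = character(),
                      stringsAsFactors = FALSE)
  rank_fusions(if (length(rows)) do.call(rbind, rows) else empty)
}

candidate_table <- function(candidates, support, pass_anchor, pass_classify,
                            pass_support, pass_repeat, pass_annot, pass_cov) {
  keys <- names(candidates)
  if (length(keys) == 0L)
    return(data.frame(key = character(), class = character(),
                      spanning_reads = integer(), supporting_pairs = integer(),
                      contradicting_reads = integer(), pass_anchor = logical(),
                      pass_classify = logical(), pass_support = logical(),
                      pass_repeat = logical(), pass_annotation = logical(),
                      pass_coverage = logical(), stringsAsFactors = FALSE))
  data.frame(key = keys,
             class = vapply(candidates, `[[`, "", "class"),
             spanning_reads = vapply(support, function(s)
               s$spanning_reads, integer(1)),
             supporting_pairs = vapply(support, function(s)
               s$supporting_pairs, integer(1)),
             contradicting_reads = vapply(support, function(s)
               s$contradicting_reads, integer(1)),
             pass_anchor = unname(pass_anchor),
             pass_classify = unname(pass_classify),
             pass_support = unname(pass_support),
             pass_repeat = unname(pass_repeat),
             pass_annotation = unname(pass_annot),
             pass_coverage = unname(pass_cov),
             stringsAsFactors = FALSE, row.names = NULL)
}

write_pipeline_outputs <- function(res, genome, outdir) {
  paths <- list(sam = file.path(outdir, "alignments.sam"),
                candidates = file.path(outdir, "candidates.tsv"),
                fusions = file.path(outdir, "fusions.tsv"),
                stages = file.path(outdir, "stage_counts.tsv"))
  writeLines(pipeline_sam_lines(res, genome), paths$sam)
  write.table(res$candidates, paths$candidates, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(res$report, paths$fusions, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(res$stage_counts, paths$stages, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths
}

pipeline_sam_lines <- function(res, genome) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(genome$chromosomes),
                      nchar(genome$chromosomes)),
              "@PG\tID:fusescan\tPN:fusescan")
  mb <- res$mapped_best
  reads <- res$reads
  gap_lines <- if (nrow(mb)) {
    seqs <- reads$sequence[mb$read_idx]
    out_seq <- ifelse(mb$strand == "-", revcomp(seqs), seqs)
    sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
            reads$id[mb$read_idx], ifelse(mb$strand == "-", 16L, 0L),
            mb$chrom, mb$start + 1L, mb$end - mb$start, out_seq,
            mb$mismatches)
  } else character(0)
  st_lines <- unlist(lapply(res$stitched, sam_records_one),
                     use.names = FALSE)
  c(header, gap_lines, st_lines)
}

#' Re-rank an existing fusion table
#'
#' Recomputes the score of each row of a `fusions.tsv` written by
#' [run_discover()] from its stored components and re-sorts.
#'
#' @param path Input TSV.
#' @param out_path Output TSV.
#' @param config An [run_config()].
#' @return The re-ranked data.frame, invisibly.
#' @export
rerank_fusions <- function(path, out_path, config = run_config()) {
  if (!file.exists(path)) fs_input_error(sprintf("table not found: %s", path))
  tab <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  if (nrow(tab)) {
    tab$score <- vapply(seq_len(nrow(tab)), function(i)
      fusion_score(as.list(tab[i, c("lcount", "rcount", "lavg", "ravg",
                                    "lgap", "rgap", "lder", "rder", "rate",
                                    "dist")]), config), numeric(1))
    tab <- rank_fusions(tab)
  }
  write.table(tab, out_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

#' @export
print.fs_result <- function(x, ...) {
  cat(sprintf("fs_result: %d read(s), %d candidate(s), %d reported fusion(s)\n",
              x$n_reads, nrow(x$candidates), nrow(x$report)))
  invisible(x)
}
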