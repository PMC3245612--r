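# Deterministic simulator: toy genomes with genes, planted fusion events
# (inter, intra >= 100 kb, inversion), read-through and repeat-artifact
# decoys, and error-bearing reads with a recorded truth set.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

#' Specification of a synthetic dataset
#'
#' Describes the world a simulation builds: a multi-chromosome genome of
#' i.i.d. uniform A/C/G/T background with genes laid out on a jittered
#' grid, planted fusion events between distinct genes, decoy events
#' (read-through transcription below the 100-kb distance rule and a
#' repeat-induced artifact whose junction word is duplicated near the
#' partner locus), and paired or single 50-bp reads at a stated coverage
#' depth and substitution error rate. Defaults follow the published test
#' geometries: 50-bp paired reads from 300-bp fragments, depth 30, error
#' rate 0.005, a ~2.1-Mb genome of 3 chromosomes.
#'
#' @param seed Integer seed; every random choice flows from it.
#' @param n_chromosomes,chrom_length Genome shape.
#' @param genes_per_chrom Genes laid out per chromosome.
#' @param n_inter,n_intra,n_inversion Counts of reportable planted events.
#' @param n_read_through Adjacent-gene (< 100 kb) decoy transcripts.
#' @param n_repeat_artifact Fusion-like decoys with a duplicated junction
#'   word.
#' @param n_intron_genes Background genes carrying one intron (to exercise
#'   spliced stitching).
#' @param read_length,fragment_length_mean,fragment_length_sd,paired Read
#'   geometry.
#' @param coverage_depth Mean per-base depth over each transcript.
#' @param error_rate Per-base substitution error probability.
#' @param planted_events Optional explicit event list (each a list with
#'   `type`, `chrom_l`, `pos_l`, `strand_l`, `chrom_r`, `pos_r`,
#'   `strand_r`); overrides the automatic gene-grid layout.
#' @return List of class `fs_simspec`.
#' @export
simulation_spec <- function(seed = 1L,
                            n_chromosomes = 3L,
                            chrom_length = 700000L,
                            genes_per_chrom = 16L,
                            n_inter = 10L,
                            n_intra = 5L,
                            n_inversion = 2L,
                            n_read_through = 1L,
                            n_repeat_artifact = 1L,
                            n_intron_genes = 6L,
                            read_length = 50L,
                            fragment_length_mean = 300L,
                            fragment_length_sd = 30L,
                            coverage_depth = 30,
                            error_rate = 0.005,
                            paired = TRUE,
                            planted_events = NULL) {
  spec <- list(seed = as.integer(seed),
               n_chromosomes = as.integer(n_chromosomes),
               chrom_length = as.integer(chrom_length),
               genes_per_chrom = as.integer(genes_per_chrom),
               n_inter = as.integer(n_inter), n_intra = as.integer(n_intra),
               n_inversion = as.integer(n_inversion),
               n_read_through = as.integer(n_read_through),
               n_repeat_artifact = as.integer(n_repeat_artifact),
               n_intron_genes = as.integer(n_intron_genes),
               read_length = as.integer(read_length),
               fragment_length_mean = as.integer(fragment_length_mean),
               fragment_length_sd = as.integer(fragment_length_sd),
               coverage_depth = as.numeric(coverage_depth),
               error_rate = as.numeric(error_rate),
               paired = isTRUE(paired),
               planted_events = planted_events)
  if (spec$paired && spec$fragment_length_mean < 2L * spec$read_length)
    fs_config_error("fragment_length_mean must be at least 2 * read_length for paired reads")
  if (!is.null(planted_events)) validate_events(planted_events)
  structure(spec, class = "fs_simspec")
}

validate_events <- function(events) {
  for (i in seq_along(events)) {
    ev <- events[[i]]
    sep <- abs(as.integer(ev$pos_l) - as.integer(ev$pos_r))
    same <- identical(ev$chrom_l, ev$chrom_r)
    if (ev$type == "intra" &&
        (!same || ev$strand_l != ev$strand_r || sep < 100000L))
      fs_input_error(sprintf(
        "event %d labelled intra must be same-chromosome, same-strand, separated by >= 100,000 bp (got %d)",
        i, sep))
    if (ev$type == "read_through" && (!same || sep >= 100000L))
      fs_input_error(sprintf(
        "event %d labelled read_through must be same-chromosome at < 100,000 bp (got %d)", i, sep))
    if (ev$type == "inter" && same)
      fs_input_error(sprintf("event %d labelled inter lies on one chromosome", i))
  }
  invisible(events)
}

# exon size inside which breakpoints are planted; breakpoints sit at the
# exon midpoint so the 300-bp coverage window on each side stays exonic
SIM_EXON <- 1200L
SIM_BP_OFF <- 600L
SIM_INTRON <- 500L

#' Generate a genome, annotation and planted events
#'
#' Lays genes out on a jittered grid, assigns donor/acceptor genes to the
#' requested events (intra pairs at >= ~127 kb, read-through pairs on
#' adjacent slots ~42 kb apart, inversion acceptors annotated on the minus
#' strand), plants breakpoints at exon midpoints, removes 1-bp
#' microhomology at every junction so breakpoints are unambiguous, and for
#' repeat artifacts copies the 40 bases ending at the left breakpoint to
#' within 100 kb of the right breakpoint. Identical seeds give
#' byte-identical output.
#'
#' @param spec An [simulation_spec()].
#' @return List with `genome` ([fs_genome()]), `annotation`
#'   (`fs_annotation`), `genes` (layout data.frame) and `events`
#'   (data.frame with breakpoint sides, `type`, `reportable`, canonical
#'   `key`).
#' @export
make_genome <- function(spec) {
  with_seed(spec$seed, make_genome_impl(spec))
}

make_genome_impl <- function(spec) {
  chroms <- sprintf("chr%d", seq_len(spec$n_chromosomes))
  seqs <- vapply(chroms, function(.)
    paste(sample(ACGT, spec$chrom_length, replace = TRUE), collapse = ""),
    "")
  names(seqs) <- chroms

  if (is.null(spec$planted_events)) {
    layout <- layout_genes_events(spec)
  } else {
    layout <- explicit_layout(spec)
  }
  genes <- layout$genes; events <- layout$events

  genome <- fs_genome(seqs)
  # remove 1-bp microhomology at every junction: the genome base just past
  # the left breakpoint must differ from the first acceptor base, and the
  # transcript base just before the right breakpoint from the last donor
  # base; otherwise the breakpoint is ambiguous by construction.
  for (i in seq_len(nrow(events))) {
    genome <- break_microhomology(genome, events[i, ])
  }
  # repeat artifacts: duplicate the 40-base word ending at the left
  # breakpoint to 20 kb downstream of the right breakpoint
  for (i in which(events$type == "repeat_artifact")) {
    ev <- events[i, ]
    word <- side_flank_left(genome,
                            side_vec(ev$chrom_l, ev$pos_l, ev$strand_l), 40L)
    at <- ev$pos_r + 20000L
    s <- genome$chromosomes[[ev$chrom_r]]
    substr(s, at + 1L, at + 40L) <- word
    genome$chromosomes[[ev$chrom_r]] <- s
  }
  events$key <- vapply(seq_len(nrow(events)), function(i) {
    ev <- events[i, ]
    fusion_candidate(ev$chrom_l, ev$pos_l, ev$strand_l,
                     ev$chrom_r, ev$pos_r, ev$strand_r)$key
  }, "")
  ann <- genes[, c("chrom", "start", "end", "name", "strand")]
  class(ann) <- c("fs_annotation", "data.frame")
  list(genome = genome, annotation = ann, genes = genes, events = events)
}

layout_genes_events <- function(spec) {
  margin <- 10000L
  span <- spec$chrom_length - 2L * margin
  slot_w <- span %/% spec$genes_per_chrom
  glen_plain <- SIM_EXON
  genes <- do.call(rbind, lapply(seq_len(spec$n_chromosomes), function(ci) {
    starts <- margin + (seq_len(spec$genes_per_chrom) - 1L) * slot_w +
      as.integer(floor(runif(spec$genes_per_chrom, 0, 2000)))
    data.frame(chrom = sprintf("chr%d", ci), slot = seq_len(spec$genes_per_chrom),
               start = starts, stringsAsFactors = FALSE)
  }))
  genes$name <- sprintf("G%03d", seq_len(nrow(genes)))
  genes$strand <- "+"
  genes$has_intron <- FALSE
  genes$end <- genes$start + glen_plain
  genes$role <- "background"

  n_ev <- spec$n_inter + spec$n_intra + spec$n_inversion +
    spec$n_read_through + spec$n_repeat_artifact
  if (2L * n_ev + spec$n_intron_genes > nrow(genes))
    fs_input_error("not enough genes for the requested events; increase genes_per_chrom")

  free <- seq_len(nrow(genes))
  take <- function(idx) { free <<- setdiff(free, idx); idx }
  pick_pair_same_chrom <- function(min_slots, max_slots = Inf) {
    for (a in free) {
      mates <- free[genes$chrom[free] == genes$chrom[a] &
                      genes$slot[free] - genes$slot[a] >= min_slots &
                      genes$slot[free] - genes$slot[a] <= max_slots]
      if (length(mates)) return(take(c(a, mates[1])))
    }
    fs_input_error("infeasible event layout: no same-chromosome gene pair available")
  }
  pick_pair_diff_chrom <- function() {
    # draw the two ends from the two best-stocked chromosomes so that
    # cross-chromosome pairs are never exhausted prematurely
    tab <- sort(table(genes$chrom[free]), decreasing = TRUE)
    if (length(tab) < 2L)
      fs_input_error("infeasible event layout: no cross-chromosome gene pair available")
    a <- free[genes$chrom[free] == names(tab)[1]][1]
    b <- free[genes$chrom[free] == names(tab)[2]][1]
    take(c(a, b))
  }
  # slots needed for >= 100 kb separation (plus margin for the repeat
  # filter's coarse start-coordinate distance)
  min_slots_intra <- as.integer(ceiling(102000 / slot_w))
  evs <- list()
  add_event <- function(type, gl, gr, strand_r = "+") {
    pos_l <- genes$start[gl] + SIM_BP_OFF - 1L     # last donor base
    pos_r <- if (strand_r == "+") genes$start[gr] + SIM_BP_OFF
             else genes$start[gr] + SIM_BP_OFF - 1L # first acceptor base
    evs[[length(evs) + 1L]] <<- data.frame(
      type = type, gene_l = genes$name[gl], gene_r = genes$name[gr],
      chrom_l = genes$chrom[gl], pos_l = pos_l, strand_l = "+",
      chrom_r = genes$chrom[gr], pos_r = pos_r, strand_r = strand_r,
      reportable = type %in% c("inter", "intra", "inversion"),
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(spec$n_inter)) {
    p <- pick_pair_diff_chrom(); add_event("inter", p[1], p[2])
  }
  for (i in seq_len(spec$n_repeat_artifact)) {
    p <- pick_pair_diff_chrom(); add_event("repeat_artifact", p[1], p[2])
  }
  for (i in seq_len(spec$n_intra)) {
    p <- pick_pair_same_chrom(min_slots_intra); add_event("intra", p[1], p[2])
  }
  for (i in seq_len(spec$n_inversion)) {
    p <- pick_pair_same_chrom(min_slots_intra)
    genes$strand[p[2]] <- "-"
    add_event("inversion", p[1], p[2], strand_r = "-")
  }
  for (i in seq_len(spec$n_read_through)) {
    p <- pick_pair_same_chrom(1L, max_slots = 2L); add_event("read_through", p[1], p[2])
  }
  intron_idx <- utils::head(free, spec$n_intron_genes)
  genes$has_intron[intron_idx] <- TRUE
  genes$end[intron_idx] <- genes$start[intron_idx] + SIM_EXON + SIM_INTRON
  used <- setdiff(seq_len(nrow(genes)), free)
  genes$role[used] <- "fused"
  events <- if (length(evs)) do.call(rbind, evs) else
    data.frame(type = character(), gene_l = character(), gene_r = character(),
               chrom_l = character(), pos_l = integer(), strand_l = character(),
               chrom_r = character(), pos_r = integer(), strand_r = character(),
               reportable = logical(), stringsAsFactors = FALSE)
  list(genes = genes, events = events)
}

explicit_layout <- function(spec) {
  evs <- do.call(rbind, lapply(seq_along(spec$planted_events), function(i) {
    ev <- spec$planted_events[[i]]
    data.frame(type = ev$type, gene_l = sprintf("GL%02d", i),
               gene_r = sprintf("GR%02d", i),
               chrom_l = ev$chrom_l, pos_l = as.integer(ev$pos_l),
               strand_l = ev$strand_l,
               chrom_r = ev$chrom_r, pos_r = as.integer(ev$pos_r),
               strand_r = ev$strand_r,
               reportable = ev$type %in% c("inter", "intra", "inversion"),
               stringsAsFactors = FALSE)
  }))
  genes <- rbind(
    data.frame(chrom = evs$chrom_l, slot = NA_integer_,
               start = evs$pos_l - SIM_BP_OFF + 1L, name = evs$gene_l,
               strand = evs$strand_l, has_intron = FALSE,
               end = evs$pos_l - SIM_BP_OFF + 1L + SIM_EXON,
               role = "fused", stringsAsFactors = FALSE),
    data.frame(chrom = evs$chrom_r, slot = NA_integer_,
               start = ifelse(evs$strand_r == "+", evs$pos_r - SIM_BP_OFF,
                              evs$pos_r + SIM_BP_OFF - SIM_EXON + 1L),
               name = evs$gene_r, strand = evs$strand_r, has_intron = FALSE,
               end = ifelse(evs$strand_r == "+",
                            evs$pos_r - SIM_BP_OFF + SIM_EXON,
                            evs$pos_r + SIM_BP_OFF + 1L),
               role = "fused", stringsAsFactors = FALSE))
  list(genes = genes, events = evs)
}

# force the genome bases adjacent to a junction to break 1-bp microhomology
break_microhomology <- function(genome, ev) {
  left <- side_vec(ev$chrom_l, ev$pos_l, ev$strand_l)
  right <- side_vec(ev$chrom_r, ev$pos_r, ev$strand_r)
  set_base <- function(genome, chrom, pos, not_base) {
    s <- genome$chromosomes[[chrom]]
    if (substr(s, pos + 1L, pos + 1L) == not_base) {
      repl <- setdiff(ACGT, not_base)[1]
      substr(s, pos + 1L, pos + 1L) <- repl
      genome$chromosomes[[chrom]] <- s
    }
    genome
  }
  comp1 <- function(b) chartr("ACGT", "TGCA", b)
  # transcript base just past the left breakpoint vs first acceptor base
  t_r0 <- side_flank_right(genome, right, 1L)
  if (ev$strand_l == "+") {
    genome <- set_base(genome, ev$chrom_l, ev$pos_l + 1L, t_r0)
  } else {
    genome <- set_base(genome, ev$chrom_l, ev$pos_l - 1L, comp1(t_r0))
  }
  # transcript base just before the right breakpoint vs last donor base
  t_ld <- side_flank_left(genome, left, 1L)
  if (ev$strand_r == "+") {
    genome <- set_base(genome, ev$chrom_r, ev$pos_r - 1L, t_ld)
  } else {
    genome <- set_base(genome, ev$chrom_r, ev$pos_r + 1L, comp1(t_ld))
  }
  genome
}

#' Build fused and background transcripts
#'
#' Each planted event yields one transcript: the donor side's exonic
#' sequence up to and including the left breakpoint, concatenated with the
#' acceptor side from the right breakpoint onward (reverse-complemented
#' for minus-strand sides). Every gene additionally contributes its normal
#' (unfused, spliced) transcript so background expression, contradicting
#' reads and the annotation filter are exercised.
#'
#' @param world A [make_genome()] result.
#' @param spec The [simulation_spec()].
#' @return Named character vector of transcript sequences; fused
#'   transcripts are named `FUS<i>`, background ones by gene name.
#' @export
make_fused_transcripts <- function(world, spec) {
  genome <- world$genome
  out <- character(0)
  ev <- world$events
  for (i in seq_len(nrow(ev))) {
    donor <- side_flank_left(genome, side_vec(ev$chrom_l[i], ev$pos_l[i],
                                              ev$strand_l[i]), SIM_BP_OFF)
    accep <- side_flank_right(genome, side_vec(ev$chrom_r[i], ev$pos_r[i],
                                               ev$strand_r[i]), SIM_BP_OFF)
    out[sprintf("FUS%02d", i)] <- paste0(donor, accep)
  }
  g <- world$genes
  for (i in seq_len(nrow(g))) {
    s <- if (g$has_intron[i]) {
      ex1 <- genome_sub(genome, g$chrom[i], g$start[i], g$start[i] + SIM_EXON %/% 2L)
      ex2 <- genome_sub(genome, g$chrom[i],
                        g$start[i] + SIM_EXON %/% 2L + SIM_INTRON, g$end[i])
      paste0(ex1, ex2)
    } else genome_sub(genome, g$chrom[i], g$start[i], g$end[i])
    if (g$strand[i] == "-") s <- revcomp(s)
    out[g$name[i]] <- s
  }
  out
}

#' Simulate reads from transcripts
#'
#' Draws fragments uniformly along each transcript at the specified
#' coverage depth with normally distributed fragment lengths, flips
#' fragment orientation with probability 1/2 (unstranded library), applies
#' per-base substitution errors, and emits single-end reads or FR read
#' pairs (mate 2 is the reverse complement of the fragment 3' end; the
#' inner distance is fragment length minus twice the read length).
#'
#' @param spec An [simulation_spec()].
#' @param transcripts Named character vector of transcript sequences.
#' @return List with `reads` (data.frame: id, sequence, mate, pair_id) and
#'   `origins` (data.frame recording transcript, fragment start and
#'   orientation per fragment).
#' @export
simulate_reads <- function(spec, transcripts) {
  with_seed(spec$seed + 1L, simulate_reads_impl(spec, transcripts))
}

simulate_reads_impl <- function(spec, transcripts) {
  rl <- spec$read_length
  per_frag <- if (spec$paired) 2L * rl else rl
  frag_min <- if (spec$paired) 2L * rl else rl
  ids <- character(0); seq1 <- character(0); seq2 <- character(0)
  org <- list()
  for (t in names(transcripts)) {
    s <- transcripts[[t]]
    len <- nchar(s)
    if (len < frag_min)
      fs_input_error(sprintf("transcript %s (%d bp) shorter than minimum fragment %d",
                             t, len, frag_min))
    nf <- as.integer(ceiling(spec$coverage_depth * len / per_frag))
    fl <- as.integer(round(rnorm(nf, spec$fragment_length_mean,
                                 spec$fragment_length_sd)))
    fl <- pmin(pmax(fl, frag_min), len)
    st <- as.integer(floor(runif(nf, 0, len - fl + 1)))
    fwd <- runif(nf) < 0.5
    frag <- substring(s, st + 1L, st + fl)
    frag[!fwd] <- revcomp(frag[!fwd])
    id <- sprintf("%s_F%05d", t, seq_len(nf))
    r1 <- substring(frag, 1L, rl)
    ids <- c(ids, id); seq1 <- c(seq1, r1)
    if (spec$paired) {
      r2 <- revcomp(substring(frag, fl - rl + 1L, fl))
      seq2 <- c(seq2, r2)
    }
    org[[t]] <- data.frame(id = id, transcript = t, start = st,
                           frag_len = fl, forward = fwd,
                           stringsAsFactors = FALSE)
  }
  seq1 <- inject_errors(seq1, spec$error_rate)
  if (spec$paired) seq2 <- inject_errors(seq2, spec$error_rate)
  n <- length(ids)
  reads <- if (spec$paired) {
    data.frame(id = c(ids, ids), sequence = c(seq1, seq2),
               mate = rep(c("first", "second"), each = n),
               pair_id = rep(seq_len(n), 2L), stringsAsFactors = FALSE)
  } else {
    data.frame(id = ids, sequence = seq1, mate = "none",
               pair_id = NA_integer_, stringsAsFactors = FALSE)
  }
  list(reads = reads, origins = do.call(rbind, org))
}

inject_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  lens <- nchar(seqs)
  k <- rbinom(length(seqs), lens, rate)
  for (i in which(k > 0L)) {
    pos <- sample.int(lens[i], k[i])
    for (p in pos) {
      old <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(ACGT, old), 1L)
    }
  }
  seqs
}

#' Simulate a complete dataset in memory
#'
#' @param spec An [simulation_spec()].
#' @return List with `genome`, `annotation`, `events`, `transcripts`,
#'   `reads` and `origins`.
#' @export
simulate_dataset <- function(spec = simulation_spec()) {
  world <- make_genome(spec)
  transcripts <- make_fused_transcripts(world, spec)
  sim <- simulate_reads(spec, transcripts)
  c(world, list(transcripts = transcripts, reads = sim$reads,
                origins = sim$origins))
}

#' Simulate a dataset and write it to disk
#'
#' Writes `genome.fa`, `genes.bed`, `truth.tsv` (event type, breakpoint
#' sides, reportable flag, canonical key) and `reads_1.fq` /
#' `reads_2.fq` (single-end: `reads.fq`). Identical specs produce
#' byte-identical files.
#'
#' @param spec An [simulation_spec()].
#' @param outdir Output directory (created if missing).
#' @return Named list of the written paths, invisibly.
#' @export
run_simulate <- function(spec = simulation_spec(), outdir = ".") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ds <- simulate_dataset(spec)
  paths <- list(genome = file.path(outdir, "genome.fa"),
                annotation = file.path(outdir, "genes.bed"),
                truth = file.path(outdir, "truth.tsv"))
  write_fasta(ds$genome, paths$genome)
  write_bed(ds$annotation, paths$annotation)
  write.table(ds$events[, c("type", "chrom_l", "pos_l", "strand_l",
                            "chrom_r", "pos_r", "strand_r", "reportable",
                            "key")],
              paths$truth, sep = "\t", quote = FALSE, row.names = FALSE)
  fq <- function(df, path) {
    qual <- strrep("I", nchar(df$sequence))
    writeLines(paste(paste0("@", df$id), df$sequence, "+", qual,
                     sep = "\n"), path)
  }
  if (spec$paired) {
    paths$reads_1 <- file.path(outdir, "reads_1.fq")
    paths$reads_2 <- file.path(outdir, "reads_2.fq")
    fq(ds$reads[ds$reads$mate == "first", ], paths$reads_1)
    fq(ds$reads[ds$reads$mate == "second", ], paths$reads_2)
  } else {
    paths$reads <- file.path(outdir, "reads.fq")
    fq(ds$reads, paths$reads)
  }
  invisible(paths)
}
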