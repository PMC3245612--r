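---
title: "Fusion transcript discovery with fusescan: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fusion transcript discovery with fusescan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusescan)
```

## The problem and the model

RNA-seq reads from a fusion transcript straddle a junction joining two
loci that may lie on different chromosomes, far apart on one chromosome,
or in opposite orientations. Such reads have no contiguous genomic
alignment, so a conventional spliced aligner discards them. `fusescan`
recovers them with a split-segment model: a read that fails end-to-end
gap-free alignment (an *IUM read*) is cut into 25-bp segments, the
segments are placed independently, and a discordant placement pattern —
two anchors that cannot belong to one collinear transcript — nominates a
candidate fusion. The junction is then located at base-pair resolution by
sliding a split point through the unexplained bases between the anchors
and minimizing mismatches against the two genomic flanks.

The model makes three assumptions worth stating explicitly. First,
junctions are clean joins: no untemplated bases are inserted at the
breakpoint, and small-scale microhomology is tolerated but resolved
deterministically (ties go to the leftmost split in transcript order).
Second, a read spans at most one fusion; chains that would require two
junctions in one read are rejected outright. Third, evidence is judged at
the fragment level: a spanning read and a bridging mate pair are distinct,
complementary observations, and reads mapping contiguously *across* a
claimed breakpoint count against it.

Discovery is deliberately annotation-free; gene annotation enters only as
a late filter (at least one side of a reported fusion must lie in an
annotated gene), so novel partners of known genes remain discoverable.

## Pipeline stages and their parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `segment_length` | 25 | bp | Segment size; final segment absorbs the remainder (25–49 bp) |
| `max_segment_mismatches` | 2 | count | Per-segment mismatch bound (configurable 0–3) |
| `max_read_mismatches` | 2 | count | Whole-read gap-free bound; defines IUM status |
| `multimap_bound_M` | 2 | count | Placements allowed before a read/segment is discarded as repetitive |
| `min_anchor` | 13 | bp | Minimum aligned bases on *each* side of a junction for a spanning read |
| `max_anchor_mismatches` | 2 | count | Mismatch bound for spanning reads |
| `min_intra_distance` | 100,000 | bp | Minimum same-chromosome, same-strand separation; closer is read-through |
| `flank_length` | 22 | bp | Flank per side of the 44-bp spliced fusion contig |
| `min_contig_overlap` | 3 | bp | Junction overlap required of a contig hit, per side |
| `repeat_kmer` | 23 | bp | Junction word length for the repeat filter |
| `window_half` | 300 | bp | Coverage window per side; also the `max_avg` cap in the score |
| `max_intron_length` | 100,000 | bp | Largest same-strand gap stitched as an intron |
| `max_indel` | 3 | bp | Largest offset stitched as an indel |
| `min_covered_fraction` | 0.5 | fraction | Covered-base requirement per window side |
| `inner_dist_mean`, `inner_dist_sd` | 200, 30 | bp | Fragment geometry for mate narrowing and pair support |
| `index_k` | 8 | bp | Genome index k-mer size |
| `collapse_radius` | 5 | bp | Junction-jitter collapse (see below) |

Three parameters are this package's own additions, with the following
rationale:

**`index_k` and the completeness guarantee.** The segment aligner seeds on
error-free k-mers at offsets 0, k, 2k, … and the final offset, which is
complete (finds every placement within the mismatch bound) whenever
`(max_mismatches + 1) · k ≤ query length`. The default k = 8 satisfies this
for 25-bp segments at 2 mismatches (3 · 8 = 24 ≤ 25). Allowing 3 mismatches
on 25-bp segments requires k ≤ 6, and the configuration constructor
enforces the inequality rather than silently losing placements. The
oracle-equivalence tests run at k = 6 so mismatch bounds up to 3 can be
checked against the exhaustive scan.

**`max_intron_length` = `min_intra_distance`.** The upstream tool this
design follows leaves the maximum intron length user-defined. Setting it
equal to the 100-kb fusion distance cutoff makes same-chromosome,
same-strand gaps partition cleanly: anything shorter stitches as an intron
(which is exactly how read-through transcription should be absorbed —
those reads get a −2 spliced alignment, never a fusion), and anything at
or beyond the cutoff is reachable only through a fusion candidate. With
independent values there would be a window in which the same gap is both
an intron and a fusion, and the −2 versus −4 penalty would silently decide
the call.

**`collapse_radius`.** At any nonzero error rate, a base-call error on the
junction-adjacent base shifts refinement by the same offset on both sides,
creating a ±1–2-bp *echo* of the true junction. Echoes attract the handful
of error-bearing reads that generated them, and — because mate-pair
support is insensitive to a 2-bp shift — share the true junction's
supporting pairs, so support thresholds cannot remove them. A candidate
whose two breakpoints both lie within `collapse_radius` (5 bp) of a
same-chromosome/strand candidate with strictly more spanning reads is
therefore absorbed. Genuine alternative fusion points caused by
alternative splicing sit full exon lengths apart and are unaffected; they
are reported separately, as intended. Exact-coordinate duplicates are
always merged regardless of this setting.

## Paired-end mate narrowing

With 50-bp reads and 25-bp segments, both segments of a junction read map
discordantly only when the junction falls within a few bases of the
segment boundary; a junction in the middle of a segment leaves a single
anchor. For paired-end data the pipeline rescues these reads: if the
partner read has a unique gap-free alignment, the fusion point is expected
within the inner mate distance ± SD of the partner (measured from the
partner's fragment-oriented outer coordinate — the phrase "left genomic
coordinate" is ambiguous for minus-strand partners, and fragment
orientation restores strand symmetry). The read's terminal 16-mer on the
unmapped side is aligned genome-wide at ≤ 1 mismatch (16 = 2 · k keeps the
pigeonhole guarantee), placements inside the window become the second
anchor, and refinement proceeds as usual. Without this path, fusion
discovery in 50-bp paired data depends on the accident of a read whose
junction sits at a segment boundary.

## What the simulator emulates — and what it does not

`simulation_spec()` describes a stated world: i.i.d. uniform A/C/G/T
chromosomes (default 3 × 700 kb), genes on a jittered grid, planted
inter/intra/inversion fusions with breakpoints at exon midpoints,
read-through decoys on adjacent genes (< 100 kb), a repeat-artifact decoy
whose left junction word is duplicated within 100 kb of the right locus,
unstranded 50-bp paired reads from 300 ± 30-bp fragments at depth 30, and
per-base substitution errors at 0.005 — the fragment and read geometries
of the published datasets this design targets. Background (unfused)
transcripts of every gene are simulated too, so contradicting-read
counting, the annotation filter and coverage windows are exercised
realistically. Every read's origin and every junction are recorded as
ground truth.

Two deliberate idealizations matter for interpreting green tests. First,
planted junctions are made free of 1-bp microhomology (the genome base
just past the left breakpoint is forced to differ from the first acceptor
base, and symmetrically): with random sequence roughly 44% of junctions
would otherwise be ambiguous by ±1 bp, making "base-pair-exact recovery"
ill-posed rather than hard. This is a property of the stated world, not a
tuning knob — real junctions with microhomology are reported at the
leftmost consistent coordinate. Second, the error model is
substitution-only; indels arise in alignment (stitching) but not in reads.
A green recovery test therefore establishes correctness of the machinery
on clean rearrangements in non-repetitive sequence — it does not establish
robustness to segmental duplication, sequencing indels, PCR chimeras or
ligation artifacts, all of which the original study handles only partially
as well.

## Numerical and procedural choices

* **Refinement tie-break:** smallest split index (leftmost junction in
  transcript order); verified against exhaustive enumeration.
* **Selection total order:** penalty, then mismatches, then (chrom, start,
  strand) of the first block — permutation-invariant by construction.
* **Deletion vs intron:** a positive same-strand gap of 1–3 bp is a
  deletion (−4), 4 bp to 100 kb an intron (−2). Splice-site dinucleotides
  are *not* checked; junction discovery by coverage islands is out of
  scope here.
* **Score operator placement:** the published form of the ranking score is
  typographically corrupted (operators lost between terms). The
  reconstruction used here — rewards for covered bases and capped average
  depth, penalties for left/right imbalance, gaps and the normalized
  coverage deviation, plus `rate · min(1000, dist)` — follows the stated
  semantics ("prefers alignments that have no gaps and uniform depth") and
  is isolated in one function so coefficients can be varied. `max_avg`
  equals the window size (300).
* **Rate denominator:** with zero contradicting reads the ratio uses
  denominator 1; the ordering among candidates is preserved and division
  by zero avoided. For single-end data the rate uses spanning reads, and
  `dist` sums spanning-read left-anchor sizes (mirroring the stated
  single-end substitution for the rate).
* **`der` at zero coverage:** defined as 1.0 and flagged; the coverage
  filter rejects such candidates before ranking under defaults.
* **Repeat filter:** junction words are matched exactly (0 mismatches) on
  both strands; placements are compared by start coordinate, which is
  adequate at a 100-kb proximity threshold.
* **Contradicting reads** must overlap the breakpoint boundary by
  `min_anchor` bases on both sides — the mirror image of the spanning-read
  anchor rule, so weak overlaps count for neither side.
* **SAM dialect:** fusion reads are emitted as two standard records with
  `XF`/`XP` tags rather than custom CIGAR opcodes, so any SAM parser can
  read the output; the XF tag is written in the read's orientation, and
  the canonical candidate identity is recoverable by flipping both sides.
* **Filter order** (anchor → multimap → classify → support → repeat →
  annotation → coverage) affects only the stage-count log; the surviving
  set is order-independent because each predicate is evaluated on the same
  inputs.
* **Determinism:** discovery contains no randomness; simulation draws all
  randomness from one seed with a fixed RNG kind, and the RNG state is
  restored afterwards. Identical inputs give byte-identical outputs.

## Known limitations

Fusions joining three or more loci in one transcript are out of scope, as
is microhomology reporting at junctions, quality-aware alignment (base
qualities are parsed and ignored), BAM/CRAM output, and statistical
calibration of the ranking score into a false-discovery rate. The
desk-scale aligner is exact but not tuned for mammalian-genome throughput;
the design treats the aligner as a replaceable black box, as its
predecessor did.
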