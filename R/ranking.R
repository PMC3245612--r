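# Read-distribution ranking of surviving fusion candidates.

#' Summary statistics of one coverage window
#'
#' For a per-base depth array over one side of the fusion window, returns
#' the number of covered bases, the mean depth, the longest run of
#' zero-depth bases, and the normalized coverage deviation
#' `der = sqrt( (1/w) * sum_n ((avg - depth_n)/avg)^2 )`,
#' which is 0 for perfectly uniform coverage and scale-invariant in depth.
#' When the mean depth is 0, `der` is defined as 1.0 and the result is
#' flagged (the coverage filter should already have rejected such a
#' window).
#'
#' @param depth Numeric vector of per-base depths.
#' @return List with `count`, `avg`, `gap`, `der`, `flagged`.
#' @export
coverage_stats <- function(depth) {
  count <- sum(depth > 0)
  avg <- mean(depth)
  r <- rle(depth == 0)
  gap <- if (any(r$values)) max(r$lengths[r$values]) else 0L
  if (avg > 0) {
    der <- sqrt(mean(((avg - depth) / avg)^2))
    flagged <- FALSE
  } else {
    der <- 1.0
    flagged <- TRUE
  }
  list(count = as.integer(count), avg = avg, gap = as.integer(gap),
       der = der, flagged = flagged)
}

#' Read-distribution score of a fusion
#'
#' Rewards covered bases and (capped) average depth on both sides;
#' penalizes left/right imbalance in coverage and depth, zero-coverage
#' gaps, and coverage variance; adds a support-rate term. With
#' `max_avg = window_half` (300):
#'
#' `score = lcount + rcount + min(max_avg, lavg) + min(max_avg, ravg)
#'   - |lcount - rcount| - min(max_avg, |lavg - ravg|)
#'   - (lgap + rgap) - (lder + rder) * max_avg
#'   + rate * min(1000, dist)`
#'
#' where `rate` is the ratio of supporting pairs (spanning reads for
#' single-end data) to contradicting reads (denominator 1 when there are
#' no contradicting reads) and `dist` sums the end-to-junction distances
#' of the supporting pairs. Higher is better.
#'
#' @param components List with `lcount`, `rcount`, `lavg`, `ravg`, `lgap`,
#'   `rgap`, `lder`, `rder`, `rate`, `dist`.
#' @param config An [run_config()] (`window_half` doubles as `max_avg`).
#' @return Numeric score.
#' @export
fusion_score <- function(components, config = run_config()) {
  max_avg <- config$window_half
  with(components,
    lcount + rcount + min(max_avg, lavg) + min(max_avg, ravg) -
      abs(lcount - rcount) - min(max_avg, abs(lavg - ravg)) -
      (lgap + rgap) - (lder + rder) * max_avg +
      rate * min(1000, dist))
}

#' Rank fusion reports
#'
#' Sorts descending by score; ties break by total support (spanning +
#' pairs, descending) and then by breakpoint coordinates so the order is
#' reproducible.
#'
#' @param reports data.frame with at least `score`, `spanning_reads`,
#'   `supporting_pairs`, `chrom_left`, `pos_left`, `chrom_right`,
#'   `pos_right` columns.
#' @return The data.frame sorted.
#' @export
rank_fusions <- function(reports) {
  if (nrow(reports) == 0L) return(reports)
  ord <- order(-reports$score,
               -(reports$spanning_reads + reports$supporting_pairs),
               reports$chrom_left, reports$pos_left,
               reports$chrom_right, reports$pos_right)
  reports[ord, , drop = FALSE]
}
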