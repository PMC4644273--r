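#' Sliding-window quality trimming
#'
#' Trims a read with the sliding-window rule used for short paired-end data:
#' a window of `max(1, round(window_frac * length))` bases (half-values
#' rounded away from zero) slides 5' to 3';
#' everything before the first window whose mean quality reaches
#' `q_threshold` is removed, as is everything from the start of the first
#' subsequent window whose mean quality falls below it.  Reads shorter than
#' `min_length` after trimming are discarded.
#'
#' @param read a single-row read data frame (or list) with `sequence` and
#'   `quality`.
#' @param q_threshold Phred threshold (default 20).
#' @param window_frac window size as a fraction of read length (default 0.1).
#' @param min_length minimum kept length in bp (default 20).
#' @return the trimmed read (same shape), or `NULL` if discarded.
#' @export
trim_read <- function(read, q_threshold = 20, window_frac = 0.1,
                      min_length = 20) {
  stopifnot(window_frac > 0, window_frac <= 1, q_threshold >= 0)
  b <- cpp_trim_bounds(read$quality, q_threshold, window_frac)
  if (b[1, 1] == 0L || (b[1, 2] - b[1, 1] + 1L) < min_length) return(NULL)
  read$sequence <- substr(read$sequence, b[1, 1], b[1, 2])
  read$quality <- substr(read$quality, b[1, 1], b[1, 2])
  read
}

# vectorised trimming over a read data frame; returns df + keep flag
trim_table <- function(reads, q_threshold, window_frac, min_length) {
  if (nrow(reads) == 0L) return(cbind(reads, keep = logical(0)))
  b <- cpp_trim_bounds(reads$quality, q_threshold, window_frac)
  keep <- b[, 1] > 0L & (b[, 2] - b[, 1] + 1L) >= min_length
  reads$sequence[keep] <- substr(reads$sequence[keep], b[keep, 1], b[keep, 2])
  reads$quality[keep] <- substr(reads$quality[keep], b[keep, 1], b[keep, 2])
  reads$keep <- keep
  reads
}

#' Trim paired-end reads
#'
#' Applies [trim_read()] to both mates of each pair.  Pairs where both mates
#' survive are kept as pairs; pairs where exactly one survives contribute a
#' single-end read; pairs where neither survives are discarded.
#'
#' @param r1_reads,r2_reads read data frames aligned by row (mate 1 / mate 2).
#' @param q_threshold,window_frac,min_length trimming parameters, see
#'   [trim_read()].
#' @return a `TrimResult`: list with `kept_r1`, `kept_r2` (aligned data
#'   frames), `kept_singles`, and `discarded_count`.
#' @export
trim_pairs <- function(r1_reads, r2_reads, q_threshold = 20,
                       window_frac = 0.1, min_length = 20) {
  if (nrow(r1_reads) != nrow(r2_reads)) {
    stop("r1 and r2 read sets differ in length (",
         nrow(r1_reads), " vs ", nrow(r2_reads), ")")
  }
  t1 <- trim_table(r1_reads, q_threshold, window_frac, min_length)
  t2 <- trim_table(r2_reads, q_threshold, window_frac, min_length)
  both <- t1$keep & t2$keep
  only1 <- t1$keep & !t2$keep
  only2 <- !t1$keep & t2$keep
  neither <- !t1$keep & !t2$keep
  singles <- rbind(t1[only1, , drop = FALSE], t2[only2, , drop = FALSE])
  if (nrow(singles)) singles$mate_id <- NA_character_
  res <- list(
    kept_r1 = t1[both, setdiff(names(t1), "keep"), drop = FALSE],
    kept_r2 = t2[both, setdiff(names(t2), "keep"), drop = FALSE],
    kept_singles = singles[, setdiff(names(singles), "keep"), drop = FALSE],
    discarded_count = 2L * sum(neither) + sum(only1) + sum(only2)
  )
  rownames(res$kept_r1) <- rownames(res$kept_r2) <-
    rownames(res$kept_singles) <- NULL
  class(res) <- "TrimResult"
  res
}

#' @export
print.TrimResult <- function(x, ...) {
  cat("TrimResult:", nrow(x$kept_r1), "pairs,", nrow(x$kept_singles),
      "singles,", x$discarded_count, "reads discarded\n")
  invisible(x)
}
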