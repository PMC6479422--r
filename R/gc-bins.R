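# GC-binned expected depth: partition the chromosome into non-overlapping
# 250-bp windows, record each window's GC fraction and median depth, and
# serve the median of GC-matched window medians as the DHBFC denominator.

#' GC fraction of a nucleotide sequence
#'
#' Computed over non-N bases: (#G + #C) / (# non-N). Returns `NA` when every
#' base is N (an all-ambiguous window carries no GC information).
#'
#' @param sequence Character scalar or a [Biostrings::DNAString] /
#'   `DNAStringSet` of length 1. Case-insensitive.
#' @return Fraction in `[0, 1]`, or `NA_real_` for an all-N sequence.
#' @examples
#' gc_fraction("ACGTN") # 0.5
#' @export
gc_fraction <- function(sequence) {
  if (is.character(sequence)) {
    stopifnot(length(sequence) == 1L)
    if (is.na(sequence) || nchar(sequence) == 0L) {
      stop("`sequence` must be non-empty", call. = FALSE)
    }
    sequence <- Biostrings::DNAString(toupper(sequence))
  } else if (methods::is(sequence, "DNAStringSet")) {
    stopifnot(length(sequence) == 1L)
    sequence <- sequence[[1L]]
  }
  n <- length(sequence)
  if (n == 0L) stop("`sequence` must be non-empty", call. = FALSE)
  counts <- Biostrings::letterFrequency(sequence, c("G", "C", "N"))
  non_n <- n - counts[["N"]]
  if (non_n == 0L) return(NA_real_)
  (counts[["G"]] + counts[["C"]]) / non_n
}

gc_bin_index <- function(gc, bin_width) {
  n_bins <- floor(1 / bin_width) + 1L
  # epsilon guards against 0.6 / 0.05 = 11.999... under binary floats
  pmin(floor(gc / bin_width + 1e-9), n_bins - 1L)
}

#' Build the GC/depth window table for one chromosome
#'
#' Tiles the chromosome with non-overlapping windows (trailing partial window
#' dropped), computes each window's GC fraction and median depth, and bins
#' windows by GC at `bin_width` resolution. Windows with more than
#' `max_n_frac` ambiguous (N) bases are excluded.
#'
#' @param reference Chromosome sequence (character, `DNAString`, or a
#'   `DNAStringSet` of length 1); length must equal the profile length.
#' @param profile A finalized [depth_profile()].
#' @param window_size Bases per window (default 250).
#' @param bin_width GC-fraction bin resolution (default 0.05).
#' @param max_n_frac Maximum tolerated fraction of N bases per window.
#' @return An object of class `gc_depth_table`.
#' @export
build_gc_table <- function(reference, profile, window_size = 250L,
                           bin_width = 0.05, max_n_frac = 0.10) {
  stopifnot(inherits(profile, "depth_profile"), profile$finalized,
            window_size > 0, bin_width > 0, bin_width <= 1)
  if (is.character(reference)) {
    reference <- Biostrings::DNAString(toupper(reference))
  } else if (methods::is(reference, "DNAStringSet")) {
    reference <- reference[[1L]]
  }
  if (length(reference) != profile$length) {
    stop("reference length does not match depth profile length", call. = FALSE)
  }
  n_win <- floor(profile$length / window_size)
  if (n_win == 0L) {
    windows <- tibble::tibble(
      window = integer(0), start = numeric(0), gc = numeric(0),
      bin = integer(0), depth = numeric(0)
    )
  } else {
    starts0 <- (seq_len(n_win) - 1L) * window_size
    views <- Biostrings::Views(
      reference,
      IRanges::IRanges(start = starts0 + 1L, width = window_size)
    )
    counts <- Biostrings::letterFrequency(views, c("G", "C", "N"))
    non_n <- window_size - counts[, "N"]
    gc <- ifelse(non_n > 0, (counts[, "G"] + counts[, "C"]) / non_n, NA_real_)
    depth <- vapply(starts0, function(s) {
      median_depth(profile, s, s + window_size)
    }, numeric(1))
    keep <- counts[, "N"] <= max_n_frac * window_size & !is.na(gc)
    gc_kept <- gc[keep]
    windows <- tibble::tibble(
      window = seq_len(n_win)[keep],
      start = starts0[keep],
      gc = gc_kept,
      bin = as.integer(gc_bin_index(gc_kept, bin_width)),
      depth = depth[keep]
    )
  }
  structure(
    list(
      chrom = profile$chrom,
      window_size = as.integer(window_size),
      bin_width = bin_width,
      n_bins = as.integer(floor(1 / bin_width) + 1L),
      windows = windows,
      n_windows_used = nrow(windows)
    ),
    class = "gc_depth_table"
  )
}

#' @export
print.gc_depth_table <- function(x, ...) {
  cat(sprintf(
    "<gc_depth_table> %s: %d window(s) of %d bp in %d occupied GC bin(s) (bin width %.2f)\n",
    x$chrom, x$n_windows_used, x$window_size,
    length(unique(x$windows$bin)), x$bin_width
  ))
  invisible(x)
}

#' Expected depth for a given GC fraction
#'
#' Returns the (lower) median of the member-window median depths in the GC
#' bin containing `gc`. A bin with fewer than `min_windows` members is not
#' trusted on its own: the nearest bin with at least `min_windows` members is
#' used instead (ties broken toward lower GC); if no bin reaches the minimum,
#' the nearest occupied bin is used. `NA` when the table is empty.
#'
#' @param table A [build_gc_table()] result.
#' @param gc GC fraction in `[0, 1]`.
#' @param min_windows Minimum bin occupancy for a direct answer.
#' @return Non-negative number, or `NA_real_` for an empty table.
#' @export
expected_depth_for_gc <- function(table, gc, min_windows = 5L) {
  stopifnot(inherits(table, "gc_depth_table"))
  if (!is.numeric(gc) || length(gc) != 1L || is.na(gc) || gc < 0 || gc > 1) {
    stop("`gc` must be a single value in [0, 1]", call. = FALSE)
  }
  w <- table$windows
  if (nrow(w) == 0L) return(NA_real_)
  target <- gc_bin_index(gc, table$bin_width)
  counts <- tabulate(w$bin + 1L, nbins = table$n_bins)
  bins <- 0:(table$n_bins - 1L)
  eligible <- bins[counts >= min_windows]
  if (length(eligible) == 0L) eligible <- bins[counts > 0L]
  d <- abs(eligible - target)
  chosen <- min(eligible[d == min(d)]) # tie toward lower GC
  lower_median(w$depth[w$bin == chosen])
}
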