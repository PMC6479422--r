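# The two fold-change statistics attached to each SV call:
#   DHFFC -- median event depth / median depth of the pooled 1,000-bp flanks
#   DHBFC -- median event depth / median depth of GC-matched 250-bp windows
# Both use medians so the values stay robust to inexact breakpoints.

SPANNING_SVTYPES <- c("DEL", "DUP", "INV", "CNV")

#' Normalize a VCF record to its 0-based half-open affected interval
#'
#' For symbolic alleles with `END = e` the affected bases are `POS+1 .. e`
#' (1-based): the VCF padding base at POS is excluded, giving the 0-based
#' half-open interval `[POS, e)`. When END is absent but SVLEN is present,
#' `end = POS + |SVLEN|`. For sequence-resolved deletions the span comes
#' from the REF allele: `[POS, POS + nchar(REF) - 1)`.
#'
#' @param pos_1based VCF POS (1-based position of the padding base).
#' @param end VCF INFO END (1-based inclusive), or `NA`.
#' @param svlen VCF INFO SVLEN (signed), or `NA`.
#' @param ref REF allele string (used for sequence-resolved records), or `NA`.
#' @return Named numeric vector `c(start, end)` (0-based half-open), or
#'   `NULL` with a warning when no valid interval can be formed.
#' @export
event_interval <- function(pos_1based, end = NA, svlen = NA, ref = NA) {
  stopifnot(is.numeric(pos_1based), length(pos_1based) == 1L, pos_1based >= 1)
  start0 <- pos_1based
  end0 <- if (!is.na(end)) {
    as.numeric(end)
  } else if (!is.na(svlen) && svlen != 0) {
    pos_1based + abs(as.numeric(svlen))
  } else if (!is.na(ref) && nchar(ref) > 1L) {
    pos_1based + nchar(ref) - 1
  } else {
    warning(sprintf(
      "record at POS %s has neither END, SVLEN, nor a multi-base REF; annotation skipped",
      format(pos_1based)
    ), call. = FALSE)
    return(NULL)
  }
  if (end0 <= start0) {
    warning(sprintf(
      "record at POS %s has end (%s) <= start (%s); annotation skipped",
      format(pos_1based), format(end0), format(start0)
    ), call. = FALSE)
    return(NULL)
  }
  c(start = start0, end = end0)
}

#' Flank fold-change (DHFFC) for one event interval
#'
#' Median depth over the event divided by the median depth of the flanking
#' bases: `flank` bases on either side of the event, clamped to the
#' chromosome, pooled into one multiset before the median is taken.
#' Zero-depth flank bases are included. `NA` when the pooled flank is empty
#' or its median depth is 0.
#'
#' @param profile A finalized [depth_profile()].
#' @param start,end 0-based half-open event interval.
#' @param flank Flank width in bases (default 1000).
#' @return Non-negative ratio, or `NA_real_`.
#' @export
dhffc <- function(profile, start, end, flank = 1000L) {
  stopifnot(inherits(profile, "depth_profile"), profile$finalized, flank > 0)
  L <- profile$length
  start <- max(0, start)
  end <- min(L, end)
  if (end <= start) return(NA_real_)
  event_med <- median_depth(profile, start, end)
  lf <- c(max(0, start - flank), start)
  rf <- c(end, min(L, end + flank))
  pooled <- c(
    if (lf[2] > lf[1]) profile$values[(lf[1] + 1):lf[2]] else numeric(0),
    if (rf[2] > rf[1]) profile$values[(rf[1] + 1):rf[2]] else numeric(0)
  )
  if (length(pooled) == 0L) return(NA_real_)
  flank_med <- lower_median(pooled)
  if (flank_med == 0) return(NA_real_)
  event_med / flank_med
}

#' GC-bin fold-change (DHBFC) for one event interval
#'
#' Median depth over the event divided by the expected depth for the event's
#' own GC content, where the expectation is the median depth of same-GC
#' 250-bp reference windows (see [build_gc_table()]). GC is computed over
#' the event's reference sequence itself. `NA` when the event sequence is
#' all N or the expected depth is 0/unavailable.
#'
#' @param profile A finalized [depth_profile()].
#' @param table A [build_gc_table()] result for the same chromosome.
#' @param reference Chromosome sequence (character, `DNAString`, or a
#'   `DNAStringSet` of length 1).
#' @param start,end 0-based half-open event interval.
#' @return Non-negative ratio, or `NA_real_`.
#' @export
dhbfc <- function(profile, table, reference, start, end) {
  stopifnot(inherits(profile, "depth_profile"), profile$finalized,
            inherits(table, "gc_depth_table"))
  if (is.character(reference)) {
    reference <- Biostrings::DNAString(toupper(reference))
  } else if (methods::is(reference, "DNAStringSet")) {
    reference <- reference[[1L]]
  }
  L <- profile$length
  start <- max(0, start)
  end <- min(L, end)
  if (end <= start) return(NA_real_)
  gc <- gc_fraction(Biostrings::subseq(reference, start + 1L, end))
  if (is.na(gc)) return(NA_real_)
  expected <- expected_depth_for_gc(table, gc)
  if (is.na(expected) || expected == 0) return(NA_real_)
  median_depth(profile, start, end) / expected
}

#' Annotate a table of SV records with DHBFC and DHFFC
#'
#' Takes a per-record tibble (one row per VCF record) and returns it with
#' `dhbfc` and `dhffc` columns added. Records whose type has no meaningful
#' genomic span (BND; INS without a usable END) get `NA` for both. Inversions
#' are copy-neutral; they are annotated by default (the statistics are still
#' informative for flagging misclassified CNVs) but can be skipped.
#'
#' @param records Data frame with columns `pos` (1-based VCF POS) and
#'   `svtype`, plus optional `end`, `svlen`, `ref`.
#' @param profile A finalized [depth_profile()].
#' @param table A [build_gc_table()] result.
#' @param reference Chromosome sequence.
#' @param flank Flank width for DHFFC.
#' @param annotate_inversions Compute fold-changes for INV records?
#' @return The input as a tibble with `dhbfc` and `dhffc` columns.
#' @export
annotate_sv <- function(records, profile, table, reference, flank = 1000L,
                        annotate_inversions = TRUE) {
  records <- tibble::as_tibble(records)
  stopifnot(all(c("pos", "svtype") %in% names(records)))
  if (is.character(reference)) {
    reference <- Biostrings::DNAString(toupper(reference))
  } else if (methods::is(reference, "DNAStringSet")) {
    reference <- reference[[1L]]
  }
  n <- nrow(records)
  get_col <- function(nm) if (nm %in% names(records)) records[[nm]] else rep(NA, n)
  end_col <- get_col("end")
  svlen_col <- get_col("svlen")
  ref_col <- get_col("ref")
  spanning <- SPANNING_SVTYPES
  if (!annotate_inversions) spanning <- setdiff(spanning, "INV")

  out_b <- rep(NA_real_, n)
  out_f <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!records$svtype[i] %in% spanning) next
    iv <- event_interval(records$pos[i], end_col[i], svlen_col[i], ref_col[i])
    if (is.null(iv)) next
    out_f[i] <- dhffc(profile, iv["start"], iv["end"], flank = flank)
    out_b[i] <- dhbfc(profile, table, reference, iv["start"], iv["end"])
  }
  records$dhbfc <- out_b
  records$dhffc <- out_f
  records
}
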