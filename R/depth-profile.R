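# Per-base depth via a difference array: +1 where a covering segment starts,
# -1 one past where it ends, then a cumulative sum. Querying any interval is
# then independent of how many alignments were ingested.

DEPTH_CAP <- 32767L

#' Create an empty per-base depth profile for one chromosome
#'
#' The profile starts in "increment" state: it accumulates +1/-1 markers as
#' alignments are ingested with [ingest_alignments()], and becomes a per-base
#' coverage array only after [finalize_depth()] runs the cumulative sum.
#' Stored depths are capped at the 16-bit maximum (32,767); the running sum
#' itself is tracked at double precision so the cap never corrupts
#' neighbouring positions.
#'
#' @param chrom Chromosome name.
#' @param length Chromosome length in bases (positive integer).
#' @return An object of class `depth_profile`.
#' @examples
#' p <- depth_profile("chr1", 10)
#' @export
depth_profile <- function(chrom, length) {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  if (!is.numeric(length) || length(length) != 1L || is.na(length) ||
      length < 1 || length != floor(length)) {
    stop("`length` must be a positive integer", call. = FALSE)
  }
  structure(
    list(
      chrom = chrom,
      length = as.numeric(length),
      values = numeric(length),
      finalized = FALSE,
      n_segments = 0L
    ),
    class = "depth_profile"
  )
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf(
    "<depth_profile> %s (%s bp), %s, %d covering segment(s)\n",
    x$chrom, format(x$length, big.mark = ","),
    if (x$finalized) "finalized" else "not finalized", x$n_segments
  ))
  invisible(x)
}

# SAM flag bits used by the default alignment filter
FLAG_UNMAPPED <- 0x4L
FLAG_SECONDARY <- 0x100L
FLAG_QCFAIL <- 0x200L
FLAG_DUPLICATE <- 0x400L

#' Split a CIGAR string into reference-covering runs
#'
#' M, `=` and X consume reference and contribute coverage; D and N consume
#' reference but contribute none, splitting the read into separate covering
#' segments (D can be counted as covered via `count_deletions`); I, S, H and
#' P consume no reference at all.
#'
#' @param ref_start 0-based leftmost reference position of the alignment.
#' @param cigar CIGAR string, e.g. `"50M10D50M"`.
#' @param count_deletions Count deletion (D) bases as covered?
#' @return Two-column matrix of 0-based half-open `[start, end)` runs.
#' @keywords internal
cigar_covered_runs <- function(ref_start, cigar, count_deletions = FALSE) {
  if (is.na(cigar) || cigar == "*" || !grepl("^([0-9]+[MIDNSHP=X])+$", cigar)) {
    stop(sprintf("malformed CIGAR string: %s", cigar), call. = FALSE)
  }
  lens <- as.numeric(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  if (any(lens <= 0)) stop("CIGAR operation with non-positive length", call. = FALSE)

  covering <- ops %in% c("M", "=", "X") | (count_deletions & ops == "D")
  consumes <- ops %in% c("M", "=", "X", "D", "N")

  starts <- numeric(0)
  ends <- numeric(0)
  pos <- ref_start
  open_at <- NA_real_
  for (i in seq_along(ops)) {
    if (covering[i]) {
      if (is.na(open_at)) open_at <- pos
      pos <- pos + lens[i]
    } else if (consumes[i]) {
      if (!is.na(open_at)) {
        starts <- c(starts, open_at); ends <- c(ends, pos)
        open_at <- NA_real_
      }
      pos <- pos + lens[i]
    }
    # I, S, H, P: neither consume reference nor break the covering run
  }
  if (!is.na(open_at)) {
    starts <- c(starts, open_at); ends <- c(ends, pos)
  }
  cbind(start = starts, end = ends)
}

#' Ingest aligned segments into a depth profile
#'
#' Records +1 at the start and -1 one past the end of every maximal
#' reference-covering run of each alignment. Alignments that are unmapped,
#' secondary, duplicate, or QC-fail are skipped; supplementary alignments are
#' kept (split reads legitimately contribute depth). No mapping-quality floor
#' is applied unless `min_mapq` is raised.
#'
#' @param profile A non-finalized [depth_profile()].
#' @param segments Data frame with columns `ref_start` (0-based), `cigar`,
#'   and optionally `chrom`, `flag` (SAM bitfield, default 0) and `mapq`.
#' @param count_deletions Count deletion (D) CIGAR bases as covered.
#' @param min_mapq Skip alignments with mapping quality below this.
#' @return The updated profile.
#' @export
ingest_alignments <- function(profile, segments, count_deletions = FALSE,
                              min_mapq = 0L) {
  stopifnot(inherits(profile, "depth_profile"))
  if (profile$finalized) {
    stop("cannot ingest into a finalized depth profile", call. = FALSE)
  }
  segments <- as.data.frame(segments)
  if (nrow(segments) == 0L) return(profile)
  stopifnot(all(c("ref_start", "cigar") %in% names(segments)))
  if ("chrom" %in% names(segments) &&
      !all(segments$chrom == profile$chrom)) {
    stop("segment chromosome does not match profile chromosome", call. = FALSE)
  }
  if (any(segments$ref_start < 0)) {
    stop("`ref_start` must be >= 0", call. = FALSE)
  }
  flag <- if ("flag" %in% names(segments)) segments$flag else rep(0L, nrow(segments))
  mapq <- if ("mapq" %in% names(segments)) segments$mapq else rep(255L, nrow(segments))
  skip_mask <- FLAG_UNMAPPED + FLAG_SECONDARY + FLAG_QCFAIL + FLAG_DUPLICATE
  keep <- bitwAnd(as.integer(flag), skip_mask) == 0L &
    (is.na(mapq) | mapq >= min_mapq)
  segments <- segments[keep, , drop = FALSE]
  if (nrow(segments) == 0L) return(profile)

  L <- profile$length
  # fast path: plain all-M CIGARs (the overwhelmingly common case)
  plain <- grepl("^[0-9]+M$", segments$cigar)
  starts <- numeric(0)
  ends <- numeric(0)
  if (any(plain)) {
    s <- segments$ref_start[plain]
    e <- s + as.numeric(sub("M$", "", segments$cigar[plain]))
    starts <- s
    ends <- e
  }
  if (any(!plain)) {
    other <- segments[!plain, , drop = FALSE]
    runs <- lapply(seq_len(nrow(other)), function(i) {
      cigar_covered_runs(other$ref_start[i], other$cigar[i], count_deletions)
    })
    runs <- do.call(rbind, runs)
    if (!is.null(runs) && nrow(runs) > 0L) {
      starts <- c(starts, runs[, "start"])
      ends <- c(ends, runs[, "end"])
    }
  }
  if (length(starts) == 0L) return(profile)

  if (any(ends > L) || any(starts < 0)) {
    warning(sprintf(
      "%d covering run(s) extend beyond '%s' [0, %d); clamped",
      sum(ends > L | starts < 0), profile$chrom, L
    ), call. = FALSE)
    starts <- pmax(starts, 0)
    ends <- pmin(ends, L)
  }
  ok <- ends > starts
  starts <- starts[ok]
  ends <- ends[ok]

  # diff-array update: +1 at run start, -1 one past run end (dropped when the
  # run touches the chromosome end -- nothing lies beyond the array)
  inc <- tabulate(as.integer(starts) + 1L, nbins = L)
  dec <- tabulate(as.integer(ends[ends < L]) + 1L, nbins = L)
  profile$values <- profile$values + inc - dec
  profile$n_segments <- profile$n_segments + length(starts)
  profile
}

#' Finalize a depth profile (cumulative sum and 16-bit cap)
#'
#' Replaces the increment array with its running cumulative sum, yielding the
#' per-base coverage. The running sum is kept at full precision; each stored
#' value is capped at 32,767. Finalizing twice is an error.
#'
#' @param profile A non-finalized [depth_profile()].
#' @return The finalized profile.
#' @export
finalize_depth <- function(profile) {
  stopifnot(inherits(profile, "depth_profile"))
  if (profile$finalized) {
    stop("depth profile is already finalized", call. = FALSE)
  }
  profile$values <- pmin(cumsum(profile$values), DEPTH_CAP)
  profile$finalized <- TRUE
  profile
}

# Lower median: element at index (n - 1) %/% 2 of the sorted vector
# (0-based), so even-length intervals yield an observed, integral value.
lower_median <- function(x) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sort(x, method = "quick")[(n - 1L) %/% 2L + 1L]
}

#' Median depth over an interval of a finalized profile
#'
#' Uses the lower-median convention: for even-length intervals the lower of
#' the two middle values, keeping the result integral and deterministic.
#'
#' @param profile A finalized [depth_profile()].
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end.
#' @return Non-negative number.
#' @export
median_depth <- function(profile, start, end) {
  stopifnot(inherits(profile, "depth_profile"))
  if (!profile$finalized) {
    stop("depth profile must be finalized before querying", call. = FALSE)
  }
  if (!is.numeric(start) || !is.numeric(end) || is.na(start) || is.na(end) ||
      start < 0 || end > profile$length || start >= end) {
    stop("invalid interval: need 0 <= start < end <= length", call. = FALSE)
  }
  lower_median(profile$values[(start + 1):end])
}

#' Build a finalized depth profile for one chromosome from a BAM/CRAM file
#'
#' Streams the alignments overlapping the chromosome from an indexed BAM (or
#' CRAM, given `reference`) and returns the finalized per-base profile.
#'
#' @param bam Path to an indexed BAM/CRAM file.
#' @param chrom Chromosome name (must be in the alignment header).
#' @param reference Optional reference FASTA path (required for CRAM).
#' @inheritParams ingest_alignments
#' @return A finalized [depth_profile()].
#' @export
depth_profile_from_bam <- function(bam, chrom, reference = NULL,
                                   count_deletions = FALSE, min_mapq = 0L) {
  targets <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (!chrom %in% names(targets)) {
    stop(sprintf("chromosome '%s' not present in '%s'", chrom, bam),
         call. = FALSE)
  }
  len <- unname(targets[[chrom]])
  if (!is.null(reference) && !file.exists(paste0(reference, ".fai"))) {
    Rsamtools::indexFa(reference)
  }
  bf <- Rsamtools::BamFile(bam)
  param <- Rsamtools::ScanBamParam(
    what = c("pos", "cigar", "flag", "mapq"),
    flag = Rsamtools::scanBamFlag(
      isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
      isDuplicate = FALSE, isNotPassingQualityControls = FALSE
    ),
    which = GenomicRanges::GRanges(chrom, IRanges::IRanges(1L, len))
  )
  res <- Rsamtools::scanBam(bf, param = param)[[1]]
  prof <- depth_profile(chrom, len)
  if (length(res$pos) > 0L) {
    prof <- ingest_alignments(
      prof,
      data.frame(
        ref_start = res$pos - 1L, cigar = res$cigar,
        flag = res$flag, mapq = res$mapq
      ),
      count_deletions = count_deletions, min_mapq = min_mapq
    )
  }
  finalize_depth(prof)
}
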