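# Event interval normalization and the two fold-change statistics.

flat_profile <- function(len, depth) {
  p <- depth_profile("c", len)
  if (depth > 0) {
    p <- ingest_alignments(p, data.frame(
      ref_start = rep(0L, depth), cigar = sprintf("%dM", len)
    ))
  }
  finalize_depth(p)
}

# profile with a depth plateau `inside` on [start, end), `outside` elsewhere
plateau_profile <- function(len, start, end, outside, inside) {
  p <- depth_profile("c", len)
  segs <- data.frame(ref_start = integer(0), cigar = character(0))
  add <- function(s, e, d) {
    if (d > 0 && e > s) {
      data.frame(ref_start = rep(as.integer(s), d),
                 cigar = sprintf("%dM", as.integer(e - s)))
    } else NULL
  }
  segs <- do.call(rbind, list(
    add(0, start, outside), add(start, end, inside), add(end, len, outside)
  ))
  if (!is.null(segs)) p <- ingest_alignments(p, segs)
  finalize_depth(p)
}

test_that("event_interval applies the VCF coordinate conventions", {
  expect_equal(event_interval(1000, end = 2000),
               c(start = 1000, end = 2000))
  expect_equal(event_interval(500, svlen = -250),
               c(start = 500, end = 750))
  expect_equal(event_interval(500, svlen = 250),
               c(start = 500, end = 750))
  # END wins over SVLEN
  expect_equal(event_interval(100, end = 300, svlen = -50),
               c(start = 100, end = 300))
  # sequence-resolved deletion: span from REF allele minus the padding base
  expect_equal(event_interval(500, ref = paste(rep("A", 101), collapse = "")),
               c(start = 500, end = 600))
  expect_warning(iv <- event_interval(500, end = 400), "skipped")
  expect_null(iv)
  expect_warning(iv2 <- event_interval(500), "skipped")
  expect_null(iv2)
})

test_that("dhffc is the event median over the pooled flank median", {
  # uniform depth -> identity
  p <- flat_profile(10000, 30)
  expect_equal(dhffc(p, 4000, 6000), 1.0)
  # half-depth event -> 0.5
  ph <- plateau_profile(10000, 4000, 6000, outside = 30, inside = 15)
  expect_equal(dhffc(ph, 4000, 6000), 0.5)
  # zero-depth flanks -> missing
  p0 <- plateau_profile(10000, 4000, 6000, outside = 0, inside = 15)
  expect_true(is.na(dhffc(p0, 4000, 6000)))
  # event at position 0: left flank empty, right flank alone is the denominator
  pl <- plateau_profile(10000, 0, 2000, outside = 40, inside = 10)
  expect_equal(dhffc(pl, 0, 2000), 0.25)
})

test_that("dhffc flanks pool into one multiset before the median", {
  # left flank deep (40), right flank shallow (10): pooled lower median is 10,
  # not the mean of per-side medians
  p <- depth_profile("c", 6000)
  p <- ingest_alignments(p, data.frame(
    ref_start = c(rep(0L, 40), rep(2000L, 30), rep(3000L, 10)),
    cigar = c(rep("2000M", 40), rep("1000M", 30), rep("3000M", 10))
  ))
  p <- finalize_depth(p)
  # event [2000, 3000) has depth 30; flanks: [1000,2000) at 40, [3000,4000) at 10
  # pooled lower median is 10 (averaging per-side medians would give 25)
  expect_equal(dhffc(p, 2000, 3000, flank = 1000), 30 / 10)
})

test_that("dhffc is scale-invariant and local", {
  base <- plateau_profile(8000, 3000, 5000, outside = 20, inside = 10)
  scaled <- plateau_profile(8000, 3000, 5000, outside = 60, inside = 30)
  expect_equal(dhffc(base, 3000, 5000), dhffc(scaled, 3000, 5000))
  # depths outside [start - flank, end + flank) are irrelevant
  spiked <- ingest_alignments(
    depth_profile("c", 8000),
    data.frame(ref_start = c(rep(0L, 20), rep(3000L, 10), rep(5000L, 20),
                             rep(7500L, 500)),
               cigar = c(rep("3000M", 20), rep("2000M", 10), rep("3000M", 20),
                         rep("100M", 500)))
  )
  spiked <- finalize_depth(spiked)
  expect_equal(dhffc(spiked, 3000, 5000, flank = 1000),
               dhffc(base, 3000, 5000, flank = 1000))
})

test_that("dhbfc compares the event to GC-matched windows", {
  # uniform GC, uniform depth -> 1.0
  len <- 20000L
  ref <- paste(rep("ACGT", len / 4), collapse = "")
  p <- flat_profile(len, 30)
  tab <- build_gc_table(ref, p)
  expect_equal(dhbfc(p, tab, ref, 8000, 12000), 1.0)
  # in-event depth 45 vs expected 30 -> 1.5
  p2 <- plateau_profile(len, 8000, 12000, outside = 30, inside = 45)
  tab2 <- build_gc_table(ref, p2)
  # most windows sit at 30, so the GC-matched expectation stays 30
  expect_equal(dhbfc(p2, tab2, ref, 8000, 12000), 1.5)
})

test_that("dhbfc uses the event's own GC to pick the comparison stratum", {
  # two GC strata at different depths; hand-built oracle table
  at <- paste(rep(c("A", "T"), 2500), collapse = "") # 5 kb, GC 0
  gc <- paste(rep(c("G", "C"), 2500), collapse = "") # 5 kb, GC 1
  ref <- paste0(at, gc)
  p <- depth_profile("c", 10000)
  p <- ingest_alignments(p, data.frame(
    ref_start = c(rep(0L, 20), rep(5000L, 44)),
    cigar = "5000M"
  ))
  p <- finalize_depth(p)
  tab <- build_gc_table(ref, p)
  # oracle: AT windows (bin 0) all sit at depth 20, GC windows (bin 20) at 44
  expect_equal(expected_depth_for_gc(tab, 0), 20)
  expect_equal(expected_depth_for_gc(tab, 1), 44)
  # an event inside the high-GC stratum is judged against the high-GC bin
  expect_equal(dhbfc(p, tab, ref, 6000, 8000), 1.0)
  # same depths, but an event in the AT stratum with depth 44 would be 2.2
  p2 <- plateau_profile(10000, 1000, 3000, outside = 20, inside = 44)
  tab2 <- build_gc_table(at_ref <- paste0(at, at), p2)
  expect_equal(dhbfc(p2, tab2, at_ref, 1000, 3000), 2.2)
})

test_that("annotate_sv fills both statistics and skips spanless records", {
  len <- 20000L
  ref <- paste(rep("ACGT", len / 4), collapse = "")
  p <- plateau_profile(len, 8000, 10000, outside = 30, inside = 15)
  tab <- build_gc_table(ref, p)
  recs <- tibble::tibble(
    pos = c(8000, 5000, 5000, 2000),
    svtype = c("DEL", "BND", "INS", "DUP"),
    end = c(10000, NA, NA, 3000),
    svlen = c(-2000, NA, NA, 1000)
  )
  ann <- annotate_sv(recs, p, tab, ref)
  expect_equal(ann$dhffc[1], 0.5)
  expect_equal(ann$dhbfc[1], 0.5)
  expect_true(all(is.na(ann$dhbfc[2:3])))
  expect_true(all(is.na(ann$dhffc[2:3])))
  expect_equal(ann$dhffc[4], 1.0) # no depth change at this DUP call
  # inversions configurable
  inv <- tibble::tibble(pos = 8000, svtype = "INV", end = 10000, svlen = NA)
  expect_equal(annotate_sv(inv, p, tab, ref)$dhffc, 0.5)
  expect_true(is.na(
    annotate_sv(inv, p, tab, ref, annotate_inversions = FALSE)$dhffc
  ))
})

test_that("median statistics tolerate breakpoint jitter on long events", {
  p <- plateau_profile(20000, 8000, 12000, outside = 30, inside = 15)
  exact <- dhffc(p, 8000, 12000)
  for (shift in c(-10, 10)) {
    expect_equal(dhffc(p, 8000 + shift, 12000 + shift), exact)
  }
})
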