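# The synthetic fixture generator: reference composition, coverage layout,
# event plateaus, null-variant placement, and on-disk consistency.

test_that("fixture specs validate their geometry", {
  expect_s3_class(fixture_spec(), "fixture_spec")
  expect_error(fixture_spec(gc_strata = data.frame(start = 0, end = 100000,
                                                   gc = 1.2)), "infeasible")
  expect_error(fixture_spec(gc_strata = data.frame(start = 0, end = 5000,
                                                   gc = 0.5)), "partition")
  expect_error(fixture_spec(events = data.frame(
    svtype = "DEL", genotype = "0/1", start = 100, end = 1100
  )), "flank_margin")
  expect_error(fixture_spec(events = data.frame(
    svtype = c("DEL", "DEL"), genotype = "0/1",
    start = c(5000, 5500), end = c(6000, 6500)
  )), "overlap")
})

test_that("reference realizes its GC targets and is seed-deterministic", {
  spec <- fixture_spec(length = 100000, seed = 3)
  ref <- make_reference(spec)
  expect_equal(length(ref), 100000)
  gc <- gc_fraction(ref)
  expect_gte(gc, 0.48)
  expect_lte(gc, 0.52)
  expect_identical(as.character(ref), as.character(make_reference(spec)))
  # boundary stratum: all G/C
  spec2 <- fixture_spec(length = 10000, seed = 3, gc_strata = data.frame(
    start = c(0, 5000), end = c(5000, 10000), gc = c(1.0, 0.2)
  ))
  ref2 <- make_reference(spec2)
  expect_equal(gc_fraction(Biostrings::subseq(ref2, 1, 5000)), 1.0)
  expect_equal(gc_fraction(Biostrings::subseq(ref2, 5001, 10000)), 0.2,
               tolerance = 0.02)
})

test_that("tiling layout yields exact depth plateaus for every genotype class", {
  events <- data.frame(
    svtype = c("DEL", "DEL", "DUP", "DUP"),
    genotype = c("0/1", "1/1", "0/1", "1/1"),
    start = c(5000, 12000, 19000, 26000),
    end = c(7000, 14000, 21000, 28000)
  )
  spec <- fixture_spec(length = 35000, events = events, seed = 5)
  aln <- simulate_alignments(spec)
  p <- finalize_depth(ingest_alignments(
    depth_profile(spec$chrom, spec$length), aln
  ))
  # diploid background 30
  expect_equal(median_depth(p, 1000, 4000), 30)
  # event interiors: het DEL 15, hom DEL 0, het DUP 45, hom DUP 60
  expect_equal(unique(p$values[5001:7000]), 15)
  expect_equal(unique(p$values[12001:14000]), 0)
  expect_equal(median_depth(p, 19000, 21000), 45)
  expect_equal(median_depth(p, 26000, 28000), 60)
  # the DUP plateau is exact away from the read-length edge ramp
  expect_equal(unique(p$values[(19000 + 150 + 1):(21000 - 150)]), 45)
})

test_that("poisson layout attains the multipliers in expectation", {
  spec <- fixture_spec(
    length = 40000, layout = "poisson", seed = 17,
    events = data.frame(svtype = "DEL", genotype = "0/1",
                        start = 15000, end = 25000)
  )
  aln <- simulate_alignments(spec)
  p <- finalize_depth(ingest_alignments(
    depth_profile(spec$chrom, spec$length), aln
  ))
  inside <- mean(p$values[15001:25000])
  # mean in-event depth within 3 standard errors of 15 (Poisson counts,
  # ~read_length-correlated: se ~= sqrt(15 * 150 / 10000))
  se <- sqrt(15 * 150 / 10000)
  expect_lt(abs(inside - 15), 3 * se)
  outside <- mean(p$values[2001:12000])
  expect_lt(abs(outside - 30), 3 * sqrt(30 * 150 / 10000))
})

test_that("null variants conserve size/type, respect regions and avoid N", {
  spec <- fixture_spec(length = 60000, seed = 9)
  ref <- as.character(make_reference(spec))
  # poison [30000, 36000) with 50% N
  substr(ref, 30001, 36000) <- paste(
    rep(c("N", "A"), 3000), collapse = ""
  )
  regions <- tibble::tibble(start = c(5000, 28000), end = c(20000, 40000))
  vars <- tibble::tibble(
    svtype = rep(c("DEL", "DUP"), 5),
    start = seq(5000, by = 1000, length.out = 10),
    end = seq(5000, by = 1000, length.out = 10) + 500,
    genotype = rep(c("0/1", "1/1"), 5)
  )
  nulls <- generate_null_variants(vars, regions, ref, seed = 2)
  expect_equal(nrow(nulls), 10)
  expect_true(all(nulls$genotype == "0/0"))
  expect_equal(nulls$svtype, vars$svtype)
  expect_equal(nulls$end - nulls$start, vars$end - vars$start)
  inside_region <- vapply(seq_len(nrow(nulls)), function(i) {
    any(nulls$start[i] >= regions$start & nulls$end[i] <= regions$end)
  }, logical(1))
  expect_true(all(inside_region))
  # recompute N content of each placement
  for (i in seq_len(nrow(nulls))) {
    sub <- substr(ref, nulls$start[i] + 1, nulls$end[i])
    n_frac <- lengths(regmatches(sub, gregexpr("N", sub))) / nchar(sub)
    expect_lte(n_frac, 0.10)
  }
  # a variant longer than every region is infeasible
  too_long <- tibble::tibble(svtype = "DEL", start = 0, end = 25000,
                             genotype = "0/1")
  expect_error(generate_null_variants(too_long, regions, ref), "region")
})

test_that("null placements are uniform over feasible starts", {
  # one region, tiny variant: starts should be uniform across the region
  ref <- paste(rep("ACGT", 5000), collapse = "")
  regions <- tibble::tibble(start = 0, end = 20000)
  vars <- tibble::tibble(svtype = rep("DEL", 400),
                         start = 0, end = 100,
                         genotype = "0/1")
  nulls <- generate_null_variants(vars, regions, ref, seed = 4)
  bins <- cut(nulls$start, breaks = seq(0, 20000, by = 2000))
  gof <- suppressWarnings(stats::chisq.test(table(bins)))
  expect_gt(gof$p.value, 0.001)
})

test_that("written fixtures are consistent and deterministic on disk", {
  spec <- fixture_spec(
    length = 25000, seed = 23,
    events = data.frame(svtype = "DEL", genotype = "0/1",
                        start = 10000, end = 12000)
  )
  d1 <- tempfile("fxa")
  d2 <- tempfile("fxb")
  fx1 <- write_fixture(spec, d1)
  fx2 <- write_fixture(spec, d2)
  expect_true(all(file.exists(fx1$fasta, fx1$fai, fx1$bam, fx1$bai, fx1$vcf)))
  expect_identical(readLines(fx1$fasta), readLines(fx2$fasta))
  expect_identical(readLines(fx1$vcf), readLines(fx2$vcf))
  # BAM round-trips through samtools machinery and matches the simulation
  aln <- simulate_alignments(spec)
  back <- Rsamtools::scanBam(fx1$bam)[[1]]
  expect_equal(length(back$pos), nrow(aln))
  expect_equal(sort(back$pos), sort(aln$pos))
  # end-to-end: annotation of the truth VCF recovers the half-depth signal
  out <- tempfile(fileext = ".vcf")
  res <- annotate_vcf(fx1$vcf, fx1$bam, fx1$fasta, out)
  expect_equal(res$records$dhffc, 0.5)
  expect_equal(res$records$dhbfc, 0.5)
})

test_that("an event-free fixture gives fold-changes of 1 everywhere", {
  spec <- fixture_spec(length = 20000, seed = 31)
  fx <- write_fixture(spec, tempfile("fxnull"))
  p <- depth_profile_from_bam(fx$bam, spec$chrom)
  tab <- build_gc_table(fx$reference, p)
  for (probe_start in c(3000, 9000, 14000)) {
    expect_equal(dhffc(p, probe_start, probe_start + 2000), 1.0)
    expect_equal(dhbfc(p, tab, fx$reference, probe_start, probe_start + 2000),
                 1.0)
  }
})
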