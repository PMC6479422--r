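# Self-contained test inputs: a reference with controlled GC composition,
# alignments tiled (or Poisson-sampled) to a target coverage with depth
# altered inside embedded events, a truth VCF, and matched homozygous-
# reference null events drawn inside high-confidence regions.
#
# Events are realized per haplotype: each of the two haplotypes is covered
# at the haploid depth; a deletion removes the reads overlapping the event
# from the carrier haplotype(s) and a tandem duplication adds a second copy
# of the reads lying wholly inside it. In deterministic-tiling mode this
# yields exact integer depth plateaus (0.5x / 0x / 1.5x / 2x of the diploid
# depth), so the fold-change statistics take exact textbook values.

#' Declarative description of a synthetic fixture
#'
#' Defaults describe the study conditions used throughout the package's
#' tests: a 30x diploid genome (haploid coverage 15 per haplotype) of
#' 150-bp single-end reads on a 50% GC reference, deterministically tiled.
#'
#' @param chrom Chromosome name.
#' @param length Reference length in bases.
#' @param gc_strata Tibble/data frame with columns `start`, `end` (0-based
#'   half-open) and `gc` (target fraction); `NULL` means one 0.5-GC stratum
#'   spanning the chromosome.
#' @param events Tibble/data frame with columns `svtype` (`"DEL"`/`"DUP"`),
#'   `start`, `end` (0-based half-open) and `genotype` (`"0/1"`/`"1/1"`);
#'   may be empty.
#' @param coverage Target haploid coverage per haplotype (diploid depth is
#'   `2 * coverage`).
#' @param read_length Read length in bases.
#' @param layout `"tiling"` (deterministic, exact plateaus) or `"poisson"`
#'   (random starts; multipliers hold in expectation).
#' @param seed Integer seed; every random draw is derived from it.
#' @param flank_margin Bases kept event-free at each chromosome end so that
#'   flanks always fit.
#' @param sample_name Sample name written to the read group and truth VCF.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(chrom = "chrS", length = 100000L, gc_strata = NULL,
                         events = NULL, coverage = 15L, read_length = 150L,
                         layout = c("tiling", "poisson"), seed = 1L,
                         flank_margin = 2000L, sample_name = "sample1") {
  layout <- match.arg(layout)
  stopifnot(length > 0, coverage > 0, read_length > 0,
            read_length <= length, flank_margin >= 0)
  if (is.null(gc_strata)) {
    gc_strata <- tibble::tibble(start = 0, end = as.numeric(length), gc = 0.5)
  }
  gc_strata <- tibble::as_tibble(gc_strata)
  stopifnot(all(c("start", "end", "gc") %in% names(gc_strata)))
  if (any(gc_strata$gc < 0 | gc_strata$gc > 1)) {
    stop("infeasible GC stratum: target fraction outside [0, 1]", call. = FALSE)
  }
  if (any(gc_strata$end <= gc_strata$start) ||
      min(gc_strata$start) != 0 || max(gc_strata$end) != length ||
      !all(sort(gc_strata$start)[-1] == sort(gc_strata$end)[-nrow(gc_strata)])) {
    stop("GC strata must partition [0, length)", call. = FALSE)
  }
  if (is.null(events)) {
    events <- tibble::tibble(svtype = character(0), start = numeric(0),
                             end = numeric(0), genotype = character(0))
  }
  events <- tibble::as_tibble(events)
  if (nrow(events) > 0L) {
    stopifnot(all(c("svtype", "start", "end", "genotype") %in% names(events)))
    stopifnot(all(events$svtype %in% c("DEL", "DUP")),
              all(events$genotype %in% c("0/1", "1/1")),
              all(events$start < events$end))
    if (any(events$start < flank_margin) ||
        any(events$end > length - flank_margin)) {
      stop("events must lie within [flank_margin, length - flank_margin)",
           call. = FALSE)
    }
    ev <- events[order(events$start), ]
    if (nrow(ev) > 1L && any(ev$start[-1] < ev$end[-nrow(ev)])) {
      stop("events must not overlap", call. = FALSE)
    }
  }
  if (4 * coverage >= DEPTH_CAP) {
    stop("coverage too high: homozygous duplications would hit the depth cap",
         call. = FALSE)
  }
  if (layout == "tiling" && read_length %% coverage != 0) {
    stop("tiling layout needs read_length divisible by coverage (integer tiling step)",
         call. = FALSE)
  }
  structure(
    list(chrom = chrom, length = as.numeric(length), gc_strata = gc_strata,
         events = events, coverage = as.numeric(coverage),
         read_length = as.numeric(read_length), layout = layout,
         seed = as.integer(seed), flank_margin = as.numeric(flank_margin),
         sample_name = sample_name),
    class = "fixture_spec"
  )
}

#' Generate the reference sequence of a fixture
#'
#' Each stratum gets exactly `round(gc * width)` G/C bases (split evenly at
#' random between G and C, likewise A/T), shuffled uniformly, so the
#' realized GC matches the target to within one base. Deterministic under
#' the spec seed.
#'
#' @param spec A [fixture_spec()].
#' @return A [Biostrings::DNAString] of the spec length.
#' @export
make_reference <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed, {
    parts <- lapply(seq_len(nrow(spec$gc_strata)), function(i) {
      s <- spec$gc_strata[i, ]
      w <- s$end - s$start
      n_gc <- round(s$gc * w)
      bases <- c(sample(c("G", "C"), n_gc, replace = TRUE),
                 sample(c("A", "T"), w - n_gc, replace = TRUE))
      paste(sample(bases), collapse = "")
    })
    Biostrings::DNAString(paste(unlist(parts), collapse = ""))
  })
}

# read starts (0-based) for one haplotype, before any event edits
haplotype_starts <- function(spec, phase) {
  L <- spec$length
  rl <- spec$read_length
  if (spec$layout == "tiling") {
    step <- rl / spec$coverage
    offset <- round((phase - 1) * step / 2)
    seq(offset, L - rl, by = step)
  } else {
    n <- stats::rpois(1L, spec$coverage * L / rl)
    sort(floor(stats::runif(n, min = 0, max = L - rl + 1)))
  }
}

#' Simulate alignments for a fixture
#'
#' Two haplotypes are each covered at the spec's haploid coverage; events
#' edit the carrier haplotype(s) (heterozygous events edit one, homozygous
#' both): deletions drop the reads overlapping the event, duplications add
#' a second copy of the reads lying wholly inside it. Reads are unpaired
#' with all-M CIGARs.
#'
#' @param spec A [fixture_spec()].
#' @return Tibble of aligned segments sorted by position: `qname`, `flag`,
#'   `chrom`, `pos` (1-based), `mapq`, `cigar`, `ref_start` (0-based).
#' @export
simulate_alignments <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  rl <- spec$read_length
  withr::with_seed(spec$seed + 1L, {
    starts <- lapply(1:2, function(phase) {
      p <- haplotype_starts(spec, phase)
      ev <- spec$events
      for (k in seq_len(nrow(ev))) {
        carrier <- ev$genotype[k] == "1/1" || phase == 2L
        if (!carrier) next
        if (ev$svtype[k] == "DEL") {
          p <- p[!(p < ev$end[k] & p + rl > ev$start[k])]
        } else { # DUP: tandem second copy of fully-contained reads
          p <- c(p, p[p >= ev$start[k] & p + rl <= ev$end[k]])
        }
      }
      p
    })
  })
  all_starts <- sort(c(starts[[1]], starts[[2]]))
  tibble::tibble(
    qname = sprintf("r%06d", seq_along(all_starts)),
    flag = 0L,
    chrom = spec$chrom,
    pos = as.integer(all_starts + 1L),
    mapq = 60L,
    cigar = sprintf("%dM", as.integer(rl)),
    ref_start = all_starts
  )
}

#' Simulate homozygous-reference null variants
#'
#' For every heterozygous (0/1) or homozygous-alternate (1/1) input variant,
#' places one homozygous-reference (0/0) variant of the same type and length
#' uniformly at random wholly inside the high-confidence regions. Any
#' placement where more than 10% of the enclosed reference bases are
#' ambiguous (N) is rejected and redrawn, up to `max_tries` draws per
#' variant.
#'
#' @param variants Tibble with columns `svtype`, `start`, `end`, `genotype`
#'   (0-based half-open intervals).
#' @param regions Tibble with columns `start`, `end`: sorted, non-
#'   overlapping 0-based half-open high-confidence intervals.
#' @param reference Reference sequence (character or `DNAString`).
#' @param seed Integer seed.
#' @param max_n_frac Maximum tolerated N fraction inside a placed event.
#' @param max_tries Draw limit per variant before erroring.
#' @return Tibble of 0/0 records with the same columns as `variants`.
#' @export
generate_null_variants <- function(variants, regions, reference, seed = 1L,
                                   max_n_frac = 0.10, max_tries = 1000L) {
  variants <- tibble::as_tibble(variants)
  regions <- tibble::as_tibble(regions)
  stopifnot(nrow(regions) > 0L,
            all(c("svtype", "start", "end", "genotype") %in% names(variants)),
            all(c("start", "end") %in% names(regions)))
  regions <- regions[order(regions$start), ]
  if (any(regions$end <= regions$start) ||
      (nrow(regions) > 1L && any(regions$start[-1] < regions$end[-nrow(regions)]))) {
    stop("high-confidence regions must be non-empty, sorted and non-overlapping",
         call. = FALSE)
  }
  if (is.character(reference)) {
    reference <- Biostrings::DNAString(toupper(reference))
  } else if (methods::is(reference, "DNAStringSet")) {
    reference <- reference[[1L]]
  }
  alt <- variants[variants$genotype %in% c("0/1", "1/1"), , drop = FALSE]
  widths <- regions$end - regions$start
  withr::with_seed(seed, {
    placed <- lapply(seq_len(nrow(alt)), function(i) {
      len <- alt$end[i] - alt$start[i]
      slots <- pmax(widths - len + 1, 0)
      if (sum(slots) == 0) {
        stop(sprintf(
          "no high-confidence region can hold variant %d (%s, %d bp)",
          i, alt$svtype[i], len
        ), call. = FALSE)
      }
      for (try in seq_len(max_tries)) {
        # uniform over all feasible placements: pick a region weighted by
        # its slot count, then a start uniform within it
        r <- sample.int(nrow(regions), 1L, prob = slots)
        s <- regions$start[r] + sample.int(slots[r], 1L) - 1
        n_frac <- 1 - sum(Biostrings::letterFrequency(
          Biostrings::subseq(reference, s + 1, s + len), c("A", "C", "G", "T")
        )) / len
        if (n_frac <= max_n_frac) {
          return(tibble::tibble(svtype = alt$svtype[i], start = s,
                                end = s + len, genotype = "0/0"))
        }
      }
      stop(sprintf(
        "could not place a null variant for input %d (%s, %d bp) in %d tries",
        i, alt$svtype[i], len, max_tries
      ), call. = FALSE)
    })
  })
  if (length(placed) == 0L) {
    return(tibble::tibble(svtype = character(0), start = numeric(0),
                          end = numeric(0), genotype = character(0)))
  }
  dplyr::bind_rows(placed)
}

truth_vcf_lines <- function(spec, reference, events) {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", spec$chrom, as.integer(spec$length)),
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="End position (1-based inclusive)">',
    '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="SV length">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", spec$sample_name, sep = "\t")
  )
  if (nrow(events) == 0L) return(header)
  events <- events[order(events$start), ]
  recs <- vapply(seq_len(nrow(events)), function(i) {
    ev <- events[i, ]
    pos <- as.integer(ev$start)           # 1-based padding base = 0-based start
    len <- as.integer(ev$end - ev$start)
    svlen <- if (ev$svtype == "DEL") -len else len
    paste(
      spec$chrom, pos, sprintf("ev%03d", i),
      as.character(Biostrings::subseq(reference, pos, pos)),
      sprintf("<%s>", ev$svtype), ".", "PASS",
      sprintf("SVTYPE=%s;END=%d;SVLEN=%d", ev$svtype, as.integer(ev$end), svlen),
      "GT", ev$genotype,
      sep = "\t"
    )
  }, character(1))
  c(header, recs)
}

#' Write a complete fixture to disk
#'
#' Materializes the spec as an indexed FASTA, a coordinate-sorted indexed
#' BAM, and a truth VCF carrying genotype and type for every event (plus
#' optional matched 0/0 null events), all mutually consistent and directly
#' consumable by [annotate_vcf()].
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @param null_regions Optional high-confidence regions tibble
#'   (`start`/`end`); when given, one matched homozygous-reference null
#'   event per real event is added to the truth VCF via
#'   [generate_null_variants()].
#' @return Named list of paths: `fasta`, `fai`, `bam`, `bai`, `vcf`, plus
#'   the `reference` sequence and the `truth` tibble (events + nulls).
#' @export
write_fixture <- function(spec, dir = tempfile("fixture"),
                          null_regions = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reference <- make_reference(spec)

  fasta <- file.path(dir, "ref.fa")
  seqs <- Biostrings::DNAStringSet(reference)
  names(seqs) <- spec$chrom
  Biostrings::writeXStringSet(seqs, fasta)
  Rsamtools::indexFa(fasta)

  aln <- simulate_alignments(spec)
  sam <- file.path(dir, "reads.sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", spec$chrom, as.integer(spec$length)),
    sprintf("@RG\tID:fix\tSM:%s", spec$sample_name),
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*\tRG:Z:fix",
            aln$qname, aln$flag, aln$chrom, aln$pos, aln$mapq, aln$cigar)
  ), sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, "reads"), overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)

  truth <- spec$events
  if (!is.null(null_regions) && nrow(spec$events) > 0L) {
    nulls <- generate_null_variants(spec$events, null_regions, reference,
                                    seed = spec$seed + 2L)
    truth <- dplyr::bind_rows(truth, nulls)
  }
  vcf <- file.path(dir, "truth.vcf")
  writeLines(truth_vcf_lines(spec, reference, truth), vcf)

  list(
    fasta = fasta, fai = paste0(fasta, ".fai"),
    bam = bam, bai = paste0(bam, ".bai"),
    vcf = vcf, reference = reference, truth = tibble::as_tibble(truth)
  )
}
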