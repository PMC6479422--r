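---
title: "Depth fold-change annotation of structural variants: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth fold-change annotation of structural variants: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svdepth)
```

## The problem and the model

Deletion and duplication calls made from discordant read pairs and split
reads carry an orthogonal, largely unused line of evidence: the depth of
aligned sequence. Under a diploid model with background depth $D$, the
expected in-event depth is $D/2$ for a heterozygous deletion, $0$ for a
homozygous deletion, $3D/2$ for a heterozygous tandem duplication and $2D$
for a homozygous one. `svdepth` turns this expectation into two per-call
statistics:

* **DHFFC**, the in-event median depth over the median depth of the
  flanking sequence ($\pm$ 1,000 bp, pooled). This captures the *local,
  rapid* change in depth a curator sees at real breakpoints.
* **DHBFC**, the in-event median depth over the median depth of 250-bp
  reference windows with similar GC content. This compares the event
  against the genome-wide depth a region of that base composition should
  have, guarding against GC-driven coverage waves masquerading as
  copy-number changes.

Medians, not means, everywhere: a shifted breakpoint changes only the few
depth values at the event edges, which a median over a $\geq$ kilobase
interval ignores.

Filtering is one strict inequality per type — retain deletions with
`DHFFC < 0.7`, duplications with `DHBFC > 1.3`. Because annotation adds no
calls, filtering can only raise precision, never recall. A missing
annotation always retains the call: absence of depth evidence must not
silently delete a variant.

## Coverage algorithm

Per-base depth for a chromosome of length $L$ is built as a difference
array: for every maximal reference-covering run of a read's CIGAR, $+1$ at
the run's start and $-1$ one past its end, then a single cumulative sum.
Building the array costs one pass over the alignments; afterwards every
variant query is an $O(\text{interval})$ median over an in-memory vector,
which is why annotating 10 or 10,000 variants on a chromosome costs almost
the same — the package counts and exposes the builds (`per_chrom` in the
`annotate_vcf()` result) so this once-per-chromosome property is testable
rather than folklore.

CIGAR semantics: `M`, `=`, `X` consume reference and count as covered;
`D` and `N` consume reference but contribute no coverage and split the read
into separate covering segments; `I`, `S`, `H`, `P` consume no reference.
Counting deleted (`D`) bases as covered is a documented minority convention,
so it is exposed as `count_deletions` rather than hard-coded. Alignments
flagged unmapped, secondary, duplicate or QC-fail are skipped;
supplementary alignments are kept, because split reads genuinely contribute
depth; there is no mapping-quality floor by default (`min_mapq` raises
one). Reads overhanging the chromosome end are clamped with a warning
rather than rejected — tolerant of slightly malformed inputs.

The running cumulative sum is tracked at full (double) precision but each
stored value is capped at the 16-bit maximum, 32,767: one `int16`-sized
array per chromosome keeps memory at ~0.5 GB for the largest human
chromosome while depths beyond the cap carry no extra information for a
fold-change.

## Numerical conventions

* **Coordinates** are 0-based half-open everywhere internally; conversion
  happens only at the VCF boundary. A symbolic record with POS $p$ and END
  $e$ affects 1-based bases $p{+}1..e$ (the padding base is excluded),
  i.e. the interval $[p, e)$. With only SVLEN, the end is
  $p + |\mathrm{SVLEN}|$; a sequence-resolved deletion spans
  $[p, p + \lvert\mathrm{REF}\rvert - 1)$. END wins over SVLEN when both are
  present and inconsistent.
* **Median convention**: for even-length intervals the *lower* of the two
  middle values. This keeps every reported median an actually observed
  (integral) depth and makes the GC-table lookup provably return the median
  of a real multiset of window medians instead of an interpolated value.
* **Flank pooling**: the two 1,000-bp flanks are pooled into one multiset
  before the median. When one flank is truncated by a chromosome end, the
  other simply dominates the pool; per-side medians averaged would weight a
  10-base truncated flank equally with a full one. Zero-depth flank bases
  are included — masking gaps would silently change what the statistic
  measures.
* **GC binning**: bin width 0.05 (21 bins, GC = 1.0 clamped into the top
  bin; an epsilon guards `floor(0.6/0.05)`-style float artifacts). Windows
  with more than 10% ambiguous (N) bases are excluded, and GC is always
  computed over non-N bases. A bin needs at least 5 member windows to
  answer on its own; otherwise the nearest bin with at least 5 members is
  used, or, when no bin reaches 5, the nearest occupied bin (ties broken
  toward lower GC). The literal reading "fall back to the nearest occupied
  bin" would make the occupancy minimum vacuous — an occupied target bin is
  its own nearest occupied bin — so the minimum is applied to the fallback
  search as well. The table is built per chromosome, matching the
  chromosome-at-a-time processing model.
* **Spanless records**: BND and INS records (no usable END beyond POS) get
  missing values; DEL, DUP, CNV and INV get both statistics. Inversions are
  copy-neutral, so their annotation is configurable
  (`annotate_inversions`) — the values remain useful for spotting
  misclassified copy-number events.
* **Output**: FORMAT fields named exactly `DHBFC` and `DHFFC`
  (`Number=1`, `Type=Float`) for downstream compatibility, written with 3
  decimals; missing is the VCF `.`. Annotation is idempotent: pre-existing
  `DHBFC`/`DHFFC` entries are stripped before the fresh values are
  appended, so re-annotating a file changes nothing else.

## Evaluation machinery

`confusion_metrics()` computes precision $tp/(tp{+}fp)$, recall
$tp/(tp{+}fn)$, their harmonic mean F1, and FDR $fp/(tp{+}fp)$, reported at
3 decimals; zero denominators are explicit errors naming the metric.
`summarize_filter_effect()` reports the fraction of false positives removed
and true positives retained as whole percentages. `roc_and_auc()` sweeps
sensitivity/specificity over the distinct score thresholds (tied scores
form one step) and integrates with the trapezoidal rule; that construction
makes the AUC *identical* to the pairwise rank statistic with ties counted
½, which is what the test suite checks it against by exhaustive pair
enumeration. Truth labels (which call is tp/fp/fn, or event vs.
homozygous-reference) are taken as input — interval-matching a call set
against a truth set is a separate tool's job.

## What the synthetic fixtures emulate — and what they do not

The generator builds, deterministically from a seed: a reference whose
per-stratum GC hits its target to within one base (exact composition,
shuffled order); unpaired 150-bp all-M reads laid down per haplotype at
haploid coverage 15 (diploid 30 — the conditions used across the package's
tests, matching a typical modern whole-genome run); a truth VCF with
symbolic alleles and genotypes; and, mirroring the evaluation design for
specificity, one homozygous-reference "null" event per real 0/1 or 1/1
event — same type and length, placed uniformly over all feasible positions
inside supplied high-confidence regions, redrawing any placement with more
than 10% N (up to 1,000 draws, then an error naming the variant).

In deterministic-tiling mode each haplotype is tiled at one read per 10 bp,
so depth plateaus are exact integers: events are realized by deleting the
carrier haplotype's reads overlapping a deletion, or adding a second copy
of the reads wholly inside a tandem duplication. In-event depths are then
exactly 15/0/45/60 against a 30× background, and the fold-change statistics
take their textbook values exactly — which is what makes sharp equality
tests possible. Poisson mode draws read starts uniformly at the same rate,
so the multipliers hold in expectation with realistic sampling noise.

What the fixtures deliberately do **not** model: sequencing error, base
qualities, paired-end fragment geometry, split-read or discordant-pair
breakpoint signals, mappability structure, or GC-dependent coverage bias.
Passing tests therefore demonstrate the *arithmetic and algorithmic*
correctness of the statistics and the separability of idealized genotype
classes (AUC 1.0 at desk scale); they do not certify performance on real
genomes, where coverage noise, reference gaps and complex events compress
the separation substantially.

## Problem sizes

The test suite runs on chromosomes of 0.3–2 kb for oracle equivalence
(100 random CIGAR mixtures against a brute-force per-position pileup),
25–50 kb single-event fixtures for the file-level round trips, a ~565 kb
fixture with 80 events plus matched nulls for the genotype-separation
check, and a 10,000-variant VCF for the once-per-chromosome build property.
These sizes were chosen so the full suite exercises every code path in a
few minutes on a laptop; all scale linearly if enlarged.

## Known limitations

* One sample, one pass: multi-sample VCFs are annotated for a single
  selected sample column (others receive `.`), never jointly.
* Depth is the only evidence stream — copy-neutral events (inversions,
  balanced translocations) and small events (where a kilobase median has
  little to average over) are outside the statistics' power, and
  duplications separate less cleanly than deletions (a het duplication is a
  1.5× change; a het deletion is 2×).
* The GC table conditions on GC only; mappability or regression-based
  coverage correction is out of scope.
* No breakpoint refinement and no re-genotyping: the annotations judge the
  stated interval as given.
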