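# Independent oracles the implementation is checked against. These stay
# deliberately naive: the pileup oracle walks every read op-by-op and
# increments every covered base directly (no difference array, no run
# merging), and the AUC oracle enumerates every label-discordant pair.

# Brute-force per-position pileup. segments: data frame with ref_start,
# cigar. Returns the per-base depth vector for a chromosome of `length`.
oracle_pileup <- function(segments, length, count_deletions = FALSE) {
  depth <- numeric(length)
  for (i in seq_len(nrow(segments))) {
    pos <- segments$ref_start[i]
    cig <- segments$cigar[i]
    lens <- as.numeric(regmatches(cig, gregexpr("[0-9]+", cig))[[1]])
    ops <- regmatches(cig, gregexpr("[A-Z=]", cig))[[1]]
    for (j in seq_along(ops)) {
      op <- ops[j]
      n <- lens[j]
      if (op %in% c("M", "=", "X") || (count_deletions && op == "D")) {
        for (b in seq_len(n)) {
          idx <- pos + b # 1-based index of 0-based position pos + b - 1
          if (idx >= 1 && idx <= length) depth[idx] <- depth[idx] + 1
        }
        pos <- pos + n
      } else if (op %in% c("D", "N")) {
        pos <- pos + n
      }
      # I, S, H, P: no reference consumed
    }
  }
  depth
}

# Pairwise rank statistic: P(score_pos ranked on the event side of
# score_neg), ties 1/2. `direction` as in roc_and_auc.
oracle_pairwise_auc <- function(scores, labels, direction = "lower") {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      win <- if (direction == "lower") p < q else p > q
      total <- total + if (win) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Random alignment set with CIGARs mixing M/I/D/N/S ops, for property tests.
random_segments <- function(n_reads, chrom_len) {
  make_cigar <- function() {
    n_ops <- sample(1:5, 1)
    ops <- character(0)
    prev <- ""
    for (i in seq_len(n_ops)) {
      op <- sample(c("M", "M", "M", "I", "D", "N", "S"), 1)
      if (op == prev) op <- "M" # no adjacent same-op runs
      ops <- c(ops, op)
      prev <- op
    }
    if (!any(ops %in% c("M"))) ops <- c(ops, "M")
    lens <- sample(1:60, length(ops), replace = TRUE)
    paste0(paste0(lens, ops, collapse = ""), "")
  }
  data.frame(
    ref_start = sample(0:(chrom_len - 1), n_reads, replace = TRUE),
    cigar = vapply(seq_len(n_reads), function(i) make_cigar(), character(1)),
    stringsAsFactors = FALSE
  )
}

# Small annotated fixture shared by vcf-interface tests.
basic_fixture <- function(dir = tempfile("fx"), n_del = 1L, seed = 7L,
                          length = 30000L) {
  events <- if (n_del > 0L) {
    starts <- seq(5000, by = 4000, length.out = n_del)
    data.frame(svtype = "DEL", genotype = "0/1",
               start = starts, end = starts + 2000)
  } else NULL
  spec <- fixture_spec(
    length = max(length, if (n_del > 0L) max(events$end) + 4000 else 0),
    seed = seed,
    events = events
  )
  c(list(spec = spec), write_fixture(spec, dir))
}
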