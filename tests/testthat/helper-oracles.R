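# Independent brute-force oracles and shared fixtures.

# Per-base alignment walk: emits one event per base of each CIGAR
# operation and tallies inserted/deleted bases against the half-open tract.
# Independent of the interval arithmetic in observed_length().
oracle_observed_length <- function(cigar, pos0, start, end) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  r <- pos0
  ins <- 0L
  del <- 0L
  for (o in ops) {
    op <- substring(o, nchar(o))
    len <- as.integer(sub(".$", "", o))
    for (k in seq_len(len)) {
      if (op %in% c("M", "=", "X")) {
        r <- r + 1L
      } else if (op %in% c("D", "N")) {
        if (r >= start && r < end) del <- del + 1L
        r <- r + 1L
      } else if (op == "I") {
        if (r >= start && r < end) ins <- ins + 1L
      }
    }
  }
  (end - start) + ins - del
}

# Exhaustive pairwise-comparison AUC: wins + half-ties over all
# (positive, negative) pairs.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Exhaustive cutoff scan for the dual thresholds (same strict-">" rule).
oracle_dual_thresholds <- function(scores, labels, target) {
  pos <- scores[labels]
  neg <- scores[!labels]
  cand <- sort(unique(scores))
  hi <- cand[vapply(cand, function(c)
    mean(neg <= c) >= target && any(pos > c), logical(1))]
  lo <- cand[vapply(cand, function(c)
    mean(pos >= c) >= target && any(neg < c), logical(1))]
  list(high = if (length(hi)) min(hi) else NA_real_,
       low = if (length(lo)) max(lo) else NA_real_)
}

tiny_panel <- function(n = 2L) {
  synthetic_panel(n_loci = n, min_len = 15L, max_len = 15L, seed = 42L)
}

# A fast config for small fixtures (depth gate lowered where noted).
tiny_config <- function(...) {
  msi_config(...)
}

write_bed_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".bed",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
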