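# Tract-length extraction, read filtering, and distribution processing.

test_that("observed_length counts only indels inside the tract", {
  # 15 bp tract at [1000, 1015)
  expect_equal(observed_length("50M", 990, 1000, 1015), 15)
  # one 2-base deletion wholly inside
  expect_equal(observed_length("15M2D35M", 990, 1000, 1015), 13)
  # 3-base insertion inside, 1-base deletion outside (in the left flank)
  expect_equal(observed_length("5M1D15M3I30M", 990, 1000, 1015), 18)
  # insertion exactly at `start` counts inside; at `end` outside
  expect_equal(observed_length("10M2I40M", 990, 1000, 1015), 17)
  expect_equal(observed_length("25M2I25M", 990, 1000, 1015), 15)
})

test_that("observed_length rejects alignments that stop before the tract", {
  expect_error(observed_length("5M", 990, 1000, 1015), "does not reach")
})

test_that("randomised CIGAR walks agree with the per-base oracle", {
  set.seed(11)
  start <- 1000L; end <- 1015L
  for (i in 1:200) {
    pos0 <- start - sample(5:20, 1)
    ops <- c(sprintf("%dM", start - pos0 + sample(0:10, 1)))
    for (k in 1:sample(1:3, 1)) {
      ops <- c(ops,
               sample(c(sprintf("%dI", sample(1:4, 1)),
                        sprintf("%dD", sample(1:4, 1))), 1),
               sprintf("%dM", sample(3:12, 1)))
    }
    ops <- c(ops, "30M")
    cigar <- paste(ops, collapse = "")
    expect_equal(observed_length(cigar, pos0, start, end),
                 oracle_observed_length(cigar, pos0, start, end),
                 info = cigar)
  }
})

test_that("read filters enforce flags, MAPQ and complete flanked coverage", {
  cfg <- msi_config()
  locus <- list(start = 1000L, end = 1015L)
  # flanked interval [995, 1020): a 30M read from pos0 992 covers it
  ok <- function(flag = 0L, mapq = 20L, pos0 = 992L, cigar = "30M") {
    read_passes_filters(flag, mapq, pos0, cigar, locus, cfg)
  }
  expect_true(ok())
  expect_false(ok(mapq = 19L))                     # below threshold
  expect_true(ok(mapq = 60L))
  expect_false(ok(flag = 0x400L, mapq = 60L))      # duplicate
  expect_false(ok(flag = 0x100L))                  # secondary
  expect_false(ok(flag = 0x800L))                  # supplementary
  expect_false(ok(flag = 0x4L))                    # unmapped
  expect_false(ok(pos0 = 996L))                    # starts inside flank
  expect_false(ok(cigar = "27M"))                  # stops inside flank
  expect_false(ok(cigar = "5S25M"))                # soft clip shrinks span
  expect_true(ok(pos0 = 995L, cigar = "25M"))      # exact flanked span
})

test_that("raising min_mapq or flank_bases never admits more reads", {
  set.seed(21)
  locus <- list(start = 1000L, end = 1015L)
  flags <- sample(c(0L, 0x400L, 0x100L), 50, replace = TRUE,
                  prob = c(0.8, 0.1, 0.1))
  mapqs <- sample(0:60, 50, replace = TRUE)
  pos0s <- 1000L - sample(3:15, 50, replace = TRUE)
  cigars <- sprintf("%dM", sample(18:40, 50, replace = TRUE))
  n_pass <- function(mapq, flank) {
    cfg <- msi_config(min_mapq = mapq, flank_bases = flank)
    sum(read_passes_filters(flags, mapqs, pos0s, cigars, locus, cfg))
  }
  for (mq in c(0, 10, 20, 30, 60)) {
    expect_true(n_pass(mq, 5) >= n_pass(mq + 10, 5))
    expect_true(n_pass(mq, 2) >= n_pass(mq, 5))
  }
})

test_that("distribution building, cleaning and normalisation follow the rules", {
  d <- build_distribution(c(15L, 15L, 14L, 15L))
  expect_equal(d$count[d$length == 15], 3)
  expect_equal(d$count[d$length == 14], 1)
  expect_equal(sum(d$count), 4)
  expect_equal(nrow(build_distribution(integer())), 0)
  expect_equal(build_distribution(rep(15L, 30))$count, 30)

  raw <- tibble::tibble(length = c(15L, 13L), count = c(30L, 1L))
  expect_equal(clean_distribution(raw)$length, 15)
  keep2 <- tibble::tibble(length = c(15L, 14L), count = c(2L, 2L))
  expect_equal(clean_distribution(keep2), keep2)
  allsing <- tibble::tibble(length = c(13L, 12L), count = c(1L, 1L))
  expect_equal(nrow(clean_distribution(allsing)), 0)

  norm <- normalize_distribution(
    tibble::tibble(length = c(14L, 15L, 16L), count = c(20L, 40L, 10L)))
  expect_equal(norm$value, c(0.5, 1.0, 0.25))
  expect_equal(normalize_distribution(
    tibble::tibble(length = 15L, count = 30L))$value, 1.0)
  expect_error(normalize_distribution(build_distribution(integer())),
               "nothing to normalize")
})

test_that("singleton cleaning conserves depth accounting", {
  set.seed(31)
  for (i in 1:50) {
    lengths <- sample(10:20, sample(30:200, 1), replace = TRUE)
    d <- build_distribution(lengths)
    cleaned <- clean_distribution(d)
    removed <- d[d$count <= 1, , drop = FALSE]
    expect_equal(sum(cleaned$count) + sum(removed$count), length(lengths))
  }
})

test_that("vectorize_profile embeds offsets and drops out-of-window lengths", {
  norm <- tibble::tibble(length = c(14L, 15L), value = c(0.5, 1.0))
  v <- vectorize_profile(norm, ref_length = 15L, window = 3L)
  expect_equal(unname(v), c(0, 0, 0.5, 1.0, 0, 0, 0))
  expect_equal(names(v), as.character(-3:3))

  far <- tibble::tibble(length = c(15L, 40L), value = c(1.0, 0.2))
  expect_warning(v2 <- vectorize_profile(far, 15L, 3L), "outside")
  expect_equal(sum(v2), 1.0)
})

test_that("the 30x evaluability boundary is inclusive", {
  panel <- tiny_panel(1)
  mk <- function(n) tibble::tibble(locus = panel$name, length = 15L,
                                   count = as.integer(n))
  f29 <- distributions_to_features(mk(29), panel)
  f30 <- distributions_to_features(mk(30), panel)
  expect_false(f29$evaluable)
  expect_true(f30$evaluable)
  expect_null(f29$profile[[1]])
  expect_equal(unname(f30$profile[[1]]["0"]), 1.0)
})

test_that("extract_sample recovers simulated profiles from a BAM", {
  panel <- tiny_panel(2)
  cfg <- msi_config()
  dist <- tibble::tibble(locus = rep(panel$name, c(1, 1)),
                         length = c(15L, 15L), count = c(100L, 10L))
  bam <- write_bam_fixture(dist, panel,
                           withr::local_tempfile(fileext = ".bam"), cfg)
  f <- extract_sample(bam, panel, cfg)
  expect_true(f$evaluable[1])
  expect_equal(unname(f$profile[[1]]["0"]), 1.0)
  expect_equal(f$depth[1], 100L)
  # locus with 10 reads fails the 30x depth gate
  expect_false(f$evaluable[2])
})

test_that("a panel chromosome missing from the BAM degrades gracefully", {
  panel <- tiny_panel(1)
  cfg <- msi_config()
  dist <- tibble::tibble(locus = panel$name, length = 15L, count = 50L)
  bam <- write_bam_fixture(dist, panel,
                           withr::local_tempfile(fileext = ".bam"), cfg)
  panel2 <- dplyr::bind_rows(panel, dplyr::mutate(
    panel, name = "ghost", chrom = "chrGhost"))
  expect_warning(f <- extract_sample(bam, panel2, cfg), "absent")
  expect_true(f$evaluable[f$locus == panel$name])
  expect_false(f$evaluable[f$locus == "ghost"])
})

test_that("normalisation is idempotent on rescaled counts", {
  set.seed(41)
  for (i in 1:20) {
    d <- build_distribution(sample(12:18, 100, replace = TRUE))
    n1 <- normalize_distribution(d)
    rescaled <- tibble::tibble(length = n1$length,
                               count = n1$value * 1000)
    n2 <- normalize_distribution(rescaled)
    expect_equal(n2$value, n1$value)
  }
})
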