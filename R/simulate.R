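# Synthetic microsatellite read data with known truth. The generator
# emulates polymerase-slippage stutter around the germline tract length and,
# for unstable loci, a tumor-purity-weighted mixture with a contracted MSI
# allele. It is the test and demo substrate standing in for clinical
# cohorts.

#' Simulation parameters for the stutter model
#'
#' @param stutter_p Probability that a read slips at all (per read).
#'   Default 0.05, so ~95% of reads report the allele length exactly.
#' @param stutter_decay Geometric decay of multi-unit slips: a slip has
#'   magnitude k bases with probability `stutter_decay^(k-1) *
#'   (1 - stutter_decay)`. Default 0.5.
#' @param deletion_bias Probability a slip is a contraction rather than an
#'   expansion. Default 0.8, matching the predominance of left-shifted MSI
#'   distributions.
#' @param msi_shift Mean contraction (bases) of the unstable allele.
#'   Default 6.
#' @param purity Tumor fraction: the proportion of reads drawn from the
#'   unstable allele at a shifted locus. Default 0.5.
#' @param unstable_locus_fraction Fraction of panel loci shifted in a dMMR
#'   sample. Default 0.8.
#' @param depth_mean Mean per-locus read depth (Poisson). Default 200.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(stutter_p = 0.05, stutter_decay = 0.5,
                       deletion_bias = 0.8, msi_shift = 6L, purity = 0.5,
                       unstable_locus_fraction = 0.8, depth_mean = 200L) {
  p <- list(stutter_p = stutter_p, stutter_decay = stutter_decay,
            deletion_bias = deletion_bias, msi_shift = as.integer(msi_shift),
            purity = purity,
            unstable_locus_fraction = unstable_locus_fraction,
            depth_mean = as.integer(depth_mean))
  for (key in c("stutter_p", "stutter_decay", "deletion_bias", "purity",
                "unstable_locus_fraction")) {
    if (p[[key]] < 0 || p[[key]] > 1) {
      stop("sim_params: '", key, "' must be in [0, 1]", call. = FALSE)
    }
  }
  if (p$msi_shift < 1) stop("sim_params: msi_shift must be >= 1", call. = FALSE)
  if (p$depth_mean < 1) stop("sim_params: depth_mean must be >= 1",
                             call. = FALSE)
  structure(p, class = "sim_params")
}

# Signed stutter offsets for n reads: 0 with prob 1 - stutter_p, otherwise a
# geometric magnitude with contraction bias.
stutter_offsets <- function(n, params) {
  slips <- stats::runif(n) < params$stutter_p
  k <- sum(slips)
  off <- integer(n)
  if (k > 0) {
    mag <- stats::rgeom(k, prob = 1 - params$stutter_decay) + 1L
    sign <- ifelse(stats::runif(k) < params$deletion_bias, -1L, 1L)
    off[slips] <- sign * mag
  }
  off
}

#' Simulate the read-length distribution at one locus
#'
#' Stable loci emit reads at the reference tract length plus stutter.
#' Unstable loci emit a mixture: a `purity` fraction of reads centred at
#' `ref_length - msi_shift` (the contracted tumor allele), the remainder from
#' the stable process, both with the same stutter. Depth is Poisson. Uses the
#' caller's RNG stream; seed upstream for reproducibility.
#'
#' @param ref_length Reference tract length (bases).
#' @param unstable Logical: is this locus shifted in this sample?
#' @param params A [sim_params()] object.
#' @return A distribution tibble (`length`, `count`).
#' @export
simulate_locus_counts <- function(ref_length, unstable, params = sim_params()) {
  n <- stats::rpois(1L, params$depth_mean)
  if (n == 0) return(tibble::tibble(length = integer(), count = integer()))
  centre <- rep.int(as.integer(ref_length), n)
  if (unstable) {
    tumor <- stats::runif(n) < params$purity
    centre[tumor] <- centre[tumor] - params$msi_shift
  }
  lengths <- pmax(0L, centre + stutter_offsets(n, params))
  build_distribution(lengths)
}

#' Simulate a labelled cohort of samples over a panel
#'
#' dMMR samples shift a random `unstable_locus_fraction` subset of loci
#' (rounded), pMMR samples shift none. Truth labels are recorded
#' independently of any scorer. Fully reproducible for a fixed seed.
#'
#' @param panel Panel tibble ([read_panel()] / [synthetic_panel()]).
#' @param n_stable,n_unstable Numbers of pMMR and dMMR samples.
#' @param params A [sim_params()] object.
#' @param seed Integer seed.
#' @return A tibble with one row per sample: `sample_id`, `label`
#'   ("pMMR"/"dMMR"), `shifted_loci` (list of character vectors) and
#'   `distributions` (list of per-locus distribution tibbles with a `locus`
#'   column).
#' @export
simulate_cohort <- function(panel, n_stable, n_unstable,
                            params = sim_params(), seed = 1L) {
  stopifnot(n_stable + n_unstable >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  labels <- c(rep("pMMR", n_stable), rep("dMMR", n_unstable))
  ids <- sprintf("S%03d_%s", seq_along(labels), labels)
  n_shift <- round(params$unstable_locus_fraction * nrow(panel))

  rows <- purrr::map2(ids, labels, function(id, label) {
    shifted <- if (label == "dMMR" && n_shift > 0) {
      sort(sample(panel$name, n_shift))
    } else character()
    per_locus <- purrr::map(seq_len(nrow(panel)), function(i) {
      simulate_locus_counts(panel$ref_length[i],
                            panel$name[i] %in% shifted, params)
    })
    n_rows <- vapply(per_locus, nrow, integer(1))
    dists <- tibble::new_tibble(list(
      locus = rep(panel$name, n_rows),
      length = unlist(lapply(per_locus, `[[`, "length"), use.names = FALSE),
      count = unlist(lapply(per_locus, `[[`, "count"), use.names = FALSE)
    ), nrow = sum(n_rows))
    tibble::tibble(sample_id = id, label = label,
                   shifted_loci = list(shifted),
                   distributions = list(dists))
  })
  dplyr::bind_rows(rows)
}

#' Convert length distributions to model-ready feature profiles
#'
#' Applies the same cleaning, depth gating, normalisation and fixed-width
#' embedding as [extract_sample()], starting from a per-locus distribution
#' table instead of a BAM file.
#'
#' @param distributions Tibble with columns `locus`, `length`, `count`.
#' @param panel Panel tibble.
#' @param config An [msi_config()].
#' @return A feature tibble as from [extract_sample()].
#' @export
distributions_to_features <- function(distributions, panel,
                                      config = msi_config()) {
  n <- nrow(panel)
  idx <- split(seq_len(nrow(distributions)), distributions$locus)
  depth_raw <- integer(n); depth <- integer(n); evaluable <- logical(n)
  dists <- vector("list", n); profiles <- vector("list", n)
  for (i in seq_len(n)) {
    rows <- idx[[panel$name[i]]]
    len <- distributions$length[rows]
    cnt <- distributions$count[rows]
    depth_raw[i] <- sum(cnt)
    keep <- cnt > config$singleton_cutoff      # singleton cleaning
    len <- len[keep]; cnt <- cnt[keep]
    depth[i] <- sum(cnt)
    dists[[i]] <- tibble::new_tibble(list(length = len, count = cnt),
                                     nrow = length(len))
    evaluable[i] <- depth[i] >= config$min_depth
    profiles[i] <- list(if (evaluable[i]) {
      norm <- tibble::new_tibble(list(length = len, value = cnt / max(cnt)),
                                 nrow = length(len))
      vectorize_profile(norm, panel$ref_length[i], config$window)
    } else NULL)
  }
  feature_tibble(panel$name, depth_raw, depth, evaluable, dists, profiles)
}

#' Attach feature profiles to a simulated cohort
#'
#' @param cohort Tibble from [simulate_cohort()].
#' @param panel Panel tibble.
#' @param config An [msi_config()].
#' @return The cohort tibble with a `features` list-column of feature
#'   tibbles (and `distributions`/`shifted_loci` dropped).
#' @export
cohort_features <- function(cohort, panel, config = msi_config()) {
  feats <- purrr::map(cohort$distributions, distributions_to_features,
                      panel = panel, config = config)
  tibble::tibble(sample_id = cohort$sample_id, label = cohort$label,
                 features = feats)
}

# --- BAM fixtures -------------------------------------------------------

#' Write a simulated sample as a sorted, indexed BAM fixture
#'
#' Each count in the distribution table becomes that many single-end mapped
#' reads spanning the flanked locus with a margin, the simulated indel
#' encoded in the CIGAR (deletion or insertion wholly inside the tract),
#' MAPQ 60 and no flags set. Optional decoy reads each violate exactly one
#' read filter, for filter testing.
#'
#' @param distributions Tibble with columns `locus`, `length`, `count`.
#' @param panel Panel tibble.
#' @param out_path Output BAM path (".bam"); the index is written alongside.
#' @param config An [msi_config()] (controls the flank the reads must span).
#' @param decoys Optional tibble with columns `locus`, `kind`
#'   ("duplicate", "low_mapq" or "partial") and `count`.
#' @param margin Extra reference bases covered beyond the flank. Default 10.
#' @return The BAM path, invisibly.
#' @export
write_bam_fixture <- function(distributions, panel, out_path,
                              config = msi_config(), decoys = NULL,
                              margin = 10L) {
  sam <- tempfile(fileext = ".sam")
  writeLines(build_sam_lines(distributions, panel, config, decoys, margin),
             sam)
  dest <- sub("\\.bam$", "", out_path)
  bam <- Rsamtools::asBam(sam, destination = dest, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  invisible(bam)
}

build_sam_lines <- function(distributions, panel, config, decoys, margin) {
  flank <- config$flank_bases
  chrom_len <- vapply(split(panel$end, panel$chrom), max, numeric(1)) +
    flank + margin + 1000
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_len),
                      as.integer(chrom_len)))

  make_read <- function(qname, chrom, locus_start, locus_end, delta,
                        flag = 0L, mapq = 60L, cover_from = NULL) {
    rstart <- if (is.null(cover_from)) locus_start - flank - margin else
      cover_from
    rend <- locus_end + flank + margin            # half-open ref interval
    if (delta == 0) {
      cigar <- sprintf("%dM", rend - rstart)
      qlen <- rend - rstart
    } else if (delta < 0) {
      # deletion of |delta| bases starting one base into the tract
      d <- -delta
      m1 <- (locus_start + 1L) - rstart
      m2 <- rend - (locus_start + 1L + d)
      cigar <- sprintf("%dM%dD%dM", m1, d, m2)
      qlen <- m1 + m2
    } else {
      # insertion of delta bases one base into the tract
      m1 <- (locus_start + 1L) - rstart
      m2 <- rend - (locus_start + 1L)
      cigar <- sprintf("%dM%dI%dM", m1, delta, m2)
      qlen <- m1 + delta + m2
    }
    paste(qname, flag, chrom, rstart + 1L, mapq, cigar, "*", 0, 0,
          strrep("A", qlen), "*", sep = "\t")
  }

  lines <- character()
  counter <- 0L
  for (i in seq_len(nrow(panel))) {
    locus <- panel[i, ]
    dist <- distributions[distributions$locus == locus$name, , drop = FALSE]
    for (j in seq_len(nrow(dist))) {
      delta <- dist$length[j] - locus$ref_length
      for (k in seq_len(dist$count[j])) {
        counter <- counter + 1L
        lines <- c(lines, make_read(sprintf("r%06d", counter), locus$chrom,
                                    locus$start, locus$end, delta))
      }
    }
    if (!is.null(decoys)) {
      dec <- decoys[decoys$locus == locus$name, , drop = FALSE]
      for (j in seq_len(nrow(dec))) {
        for (k in seq_len(dec$count[j])) {
          counter <- counter + 1L
          qn <- sprintf("d%06d", counter)
          lines <- c(lines, switch(
            dec$kind[j],
            duplicate = make_read(qn, locus$chrom, locus$start, locus$end,
                                  0L, flag = FLAG_DUPLICATE),
            low_mapq = make_read(qn, locus$chrom, locus$start, locus$end,
                                 0L, mapq = config$min_mapq - 1L),
            partial = make_read(qn, locus$chrom, locus$start, locus$end,
                                0L, cover_from = locus$start - flank + 1L),
            stop("unknown decoy kind: ", dec$kind[j], call. = FALSE)
          ))
        }
      }
    }
  }
  c(header, lines)
}
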