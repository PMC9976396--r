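#' @importFrom rlang .data
NULL

# --- CIGAR handling -----------------------------------------------------
#
# The microsatellite tract length seen by a read is the reference tract
# length adjusted by the net indel length *inside* the tract. Indels in the
# flanks are unrelated variation and must not count, so the alignment is
# walked operation by operation against a reference cursor.

parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*") return(list(op = character(), len = integer()))
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  if (sum(nchar(ops)) != nchar(cigar)) {
    stop("malformed CIGAR string: ", cigar, call. = FALSE)
  }
  list(op = substring(ops, nchar(ops)), len = as.integer(sub(".$", "", ops)))
}

#' Reference span of an alignment
#'
#' Number of reference bases consumed by a CIGAR string (M/D/N/=/X
#' operations). Soft- and hard-clipped bases consume no reference, so a
#' clipped read cannot claim coverage of the clipped span.
#'
#' @param cigar CIGAR string(s).
#' @return Integer vector of reference spans.
#' @export
cigar_ref_span <- function(cigar) {
  vapply(cigar, function(cg) {
    p <- parse_cigar(cg)
    sum(p$len[p$op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Observed microsatellite tract length of one aligned read
#'
#' Walks the alignment operations of a read and returns the tract length it
#' observed: the reference tract length (`end - start`) plus inserted bases
#' minus deleted bases falling inside the half-open tract `[start, end)`.
#' Matches and mismatches contribute reference span only; indels in the
#' flanking sequence do not count. An insertion occurring exactly at
#' reference position `start` is inside the tract; at `end` it is outside
#' (half-open consistency).
#'
#' @param cigar CIGAR string of the read.
#' @param pos0 0-based leftmost aligned reference position of the read.
#' @param start,end 0-based half-open tract coordinates.
#' @return Integer observed length (bases).
#' @export
#' @examples
#' observed_length("50M", 990, 1000, 1015)            # pure match: 15
#' observed_length("20M2D28M", 995, 1000, 1015)       # 2 bp deletion inside: 13
observed_length <- function(cigar, pos0, start, end) {
  p <- parse_cigar(cigar)
  r <- pos0
  ins_inside <- 0L
  del_inside <- 0L
  for (i in seq_along(p$op)) {
    op <- p$op[i]
    len <- p$len[i]
    if (op %in% c("M", "=", "X")) {
      r <- r + len
    } else if (op %in% c("D", "N")) {
      del_inside <- del_inside + max(0L, min(r + len, end) - max(r, start))
      r <- r + len
    } else if (op == "I") {
      if (r >= start && r < end) ins_inside <- ins_inside + len
    }
    # S/H/P consume no reference
  }
  if (r < end) {
    stop("alignment does not reach the tract end (cigar ", cigar,
         " at pos0 ", pos0, ")", call. = FALSE)
  }
  as.integer((end - start) + ins_inside - del_inside)
}

# --- Read filtering -----------------------------------------------------

FLAG_UNMAPPED <- 0x4L
FLAG_SECONDARY <- 0x100L
FLAG_DUPLICATE <- 0x400L
FLAG_SUPPLEMENTARY <- 0x800L

#' Read-level filter for microsatellite evaluation
#'
#' A read is used for a locus iff it is mapped, not duplicate-flagged, not a
#' secondary or supplementary alignment, has mapping quality at or above
#' `min_mapq`, and its aligned reference span covers the *complete* tract
#' plus `flank_bases` on each side. Vectorised over reads.
#'
#' @param flag SAM flag(s).
#' @param mapq Mapping qualities.
#' @param pos0 0-based leftmost aligned positions.
#' @param cigar CIGAR strings.
#' @param locus One panel row (list or one-row tibble with `start`, `end`).
#' @param config An [msi_config()].
#' @return Logical vector, `TRUE` for reads that pass all filters.
#' @export
read_passes_filters <- function(flag, mapq, pos0, cigar, locus, config) {
  flank <- config$flank_bases
  lo <- locus$start - flank
  hi <- locus$end + flank
  span <- cigar_ref_span(cigar)
  mapped <- bitwAnd(flag, FLAG_UNMAPPED) == 0L
  primary <- bitwAnd(flag, FLAG_SECONDARY) == 0L &
    bitwAnd(flag, FLAG_SUPPLEMENTARY) == 0L
  not_dup <- bitwAnd(flag, FLAG_DUPLICATE) == 0L
  mq <- !is.na(mapq) & mapq >= config$min_mapq
  covers <- pos0 <= lo & (pos0 + span) >= hi
  mapped & primary & not_dup & mq & covers
}

# --- Length distributions ----------------------------------------------

#' Tally observed lengths into a length distribution
#'
#' @param lengths Integer vector of observed tract lengths (one per read).
#' @return A tibble with columns `length` and `count`, ordered by length.
#'   Its total count is the locus depth.
#' @export
build_distribution <- function(lengths) {
  if (length(lengths) == 0) return(empty_distribution())
  tab <- table(lengths)
  tibble::new_tibble(list(length = as.integer(names(tab)),
                          count = as.integer(tab)), nrow = length(tab))
}

empty_distribution <- function() {
  tibble::new_tibble(list(length = integer(), count = integer()), nrow = 0L)
}

#' Remove singleton lengths from a distribution
#'
#' Lengths supported by `singleton_cutoff` reads or fewer (default: exactly
#' one read) are removed to reduce the complexity of the distribution before
#' normalisation. The input is not modified.
#'
#' @param dist A distribution tibble from [build_distribution()].
#' @param singleton_cutoff Integer count at or below which a length is
#'   dropped. Default 1.
#' @return The cleaned distribution tibble.
#' @export
clean_distribution <- function(dist, singleton_cutoff = 1L) {
  dist[dist$count > singleton_cutoff, , drop = FALSE]
}

#' Max-normalise a length distribution
#'
#' Divides each length's read count by the maximum count observed at the
#' locus, giving a value in (0, 1] per length with at least one exact 1.0.
#'
#' @param dist A non-empty distribution tibble.
#' @return A tibble with columns `length` and `value`.
#' @export
normalize_distribution <- function(dist) {
  if (nrow(dist) == 0 || sum(dist$count) == 0) {
    stop("nothing to normalize: empty length distribution", call. = FALSE)
  }
  tibble::new_tibble(list(length = dist$length,
                          value = dist$count / max(dist$count)),
                     nrow = nrow(dist))
}

#' Embed a normalised distribution into a fixed-width profile
#'
#' Maps normalised values onto length offsets relative to the reference
#' tract length: element `i` of the result is the value at offset
#' `i - window - 1` (offsets `-window .. +window`). Offsets with no observed
#' length are 0; observed lengths outside the window are dropped with a
#' warning.
#'
#' @param normalized Tibble from [normalize_distribution()] (may be empty).
#' @param ref_length Reference tract length of the locus.
#' @param window Half-width in bases.
#' @return Named numeric vector of length `2 * window + 1`; names are the
#'   offsets as characters.
#' @export
vectorize_profile <- function(normalized, ref_length, window = 20L) {
  offsets <- seq.int(-window, window)
  values <- stats::setNames(numeric(length(offsets)), as.character(offsets))
  if (nrow(normalized) > 0) {
    off <- normalized$length - ref_length
    outside <- abs(off) > window
    if (any(outside)) {
      warning(sum(outside), " observed length(s) outside the +/-", window,
              " bp window dropped", call. = FALSE)
    }
    keep <- !outside
    values[as.character(off[keep])] <- normalized$value[keep]
  }
  values
}

# --- BAM extraction -----------------------------------------------------

#' Extract per-locus feature profiles from an aligned sample
#'
#' For every panel locus: fetch overlapping reads, apply the read filters
#' ([read_passes_filters()]), compute observed tract lengths, tally, clean
#' singleton lengths, max-normalise, and embed into a fixed-width profile.
#' A locus is evaluable when its post-cleaning depth reaches
#' `config$min_depth`; non-evaluable loci carry an empty profile. Loci on
#' chromosomes absent from the BAM header are marked non-evaluable with a
#' warning and the run continues.
#'
#' @param bam_path Path to a coordinate-sorted, indexed BAM file.
#' @param panel Panel tibble from [read_panel()].
#' @param config An [msi_config()].
#' @return A tibble with one row per locus: `locus`, `depth_raw` (filtered
#'   reads), `depth` (post-cleaning), `evaluable`, `distribution` (list of
#'   cleaned distribution tibbles) and `profile` (list of named numeric
#'   vectors; `NULL` when non-evaluable).
#' @export
extract_sample <- function(bam_path, panel, config = msi_config()) {
  if (!file.exists(bam_path)) {
    stop("BAM file not found: ", bam_path, call. = FALSE)
  }
  bf <- Rsamtools::BamFile(bam_path)
  header_chroms <- names(Rsamtools::scanBamHeader(bf)$targets)
  validate_panel(panel, flank = config$flank_bases)

  rows <- purrr::pmap(panel, function(name, chrom, start, end, ref_length,
                                      ...) {
    if (!chrom %in% header_chroms) {
      warning("locus '", name, "': chromosome '", chrom,
              "' absent from BAM header; marked non-evaluable",
              call. = FALSE)
      return(feature_row(name, tibble::tibble(length = integer(),
                                              count = integer()),
                         0L, 0L, FALSE, NULL))
    }
    flank <- config$flank_bases
    which <- GenomicRanges::GRanges(chrom,
                                    IRanges::IRanges(start - flank + 1L,
                                                     end + flank))
    param <- Rsamtools::ScanBamParam(
      what = c("flag", "mapq", "pos", "cigar"), which = which)
    reads <- Rsamtools::scanBam(bf, param = param)[[1]]
    n <- length(reads$flag)
    if (n == 0) {
      return(feature_row(name, tibble::tibble(length = integer(),
                                              count = integer()),
                         0L, 0L, FALSE, NULL))
    }
    locus <- list(start = start, end = end)
    pos0 <- reads$pos - 1L
    keep <- read_passes_filters(reads$flag, reads$mapq, pos0, reads$cigar,
                                locus, config)
    lens <- purrr::map2_int(reads$cigar[keep], pos0[keep],
                            function(cg, p0) observed_length(cg, p0, start, end))
    dist <- build_distribution(lens)
    cleaned <- clean_distribution(dist, config$singleton_cutoff)
    depth <- sum(cleaned$count)
    evaluable <- depth >= config$min_depth
    profile <- if (evaluable) {
      vectorize_profile(normalize_distribution(cleaned), ref_length,
                        config$window)
    } else NULL
    feature_row(name, cleaned, sum(keep), depth, evaluable, profile)
  })
  dplyr::bind_rows(rows)
}

feature_row <- function(name, dist, depth_raw, depth, evaluable, profile) {
  tibble::new_tibble(list(
    locus = name,
    depth_raw = as.integer(depth_raw),
    depth = as.integer(depth),
    evaluable = evaluable,
    distribution = list(dist),
    profile = list(profile)
  ), nrow = 1L)
}

# Column-wise constructor used by the per-locus extraction loops.
feature_tibble <- function(locus, depth_raw, depth, evaluable, distribution,
                           profile) {
  tibble::new_tibble(list(
    locus = locus,
    depth_raw = as.integer(depth_raw),
    depth = as.integer(depth),
    evaluable = evaluable,
    distribution = distribution,
    profile = profile
  ), nrow = length(locus))
}

#' Write a per-sample audit table of length distributions
#'
#' One row per observed length per locus: locus, length, raw (cleaned)
#' count, and max-normalised value, written as TSV.
#'
#' @param features Feature tibble from [extract_sample()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sample_profiles <- function(features, path) {
  rows <- purrr::map2(features$locus, features$distribution,
                      function(locus, dist) {
    if (nrow(dist) == 0) return(NULL)
    norm <- normalize_distribution(dist)
    tibble::tibble(locus = locus, length = dist$length, count = dist$count,
                   value = norm$value)
  })
  readr::write_tsv(dplyr::bind_rows(rows), path)
  invisible(path)
}
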