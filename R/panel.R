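#' Read a microsatellite panel from a BED file
#'
#' The panel defines the microsatellite target loci: BED3+ (tab-separated, no
#' header), coordinates 0-based half-open as written. Column 4, when present,
#' is the locus name; missing names are auto-generated as `chrom_start_end`.
#' Column 5+ are ignored except column 5 which, if non-numeric, is kept as a
#' free-text `source` tag.
#'
#' @param path Path to a BED file.
#' @return A tibble with one row per locus: `name`, `chrom`, `start`, `end`,
#'   `ref_length` (= end - start), `source`.
#' @export
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr2\t1000\t1015\tMSI_BAT26", bed)
#' read_panel(bed)
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0) stop("panel file is empty: ", path, call. = FALSE)

  rows <- purrr::imap(lines, function(line, i) {
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop("malformed BED line ", i, ": fewer than 3 tab-separated columns",
           call. = FALSE)
    }
    start <- suppressWarnings(as.integer(fields[2]))
    end <- suppressWarnings(as.integer(fields[3]))
    if (is.na(start) || is.na(end)) {
      stop("malformed BED line ", i, ": non-integer coordinates",
           call. = FALSE)
    }
    name <- if (length(fields) >= 4 && nzchar(fields[4])) fields[4] else
      paste(fields[1], start, end, sep = "_")
    src <- if (length(fields) >= 5 && nzchar(fields[5]) &&
                 is.na(suppressWarnings(as.numeric(fields[5])))) fields[5] else
      NA_character_
    tibble::tibble(name = name, chrom = fields[1], start = start, end = end,
                   source = src)
  })
  panel <- dplyr::mutate(dplyr::bind_rows(rows),
                         ref_length = .data$end - .data$start)
  panel <- panel[, c("name", "chrom", "start", "end", "ref_length", "source")]
  validate_panel(panel)
  panel
}

validate_panel <- function(panel, flank = 0L) {
  bad <- which(panel$end <= panel$start)
  if (length(bad) > 0) {
    stop("invalid locus '", panel$name[bad[1]], "': end <= start",
         call. = FALSE)
  }
  dup <- panel$name[duplicated(panel$name)]
  if (length(dup) > 0) {
    stop("duplicate locus name(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (any(panel$start - flank < 0)) {
    stop("flanked interval underflows position 0 for locus '",
         panel$name[which(panel$start - flank < 0)[1]], "'", call. = FALSE)
  }
  invisible(panel)
}

#' Write a microsatellite panel to a BED file
#'
#' Inverse of [read_panel()]: emits BED with name in column 4 and the source
#' tag, when present, in column 5. `read_panel(write_panel(p))` reproduces
#' `p` field for field.
#'
#' @param panel A panel tibble as returned by [read_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  validate_panel(panel)
  lines <- purrr::pmap_chr(panel, function(name, chrom, start, end,
                                           ref_length, source, ...) {
    base <- paste(chrom, start, end, name, sep = "\t")
    if (!is.na(source)) paste(base, source, sep = "\t") else base
  })
  readr::write_lines(lines, path)
  invisible(path)
}

#' Generate a synthetic microsatellite panel
#'
#' Builds a plausible small-panel design for simulation and testing: loci on
#' a single synthetic contig, tract lengths drawn between `min_len` and
#' `max_len` bases, spaced widely enough that flanked intervals never overlap.
#'
#' @param n_loci Number of loci. Default 28, the size of the retained panel
#'   in the published protocol.
#' @param min_len,max_len Tract length range (bases). Defaults 12 and 27,
#'   typical of mononucleotide MSI marker tracts.
#' @param chrom Contig name. Default "msim1".
#' @param spacing Distance between locus starts (bp). Default 1000.
#' @param seed Integer seed.
#' @return A panel tibble (see [read_panel()]).
#' @export
synthetic_panel <- function(n_loci = 28L, min_len = 12L, max_len = 27L,
                            chrom = "msim1", spacing = 1000L, seed = 1L) {
  stopifnot(n_loci >= 1, min_len >= 1, max_len >= min_len)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  len_choices <- seq.int(min_len, max_len)
  lens <- len_choices[sample.int(length(len_choices), n_loci,
                                 replace = TRUE)]
  starts <- 100L + spacing * (seq_len(n_loci) - 1L)
  tibble::tibble(
    name = sprintf("MS%02d_sim", seq_len(n_loci)),
    chrom = chrom,
    start = starts,
    end = starts + lens,
    ref_length = lens,
    source = "synthetic"
  )
}

# Save/restore the global RNG state so generators with their own seed do not
# disturb the caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
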