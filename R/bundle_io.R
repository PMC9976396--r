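# Bundle persistence: a directory with a human-readable manifest
# (key/value), a per-locus selection table and the split record as TSV, and
# the fitted model objects in an RDS store. Manifests contain no timestamps
# so identical seeds give byte-identical metadata.

#' Save a model bundle to a directory
#'
#' @param bundle An `msi_bundle` from [msi_train()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "msi_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  cfg <- bundle$config
  thr <- cfg$thresholds
  manifest <- c(
    paste0("bundle_version=", bundle$version),
    paste0("seed=", bundle$seed),
    paste0("n_loci_panel=", nrow(bundle$panel)),
    paste0("n_loci_retained=", sum(bundle$pairs$retained)),
    sprintf("flank_bases=%d", cfg$flank_bases),
    sprintf("min_mapq=%d", cfg$min_mapq),
    sprintf("min_depth=%d", cfg$min_depth),
    sprintf("singleton_cutoff=%d", cfg$singleton_cutoff),
    sprintf("coverage_fraction=%.6f", cfg$coverage_fraction),
    sprintf("locus_auc_min=%.6f", cfg$locus_auc_min),
    sprintf("window=%d", cfg$window),
    sprintf("kfold=%d", cfg$kfold),
    sprintf("threshold_mode=%s", thr$mode),
    sprintf("threshold_low=%.6f", thr$low),
    sprintf("threshold_high=%.6f", thr$high),
    sprintf("binary_cutoff=%.6f", thr$binary_cutoff)
  )
  writeLines(manifest, file.path(dir, "manifest.txt"))

  loci <- dplyr::mutate(bundle$pairs,
                        dplyr::across(dplyr::where(is.numeric),
                                      ~ sprintf("%.6f", .x)))
  readr::write_tsv(loci, file.path(dir, "loci.tsv"))
  readr::write_tsv(bundle$split, file.path(dir, "split.tsv"))
  write_panel(bundle$panel, file.path(dir, "panel.bed"))
  saveRDS(bundle, file.path(dir, "bundle.rds"), version = 2)
  invisible(dir)
}

#' Load a model bundle from a directory
#'
#' Fails hard when the manifest and the model store disagree on the bundle
#' version (e.g. a tampered or partially copied bundle); no silent
#' best-effort loading.
#'
#' @param dir Bundle directory written by [save_bundle()].
#' @return An `msi_bundle`.
#' @export
load_bundle <- function(dir) {
  manifest_path <- file.path(dir, "manifest.txt")
  rds_path <- file.path(dir, "bundle.rds")
  if (!file.exists(manifest_path) || !file.exists(rds_path)) {
    stop("not a model bundle directory: ", dir, call. = FALSE)
  }
  manifest <- read_manifest(manifest_path)
  bundle <- readRDS(rds_path)
  if (!inherits(bundle, "msi_bundle")) {
    stop("corrupt bundle store in ", dir, call. = FALSE)
  }
  if (!identical(manifest[["bundle_version"]], bundle$version)) {
    stop("bundle version mismatch: manifest says '",
         manifest[["bundle_version"]], "', model store says '",
         bundle$version, "'", call. = FALSE)
  }
  bundle
}

read_manifest <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  stats::setNames(vapply(kv, function(x) paste(x[-1], collapse = "="),
                         character(1)),
                  vapply(kv, `[[`, character(1), 1))
}
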