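#' Pipeline configuration
#'
#' Builds the configuration object that controls read filtering, feature
#' construction, locus selection and sample classification. Defaults are the
#' constants of the published screening protocol: reads need mapping quality
#' >= 20 and must span the locus plus a 5 bp flank on each side; a locus is
#' evaluable in a sample at >= 30x post-cleaning depth; lengths supported by a
#' single read are removed; a locus must be evaluable in >= 75% of training
#' samples and reach validation AUC >= 0.60 in both models to be retained.
#'
#' @param flank_bases Integer, flank (bp) on each side of the tract a read
#'   must fully cover. Default 5.
#' @param min_mapq Integer, minimum mapping quality (inclusive). Default 20.
#' @param min_depth Integer, minimum post-cleaning read depth for a locus to
#'   be evaluable in a sample (inclusive). Default 30.
#' @param singleton_cutoff Integer; observed lengths with a read count at or
#'   below this are removed when cleaning a distribution. Default 1.
#' @param coverage_fraction Fraction of training samples in which a locus must
#'   be evaluable to pass coverage selection (inclusive). Default 0.75.
#' @param locus_auc_min Minimum validation AUC required of *both* per-locus
#'   models (inclusive). Default 0.60.
#' @param window Feature-vector half-width in bases; profiles cover length
#'   offsets -window..+window around the reference tract length, giving
#'   vectors of length `2 * window + 1`. Default 20.
#' @param min_evaluable_loci Minimum number of evaluable loci below which a
#'   sample result is flagged low-confidence. `NA` (default) means half the
#'   retained panel, decided at prediction time.
#' @param kfold Number of cross-validation folds in the hyperparameter grid
#'   search. Default 3.
#' @param thresholds List with elements `mode` ("binary" or "dual"), `low`,
#'   `high` (gray-zone bounds, dual mode) and `binary_cutoff` (default 0.26;
#'   a sample is MSI when its combined score is strictly greater).
#' @param seed Integer seed driving the cohort split and fold assignment.
#'
#' @return A list of class `msi_config`.
#' @export
#' @examples
#' cfg <- msi_config()
#' cfg$min_mapq
msi_config <- function(flank_bases = 5L,
                       min_mapq = 20L,
                       min_depth = 30L,
                       singleton_cutoff = 1L,
                       coverage_fraction = 0.75,
                       locus_auc_min = 0.60,
                       window = 20L,
                       min_evaluable_loci = NA_integer_,
                       kfold = 3L,
                       thresholds = list(),
                       seed = 1L) {
  thr_defaults <- list(mode = "binary", low = 0.10, high = 0.26,
                       binary_cutoff = 0.26)
  unknown_thr <- setdiff(names(thresholds), names(thr_defaults))
  if (length(unknown_thr) > 0) {
    stop("unknown threshold key(s): ", paste(unknown_thr, collapse = ", "),
         call. = FALSE)
  }
  thr <- utils::modifyList(thr_defaults, thresholds)

  cfg <- structure(list(
    flank_bases = as.integer(flank_bases),
    min_mapq = as.integer(min_mapq),
    min_depth = as.integer(min_depth),
    singleton_cutoff = as.integer(singleton_cutoff),
    coverage_fraction = as.numeric(coverage_fraction),
    locus_auc_min = as.numeric(locus_auc_min),
    window = as.integer(window),
    min_evaluable_loci = as.integer(min_evaluable_loci),
    kfold = as.integer(kfold),
    thresholds = thr,
    seed = as.integer(seed)
  ), class = "msi_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  chk <- function(ok, key, msg) {
    if (!isTRUE(ok)) stop("invalid config value for '", key, "': ", msg,
                          call. = FALSE)
  }
  for (key in c("flank_bases", "min_mapq", "min_depth", "singleton_cutoff",
                "window", "kfold", "seed")) {
    chk(is.finite(cfg[[key]]) && cfg[[key]] >= 0, key, "must be nonnegative")
  }
  chk(cfg$kfold >= 2, "kfold", "must be >= 2")
  chk(cfg$coverage_fraction > 0 && cfg$coverage_fraction <= 1,
      "coverage_fraction", "must be in (0, 1]")
  chk(cfg$locus_auc_min >= 0.5 && cfg$locus_auc_min < 1,
      "locus_auc_min", "must be in [0.5, 1)")
  thr <- cfg$thresholds
  chk(thr$mode %in% c("binary", "dual"), "thresholds.mode",
      "must be 'binary' or 'dual'")
  for (key in c("low", "high", "binary_cutoff")) {
    chk(is.numeric(thr[[key]]) && thr[[key]] >= 0 && thr[[key]] <= 1,
        paste0("thresholds.", key), "must be in [0, 1]")
  }
  chk(thr$low <= thr$high, "thresholds.low", "must satisfy low <= high")
  invisible(cfg)
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat key/value YAML; absent keys take the package defaults, unknown keys
#' are rejected. Threshold settings nest under a `thresholds` mapping.
#'
#' @param path Path to a YAML file. An empty file yields the full defaults.
#' @return An `msi_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- setdiff(names(formals(msi_config)), "")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(msi_config, raw)
}

#' @exportS3Method base::print
print.msi_config <- function(x, ...) {
  cat("<msi_config>\n")
  for (key in setdiff(names(x), "thresholds")) {
    cat(sprintf("  %-20s %s\n", key, format(x[[key]])))
  }
  thr <- x$thresholds
  cat(sprintf("  thresholds           mode=%s low=%g high=%g binary_cutoff=%g\n",
              thr$mode, thr$low, thr$high, thr$binary_cutoff))
  invisible(x)
}
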