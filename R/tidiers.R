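#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-locus table of a fitted bundle
#'
#' @param x An `msi_bundle`.
#' @param ... Unused.
#' @return Tibble with one row per panel locus: coverage, training class
#'   counts, validation AUC of both models, retention.
#' @export
tidy.msi_bundle <- function(x, ...) {
  x$pairs
}

#' One-row summary of a fitted bundle
#'
#' @param x An `msi_bundle`.
#' @param ... Unused.
#' @return One-row tibble: panel size, loci passing coverage, loci
#'   retained, seed, version.
#' @export
glance.msi_bundle <- function(x, ...) {
  tibble::tibble(
    n_loci_panel = nrow(x$panel),
    n_loci_coverage = sum(x$pairs$coverage_pass),
    n_loci_retained = sum(x$pairs$retained),
    n_train = sum(x$split$subset == "train"),
    n_validation = sum(x$split$subset == "validation"),
    n_test = sum(x$split$subset == "test"),
    seed = x$seed,
    version = x$version
  )
}

#' Tidy the per-locus calls of a sample result
#'
#' @param x An `msi_result`.
#' @param ... Unused.
#' @return The call tibble (locus, evaluable, per-model and combined
#'   calls).
#' @export
tidy.msi_result <- function(x, ...) {
  x$calls
}

#' One-row summary of a sample result
#'
#' @param x An `msi_result`.
#' @param ... Unused.
#' @return One-row tibble: sample id, evaluable-locus count, the three
#'   sample scores, classification, low-confidence flag, bundle version.
#' @export
glance.msi_result <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(sample_id = x$sample_id), x$score,
                   tibble::tibble(classification = x$classification,
                                  bundle_version = x$bundle_version))
}
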