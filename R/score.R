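# Sample scoring: each retained locus gets a binary call from both models;
# the combined call is the logical AND ("unstable only if both agree"). The
# sample score is the fraction of evaluable loci called unstable, classified
# against a single binary cutoff (default 0.26, strict >) or a dual
# rule-out/rule-in threshold pair with a gray zone between.

#' Per-locus stability calls for one sample
#'
#' @param bundle An `msi_bundle`.
#' @param features Feature tibble for the sample ([extract_sample()] or
#'   [distributions_to_features()]).
#' @return A tibble with one row per retained locus: `locus`, `evaluable`,
#'   `call_logreg`, `call_svc`, `call_combined` (logical, `TRUE` =
#'   unstable; `NA` when non-evaluable).
#' @export
call_loci <- function(bundle, features) {
  retained <- bundle$pairs$locus[bundle$pairs$retained]
  n <- length(retained)
  evaluable <- logical(n)
  cl <- rep(NA, n); cs <- rep(NA, n)
  for (k in seq_len(n)) {
    i <- match(retained[k], features$locus)
    if (is.na(i) || !features$evaluable[i]) next
    X <- matrix(features$profile[[i]], nrow = 1)
    pair <- bundle$models[[retained[k]]]
    evaluable[k] <- TRUE
    cl[k] <- model_calls(pair$logreg, X)
    cs[k] <- model_calls(pair$svc, X)
  }
  tibble::new_tibble(list(locus = retained, evaluable = evaluable,
                          call_logreg = cl, call_svc = cs,
                          call_combined = cl & cs), nrow = n)
}

#' Aggregate locus calls into a sample score
#'
#' Per model, the score is the fraction of evaluable loci called unstable;
#' non-evaluable loci enter neither numerator nor denominator. The combined
#' score can never exceed either single-model score.
#'
#' @param calls Call tibble from [call_loci()].
#' @param min_evaluable_loci Below this many evaluable loci the result is
#'   flagged low-confidence (not refused). `NA` means half the retained
#'   panel.
#' @return One-row tibble: `n_evaluable`, `n_unstable_logreg`,
#'   `n_unstable_svc`, `n_unstable_combined`, `score_logreg`, `score_svc`,
#'   `score_combined`, `low_confidence`.
#' @export
sample_score <- function(calls, min_evaluable_loci = NA_integer_) {
  ev <- calls[calls$evaluable, , drop = FALSE]
  n_ev <- nrow(ev)
  if (n_ev == 0) stop("sample not scoreable: zero evaluable loci",
                      call. = FALSE)
  if (is.na(min_evaluable_loci)) {
    min_evaluable_loci <- ceiling(nrow(calls) / 2)
  }
  tibble::tibble(
    n_evaluable = n_ev,
    n_unstable_logreg = sum(ev$call_logreg),
    n_unstable_svc = sum(ev$call_svc),
    n_unstable_combined = sum(ev$call_combined),
    score_logreg = n_unstable_logreg / n_ev,
    score_svc = n_unstable_svc / n_ev,
    score_combined = n_unstable_combined / n_ev,
    low_confidence = n_ev < min_evaluable_loci
  )
}

#' Classify a sample score
#'
#' Binary mode: MSI iff the combined score is strictly greater than
#' `binary_cutoff`, else MSS. Dual mode: MSS below `low`, MSI above `high`,
#' GRAY in between (boundaries inclusive into the gray zone).
#'
#' @param score_combined Combined sample score in `[0, 1]`.
#' @param thresholds Threshold list from an [msi_config()]
#'   (`config$thresholds`).
#' @return "MSS", "GRAY" or "MSI".
#' @export
classify_score <- function(score_combined, thresholds) {
  if (thresholds$mode == "binary") {
    if (score_combined > thresholds$binary_cutoff) "MSI" else "MSS"
  } else {
    if (score_combined < thresholds$low) "MSS"
    else if (score_combined > thresholds$high) "MSI"
    else "GRAY"
  }
}

#' Predict the MSI status of one aligned sample
#'
#' Full pipeline under the bundle's own configuration snapshot: feature
#' extraction from the BAM, per-locus dual-model calls, sample score,
#' classification. Any per-locus failure downgrades that locus to
#' non-evaluable rather than aborting the sample.
#'
#' @param bam_path Path to an indexed BAM.
#' @param bundle An `msi_bundle` (or a bundle directory path).
#' @param sample_id Sample identifier; defaults to the BAM basename.
#' @return An object of class `msi_result`; see [tidy.msi_result()] and
#'   [glance.msi_result()].
#' @export
predict_sample <- function(bam_path, bundle, sample_id = NULL) {
  if (is.character(bundle)) bundle <- load_bundle(bundle)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.bam$", "", basename(bam_path))
  }
  features <- extract_sample(bam_path, bundle$panel, bundle$config)
  predict_features(features, bundle, sample_id)
}

#' Predict the MSI status from precomputed features
#'
#' Same as [predict_sample()] but starting from a feature tibble — the entry
#' point for simulated cohorts and for re-scoring stored profiles.
#'
#' @param features Feature tibble for one sample.
#' @param bundle An `msi_bundle`.
#' @param sample_id Sample identifier.
#' @return An `msi_result` object.
#' @export
predict_features <- function(features, bundle, sample_id = "sample") {
  calls <- call_loci(bundle, features)
  score <- sample_score(calls, bundle$config$min_evaluable_loci)
  classification <- classify_score(score$score_combined,
                                   bundle$config$thresholds)
  structure(list(
    sample_id = sample_id,
    calls = calls,
    score = score,
    classification = classification,
    bundle_version = bundle$version
  ), class = "msi_result")
}

#' Score a whole cohort of samples with features
#'
#' @param cohort Tibble with `sample_id` and `features` (and optionally
#'   `label`, carried through).
#' @param bundle An `msi_bundle`.
#' @return A tibble with one row per sample: the [glance.msi_result()]
#'   columns plus `label` when present.
#' @export
predict_cohort <- function(cohort, bundle) {
  retained <- bundle$pairs$locus[bundle$pairs$retained]
  n_samp <- nrow(cohort)
  # batch model predictions by locus: one model call per locus over all
  # samples with an evaluable profile there
  call_lr <- matrix(NA, n_samp, length(retained))
  call_sv <- matrix(NA, n_samp, length(retained))
  for (k in seq_along(retained)) {
    locus_name <- retained[k]
    prof <- vector("list", n_samp)
    for (s in seq_len(n_samp)) {
      f <- cohort$features[[s]]
      i <- match(locus_name, f$locus)
      if (!is.na(i) && f$evaluable[i]) prof[[s]] <- f$profile[[i]]
    }
    has <- !vapply(prof, is.null, logical(1))
    if (!any(has)) next
    X <- do.call(rbind, prof[has])
    pair <- bundle$models[[locus_name]]
    call_lr[has, k] <- model_calls(pair$logreg, X)
    call_sv[has, k] <- model_calls(pair$svc, X)
  }
  combined <- call_lr & call_sv
  min_ev <- bundle$config$min_evaluable_loci
  if (is.na(min_ev)) min_ev <- ceiling(length(retained) / 2)
  thr <- bundle$config$thresholds

  rows <- purrr::map(seq_len(n_samp), function(s) {
    ev <- !is.na(call_lr[s, ])
    n_ev <- sum(ev)
    if (n_ev == 0) {
      stop("sample '", cohort$sample_id[s],
           "' not scoreable: zero evaluable loci", call. = FALSE)
    }
    sc <- tibble::new_tibble(list(
      n_evaluable = n_ev,
      n_unstable_logreg = sum(call_lr[s, ev]),
      n_unstable_svc = sum(call_sv[s, ev]),
      n_unstable_combined = sum(combined[s, ev]),
      score_logreg = sum(call_lr[s, ev]) / n_ev,
      score_svc = sum(call_sv[s, ev]) / n_ev,
      score_combined = sum(combined[s, ev]) / n_ev,
      low_confidence = n_ev < min_ev
    ), nrow = 1L)
    dplyr::bind_cols(
      tibble::new_tibble(list(sample_id = cohort$sample_id[s]), nrow = 1L),
      sc,
      tibble::new_tibble(list(
        classification = classify_score(sc$score_combined, thr),
        bundle_version = bundle$version), nrow = 1L))
  })
  out <- dplyr::bind_rows(rows)
  if ("label" %in% names(cohort)) out$label <- cohort$label
  out
}

#' @exportS3Method base::print
print.msi_result <- function(x, ...) {
  s <- x$score
  cat("<msi_result>", x$sample_id, "->", x$classification, "\n")
  cat(sprintf("  combined score %.3f (%d/%d loci unstable)%s\n",
              s$score_combined, s$n_unstable_combined, s$n_evaluable,
              if (s$low_confidence) " [LOW CONFIDENCE]" else ""))
  cat(sprintf("  per-model scores: logreg %.3f, svc %.3f\n",
              s$score_logreg, s$score_svc))
  invisible(x)
}

#' Write per-sample and per-locus result tables
#'
#' Emits the one-row sample summary (`<id>_summary.tsv`) and the per-locus
#' call table (`<id>_loci.tsv`).
#'
#' @param result An `msi_result`.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_result <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(glance(result),
                   file.path(out_dir,
                             paste0(result$sample_id, "_summary.tsv")))
  readr::write_tsv(result$calls,
                   file.path(out_dir, paste0(result$sample_id, "_loci.tsv")))
  invisible(out_dir)
}
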