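# ROC/AUC analysis, threshold derivation with likelihood ratios, and the
# shrinking-training-set robustness experiment. Positive calls use strict
# ">" at every cutoff, consistent with the default sample-score cutoff.

#' Area under the ROC curve
#'
#' Rank-based AUC: the probability that a randomly chosen positive outranks
#' a randomly chosen negative, with ties counting one half. Equivalent to
#' the Mann-Whitney U statistic divided by `n_pos * n_neg`.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Logical (or coercible) vector, `TRUE` = positive (dMMR).
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3, 0.2), c(TRUE, TRUE, FALSE, FALSE))  # 1
roc_auc <- function(scores, labels) {
  labels <- as_positive(labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUC needs both classes present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels != 0)
  labels <- as.character(labels)
  labels %in% c("dMMR", "unstable", "MSI", "TRUE", "1", "positive")
}

#' AUC with DeLong confidence interval
#'
#' @inheritParams roc_auc
#' @param conf_level Confidence level. Default 0.95.
#' @return One-row tibble: `auc`, `auc_ci_low`, `auc_ci_high`.
#' @export
auc_with_ci <- function(scores, labels, conf_level = 0.95) {
  labels <- as_positive(labels)
  roc <- pROC::roc(response = labels, predictor = scores,
                   levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  ci <- pROC::ci.auc(roc, conf.level = conf_level, method = "delong")
  tibble::tibble(auc = as.numeric(ci[2]), auc_ci_low = as.numeric(ci[1]),
                 auc_ci_high = as.numeric(ci[3]))
}

#' Dual rule-out / rule-in thresholds at a target specificity
#'
#' `high` is the smallest observed score cutoff at which calling MSI by
#' "score > high" reaches the target specificity against negatives while
#' still calling at least one positive; `low` is the largest cutoff at
#' which ruling out by "score < low" keeps at least the target fraction of
#' positives while ruling out at least one negative. When the classes
#' separate completely the two cross; they are then clamped to their
#' midpoint (empty gray zone) with a warning.
#'
#' @inheritParams roc_auc
#' @param target_spec Target specificity for each side. Default 0.95.
#' @return One-row tibble: `low`, `high` (clamped so `low <= high`),
#'   `low_raw`, `high_raw` (the unclamped optima; `low_raw > high_raw`
#'   exactly when one cutoff meets both targets), `target_spec`.
#' @export
dual_thresholds <- function(scores, labels, target_spec = 0.95) {
  labels <- as_positive(labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  if (length(pos) == 0 || length(neg) == 0) {
    stop("dual_thresholds needs both classes present", call. = FALSE)
  }
  cand <- sort(unique(scores))

  spec_at <- vapply(cand, function(c) mean(neg <= c), numeric(1))
  feasible_high <- spec_at >= target_spec &
    vapply(cand, function(c) any(pos > c), logical(1))
  if (!any(feasible_high)) {
    stop(sprintf(paste0("rule-in target specificity %.3f unattainable; ",
                        "achievable maximum with nonzero sensitivity is %.3f"),
                 target_spec,
                 max(c(0, spec_at[vapply(cand, function(c) any(pos > c),
                                         logical(1))]))),
         call. = FALSE)
  }
  high <- min(cand[feasible_high])

  keep_at <- vapply(cand, function(c) mean(pos >= c), numeric(1))
  feasible_low <- keep_at >= target_spec &
    vapply(cand, function(c) any(neg < c), logical(1))
  if (!any(feasible_low)) {
    stop(sprintf(paste0("rule-out target %.3f unattainable; achievable ",
                        "maximum with nonzero rule-out rate is %.3f"),
                 target_spec,
                 max(c(0, keep_at[vapply(cand, function(c) any(neg < c),
                                         logical(1))]))),
         call. = FALSE)
  }
  low <- max(cand[feasible_low])

  low_raw <- low
  high_raw <- high
  if (low > high) {
    mid <- (low + high) / 2
    warning(sprintf(paste0("rule-out cutoff %.4f exceeds rule-in cutoff ",
                           "%.4f (a single cutoff meets both targets); ",
                           "clamped to %.4f, gray zone empty"),
                    low, high, mid),
            call. = FALSE)
    low <- high <- mid
  }
  tibble::tibble(low = low, high = high, low_raw = low_raw,
                 high_raw = high_raw, target_spec = target_spec)
}

#' Diagnostic metrics at a score cutoff
#'
#' Sensitivity and specificity of "score > cutoff => positive" with exact
#' binomial (Clopper-Pearson) confidence intervals, and the positive and
#' negative likelihood ratios. `lr_pos` is infinite at perfect specificity
#' (flagged via `lr_pos_infinite`).
#'
#' @inheritParams roc_auc
#' @param cutoff Score cutoff (strict `>` calls positive).
#' @param conf_level Confidence level for the binomial CIs. Default 0.95.
#' @return One-row tibble with counts, sensitivity/specificity (+ CIs),
#'   `lr_pos`, `lr_neg`, `lr_pos_infinite`.
#' @export
diagnostic_metrics <- function(scores, labels, cutoff, conf_level = 0.95) {
  labels <- as_positive(labels)
  if (!any(labels) || all(labels)) {
    stop("diagnostic_metrics needs both classes present", call. = FALSE)
  }
  called <- scores > cutoff
  tp <- sum(called & labels); fn <- sum(!called & labels)
  fp <- sum(called & !labels); tn <- sum(!called & !labels)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  sens_ci <- stats::binom.test(tp, tp + fn,
                               conf.level = conf_level)$conf.int
  spec_ci <- stats::binom.test(tn, tn + fp,
                               conf.level = conf_level)$conf.int
  tibble::tibble(
    cutoff = cutoff, tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = sens, sens_ci_low = sens_ci[1], sens_ci_high = sens_ci[2],
    specificity = spec, spec_ci_low = spec_ci[1], spec_ci_high = spec_ci[2],
    lr_pos = if (spec == 1) Inf else sens / (1 - spec),
    lr_neg = (1 - sens) / spec,
    lr_pos_infinite = spec == 1
  )
}

#' The published robustness design
#'
#' The five train:validation size tuples (pMMR-dMMR counts) of the
#' shrinking-sample-size experiment.
#'
#' @return A tibble with `label`, `train_stable`, `train_unstable`,
#'   `val_stable`, `val_unstable`.
#' @export
robustness_design <- function() {
  tibble::tribble(
    ~label,          ~train_stable, ~train_unstable, ~val_stable, ~val_unstable,
    "20-10:20-10",   20L,           10L,             20L,         10L,
    "20-10:10-5",    20L,           10L,             10L,         5L,
    "20-20:10-10",   20L,           20L,             10L,         10L,
    "40-20:20-10",   40L,           20L,             20L,         10L,
    "45-16:43-15",   45L,           16L,             43L,         15L
  )
}

#' Robustness of the sample-level AUC to training-set size
#'
#' For each design row and each simulation: draw the stated pMMR/dMMR
#' counts without replacement for the training and validation sets, train a
#' bundle, score the untouched remainder of the cohort with the combined
#' voting model, and record the AUC against the truth labels. Deterministic
#' per seed; infeasible sizes are skipped with a warning.
#'
#' @param cohort Labelled cohort tibble with `features`
#'   ([cohort_features()]).
#' @param panel Panel tibble.
#' @param design Design tibble as from [robustness_design()] (any subset).
#' @param n_sim Simulations per design row.
#' @param config An [msi_config()].
#' @param seed Integer seed.
#' @return Tibble with `label`, `sim`, `n_test`, `auc` (one row per
#'   simulation).
#' @export
bootstrap_robustness <- function(cohort, panel, design = robustness_design(),
                                 n_sim = 50L, config = msi_config(),
                                 seed = 1L) {
  stopifnot(n_sim >= 1)
  rows <- list()
  for (d in seq_len(nrow(design))) {
    dd <- design[d, ]
    need_stable <- dd$train_stable + dd$val_stable
    need_unstable <- dd$train_unstable + dd$val_unstable
    n_stable <- sum(cohort$label == "pMMR")
    n_unstable <- sum(cohort$label == "dMMR")
    if (need_stable >= n_stable || need_unstable >= n_unstable) {
      warning("design '", dd$label, "' infeasible for this cohort (needs ",
              need_stable, " pMMR + ", need_unstable,
              " dMMR plus a nonempty test remainder); skipped",
              call. = FALSE)
      next
    }
    for (s in seq_len(n_sim)) {
      sim_seed <- (seed * 10007L + d * 101L + s) %% .Machine$integer.max
      old <- .Random.seed_save()
      set.seed(sim_seed)
      st <- sample(cohort$sample_id[cohort$label == "pMMR"], need_stable)
      un <- sample(cohort$sample_id[cohort$label == "dMMR"], need_unstable)
      .Random.seed_restore(old)
      split <- c(
        stats::setNames(rep("train", dd$train_stable),
                        st[seq_len(dd$train_stable)]),
        stats::setNames(rep("validation", dd$val_stable),
                        st[dd$train_stable + seq_len(dd$val_stable)]),
        stats::setNames(rep("train", dd$train_unstable),
                        un[seq_len(dd$train_unstable)]),
        stats::setNames(rep("validation", dd$val_unstable),
                        un[dd$train_unstable + seq_len(dd$val_unstable)])
      )
      test_ids <- setdiff(cohort$sample_id, names(split))
      split <- c(split, stats::setNames(rep("test", length(test_ids)),
                                        test_ids))
      cfg <- config
      cfg$seed <- as.integer(sim_seed)
      auc <- tryCatch({
        bundle <- suppressWarnings(msi_train(cohort, panel, cfg,
                                             split = split))
        test <- cohort[cohort$sample_id %in% test_ids, , drop = FALSE]
        scored <- predict_cohort(test, bundle)
        roc_auc(scored$score_combined, scored$label)
      }, error = function(e) {
        warning("design '", dd$label, "' sim ", s, " failed: ",
                conditionMessage(e), call. = FALSE)
        NA_real_
      })
      rows[[length(rows) + 1L]] <- tibble::tibble(
        label = dd$label, sim = s, n_test = length(test_ids), auc = auc)
    }
  }
  dplyr::bind_rows(rows)
}
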