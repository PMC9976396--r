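# Per-locus model training: ridge logistic regression and a support-vector
# classifier, trained on max-normalized indel-length profiles against
# sample-level dMMR/pMMR labels (each locus inherits its sample's label).
# Hyperparameters by grid search with shared stratified k-fold CV; loci are
# auto-selected first by training coverage, then by validation AUC of both
# models.

C_GRID <- c(0.01, 0.1, 1, 10, 100)

#' Split a labelled cohort into train / validation / test subsets
#'
#' Random stratified split into three subsets whose total sizes differ by at
#' most one; per-class remainders go to distinct subsets (train first) so the
#' overall sizes balance. Deterministic for a fixed seed.
#'
#' @param cohort Tibble with `sample_id` and `label` columns
#'   ("pMMR"/"dMMR").
#' @param seed Integer seed.
#' @return The cohort tibble with a `subset` column
#'   ("train"/"validation"/"test").
#' @export
split_cohort <- function(cohort, seed = 1L) {
  stopifnot(all(cohort$label %in% c("pMMR", "dMMR")))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  subsets <- c("train", "validation", "test")
  assignment <- stats::setNames(rep(NA_character_, nrow(cohort)),
                                cohort$sample_id)
  rotation <- 0L
  for (lab in c("pMMR", "dMMR")) {
    ids <- sample(cohort$sample_id[cohort$label == lab])
    n <- length(ids)
    base <- n %/% 3L
    rem <- n %% 3L
    counts <- rep.int(base, 3L)
    if (rem > 0) {
      extra <- ((rotation + seq_len(rem) - 1L) %% 3L) + 1L
      counts[extra] <- counts[extra] + 1L
      rotation <- (rotation + rem) %% 3L
    }
    assignment[ids] <- rep(subsets, counts)
  }
  out <- dplyr::mutate(cohort, subset = unname(assignment[.data$sample_id]))
  tab <- table(out$label, out$subset)
  if (any(tab == 0)) {
    stop("a class is absent from at least one subset; ",
         "a larger cohort is needed (>= 3 samples per class)", call. = FALSE)
  }
  out
}

# Long per-locus view of a cohort with features: sample_id, label, locus,
# evaluable, profile (list).
cohort_long <- function(cohort) {
  rows <- purrr::pmap(cohort[, c("sample_id", "label", "features")],
                      function(sample_id, label, features) {
    tibble::tibble(sample_id = sample_id, label = label,
                   locus = features$locus, evaluable = features$evaluable,
                   profile = features$profile)
  })
  dplyr::bind_rows(rows)
}

#' Select loci by training-set coverage
#'
#' A locus passes when it is evaluable (post-cleaning depth at or above
#' `min_depth`) in at least `coverage_fraction` of training samples
#' (boundary inclusive).
#'
#' @param train Cohort tibble (rows restricted to the training subset) with
#'   a `features` list-column.
#' @param panel Panel tibble.
#' @param config An [msi_config()].
#' @return Tibble with `locus`, `coverage`, `coverage_pass`.
#' @export
select_loci_by_coverage <- function(train, panel, config = msi_config()) {
  stopifnot(nrow(train) > 0)
  long <- cohort_long(train)
  cov <- long |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(coverage = sum(.data$evaluable) / nrow(train),
                     .groups = "drop")
  out <- tibble::tibble(locus = panel$name) |>
    dplyr::left_join(cov, by = "locus") |>
    dplyr::mutate(coverage = dplyr::coalesce(.data$coverage, 0),
                  coverage_pass = .data$coverage >= config$coverage_fraction)
  if (!any(out$coverage_pass)) {
    stop("panel incompatible with data: no locus passes the coverage filter",
         call. = FALSE)
  }
  out
}

# Stratified fold assignment over the training samples, shared by all model
# kinds and loci; a locus's evaluable subset keeps the global fold ids.
assign_folds <- function(train, kfold, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  fold <- stats::setNames(rep(NA_integer_, nrow(train)), train$sample_id)
  for (lab in unique(train$label)) {
    ids <- sample(train$sample_id[train$label == lab])
    fold[ids] <- rep_len(seq_len(kfold), length(ids))
  }
  fold
}

balanced_weights <- function(y) {
  tab <- table(y)
  n <- length(y)
  as.numeric(n / (length(tab) * tab[as.character(y)]))
}

locus_design <- function(long, locus_name) {
  rows <- long[long$locus == locus_name & long$evaluable, , drop = FALSE]
  X <- do.call(rbind, rows$profile)
  rownames(X) <- rows$sample_id
  y <- factor(ifelse(rows$label == "dMMR", "unstable", "stable"),
              levels = c("stable", "unstable"))
  list(X = X, y = y, sample_id = rows$sample_id)
}

# Mean cross-validated AUC of score columns; scores is a function(fit, X)
# only evaluated out-of-fold. Folds with a single class are skipped.
cv_auc <- function(X, y, fold, fit_fun, score_fun) {
  aucs <- c()
  for (f in sort(unique(fold))) {
    tr <- fold != f
    if (length(unique(y[!tr])) < 2 || length(unique(y[tr])) < 2) next
    fit <- fit_fun(X[tr, , drop = FALSE], y[tr])
    sc <- score_fun(fit, X[!tr, , drop = FALSE])
    aucs <- rbind(aucs, apply(as.matrix(sc), 2, function(s)
      roc_auc(s, y[!tr] == "unstable")))
  }
  if (is.null(aucs)) return(NULL)
  colMeans(as.matrix(aucs))
}

# --- model kinds --------------------------------------------------------

# Index of the best grid point: maximal CV AUC, ties broken toward the
# canonical moderate regularization (C closest to 1, then grid order). With
# small separable training sets every grid point ranks perfectly; the
# extreme points then give degenerate decision boundaries whose binary
# calls are noise, while AUC cannot tell them apart.
pick_best <- function(cv, pref_order) {
  if (all(is.na(cv))) return(pref_order[1])
  top <- which(cv == max(cv, na.rm = TRUE))
  pref_order[pref_order %in% top][1]
}

fit_logreg <- function(X, y, fold) {
  # lambda decreasing <=> C_GRID ascending, index-aligned with C_GRID
  lambda_grid <- 1 / (sort(C_GRID) * nrow(X))
  fit_fun <- function(Xt, yt) {
    # small CV folds trip glmnet's small-class nuisance warning
    suppressWarnings(
      glmnet::glmnet(Xt, yt, family = "binomial", alpha = 0,
                     lambda = lambda_grid, weights = balanced_weights(yt),
                     standardize = FALSE))
  }
  score_fun <- function(fit, Xv) {
    stats::predict(fit, Xv, s = lambda_grid, type = "link")
  }
  mean_auc <- cv_auc(X, y, fold, fit_fun, score_fun)
  pref <- order(abs(log10(sort(C_GRID))))
  best <- if (is.null(mean_auc)) pref[1] else pick_best(mean_auc, pref)
  final <- fit_fun(X, y)
  structure(list(kind = "logreg", fit = final,
                 lambda = lambda_grid[best], lambda_grid = lambda_grid,
                 cv_auc = mean_auc),
            class = "msi_locus_model")
}

fit_svc <- function(X, y, fold) {
  grid <- expand.grid(kernel = c("linear", "radial"), cost = C_GRID,
                      stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$kernel, c("linear", "radial")), grid$cost), ]
  wts <- function(yt) {
    tab <- table(yt)
    stats::setNames(length(yt) / (length(tab) * as.numeric(tab)), names(tab))
  }
  cv <- vapply(seq_len(nrow(grid)), function(i) {
    fit_fun <- function(Xt, yt) {
      e1071::svm(Xt, yt, kernel = grid$kernel[i], cost = grid$cost[i],
                 class.weights = wts(yt), scale = FALSE)
    }
    score_fun <- function(fit, Xv) svm_decision_unstable(fit, Xv)
    a <- cv_auc(X, y, fold, fit_fun, score_fun)
    if (is.null(a)) NA_real_ else a
  }, numeric(1))
  pref <- order(abs(log10(grid$cost)),
                match(grid$kernel, c("linear", "radial")))
  best <- pick_best(cv, pref)
  final <- e1071::svm(X, y, kernel = grid$kernel[best], cost = grid$cost[best],
                      class.weights = wts(y), scale = FALSE)
  structure(list(kind = "svc", fit = final, kernel = grid$kernel[best],
                 cost = grid$cost[best], cv_auc = cv, grid = grid),
            class = "msi_locus_model")
}

# Orientation-corrected decision values: higher = more unstable.
svm_decision_unstable <- function(fit, X) {
  pred <- stats::predict(fit, X, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  sgn <- if (startsWith(colnames(dv)[1], "unstable")) 1 else -1
  as.numeric(dv[, 1]) * sgn
}

# Optional model zoo (never enters bundles): outlier methods trained on
# stable samples only, plus supervised alternatives.
fit_zoo <- function(X, y, fold, kind) {
  switch(kind,
    oneclass_svm = {
      Xs <- X[y == "stable", , drop = FALSE]
      fit <- e1071::svm(Xs, y = NULL, type = "one-classification",
                        nu = 0.1, scale = FALSE)
      structure(list(kind = kind, fit = fit), class = "msi_locus_model")
    },
    naive_bayes = {
      fit <- e1071::naiveBayes(as.data.frame(X), y)
      structure(list(kind = kind, fit = fit), class = "msi_locus_model")
    },
    random_forest = {
      if (!requireNamespace("randomForest", quietly = TRUE)) {
        stop("randomForest not installed", call. = FALSE)
      }
      fit <- randomForest::randomForest(X, y, ntree = 500)
      structure(list(kind = kind, fit = fit), class = "msi_locus_model")
    },
    stop("unknown model kind: ", kind, call. = FALSE)
  )
}

#' Continuous instability score of a fitted locus model
#'
#' Higher scores mean more evidence for instability; the scale is
#' model-specific (log-odds, decision values, probabilities).
#'
#' @param model An `msi_locus_model`.
#' @param X Profile matrix (rows = samples).
#' @return Numeric vector of scores.
#' @export
model_scores <- function(model, X) {
  switch(model$kind,
    logreg = as.numeric(stats::predict(model$fit, X, s = model$lambda,
                                       type = "link")),
    svc = svm_decision_unstable(model$fit, X),
    oneclass_svm = {
      pred <- stats::predict(model$fit, X, decision.values = TRUE)
      -as.numeric(attr(pred, "decision.values")[, 1])
    },
    naive_bayes = stats::predict(model$fit, as.data.frame(X),
                                 type = "raw")[, "unstable"],
    random_forest = stats::predict(model$fit, X,
                                   type = "prob")[, "unstable"],
    stop("unknown model kind: ", model$kind, call. = FALSE)
  )
}

#' Binary stable/unstable call of a fitted locus model
#'
#' The model's native class decision: probability >= 0.5 for logistic
#' regression and naive Bayes, decision-function side for (one-class) SVM,
#' majority vote for random forest.
#'
#' @inheritParams model_scores
#' @return Logical vector, `TRUE` = unstable.
#' @export
model_calls <- function(model, X) {
  switch(model$kind,
    logreg = as.numeric(stats::predict(model$fit, X, s = model$lambda,
                                       type = "link")) >= 0,
    svc = stats::predict(model$fit, X) == "unstable",
    oneclass_svm = !as.logical(stats::predict(model$fit, X)),
    naive_bayes = stats::predict(model$fit, as.data.frame(X)) == "unstable",
    random_forest = stats::predict(model$fit, X) == "unstable",
    stop("unknown model kind: ", model$kind, call. = FALSE)
  )
}

#' Train the per-locus models for one locus
#'
#' Grid search with shared stratified k-fold cross-validation on the
#' training set; supervised kinds see both classes, outlier kinds only
#' stable-labelled profiles.
#'
#' @param train Cohort tibble (training subset) with `features`.
#' @param locus_name Locus to train.
#' @param config An [msi_config()].
#' @param kinds Model kinds; the bundle pair is `c("logreg", "svc")`. Zoo
#'   kinds: "oneclass_svm", "naive_bayes", "random_forest".
#' @param folds Optional named fold vector from the internal shared
#'   assignment; computed from `config` when missing.
#' @return Named list of `msi_locus_model` objects.
#' @export
train_locus_models <- function(train, locus_name, config = msi_config(),
                               kinds = c("logreg", "svc"), folds = NULL) {
  long <- cohort_long(train)
  des <- locus_design(long, locus_name)
  if (min(table(des$y)) < config$kfold) {
    stop("locus '", locus_name, "': fewer than kfold (", config$kfold,
         ") evaluable training samples in a class", call. = FALSE)
  }
  if (is.null(folds)) folds <- assign_folds(train, config$kfold, config$seed)
  train_pair_from_design(des, folds, kinds)
}

train_pair_from_design <- function(des, folds, kinds) {
  fold <- unname(folds[des$sample_id])
  purrr::map(stats::setNames(kinds, kinds), function(kind) {
    switch(kind,
      logreg = fit_logreg(des$X, des$y, fold),
      svc = fit_svc(des$X, des$y, fold),
      fit_zoo(des$X, des$y, fold, kind))
  })
}

#' Validation AUC of fitted locus models
#'
#' @param models Named list of `msi_locus_model`s for one locus.
#' @param validation Cohort tibble (validation subset) with `features`.
#' @param locus_name Locus name.
#' @return Named numeric vector of AUCs, or `NULL` (with a warning) when the
#'   validation set has a single class at this locus.
#' @export
evaluate_locus_auc <- function(models, validation, locus_name) {
  long <- cohort_long(validation)
  evaluate_auc_from_long(models, long, locus_name)
}

evaluate_auc_from_long <- function(models, long, locus_name) {
  des <- locus_design(long, locus_name)
  if (length(unique(des$y)) < 2) {
    warning("locus '", locus_name,
            "': single-class validation set, AUC undefined; locus dropped",
            call. = FALSE)
    return(NULL)
  }
  vapply(models, function(m)
    roc_auc(model_scores(m, des$X), des$y == "unstable"), numeric(1))
}

#' Final locus selection by dual-model validation AUC
#'
#' A locus is retained iff it passed coverage and *both* models reach
#' `locus_auc_min` (inclusive) on the validation set.
#'
#' @param pairs Tibble with `locus`, `coverage_pass`, `auc_logreg`,
#'   `auc_svc`.
#' @param config An [msi_config()].
#' @return The tibble with a `retained` column.
#' @export
select_final_loci <- function(pairs, config = msi_config()) {
  dplyr::mutate(pairs, retained = .data$coverage_pass &
                  !is.na(.data$auc_logreg) & !is.na(.data$auc_svc) &
                  pmin(.data$auc_logreg, .data$auc_svc) >= config$locus_auc_min)
}

#' Train a complete model bundle on a labelled cohort
#'
#' Runs the full training pipeline: stratified train/validation/test split
#' (unless `split` is supplied), coverage-based locus selection on the
#' training set, per-locus grid-searched logistic-regression + SVC fits,
#' validation-AUC locus selection, and packaging of the fitted pairs with
#' the stable-sample baseline profiles used for plotting.
#'
#' @param cohort Tibble with `sample_id`, `label`, `features` (from
#'   [cohort_features()] or built from [extract_sample()] outputs).
#' @param panel Panel tibble.
#' @param config An [msi_config()].
#' @param split Optional precomputed `subset` assignment (character vector
#'   named by sample_id with values train/validation/test). By default
#'   [split_cohort()] with `config$seed`.
#' @return An object of class `msi_bundle`.
#' @export
msi_train <- function(cohort, panel, config = msi_config(), split = NULL) {
  if (is.null(split)) {
    cohort <- split_cohort(cohort, config$seed)
  } else {
    stopifnot(all(cohort$sample_id %in% names(split)))
    cohort$subset <- unname(split[cohort$sample_id])
  }
  train <- cohort[cohort$subset == "train", , drop = FALSE]
  validation <- cohort[cohort$subset == "validation", , drop = FALSE]

  coverage <- select_loci_by_coverage(train, panel, config)
  folds <- assign_folds(train, config$kfold, config$seed)
  train_long <- cohort_long(train)
  val_long <- cohort_long(validation)

  pair_rows <- list()
  models <- list()
  for (locus_name in coverage$locus[coverage$coverage_pass]) {
    des <- locus_design(train_long, locus_name)
    n_st <- sum(des$y == "stable")
    n_un <- sum(des$y == "unstable")
    if (min(n_st, n_un) < config$kfold) {
      warning("locus '", locus_name, "' skipped: a class has fewer than ",
              config$kfold, " evaluable training samples", call. = FALSE)
      next
    }
    fitted <- train_pair_from_design(des, folds, c("logreg", "svc"))
    aucs <- evaluate_auc_from_long(fitted, val_long, locus_name)
    if (is.null(aucs)) next
    models[[locus_name]] <- fitted
    pair_rows[[locus_name]] <- tibble::tibble(
      locus = locus_name, n_train_stable = n_st, n_train_unstable = n_un,
      auc_logreg = aucs[["logreg"]], auc_svc = aucs[["svc"]])
  }
  if (length(pair_rows) == 0) {
    stop("no locus could be trained and validated", call. = FALSE)
  }
  pairs <- coverage |>
    dplyr::left_join(dplyr::bind_rows(pair_rows), by = "locus") |>
    select_final_loci(config)
  if (!any(pairs$retained)) {
    stop("no locus retained: all below the AUC threshold of ",
         config$locus_auc_min, call. = FALSE)
  }

  # Stable training-sample profiles per retained locus, for audit plots.
  baselines <- purrr::map(
    stats::setNames(pairs$locus[pairs$retained], pairs$locus[pairs$retained]),
    function(locus_name) {
      rows <- train_long[train_long$locus == locus_name &
                           train_long$evaluable &
                           train_long$label == "pMMR", , drop = FALSE]
      m <- do.call(rbind, rows$profile)
      if (!is.null(m)) rownames(m) <- rows$sample_id
      m
    })

  structure(list(
    panel = panel,
    config = config,
    pairs = pairs,
    models = models[pairs$locus[pairs$retained]],
    baselines = baselines,
    split = cohort[, c("sample_id", "label", "subset")],
    version = as.character(utils::packageVersion("msivote")),
    seed = config$seed
  ), class = "msi_bundle")
}

#' @exportS3Method base::print
print.msi_bundle <- function(x, ...) {
  cat("<msi_bundle> version", x$version, "seed", x$seed, "\n")
  cat("  panel:", nrow(x$panel), "loci;", sum(x$pairs$retained),
      "retained\n")
  cat("  split:", paste(sprintf("%s=%d", names(table(x$split$subset)),
                                table(x$split$subset)), collapse = " "), "\n")
  invisible(x)
}
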