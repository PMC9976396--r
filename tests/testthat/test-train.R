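# Cohort splitting, locus selection, per-locus model fitting, bundle
# persistence.

make_labeled_cohort <- function(n_stable, n_unstable) {
  tibble::tibble(
    sample_id = sprintf("S%03d", seq_len(n_stable + n_unstable)),
    label = c(rep("pMMR", n_stable), rep("dMMR", n_unstable)))
}

# Cohort with hand-built profiles: stable samples peak at offset 0,
# unstable at `shift`; optionally a locus is non-evaluable in some samples.
separable_cohort <- function(n_stable, n_unstable, panel, shift = -6L,
                             window = 20L, noise_sd = 0.02, seed = 1) {
  set.seed(seed)
  cohort <- make_labeled_cohort(n_stable, n_unstable)
  cohort$features <- purrr::map(cohort$label, function(lab) {
    profs <- purrr::map(seq_len(nrow(panel)), function(i) {
      v <- stats::setNames(numeric(2 * window + 1),
                           as.character(-window:window))
      peak <- if (lab == "dMMR") as.character(shift) else "0"
      v[peak] <- 1
      v["1"] <- min(1, abs(stats::rnorm(1, 0.2, noise_sd)))
      v
    })
    feature_tbl <- tibble::tibble(
      locus = panel$name, depth_raw = 100L, depth = 100L, evaluable = TRUE,
      distribution = list(tibble::tibble(length = integer(),
                                         count = integer())),
      profile = profs)
    feature_tbl
  })
  cohort
}

test_that("a 179-sample cohort splits 60/60/59, stratified and seeded", {
  cohort <- make_labeled_cohort(133, 46)
  s1 <- split_cohort(cohort, seed = 7)
  expect_equal(sort(as.vector(table(s1$subset))), c(59, 60, 60))
  tab <- table(s1$label, s1$subset)
  # every class present everywhere; per-class sizes within 1 of a third
  expect_true(all(tab > 0))
  expect_true(all(abs(tab["pMMR", ] - 133 / 3) <= 1))
  expect_true(all(abs(tab["dMMR", ] - 46 / 3) <= 1))
  # determinism
  expect_identical(s1, split_cohort(cohort, seed = 7))
  expect_false(identical(s1$subset, split_cohort(cohort, seed = 8)$subset))
})

test_that("the smallest balanced cohort splits one of each class per subset", {
  cohort <- make_labeled_cohort(3, 3)
  s <- split_cohort(cohort, seed = 1)
  tab <- table(s$label, s$subset)
  expect_true(all(tab == 1))
})

test_that("degenerate cohorts are refused with advice", {
  expect_error(split_cohort(make_labeled_cohort(5, 2), seed = 1),
               "larger cohort")
})

test_that("coverage selection uses the inclusive 75% boundary", {
  panel <- synthetic_panel(3, seed = 1)
  cohort <- make_labeled_cohort(80, 20)
  # locus 1 evaluable in 75/100, locus 2 in 74/100, locus 3 everywhere
  cohort$features <- purrr::map(seq_len(100), function(s) {
    tibble::tibble(
      locus = panel$name, depth_raw = 100L, depth = 100L,
      evaluable = c(s <= 75, s <= 74, TRUE),
      distribution = list(tibble::tibble()),
      profile = list(stats::setNames(numeric(41), as.character(-20:20))))
  })
  cov <- select_loci_by_coverage(cohort, panel, msi_config())
  expect_equal(cov$coverage_pass, c(TRUE, FALSE, TRUE))
  # raising coverage_fraction never grows the passing set
  for (cf in c(0.5, 0.74, 0.76, 0.9, 1)) {
    pass_lo <- select_loci_by_coverage(cohort, panel,
                                       msi_config(coverage_fraction = cf))
    if (cf > 0.75) expect_true(all(which(pass_lo$coverage_pass) %in%
                                     which(cov$coverage_pass)))
  }
  expect_error(select_loci_by_coverage(
    cohort[0, ], panel, msi_config()))
})

test_that("perfectly separable loci reach validation AUC 1 in both models", {
  panel <- synthetic_panel(2, seed = 2)
  cohort <- separable_cohort(45, 16, panel)
  cohort$subset <- "train"
  models <- train_locus_models(cohort, panel$name[1], msi_config())
  expect_named(models, c("logreg", "svc"))
  val <- separable_cohort(10, 5, panel, seed = 99)
  aucs <- evaluate_locus_auc(models, val, panel$name[1])
  expect_equal(unname(aucs), c(1, 1))
  # scores separate the classes on the training set itself
  des <- msivote:::locus_design(msivote:::cohort_long(cohort),
                                panel$name[1])
  sc <- model_scores(models$logreg, des$X)
  expect_gt(min(sc[des$y == "unstable"]), max(sc[des$y == "stable"]))
})

test_that("outlier models train on stable samples only", {
  panel <- synthetic_panel(1, seed = 3)
  cohort <- separable_cohort(45, 16, panel)
  cohort$subset <- "train"
  # poison the unstable profiles: if the one-class SVM ever saw them,
  # fitting would fail on the non-finite values
  cohort$features <- purrr::map2(cohort$features, cohort$label, function(f, lab) {
    if (lab == "dMMR") f$profile <- purrr::map(f$profile, function(p) p * NaN)
    f
  })
  models <- train_locus_models(cohort, panel$name[1], msi_config(),
                               kinds = "oneclass_svm")
  expect_s3_class(models$oneclass_svm, "msi_locus_model")
  # and it flags a clearly shifted profile as an outlier
  shifted <- stats::setNames(numeric(41), as.character(-20:20))
  shifted["-6"] <- 1
  expect_true(model_calls(models$oneclass_svm, matrix(shifted, 1)))
})

test_that("too few evaluable samples in a class aborts the locus", {
  panel <- synthetic_panel(1, seed = 4)
  cohort <- separable_cohort(6, 2, panel)
  cohort$subset <- "train"
  expect_error(train_locus_models(cohort, panel$name[1],
                                  msi_config(kfold = 3)),
               "fewer than kfold")
})

test_that("final locus selection needs both AUCs at or above the threshold", {
  pairs <- tibble::tibble(
    locus = c("a", "b", "c", "d"),
    coverage_pass = c(TRUE, TRUE, TRUE, FALSE),
    auc_logreg = c(0.60, 0.59, 0.95, 0.99),
    auc_svc = c(0.85, 0.99, 0.95, 0.99))
  sel <- select_final_loci(pairs, msi_config())
  expect_equal(sel$retained, c(TRUE, FALSE, TRUE, FALSE))
  # monotonicity: a stricter AUC floor never grows the retained set
  stricter <- select_final_loci(pairs, msi_config(locus_auc_min = 0.9))
  expect_true(all(which(stricter$retained) %in% which(sel$retained)))
})

test_that("locus training vectors inherit their sample's label", {
  panel <- synthetic_panel(2, seed = 5)
  cohort <- separable_cohort(5, 4, panel)
  long <- msivote:::cohort_long(cohort)
  des <- msivote:::locus_design(long, panel$name[2])
  lab <- cohort$label[match(des$sample_id, cohort$sample_id)]
  expect_equal(des$y == "unstable", lab == "dMMR", ignore_attr = TRUE)
})

test_that("bundles round-trip through disk with identical predictions", {
  panel <- synthetic_panel(6, seed = 6)
  cohort <- simulate_cohort(panel, 15, 9, sim_params(depth_mean = 120),
                            seed = 17)
  cf <- cohort_features(cohort, panel, msi_config(seed = 17))
  bundle <- msi_train(cf, panel, msi_config(seed = 17))
  dir <- withr::local_tempdir()
  save_bundle(bundle, dir)

  loaded <- load_bundle(dir)
  expect_equal(loaded$pairs, bundle$pairs)
  # identical calls on probe vectors
  probes <- cf$features[1:10]
  for (i in seq_along(probes)) {
    a <- predict_features(probes[[i]], bundle, "p")
    b <- predict_features(probes[[i]], loaded, "p")
    expect_identical(a$calls, b$calls)
    expect_identical(a$classification, b$classification)
  }
  # manifest lists the retained locus count
  manifest <- msivote:::read_manifest(file.path(dir, "manifest.txt"))
  expect_equal(as.integer(manifest[["n_loci_retained"]]),
               sum(bundle$pairs$retained))

  # tampered manifest version -> hard load error
  lines <- readLines(file.path(dir, "manifest.txt"))
  lines[1] <- "bundle_version=99.99.99"
  writeLines(lines, file.path(dir, "manifest.txt"))
  expect_error(load_bundle(dir), "version mismatch")
})
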