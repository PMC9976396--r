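# Audit plots: per-locus indel-length profiles of a sample against the
# envelope of stable (pMMR) training samples, plus bundle/result overviews.

#' Plot one locus profile against the stable baseline
#'
#' The bundle's stable training profiles form a background envelope
#' (min-max ribbon and mean line); the sample profile is overlaid. An MSI
#' shift appears as sample mass left of the envelope. Non-evaluable loci
#' yield a placeholder noting insufficient depth.
#'
#' @param features Feature tibble for one sample.
#' @param bundle The `msi_bundle` used for prediction (source of the
#'   baseline profiles).
#' @param locus_name Locus to plot.
#' @return A ggplot object.
#' @export
plot_locus_profile <- function(features, bundle, locus_name) {
  window <- bundle$config$window
  offsets <- seq.int(-window, window)

  profile <- NULL
  i <- match(locus_name, features$locus)
  if (!is.na(i) && features$evaluable[i]) profile <- features$profile[[i]]

  base <- bundle$baselines[[locus_name]]
  p <- ggplot2::ggplot() +
    ggplot2::labs(title = locus_name, x = "length offset (bases)",
                  y = "normalized read depth") +
    ggplot2::theme_minimal()

  if (is.null(profile)) {
    return(p + ggplot2::annotate("text", x = 0, y = 0.5,
                                 label = "insufficient depth") +
             ggplot2::ylim(0, 1))
  }
  if (is.null(base) || nrow(base) == 0) {
    warning("locus '", locus_name, "': empty baseline, plotting sample alone",
            call. = FALSE)
  } else {
    env <- tibble::tibble(offset = offsets,
                          lo = apply(base, 2, min),
                          hi = apply(base, 2, max),
                          mean = colMeans(base))
    p <- p +
      ggplot2::geom_ribbon(data = env,
                           ggplot2::aes(x = .data$offset, ymin = .data$lo,
                                        ymax = .data$hi),
                           fill = "grey70", alpha = 0.6) +
      ggplot2::geom_line(data = env,
                         ggplot2::aes(x = .data$offset, y = .data$mean),
                         colour = "grey35", linewidth = 0.4)
  }
  samp <- tibble::tibble(offset = offsets, value = as.numeric(profile))
  p +
    ggplot2::geom_line(data = samp,
                       ggplot2::aes(x = .data$offset, y = .data$value),
                       colour = "#C0392B") +
    ggplot2::geom_point(data = samp[samp$value > 0, ],
                        ggplot2::aes(x = .data$offset, y = .data$value),
                        colour = "#C0392B", size = 1)
}

#' Write the full per-locus plot report for a sample
#'
#' One image per retained locus plus an `index.html` page linking them.
#'
#' @param features Feature tibble of the sample.
#' @param bundle An `msi_bundle`.
#' @param out_dir Output directory.
#' @param format "png" or "svg".
#' @param sample_id Label used in filenames and the index.
#' @return `out_dir`, invisibly.
#' @export
plot_sample_report <- function(features, bundle, out_dir, format = "png",
                               sample_id = "sample") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  retained <- bundle$pairs$locus[bundle$pairs$retained]
  files <- character()
  for (locus_name in retained) {
    p <- plot_locus_profile(features, bundle, locus_name)
    file <- file.path(out_dir, paste0(sample_id, "_", locus_name, ".",
                                      format))
    ggplot2::ggsave(file, p, width = 5, height = 3.5, dpi = 120,
                    device = format)
    files <- c(files, basename(file))
  }
  index <- c("<html><body>",
             paste0("<h1>", sample_id, " locus profiles</h1>"),
             sprintf('<div><h3>%s</h3><img src="%s" width="480"/></div>',
                     retained, files),
             "</body></html>")
  writeLines(index, file.path(out_dir, "index.html"))
  invisible(out_dir)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Overview plot of a fitted bundle
#'
#' Validation AUC per locus and model, with the retention threshold.
#'
#' @param object An `msi_bundle`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.msi_bundle <- function(object, ...) {
  long <- object$pairs |>
    tidyr::pivot_longer(cols = c("auc_logreg", "auc_svc"),
                        names_to = "model", values_to = "auc",
                        names_prefix = "auc_")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$locus, y = .data$auc,
                               fill = .data$model,
                               alpha = .data$retained)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = object$config$locus_auc_min,
                        linetype = "dashed") +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.35),
                                guide = "none") +
    ggplot2::labs(x = NULL, y = "validation AUC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
}

#' Per-locus call plot of a sample result
#'
#' @param object An `msi_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.msi_result <- function(object, ...) {
  calls <- object$calls |>
    tidyr::pivot_longer(cols = c("call_logreg", "call_svc", "call_combined"),
                        names_to = "model", values_to = "unstable",
                        names_prefix = "call_")
  ggplot2::ggplot(calls,
                  ggplot2::aes(x = .data$locus, y = .data$model,
                               fill = .data$unstable)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "#C0392B", `FALSE` = "#2C7FB8"),
      na.value = "grey80", name = "unstable") +
    ggplot2::labs(title = sprintf("%s: %s (combined score %.3f)",
                                  object$sample_id, object$classification,
                                  object$score$score_combined),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
}
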