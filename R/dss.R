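#' Per-class mean spectra with pointwise 95% confidence bands
#'
#' Spectra must be baseline-subtracted and water-normalized before
#' averaging (see [subtract_baseline()] and [water_normalize()]); each class
#' needs at least two spectra. Spectra are resampled onto a common ppm grid
#' by linear interpolation if needed, then the pointwise mean of the real
#' part and a t-based confidence band are computed per class.
#'
#' @param spectra List of `mrs_spectrum` objects.
#' @param labels Character vector of class labels, one per spectrum.
#' @param ppm_grid Common ppm grid; default: axis of the first spectrum
#'   restricted to the overlap of all spectra.
#' @param conf_level Confidence level (0.95).
#' @param ci_method `"t"` for the pointwise t-interval (default) or
#'   `"bootstrap"` for a percentile bootstrap over subjects.
#' @param boot_n Bootstrap resamples.
#' @param check_normalized Require the `water_normalized` tag.
#' @return An `mrs_class_means` object: tibble with `class`, `ppm`, `mean`,
#'   `ci_lo`, `ci_hi`, `n`.
#' @export
mean_class_spectra <- function(spectra, labels, ppm_grid = NULL,
                               conf_level = 0.95,
                               ci_method = c("t", "bootstrap"),
                               boot_n = 400, check_normalized = TRUE) {
  ci_method <- match.arg(ci_method)
  stopifnot(length(spectra) == length(labels))
  if (check_normalized) {
    ok <- vapply(spectra, function(s) s$normalization == "water_normalized", TRUE)
    if (!all(ok)) abort("all spectra must be water-normalized before averaging")
  }
  tab <- table(labels)
  if (any(tab < 2)) {
    abort(paste0("class(es) with fewer than 2 spectra: ",
                 paste(names(tab)[tab < 2], collapse = ", ")))
  }
  if (is.null(ppm_grid)) {
    lo <- max(vapply(spectra, function(s) min(s$ppm), 0))
    hi <- min(vapply(spectra, function(s) max(s$ppm), 0))
    ppm_grid <- spectra[[1]]$ppm[spectra[[1]]$ppm >= lo & spectra[[1]]$ppm <= hi]
  }
  mat <- vapply(spectra, function(s) {
    stats::approx(s$ppm, Re(s$values), xout = ppm_grid, rule = 2)$y
  }, numeric(length(ppm_grid)))
  alpha <- 1 - conf_level
  out <- purrr::map_dfr(sort(unique(labels)), function(cl) {
    sub <- mat[, labels == cl, drop = FALSE]
    n <- ncol(sub)
    m <- rowMeans(sub)
    if (ci_method == "t") {
      se <- apply(sub, 1, sd) / sqrt(n)
      tcrit <- qt(1 - alpha / 2, df = n - 1)
      lo <- m - tcrit * se
      hi <- m + tcrit * se
    } else {
      boots <- vapply(seq_len(boot_n), function(b) {
        rowMeans(sub[, sample.int(n, n, replace = TRUE), drop = FALSE])
      }, numeric(nrow(sub)))
      lo <- pmin(apply(boots, 1, quantile, alpha / 2), m)
      hi <- pmax(apply(boots, 1, quantile, 1 - alpha / 2), m)
    }
    tibble(class = cl, ppm = ppm_grid, mean = m, ci_lo = lo, ci_hi = hi,
           n = n)
  })
  structure(out, class = c("mrs_class_means", class(out)))
}

dss_class_colours <- c(PA = "#2ca02c", EP = "#1f77b4", MB = "#17becf")

#' Plot per-class mean spectra
#'
#' @param object An `mrs_class_means`.
#' @param window_ppm Display window (0.5-4.3 ppm; ppm decreases rightward
#'   per MRS convention).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mrs_class_means <- function(object, window_ppm = c(0.5, 4.3), ...) {
  df <- filter(as_tibble(object), .data$ppm >= window_ppm[1],
               .data$ppm <= window_ppm[2])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ppm)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi, fill = .data$class),
      alpha = 0.3
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean, colour = .data$class)) +
    ggplot2::scale_x_reverse() +
    ggplot2::scale_colour_manual(values = dss_class_colours, na.value = "grey40") +
    ggplot2::scale_fill_manual(values = dss_class_colours, na.value = "grey70") +
    ggplot2::labs(x = "chemical shift (ppm)", y = "normalized intensity",
                  colour = "class", fill = "class") +
    ggplot2::theme_minimal()
}

#' Plot a single spectrum
#'
#' @param object An `mrs_spectrum`.
#' @param window_ppm Display window.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mrs_spectrum <- function(object, window_ppm = c(0.5, 4.3), ...) {
  df <- filter(tidy(object), .data$ppm >= window_ppm[1],
               .data$ppm <= window_ppm[2])
  ggplot2::ggplot(df, ggplot2::aes(.data$ppm, .data$real)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "chemical shift (ppm)", y = "intensity") +
    ggplot2::theme_minimal()
}

#' Plot DF scores with decision boundaries
#'
#' @param object An `mrs_lda`.
#' @param index_case Optional one-row tibble from [apply_lda()] marking an
#'   index case.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mrs_lda <- function(object, index_case = NULL, ...) {
  bnd <- decision_boundaries(object)
  p <- ggplot2::ggplot(object$train_scores,
                       ggplot2::aes(.data$DF1, .data$DF2)) +
    ggplot2::geom_path(data = bnd, ggplot2::aes(group = .data$pair),
                       colour = "grey40", linetype = 2, inherit.aes = TRUE) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$label), shape = 1, size = 2) +
    ggplot2::scale_colour_manual(values = dss_class_colours) +
    ggplot2::labs(x = "D.F. 1", y = "D.F. 2", colour = "class") +
    ggplot2::theme_minimal()
  if (!is.null(index_case)) {
    p <- p + ggplot2::geom_point(
      data = index_case,
      ggplot2::aes(.data$DF1, .data$DF2),
      colour = "red", size = 3, shape = 17
    )
  }
  p
}

#' Render the three-panel decision-support output for one case
#'
#' Produces the decision-support display: (left) the case's standardized
#' metabolite profile as bars — the exact z-scores the classifier consumed;
#' (centre) DF scores of the training cohort with decision boundaries and
#' the index case marked in red; (right) the index spectrum overlaid on the
#' per-class mean spectra with confidence bands. A machine-readable JSON
#' sidecar carries the posteriors, DF scores, nearest class and boundary
#' distance. Neither the model nor the case data are modified.
#'
#' @param case_features One-row data frame (or named vector) with the
#'   model's feature columns for the index case.
#' @param model An `mrs_lda`.
#' @param class_means An `mrs_class_means`.
#' @param case_spectrum The index `mrs_spectrum` (baseline-subtracted,
#'   water-normalized) for the overlay panel.
#' @param out_dir Output directory (created if needed).
#' @param case_id Identifier used in file names.
#' @param format `"png"` or `"svg"`.
#' @return Invisibly, a list with `figure`, `json` (file paths) and
#'   `result` (the [apply_lda()] row).
#' @export
render_dss <- function(case_features, model, class_means, case_spectrum,
                       out_dir, case_id = "case", format = c("png", "svg")) {
  format <- match.arg(format)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- apply_lda(model, case_features)

  z <- standardize_features(model, case_features)[1, ]
  prof <- tibble(feature = factor(model$features, levels = model$features),
                 z = as.numeric(z))
  p1 <- ggplot2::ggplot(prof, ggplot2::aes(.data$feature, .data$z)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "standardized concentration (z)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))

  p2 <- autoplot.mrs_lda(model, index_case = res)

  p3 <- autoplot.mrs_class_means(class_means) +
    ggplot2::geom_line(
      data = filter(tidy(case_spectrum), .data$ppm >= 0.5, .data$ppm <= 4.3),
      ggplot2::aes(.data$ppm, .data$real),
      colour = "red", inherit.aes = FALSE
    )

  fig <- patchwork::wrap_plots(p1, p2, p3, nrow = 1)
  fig_path <- file.path(out_dir, paste0(case_id, "_dss.", format))
  ggplot2::ggsave(fig_path, fig, width = 12, height = 4, dpi = 150)

  nearest <- res$predicted[1]
  sidecar <- list(
    case_id = case_id,
    posteriors = as.list(stats::setNames(
      as.numeric(res[1, paste0("post_", model$classes)]), model$classes
    )),
    df_scores = list(DF1 = res$DF1[1], DF2 = res$DF2[1]),
    nearest_class = nearest,
    boundary_distance = res$boundary_distance[1]
  )
  json_path <- file.path(out_dir, paste0(case_id, "_dss.json"))
  jsonlite::write_json(sidecar, json_path, auto_unbox = TRUE, digits = NA)
  invisible(list(figure = fig_path, json = json_path, result = res))
}
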