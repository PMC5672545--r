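# ggplot2 graphics for QC, differential expression and fitted curves.

#' Plot vehicle-control PCA scores
#'
#' @param qc A [qc_counts()] result (or a [control_pca()] result).
#' @return A ggplot.
#' @export
plot_control_pca <- function(qc) {
  pca <- if (inherits(qc, "crpod_qc")) qc$pca else qc
  if (is.null(pca)) stop("no control PCA available")
  ve <- round(100 * pca$var_explained[1:2], 1)
  ggplot2::ggplot(pca$scores, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::geom_point(size = 2, colour = "steelblue") +
    ggplot2::labs(x = paste0("PC1 (", ve[1], "%)"),
                  y = paste0("PC2 (", ve[2], "%)"),
                  title = "Vehicle controls: principal components") +
    ggplot2::theme_bw()
}

#' Histogram of control D statistics with the exclusion cut
#'
#' @param qc A [qc_counts()] result (or [d_statistic()] tibble).
#' @param sd_cut SD multiplier used for the cut line (default 3).
#' @return A ggplot.
#' @export
plot_d_statistic <- function(qc, sd_cut = 3) {
  d <- if (inherits(qc, "crpod_qc")) qc$d else qc
  ok <- !is.na(d$d)
  cut <- mean(d$d[ok]) - sd_cut * sd(d$d[ok])
  ggplot2::ggplot(d[ok, ], ggplot2::aes(.data$d)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = mean(d$d[ok]), linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = cut, colour = "red", linewidth = 0.8) +
    ggplot2::labs(x = "D statistic (mean correlation with other controls)",
                  y = "controls",
                  title = "Control D statistics (red: exclusion cut)") +
    ggplot2::theme_bw()
}

#' Plot per-chemical log2-fold-change PCA
#'
#' @param de A [de_max_dose()] result.
#' @return A ggplot.
#' @export
plot_l2fc_pca <- function(de) {
  pca <- l2fc_pca(de)
  ggplot2::ggplot(pca$scores, ggplot2::aes(.data$PC1, .data$PC2,
                                           label = .data$chemical)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(vjust = -0.8) +
    ggplot2::labs(title = "Chemicals in log2-fold-change space") +
    ggplot2::theme_bw()
}

#' Plot a fitted concentration-response curve with its POD
#'
#' Shows the series points, the winning model curve, the +/- BSD band and
#' the POD location.
#'
#' @param object A `crpod_fitset`.
#' @param bsd_multiplier Multiplier on the control SD.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.crpod_fitset <- function(object, bsd_multiplier = 1, ...) {
  s <- object$series
  fit <- object$fits[[object$winner]]
  pod <- pod_from_fit(object, bsd_multiplier = bsd_multiplier)
  grid <- seq(min(s$dose), max(s$dose), length.out = 200)
  sgn <- if (fit$model != "hill4" && fit$direction == "down") -1 else 1
  curve_df <- tibble::tibble(dose = grid,
                             response = sgn * cr_curve(fit$model, fit$params, grid))
  ggplot2::ggplot(s, ggplot2::aes(.data$dose, .data$response)) +
    ggplot2::geom_hline(yintercept = c(-1, 1) * pod$bsd, linetype = "dotted",
                        colour = "purple") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$is_control)) +
    ggplot2::geom_line(data = curve_df, colour = "black") +
    ggplot2::geom_vline(xintercept = pod$pod_log10, colour = "red",
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "darkgreen",
                                            `FALSE` = "orange"),
                                 labels = c(`TRUE` = "control",
                                            `FALSE` = "treatment"),
                                 name = NULL) +
    ggplot2::labs(x = "log10 concentration (uM)",
                  y = "centered log2 response",
                  title = paste0(attr(s, "gene") %||% "", " / ",
                                 attr(s, "chemical") %||% "",
                                 ": ", fit$model, " fit, POD = ",
                                 signif(pod$pod_log10, 3))) +
    ggplot2::theme_bw()
}

#' Boxplot of fitted PODs per chemical
#'
#' @param pods An [estimate_pods()] result.
#' @return A ggplot.
#' @export
plot_pod_summary <- function(pods) {
  df <- dplyr::filter(pods, .data$basis == "curve_crossing")
  ggplot2::ggplot(df, ggplot2::aes(.data$chemical, .data$pod_log10)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(x = NULL, y = "POD (log10 uM)",
                  title = "Fitted points of departure by chemical") +
    ggplot2::theme_bw()
}
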