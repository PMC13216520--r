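#' Elbow plot of the WSS curve
#'
#' @param curve Tibble from [wss_curve()].
#' @param k_selected Optional k to mark with a dashed reference line.
#' @return A ggplot object.
#' @export
plot_elbow <- function(curve, k_selected = NULL) {
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$k, y = .data$wss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = curve$k) +
    ggplot2::labs(x = "Number of clusters k",
                  y = "Total within-cluster sum of squares") +
    ggplot2::theme_minimal()
  if (!is.null(k_selected)) {
    p <- p + ggplot2::geom_vline(xintercept = as.numeric(k_selected),
                                 linetype = "dashed", colour = "red")
  }
  p
}

#' PCA biplot coloured by cluster label
#'
#' First two principal components of the hallmark profiles, with hallmark
#' loading arrows.
#'
#' @param pca A `hallmark_pca` object.
#' @param labels Optional tibble `sample_id`, `label`.
#' @param arrow_scale Multiplier applied to loading arrows.
#' @return A ggplot object.
#' @export
plot_pca <- function(pca, labels = NULL, arrow_scale = NULL) {
  sc <- pca$scores
  if (!is.null(labels)) {
    sc <- dplyr::left_join(sc, labels[, c("sample_id", "label")],
                           by = "sample_id")
  }
  ve <- round(100 * pca$var_explained[1:2], 1)
  p <- ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", ve[1]),
                  y = sprintf("PC2 (%.1f%%)", ve[2])) +
    ggplot2::theme_minimal()
  p <- if (!is.null(labels)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$label), alpha = 0.7)
  } else {
    p + ggplot2::geom_point(alpha = 0.7)
  }
  ld <- pca$loadings
  if (is.null(arrow_scale)) {
    arrow_scale <- 0.8 * max(abs(c(sc$PC1, sc$PC2))) /
      max(abs(as.matrix(ld[, c("PC1", "PC2")])))
  }
  p + ggplot2::geom_segment(
    data = ld,
    ggplot2::aes(x = 0, y = 0, xend = .data$PC1 * arrow_scale,
                 yend = .data$PC2 * arrow_scale),
    arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
    colour = "grey30"
  ) +
    ggplot2::geom_text(
      data = ld,
      ggplot2::aes(x = .data$PC1 * arrow_scale * 1.1,
                   y = .data$PC2 * arrow_scale * 1.1,
                   label = .data$hallmark),
      size = 2.7, colour = "grey30"
    )
}

#' Rank-ordered hallmark VAF curves per cluster
#'
#' Mean VAF (with standard-error bars) of each hallmark, ordered by its mean
#' rank within each cluster — the per-cluster acquisition-order view.
#'
#' @param profiles Ranked profile tibble.
#' @param labels Tibble `sample_id`, `label`.
#' @return A ggplot object (one panel per cluster).
#' @export
plot_hallmark_vaf <- function(profiles, labels) {
  dat <- dplyr::inner_join(profiles, labels[, c("sample_id", "label")],
                           by = "sample_id") |>
    dplyr::filter(!is.na(.data$mean_vaf)) |>
    dplyr::group_by(.data$label, .data$hallmark) |>
    dplyr::summarise(
      vaf = mean(.data$mean_vaf),
      se = sd(.data$mean_vaf) / sqrt(dplyr::n()),
      mean_rank = mean(.data$rank, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::group_by(.data$label) |>
    dplyr::arrange(.data$mean_rank, .by_group = TRUE) |>
    dplyr::mutate(order = dplyr::row_number()) |>
    dplyr::ungroup()
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$order, y = .data$vaf)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$vaf - .data$se,
                                        ymax = .data$vaf + .data$se),
                           width = 0.2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$hallmark),
                       angle = 45, hjust = 0, vjust = -0.8, size = 2.5) +
    ggplot2::facet_wrap(~label) +
    ggplot2::scale_x_continuous(breaks = 1:10) +
    ggplot2::labs(x = "Hallmark rank (1 = earliest)", y = "Mean VAF") +
    ggplot2::theme_minimal()
}

#' Dominant-signature count histogram per cluster
#'
#' Counts of patients per dominant signature and cluster, with significance
#' asterisks at adjusted p below `alpha` taken from the association table.
#'
#' @param calls Dominant-call tibble.
#' @param labels Tibble `sample_id`, `label`.
#' @param tests Optional tibble from [signature_cluster_tests()].
#' @param alpha Significance level for asterisks.
#' @return A ggplot object.
#' @export
plot_dominant_counts <- function(calls, labels, tests = NULL, alpha = 0.05) {
  dat <- dplyr::inner_join(calls, labels[, c("sample_id", "label")],
                           by = "sample_id") |>
    dplyr::count(.data$signature, .data$label)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$signature, y = .data$n,
                                         fill = .data$label)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Dominant signature", y = "Patients") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (!is.null(tests)) {
    sig <- tests$feature[tests$p_adj < alpha & !tests$degenerate]
    if (length(sig) > 0) {
      tops <- dat |>
        dplyr::group_by(.data$signature) |>
        dplyr::summarise(y = max(.data$n), .groups = "drop") |>
        dplyr::filter(.data$signature %in% sig)
      p <- p + ggplot2::geom_text(data = tops,
                                  ggplot2::aes(x = .data$signature,
                                               y = .data$y, label = "*"),
                                  inherit.aes = FALSE, size = 6, vjust = 0)
    }
  }
  p
}

#' Forest plot of odds ratios
#'
#' Odds ratios with confidence intervals on a log scale, an OR = 1 reference
#' line, and three-way colouring: significant EGI-association (OR < 1),
#' significant LGI-association (OR > 1), or non-significant.
#'
#' @param assoc Association tibble from [feature_association_table()].
#' @param alpha Significance level.
#' @return A ggplot object.
#' @export
plot_forest <- function(assoc, alpha = 0.05) {
  if (nrow(assoc) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0, label = "no associations") +
             ggplot2::theme_void())
  }
  dat <- assoc |>
    dplyr::mutate(class = dplyr::case_when(
      .data$p_adj < alpha & .data$estimate < 1 ~ "EGI (significant)",
      .data$p_adj < alpha & .data$estimate > 1 ~ "LGI (significant)",
      TRUE ~ "not significant"
    ))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$estimate,
                                    y = stats::reorder(.data$feature,
                                                       .data$estimate),
                                    colour = .data$class)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "red") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lo,
                                         xmax = .data$ci_hi), height = 0.2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(
      "EGI (significant)" = "black",
      "LGI (significant)" = "grey55",
      "not significant" = "red"
    )) +
    ggplot2::labs(x = "Odds ratio (LGI vs EGI)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
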