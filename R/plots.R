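#' Plot a fitted dose-response curve over its data
#'
#' @param object A converged `dr_fit`.
#' @param ... Unused.
#' @return A ggplot: observed viabilities and the fitted 4PL curve on a
#'   log-dose axis, with the IC50 marked.
#' @exportS3Method ggplot2::autoplot
autoplot.dr_fit <- function(object, ...) {
  if (!isTRUE(object$converged)) abort("cannot plot a non-converged fit.")
  rng <- range(object$data$dose)
  curve <- tibble(dose = 10^seq(log10(rng[1]), log10(rng[2]), length.out = 200))
  curve$viability <- predict(object, curve$dose)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$dose, y = .data$viability)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = curve, color = "#2166ac") +
    ggplot2::geom_vline(xintercept = object$ic50, linetype = "dashed",
                        color = "grey40") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose (uM)", y = "relative viability",
                  title = sprintf("4PL fit: IC50 = %.3g uM, hill = %.2f",
                                  object$ic50, object$hill)) +
    ggplot2::theme_minimal()
}

#' Heatmap of Bliss indices for a combination screen
#'
#' @param object A `synergy_matrix`.
#' @param ... Unused.
#' @return A ggplot tile heatmap of BI per pair (upper triangle), white at
#'   additivity (BI = 1) and red toward synergy.
#' @exportS3Method ggplot2::autoplot
autoplot.synergy_matrix <- function(object, ...) {
  tab <- object$table
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$drug_a, y = .data$drug_b,
                                    fill = .data$BI)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(midpoint = 1, low = "#2166ac",
                                  mid = "white", high = "#b2182b") +
    ggplot2::labs(x = NULL, y = NULL, fill = "BI",
                  title = sprintf("Bliss indices (%d pairs, %.1f%% obvious synergy)",
                                  object$summary$n_pairs,
                                  object$summary$fraction_obvious)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Volcano plot of a differential-expression table
#'
#' @param records Differential table from [differential_expression()].
#' @param fc_min,alpha Significance bounds drawn as guides (defaults match
#'   [filter_tsg()]).
#' @return A ggplot of log2 fold change against -log10 adjusted p, with the
#'   significant up/down genes colored.
#' @export
plot_volcano <- function(records, fc_min = 2, alpha = 0.05) {
  records <- records |>
    dplyr::mutate(status = dplyr::case_when(
      .data$log2fc >= log2(fc_min) & .data$adj_p < alpha ~ "up",
      .data$log2fc <= -log2(fc_min) & .data$adj_p < alpha ~ "down",
      TRUE ~ "ns"))
  ggplot2::ggplot(records, ggplot2::aes(x = .data$log2fc,
                                        y = -log10(.data$adj_p),
                                        color = .data$status)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_color_manual(values = c(up = "#b2182b", down = "#2166ac",
                                           ns = "grey70")) +
    ggplot2::geom_vline(xintercept = c(-log2(fc_min), log2(fc_min)),
                        linetype = "dashed", color = "grey40") +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed",
                        color = "grey40") +
    ggplot2::labs(x = "log2 fold change (tumor / normal)",
                  y = "-log10 adjusted p") +
    ggplot2::theme_minimal()
}

#' Per-method centrality score distributions with consensus hubs marked
#'
#' @param x A `hub_consensus`.
#' @return A ggplot of score distributions per centrality method (free
#'   scales) with consensus hub genes highlighted.
#' @export
plot_hub_scores <- function(x) {
  long <- tidyr::pivot_longer(x$scores, -"node", names_to = "method",
                              values_to = "score")
  long$consensus <- long$node %in% x$consensus
  ggplot2::ggplot(long, ggplot2::aes(x = .data$score, y = .data$method)) +
    ggplot2::geom_jitter(ggplot2::aes(color = .data$consensus), height = 0.2,
                         alpha = 0.6, size = 0.8) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "#b2182b",
                                           `FALSE` = "grey60")) +
    ggplot2::facet_wrap(~method, scales = "free_x") +
    ggplot2::labs(x = "score", y = NULL, color = "consensus hub") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   strip.text = ggplot2::element_text(face = "bold"))
}

#' Distribution of PSI differences from a differential splicing screen
#'
#' @param diff_tbl Output of [differential_as()].
#' @param dpsi_min Strict |dPSI| guide (default 0.10).
#' @return A ggplot histogram of per-event dPSI, significant events colored.
#' @export
plot_dpsi <- function(diff_tbl, dpsi_min = 0.10) {
  ggplot2::ggplot(diff_tbl, ggplot2::aes(x = .data$dpsi,
                                         fill = .data$significant)) +
    ggplot2::geom_histogram(bins = 40, color = "white") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#b2182b",
                                          `FALSE` = "grey70")) +
    ggplot2::geom_vline(xintercept = c(-dpsi_min, dpsi_min),
                        linetype = "dashed", color = "grey40") +
    ggplot2::labs(x = "dPSI (tumor - normal)", y = "events",
                  fill = "significant") +
    ggplot2::theme_minimal()
}
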