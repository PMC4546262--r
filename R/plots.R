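#' Plot Kaplan-Meier curves
#'
#' Step survival curves per group, annotated with the log-rank p-value.
#'
#' @param object a `pam_km` from [kaplan_meier()].
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot pam_km
#' @export
autoplot.pam_km <- function(object, ...) {
  # prepend the (0, 1) origin per group so steps start at S(0) = 1
  origins <- object$curves |>
    dplyr::distinct(.data$group) |>
    dplyr::mutate(time = 0, survival = 1)
  dat <- dplyr::bind_rows(origins,
                          object$curves[, c("group", "time", "survival")])
  p <- ggplot2::ggplot(dat, ggplot2::aes(.data$time, .data$survival,
                                         colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Years", y = "Survival probability",
                  colour = "Group") +
    ggplot2::theme_minimal()
  if (is.finite(object$logrank_p %||% NA_real_)) {
    p <- p + ggplot2::labs(
      subtitle = sprintf("log-rank p = %.3g", object$logrank_p))
  }
  p
}

#' Plot a centroid model as a gene-by-subtype heatmap
#'
#' @param object a `pam_centroid_model`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot pam_centroid_model
#' @export
autoplot.pam_centroid_model <- function(object, ...) {
  tidy(object) |>
    dplyr::mutate(subtype = factor(.data$subtype, levels = SUBTYPES),
                  gene = factor(.data$gene, levels = rev(object$genes))) |>
    ggplot2::ggplot(ggplot2::aes(.data$subtype, .data$gene,
                                 fill = .data$centroid)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 6))
}

#' Plot paired scores of the two ROR variants
#'
#' @param object a `pam_variant_comparison` from [compare_variants()].
#' @param ... unused.
#' @return A ggplot of 46-gene vs 50-gene scaled scores with the
#'   identity line and the fitted R².
#' @method autoplot pam_variant_comparison
#' @export
autoplot.pam_variant_comparison <- function(object, ...) {
  ggplot2::ggplot(object$paired,
                  ggplot2::aes(.data$scaled_50, .data$scaled_46)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::labs(x = "50-gene ROR (0-100)", y = "46-gene ROR (0-100)",
                  subtitle = sprintf("R² = %.4f, slope = %.3f, intercept = %.2f",
                                     object$r_squared, object$slope,
                                     object$intercept)) +
    ggplot2::theme_minimal()
}

#' Plot bootstrap C-index distributions per model
#'
#' @param object a `pam_boot_cindex`.
#' @param ... unused.
#' @return A ggplot boxplot of the bootstrap distributions.
#' @method autoplot pam_boot_cindex
#' @export
autoplot.pam_boot_cindex <- function(object, ...) {
  ggplot2::ggplot(object$replicates,
                  ggplot2::aes(.data$model, .data$c_index)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "C-index") +
    ggplot2::theme_minimal()
}

#' Bar chart of cohort subtype frequencies
#'
#' @param calls tibble of subtype calls as returned by
#'   [classify_cohort()]`$calls`.
#' @return A ggplot.
#' @export
plot_subtype_frequencies <- function(calls) {
  calls |>
    dplyr::count(subtype = factor(.data$subtype, levels = SUBTYPES),
                 .drop = FALSE) |>
    ggplot2::ggplot(ggplot2::aes(.data$subtype, .data$n,
                                 fill = .data$subtype)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "Samples") +
    ggplot2::theme_minimal()
}

#' ROR score distribution by subtype with risk cutoffs
#'
#' @param scores tibble from [score_samples()] (needs `subtype` and
#'   `scaled_score`).
#' @param cutoffs numeric `c(low, high)` drawn as dashed lines.
#' @return A ggplot.
#' @export
plot_ror_distribution <- function(scores, cutoffs = c(40, 60)) {
  ggplot2::ggplot(scores, ggplot2::aes(.data$subtype, .data$scaled_score)) +
    ggplot2::geom_hline(yintercept = cutoffs, linetype = 2,
                        colour = "grey40") +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 1) +
    ggplot2::labs(x = NULL, y = "ROR score (0-100)") +
    ggplot2::theme_minimal()
}

#' @export
ggplot2::autoplot
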