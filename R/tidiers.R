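#' Tidy a centroid model
#'
#' @param x a `pam_centroid_model`.
#' @param ... unused.
#' @return Long tibble: `gene`, `subtype`, `centroid` (Z-scale value).
#' @export
tidy.pam_centroid_model <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x$centroids), rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "subtype",
                        values_to = "centroid")
}

#' @rdname tidy.pam_centroid_model
#' @return For `glance()`: one-row tibble with gene and prototype counts.
#' @export
glance.pam_centroid_model <- function(x, ...) {
  np <- x$training_metadata$n_per_centroid
  tibble::tibble(
    n_genes = length(x$genes),
    n_prototypes = sum(np),
    n_LumA = np[["LumA"]], n_LumB = np[["LumB"]],
    n_Her2E = np[["Her2E"]], n_Basal = np[["Basal"]],
    summary = x$training_metadata$summary %||% "mean"
  )
}

#' Tidy an ROR model
#'
#' @param x a `pam_ror_model`.
#' @param ... unused.
#' @return Tibble of `term`, `estimate` (the Cox linear-predictor
#'   coefficients).
#' @export
tidy.pam_ror_model <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @rdname tidy.pam_ror_model
#' @return For `glance()`: one-row tibble with variant, penalty and
#'   scaling.
#' @export
glance.pam_ror_model <- function(x, ...) {
  tibble::tibble(
    variant = x$variant,
    n_genes = length(x$genes),
    lambda = x$lambda,
    alpha = x$scaling$alpha,
    beta = x$scaling$beta,
    cutoff_low = unname(x$cutoffs[1]),
    cutoff_high = unname(x$cutoffs[2])
  )
}

#' Tidy a ridge-Cox fit
#'
#' @param x a `pam_ridge_cox` from [fit_ror_coefficients()].
#' @param ... unused.
#' @return Tibble of `term`, `estimate`.
#' @export
tidy.pam_ridge_cox <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @rdname tidy.pam_ridge_cox
#' @export
glance.pam_ridge_cox <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, ties = x$ties,
                 standardize = x$standardize,
                 cv_selected = !is.null(x$cv))
}

#' Tidy Kaplan-Meier output
#'
#' @param x a `pam_km` from [kaplan_meier()].
#' @param ... unused.
#' @return The per-group curve tibble.
#' @export
tidy.pam_km <- function(x, ...) x$curves

#' @rdname tidy.pam_km
#' @export
glance.pam_km <- function(x, ...) {
  tibble::tibble(logrank_chisq = x$logrank_chisq,
                 logrank_df = x$logrank_df,
                 logrank_p = x$logrank_p,
                 n_groups = nrow(x$n_per_group))
}

#' Tidy a bootstrap C-index comparison
#'
#' @param x a `pam_boot_cindex`.
#' @param ... unused.
#' @return The per-model summary tibble (mean and percentile CI).
#' @export
tidy.pam_boot_cindex <- function(x, ...) {
  dplyr::left_join(x$observed, x$summary, by = "model")
}

#' @rdname tidy.pam_boot_cindex
#' @export
glance.pam_boot_cindex <- function(x, ...) {
  tibble::tibble(n_boot = x$n_boot, n_dropped = x$n_dropped,
                 conf_level = x$conf_level)
}
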