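#' Classify one sample by maximum centroid correlation
#'
#' Computes the Pearson correlation of a Z-scaled sample vector with each
#' of the four subtype centroids and assigns the subtype attaining the
#' maximum. The call is a pure function of the sample vector and the
#' model: no cohort renormalization of any kind, so a sample receives the
#' same subtype whether scored alone or in a batch. Correlation is
#' invariant to positive affine transforms of the sample vector. Exact
#' correlation ties (measure-zero in practice) are broken by the fixed
#' subtype order LumA, LumB, Her2E, Basal with a warning.
#'
#' @param x named numeric vector of Z-scaled expression covering all
#'   model genes (extra genes ignored), or a 1-column [pam_expr()].
#' @param model a `pam_centroid_model`.
#' @return A one-row tibble: `sample`, `rho_LumA`, `rho_LumB`,
#'   `rho_Her2E`, `rho_Basal`, `subtype`, `margin` (top correlation minus
#'   runner-up).
#' @export
classify <- function(x, model) {
  stopifnot(inherits(model, "pam_centroid_model"))
  if (inherits(x, "pam_expr")) {
    stopifnot(ncol(x) == 1)
    id <- colnames(x)[1]
    v <- stats::setNames(unclass(x)[, 1], rownames(x))
  } else {
    id <- attr(x, "sample_id") %||% "sample"
    v <- x
  }
  missing <- setdiff(model$genes, names(v))
  if (length(missing) > 0) {
    stop("missing gene(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  v <- v[model$genes]
  if (stats::sd(v) == 0) stop("zero-variance sample vector", call. = FALSE)
  rho <- vapply(SUBTYPES, function(st) stats::cor(v, model$centroids[, st]),
                numeric(1))
  top <- which(rho == max(rho))
  if (length(top) > 1) {
    warning("exact correlation tie; broken by fixed subtype order")
  }
  assigned <- SUBTYPES[top[1]]
  margin <- max(rho) - max(rho[-top[1]])
  tibble::tibble(
    sample = id,
    rho_LumA = rho[["LumA"]], rho_LumB = rho[["LumB"]],
    rho_Her2E = rho[["Her2E"]], rho_Basal = rho[["Basal"]],
    subtype = assigned, margin = margin
  )
}

#' Classify every sample of a cohort
#'
#' Vectorized [classify()]: per-sample results are identical to
#' classifying each sample alone (single-sample contract).
#'
#' @param x a [pam_expr()] in `z_scaled` space.
#' @param model a `pam_centroid_model`.
#' @return A list with `calls` (tibble, one row per sample as in
#'   [classify()]) and `frequencies` (tibble `subtype`, `n`, `pct`).
#' @export
classify_cohort <- function(x, model) {
  stopifnot(inherits(x, "pam_expr"))
  calls <- purrr::map_dfr(colnames(x), function(s) {
    classify(pam_expr(unclass(x)[, s, drop = FALSE], value_space(x)), model)
  })
  freq <- calls |>
    dplyr::count(subtype = factor(.data$subtype, levels = SUBTYPES),
                 .drop = FALSE, name = "n") |>
    dplyr::mutate(subtype = as.character(.data$subtype),
                  pct = 100 * .data$n / sum(.data$n))
  list(calls = calls, frequencies = freq)
}
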