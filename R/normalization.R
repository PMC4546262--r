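#' Per-sample quality control on control probes
#'
#' For each sample, three quantities are computed from the control probes
#' of the codeset:
#' * `positive_control_r2`: coefficient of determination of
#'   `log2(count + pseudocount)` against `log2(expected concentration)`
#'   across the positive-control titration probes;
#' * `background_level`: mean + `background_sd_mult` * SD of the
#'   negative-control counts (a conventional digital-counting background
#'   estimate; the multiplier defaults to 2);
#' * `low_signal_flag`: `TRUE` when the geometric mean of the housekeeper
#'   counts does not exceed the background level.
#'
#' A sample passes QC when it is not low-signal and its positive-control
#' linearity exceeds `min_pos_r2`.
#'
#' @param counts a [pam_expr()] in the `raw_counts` space containing the
#'   control probes and housekeepers of `codeset`.
#' @param codeset a [pam_codeset()].
#' @param pseudocount added before log2 of positive-control counts.
#' @param background_sd_mult multiplier on the negative-control SD.
#' @param min_pos_r2 minimum acceptable positive-control R².
#' @return A tibble with one row per sample: `sample`,
#'   `positive_control_r2`, `background_level`, `housekeeper_geomean`,
#'   `low_signal_flag`, `pass`, `messages`.
#' @export
qc_sample <- function(counts, codeset, pseudocount = 1,
                      background_sd_mult = 2, min_pos_r2 = 0.95) {
  stopifnot(inherits(counts, "pam_expr"),
            value_space(counts) == "raw_counts",
            inherits(codeset, "pam_codeset"))
  require_genes(counts, codeset$positive_controls$id, "positive-control probe")
  require_genes(counts, codeset$negative_controls, "negative-control probe")
  require_genes(counts, codeset$housekeeper_genes, "housekeeper gene")

  lx <- log2(codeset$positive_controls$concentration)
  purrr::map_dfr(colnames(counts), function(s) {
    pos <- unclass(counts)[codeset$positive_controls$id, s]
    neg <- unclass(counts)[codeset$negative_controls, s]
    hk <- unclass(counts)[codeset$housekeeper_genes, s]
    ly <- log2(pos + pseudocount)
    r2 <- if (stats::sd(ly) == 0) 0 else stats::cor(lx, ly)^2
    bg <- mean(neg) + background_sd_mult * stats::sd(neg)
    if (length(neg) == 1) bg <- neg  # no SD from a single probe
    hk_gm <- exp(mean(log(pmax(hk, .Machine$double.xmin))))
    if (any(hk == 0)) hk_gm <- 0
    low <- hk_gm <= bg
    msgs <- character()
    if (low) msgs <- c(msgs, "housekeeper signal at or below background")
    if (r2 < min_pos_r2) msgs <- c(msgs, sprintf(
      "positive-control linearity R2 %.3f below %.3f", r2, min_pos_r2))
    tibble::tibble(
      sample = s,
      positive_control_r2 = r2,
      background_level = bg,
      housekeeper_geomean = hk_gm,
      low_signal_flag = low,
      pass = !low && r2 >= min_pos_r2,
      messages = paste(msgs, collapse = "; ")
    )
  })
}

#' Normalize raw counts to log2 expression
#'
#' Implements the two-stage normalization of the digital assay: each count
#' is log2-transformed (with a pseudocount guard), expressed as a log-ratio
#' to a reference-sample profile when one is supplied, and then centred per
#' sample by the arithmetic mean of the housekeeper values in log2 space —
#' equivalently, divided by the geometric mean of the housekeeper ratios.
#' After normalization the housekeeper mean of every sample is exactly 0,
#' which makes the classifier output invariant to global per-sample scaling
#' of the raw counts (library size).
#'
#' Reference correction and housekeeper centring commute in log space
#' (both are additive), so the order is fixed as reference-first. When
#' `reference_profile` is `NULL` only housekeeper normalization is applied
#' (the feasibility-study configuration).
#'
#' @param counts a [pam_expr()] in `raw_counts` space.
#' @param codeset a [pam_codeset()].
#' @param reference_profile named numeric vector of strictly positive
#'   reference counts covering every classifier and housekeeper gene, or
#'   `NULL` to skip reference correction.
#' @param pseudocount non-negative value added to counts (and reference)
#'   before log2; default 1, may be 0 when all counts are strictly
#'   positive.
#' @return A [pam_expr()] in `log2_normalized` space containing the
#'   classifier and housekeeper genes.
#' @export
normalize_counts <- function(counts, codeset, reference_profile = NULL,
                             pseudocount = 1) {
  stopifnot(inherits(counts, "pam_expr"),
            value_space(counts) == "raw_counts",
            inherits(codeset, "pam_codeset"),
            pseudocount >= 0)
  genes <- c(codeset$classifier_genes, codeset$housekeeper_genes)
  require_genes(counts, genes)
  m <- unclass(counts)[genes, , drop = FALSE]
  if (pseudocount == 0 && any(m == 0)) {
    stop("pseudocount 0 requires strictly positive counts", call. = FALSE)
  }
  x <- log2(m + pseudocount)
  if (!is.null(reference_profile)) {
    missing_ref <- setdiff(genes, names(reference_profile))
    if (length(missing_ref) > 0) {
      stop("gene(s) missing from reference_profile: ",
           paste(missing_ref, collapse = ", "), call. = FALSE)
    }
    ref <- reference_profile[genes]
    if (any(!is.finite(ref)) || any(ref <= 0)) {
      stop("reference_profile must be strictly positive for every ",
           "classifier and housekeeper gene", call. = FALSE)
    }
    x <- x - log2(ref + pseudocount)
  }
  hk_mean <- colMeans(x[codeset$housekeeper_genes, , drop = FALSE])
  x <- sweep(x, 2, hk_mean)
  out <- pam_expr(x, "log2_normalized", provenance = attr(counts, "provenance"))
  expr_append_prov(out, sprintf(
    "normalized (reference=%s, housekeepers=%d, pseudocount=%g)",
    if (is.null(reference_profile)) "none" else "yes",
    length(codeset$housekeeper_genes), pseudocount))
}

#' Per-gene coefficient of variation across replicates
#'
#' CV is computed on the linear scale (`2^x` for log2 input), the
#' convention behind "%CV" in platform-reproducibility work:
#' `CV = 100 * SD / mean`. Genes whose replicate mean is 0 or with fewer
#' than 2 replicates are reported as missing and excluded from the median.
#'
#' @param replicates numeric matrix, genes in rows, replicates in columns
#'   (NAs allowed and dropped per gene), or a `pam_expr`.
#' @param space `"linear"` when values are already linear,
#'   `"log2"` to linearize via `2^x` first.
#' @return A list with `per_gene` (tibble: `gene`, `n`, `cv_pct`) and
#'   `median_cv_pct`.
#' @export
coefficient_of_variation <- function(replicates, space = c("linear", "log2")) {
  space <- match.arg(space)
  m <- as.matrix(unclass(replicates))
  if (space == "log2") m <- 2^m
  per_gene <- purrr::map_dfr(seq_len(nrow(m)), function(i) {
    v <- m[i, ]
    v <- v[!is.na(v)]
    cv <- if (length(v) < 2 || mean(v) == 0) NA_real_ else
      100 * stats::sd(v) / mean(v)
    tibble::tibble(
      gene = rownames(m)[i] %||% as.character(i),
      n = length(v),
      cv_pct = cv
    )
  })
  list(per_gene = per_gene,
       median_cv_pct = stats::median(per_gene$cv_pct, na.rm = TRUE))
}
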