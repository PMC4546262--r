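#' Proliferation score
#'
#' Arithmetic mean of the Z-scaled expression of the proliferation gene
#' subset, per sample.
#'
#' @param xz a [pam_expr()] in `z_scaled` space (or a named vector for a
#'   single sample).
#' @param subset non-empty character vector of proliferation genes.
#' @return Named numeric vector of scores, one per sample.
#' @export
proliferation_score <- function(xz, subset) {
  if (length(subset) == 0) stop("empty proliferation subset", call. = FALSE)
  if (is.null(dim(xz))) {
    missing <- setdiff(subset, names(xz))
    if (length(missing) > 0) stop("missing proliferation gene(s): ",
                                  paste(missing, collapse = ", "),
                                  call. = FALSE)
    return(mean(xz[subset]))
  }
  require_genes(xz, subset, "proliferation gene")
  colMeans(unclass(xz)[subset, , drop = FALSE])
}

#' Binary tumor-size indicator
#'
#' `0` for tumors measuring 2.0 cm or less in the greatest dimension,
#' `1` for tumors measuring more than 2.0 cm. Missing sizes propagate as
#' `NA`; callers exclude those samples from size-dependent scoring.
#'
#' @param tumor_size_cm numeric vector of tumor sizes (cm, positive).
#' @param threshold_cm the size threshold (default 2.0).
#' @return Integer vector of 0/1 (NA where size is missing).
#' @export
size_indicator <- function(tumor_size_cm, threshold_cm = 2.0) {
  bad <- which(!is.na(tumor_size_cm) & tumor_size_cm <= 0)
  if (length(bad) > 0) stop("non-positive tumor size at position ",
                            bad[1], call. = FALSE)
  as.integer(ifelse(is.na(tumor_size_cm), NA_integer_,
                    tumor_size_cm > threshold_cm))
}

# Breslow-ties Cox partial log-likelihood for a coefficient vector
cox_partial_loglik <- function(beta, x, time, event) {
  eta <- drop(x %*% beta)
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; eta <- eta[ord]
  # risk set sums from the right
  rev_cumsum <- rev(cumsum(rev(exp(eta))))
  # Breslow: each event time contributes eta_i - log(sum over risk set);
  # tied event times share the same risk-set denominator
  denom <- rev_cumsum[match(time, time)]  # first index at each time value
  sum(event * (eta - log(denom)))
}

#' Fit ROR coefficients by ridge-penalized Cox regression
#'
#' Maximizes the Cox partial log-likelihood (Breslow tie handling, Efron
#' available behind `ties`) minus `lambda * sum(coef^2) / 2`, via
#' [survival::coxph()] with a ridge penalty term. When
#' `lambda = "auto"`, lambda is chosen on a log-spaced grid by k-fold
#' cross-validated partial likelihood (Verweij–van Houwelingen: the full
#' likelihood at the held-out-fit coefficients minus the training-fold
#' likelihood), with a fold assignment fixed by `seed`. With
#' `standardize = TRUE` covariates are scaled inside the penalty and the
#' coefficients are reported on the original scale.
#'
#' @param features data frame or matrix of covariates (one row per
#'   sample), e.g. the four centroid correlations, proliferation score
#'   and size indicator.
#' @param survival data frame with columns `time` (>= 0) and `event`
#'   (0/1), row-aligned to `features`.
#' @param lambda non-negative penalty, or `"auto"` for CV selection.
#' @param standardize scale covariates inside the penalty.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param nfolds,seed CV folds and fold-assignment seed (`lambda =
#'   "auto"` only).
#' @param lambda_grid candidate penalties for CV.
#' @return List of class `pam_ridge_cox`: `coefficients` (named),
#'   `lambda`, `cv` (tibble of lambda vs CV partial likelihood, or NULL),
#'   `ties`, `standardize`.
#' @export
fit_ror_coefficients <- function(features, survival, lambda = "auto",
                                 standardize = TRUE,
                                 ties = c("breslow", "efron"),
                                 nfolds = 5, seed = 1,
                                 lambda_grid = 10^seq(-3, 3, length.out = 25)) {
  ties <- match.arg(ties)
  x <- as.matrix(features)
  if (any(!is.finite(x))) stop("non-finite feature values", call. = FALSE)
  time <- survival$time
  event <- survival$event
  stopifnot(length(time) == nrow(x), all(event %in% c(0, 1)))
  if (sum(event) < 2) stop("need at least 2 events", call. = FALSE)

  fit_one <- function(lam, xs, ts, es) {
    fml <- survival::Surv(ts, es) ~
      survival::ridge(xs, theta = lam, scale = standardize)
    f <- survival::coxph(fml, ties = ties,
                         control = survival::coxph.control(iter.max = 100))
    stats::setNames(unname(stats::coef(f)), colnames(xs))
  }

  cv_tbl <- NULL
  if (identical(lambda, "auto")) {
    set.seed(seed)
    fold <- sample(rep_len(seq_len(nfolds), nrow(x)))
    cvpl <- vapply(lambda_grid, function(lam) {
      sum(vapply(seq_len(nfolds), function(k) {
        idx <- fold != k
        b <- tryCatch(fit_one(lam, x[idx, , drop = FALSE],
                              time[idx], event[idx]),
                      error = function(e) rep(NA_real_, ncol(x)))
        if (any(is.na(b))) return(NA_real_)
        cox_partial_loglik(b, x, time, event) -
          cox_partial_loglik(b, x[idx, , drop = FALSE], time[idx], event[idx])
      }, numeric(1)))
    }, numeric(1))
    cv_tbl <- tibble::tibble(lambda = lambda_grid, cv_partial_loglik = cvpl)
    if (all(is.na(cvpl))) stop("cross-validation failed for every lambda",
                               call. = FALSE)
    lambda <- lambda_grid[which.max(cvpl)]
  }
  stopifnot(is.numeric(lambda), lambda >= 0)

  beta <- tryCatch(fit_one(lambda, x, time, event), error = function(e) {
    stop("ridge Cox fit failed to converge: ", conditionMessage(e),
         call. = FALSE)
  })
  structure(
    list(coefficients = beta, lambda = lambda, cv = cv_tbl,
         ties = ties, standardize = standardize),
    class = "pam_ridge_cox"
  )
}

#' Raw ROR linear predictor
#'
#' `raw = sum_k a_k * rho_k + b * P + c * T`: the fitted linear predictor
#' over the four centroid correlations, the proliferation score and the
#' binary size indicator.
#'
#' @param features data frame/tibble with columns `rho_LumA`, `rho_LumB`,
#'   `rho_Her2E`, `rho_Basal`, `proliferation`, `size_indicator`.
#' @param model a `pam_ror_model` (or anything with a named
#'   `coefficients` vector over those columns).
#' @return Numeric vector of raw scores.
#' @export
ror_raw <- function(features, model) {
  co <- model$coefficients
  features <- tibble::as_tibble(features)
  missing <- setdiff(names(co), names(features))
  if (length(missing) > 0) stop("missing feature column(s): ",
                                paste(missing, collapse = ", "),
                                call. = FALSE)
  drop(as.matrix(features[names(co)]) %*% co)
}

#' Fit the 0-100 score scaling
#'
#' Linear map `scaled = alpha + beta * raw` sending the minimum raw score
#' of the designated scaling cohort to 0 and the maximum to 100
#' (`beta > 0`). Scores of new samples outside the cohort range are
#' clamped to [0, 100] with a warning at application time.
#'
#' @param raw_scores numeric vector (at least 2 distinct values).
#' @return List `(alpha, beta)`.
#' @export
fit_ror_scaler <- function(raw_scores) {
  r <- range(raw_scores, finite = TRUE)
  if (!all(is.finite(r)) || r[1] == r[2]) {
    stop("raw scores are constant; cannot fit a 0-100 scaling",
         call. = FALSE)
  }
  beta <- 100 / (r[2] - r[1])
  list(alpha = -beta * r[1], beta = beta)
}

#' Apply the 0-100 scaling
#'
#' @param raw numeric raw scores.
#' @param scaling list `(alpha, beta)` from [fit_ror_scaler()].
#' @return Scaled scores in [0, 100] (out-of-range values clamped with a
#'   warning).
#' @export
ror_scaled <- function(raw, scaling) {
  s <- scaling$alpha + scaling$beta * raw
  n_out <- sum(s < 0 | s > 100, na.rm = TRUE)
  if (n_out > 0) {
    warning(sprintf("%d score(s) outside [0, 100] clamped", n_out))
  }
  pmin(pmax(s, 0), 100)
}

#' Node-negative risk group from a scaled score
#'
#' Low risk below 40, high risk above 60, intermediate otherwise (scores
#' of exactly 40 or 60 fall in the intermediate band: the published
#' cutoffs are strict inequalities). Cutoffs are defined for
#' node-negative patients only.
#'
#' @param scaled_score numeric scores on the 0-100 scale.
#' @param node_status `"negative"` (anything else errors: cutoffs for
#'   other node statuses are not defined here).
#' @param cutoffs numeric `c(low, high)`, strictly increasing.
#' @return Character vector: `"low"`, `"intermediate"` or `"high"`.
#' @export
risk_group <- function(scaled_score, node_status = "negative",
                       cutoffs = c(low = 40, high = 60)) {
  if (!all(node_status == "negative")) {
    stop("risk-group cutoffs are defined for node-negative patients only",
         call. = FALSE)
  }
  stopifnot(length(cutoffs) == 2, cutoffs[1] < cutoffs[2])
  dplyr::case_when(
    scaled_score < cutoffs[1] ~ "low",
    scaled_score > cutoffs[2] ~ "high",
    TRUE ~ "intermediate"
  )
}

# restrict a centroid model to a gene subset (used by the 46-gene variant)
restrict_centroid_model <- function(model, genes) {
  stopifnot(inherits(model, "pam_centroid_model"))
  missing <- setdiff(genes, model$genes)
  if (length(missing) > 0) stop("gene(s) not in centroid model: ",
                                paste(missing, collapse = ", "),
                                call. = FALSE)
  model$centroids <- model$centroids[genes, , drop = FALSE]
  model$scaler$params <- model$scaler$params[
    match(genes, model$scaler$params$gene), ]
  model$genes <- genes
  model
}

# per-sample ROR feature table: correlations + proliferation + size
ror_features <- function(x_norm, centroid_model, clinical, codeset,
                         variant = c("50-gene", "46-gene")) {
  variant <- match.arg(variant)
  genes <- codeset$classifier_genes
  prolif <- codeset$proliferation_subset
  if (variant == "46-gene") {
    genes <- setdiff(genes, codeset$reduced_model_exclusions)
    prolif <- setdiff(prolif, codeset$reduced_model_exclusions)
  }
  cm <- restrict_centroid_model(centroid_model, genes)
  xz <- apply_gene_scaler(x_norm, cm$scaler)
  calls <- classify_cohort(xz, cm)$calls
  pro <- proliferation_score(xz, prolif)
  clinical <- tibble::as_tibble(clinical)
  stopifnot("sample" %in% names(clinical))
  calls |>
    dplyr::mutate(proliferation = unname(pro[.data$sample])) |>
    dplyr::left_join(
      clinical |>
        dplyr::transmute(sample = .data$sample,
                         size_indicator = size_indicator(.data$tumor_size_cm)),
      by = "sample")
}

#' Train an ROR model
#'
#' Builds the per-sample feature table (the four centroid correlations
#' from the — possibly reduced — gene panel, the proliferation score, the
#' binary size indicator), fits the ridge-Cox coefficients against the
#' supplied survival records, computes the raw linear predictor on the
#' training cohort and freezes the 0-100 scaling on its range. Samples
#' with missing tumor size are excluded from fitting and scaling, with a
#' message.
#'
#' @param x_norm a [pam_expr()] in `log2_normalized` space.
#' @param centroid_model a `pam_centroid_model` trained on the same
#'   codeset.
#' @param clinical tibble with columns `sample`, `tumor_size_cm`.
#' @param survival tibble with columns `sample`, `time`, `event`.
#' @param codeset the [pam_codeset()].
#' @param variant `"50-gene"` or `"46-gene"` (the latter removes the
#'   codeset's `reduced_model_exclusions` from the correlation panel and
#'   the proliferation subset).
#' @inheritParams fit_ror_coefficients
#' @param cutoffs node-negative risk cutoffs.
#' @return An object of class `pam_ror_model`.
#' @export
train_ror <- function(x_norm, centroid_model, clinical, survival, codeset,
                      variant = c("50-gene", "46-gene"), lambda = "auto",
                      standardize = TRUE, nfolds = 5, seed = 1,
                      ties = "breslow", cutoffs = c(low = 40, high = 60)) {
  variant <- match.arg(variant)
  feats <- ror_features(x_norm, centroid_model, clinical, codeset, variant)
  n_missing <- sum(is.na(feats$size_indicator))
  if (n_missing > 0) {
    message(n_missing, " sample(s) without tumor size excluded from ",
            "ROR training")
    feats <- dplyr::filter(feats, !is.na(.data$size_indicator))
  }
  survival <- tibble::as_tibble(survival)
  feats <- dplyr::inner_join(feats,
                             survival[, c("sample", "time", "event")],
                             by = "sample")
  covars <- c("rho_LumA", "rho_LumB", "rho_Her2E", "rho_Basal",
              "proliferation", "size_indicator")
  fit <- fit_ror_coefficients(feats[covars],
                              feats[, c("time", "event")],
                              lambda = lambda, standardize = standardize,
                              ties = ties, nfolds = nfolds, seed = seed)
  model <- structure(
    list(coefficients = fit$coefficients,
         variant = variant,
         proliferation_subset = if (variant == "46-gene")
           setdiff(codeset$proliferation_subset,
                   codeset$reduced_model_exclusions)
         else codeset$proliferation_subset,
         genes = if (variant == "46-gene")
           setdiff(codeset$classifier_genes, codeset$reduced_model_exclusions)
         else codeset$classifier_genes,
         scaling = NULL,
         cutoffs = cutoffs,
         lambda = fit$lambda,
         ties = fit$ties,
         standardize = fit$standardize,
         codeset_hash = codeset_hash(codeset)),
    class = "pam_ror_model"
  )
  raw <- ror_raw(feats, model)
  model$scaling <- fit_ror_scaler(raw)
  model
}

#' @export
print.pam_ror_model <- function(x, ...) {
  cat(sprintf("<pam_ror_model> %s variant, lambda = %g\n", x$variant,
              x$lambda))
  print(round(x$coefficients, 4))
  cat(sprintf("  scaling: alpha = %.4f, beta = %.4f; cutoffs %g/%g\n",
              x$scaling$alpha, x$scaling$beta, x$cutoffs[1], x$cutoffs[2]))
  invisible(x)
}

#' Score samples with trained centroid and ROR models
#'
#' The complete per-sample read-out: subtype call with the four
#' correlations, proliferation score, size indicator, raw and 0-100
#' scaled ROR, and node-negative risk group. Scoring one sample is
#' independent of the rest of the batch — the scaler and all model
#' parameters are frozen at training time.
#'
#' @inheritParams train_ror
#' @param ror_model a `pam_ror_model`.
#' @return A tibble with one row per scored sample; samples lacking tumor
#'   size are dropped with a message.
#' @export
score_samples <- function(x_norm, centroid_model, ror_model, clinical,
                          codeset) {
  stopifnot(inherits(ror_model, "pam_ror_model"))
  if (!identical(ror_model$codeset_hash, codeset_hash(codeset))) {
    stop("codeset does not match the one the ROR model was trained on",
         call. = FALSE)
  }
  variant <- ror_model$variant
  feats <- ror_features(x_norm, centroid_model, clinical, codeset, variant)
  n_missing <- sum(is.na(feats$size_indicator))
  if (n_missing > 0) {
    message(n_missing, " sample(s) without tumor size excluded from scoring")
    feats <- dplyr::filter(feats, !is.na(.data$size_indicator))
  }
  raw <- ror_raw(feats, ror_model)
  scaled <- ror_scaled(raw, ror_model$scaling)
  feats |>
    dplyr::mutate(raw_score = raw,
                  scaled_score = scaled,
                  risk_group = risk_group(scaled,
                                          cutoffs = ror_model$cutoffs))
}

#' Compare the 46-gene and 50-gene ROR variants
#'
#' Trains both variants on the same cohort (shared centroid model and
#' survival records), scores every sample with each, and summarizes the
#' agreement by least-squares R², slope and intercept of the paired
#' scaled scores.
#'
#' @inheritParams train_ror
#' @return A list of class `pam_variant_comparison`: `paired` (tibble
#'   `sample`, `scaled_50`, `scaled_46`), `r_squared`, `slope`,
#'   `intercept`, `models`.
#' @export
compare_variants <- function(x_norm, centroid_model, clinical, survival,
                             codeset, lambda = "auto", seed = 1, ...) {
  m50 <- train_ror(x_norm, centroid_model, clinical, survival, codeset,
                   variant = "50-gene", lambda = lambda, seed = seed, ...)
  m46 <- train_ror(x_norm, centroid_model, clinical, survival, codeset,
                   variant = "46-gene", lambda = lambda, seed = seed, ...)
  s50 <- score_samples(x_norm, centroid_model, m50, clinical, codeset)
  s46 <- score_samples(x_norm, centroid_model, m46, clinical, codeset)
  paired <- dplyr::inner_join(
    dplyr::select(s50, "sample", scaled_50 = "scaled_score"),
    dplyr::select(s46, "sample", scaled_46 = "scaled_score"),
    by = "sample")
  if (nrow(paired) == 0) stop("cohort mismatch: no shared scored samples",
                              call. = FALSE)
  fit <- stats::lm(scaled_46 ~ scaled_50, data = paired)
  structure(
    list(paired = paired,
         r_squared = summary(fit)$r.squared,
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         models = list(`50-gene` = m50, `46-gene` = m46)),
    class = "pam_variant_comparison"
  )
}

#' @export
print.pam_variant_comparison <- function(x, ...) {
  cat(sprintf(
    "<pam_variant_comparison> n = %d; R^2 = %.4f, slope = %.3f, intercept = %.2f\n",
    nrow(x$paired), x$r_squared, x$slope, x$intercept))
  invisible(x)
}
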