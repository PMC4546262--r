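RFS_EVENTS <- c("local_recurrence", "regional_recurrence",
                "distant_recurrence", "death_breast_cancer")
DRFS_EVENTS <- c("distant_recurrence", "death_breast_cancer")
DSS_EVENTS <- "death_breast_cancer"
KNOWN_EVENT_TYPES <- c("none", RFS_EVENTS, "contralateral_breast_cancer",
                       "death_other")

#' Derive a survival endpoint from clinical event records
#'
#' Maps raw follow-up records to `(time, event)` pairs under one of three
#' endpoints. Recurrence-free survival (RFS): local, regional or distant
#' recurrence, or death due to breast cancer, count as events (a
#' breast-cancer death with no recorded recurrence is an event at the
#' death date); contralateral breast cancer and death from other causes
#' are censoring events, as is event-free follow-up. Distant
#' recurrence-free survival (DRFS): only distant recurrence and
#' breast-cancer death are events; local/regional recurrence and
#' contralateral disease censor. Disease-specific survival (DSS): death
#' due to breast cancer is the event.
#'
#' @param records tibble with columns `sample`, `followup_years` (>= 0)
#'   and `event_type` (one of `none`, `local_recurrence`,
#'   `regional_recurrence`, `distant_recurrence`,
#'   `contralateral_breast_cancer`, `death_breast_cancer`,
#'   `death_other`).
#' @param endpoint `"RFS"`, `"DRFS"` or `"DSS"`.
#' @return A tibble `sample`, `time`, `event` (0/1), `endpoint`.
#' @export
derive_endpoint <- function(records, endpoint = c("RFS", "DRFS", "DSS")) {
  endpoint <- match.arg(endpoint)
  records <- tibble::as_tibble(records)
  stopifnot(all(c("sample", "followup_years", "event_type") %in%
                  names(records)))
  unknown <- setdiff(unique(records$event_type), KNOWN_EVENT_TYPES)
  if (length(unknown) > 0) stop("unknown event_type(s): ",
                                paste(unknown, collapse = ", "),
                                call. = FALSE)
  if (any(records$followup_years < 0)) stop("negative follow-up time",
                                            call. = FALSE)
  events <- switch(endpoint, RFS = RFS_EVENTS, DRFS = DRFS_EVENTS,
                   DSS = DSS_EVENTS)
  tibble::tibble(
    sample = records$sample,
    time = records$followup_years,
    event = as.integer(records$event_type %in% events),
    endpoint = endpoint
  )
}

#' Harrell's concordance index
#'
#' Over all subject pairs whose event ordering is determinable under
#' censoring, the fraction in which the higher risk score belongs to the
#' subject with the shorter time. A pair is comparable when the shorter
#' time ends in an event (including a tied time where exactly one subject
#' has the event, the censored one being known to survive at least as
#' long); two events at the same time, or two censored times, are not
#' comparable. Tied scores on a comparable pair receive half credit. The
#' computation is an explicit vectorized enumeration of all n² ordered
#' pairs.
#'
#' @param scores numeric risk scores (higher = riskier).
#' @param survival data frame with columns `time` and `event` (0/1),
#'   aligned to `scores`.
#' @return The concordance index in [0, 1].
#' @export
c_index <- function(scores, survival) {
  time <- survival$time
  event <- survival$event
  n <- length(scores)
  stopifnot(length(time) == n, all(event %in% c(0, 1)))
  dt <- outer(time, time, "-")          # t_i - t_j
  ei <- matrix(event, n, n)             # event of i (rows)
  ej <- t(ei)
  # ordered pairs (i, j) where i is determinably earlier
  earlier <- (dt < 0 & ei == 1) | (dt == 0 & ei == 1 & ej == 0)
  npairs <- sum(earlier)
  if (npairs == 0) stop("no comparable pairs", call. = FALSE)
  ds <- outer(scores, scores, "-")      # s_i - s_j
  (sum(earlier & ds > 0) + 0.5 * sum(earlier & ds == 0)) / npairs
}

#' Bootstrap comparison of concordance indices
#'
#' Resamples subjects with replacement `n_boot` times and recomputes the
#' C-index of every model on each replicate; reports percentile
#' confidence intervals per model and for all pairwise differences.
#' Replicates in which any model has no comparable pairs are dropped,
#' with the count reported.
#'
#' @param scores_by_model named list of score vectors, all aligned to
#'   `survival`.
#' @param survival data frame with `time`, `event`.
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param conf_level percentile CI level (default 0.95).
#' @return List of class `pam_boot_cindex`: `observed` (tibble `model`,
#'   `c_index`), `replicates` (tibble `replicate`, `model`, `c_index`),
#'   `summary` (model CIs), `differences` (pairwise difference CIs),
#'   `n_dropped`.
#' @export
bootstrap_c_index <- function(scores_by_model, survival, n_boot = 1000,
                              seed = 1, conf_level = 0.95) {
  stopifnot(is.list(scores_by_model), length(names(scores_by_model)) ==
              length(scores_by_model))
  n <- nrow(survival)
  observed <- tibble::tibble(
    model = names(scores_by_model),
    c_index = purrr::map_dbl(scores_by_model, c_index, survival = survival)
  )
  set.seed(seed)
  reps <- vector("list", n_boot)
  n_dropped <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    surv_b <- survival[idx, , drop = FALSE]
    cs <- tryCatch(
      purrr::map_dbl(scores_by_model, ~ c_index(.x[idx], surv_b)),
      error = function(e) NULL)
    if (is.null(cs)) { n_dropped <- n_dropped + 1L; next }
    reps[[b]] <- tibble::tibble(replicate = b,
                                model = names(scores_by_model),
                                c_index = unname(cs))
  }
  if (n_dropped > 0) message(n_dropped,
                             " replicate(s) without comparable pairs dropped")
  replicates <- dplyr::bind_rows(reps)
  probs <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
  smry <- replicates |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(mean = mean(.data$c_index),
                     ci_lower = stats::quantile(.data$c_index, probs[1]),
                     ci_upper = stats::quantile(.data$c_index, probs[2]),
                     .groups = "drop")
  wide <- tidyr::pivot_wider(replicates, names_from = "model",
                             values_from = "c_index")
  mods <- names(scores_by_model)
  diffs <- if (length(mods) < 2) {
    tibble::tibble(model_a = character(), model_b = character(),
                   mean_difference = numeric(), ci_lower = numeric(),
                   ci_upper = numeric())
  } else {
    purrr::map_dfr(utils::combn(mods, 2, simplify = FALSE), function(pr) {
      d <- wide[[pr[1]]] - wide[[pr[2]]]
      tibble::tibble(model_a = pr[1], model_b = pr[2],
                     mean_difference = mean(d),
                     ci_lower = stats::quantile(d, probs[1]),
                     ci_upper = stats::quantile(d, probs[2]))
    })
  }
  structure(
    list(observed = observed, replicates = replicates, summary = smry,
         differences = diffs, n_dropped = n_dropped,
         n_boot = n_boot, conf_level = conf_level),
    class = "pam_boot_cindex"
  )
}

#' @export
print.pam_boot_cindex <- function(x, ...) {
  cat(sprintf("<pam_boot_cindex> %d replicates (%d dropped)\n",
              x$n_boot, x$n_dropped))
  print(dplyr::left_join(x$observed, x$summary, by = "model"))
  invisible(x)
}

#' Subtype hazard ratios from an unpenalized Cox model
#'
#' Fits a Cox proportional-hazards model with the subtype as a
#' categorical covariate and reports exponentiated coefficients relative
#' to the reference subtype. Optional truncation at a fixed horizon (e.g.
#' 10-year recurrence-free survival) is applied as administrative
#' censoring: follow-up beyond the horizon is cut to it and censored
#' (events at exactly the horizon still count).
#'
#' @param subtype_labels character/factor vector of subtype calls.
#' @param survival data frame with `time`, `event`, aligned to labels.
#' @param reference reference subtype (default `"LumA"`).
#' @param truncate_years optional administrative-censoring horizon.
#' @param conf_level Wald CI level.
#' @return A tibble: `subtype`, `n`, `events`, `hr`, `ci_lower`,
#'   `ci_upper`, `p_value` (reference row has `hr = 1` and NA CI).
#' @export
cox_hazard_ratios <- function(subtype_labels, survival, reference = "LumA",
                              truncate_years = NULL, conf_level = 0.95) {
  labels <- as.character(subtype_labels)
  if (!reference %in% labels) stop("reference level '", reference,
                                   "' absent", call. = FALSE)
  time <- survival$time
  event <- survival$event
  if (!is.null(truncate_years)) {
    over <- time > truncate_years
    event[over] <- 0L
    time[over] <- truncate_years
  }
  tab <- tibble::tibble(label = labels, event = event) |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(n = dplyr::n(), events = sum(.data$event),
                     .groups = "drop")
  zero_ev <- tab$label[tab$events == 0 & tab$label != reference]
  if (length(zero_ev) > 0) {
    warning("subtype(s) with zero events: ",
            paste(zero_ev, collapse = ", "),
            "; hazard ratio unstable (infinite upper CI)")
  }
  if (sum(tab$label != reference & tab$events > 0) == 0 ||
      sum(tab$events) < 2) {
    stop("need events in at least two subtypes", call. = FALSE)
  }
  f <- stats::relevel(factor(labels), ref = reference)
  fit <- survival::coxph(survival::Surv(time, event) ~ f)
  s <- summary(fit, conf.int = conf_level)
  lev <- levels(f)[-1]
  res <- tibble::tibble(
    subtype = lev,
    hr = unname(s$conf.int[, "exp(coef)"]),
    ci_lower = unname(s$conf.int[, 3]),
    ci_upper = unname(s$conf.int[, 4]),
    p_value = unname(s$coefficients[, "Pr(>|z|)"])
  )
  res$ci_upper[res$subtype %in% zero_ev] <- Inf
  dplyr::bind_rows(
    tibble::tibble(subtype = reference, hr = 1, ci_lower = NA_real_,
                   ci_upper = NA_real_, p_value = NA_real_),
    res) |>
    dplyr::left_join(tab, by = c(subtype = "label")) |>
    dplyr::relocate("n", "events", .after = "subtype")
}

#' Kaplan-Meier curves with a log-rank test
#'
#' Product-limit estimate per group plus the unstratified log-rank
#' statistic (chi-squared reference with groups - 1 degrees of freedom).
#' Empty groups are dropped with a warning.
#'
#' @param survival data frame with `time`, `event`.
#' @param groups vector of group labels aligned to `survival`.
#' @return List of class `pam_km`: `curves` (tibble `group`, `time`,
#'   `n_risk`, `n_event`, `survival`), `logrank_chisq`, `logrank_df`,
#'   `logrank_p`, `n_per_group`.
#' @export
kaplan_meier <- function(survival, groups) {
  g <- if (is.factor(groups)) groups else factor(groups)
  empty <- levels(g)[table(g) == 0]
  if (length(empty) > 0) {
    warning("empty group(s) dropped: ", paste(empty, collapse = ", "))
    g <- droplevels(g)
  }
  time <- survival$time
  event <- survival$event
  sf <- survival::survfit(survival::Surv(time, event) ~ g)
  strata_names <- if (is.null(sf$strata)) levels(g)[1] else
    sub("^g=", "", names(sf$strata))
  grp <- if (is.null(sf$strata)) rep(strata_names, length(sf$time)) else
    rep(strata_names, sf$strata)
  curves <- tibble::tibble(
    group = grp, time = sf$time, n_risk = sf$n.risk,
    n_event = sf$n.event, survival = sf$surv
  )
  if (nlevels(g) >= 2) {
    sd <- survival::survdiff(survival::Surv(time, event) ~ g)
    chisq <- sd$chisq
    df <- length(sd$n) - 1
    p <- stats::pchisq(chisq, df, lower.tail = FALSE)
  } else {
    chisq <- NA_real_; df <- NA_integer_; p <- NA_real_
  }
  structure(
    list(curves = curves, logrank_chisq = chisq, logrank_df = df,
         logrank_p = p,
         n_per_group = tibble::as_tibble(as.data.frame(table(group = g),
                                                       stringsAsFactors = FALSE))),
    class = "pam_km"
  )
}

#' @export
print.pam_km <- function(x, ...) {
  cat(sprintf("<pam_km> %d group(s); log-rank chisq = %.3f (df %s, p = %.3g)\n",
              nrow(x$n_per_group), x$logrank_chisq,
              format(x$logrank_df), x$logrank_p))
  invisible(x)
}

#' Intraclass correlation coefficient (two-way mixed, absolute agreement)
#'
#' Single-measure ICC from the two-way ANOVA mean squares — the standard
#' summary for platform-reproducibility studies:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))` with
#' subjects as rows and replicate measurements as columns. Constant data
#' have an undefined ICC and return `NA` with a message.
#'
#' @param m numeric matrix, subjects in rows (>= 2), replicates in
#'   columns (>= 2); complete cases only.
#' @return The ICC (a single number <= 1), or NA when undefined.
#' @export
icc <- function(m) {
  m <- as.matrix(m)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need >= 2 subjects and >= 2 replicates",
                           call. = FALSE)
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  mse <- sum((m - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2) / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (denom <= 0 || !is.finite(denom)) {
    message("ICC undefined (no variance); returning NA")
    return(NA_real_)
  }
  (msr - mse) / denom
}

#' Concordance of two subtype call vectors
#'
#' @param calls_a,calls_b character vectors of subtype calls; when both
#'   are named, they are aligned by name (mismatched id sets error).
#' @return List: `concordance_pct`, `n`, `confusion` (contingency table).
#' @export
subtype_concordance <- function(calls_a, calls_b) {
  if (!is.null(names(calls_a)) && !is.null(names(calls_b))) {
    if (!setequal(names(calls_a), names(calls_b))) {
      stop("sample ids of the two call sets differ", call. = FALSE)
    }
    calls_b <- calls_b[names(calls_a)]
  } else if (length(calls_a) != length(calls_b)) {
    stop("call vectors have different lengths and no ids to align by",
         call. = FALSE)
  }
  list(
    concordance_pct = 100 * mean(calls_a == calls_b),
    n = length(calls_a),
    confusion = table(a = calls_a, b = calls_b)
  )
}
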