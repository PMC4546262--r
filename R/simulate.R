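#' Default subtype expression templates
#'
#' Builds five per-gene log2 expression templates (four tumor subtypes
#' plus a non-tumor "Normal" profile) over the codeset's classifier
#' genes, with the marker structure the classifier expects: basal
#' cytokeratins high only in Basal-like, ERBB2/GRB7/FGFR4 high in
#' HER2-enriched, the estrogen module high in both luminal subtypes, and
#' the proliferation module separating Luminal A (low) from Luminal B
#' (high). Genes outside the named modules receive a small fixed
#' template-specific offset (drawn once from a fixed internal seed) so
#' templates differ over the full panel while remaining deterministic.
#'
#' @param codeset a [pam_codeset()].
#' @return A genes x 5 matrix (columns LumA, LumB, Her2E, Basal, Normal).
#' @export
default_templates <- function(codeset = pam50_codeset()) {
  genes <- codeset$classifier_genes
  er <- intersect(c("ESR1", "PGR", "FOXA1", "MLPH", "SLC39A6", "NAT1",
                    "MAPT", "BCL2", "BAG1", "CXXC5"), genes)
  basal <- intersect(c("KRT5", "KRT14", "KRT17", "FOXC1", "MIA", "CDH3",
                       "SFRP1", "EGFR", "PHGDH"), genes)
  her2 <- intersect(c("ERBB2", "GRB7", "FGFR4"), genes)
  prolif <- intersect(codeset$proliferation_subset, genes)

  tmpl <- matrix(0, length(genes), 5,
                 dimnames = list(genes,
                                 c(SUBTYPES, "Normal")))
  set_block <- function(t, col, set, val) { t[set, col] <- val; t }
  tmpl <- tmpl |>
    set_block("LumA", er, 2.2) |> set_block("LumA", prolif, -1.6) |>
    set_block("LumA", basal, -1.0) |> set_block("LumA", her2, -0.5) |>
    set_block("LumB", er, 1.8) |> set_block("LumB", prolif, 1.6) |>
    set_block("LumB", basal, -1.0) |> set_block("LumB", her2, -0.3) |>
    set_block("Her2E", her2, 2.5) |> set_block("Her2E", prolif, 1.5) |>
    set_block("Her2E", er, -1.5) |> set_block("Her2E", basal, -0.5) |>
    set_block("Basal", basal, 2.5) |> set_block("Basal", prolif, 1.8) |>
    set_block("Basal", er, -2.0) |> set_block("Basal", her2, -1.0) |>
    set_block("Normal", prolif, -2.0) |> set_block("Normal", er, 0.5) |>
    set_block("Normal", basal, 0.8)

  # deterministic per-template jitter for genes outside the modules
  in_module <- genes %in% c(er, basal, her2, prolif)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(101)
  jitter <- matrix(stats::rnorm(length(genes) * 5, sd = 0.35),
                   length(genes), 5)
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv())
  tmpl[!in_module, ] <- tmpl[!in_module, ] + jitter[!in_module, ]
  tmpl
}

#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults describe a mid-sized training cohort with clearly separated
#' subtypes, moderate per-gene measurement noise, realistic library-size
#' variation and a proportional-hazards outcome whose subtype log-hazard
#' pattern mirrors the published ordering (HER2-enriched worst, both
#' Luminal B and Basal-like elevated, Luminal A reference).
#'
#' @param n_per_subtype named integer vector of tumor sample counts.
#' @param n_normal number of non-tumor (reduction-mammoplasty-like)
#'   samples.
#' @param templates genes x 5 template matrix (see
#'   [default_templates()]).
#' @param noise_sd per-gene Gaussian noise SD on the log2 scale.
#' @param library_size_sdlog SD of the lognormal per-sample library-size
#'   factor.
#' @param baseline_log2 log2 of the count level a template value of 0
#'   maps to.
#' @param housekeeper_baseline counts of the housekeeper genes at unit
#'   library size (recycled over the codeset's housekeepers).
#' @param housekeeper_jitter_sdlog lognormal jitter SD on housekeepers.
#' @param negative_control_mean Poisson mean of background probes.
#' @param positive_control_scale counts per concentration unit for the
#'   positive-control titration.
#' @param subtype_log_hr named log hazard ratios of the four subtypes.
#' @param proliferation_coef,size_coef true linear-predictor coefficients
#'   on the (population-standardized) proliferation feature and the
#'   binary size indicator.
#' @param baseline_hazard events per year at linear predictor 0.
#' @param censoring_rate target fraction censored, in [0, 1).
#' @param size_meanlog,size_sdlog lognormal parameters of tumor size (cm).
#' @param seed mandatory integer seed.
#' @param codeset a [pam_codeset()].
#' @return A validated list of class `pam_sim_config`.
#' @export
sim_config <- function(n_per_subtype = c(LumA = 60, LumB = 50, Her2E = 40,
                                         Basal = 40),
                       n_normal = 12,
                       templates = default_templates(codeset),
                       noise_sd = 0.4,
                       library_size_sdlog = 0.2,
                       baseline_log2 = 9,
                       housekeeper_baseline = c(800, 1200, 600, 1500,
                                                1000, 900, 2000, 700),
                       housekeeper_jitter_sdlog = 0.05,
                       negative_control_mean = 8,
                       positive_control_scale = 30,
                       subtype_log_hr = c(LumA = 0, LumB = log(3),
                                          Her2E = log(5), Basal = log(3)),
                       proliferation_coef = 0.5,
                       size_coef = 0.6,
                       baseline_hazard = 0.05,
                       censoring_rate = 0.3,
                       size_meanlog = log(2),
                       size_sdlog = 0.45,
                       seed,
                       codeset = pam50_codeset()) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory",
                                           call. = FALSE)
  stopifnot(setequal(names(n_per_subtype), SUBTYPES),
            all(n_per_subtype >= 0), n_normal >= 0,
            noise_sd >= 0, library_size_sdlog >= 0,
            censoring_rate >= 0, censoring_rate < 1,
            baseline_hazard > 0,
            all(housekeeper_baseline > 0),
            negative_control_mean >= 0, positive_control_scale > 0,
            setequal(names(subtype_log_hr), SUBTYPES))
  stopifnot(all(codeset$classifier_genes %in% rownames(templates)),
            all(c(SUBTYPES, "Normal") %in% colnames(templates)))
  structure(
    list(n_per_subtype = n_per_subtype[SUBTYPES], n_normal = n_normal,
         templates = templates, noise_sd = noise_sd,
         library_size_sdlog = library_size_sdlog,
         baseline_log2 = baseline_log2,
         housekeeper_baseline = housekeeper_baseline,
         housekeeper_jitter_sdlog = housekeeper_jitter_sdlog,
         negative_control_mean = negative_control_mean,
         positive_control_scale = positive_control_scale,
         subtype_log_hr = subtype_log_hr[SUBTYPES],
         proliferation_coef = proliferation_coef, size_coef = size_coef,
         baseline_hazard = baseline_hazard,
         censoring_rate = censoring_rate,
         size_meanlog = size_meanlog, size_sdlog = size_sdlog,
         seed = as.integer(seed), codeset = codeset),
    class = "pam_sim_config"
  )
}

#' Simulate a raw count matrix with control probes
#'
#' Per sample: classifier log2 expression = subtype template + Gaussian
#' noise, exponentiated to counts around `2^baseline_log2` and multiplied
#' by a lognormal library-size factor; housekeepers = baseline counts x
#' library size x small lognormal jitter; negative controls Poisson;
#' positive controls Poisson around `concentration x scale`. All counts
#' are floored at 1 so every probe is strictly positive. Deterministic
#' under the config seed.
#'
#' @param config a [sim_config()].
#' @return List: `counts` (a [pam_expr()], all probes x samples),
#'   `truth` (tibble `sample`, `true_subtype`; `"Normal"` for non-tumor
#'   samples), `reference_profile` (named counts for classifier +
#'   housekeeper genes), `library_size` (named factors), `log2_signal`
#'   (the noiseless-plus-noise classifier log2 matrix before
#'   library-size effects, for diagnostics).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "pam_sim_config"))
  cs <- config$codeset
  set.seed(config$seed)
  labels <- c(rep(SUBTYPES, times = config$n_per_subtype),
              rep("Normal", config$n_normal))
  n <- length(labels)
  if (n == 0) stop("no samples requested", call. = FALSE)
  ids <- sprintf("S%03d", seq_len(n))
  genes <- cs$classifier_genes

  lib <- exp(stats::rnorm(n, 0, config$library_size_sdlog))
  names(lib) <- ids
  tmpl <- config$templates[genes, labels, drop = FALSE]
  noise <- matrix(stats::rnorm(length(genes) * n, 0, config$noise_sd),
                  length(genes), n)
  log2sig <- config$baseline_log2 + tmpl + noise
  cls_counts <- round(2^log2sig %*% diag(lib, n, n))

  hk_base <- rep_len(config$housekeeper_baseline,
                     length(cs$housekeeper_genes))
  hk_jit <- matrix(exp(stats::rnorm(length(hk_base) * n, 0,
                                    config$housekeeper_jitter_sdlog)),
                   length(hk_base), n)
  hk_counts <- round(hk_base * hk_jit %*% diag(lib, n, n))

  neg_counts <- matrix(stats::rpois(length(cs$negative_controls) * n,
                                    config$negative_control_mean),
                       length(cs$negative_controls), n)
  pos_lambda <- cs$positive_controls$concentration *
    config$positive_control_scale
  pos_counts <- matrix(stats::rpois(nrow(cs$positive_controls) * n,
                                    rep(pos_lambda, n)),
                       nrow(cs$positive_controls), n)

  m <- rbind(cls_counts, hk_counts, pos_counts, neg_counts)
  m <- pmax(m, 1)
  rownames(m) <- c(genes, cs$housekeeper_genes, cs$positive_controls$id,
                   cs$negative_controls)
  colnames(m) <- ids
  dimnames(log2sig) <- list(genes, ids)

  ref <- stats::setNames(
    c(rep(2^config$baseline_log2, length(genes)), hk_base),
    c(genes, cs$housekeeper_genes))

  list(
    counts = pam_expr(m, "raw_counts",
                      provenance = sprintf("simulated (seed=%d, n=%d)",
                                           config$seed, n)),
    truth = tibble::tibble(sample = ids, true_subtype = labels),
    reference_profile = ref,
    library_size = lib,
    log2_signal = log2sig
  )
}

#' Simulate proportional-hazards outcomes and clinical records
#'
#' Event times are exponential with hazard
#' `baseline_hazard * exp(subtype log-HR + b_P * proliferation + b_T *
#' size indicator)`. Independent exponential censoring is calibrated (by
#' root-finding on the censoring probability) to hit the configured
#' censoring rate in expectation. Tumor sizes are lognormal so both size
#' categories occur; event types are assigned consistently with the
#' endpoint semantics (recurrences and breast-cancer deaths for events;
#' event-free follow-up, contralateral disease or other-cause death for
#' censoring). Non-tumor samples receive no outcome records.
#'
#' @param truth tibble `sample`, `true_subtype` from
#'   [simulate_expression()].
#' @param features tibble `sample`, `proliferation` (population-scale
#'   feature used in the linear predictor).
#' @param config a [sim_config()].
#' @return List: `clinical` (tibble `sample`, `tumor_size_cm`,
#'   `node_status`, `treatment_label`, `followup_years`, `event_type`),
#'   `survival` (tibble `sample`, `time`, `event`, endpoint `"RFS"`),
#'   `linear_predictor` (named numeric; the generating truth).
#' @export
simulate_survival <- function(truth, features, config) {
  stopifnot(inherits(config, "pam_sim_config"))
  tumor <- dplyr::filter(tibble::as_tibble(truth),
                         .data$true_subtype %in% SUBTYPES)
  n <- nrow(tumor)
  if (n == 0) stop("no tumor samples", call. = FALSE)
  features <- tibble::as_tibble(features)
  pro <- features$proliferation[match(tumor$sample, features$sample)]
  if (any(is.na(pro))) stop("features not aligned to labels", call. = FALSE)

  set.seed(config$seed + 1L)
  size_cm <- stats::rlnorm(n, config$size_meanlog, config$size_sdlog)
  t_ind <- size_indicator(size_cm)
  lp <- unname(config$subtype_log_hr[tumor$true_subtype]) +
    config$proliferation_coef * pro + config$size_coef * t_ind
  rate <- config$baseline_hazard * exp(lp)
  if (all(rate <= 0)) stop("all-zero hazard", call. = FALSE)
  t_event <- stats::rexp(n, rate)

  q <- config$censoring_rate
  if (q > 0) {
    # exponential censoring at rate theta: P(censored) = theta/(theta+r)
    f <- function(theta) mean(theta / (theta + rate)) - q
    theta <- stats::uniroot(f, c(1e-9, 1e6), tol = 1e-10)$root
    t_cens <- stats::rexp(n, theta)
  } else {
    t_cens <- rep(Inf, n)
  }
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)

  ev_type <- ifelse(
    event == 1,
    sample(c("local_recurrence", "regional_recurrence",
             "distant_recurrence", "death_breast_cancer"),
           n, replace = TRUE, prob = c(0.12, 0.08, 0.60, 0.20)),
    sample(c("none", "contralateral_breast_cancer", "death_other"),
           n, replace = TRUE, prob = c(0.85, 0.07, 0.08)))

  list(
    clinical = tibble::tibble(
      sample = tumor$sample,
      tumor_size_cm = size_cm,
      node_status = "negative",
      treatment_label = "none",
      followup_years = time,
      event_type = ev_type
    ),
    survival = tibble::tibble(sample = tumor$sample, time = time,
                              event = event, endpoint = "RFS"),
    linear_predictor = stats::setNames(lp, tumor$sample)
  )
}

#' Simulate a complete cohort
#'
#' Chains [simulate_expression()] and [simulate_survival()]; the
#' proliferation feature driving the outcome model is the
#' population-standardized mean of the realized log2 signal over the
#' codeset's proliferation genes, so risk genuinely increases with
#' measured proliferation.
#'
#' @param config a [sim_config()].
#' @return A list merging the outputs of both generator stages plus
#'   `features` and the `config`.
#' @export
simulate_cohort <- function(config) {
  ex <- simulate_expression(config)
  prolif_genes <- intersect(config$codeset$proliferation_subset,
                            rownames(ex$log2_signal))
  pm <- colMeans(ex$log2_signal[prolif_genes, , drop = FALSE])
  features <- tibble::tibble(
    sample = names(pm),
    proliferation = as.numeric(scale(pm))
  )
  sv <- simulate_survival(ex$truth, features, config)
  c(ex, sv, list(features = features, config = config))
}
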