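test_that("proliferation score is the plain mean over the subset", {
  m <- matrix(c(1, 2, 3, 9, 9, 9), 6, 1,
              dimnames = list(paste0("g", 1:6), "s1"))
  xz <- pam_expr(m, "z_scaled")
  expect_equal(unname(proliferation_score(xz, c("g1", "g2", "g3"))), 2)
  expect_equal(unname(proliferation_score(xz, paste0("g", 1:3))[1]), 2)
  # all-zero subset values -> 0
  m0 <- matrix(0, 3, 2, dimnames = list(paste0("g", 1:3),
                                        c("a", "b")))
  expect_equal(unname(proliferation_score(pam_expr(m0, "z_scaled"),
                                          c("g1", "g2"))),
               c(0, 0))
  expect_error(proliferation_score(xz, c("g1", "gX")), "gX")
  expect_error(proliferation_score(xz, character()), "empty")
})

test_that("the 46-gene variant prunes its exclusions from the subset", {
  cs <- pam50_codeset()
  reduced <- setdiff(cs$proliferation_subset, cs$reduced_model_exclusions)
  expect_false(any(c("BIRC5", "CCNB1") %in% reduced))
  expect_true(all(c("GRB7", "MYBL2") %in% cs$reduced_model_exclusions))
  expect_setequal(union(reduced, intersect(cs$proliferation_subset,
                                           cs$reduced_model_exclusions)),
                  cs$proliferation_subset)
})

test_that("size indicator uses the strict 2.0 cm rule and flags missing", {
  expect_identical(size_indicator(c(2.0, 2.1, 0.5, NA)),
                   c(0L, 1L, 0L, NA_integer_))
  expect_error(size_indicator(-1), "positive")
})

test_that("ridge Cox matches a brute-force optimizer on a 5-subject toy", {
  set.seed(3)
  x <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("a", "b")))
  t <- c(2, 4, 3, 1, 5); e <- c(1, 0, 1, 1, 1)
  fit <- fit_ror_coefficients(x, data.frame(time = t, event = e),
                              lambda = 1, standardize = FALSE)
  # independent oracle: numerical optimizer of the penalized Breslow
  # partial likelihood
  pll <- function(beta) {
    eta <- drop(x %*% beta); ord <- order(t)
    tt <- t[ord]; ee <- e[ord]; et <- eta[ord]
    den <- rev(cumsum(rev(exp(et))))[match(tt, tt)]
    sum(ee * (et - log(den))) - sum(beta^2) / 2
  }
  opt <- optim(c(0, 0), function(b) -pll(b), method = "BFGS",
               control = list(reltol = 1e-14))
  expect_equal(unname(fit$coefficients), opt$par, tolerance = 1e-4)
})

test_that("the ridge penalty shrinks all coefficients to zero in the limit", {
  set.seed(13)
  x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  surv <- data.frame(time = rexp(20, 0.2 * exp(x[, 1])),
                     event = rbinom(20, 1, 0.8))
  fit <- fit_ror_coefficients(x, surv, lambda = 1e8, standardize = FALSE)
  expect_lt(sqrt(sum(fit$coefficients^2)), 1e-4)
})

test_that("ridge Cox recovers a single true coefficient at large n", {
  set.seed(4)
  n <- 2000
  z <- rnorm(n)
  t_ev <- rexp(n, 0.1 * exp(0.7 * z))
  t_cs <- rexp(n, 0.025)
  surv <- data.frame(time = pmin(t_ev, t_cs),
                     event = as.integer(t_ev <= t_cs))
  fit <- fit_ror_coefficients(matrix(z, ncol = 1,
                                     dimnames = list(NULL, "z")),
                              surv, lambda = 0, standardize = FALSE)
  expect_equal(unname(fit$coefficients), 0.7, tolerance = 0.1 / 0.7)
  expect_lt(abs(unname(fit$coefficients) - 0.7), 0.1)
})

test_that("automatic lambda selection is deterministic under a seed", {
  set.seed(14)
  n <- 120
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  surv <- data.frame(time = rexp(n, 0.2 * exp(0.5 * x[, 1])),
                     event = rbinom(n, 1, 0.8))
  f1 <- fit_ror_coefficients(x, surv, lambda = "auto", nfolds = 4, seed = 9)
  f2 <- fit_ror_coefficients(x, surv, lambda = "auto", nfolds = 4, seed = 9)
  expect_identical(f1$lambda, f2$lambda)
  expect_identical(f1$coefficients, f2$coefficients)
  expect_s3_class(f1$cv, "tbl_df")
})

test_that("no events is rejected", {
  x <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(fit_ror_coefficients(x, data.frame(time = 1:5,
                                                  event = rep(0, 5)),
                                    lambda = 1),
               "event")
})

test_that("raw score is the linear predictor, additively in each term", {
  model <- structure(list(coefficients = c(rho_LumA = 1, rho_LumB = 0,
                                           rho_Her2E = 0, rho_Basal = 0,
                                           proliferation = 0,
                                           size_indicator = 0)),
                     class = "pam_ror_model")
  feats <- tibble::tibble(rho_LumA = 0.5, rho_LumB = 0.2, rho_Her2E = 0,
                          rho_Basal = -0.1, proliferation = 1,
                          size_indicator = 1)
  expect_equal(ror_raw(feats, model), 0.5)

  zero <- feats
  zero[1, ] <- 0
  expect_equal(ror_raw(zero, model), 0)

  model$coefficients[] <- c(0.3, -0.2, 0.5, 0.1, 0.4, 0.25)
  f0 <- feats; f0$size_indicator <- 0
  f1 <- feats; f1$size_indicator <- 1
  expect_equal(ror_raw(f1, model) - ror_raw(f0, model), 0.25)
})

test_that("the 0-100 scaling maps the cohort extremes exactly", {
  sc <- fit_ror_scaler(c(-2, 3))
  expect_equal(sc$alpha, 40)
  expect_equal(sc$beta, 20)
  expect_equal(ror_scaled(c(-2, 3), sc), c(0, 100))
  # midpoint maps to 50
  expect_equal(ror_scaled(0.5, sc), 50)
  # out-of-range values clamp with a warning
  expect_warning(low <- ror_scaled(-5, sc), "clamped")
  expect_equal(low, 0)
  expect_error(fit_ror_scaler(rep(1.3, 4)), "constant")
})

test_that("risk groups follow the strict 40/60 cutoffs", {
  expect_identical(risk_group(c(39.9, 40, 50, 60, 61)),
                   c("low", "intermediate", "intermediate", "intermediate",
                     "high"))
  expect_error(risk_group(50, node_status = "positive"), "node-negative")
})

test_that("trained ROR scores rank simulated risk and respect the contract", {
  sim <- small_cohort(seed = 41)
  cs <- sim$config$codeset
  xn <- normalize_counts(sim$counts, cs, sim$reference_profile)
  tr <- train_centroids(xn, cs, n_sim = 200, seed = 3)
  surv <- derive_endpoint(sim$clinical, "RFS")
  m <- train_ror(xn, tr$model, sim$clinical, surv, cs, lambda = 0.1,
                 seed = 2)
  sc <- score_samples(xn, tr$model, m, sim$clinical, cs)
  expect_true(all(sc$scaled_score >= 0 & sc$scaled_score <= 100))
  expect_true(all(sc$risk_group %in% c("low", "intermediate", "high")))

  # training-cohort scores discriminate outcome clearly better than chance
  ci <- c_index(sc$scaled_score,
                surv[match(sc$sample, surv$sample), ])
  expect_gt(ci, 0.6)

  # monotonicity in proliferation when its coefficient is positive
  expect_gt(unname(m$coefficients["proliferation"]), 0)
  base <- sc[1, ]
  probe <- tibble::tibble(
    rho_LumA = base$rho_LumA, rho_LumB = base$rho_LumB,
    rho_Her2E = base$rho_Her2E, rho_Basal = base$rho_Basal,
    proliferation = seq(-2, 2, length.out = 9),
    size_indicator = base$size_indicator)
  raws <- ror_raw(probe, m)
  expect_true(all(diff(raws) > 0))

  # single-sample contract: a subset batch scores identically
  sub <- sim$clinical[1:5, ]
  sc_sub <- score_samples(xn, tr$model, m, sub, cs)
  joint <- sc[match(sc_sub$sample, sc$sample), ]
  expect_equal(sc_sub$scaled_score, joint$scaled_score, tolerance = 1e-12)
  expect_identical(sc_sub$risk_group, joint$risk_group)
})

test_that("variant comparison is reflexive and near-identity on cohorts", {
  sim <- small_cohort(seed = 42)
  cs <- sim$config$codeset
  xn <- normalize_counts(sim$counts, cs, sim$reference_profile)
  tr <- train_centroids(xn, cs, n_sim = 200, seed = 4)
  surv <- derive_endpoint(sim$clinical, "RFS")
  cmp <- compare_variants(xn, tr$model, sim$clinical, surv, cs,
                          lambda = 0.1, seed = 2)
  expect_gte(cmp$r_squared, 0.95)
  expect_equal(cmp$slope, 1, tolerance = 0.15)

  # a variant against itself is exactly R^2 = 1, slope 1, intercept 0
  s50 <- score_samples(xn, tr$model, cmp$models$`50-gene`, sim$clinical, cs)
  self_fit <- lm(y ~ x, data = data.frame(x = s50$scaled_score,
                                          y = s50$scaled_score))
  expect_equal(unname(coef(self_fit)), c(0, 1), tolerance = 1e-10)
  expect_equal(summary(self_fit)$r.squared, 1)

  # breaking the pairing destroys the agreement
  set.seed(1)
  shuffled <- cor(cmp$paired$scaled_50, sample(cmp$paired$scaled_46))^2
  expect_lt(shuffled, 0.2)
})
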