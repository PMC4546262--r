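test_that("endpoint derivation applies the event and censoring rules", {
  rec <- tibble::tibble(
    sample = paste0("p", 1:6),
    followup_years = c(4.2, 6, 3, 8, 5, 7),
    event_type = c("contralateral_breast_cancer", "death_breast_cancer",
                   "local_recurrence", "none", "death_other",
                   "distant_recurrence"))
  rfs <- derive_endpoint(rec, "RFS")
  expect_equal(rfs$time, rec$followup_years)
  # contralateral censors; breast-cancer death without recurrence is an
  # event at the death date; local recurrence is an event
  expect_equal(rfs$event, c(0L, 1L, 1L, 0L, 0L, 1L))

  drfs <- derive_endpoint(rec, "DRFS")
  # local recurrence censors under DRFS; distant and bc-death are events
  expect_equal(drfs$event, c(0L, 1L, 0L, 0L, 0L, 1L))

  dss <- derive_endpoint(rec, "DSS")
  expect_equal(dss$event, c(0L, 1L, 0L, 0L, 0L, 0L))

  expect_error(derive_endpoint(dplyr::mutate(rec, event_type = "galaxy"),
                               "RFS"),
               "galaxy")
})

test_that("c-index is 1 for perfectly anti-ordered scores and matches a
          hand-enumerated pair table", {
  surv <- data.frame(time = c(1, 2, 3, 4), event = c(1, 1, 0, 1))
  expect_equal(c_index(c(4, 3, 2, 1), surv), 1)
  # hand enumeration for scores (1,3,2,4): comparable pairs are
  # (1,2),(1,3),(1,4),(2,3),(2,4); only (2,3) is concordant -> 1/5
  expect_equal(c_index(c(1, 3, 2, 4), surv), 0.2)
  # complement identity without score ties
  expect_equal(c_index(c(4, 3, 2, 1), surv) +
                 c_index(-c(4, 3, 2, 1), surv), 1)
  expect_error(c_index(c(1, 2), data.frame(time = c(1, 2),
                                           event = c(0, 0))),
               "comparable")
})

test_that("c-index equals the brute-force pair enumeration with ties and
          censoring", {
  set.seed(2)
  for (rep in 1:60) {
    n <- sample(5:50, 1)
    time <- sample(1:8, n, replace = TRUE)
    event <- rbinom(n, 1, 0.6)
    scores <- sample(1:5, n, replace = TRUE)
    oracle <- brute_force_cindex(scores, time, event)
    if (is.na(oracle)) {
      expect_error(c_index(scores, data.frame(time = time, event = event)))
    } else {
      expect_equal(c_index(scores, data.frame(time = time, event = event)),
                   oracle, tolerance = 1e-12)
    }
  }
})

test_that("c-index agrees with survival::concordance", {
  set.seed(3)
  for (rep in 1:20) {
    n <- sample(10:60, 1)
    time <- round(rexp(n, 0.2), 2)
    event <- rbinom(n, 1, 0.7)
    scores <- rnorm(n)
    cf <- survival::concordance(survival::Surv(time, event) ~ scores,
                                reverse = TRUE)$concordance
    expect_equal(c_index(scores, data.frame(time = time, event = event)),
                 cf, tolerance = 1e-12)
  }
})

test_that("bootstrap c-index is reproducible and self-difference is zero", {
  set.seed(5)
  n <- 80
  risk <- rnorm(n)
  surv <- data.frame(time = rexp(n, 0.2 * exp(0.8 * risk)),
                     event = rbinom(n, 1, 0.85))
  b1 <- bootstrap_c_index(list(m = risk, same = risk), surv,
                          n_boot = 100, seed = 7)
  expect_equal(b1$differences$mean_difference, 0)
  expect_equal(unname(b1$differences$ci_lower), 0)
  b2 <- bootstrap_c_index(list(m = risk, same = risk), surv,
                          n_boot = 100, seed = 7)
  expect_identical(b1$replicates, b2$replicates)
})

test_that("an informative score separates from a random one under the
          bootstrap", {
  set.seed(6)
  n <- 300
  risk <- rnorm(n)
  surv <- data.frame(time = rexp(n, 0.1 * exp(1.2 * risk)),
                     event = rbinom(n, 1, 0.8))
  noise <- rnorm(n)
  b <- bootstrap_c_index(list(informative = risk, random = noise), surv,
                         n_boot = 200, seed = 8)
  s <- b$summary
  expect_gt(s$ci_lower[s$model == "informative"],
            s$ci_upper[s$model == "random"])
})

test_that("subtype hazard ratios behave under identity, recovery and
          relabeling", {
  # identical event patterns in two groups -> HR 1
  surv <- data.frame(time = rep(c(1, 2, 3, 4), 2),
                     event = rep(c(1, 0, 1, 1), 2))
  labs <- rep(c("LumA", "LumB"), each = 4)
  hr <- cox_hazard_ratios(labs, surv)
  expect_equal(hr$hr[hr$subtype == "LumB"], 1, tolerance = 1e-6)

  # parameter recovery at n = 2000 with true HR 3
  set.seed(7)
  n <- 2000
  lab2 <- sample(c("LumA", "LumB"), n, replace = TRUE)
  rate <- 0.08 * ifelse(lab2 == "LumB", 3, 1)
  t_ev <- rexp(n, rate); t_cs <- rexp(n, 0.03)
  surv2 <- data.frame(time = pmin(t_ev, t_cs),
                      event = as.integer(t_ev <= t_cs))
  hr2 <- cox_hazard_ratios(lab2, surv2)
  est <- hr2$hr[hr2$subtype == "LumB"]
  expect_gt(est, 2.4); expect_lt(est, 3.75)

  # swapping the reference inverts the ratio
  hr_rev <- cox_hazard_ratios(lab2, surv2, reference = "LumB")
  expect_equal(est * hr_rev$hr[hr_rev$subtype == "LumA"], 1,
               tolerance = 1e-9)

  # invariance to time-unit rescaling
  surv_m <- transform(surv2, time = time * 12)
  hr_m <- cox_hazard_ratios(lab2, surv_m)
  expect_equal(hr_m$hr, hr2$hr, tolerance = 1e-9)
})

test_that("administrative truncation censors beyond the horizon", {
  surv <- data.frame(time = c(2, 9, 11, 15, 10), event = c(1, 1, 1, 0, 1))
  labs <- c("LumA", "LumA", "LumB", "LumB", "LumB")
  hr <- cox_hazard_ratios(labs, surv, truncate_years = 10)
  tab <- hr[hr$subtype == "LumB", ]
  # the event at 11 y is censored at 10; the event at exactly 10 y remains
  expect_equal(tab$events, 1L)
})

test_that("zero-event subtypes are flagged with an unstable upper CI", {
  surv <- data.frame(time = c(1, 2, 3, 4, 5, 2, 4, 6, 8, 3, 5, 7),
                     event = c(1, 1, 1, 0, 1, 1, 1, 1, 0, 0, 0, 0))
  labs <- c(rep("LumA", 5), rep("LumB", 4), rep("Basal", 3))
  expect_warning(hr <- cox_hazard_ratios(labs, surv), "Basal")
  expect_equal(hr$ci_upper[hr$subtype == "Basal"], Inf)
})

test_that("Kaplan-Meier matches the hand product-limit and log-rank null", {
  # two subjects, both events: S = 0.5 after t=1, 0 after t=2
  km <- kaplan_meier(data.frame(time = c(1, 2), event = c(1, 1)),
                     rep("g", 2))
  expect_equal(km$curves$survival, c(0.5, 0))

  # no events -> survival stays 1
  km0 <- kaplan_meier(data.frame(time = c(1, 2, 3), event = c(0, 0, 0)),
                      rep("g", 3))
  expect_true(all(km0$curves$survival == 1))

  # randomized instances against the hand estimator
  set.seed(8)
  for (rep in 1:40) {
    n <- sample(2:5, 1)
    time <- sample(1:4, n, replace = TRUE)
    event <- rbinom(n, 1, 0.6)
    km_i <- kaplan_meier(data.frame(time = time, event = event),
                         rep("g", n))
    oracle <- product_limit(time, event)
    expect_equal(km_i$curves$time, oracle$time)
    expect_equal(km_i$curves$survival, oracle$survival, tolerance = 1e-12)
  }

  # identical groups -> log-rank statistic near zero
  surv <- data.frame(time = rep(c(1, 2, 3, 4, 6), 2),
                     event = rep(c(1, 1, 0, 1, 1), 2))
  km2 <- kaplan_meier(surv, rep(c("a", "b"), each = 5))
  expect_lt(km2$logrank_chisq, 1e-9)
  expect_gt(km2$logrank_p, 0.99)

  expect_warning(kaplan_meier(surv, factor(rep("a", 10),
                                           levels = c("a", "empty"))),
                 "empty")
})

test_that("ICC matches the ANOVA mean-square formula and its edge cases", {
  # identical replicates per subject, subjects differ -> ICC 1
  m <- cbind(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(icc(m), 1)

  # 4 x 2 toy table against mean squares computed via aov (independent
  # route through R's ANOVA machinery)
  m2 <- matrix(c(9, 10, 6, 8, 7, 6, 4, 5), 4, 2)
  long <- data.frame(y = as.vector(m2),
                     subject = factor(rep(1:4, 2)),
                     rater = factor(rep(1:2, each = 4)))
  ms <- summary(aov(y ~ subject + rater, data = long))[[1]]$`Mean Sq`
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  k <- 2; n <- 4
  oracle <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  expect_equal(icc(m2), oracle, tolerance = 1e-6)

  # pure noise at n = 500 -> ICC near 0
  set.seed(9)
  m3 <- matrix(rnorm(1000), 500, 2)
  expect_lt(abs(icc(m3)), 0.1)

  # constant data undefined
  expect_message(v <- icc(matrix(5, 3, 2)), "undefined")
  expect_true(is.na(v))
  expect_error(icc(matrix(1:2, 1, 2)), "subjects")
})

test_that("subtype concordance counts exact agreement", {
  a <- rep(c("LumA", "LumB"), 25)
  expect_equal(subtype_concordance(a, a)$concordance_pct, 100)
  b <- a; b[1] <- "Basal"
  expect_equal(subtype_concordance(a, b)$concordance_pct, 98)
  # named vectors align by sample id
  names(a) <- names(b) <- paste0("s", 1:50)
  expect_equal(subtype_concordance(a, b[sample(names(b))])$concordance_pct,
               98)
  names(b)[1] <- "zz"
  expect_error(subtype_concordance(a, b), "ids")
})

test_that("replicate expression profiles give concordant calls at low
          noise", {
  cfg1 <- sim_config(seed = 51, noise_sd = 0.25,
                     n_per_subtype = c(LumA = 20, LumB = 20, Her2E = 20,
                                       Basal = 20), n_normal = 0)
  sim <- simulate_cohort(cfg1)
  cs <- cfg1$codeset
  xn <- normalize_counts(sim$counts, cs, sim$reference_profile)
  tr <- train_centroids(xn, cs, n_sim = 150, seed = 2)
  xz <- apply_gene_scaler(xn, tr$model$scaler)
  calls_a <- classify_cohort(xz, tr$model)$calls

  # an independent replicate of the same cohort design
  cfg2 <- sim_config(seed = 52, noise_sd = 0.25,
                     n_per_subtype = c(LumA = 20, LumB = 20, Her2E = 20,
                                       Basal = 20), n_normal = 0)
  sim2 <- simulate_cohort(cfg2)
  xn2 <- normalize_counts(sim2$counts, cs, sim2$reference_profile)
  xz2 <- apply_gene_scaler(xn2, tr$model$scaler)
  calls_b <- classify_cohort(xz2, tr$model)$calls

  # same generating labels order in both cohorts -> compare positionally
  conc <- subtype_concordance(calls_a$subtype, calls_b$subtype)
  expect_gte(conc$concordance_pct, 95)
})
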