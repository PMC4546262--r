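test_that("positive-control linearity gives R2 = 1 for proportional counts", {
  cs <- tiny_codeset()
  x <- tiny_counts()
  # counts exactly proportional to expected concentrations, pseudocount 0
  m <- unclass(x)
  m[cs$positive_controls$id, ] <- cs$positive_controls$concentration * 40
  qc <- qc_sample(pam_expr(m, "raw_counts"), cs, pseudocount = 0)
  expect_equal(qc$positive_control_r2, rep(1, ncol(m)), tolerance = 1e-12)
})

test_that("background and low-signal flag follow the mean + 2 SD rule", {
  cs <- tiny_codeset()
  base <- unclass(tiny_counts(1))

  # negative controls all 0, housekeepers 100 -> background 0, no flag
  m <- base
  m[cs$negative_controls, ] <- 0
  m[cs$housekeeper_genes, ] <- 100
  qc <- qc_sample(pam_expr(m, "raw_counts"), cs)
  expect_equal(qc$background_level, 0)
  expect_false(qc$low_signal_flag)
  expect_true(qc$pass)

  # the stated worked case: 8 negative controls, housekeepers at 5
  cs8 <- pam_codeset(paste0("g", 1:6), c("hk1", "hk2"),
                     data.frame(id = paste0("P", 1:6),
                                concentration = c(128, 32, 8, 2, 0.5, 0.125)),
                     paste0("N", 1:8), name = "tiny8")
  probes <- c(cs8$classifier_genes, cs8$housekeeper_genes,
              cs8$positive_controls$id, cs8$negative_controls)
  m8 <- matrix(100, length(probes), 1, dimnames = list(probes, "s1"))
  m8[cs8$positive_controls$id, ] <- cs8$positive_controls$concentration * 20
  m8[cs8$negative_controls, ] <- c(10, 12, 8, 11, 9, 10, 12, 8)
  m8[cs8$housekeeper_genes, ] <- 5
  qc8 <- qc_sample(pam_expr(m8, "raw_counts"), cs8)
  expect_equal(qc8$background_level, 10 + 2 * sd(c(10, 12, 8, 11, 9, 10, 12, 8)))
  expect_true(qc8$low_signal_flag)
  expect_false(qc8$pass)  # pass is FALSE whenever low_signal_flag is TRUE
})

test_that("qc_sample names a missing control probe", {
  cs <- tiny_codeset()
  m <- unclass(tiny_counts())
  m <- m[setdiff(rownames(m), "P3"), ]
  expect_error(qc_sample(pam_expr(m, "raw_counts"), cs), "P3")
})

test_that("qc_sample is permutation-invariant in sample order", {
  cs <- tiny_codeset()
  x <- tiny_counts(4, seed = 9)
  qc <- qc_sample(x, cs)
  perm <- c(3, 1, 4, 2)
  qc_p <- qc_sample(pam_expr(unclass(x)[, perm], "raw_counts"), cs)
  expect_equal(qc_p, qc[perm, ], ignore_attr = TRUE)
})

test_that("normalization reproduces the hand-computed log-ratio case", {
  # 2 housekeepers with ratios 4 and 1 (log2: 2, 0); classifier ratio 2
  # (log2: 1) -> normalized value 1 - mean(2, 0) = 0
  cs <- pam_codeset("g1", c("hk1", "hk2"),
                    data.frame(id = "P1", concentration = 1), "N1")
  m <- matrix(c(2, 4, 1), 3, 1, dimnames = list(c("g1", "hk1", "hk2"), "s"))
  ref <- c(g1 = 1, hk1 = 1, hk2 = 1)
  out <- normalize_counts(pam_expr(m, "raw_counts"), cs, ref,
                          pseudocount = 0)
  expect_equal(unclass(out)["g1", "s"], 0)
  expect_identical(attr(out, "value_space"), "log2_normalized")
})

test_that("counts identical to the reference normalize to all zeros", {
  cs <- tiny_codeset()
  x <- tiny_counts(2)
  genes <- c(cs$classifier_genes, cs$housekeeper_genes)
  ref <- unclass(x)[genes, 1]
  m <- unclass(x)
  m[genes, ] <- ref
  out <- normalize_counts(pam_expr(m, "raw_counts"), cs, ref,
                          pseudocount = 0)
  expect_equal(max(abs(unclass(out))), 0)
})

test_that("normalization is invariant to global per-sample scaling", {
  cs <- tiny_codeset()
  x <- tiny_counts(3, seed = 4)
  ref <- unclass(x)[c(cs$classifier_genes, cs$housekeeper_genes), 1]
  out1 <- normalize_counts(x, cs, ref, pseudocount = 0)
  m16 <- unclass(x); m16[, 2] <- m16[, 2] * 16
  out2 <- normalize_counts(pam_expr(m16, "raw_counts"), cs, ref,
                           pseudocount = 0)
  expect_equal(unclass(out2), unclass(out1), tolerance = 1e-12)
})

test_that("housekeeper mean of normalized values is 0 per sample", {
  cs <- tiny_codeset()
  x <- tiny_counts(5, seed = 6)
  out <- normalize_counts(x, cs, reference_profile = NULL, pseudocount = 1)
  hk_means <- colMeans(unclass(out)[cs$housekeeper_genes, ])
  expect_lt(max(abs(hk_means)), 1e-9)
})

test_that("normalization errors on bad reference profiles", {
  cs <- tiny_codeset()
  x <- tiny_counts()
  genes <- c(cs$classifier_genes, cs$housekeeper_genes)
  ref <- unclass(x)[genes, 1]
  ref["g1"] <- 0
  expect_error(normalize_counts(x, cs, ref), "positive")
  expect_error(normalize_counts(x, cs, ref[-1]), "g1")
})

test_that("coefficient of variation matches direct arithmetic", {
  m <- rbind(a = c(100, 100, 100), b = c(90, 100, 110))
  cv <- coefficient_of_variation(m)
  expect_equal(cv$per_gene$cv_pct[1], 0)
  expect_equal(cv$per_gene$cv_pct[2], 10)
  expect_equal(cv$median_cv_pct, 5)

  # a gene with one replicate is missing and excluded from the median
  m2 <- rbind(a = c(100, 110, NA), b = c(50, NA, NA), c = c(10, 30, NA))
  cv2 <- coefficient_of_variation(m2)
  expect_true(is.na(cv2$per_gene$cv_pct[2]))
  expect_equal(cv2$median_cv_pct,
               median(cv2$per_gene$cv_pct, na.rm = TRUE))
})
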