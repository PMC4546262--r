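# shared in-code fixtures for the unit tests

tiny_codeset <- function() {
  pam_codeset(
    classifier_genes = paste0("g", 1:6),
    housekeeper_genes = c("hk1", "hk2"),
    positive_controls = data.frame(
      id = paste0("P", 1:6),
      concentration = c(128, 32, 8, 2, 0.5, 0.125)),
    negative_controls = c("N1", "N2"),
    proliferation_subset = c("g1", "g2"),
    reduced_model_exclusions = c("g5", "g6"),
    name = "tiny"
  )
}

# counts matrix containing every probe role of tiny_codeset()
tiny_counts <- function(n_samples = 3, seed = 1) {
  set.seed(seed)
  cs <- tiny_codeset()
  probes <- c(cs$classifier_genes, cs$housekeeper_genes,
              cs$positive_controls$id, cs$negative_controls)
  m <- matrix(rpois(length(probes) * n_samples, 200),
              length(probes), n_samples,
              dimnames = list(probes, paste0("s", seq_len(n_samples))))
  m[cs$positive_controls$id, ] <- round(cs$positive_controls$concentration * 20)
  m[cs$negative_controls, ] <- 5
  pam_expr(m, "raw_counts")
}

# write one per-sample count file in the package's RCC-like dialect
write_rcc_fixture <- function(path, sample_id, probes, counts,
                              classes = rep("Endogenous", length(probes))) {
  lines <- c(
    "# test fixture",
    "<Header>",
    paste0("sample_id,", sample_id),
    "instrument,synthetic",
    "</end>",
    "<Code_Summary>",
    sprintf("%s,%s,NA,%s", classes, probes, format(counts, trim = TRUE)),
    "</end>"
  )
  writeLines(lines, path)
  path
}

# brute-force UPGMA oracle: recomputes every inter-cluster average from the
# original distance matrix at each step (independent of the package's
# incremental update), same lowest-index tie-break
brute_force_upgma <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- NULL
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        key <- c(h, min(clusters[[i]], clusters[[j]]),
                 max(min(clusters[[i]]), min(clusters[[j]])))
        if (is.null(best) || h < best$h - 1e-12 ||
            (abs(h - best$h) <= 1e-12 &&
             (key[2] < best$key[2] ||
              (key[2] == best$key[2] && key[3] < best$key[3])))) {
          best <- list(h = h, i = i, j = j, key = key)
        }
      }
    }
    merged <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    clusters[[best$i]] <- merged
    clusters[[best$j]] <- NULL
    heights <- c(heights, best$h)
    partitions <- c(partitions, list(lapply(clusters, sort)))
  }
  list(heights = heights, partitions = partitions)
}

# canonical form of a partition (set of clusters) for comparison
canon_partition <- function(p) {
  sort(vapply(p, function(cl) paste(sort(cl), collapse = ","), character(1)))
}

# partition of leaves after each merge step of an hclust tree
hclust_partitions <- function(hc) {
  n <- length(hc$height) + 1
  clusters <- as.list(seq_len(n))
  names(clusters) <- as.character(-seq_len(n))
  out <- list()
  for (s in seq_len(n - 1)) {
    a <- as.character(hc$merge[s, 1]); b <- as.character(hc$merge[s, 2])
    clusters[[as.character(s)]] <- sort(c(clusters[[a]], clusters[[b]]))
    clusters[[a]] <- NULL; clusters[[b]] <- NULL
    out <- c(out, list(unname(clusters)))
  }
  out
}

# brute-force Harrell C: literal double loop over ordered pairs
brute_force_cindex <- function(scores, time, event) {
  num <- 0; den <- 0
  n <- length(scores)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      comparable <- (time[i] < time[j] && event[i] == 1) ||
        (time[i] == time[j] && event[i] == 1 && event[j] == 0)
      if (!comparable) next
      den <- den + 1
      if (scores[i] > scores[j]) num <- num + 1
      else if (scores[i] == scores[j]) num <- num + 0.5
    }
  }
  if (den == 0) return(NA_real_)
  num / den
}

# hand product-limit estimator at the observed times of one group
product_limit <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  ut <- sort(unique(time))
  s <- 1
  surv <- numeric(length(ut))
  for (k in seq_along(ut)) {
    at_risk <- sum(time >= ut[k])
    d <- sum(time == ut[k] & event == 1)
    s <- s * (1 - d / at_risk)
    surv[k] <- s
  }
  data.frame(time = ut, survival = surv)
}

# small, fast simulated cohort for integration-style tests
small_cohort <- function(seed = 11, noise_sd = 0.3,
                         n = c(LumA = 40, LumB = 35, Her2E = 30,
                               Basal = 30),
                         n_normal = 10, ...) {
  simulate_cohort(sim_config(n_per_subtype = n, n_normal = n_normal,
                             noise_sd = noise_sd, seed = seed, ...))
}

# bare numeric matrix of a pam_expr (drops provenance bookkeeping)
expr_values <- function(x) {
  m <- unclass(x)
  attr(m, "provenance") <- NULL
  attr(m, "value_space") <- NULL
  m
}
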