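#' Pearson correlation distance between samples
#'
#' `d(i, j) = 1 - cor(x_i, x_j)` over genes, for every pair of sample
#' columns. The result is symmetric with a zero diagonal and values in
#' `[0, 2]`.
#'
#' @param x a [pam_expr()] or numeric matrix, genes in rows, samples in
#'   columns.
#' @return A samples-by-samples numeric distance matrix.
#' @export
pearson_distance <- function(x) {
  m <- as.matrix(unclass(x))
  sds <- apply(m, 2, stats::sd)
  flat <- which(sds == 0 | !is.finite(sds))
  if (length(flat) > 0) {
    stop("constant sample vector(s): ",
         paste(colnames(m)[flat] %||% flat, collapse = ", "), call. = FALSE)
  }
  d <- 1 - stats::cor(m)
  d[d < 0] <- 0           # guard fp noise
  diag(d) <- 0
  d
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Deterministic UPGMA over a precomputed distance matrix: the merge
#' height of two clusters is the arithmetic mean of all inter-cluster
#' pairwise distances. Ties in the minimum inter-cluster distance are
#' broken by the lexicographically lowest pair of original sample indices
#' (each cluster represented by its smallest member index), which makes
#' the dendrogram reproducible where generic implementations are not.
#'
#' @param d symmetric numeric distance matrix with zero diagonal.
#' @return An object of class `hclust` (merge, height, order, labels),
#'   usable with [stats::cutree()] and plotting.
#' @export
average_linkage <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n != ncol(d) || any(abs(d - t(d)) > 1e-12)) {
    stop("distance matrix must be square and symmetric", call. = FALSE)
  }
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  labels <- rownames(d) %||% as.character(seq_len(n))

  # active-cluster bookkeeping
  dc <- d
  diag(dc) <- Inf
  active <- rep(TRUE, n)
  size <- rep(1L, n)
  node_id <- -seq_len(n)        # hclust convention: negatives = leaves
  rep_idx <- seq_len(n)         # smallest original member index per cluster
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)

  for (s in seq_len(n - 1)) {
    dmin <- min(dc[active, active])
    cand <- which(dc == dmin & outer(active, active, "&"), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- cbind(pmin(rep_idx[cand[, 1]], rep_idx[cand[, 2]]),
                 pmax(rep_idx[cand[, 1]], rep_idx[cand[, 2]]))
    pick <- order(key[, 1], key[, 2])[1]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    merge[s, ] <- sort(c(node_id[i], node_id[j]))
    height[s] <- dmin
    # weighted average update (UPGMA): i absorbs j
    others <- which(active); others <- setdiff(others, c(i, j))
    if (length(others) > 0) {
      newd <- (size[i] * dc[i, others] + size[j] * dc[j, others]) /
        (size[i] + size[j])
      dc[i, others] <- newd
      dc[others, i] <- newd
    }
    size[i] <- size[i] + size[j]
    rep_idx[i] <- min(rep_idx[i], rep_idx[j])
    node_id[i] <- s
    active[j] <- FALSE
    dc[j, ] <- Inf
    dc[, j] <- Inf
  }

  structure(
    list(merge = merge, height = height,
         order = hclust_leaf_order(merge, n),
         labels = labels, method = "average",
         call = match.call(), dist.method = "precomputed"),
    class = "hclust"
  )
}

# leaf ordering by depth-first traversal of the merge matrix
hclust_leaf_order <- function(merge, n) {
  out <- integer(0)
  stack <- nrow(merge)  # root
  while (length(stack) > 0) {
    node <- stack[1]
    stack <- stack[-1]
    if (node < 0) {
      out <- c(out, -node)
    } else {
      stack <- c(merge[node, 1], merge[node, 2], stack)
    }
  }
  out
}

# member leaf indices of each internal node
hclust_members <- function(hc) {
  n <- nrow(hc$merge) + 1
  members <- vector("list", n - 1)
  for (s in seq_len(n - 1)) {
    m <- hc$merge[s, ]
    members[[s]] <- sort(c(
      if (m[1] < 0) -m[1] else members[[m[1]]],
      if (m[2] < 0) -m[2] else members[[m[2]]]
    ))
  }
  members
}

#' Monte-Carlo significance test for a cluster split
#'
#' Tests whether the two-way split observed at a dendrogram node is
#' stronger than expected from a single multivariate Gaussian, in the
#' style of the SigClust procedure. The statistic is the 2-means cluster
#' index — within-cluster sum of squares of the split divided by total
#' sum of squares. The null model is a single Gaussian with diagonal
#' covariance whose eigenvalue spectrum is the sample covariance spectrum
#' of the node's data, hard-thresholded from below at a background noise
#' variance estimated by the scaled MAD of all matrix entries (the cluster
#' index is rotation invariant, so only the spectrum matters). For each of
#' `n_sim` null datasets the minimal 2-means cluster index is found by a
#' compiled Lloyd search, and the p-value is the fraction of null indices
#' at or below the observed one.
#'
#' @param x node-scope data: a [pam_expr()] or matrix, genes in rows,
#'   samples (the node's members) in columns.
#' @param cluster_members sample ids (or column indices) forming one side
#'   of the split; the remaining columns form the other side.
#' @param n_sim number of null datasets (values below 100 trigger a
#'   warning: the p-value resolution becomes too coarse).
#' @param seed optional integer seed for reproducibility.
#' @param n_start random restarts of the null 2-means search.
#' @param background_var optional fixed background noise variance;
#'   default estimated from the data by `mad(x)^2`.
#' @return A list of class `pam_sigclust`: `p_value`, `ci_observed`,
#'   `ci_null` (numeric vector), `eigenvalues`, `background_var`, `n`,
#'   `n_sim`.
#' @export
cluster_significance <- function(x, cluster_members, n_sim = 1000,
                                 seed = NULL, n_start = 3,
                                 background_var = NULL) {
  m <- as.matrix(unclass(x))
  ids <- colnames(m) %||% as.character(seq_len(ncol(m)))
  if (is.character(cluster_members)) {
    bad <- setdiff(cluster_members, ids)
    if (length(bad) > 0) stop("unknown sample(s): ",
                              paste(bad, collapse = ", "), call. = FALSE)
    in_cluster <- ids %in% cluster_members
  } else {
    in_cluster <- seq_len(ncol(m)) %in% cluster_members
  }
  n1 <- sum(in_cluster); n2 <- sum(!in_cluster)
  if (n1 < 3 || n2 < 3) {
    stop(sprintf(
      "cluster too small to test (%d members vs %d non-members; need >= 3 each)",
      n1, n2), call. = FALSE)
  }
  if (n_sim < 100) warning("n_sim < 100 gives a very coarse p-value")

  dat <- t(m)  # samples x genes
  ci_obs <- split_cluster_index(dat, in_cluster)

  ev <- eigen(stats::cov(dat), symmetric = TRUE, only.values = TRUE)$values
  ev[ev < 0] <- 0
  bg <- background_var %||% stats::mad(as.vector(dat))^2
  ev <- pmax(ev, bg)

  if (!is.null(seed)) set.seed(seed)
  ci_null <- .cpp_null_cluster_indices(nrow(dat), ev, as.integer(n_sim),
                                       as.integer(n_start), 100L)
  structure(
    list(p_value = mean(ci_null <= ci_obs),
         ci_observed = ci_obs,
         ci_null = ci_null,
         eigenvalues = ev,
         background_var = bg,
         n = nrow(dat),
         n_sim = n_sim),
    class = "pam_sigclust"
  )
}

#' @export
print.pam_sigclust <- function(x, ...) {
  cat(sprintf(
    "<pam_sigclust> n = %d, observed cluster index = %.4f, p = %.4g (%d sims)\n",
    x$n, x$ci_observed, x$p_value, x$n_sim))
  invisible(x)
}

# cluster index of a given 2-partition: within-group SS / total SS
split_cluster_index <- function(dat, in_cluster) {
  tss <- sum(scale(dat, scale = FALSE)^2)
  if (tss <= 0) return(1)
  w1 <- sum(scale(dat[in_cluster, , drop = FALSE], scale = FALSE)^2)
  w2 <- sum(scale(dat[!in_cluster, , drop = FALSE], scale = FALSE)^2)
  (w1 + w2) / tss
}
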