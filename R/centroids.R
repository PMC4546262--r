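SUBTYPES <- c("LumA", "LumB", "Her2E", "Basal")

#' Default marker map for prototype labeling
#'
#' Encodes the expected expression pattern of each intrinsic subtype as
#' `up`/`down` marker gene sets, used to label significant clusters:
#' Basal-like — basal cytokeratins (KRT5/14/17) and proliferation high,
#' estrogen-associated genes and ERBB2 low; HER2-enriched — ERBB2, GRB7,
#' FGFR4 and proliferation high, estrogen-associated genes low; Luminal A
#' and B — estrogen-associated genes high, separated by the proliferation
#' module (low in A, high in B). Gene sets are intersected with the
#' codeset's classifier genes and are fully configurable.
#'
#' @param codeset a [pam_codeset()].
#' @return Named list (LumA, LumB, Her2E, Basal) of lists with `up` and
#'   `down` character vectors.
#' @export
default_marker_map <- function(codeset = pam50_codeset()) {
  er <- c("ESR1", "PGR", "FOXA1", "MLPH", "SLC39A6", "NAT1", "MAPT",
          "BCL2", "BAG1", "CXXC5")
  basal <- c("KRT5", "KRT14", "KRT17", "FOXC1", "MIA", "CDH3", "SFRP1",
             "EGFR", "PHGDH")
  her2 <- c("ERBB2", "GRB7", "FGFR4")
  prolif <- codeset$proliferation_subset
  keep <- function(g) intersect(g, codeset$classifier_genes)
  list(
    LumA = list(up = keep(er), down = keep(prolif)),
    LumB = list(up = keep(c(er, prolif)), down = keep(basal)),
    Her2E = list(up = keep(c(her2, prolif)), down = keep(er)),
    Basal = list(up = keep(c(basal, prolif)), down = keep(c(er, her2)))
  )
}

#' Identify and label prototypical subtype clusters
#'
#' Performs the prototype-selection stage of centroid training. The
#' normalized expression is median-centered per gene, samples are
#' clustered by Pearson-distance UPGMA, and the dendrogram is traversed
#' top-down: a node whose two-way split is significant
#' ([cluster_significance()], `p < alpha`) is descended into; a node
#' whose split is not significant (or is too small to test) is retained
#' as a coherent cluster. Retained clusters of at least
#' `min_cluster_size` samples are scored against the marker map (mean
#' centered expression of `up` markers minus `down` markers, averaged
#' over the cluster) and greedily assigned to the four subtypes by
#' decreasing score; an assignment requires a positive score. Clusters
#' left over — e.g. non-tumor (reduction-mammoplasty-like) groups — stay
#' unlabeled. When Luminal B receives no cluster but two clusters both
#' best match Luminal A, the one with the strictly higher proliferation
#' score is relabeled Luminal B.
#'
#' @param x a [pam_expr()] in `log2_normalized` space (classifier genes).
#' @param codeset a [pam_codeset()].
#' @param markers marker map as from [default_marker_map()].
#' @param alpha significance threshold for a split (default 0.001).
#' @param n_sim Monte-Carlo simulations per tested node.
#' @param min_cluster_size smallest cluster considered for labeling.
#' @param seed integer seed for the Monte-Carlo tests.
#' @param dendrogram optional precomputed `hclust` on the same samples.
#' @return A list of class `pam_prototypes`: `labels` (tibble `sample`,
#'   `subtype`), `clusters` (tibble per retained cluster: id, size,
#'   split p-value of its parent, marker scores, assigned subtype),
#'   `dendrogram`, `alpha`.
#' @export
select_prototypes <- function(x, codeset, markers = default_marker_map(codeset),
                              alpha = 0.001, n_sim = 1000,
                              min_cluster_size = 5, seed = 1,
                              dendrogram = NULL) {
  stopifnot(inherits(x, "pam_expr"))
  require_genes(x, codeset$classifier_genes)
  xc <- unclass(x)[codeset$classifier_genes, , drop = FALSE]
  med <- apply(xc, 1, stats::median)
  xc <- sweep(xc, 1, med)        # median-centred view for clustering/scoring
  hc <- dendrogram %||% average_linkage(pearson_distance(xc))
  n <- ncol(xc)
  members <- hclust_members(hc)
  node_members <- function(id) if (id < 0) -id else members[[id]]

  clusters <- list()
  tested_p <- c()
  recurse <- function(node, depth_seed) {
    mem <- node_members(node)
    kids <- if (node > 0) hc$merge[node, ] else c(NA, NA)
    left <- if (node > 0) node_members(kids[1]) else integer()
    right <- if (node > 0) node_members(kids[2]) else integer()
    if (node < 0 || length(left) < 3 || length(right) < 3) {
      clusters[[length(clusters) + 1]] <<- list(members = mem, p = NA_real_)
      return(invisible())
    }
    sig <- cluster_significance(xc[, mem, drop = FALSE],
                                colnames(xc)[left],
                                n_sim = n_sim, seed = depth_seed)
    tested_p[length(tested_p) + 1] <<- sig$p_value
    if (sig$p_value < alpha) {
      recurse(kids[1], depth_seed + 1L)
      recurse(kids[2], depth_seed + 100003L)
    } else {
      clusters[[length(clusters) + 1]] <<- list(members = mem,
                                                p = sig$p_value)
    }
    invisible()
  }
  recurse(n - 1L, as.integer(seed))

  big <- purrr::keep(clusters, ~ length(.x$members) >= min_cluster_size)
  if (length(big) < 4 && alpha > 0) {
    stop("training set insufficient: fewer than 4 candidate clusters",
         call. = FALSE)
  }
  if (alpha <= 0 || length(tested_p) == 0 ||
      !any(tested_p < alpha, na.rm = TRUE)) {
    stop("training set insufficient: no significant clusters at alpha = ",
         alpha, call. = FALSE)
  }

  score_cluster <- function(mem, mk) {
    up <- mean(xc[mk$up, mem, drop = FALSE])
    dn <- if (length(mk$down) > 0) mean(xc[mk$down, mem, drop = FALSE]) else 0
    up - dn
  }
  scores <- t(vapply(big, function(cl) {
    vapply(SUBTYPES, function(st) score_cluster(cl$members, markers[[st]]),
           numeric(1))
  }, numeric(length(SUBTYPES))))
  colnames(scores) <- SUBTYPES

  assignment <- rep(NA_character_, length(big))
  avail <- matrix(TRUE, nrow(scores), ncol(scores))
  for (k in seq_len(min(4, length(big)))) {
    live <- scores
    live[!avail] <- -Inf
    if (all(!is.finite(live)) || max(live) <= 0) break
    idx <- which(live == max(live), arr.ind = TRUE)[1, ]
    assignment[idx[1]] <- SUBTYPES[idx[2]]
    avail[idx[1], ] <- FALSE
    avail[, idx[2]] <- FALSE
  }

  # Luminal A / Luminal B disambiguation on proliferation
  prolif_score <- vapply(big, function(cl) {
    mean(xc[intersect(codeset$proliferation_subset, rownames(xc)),
            cl$members, drop = FALSE])
  }, numeric(1))
  if (!"LumB" %in% assignment) {
    luma_pref <- which(is.na(assignment) | assignment == "LumA")
    luma_pref <- luma_pref[apply(scores[luma_pref, , drop = FALSE], 1,
                                 which.max) == 1]
    if (length(luma_pref) >= 2) {
      ord <- luma_pref[order(prolif_score[luma_pref], decreasing = TRUE)]
      if (prolif_score[ord[1]] > prolif_score[ord[2]]) {
        assignment[ord[1]] <- "LumB"
        assignment[ord[2]] <- "LumA"
      }
    }
  }
  if (!all(SUBTYPES %in% assignment)) {
    stop("training set insufficient: could not label all four subtypes (",
         "got: ", paste(stats::na.omit(assignment), collapse = ", "), ")",
         call. = FALSE)
  }

  cluster_tbl <- tibble::tibble(
    cluster = seq_along(big),
    size = purrr::map_int(big, ~ length(.x$members)),
    split_p = purrr::map_dbl(big, "p"),
    subtype = assignment,
    proliferation = prolif_score
  ) |>
    dplyr::bind_cols(tibble::as_tibble(scores))

  empty_labels <- tibble::tibble(sample = character(),
                                 subtype = character())
  labels <- dplyr::bind_rows(empty_labels, purrr::map_dfr(
    seq_along(big), function(i) {
      if (is.na(assignment[i])) return(NULL)
      tibble::tibble(sample = colnames(xc)[big[[i]]$members],
                     subtype = assignment[i])
    }))
  unlabeled <- dplyr::bind_rows(tibble::tibble(sample = character()),
                                purrr::map_dfr(seq_along(big), function(i) {
    if (!is.na(assignment[i])) return(NULL)
    tibble::tibble(sample = colnames(xc)[big[[i]]$members])
  }))

  structure(
    list(labels = labels, clusters = cluster_tbl, unlabeled = unlabeled,
         dendrogram = hc, alpha = alpha),
    class = "pam_prototypes"
  )
}

#' @export
print.pam_prototypes <- function(x, ...) {
  cat("<pam_prototypes>", nrow(x$labels), "prototype samples in 4 clusters\n")
  print(x$clusters)
  invisible(x)
}

#' Fit a per-gene Z-score scaler on training samples
#'
#' Stores the per-gene mean and standard deviation (n - 1 denominator) of
#' the training matrix. The scaler is frozen: applying it to new samples
#' always uses the stored parameters, never re-centres on the new cohort —
#' the property that makes downstream classification a single-sample
#' operation.
#'
#' @param x a [pam_expr()] in `log2_normalized` space.
#' @param genes genes to include (default: all rows of `x`).
#' @return An object of class `pam_gene_scaler` (tibble of `gene`, `mu`,
#'   `sigma` plus the training sample count).
#' @export
fit_gene_scaler <- function(x, genes = rownames(x)) {
  require_genes(x, genes)
  m <- unclass(x)[genes, , drop = FALSE]
  mu <- rowMeans(m)
  sigma <- apply(m, 1, stats::sd)
  degenerate <- names(sigma)[sigma <= 0 | !is.finite(sigma)]
  if (length(degenerate) > 0) {
    stop("zero-variance gene(s) at scaler fit: ",
         paste(degenerate, collapse = ", "), call. = FALSE)
  }
  structure(
    list(params = tibble::tibble(gene = genes, mu = unname(mu),
                                 sigma = unname(sigma)),
         n_train = ncol(m)),
    class = "pam_gene_scaler"
  )
}

#' Apply a frozen Z-score scaler
#'
#' @param x a [pam_expr()] in `log2_normalized` space covering the
#'   scaler's genes.
#' @param scaler a [fit_gene_scaler()] object.
#' @return A [pam_expr()] in `z_scaled` space over the scaler's genes.
#' @export
apply_gene_scaler <- function(x, scaler) {
  stopifnot(inherits(scaler, "pam_gene_scaler"))
  require_genes(x, scaler$params$gene)
  m <- unclass(x)[scaler$params$gene, , drop = FALSE]
  z <- (m - scaler$params$mu) / scaler$params$sigma
  out <- pam_expr(z, "z_scaled", provenance = attr(x, "provenance"))
  expr_append_prov(out, sprintf("z-scaled with frozen scaler (n_train=%d)",
                                scaler$n_train))
}

#' Compute subtype centroids from labeled prototypes
#'
#' Each centroid is the per-gene summary (arithmetic mean by default,
#' median optionally) of the Z-scaled expression of that subtype's
#' prototype samples.
#'
#' @param xz a [pam_expr()] in `z_scaled` space.
#' @param prototype_labels tibble with columns `sample`, `subtype`
#'   (values among LumA, LumB, Her2E, Basal).
#' @param scaler the [fit_gene_scaler()] embedded into the model.
#' @param codeset the [pam_codeset()] the model is bound to.
#' @param summary `"mean"` or `"median"`.
#' @return An object of class `pam_centroid_model`.
#' @export
compute_centroids <- function(xz, prototype_labels, scaler, codeset,
                              summary = c("mean", "median")) {
  summary <- match.arg(summary)
  stopifnot(inherits(xz, "pam_expr"), value_space(xz) == "z_scaled")
  prototype_labels <- tibble::as_tibble(prototype_labels)
  bad <- setdiff(prototype_labels$subtype, SUBTYPES)
  if (length(bad) > 0) stop("unknown subtype label(s): ",
                            paste(bad, collapse = ", "), call. = FALSE)
  genes <- codeset$classifier_genes
  require_genes(xz, genes)
  fun <- if (summary == "mean") rowMeans else
    function(m) apply(m, 1, stats::median)
  centroids <- vapply(SUBTYPES, function(st) {
    s <- prototype_labels$sample[prototype_labels$subtype == st]
    if (length(s) == 0) stop("empty prototype cluster for ", st,
                             call. = FALSE)
    if (length(s) < 2) stop("centroid for ", st,
                            " needs >= 2 prototype samples", call. = FALSE)
    missing <- setdiff(s, colnames(xz))
    if (length(missing) > 0) stop("prototype sample(s) absent from matrix: ",
                                  paste(missing, collapse = ", "),
                                  call. = FALSE)
    fun(unclass(xz)[genes, s, drop = FALSE])
  }, numeric(length(genes)))
  rownames(centroids) <- genes

  structure(
    list(scaler = scaler,
         centroids = centroids,
         genes = genes,
         codeset_hash = codeset_hash(codeset),
         training_metadata = list(
           n_per_centroid = stats::setNames(
             as.integer(table(factor(prototype_labels$subtype,
                                     levels = SUBTYPES))), SUBTYPES),
           summary = summary)),
    class = "pam_centroid_model"
  )
}

#' @export
print.pam_centroid_model <- function(x, ...) {
  np <- x$training_metadata$n_per_centroid
  cat(sprintf("<pam_centroid_model> %d genes; prototypes: %s\n",
              length(x$genes),
              paste(sprintf("%s=%d", names(np), np), collapse = ", ")))
  invisible(x)
}

#' Train the four-subtype centroid model end to end
#'
#' Convenience wrapper chaining [select_prototypes()] (clustering +
#' significance testing + marker labeling), [fit_gene_scaler()] on the
#' tumor (non-unlabeled) samples, [apply_gene_scaler()], and
#' [compute_centroids()].
#'
#' @inheritParams select_prototypes
#' @inheritParams compute_centroids
#' @return A list: `model` (a `pam_centroid_model`), `prototypes` (the
#'   [select_prototypes()] result).
#' @export
train_centroids <- function(x, codeset, markers = default_marker_map(codeset),
                            alpha = 0.001, n_sim = 1000,
                            min_cluster_size = 5, seed = 1,
                            summary = "mean") {
  protos <- select_prototypes(x, codeset, markers = markers, alpha = alpha,
                              n_sim = n_sim,
                              min_cluster_size = min_cluster_size,
                              seed = seed)
  tumor_samples <- setdiff(colnames(x), protos$unlabeled$sample)
  scaler <- fit_gene_scaler(
    pam_expr(unclass(x)[codeset$classifier_genes, tumor_samples,
                        drop = FALSE],
             "log2_normalized"),
    genes = codeset$classifier_genes)
  xz <- apply_gene_scaler(x, scaler)
  model <- compute_centroids(xz, protos$labels, scaler, codeset,
                             summary = summary)
  list(model = model, prototypes = protos)
}
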