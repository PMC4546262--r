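MODEL_SCHEMA <- "pamror-model/1"

#' Serialize a trained model to structured text
#'
#' Writes a centroid or ROR model as versioned JSON with full floating
#' point precision, so a round-tripped model produces bit-identical
#' scores. The file embeds the codeset hash recorded at training time;
#' scoring functions refuse a model applied to a mismatched panel.
#'
#' @param model a `pam_centroid_model` or `pam_ror_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  if (inherits(model, "pam_centroid_model")) {
    payload <- list(
      type = "centroid",
      genes = model$genes,
      scaler = list(gene = model$scaler$params$gene,
                    mu = model$scaler$params$mu,
                    sigma = model$scaler$params$sigma,
                    n_train = model$scaler$n_train),
      centroids = stats::setNames(
        lapply(SUBTYPES, function(st) unname(model$centroids[, st])),
        SUBTYPES),
      codeset_hash = model$codeset_hash,
      training_metadata = model$training_metadata
    )
  } else if (inherits(model, "pam_ror_model")) {
    payload <- list(
      type = "ror",
      coefficients = as.list(model$coefficients),
      variant = model$variant,
      proliferation_subset = model$proliferation_subset,
      genes = model$genes,
      scaling = model$scaling,
      cutoffs = as.list(model$cutoffs),
      lambda = model$lambda,
      ties = model$ties,
      standardize = model$standardize,
      codeset_hash = model$codeset_hash
    )
  } else {
    stop("unsupported model class: ", paste(class(model), collapse = "/"),
         call. = FALSE)
  }
  # I(17) = 17 *significant* digits, enough to round-trip IEEE doubles
  # exactly, so a reloaded model scores bit-identically
  jsonlite::write_json(c(list(schema = MODEL_SCHEMA), payload), path,
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' Load a serialized model
#'
#' @param path a file written by [write_model()].
#' @return The reconstructed `pam_centroid_model` or `pam_ror_model`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path,
                               call. = FALSE)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$schema, MODEL_SCHEMA)) {
    stop("unsupported model schema version: ",
         j$schema %||% "<missing>", " (expected ", MODEL_SCHEMA, ")",
         call. = FALSE)
  }
  if (identical(j$type, "centroid")) {
    centroids <- vapply(SUBTYPES, function(st) as.numeric(j$centroids[[st]]),
                        numeric(length(j$genes)))
    rownames(centroids) <- j$genes
    scaler <- structure(
      list(params = tibble::tibble(gene = j$scaler$gene,
                                   mu = as.numeric(j$scaler$mu),
                                   sigma = as.numeric(j$scaler$sigma)),
           n_train = j$scaler$n_train),
      class = "pam_gene_scaler")
    meta <- j$training_metadata
    if (!is.null(meta$n_per_centroid)) {
      meta$n_per_centroid <- unlist(meta$n_per_centroid)
    }
    structure(
      list(scaler = scaler, centroids = centroids, genes = j$genes,
           codeset_hash = j$codeset_hash, training_metadata = meta),
      class = "pam_centroid_model")
  } else if (identical(j$type, "ror")) {
    structure(
      list(coefficients = unlist(j$coefficients),
           variant = j$variant,
           proliferation_subset = as.character(j$proliferation_subset),
           genes = as.character(j$genes),
           scaling = list(alpha = j$scaling$alpha, beta = j$scaling$beta),
           cutoffs = unlist(j$cutoffs),
           lambda = j$lambda, ties = j$ties, standardize = j$standardize,
           codeset_hash = j$codeset_hash),
      class = "pam_ror_model")
  } else {
    stop("unknown model type in file: ", j$type %||% "<missing>",
         call. = FALSE)
  }
}
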