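#' Construct a codeset
#'
#' A codeset describes the probe panel of a digital expression assay: the
#' classifier genes, the housekeeping (endogenous control) genes used for
#' normalization, the positive-control probes with their expected spike-in
#' concentrations, the negative-control (background) probes, the subset of
#' classifier genes averaged into the proliferation score, and the genes a
#' reduced ROR model excludes.
#'
#' @param classifier_genes character vector of classifier gene symbols
#'   (canonically 50).
#' @param housekeeper_genes character vector of housekeeping gene symbols
#'   (at least 2; canonically 8 for the clinical assay, 5 for the
#'   feasibility configuration).
#' @param positive_controls data frame (or tibble) with columns `id` and
#'   `concentration` (strictly positive, distinct; stored sorted by
#'   decreasing concentration).
#' @param negative_controls character vector of background probe ids.
#' @param proliferation_subset subset of `classifier_genes` averaged into
#'   the proliferation score.
#' @param reduced_model_exclusions subset of `classifier_genes` excluded by
#'   the reduced (46-gene) model variant.
#' @param name free-text codeset name.
#'
#' @return An object of class `pam_codeset`.
#' @export
#' @examples
#' cs <- pam50_codeset()
#' length(cs$classifier_genes)
pam_codeset <- function(classifier_genes,
                        housekeeper_genes,
                        positive_controls,
                        negative_controls,
                        proliferation_subset = character(),
                        reduced_model_exclusions = character(),
                        name = "custom") {
  positive_controls <- tibble::as_tibble(positive_controls)
  stopifnot(all(c("id", "concentration") %in% names(positive_controls)))
  positive_controls <- dplyr::arrange(positive_controls,
                                      dplyr::desc(.data$concentration))
  cs <- structure(
    list(
      name = as.character(name)[1],
      classifier_genes = as.character(classifier_genes),
      housekeeper_genes = as.character(housekeeper_genes),
      positive_controls = positive_controls,
      negative_controls = as.character(negative_controls),
      proliferation_subset = as.character(proliferation_subset),
      reduced_model_exclusions = as.character(reduced_model_exclusions)
    ),
    class = "pam_codeset"
  )
  validate_codeset(cs)
}

validate_codeset <- function(cs) {
  all_ids <- c(cs$classifier_genes, cs$housekeeper_genes,
               cs$positive_controls$id, cs$negative_controls)
  dup <- unique(all_ids[duplicated(all_ids)])
  if (length(dup) > 0) {
    stop("duplicate probe identifier(s) across codeset roles: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  if (length(cs$housekeeper_genes) < 2) {
    stop("a codeset needs at least 2 housekeeper genes", call. = FALSE)
  }
  conc <- cs$positive_controls$concentration
  if (length(conc) > 0) {
    if (any(!is.finite(conc)) || any(conc <= 0)) {
      stop("positive-control concentrations must be strictly positive",
           call. = FALSE)
    }
    if (any(duplicated(conc))) {
      stop("positive-control concentrations must be strictly increasing ",
           "when sorted (found duplicates)", call. = FALSE)
    }
  }
  bad_prolif <- setdiff(cs$proliferation_subset, cs$classifier_genes)
  if (length(bad_prolif) > 0) {
    stop("proliferation_subset gene(s) not in classifier list: ",
         paste(bad_prolif, collapse = ", "), call. = FALSE)
  }
  bad_excl <- setdiff(cs$reduced_model_exclusions, cs$classifier_genes)
  if (length(bad_excl) > 0) {
    stop("reduced_model_exclusions gene(s) not in classifier list: ",
         paste(bad_excl, collapse = ", "), call. = FALSE)
  }
  cs
}

#' Read a codeset definition from a YAML file
#'
#' The file format is a flat YAML document with fields `classifier_genes`,
#' `housekeeper_genes`, `positive_controls` (list of `id`/`concentration`
#' pairs), `negative_controls`, `proliferation_subset`,
#' `reduced_model_exclusions` and optional `name`; see the packaged
#' `pam50_codeset.yaml` for a worked example. Gene identifiers are
#' case-sensitive and matched exactly throughout the package.
#'
#' @param path path to a codeset YAML file.
#' @return A [pam_codeset()] object.
#' @export
read_codeset <- function(path) {
  if (!file.exists(path)) stop("codeset file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  pos <- y$positive_controls
  pos_tbl <- if (is.null(pos)) {
    tibble::tibble(id = character(), concentration = numeric())
  } else {
    tibble::tibble(
      id = purrr::map_chr(pos, "id"),
      concentration = purrr::map_dbl(pos, "concentration")
    )
  }
  pam_codeset(
    classifier_genes = y$classifier_genes,
    housekeeper_genes = y$housekeeper_genes,
    positive_controls = pos_tbl,
    negative_controls = y$negative_controls %||% character(),
    proliferation_subset = y$proliferation_subset %||% character(),
    reduced_model_exclusions = y$reduced_model_exclusions %||% character(),
    name = y$name %||% "unnamed"
  )
}

#' Write a codeset definition to a YAML file
#'
#' @param codeset a [pam_codeset()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_codeset <- function(codeset, path) {
  stopifnot(inherits(codeset, "pam_codeset"))
  y <- list(
    schema = "pamror-codeset/1",
    name = codeset$name,
    classifier_genes = codeset$classifier_genes,
    housekeeper_genes = codeset$housekeeper_genes,
    positive_controls = purrr::pmap(codeset$positive_controls,
                                    function(id, concentration) {
                                      list(id = id, concentration = concentration)
                                    }),
    negative_controls = codeset$negative_controls,
    proliferation_subset = codeset$proliferation_subset,
    reduced_model_exclusions = codeset$reduced_model_exclusions
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

#' The packaged default 50-gene codeset
#'
#' Loads the codeset shipped with the package: the published 50-gene
#' intrinsic-subtype panel, eight housekeeping genes, six positive-control
#' titration probes, eight negative controls, the 11-gene proliferation
#' subset, and the four genes (`BIRC5`, `CCNB1`, `GRB7`, `MYBL2`) excluded
#' by the reduced 46-gene ROR variant. Provenance is documented in the
#' packaged YAML file itself.
#'
#' @return A [pam_codeset()] object.
#' @export
pam50_codeset <- function() {
  read_codeset(system.file("extdata", "pam50_codeset.yaml",
                           package = "pamror", mustWork = TRUE))
}

#' @export
print.pam_codeset <- function(x, ...) {
  cat("<pam_codeset> ", x$name, "\n", sep = "")
  cat("  classifier genes:    ", length(x$classifier_genes), "\n", sep = "")
  cat("  housekeepers:        ", length(x$housekeeper_genes), "\n", sep = "")
  cat("  positive controls:   ", nrow(x$positive_controls), "\n", sep = "")
  cat("  negative controls:   ", length(x$negative_controls), "\n", sep = "")
  cat("  proliferation genes: ", length(x$proliferation_subset), "\n", sep = "")
  cat("  reduced-model drops: ",
      paste(x$reduced_model_exclusions, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# stable content hash of a codeset so a trained model can refuse to score
# a mismatched panel
codeset_hash <- function(cs) {
  key <- paste(
    paste(cs$classifier_genes, collapse = ","),
    paste(cs$housekeeper_genes, collapse = ","),
    paste(cs$positive_controls$id, collapse = ","),
    paste(format(cs$positive_controls$concentration, digits = 12),
          collapse = ","),
    paste(cs$negative_controls, collapse = ","),
    paste(cs$proliferation_subset, collapse = ","),
    paste(cs$reduced_model_exclusions, collapse = ","),
    sep = "|"
  )
  # small polynomial rolling hash; stability matters, cryptography does not
  bytes <- utf8ToInt(key)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
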