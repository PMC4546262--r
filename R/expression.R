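#' Construct an expression matrix container
#'
#' A light wrapper around a genes-by-samples numeric matrix that tracks
#' which value space the matrix lives in (`raw_counts`, `log2_normalized`
#' or `z_scaled`) and a free-text processing history. Value-space
#' transitions happen only through [normalize_counts()] and
#' [apply_gene_scaler()].
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   dimnames.
#' @param value_space one of `"raw_counts"`, `"log2_normalized"`,
#'   `"z_scaled"`.
#' @param provenance character vector of processing steps.
#' @return A `pam_expr` object (matrix subclass with attributes).
#' @export
pam_expr <- function(values,
                     value_space = c("raw_counts", "log2_normalized",
                                     "z_scaled"),
                     provenance = character()) {
  value_space <- match.arg(value_space)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs gene rownames and sample colnames",
         call. = FALSE)
  }
  storage.mode(values) <- "double"
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g) > 0) {
    stop("duplicate gene identifier(s): ", paste(dup_g, collapse = ", "),
         call. = FALSE)
  }
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s) > 0) {
    stop("duplicate sample identifier(s): ", paste(dup_s, collapse = ", "),
         call. = FALSE)
  }
  if (value_space == "raw_counts" && any(values < 0, na.rm = TRUE)) {
    idx <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at (%s, %s)",
                 rownames(values)[idx[1]], colnames(values)[idx[2]]),
         call. = FALSE)
  }
  structure(values,
            value_space = value_space,
            provenance = provenance,
            class = c("pam_expr", "matrix", "array"))
}

#' @export
print.pam_expr <- function(x, ...) {
  cat(sprintf("<pam_expr> %d genes x %d samples [%s]\n",
              nrow(x), ncol(x), attr(x, "value_space")))
  prov <- attr(x, "provenance")
  if (length(prov) > 0) cat("  provenance:", paste(prov, collapse = " -> "), "\n")
  invisible(x)
}

value_space <- function(x) attr(x, "value_space")

expr_append_prov <- function(x, step) {
  attr(x, "provenance") <- c(attr(x, "provenance"), step)
  x
}

#' Convert an expression container to a long tibble
#'
#' @param x a `pam_expr` object.
#' @param ... unused.
#' @return A tibble with columns `gene`, `sample`, `value`, `value_space`.
#' @export
tidy.pam_expr <- function(x, ...) {
  tibble::tibble(
    gene = rep(rownames(x), times = ncol(x)),
    sample = rep(colnames(x), each = nrow(x)),
    value = as.vector(unclass(x)[, , drop = FALSE]),
    value_space = value_space(x)
  )
}

#' Read a genes-by-samples count matrix
#'
#' Two on-disk layouts are supported: a TSV matrix (first column = gene
#' identifier, header row = sample identifiers) and a directory of
#' per-sample count files in a minimal RCC-like dialect (see
#' [read_rcc_file()]). Counts must be non-negative; gene identifiers must
#' be unique and, for per-sample files, identical across files.
#'
#' @param path a TSV file path, or (for `per_sample_count_files`) a
#'   directory or character vector of file paths.
#' @param format `"tsv_matrix"` or `"per_sample_count_files"`.
#' @return A [pam_expr()] in the `raw_counts` value space.
#' @export
read_count_matrix <- function(path,
                              format = c("tsv_matrix",
                                         "per_sample_count_files")) {
  format <- match.arg(format)
  if (format == "tsv_matrix") {
    if (!file.exists(path)) stop("count file not found: ", path, call. = FALSE)
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    genes <- as.character(df[[1]])
    dup <- unique(genes[duplicated(genes)])
    if (length(dup) > 0) {
      stop("duplicated gene id(s) in ", path, ": ",
           paste(dup, collapse = ", "), call. = FALSE)
    }
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric counts in ", path, call. = FALSE)
    rownames(m) <- genes
    pam_expr(m, "raw_counts", provenance = paste0("read tsv_matrix: ", path))
  } else {
    files <- if (length(path) == 1 && dir.exists(path)) {
      list.files(path, pattern = "\\.(rcc|csv|txt)$", ignore.case = TRUE,
                 full.names = TRUE)
    } else {
      path
    }
    if (length(files) == 0) stop("no per-sample count files found",
                                 call. = FALSE)
    parsed <- purrr::map(files, read_rcc_file)
    probes <- purrr::map(parsed, ~ .x$counts$probe)
    ref <- probes[[1]]
    for (i in seq_along(probes)[-1]) {
      if (!identical(sort(probes[[i]]), sort(ref))) {
        extra <- setdiff(probes[[i]], ref)
        missing <- setdiff(ref, probes[[i]])
        stop(sprintf(
          "probe manifest mismatch between '%s' and '%s'; only in former: [%s]; only in latter: [%s]",
          files[i], files[1],
          paste(extra, collapse = ", "), paste(missing, collapse = ", ")),
          call. = FALSE)
      }
    }
    m <- vapply(parsed,
                function(p) p$counts$count[match(ref, p$counts$probe)],
                numeric(length(ref)))
    dim(m) <- c(length(ref), length(parsed))
    rownames(m) <- ref
    colnames(m) <- purrr::map_chr(parsed, "sample_id")
    pam_expr(m, "raw_counts",
             provenance = sprintf("read %d per-sample count files",
                                  length(files)))
  }
}

#' Read one per-sample count file (minimal RCC-like dialect)
#'
#' The dialect is plain text with two blocks: a `<Header>` block of
#' `key,value` lines (must contain `sample_id`) and a `<Code_Summary>`
#' block whose CSV lines are `class,probe,accession,count`. Lines starting
#' with `#` are comments. This is a minimal stand-in for the vendor count
#' format, which is not part of this package's scope.
#'
#' @param path file path.
#' @return list with `sample_id` and a `counts` tibble
#'   (`class`, `probe`, `accession`, `count`).
#' @export
read_rcc_file <- function(path) {
  if (!file.exists(path)) stop("count file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  hdr_i <- which(trimws(lines) == "<Header>")
  code_i <- which(trimws(lines) == "<Code_Summary>")
  if (length(hdr_i) != 1 || length(code_i) != 1) {
    stop("malformed count file (need one <Header> and one <Code_Summary> ",
         "block): ", path, call. = FALSE)
  }
  ends <- which(trimws(lines) == "</end>")
  hdr_end <- min(ends[ends > hdr_i])
  code_end <- min(ends[ends > code_i])
  hdr_lines <- lines[(hdr_i + 1):(hdr_end - 1)]
  kv <- strsplit(hdr_lines, ",", fixed = TRUE)
  header <- stats::setNames(
    purrr::map_chr(kv, ~ trimws(paste(.x[-1], collapse = ","))),
    purrr::map_chr(kv, ~ trimws(.x[1]))
  )
  if (!"sample_id" %in% names(header)) {
    stop("count file header lacks sample_id: ", path, call. = FALSE)
  }
  code_lines <- lines[(code_i + 1):(code_end - 1)]
  parts <- strsplit(code_lines, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 4)
  if (length(bad) > 0) {
    stop("malformed code-summary line in ", path, ": '",
         code_lines[bad[1]], "'", call. = FALSE)
  }
  counts <- tibble::tibble(
    class = trimws(purrr::map_chr(parts, 1)),
    probe = trimws(purrr::map_chr(parts, 2)),
    accession = trimws(purrr::map_chr(parts, 3)),
    count = suppressWarnings(as.numeric(purrr::map_chr(parts, 4)))
  )
  if (any(is.na(counts$count))) {
    stop("non-numeric count in ", path, call. = FALSE)
  }
  neg <- which(counts$count < 0)
  if (length(neg) > 0) {
    stop(sprintf("negative count at (%s, %s) in %s",
                 counts$probe[neg[1]], header[["sample_id"]], path),
         call. = FALSE)
  }
  dup <- unique(counts$probe[duplicated(counts$probe)])
  if (length(dup) > 0) {
    stop("duplicated probe(s) in ", path, ": ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  list(sample_id = unname(header[["sample_id"]]), counts = counts)
}

#' Write an expression container as a TSV matrix
#'
#' @param x a [pam_expr()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path) {
  stopifnot(inherits(x, "pam_expr"))
  df <- data.frame(gene = rownames(x), unclass(x), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# check that all requested genes exist; error names the offenders
require_genes <- function(x, genes, what = "gene") {
  missing <- setdiff(genes, rownames(x))
  if (length(missing) > 0) {
    stop("missing ", what, "(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}
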