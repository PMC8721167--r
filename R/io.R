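## Delimited-file plumbing. All readers sniff the delimiter (tab vs comma)
## from the header line, require a header, and realign rows to the catalog
## order so downstream matrices share one indexing.

sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty file: ", path)
  if (grepl("\t", header)) "\t" else ","
}

read_delim_file <- function(path) {
  sep <- sniff_sep(path)
  utils::read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "\"", comment.char = "",
                    colClasses = NA, fileEncoding = "UTF-8")
}

write_delim_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
}

#' Load a binary drug feature matrix
#'
#' Accepts either a dense table (first column drug id, remaining columns
#' 0/1 descriptor indicators) or a sparse two-column pair list
#' `(drug_id, descriptor_id)` meaning "this drug has this descriptor".
#' The returned matrix is aligned to the catalog order; catalog drugs
#' absent from the file get all-zero rows with a logged warning.
#'
#' @param path path to a tab- or comma-delimited file with a header row.
#' @param source_name one of `"struct"`, `"target"`, `"pathway"`, `"enzyme"`.
#' @param catalog a [drug_catalog()].
#' @return a [feature_matrix()].
#' @export
load_drug_features <- function(path, source_name, catalog) {
  df <- read_delim_file(path)
  if (ncol(df) < 2L) stop("feature file needs at least two columns: ", path)
  sparse <- ncol(df) == 2L && !all(unlist(df[[2L]]) %in% c(0, 1, NA))
  if (sparse) {
    drugs <- as.character(df[[1L]])
    descs <- as.character(df[[2L]])
    desc_ids <- sort(unique(descs))
    values <- matrix(0, nrow = length(catalog), ncol = length(desc_ids),
                     dimnames = list(catalog$drug_ids, desc_ids))
    idx <- cbind(catalog_index(catalog, drugs), match(descs, desc_ids))
    values[idx] <- 1
  } else {
    drugs <- as.character(df[[1L]])
    if (anyDuplicated(drugs))
      stop("duplicate drug_id rows in ", path, ": ",
           paste(unique(drugs[duplicated(drugs)]), collapse = ", "))
    mat <- as.matrix(df[, -1L, drop = FALSE])
    bad <- which(!(mat %in% c(0, 1)))
    if (length(bad)) {
      i <- ((bad[1] - 1L) %% nrow(mat)) + 1L
      j <- ((bad[1] - 1L) %/% nrow(mat)) + 1L
      stop(sprintf("non-binary cell '%s' for drug '%s', column '%s' in %s",
                   format(mat[bad[1]]), drugs[i], colnames(mat)[j], path))
    }
    storage.mode(mat) <- "double"
    values <- matrix(0, nrow = length(catalog), ncol = ncol(mat),
                     dimnames = list(catalog$drug_ids, colnames(mat)))
    known <- drugs %in% catalog$drug_ids
    if (any(!known))
      ddi_log("warn", "ignoring %d drug(s) not in the catalog", sum(!known))
    values[drugs[known], ] <- mat[known, , drop = FALSE]
  }
  feature_matrix(values, source_name, catalog, colnames(values))
}

#' Load an ATC code table
#'
#' @param path delimited file with header and columns `(drug_id, atc_code)`.
#' @return an [atc_table()].
#' @export
load_atc_codes <- function(path) {
  df <- read_delim_file(path)
  if (ncol(df) < 2L) stop("ATC file needs columns (drug_id, atc_code)")
  entries <- split(as.character(df[[2L]]), as.character(df[[1L]]))
  atc_table(entries)
}

#' Load a labeled DDI table
#'
#' Type names are mapped to contiguous integer labels in first-appearance
#' order; write the mapping out with [save_type_map()] so runs stay
#' comparable. Self-pairs and unordered pairs carrying two distinct types
#' are rejected (pairs with more than one interaction type are excluded
#' from the problem definition).
#'
#' @param path delimited file with header and columns
#'   `(drug_a, drug_b, type_name)`.
#' @param catalog a [drug_catalog()].
#' @return a [ddi_table()].
#' @export
load_ddi_table <- function(path, catalog) {
  df <- read_delim_file(path)
  if (ncol(df) < 3L) stop("DDI file needs columns (drug_a, drug_b, type)")
  type_names <- unique(as.character(df[[3L]]))
  pairs <- data.frame(drug_a = as.character(df[[1L]]),
                      drug_b = as.character(df[[2L]]),
                      type = match(as.character(df[[3L]]), type_names) - 1L,
                      stringsAsFactors = FALSE)
  ddi_table(pairs, type_names, catalog)
}

#' Write / read the integer label to type-name mapping
#'
#' @param ddis a [ddi_table()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
save_type_map <- function(ddis, path) {
  write_delim_file(data.frame(label = seq_along(ddis$type_names) - 1L,
                              type_name = ddis$type_names), path)
  invisible(path)
}

#' Save / load a catalog-aligned numeric matrix
#'
#' The drug ids are written as the first column; on load, rows are
#' realigned to the catalog order (a shuffled file round-trips to the
#' canonical order) and missing drugs are an error.
#'
#' @param mat numeric matrix with one row per catalog drug.
#' @param path file path (TSV).
#' @param catalog a [drug_catalog()].
#' @return `save_matrix`: `path` invisibly; `load_matrix`: the matrix.
#' @export
save_matrix <- function(mat, path, catalog) {
  stopifnot(nrow(mat) == length(catalog))
  df <- data.frame(drug_id = catalog$drug_ids, mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (is.null(colnames(mat)))
    names(df)[-1L] <- paste0("V", seq_len(ncol(mat)))
  write_delim_file(df, path)
  invisible(path)
}

#' @rdname save_matrix
#' @export
load_matrix <- function(path, catalog) {
  df <- read_delim_file(path)
  ids <- as.character(df[[1L]])
  missing <- setdiff(catalog$drug_ids, ids)
  if (length(missing))
    stop("matrix file ", path, " is missing catalog drug(s): ",
         paste(utils::head(missing, 10L), collapse = ", "))
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  mat[catalog$drug_ids, , drop = FALSE]
}

#' Read / write a pipeline configuration as JSON (or YAML)
#'
#' @param path file path; `.yaml`/`.yml` uses YAML if the yaml package is
#'   available, anything else JSON.
#' @param config a [pipeline_config()] list for writing.
#' @return `load_config`: a [pipeline_config()].
#' @export
load_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required to read ", path)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(pipeline_config, raw)
}

#' @rdname load_config
#' @export
save_config <- function(config, path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required to write ", path)
    yaml::write_yaml(unclass(config), path)
  } else {
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}
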