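#' Drug catalog
#'
#' The ordered set of drug identifiers. Its order is the single source of
#' row/column indexing for every matrix in the pipeline: feature matrices,
#' similarity networks, diffusion states and embeddings are all aligned to
#' it, and any reindexing on load is explicit.
#'
#' @param drug_ids character vector of unique, non-empty drug identifiers.
#' @return an object of class `drug_catalog`.
#' @export
drug_catalog <- function(drug_ids) {
  drug_ids <- as.character(drug_ids)
  if (length(drug_ids) == 0L) stop("catalog must contain at least one drug")
  if (anyNA(drug_ids) || any(!nzchar(drug_ids)))
    stop("drug ids must be non-empty strings")
  if (anyDuplicated(drug_ids))
    stop("duplicate drug ids: ",
         paste(unique(drug_ids[duplicated(drug_ids)]), collapse = ", "))
  structure(list(drug_ids = drug_ids), class = "drug_catalog")
}

#' @export
length.drug_catalog <- function(x) length(x$drug_ids)

#' @export
print.drug_catalog <- function(x, ...) {
  cat(sprintf("<drug_catalog> %d drugs: %s%s\n", length(x),
              paste(utils::head(x$drug_ids, 5L), collapse = ", "),
              if (length(x) > 5L) ", ..." else ""))
  invisible(x)
}

catalog_index <- function(catalog, ids, what = "drug") {
  idx <- match(ids, catalog$drug_ids)
  if (anyNA(idx))
    stop("unknown ", what, " id(s): ",
         paste(unique(ids[is.na(idx)]), collapse = ", "))
  idx
}

#' Binary feature matrix for one descriptor source
#'
#' Holds the drugs-by-descriptors 0/1 matrix for one feature space
#' (chemical substructure bits, target, pathway or enzyme associations).
#' Rows follow the catalog order; all-zero rows are allowed (a drug simply
#' has no annotation in that source) and are reported, not rejected.
#'
#' @param values numeric or integer matrix with entries in \{0, 1\}.
#' @param source_name one of `"struct"`, `"target"`, `"pathway"`, `"enzyme"`.
#' @param catalog a [drug_catalog()]; `nrow(values)` must equal its length.
#' @param descriptor_ids optional character vector of column names.
#' @return an object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, source_name, catalog, descriptor_ids = NULL) {
  source_name <- match.arg(source_name, c("struct", "target", "pathway", "enzyme"))
  values <- as.matrix(values)
  if (nrow(values) != length(catalog))
    stop("feature matrix has ", nrow(values), " rows but catalog has ",
         length(catalog), " drugs")
  bad <- which(!(values %in% c(0, 1)))
  if (length(bad)) {
    i <- ((bad[1] - 1L) %% nrow(values)) + 1L
    j <- ((bad[1] - 1L) %/% nrow(values)) + 1L
    stop(sprintf("non-binary value %s at drug '%s', descriptor column %d",
                 format(values[bad[1]]), catalog$drug_ids[i], j))
  }
  storage.mode(values) <- "double"
  rownames(values) <- catalog$drug_ids
  if (!is.null(descriptor_ids)) {
    stopifnot(length(descriptor_ids) == ncol(values))
    colnames(values) <- descriptor_ids
  }
  zero <- rowSums(values) == 0
  if (any(zero))
    ddi_log("warn", "%d drug(s) with no '%s' annotations (all-zero rows): %s",
            sum(zero), source_name,
            paste(utils::head(catalog$drug_ids[zero], 5L), collapse = ", "))
  structure(list(source_name = source_name, values = values,
                 descriptor_ids = colnames(values)),
            class = "feature_matrix")
}

#' ATC code table
#'
#' Maps drug ids to sets of WHO Anatomical Therapeutic Chemical codes.
#' A code is 7 characters spanning 5 hierarchy levels
#' (letter | 2 digits | letter | letter | 2 digits, e.g. `"B01AC06"`).
#' Drugs may carry zero or several codes.
#'
#' @param entries named list: drug id -> character vector of codes.
#' @return an object of class `atc_table`.
#' @export
atc_table <- function(entries) {
  stopifnot(is.list(entries))
  if (length(entries) && is.null(names(entries)))
    stop("entries must be a named list keyed by drug id")
  for (id in names(entries)) {
    codes <- entries[[id]]
    bad <- codes[!grepl("^[A-Z][0-9]{2}[A-Z][A-Z][0-9]{2}$", codes)]
    if (length(bad))
      stop("malformed ATC code(s) for drug '", id, "': ",
           paste(bad, collapse = ", "))
    entries[[id]] <- unique(codes)
  }
  structure(list(entries = entries), class = "atc_table")
}

#' Labeled drug-drug interaction table
#'
#' Stores unordered drug pairs with an integer interaction-type label.
#' Types are contiguous integers `0..l-1` assigned in first-appearance
#' order of their names; the label-name mapping travels with the table.
#'
#' @param pairs data.frame with columns `drug_a`, `drug_b`, `type`
#'   (integer labels in `0..l-1`).
#' @param type_names character vector of length `l`; `type_names[k+1]` is
#'   the name of label `k`.
#' @param catalog a [drug_catalog()] containing every drug in `pairs`.
#' @return an object of class `ddi_table`.
#' @export
ddi_table <- function(pairs, type_names, catalog) {
  stopifnot(is.data.frame(pairs),
            all(c("drug_a", "drug_b", "type") %in% names(pairs)))
  pairs$drug_a <- as.character(pairs$drug_a)
  pairs$drug_b <- as.character(pairs$drug_b)
  pairs$type <- as.integer(pairs$type)
  if (any(pairs$drug_a == pairs$drug_b)) {
    bad <- pairs$drug_a[pairs$drug_a == pairs$drug_b][1]
    stop("self-interaction not allowed (drug '", bad, "' paired with itself)")
  }
  catalog_index(catalog, pairs$drug_a)
  catalog_index(catalog, pairs$drug_b)
  l <- length(type_names)
  if (any(pairs$type < 0L | pairs$type >= l))
    stop("type labels must lie in 0..", l - 1L)
  key <- pair_key(pairs$drug_a, pairs$drug_b)
  if (anyDuplicated(key)) {
    dups <- unique(key[duplicated(key)])
    conflict <- vapply(dups, function(k) {
      length(unique(pairs$type[key == k])) > 1L
    }, logical(1))
    if (any(conflict))
      stop("conflicting type for unordered pair(s): ",
           paste(utils::head(dups[conflict], 5L), collapse = "; "))
    keep <- !duplicated(key)
    ddi_log("warn", "dropped %d duplicate pair record(s)", sum(!keep))
    pairs <- pairs[keep, , drop = FALSE]
  }
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, type_names = as.character(type_names)),
            class = "ddi_table")
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' @export
print.ddi_table <- function(x, ...) {
  cat(sprintf("<ddi_table> %d pairs, %d interaction types\n",
              nrow(x$pairs), length(x$type_names)))
  invisible(x)
}
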