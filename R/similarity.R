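#' Jaccard similarity network from a binary feature matrix
#'
#' For drugs i and j with descriptor sets A and B the similarity is
#' `|A \U2229 B| / |A \U222A B|`. Two drugs with no descriptors at all
#' (empty union) get similarity 0 off-diagonal — absent annotation is not
#' evidence of similarity — while the diagonal is forced to 1.
#'
#' @param F a [feature_matrix()].
#' @return a `similarity_matrix`: list with `source_name` and the m-by-m
#'   symmetric `values` in \[0, 1\] with unit diagonal.
#' @export
jaccard_similarity <- function(F) {
  stopifnot(inherits(F, "feature_matrix"))
  V <- F$values
  if (!all(V %in% c(0, 1))) stop("feature matrix must be binary")
  inter <- V %*% t(V)                 # |A n B|
  sizes <- rowSums(V)
  un <- outer(sizes, sizes, `+`) - inter
  S <- ifelse(un > 0, inter / un, 0)
  diag(S) <- 1
  similarity_matrix(S, F$source_name)
}

similarity_matrix <- function(values, source_name) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == ncol(values))
  if (max(abs(values - t(values))) > 1e-12) stop("similarity must be symmetric")
  if (min(values) < 0 || max(values) > 1 + 1e-12)
    stop("similarity entries must lie in [0, 1]")
  structure(list(source_name = source_name, values = values),
            class = "similarity_matrix")
}

## Split a 7-character ATC code into its 5 hierarchy levels:
## anatomical group | therapeutic subgroup | pharmacological subgroup |
## chemical subgroup | chemical substance.
atc_levels <- function(code) {
  if (!grepl("^[A-Z][0-9]{2}[A-Z][A-Z][0-9]{2}$", code))
    stop("malformed ATC code: '", code, "'")
  c(substr(code, 1, 1), substr(code, 2, 3), substr(code, 4, 4),
    substr(code, 5, 5), substr(code, 6, 7))
}

## Similarity of two single codes: k/5 where k is the length of the common
## level prefix counted from the top of the hierarchy.
atc_code_similarity <- function(code_a, code_b) {
  la <- atc_levels(code_a); lb <- atc_levels(code_b)
  k <- 0L
  for (i in 1:5) {
    if (la[i] != lb[i]) break
    k <- i
  }
  k / 5
}

#' ATC hierarchy-prefix similarity network
#'
#' Each 7-character ATC code spans 5 hierarchy levels; two codes score
#' `k/5` where k is the number of leading levels they share. A drug pair
#' with several codes scores the maximum over all code pairs. Drugs
#' without any code get similarity 0 to every other drug; the diagonal is
#' forced to 1.
#'
#' @param atc an [atc_table()].
#' @param catalog a [drug_catalog()].
#' @return a `similarity_matrix` with `source_name = "atc"`; off-diagonal
#'   values lie in \{0, 0.2, 0.4, 0.6, 0.8, 1\}.
#' @export
atc_similarity <- function(atc, catalog) {
  stopifnot(inherits(atc, "atc_table"), inherits(catalog, "drug_catalog"))
  m <- length(catalog)
  ids <- catalog$drug_ids
  # precompute the level split of every code once
  codes <- lapply(ids, function(id) {
    cs <- atc$entries[[id]]
    if (is.null(cs)) list() else lapply(cs, atc_levels)
  })
  S <- matrix(0, m, m, dimnames = list(ids, ids))
  for (i in seq_len(m)) {
    if (!length(codes[[i]])) next
    for (j in seq_len(m)) {
      if (j <= i || !length(codes[[j]])) next
      best <- 0
      for (la in codes[[i]]) for (lb in codes[[j]]) {
        k <- 0L
        for (lev in 1:5) {
          if (la[lev] != lb[lev]) break
          k <- lev
        }
        if (k / 5 > best) best <- k / 5
      }
      S[i, j] <- S[j, i] <- best
    }
  }
  diag(S) <- 1
  similarity_matrix(S, "atc")
}

#' Build the full set of drug similarity networks
#'
#' Produces the five networks in the fixed order struct, target, pathway,
#' enzyme, ATC. With `atc = NULL` the ATC network is omitted and four
#' networks are returned (the no-ATC pipeline variant).
#'
#' @param features named list of four [feature_matrix()] objects with
#'   sources struct, target, pathway, enzyme.
#' @param atc an [atc_table()], or `NULL` to skip the ATC network.
#' @param catalog a [drug_catalog()].
#' @return named list of `similarity_matrix` objects.
#' @export
build_all_similarities <- function(features, atc, catalog) {
  wanted <- c("struct", "target", "pathway", "enzyme")
  sources <- vapply(features, function(f) f$source_name, character(1))
  if (!setequal(sources, wanted))
    stop("need exactly the four feature sources: ",
         paste(wanted, collapse = ", "))
  features <- features[match(wanted, sources)]
  for (f in features) {
    if (!identical(rownames(f$values), catalog$drug_ids))
      stop("feature matrix '", f$source_name,
           "' is not aligned to the catalog")
  }
  sims <- lapply(features, jaccard_similarity)
  names(sims) <- wanted
  if (!is.null(atc)) sims$atc <- atc_similarity(atc, catalog)
  sims
}
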