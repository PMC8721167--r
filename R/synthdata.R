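#' Synthetic dataset configuration
#'
#' Describes a planted-group benchmark with the statistical structure the
#' pipeline assumes: drugs fall into latent groups; each feature source
#' has one descriptor block per group, fired with probability `p_in`
#' inside the drug's group block and `p_out` elsewhere; ATC codes share
#' leading hierarchy levels within a group; and the interaction type of a
#' sampled pair is a deterministic function of the two groups, flipped to
#' a uniformly drawn other type with probability `label_noise`.
#'
#' Defaults define the bundled benchmark: 80 drugs, 4 groups, descriptor
#' widths 120/100/80/40, 5 interaction types, within/background
#' activation 0.5/0.02, 5% label noise, 60% of pairs labeled.
#'
#' @param m drug count.
#' @param n_groups latent group count.
#' @param dims named or unnamed vector of 4 descriptor widths
#'   (struct, target, pathway, enzyme).
#' @param p_in,p_out descriptor activation probability inside / outside
#'   the drug's group block; `0 <= p_out < p_in <= 1`.
#' @param atc_depth_probs probability over matched ATC depths 0..5: each
#'   drug's code agrees with its group's reference code on the first `d`
#'   levels, `d` drawn from this distribution.
#' @param l interaction type count.
#' @param type_rule `n_groups x n_groups` symmetric integer matrix mapping
#'   a group pair to a type label in `0..l-1`, or `NULL` for the default
#'   rule `(g_a + g_b - 2) mod l`.
#' @param label_noise probability a pair's type is flipped, in \[0, 0.5).
#' @param pair_density fraction of all unordered pairs that get a label,
#'   in (0, 1\].
#' @param seed master seed; one named substream per artifact (features,
#'   ATC, pairs, noise) so e.g. changing `pair_density` never perturbs
#'   the feature draw.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(m = 80L, n_groups = 4L,
                         dims = c(struct = 120L, target = 100L,
                                  pathway = 80L, enzyme = 40L),
                         p_in = 0.5, p_out = 0.02,
                         atc_depth_probs = c(0, 0, 0, 0.3, 0.4, 0.3),
                         l = 5L, type_rule = NULL,
                         label_noise = 0.05, pair_density = 0.6,
                         seed = 1L) {
  stopifnot(m >= n_groups, n_groups >= 2, length(dims) == 4,
            p_out >= 0, p_out < p_in, p_in <= 1,
            length(atc_depth_probs) == 6, all(atc_depth_probs >= 0),
            l >= 2, label_noise >= 0, label_noise < 0.5,
            pair_density > 0, pair_density <= 1)
  if (is.null(names(dims))) names(dims) <- c("struct", "target", "pathway", "enzyme")
  if (is.null(type_rule)) {
    type_rule <- outer(seq_len(n_groups), seq_len(n_groups),
                       function(a, b) (a + b - 2L) %% l)
  }
  type_rule <- as.matrix(type_rule)
  if (!identical(dim(type_rule), c(as.integer(n_groups), as.integer(n_groups))))
    stop("type_rule must be an n_groups x n_groups matrix")
  if (any(is.na(type_rule)) || any(type_rule < 0) || any(type_rule >= l))
    stop("type_rule must cover every group pair with a label in 0..l-1")
  if (max(abs(type_rule - t(type_rule))) > 0)
    stop("type_rule must be symmetric in the group pair")
  structure(list(m = as.integer(m), n_groups = as.integer(n_groups),
                 dims = dims, p_in = p_in, p_out = p_out,
                 atc_depth_probs = atc_depth_probs / sum(atc_depth_probs),
                 l = as.integer(l), type_rule = type_rule,
                 label_noise = label_noise, pair_density = pair_density,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic planted-group dataset
#'
#' Fully reproducible from `config$seed`. Returns the complete input set
#' of the pipeline: catalog, the four binary feature matrices, ATC codes
#' and a labeled DDI table, plus the hidden group assignment for use in
#' recovery tests.
#'
#' @param config a [synth_config()].
#' @return a list of class `ddi_dataset` with elements `catalog`,
#'   `features` (named list of 4 [feature_matrix()]), `atc`
#'   ([atc_table()]), `ddis` ([ddi_table()]), `groups` (integer vector of
#'   latent group per drug) and `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  m <- config$m; g <- config$n_groups
  ids <- sprintf("D%03d", seq_len(m))
  catalog <- drug_catalog(ids)
  groups <- with_seed(substream_seed(config$seed, "groups"),
                      sample(rep_len(seq_len(g), m)))

  features <- with_seed(substream_seed(config$seed, "features"), {
    out <- list()
    for (src in names(config$dims)) {
      w <- config$dims[[src]]
      # contiguous descriptor block per group (last block absorbs remainder)
      block <- rep(seq_len(g), each = ceiling(w / g))[seq_len(w)]
      probs <- matrix(config$p_out, m, w)
      for (gi in seq_len(g)) probs[groups == gi, block == gi] <- config$p_in
      vals <- matrix(as.numeric(stats::runif(m * w) < probs), m, w)
      colnames(vals) <- sprintf("%s_%03d", src, seq_len(w))
      out[[src]] <- feature_matrix(vals, src, catalog, colnames(vals))
    }
    out
  })

  atc <- with_seed(substream_seed(config$seed, "atc"), {
    # one reference code per group; groups differ already at level 1
    ref <- lapply(seq_len(g), function(gi) {
      c(LETTERS[gi], sprintf("%02d", sample(1:99, 1)),
        sample(LETTERS, 1), sample(LETTERS, 1), sprintf("%02d", sample(1:99, 1)))
    })
    rand_level <- function(lev) switch(lev,
      sample(LETTERS, 1), sprintf("%02d", sample(1:99, 1)),
      sample(LETTERS, 1), sample(LETTERS, 1), sprintf("%02d", sample(1:99, 1)))
    entries <- list()
    for (i in seq_len(m)) {
      depth <- sample(0:5, 1, prob = config$atc_depth_probs)
      lv <- ref[[groups[i]]]
      if (depth < 5) for (lev in (depth + 1):5) {
        repeat {
          cand <- rand_level(lev)
          if (cand != lv[lev] || lev > depth + 1) { lv[lev] <- cand; break }
        }
      }
      entries[[ids[i]]] <- paste0(lv, collapse = "")
    }
    atc_table(entries)
  })

  all_pairs <- utils::combn(m, 2)
  n_all <- ncol(all_pairs)
  keep <- with_seed(substream_seed(config$seed, "pairs"),
                    sort(sample(n_all, max(1L, round(config$pair_density * n_all)))))
  a_idx <- all_pairs[1, keep]; b_idx <- all_pairs[2, keep]
  types <- config$type_rule[cbind(groups[a_idx], groups[b_idx])]
  types <- with_seed(substream_seed(config$seed, "noise"), {
    flip <- stats::runif(length(types)) < config$label_noise
    shifted <- (types + sample.int(config$l - 1L, length(types),
                                   replace = TRUE)) %% config$l
    ifelse(flip, shifted, types)
  })
  ddis <- ddi_table(data.frame(drug_a = ids[a_idx], drug_b = ids[b_idx],
                               type = as.integer(types),
                               stringsAsFactors = FALSE),
                    type_names = sprintf("type_%02d", seq_len(config$l) - 1L),
                    catalog = catalog)

  structure(list(catalog = catalog, features = features, atc = atc,
                 ddis = ddis, groups = groups, config = config),
            class = "ddi_dataset")
}

#' Write a synthetic dataset out in the standard delimited formats
#'
#' @param dataset a `ddi_dataset` from [generate_dataset()].
#' @param dir output directory (created if absent).
#' @return named character vector of written file paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (src in names(dataset$features)) {
    p <- file.path(dir, paste0("features_", src, ".tsv"))
    df <- data.frame(drug_id = dataset$catalog$drug_ids,
                     dataset$features[[src]]$values, check.names = FALSE)
    write_delim_file(df, p)
    paths[paste0("features_", src)] <- p
  }
  atc_df <- do.call(rbind, lapply(names(dataset$atc$entries), function(id) {
    data.frame(drug_id = id, atc_code = dataset$atc$entries[[id]],
               stringsAsFactors = FALSE)
  }))
  paths["atc"] <- file.path(dir, "atc_codes.tsv")
  write_delim_file(atc_df, paths["atc"])
  ddi_df <- dataset$ddis$pairs
  ddi_df$type <- dataset$ddis$type_names[ddi_df$type + 1L]
  paths["ddis"] <- file.path(dir, "ddi_table.tsv")
  write_delim_file(ddi_df, paths["ddis"])
  paths["catalog"] <- file.path(dir, "catalog.tsv")
  write_delim_file(data.frame(drug_id = dataset$catalog$drug_ids), paths["catalog"])
  invisible(paths)
}
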