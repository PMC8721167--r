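#' Build a cross-validation plan for one evaluation scene
#'
#' Three scenes of increasing difficulty:
#' * **S1** — hide labeled pairs among known drugs: pairs are split into
#'   `n_folds` test sets with per-type stratification.
#' * **S2** — cold start on one side: drugs are split into `n_folds`
#'   groups; a fold's test pairs have exactly one drug held out, its
#'   training pairs none.
#' * **S3** — full cold start: test pairs have both drugs held out;
#'   training pairs again touch no held-out drug.
#'
#' In S2/S3 a pair with the "wrong" number of held-out drugs for the
#' scene belongs to neither set of that fold, exactly as the scene
#' definitions require. Types with fewer pairs than folds cannot be
#' stratified and are assigned to random folds with a warning.
#'
#' @param ddis a [ddi_table()].
#' @param catalog a [drug_catalog()].
#' @param scene `"S1"`, `"S2"` or `"S3"`.
#' @param n_folds number of folds (>= 2).
#' @param seed integer seed; the plan is deterministic given it.
#' @return a `cv_plan`: list with `scene`, `folds` (per fold: `train`,
#'   `test` pair-row indices and, for S2/S3, `held_drugs`), `n_folds`,
#'   `seed`.
#' @export
split_cv <- function(ddis, catalog, scene = c("S1", "S2", "S3"),
                     n_folds = 5L, seed = 1L) {
  scene <- match.arg(toupper(scene), c("S1", "S2", "S3"))
  stopifnot(n_folds >= 2L)
  pairs <- ddis$pairs
  n <- nrow(pairs)
  folds <- with_seed(substream_seed(seed, paste0("cv_", scene)), {
    if (scene == "S1") {
      fold_of <- integer(n)
      for (t in unique(pairs$type)) {
        ix <- which(pairs$type == t)
        if (length(ix) < n_folds) {
          ddi_log("warn", "type %d has %d pair(s) < %d folds; unstratified",
                  t, length(ix), n_folds)
          fold_of[ix] <- sample.int(n_folds, length(ix), replace = TRUE)
        } else {
          fold_of[ix] <- sample(rep_len(seq_len(n_folds), length(ix)))
        }
      }
      lapply(seq_len(n_folds), function(f) {
        list(train = which(fold_of != f), test = which(fold_of == f))
      })
    } else {
      m <- length(catalog)
      drug_fold <- sample(rep_len(seq_len(n_folds), m))
      ia <- catalog_index(catalog, pairs$drug_a)
      ib <- catalog_index(catalog, pairs$drug_b)
      lapply(seq_len(n_folds), function(f) {
        a_held <- drug_fold[ia] == f
        b_held <- drug_fold[ib] == f
        n_held <- a_held + b_held
        list(train = which(n_held == 0L),
             test = which(n_held == (if (scene == "S2") 1L else 2L)),
             held_drugs = catalog$drug_ids[drug_fold == f])
      })
    }
  })
  structure(list(scene = scene, folds = folds, n_folds = n_folds, seed = seed),
            class = "cv_plan")
}

#' Multiclass evaluation metrics
#'
#' Per-class one-vs-rest confusion counts are taken from the argmax
#' labels. Reported metrics:
#' * `acc` — mean over classes of the one-vs-rest accuracy
#'   `(TP_i + TN_i) / n`; `acc_plain` is ordinary multiclass accuracy.
#' * `precision_macro`, `recall_macro` — per-class precision/recall
#'   (0/0 -> 0) averaged over all `l` classes, including classes absent
#'   from `y_true`.
#' * `f1_macro` — harmonic mean of the macro precision and macro recall.
#'   `f1_macro_perclass` (per-class F1 averaged) is reported alongside.
#' * `precision_micro`, `recall_micro` — pooled counts. With argmax
#'   labeling every sample gets exactly one prediction, so both pooled
#'   metrics coincide with plain accuracy; they are reported for
#'   completeness.
#' * `aupr_micro`, `auc_micro` — area under the precision-recall / ROC
#'   curve of the flattened n-by-l one-vs-rest binarized labels against
#'   the flattened probabilities, integrated trapezoidally over all
#'   distinct thresholds.
#'
#' @param y_true integer labels in `0..l-1`.
#' @param proba a `type_prediction` or an n-by-l probability matrix with
#'   rows summing to 1.
#' @param l number of classes.
#' @return a `metrics_report`: named list of metrics plus the per-class
#'   count table.
#' @export
compute_metrics <- function(y_true, proba, l) {
  probs <- if (inherits(proba, "type_prediction")) proba$probs else as.matrix(proba)
  y_true <- as.integer(y_true)
  n <- length(y_true)
  stopifnot(nrow(probs) == n, ncol(probs) == l, l >= 2)
  if (max(abs(rowSums(probs) - 1)) > 1e-6)
    stop("probability rows must sum to 1")
  y_pred <- max.col(probs, ties.method = "first") - 1L
  counts <- data.frame(class = seq_len(l) - 1L, TP = 0L, FP = 0L,
                       FN = 0L, TN = 0L)
  for (i in seq_len(l)) {
    k <- i - 1L
    counts$TP[i] <- sum(y_true == k & y_pred == k)
    counts$FP[i] <- sum(y_true != k & y_pred == k)
    counts$FN[i] <- sum(y_true == k & y_pred != k)
    counts$TN[i] <- sum(y_true != k & y_pred != k)
  }
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  prec_c <- safe_div(counts$TP, counts$TP + counts$FP)
  rec_c <- safe_div(counts$TP, counts$TP + counts$FN)
  precision_macro <- mean(prec_c)
  recall_macro <- mean(rec_c)
  f1_macro <- if (precision_macro + recall_macro > 0) {
    2 * precision_macro * recall_macro / (precision_macro + recall_macro)
  } else 0
  f1_c <- ifelse(prec_c + rec_c > 0, 2 * prec_c * rec_c / (prec_c + rec_c), 0)
  y_bin <- matrix(0, n, l); y_bin[cbind(seq_len(n), y_true + 1L)] <- 1
  roc <- roc_pr_curves(as.vector(y_bin), as.vector(probs))
  structure(list(
    acc = mean((counts$TP + counts$TN) / n),
    acc_plain = mean(y_true == y_pred),
    precision_macro = precision_macro,
    recall_macro = recall_macro,
    f1_macro = f1_macro,
    f1_macro_perclass = mean(f1_c),
    precision_micro = safe_div(sum(counts$TP), sum(counts$TP) + sum(counts$FP)),
    recall_micro = safe_div(sum(counts$TP), sum(counts$TP) + sum(counts$FN)),
    aupr_micro = roc$aupr,
    auc_micro = roc$auc,
    counts = counts
  ), class = "metrics_report")
}

## ROC and precision-recall areas by cumulative counting over scores
## sorted decreasing, one curve point per distinct threshold, trapezoidal
## integration. ROC is anchored at (0,0); the PR curve starts at recall 0
## with the precision of the highest threshold.
roc_pr_curves <- function(y, scores) {
  stopifnot(length(y) == length(scores))
  P <- sum(y == 1); Ng <- sum(y == 0)
  if (P == 0 || Ng == 0) stop("need both positive and negative labels")
  ord <- order(scores, decreasing = TRUE)
  y_s <- y[ord]; s_s <- scores[ord]
  last <- cumsum(rle(s_s)$lengths)     # index of last tie in each group
  tp <- cumsum(y_s == 1)[last]
  fp <- cumsum(y_s == 0)[last]
  tpr <- tp / P; fpr <- fp / Ng
  prec <- tp / (tp + fp); rec <- tpr
  list(auc = trapz(c(0, fpr), c(0, tpr)),
       aupr = trapz(c(0, rec), c(prec[1], prec)))
}

#' Macro-F1 of a label-frequency-matched random predictor
#'
#' For a predictor that draws labels from the observed class frequencies
#' independently of the truth, the expected per-class precision is the
#' class frequency and the expected per-class recall is its own draw
#' frequency; averaging either over all `l` classes gives `1/l`, so the
#' chance macro-F1 is `1/l`. Used as the reference level for signal
#' recovery checks.
#'
#' @param y observed integer labels.
#' @param l number of classes.
#' @return the chance macro-F1.
#' @export
chance_macro_f1 <- function(y, l) {
  freq <- tabulate(as.integer(y) + 1L, nbins = l) / length(y)
  p <- mean(freq)           # expected macro precision = mean class frequency
  r <- mean(freq)           # draw frequencies match class frequencies
  if (p + r == 0) 0 else 2 * p * r / (p + r)
}

#' Cross-validated evaluation of the full pipeline
#'
#' Similarity networks, diffusion and the autoencoder embedding use no
#' interaction labels, so they are computed once on all drugs; only the
#' pair classifier sees training-fold labels, which keeps the cold-start
#' scenes honest (held-out drugs contribute no labels anywhere). Per
#' fold, the DNN is trained on the training pairs and evaluated on the
#' test pairs; the aggregate is the unweighted mean over folds.
#'
#' @param dataset a `ddi_dataset` (see [generate_dataset()] or assemble
#'   one from loaded components).
#' @param config a [pipeline_config()]; `config$cv` sets scene, folds
#'   and seed.
#' @param variant pipeline variant, see [ablation_run()].
#' @param embedding optional precomputed `unified_embedding` for this
#'   dataset/config (or, for `variant = "sim_avg"`, the averaged
#'   similarity matrix), to avoid refitting label-free stages.
#' @return a `cv_report`: list with `per_fold` (list of
#'   `metrics_report`), `aggregate` and `sd` (named numeric), `scene`,
#'   `chance_f1_macro`.
#' @export
run_cv <- function(dataset, config, variant = "full", embedding = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(embedding)) embedding <- build_embedding(dataset, config, variant)
  plan <- split_cv(dataset$ddis, dataset$catalog, config$cv$scene,
                   config$cv$folds, config$cv$seed)
  l <- length(dataset$ddis$type_names)
  pairs <- dataset$ddis$pairs
  per_fold <- vector("list", plan$n_folds)
  for (f in seq_len(plan$n_folds)) {
    tr <- plan$folds[[f]]$train; te <- plan$folds[[f]]$test
    if (length(te) == 0L) {
      ddi_log("warn", "fold %d has no test pairs; skipped", f)
      next
    }
    samp <- training_samples(embedding, pairs[tr, ], pairs$type[tr],
                             config$operator, dataset$catalog)
    model <- train_dnn(samp$values, samp$labels, config$dnn, l = l,
                       seed = substream_seed(config$cv$seed, paste0("fold", f)))
    pred <- predict_pair_types(model, embedding, pairs[te, ],
                               config$operator, dataset$catalog)
    per_fold[[f]] <- compute_metrics(pairs$type[te], pred, l)
  }
  per_fold <- Filter(Negate(is.null), per_fold)
  metric_names <- c("acc", "acc_plain", "precision_macro", "recall_macro",
                    "f1_macro", "f1_macro_perclass", "precision_micro",
                    "recall_micro", "aupr_micro", "auc_micro")
  vals <- sapply(per_fold, function(mr) unlist(mr[metric_names]))
  structure(list(per_fold = per_fold,
                 aggregate = rowMeans(vals),
                 sd = apply(vals, 1L, stats::sd),
                 scene = plan$scene,
                 chance_f1_macro = chance_macro_f1(pairs$type, l)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> scene %s, %d folds\n", x$scene, length(x$per_fold)))
  agg <- x$aggregate
  for (nm in names(agg))
    cat(sprintf("  %-18s %.4f (sd %.4f)\n", nm, agg[[nm]], x$sd[[nm]]))
  invisible(x)
}
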