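## Softmax deep neural network over drug-pair features.
##
## Hidden layers are linear -> batch normalization -> ReLU -> dropout;
## the output layer is linear -> softmax. Cross-entropy is minimized with
## Adam; a stratified validation slice drives early stopping with
## best-weights restoration. Everything is hand-rolled matrix code with
## analytic backprop (including through batch normalization).

#' Aggregate two drugs' embeddings into one pair feature vector
#'
#' Three operators: `"concat"` gives `[h_a, h_b]` (width 2 d_u, orientation
#' dependent), `"inner"` the elementwise product (width d_u), `"sum"` the
#' elementwise sum (width d_u); the latter two are orientation invariant.
#'
#' @param emb a `unified_embedding` (or plain matrix with drug-id rownames).
#' @param pairs data.frame or matrix with columns `drug_a`, `drug_b`.
#' @param operator `"concat"`, `"inner"` or `"sum"`.
#' @param catalog a [drug_catalog()].
#' @return a `pair_feature_matrix`: list with `values` (n_pairs x p),
#'   `operator` and the pair index.
#' @export
aggregate_pairs <- function(emb, pairs, operator, catalog) {
  operator <- match.arg(operator, c("concat", "inner", "sum"))
  H <- if (inherits(emb, "unified_embedding")) emb$values else as.matrix(emb)
  pairs <- as.data.frame(pairs)
  ia <- catalog_index(catalog, as.character(pairs$drug_a))
  ib <- catalog_index(catalog, as.character(pairs$drug_b))
  Ha <- H[ia, , drop = FALSE]; Hb <- H[ib, , drop = FALSE]
  values <- switch(operator,
                   concat = cbind(Ha, Hb),
                   inner = Ha * Hb,
                   sum = Ha + Hb)
  rownames(values) <- NULL
  structure(list(values = values, operator = operator,
                 pairs = pairs[, c("drug_a", "drug_b")]),
            class = "pair_feature_matrix")
}

relu <- function(x) pmax(x, 0)

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

dnn_init <- function(p_in, hidden, l) {
  dims <- c(p_in, hidden)
  params <- list()
  for (k in seq_along(hidden)) {
    params[[paste0("W", k)]] <- glorot(dims[k], dims[k + 1])
    params[[paste0("gamma", k)]] <- rep(1, dims[k + 1])
    params[[paste0("beta", k)]] <- rep(0, dims[k + 1])
  }
  params$W_out <- glorot(dims[length(dims)], l)
  params$b_out <- rep(0, l)
  params
}

## Forward pass. In training mode batch statistics are used; in inference
## mode the stored population statistics are used, so predictions are a
## pure function of the input.
dnn_forward <- function(model, X, train = FALSE) {
  p <- model$params
  nh <- length(model$hidden)
  cache <- list(A = vector("list", nh), Xhat = vector("list", nh),
                invstd = vector("list", nh), Z = vector("list", nh),
                masks = vector("list", nh), A_in = X)
  A <- X
  eps <- 1e-5
  for (k in seq_len(nh)) {
    Z <- A %*% p[[paste0("W", k)]]
    if (train) {
      mu <- colMeans(Z)
      va <- colMeans(Z^2) - mu^2          # biased batch variance
    } else {
      mu <- model$run_mean[[k]]; va <- model$run_var[[k]]
    }
    invstd <- 1 / sqrt(va + eps)
    Xhat <- sweep(sweep(Z, 2L, mu), 2L, invstd, `*`)
    Y <- sweep(sweep(Xhat, 2L, p[[paste0("gamma", k)]], `*`), 2L,
               p[[paste0("beta", k)]], `+`)
    A_new <- relu(Y)
    if (train && model$dropout > 0) {
      mask <- matrix(stats::runif(length(A_new)) >= model$dropout,
                     nrow(A_new), ncol(A_new)) / (1 - model$dropout)
      cache$masks[[k]] <- mask
      A_new <- A_new * mask
    }
    cache$Z[[k]] <- Z; cache$Xhat[[k]] <- Xhat; cache$invstd[[k]] <- invstd
    cache$A[[k]] <- A_new
    A <- A_new
  }
  scores <- add_bias(A %*% p$W_out, p$b_out)
  probs <- softmax_rows(scores)
  list(probs = probs, cache = cache)
}

## Exact batch-norm population statistics under the current weights,
## computed layer by layer over the full training matrix (no dropout).
## Recomputed before every validation evaluation, so inference never
## suffers from exponential-moving-average warm-up lag.
dnn_population_stats <- function(model, X_train) {
  p <- model$params
  A <- X_train
  eps <- 1e-5
  for (k in seq_along(model$hidden)) {
    Z <- A %*% p[[paste0("W", k)]]
    mu <- colMeans(Z)
    va <- colMeans(Z^2) - mu^2
    model$run_mean[[k]] <- mu
    model$run_var[[k]] <- va
    Xhat <- sweep(sweep(Z, 2L, mu), 2L, 1 / sqrt(va + eps), `*`)
    A <- relu(sweep(sweep(Xhat, 2L, p[[paste0("gamma", k)]], `*`), 2L,
                    p[[paste0("beta", k)]], `+`))
  }
  model
}

dnn_backward <- function(model, fw, X, y_onehot) {
  p <- model$params
  nh <- length(model$hidden)
  cache <- fw$cache
  n <- nrow(X)
  grads <- list()
  dZout <- (fw$probs - y_onehot) / n
  A_last <- if (nh > 0) cache$A[[nh]] else X
  grads$W_out <- t(A_last) %*% dZout
  grads$b_out <- colSums(dZout)
  dA <- dZout %*% t(p$W_out)
  for (k in rev(seq_len(nh))) {
    if (!is.null(cache$masks[[k]])) dA <- dA * cache$masks[[k]]
    # ReLU was applied to Y = gamma*xhat + beta; recover Y > 0 from A pre-mask
    Y <- sweep(sweep(cache$Xhat[[k]], 2L, p[[paste0("gamma", k)]], `*`), 2L,
               p[[paste0("beta", k)]], `+`)
    dY <- dA * (Y > 0)
    grads[[paste0("gamma", k)]] <- colSums(dY * cache$Xhat[[k]])
    grads[[paste0("beta", k)]] <- colSums(dY)
    # batch-norm backward (per feature column)
    g <- p[[paste0("gamma", k)]]
    dXhat <- sweep(dY, 2L, g, `*`)
    mean_dXhat <- colMeans(dXhat)
    mean_dXhat_xhat <- colMeans(dXhat * cache$Xhat[[k]])
    dZ <- sweep(dXhat -
                  rep(mean_dXhat, each = n) -
                  cache$Xhat[[k]] * rep(mean_dXhat_xhat, each = n),
                2L, cache$invstd[[k]], `*`)
    A_prev <- if (k == 1L) X else cache$A[[k - 1L]]
    grads[[paste0("W", k)]] <- t(A_prev) %*% dZ
    dA <- dZ %*% t(p[[paste0("W", k)]])
  }
  grads
}

cross_entropy <- function(probs, y_onehot) {
  -mean(log(pmax(rowSums(probs * y_onehot), 1e-12)))
}

#' Train the softmax DNN on drug-pair features
#'
#' A stratified `val_fraction` slice of the samples is held out for early
#' stopping: training stops when the validation cross-entropy has not
#' improved for `patience` epochs, and the best-scoring weights are
#' restored. Deterministic given `seed`.
#'
#' @param X a `pair_feature_matrix` or numeric matrix (n samples x p).
#' @param y integer labels in `0..l-1`; at least two classes must be present.
#' @param l total number of types (output width); defaults to `max(y)+1`.
#' @param hyper the `dnn` element of a [pipeline_config()].
#' @param seed integer seed.
#' @return a `dnn_model` with parameters, batch-norm running statistics
#'   and a per-epoch training log (train/validation loss).
#' @export
train_dnn <- function(X, y, hyper, l = NULL, seed = 1L) {
  Xv <- if (inherits(X, "pair_feature_matrix")) X$values else as.matrix(X)
  y <- as.integer(y)
  stopifnot(nrow(Xv) == length(y), all(y >= 0))
  if (is.null(l)) l <- max(y) + 1L
  if (length(unique(y)) < 2L)
    stop("training labels contain a single class; need at least 2")
  n <- nrow(Xv)
  with_seed(substream_seed(seed, "dnn"), {
    model <- list(params = dnn_init(ncol(Xv), hyper$hidden, l),
                  hidden = hyper$hidden, l = l, p_in = ncol(Xv),
                  dropout = hyper$dropout,
                  run_mean = lapply(hyper$hidden, function(h) rep(0, h)),
                  run_var = lapply(hyper$hidden, function(h) rep(1, h)))
    # stratified validation split
    val_idx <- unlist(lapply(split(seq_len(n), y), function(ix) {
      nv <- max(1L, round(hyper$val_fraction * length(ix)))
      if (length(ix) <= 1L) integer(0) else sample(ix, min(nv, length(ix) - 1L))
    }), use.names = FALSE)
    train_idx <- setdiff(seq_len(n), val_idx)
    Y_onehot <- matrix(0, n, l); Y_onehot[cbind(seq_len(n), y + 1L)] <- 1
    state <- adam_init(model$params)
    best <- list(loss = Inf, params = model$params,
                 run_mean = model$run_mean, run_var = model$run_var)
    wait <- 0L
    log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                      val_loss = numeric(0))
    for (epoch in seq_len(hyper$epochs)) {
      ord <- sample(train_idx)
      ep_loss <- 0; nb <- 0L
      for (start in seq(1L, length(ord), by = hyper$batch_size)) {
        rows <- ord[start:min(start + hyper$batch_size - 1L, length(ord))]
        if (length(rows) < 2L) next     # batch norm needs >= 2 samples
        fw <- dnn_forward(model, Xv[rows, , drop = FALSE], train = TRUE)
        grads <- dnn_backward(model, fw, Xv[rows, , drop = FALSE],
                              Y_onehot[rows, , drop = FALSE])
        upd <- adam_step(model$params, grads, state, hyper$lr)
        model$params <- upd$params; state <- upd$state
        ep_loss <- ep_loss + cross_entropy(fw$probs, Y_onehot[rows, , drop = FALSE])
        nb <- nb + 1L
      }
      if (!is.finite(ep_loss)) stop("non-finite training loss at epoch ", epoch)
      model <- dnn_population_stats(model, Xv[train_idx, , drop = FALSE])
      val_loss <- if (length(val_idx)) {
        fw_val <- dnn_forward(model, Xv[val_idx, , drop = FALSE])
        cross_entropy(fw_val$probs, Y_onehot[val_idx, , drop = FALSE])
      } else NA_real_
      log <- rbind(log, data.frame(epoch = epoch, train_loss = ep_loss / max(nb, 1L),
                                   val_loss = val_loss))
      ddi_log("debug", "dnn epoch %d train %.4f val %.4f", epoch,
              ep_loss / max(nb, 1L), val_loss)
      if (!is.na(val_loss)) {
        if (val_loss < best$loss - 1e-8) {
          best <- list(loss = val_loss, params = model$params,
                       run_mean = model$run_mean, run_var = model$run_var)
          wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= hyper$patience) {
            ddi_log("debug", "early stop at epoch %d", epoch)
            break
          }
        }
      }
    }
    if (is.finite(best$loss)) {
      model$params <- best$params
      model$run_mean <- best$run_mean
      model$run_var <- best$run_var
    }
    model$log <- log
    class(model) <- "dnn_model"
    model
  })
}

#' Predict type probabilities for raw pair feature rows
#'
#' Pure inference: batch normalization uses the stored running statistics
#' and dropout is off, so identical rows give identical outputs. Each
#' output row sums to 1; `predicted` is the argmax with ties broken
#' toward the lowest label.
#'
#' @param model a `dnn_model`.
#' @param X a `pair_feature_matrix` or numeric matrix with `model$p_in`
#'   columns.
#' @return a `type_prediction`: list with `probs` (n x l) and `predicted`
#'   (integer labels in `0..l-1`).
#' @export
predict_proba <- function(model, X) {
  Xv <- if (inherits(X, "pair_feature_matrix")) X$values else as.matrix(X)
  if (ncol(Xv) != model$p_in)
    stop("feature width ", ncol(Xv), " does not match model input width ",
         model$p_in)
  probs <- dnn_forward(model, Xv)$probs
  structure(list(probs = probs,
                 predicted = max.col(probs, ties.method = "first") - 1L),
            class = "type_prediction")
}

#' Predict interaction types for unordered drug pairs
#'
#' Applies the configured aggregation operator and, for the
#' orientation-dependent `concat` operator, scores both orientations
#' (a,b) and (b,a), averages the two probability vectors and
#' renormalizes — so the reported probabilities are invariant to pair
#' orientation. `inner` and `sum` are orientation invariant already.
#'
#' @param model a `dnn_model`.
#' @param emb a `unified_embedding`.
#' @param pairs data.frame with columns `drug_a`, `drug_b`.
#' @param operator aggregation operator used at training time.
#' @param catalog a [drug_catalog()].
#' @return a `type_prediction`.
#' @export
predict_pair_types <- function(model, emb, pairs, operator, catalog) {
  Xab <- aggregate_pairs(emb, pairs, operator, catalog)
  probs <- predict_proba(model, Xab)$probs
  if (operator == "concat") {
    rev_pairs <- data.frame(drug_a = pairs$drug_b, drug_b = pairs$drug_a)
    Xba <- aggregate_pairs(emb, rev_pairs, operator, catalog)
    probs <- (probs + predict_proba(model, Xba)$probs) / 2
    probs <- probs / rowSums(probs)
  }
  structure(list(probs = probs,
                 predicted = max.col(probs, ties.method = "first") - 1L),
            class = "type_prediction")
}

## Training-sample construction shared by run_cv / run_pipeline: for the
## orientation-dependent concat operator both orientations enter training
## as augmented samples.
training_samples <- function(emb, pairs, labels, operator, catalog) {
  X <- aggregate_pairs(emb, pairs, operator, catalog)
  if (operator == "concat") {
    rev_pairs <- data.frame(drug_a = pairs$drug_b, drug_b = pairs$drug_a)
    Xr <- aggregate_pairs(emb, rev_pairs, operator, catalog)
    list(values = rbind(X$values, Xr$values), labels = c(labels, labels))
  } else {
    list(values = X$values, labels = labels)
  }
}

#' Rank unlabeled drug pairs by predicted probability of one type
#'
#' Scores every unordered drug pair not present in the known DDI table
#' and returns the `k` pairs with the highest probability of `type_id`.
#'
#' @param model a trained `dnn_model`.
#' @param emb a `unified_embedding`.
#' @param known a [ddi_table()] of labeled pairs (always excluded).
#' @param type_id integer label in `0..l-1` to rank by.
#' @param k number of pairs to return (all candidates if fewer).
#' @param operator aggregation operator used at training time.
#' @param catalog a [drug_catalog()].
#' @return data.frame with `drug_a`, `drug_b`, `score` sorted decreasing.
#' @export
rank_novel_pairs <- function(model, emb, known, type_id, k, operator, catalog) {
  if (type_id < 0 || type_id >= model$l)
    stop("type_id must lie in 0..", model$l - 1L)
  m <- length(catalog)
  all_pairs <- utils::combn(m, 2)
  cand <- data.frame(drug_a = catalog$drug_ids[all_pairs[1, ]],
                     drug_b = catalog$drug_ids[all_pairs[2, ]],
                     stringsAsFactors = FALSE)
  known_keys <- pair_key(known$pairs$drug_a, known$pairs$drug_b)
  cand <- cand[!(pair_key(cand$drug_a, cand$drug_b) %in% known_keys), ,
               drop = FALSE]
  if (nrow(cand) == 0L)
    return(data.frame(drug_a = character(0), drug_b = character(0),
                      score = numeric(0)))
  pred <- predict_pair_types(model, emb, cand, operator, catalog)
  cand$score <- pred$probs[, type_id + 1L]
  cand <- cand[order(-cand$score), , drop = FALSE]
  rownames(cand) <- NULL
  utils::head(cand, k)
}
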