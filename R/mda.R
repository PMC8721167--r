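## Multimodal deep autoencoder (MDA) for similarity-network fusion.
##
## One sigmoid encoder branch per input network maps each drug's m network
## neighbours to a d_embed-dimensional code; the K branch codes are
## concatenated and passed through L shared sigmoid integration layers down
## to the unified embedding (the bottleneck); a mirrored shared stack and
## per-network sigmoid decoder branches reconstruct each network row. All
## parameters are trained jointly by Adam on the summed per-network mean
## squared reconstruction error. Gradients are analytic (closed-form
## backprop through the sigmoid chain) and are validated against central
## finite differences in the test suite.

#' Min-max scale topological networks to \[0, 1\]
#'
#' PPMI values are unbounded above while the autoencoder reconstructs
#' through a sigmoid, so each network is independently scaled to \[0, 1\].
#' The scaling parameters are recorded for reproducibility. A constant
#' network scales to all zeros with a warning.
#'
#' @param nets list of `ppmi_network` objects (or plain matrices).
#' @return list with `nets` (scaled matrices, named as the input) and
#'   `scaling` (per-network min/max).
#' @export
scale_networks <- function(nets) {
  vals <- lapply(nets, function(n) if (inherits(n, "ppmi_network")) n$values else as.matrix(n))
  scaling <- list()
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (min(v) < 0) stop("network '", nm, "' has negative entries")
    lo <- min(v); hi <- max(v)
    if (hi == lo) {
      ddi_log("warn", "network '%s' is constant; scaled to all zeros", nm)
      vals[[nm]] <- v * 0
    } else {
      vals[[nm]] <- (v - lo) / (hi - lo)
    }
    scaling[[nm]] <- c(min = lo, max = hi)
  }
  list(nets = vals, scaling = scaling)
}

sigmoid_grad <- function(a) a * (1 - a)

glorot <- function(n_in, n_out) {
  s <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -s, s), n_in, n_out)
}

add_bias <- function(Z, b) Z + rep(b, each = nrow(Z))

mda_init <- function(m, K, d_embed, shared_dims) {
  enc_chain <- c(K * d_embed, shared_dims)              # encoder side
  dec_chain <- rev(enc_chain)                           # mirrored decoder
  params <- list()
  for (j in seq_len(K)) {
    params[[paste0("enc", j, "_W")]] <- glorot(m, d_embed)
    params[[paste0("enc", j, "_b")]] <- numeric(d_embed)
  }
  nL <- length(shared_dims)
  dims_all <- c(enc_chain, dec_chain[-1])               # full shared chain
  for (l in seq_len(2 * nL)) {
    params[[paste0("sh", l, "_W")]] <- glorot(dims_all[l], dims_all[l + 1])
    params[[paste0("sh", l, "_b")]] <- numeric(dims_all[l + 1])
  }
  for (j in seq_len(K)) {
    params[[paste0("dec1_", j, "_W")]] <- glorot(K * d_embed, d_embed)
    params[[paste0("dec1_", j, "_b")]] <- numeric(d_embed)
    params[[paste0("dec2_", j, "_W")]] <- glorot(d_embed, m)
    params[[paste0("dec2_", j, "_b")]] <- numeric(m)
  }
  list(params = params, m = m, K = K, d_embed = d_embed,
       shared_dims = shared_dims, n_shared = 2L * nL, bottleneck = nL)
}

## Forward pass over the rows in `rows`; returns activations for backprop.
## `raw` holds each layer's sigmoid output (for the activation derivative);
## `fed` holds the dropout-masked version actually consumed downstream.
mda_forward <- function(model, X, rows, dropout = 0, train = FALSE) {
  p <- model$params; K <- model$K
  masks <- list()
  drop_fn <- function(A, key) {
    if (train && dropout > 0) {
      mask <- matrix(stats::runif(length(A)) >= dropout, nrow(A), ncol(A)) / (1 - dropout)
      masks[[key]] <<- mask
      A * mask
    } else A
  }
  A_enc <- vector("list", K); A_enc_fed <- vector("list", K)
  for (j in seq_len(K)) {
    A_enc[[j]] <- stable_sigmoid(add_bias(X[[j]][rows, , drop = FALSE] %*%
                                            p[[paste0("enc", j, "_W")]],
                                          p[[paste0("enc", j, "_b")]]))
    A_enc_fed[[j]] <- drop_fn(A_enc[[j]], paste0("enc", j))
  }
  H <- do.call(cbind, A_enc_fed)
  H_concat <- H
  H_shared <- vector("list", model$n_shared)
  H_shared_fed <- vector("list", model$n_shared)
  for (l in seq_len(model$n_shared)) {
    A <- stable_sigmoid(add_bias(H %*% p[[paste0("sh", l, "_W")]],
                                 p[[paste0("sh", l, "_b")]]))
    H_shared[[l]] <- A
    H <- drop_fn(A, paste0("sh", l))
    H_shared_fed[[l]] <- H
  }
  D1 <- vector("list", K); D1_fed <- vector("list", K); Nhat <- vector("list", K)
  for (j in seq_len(K)) {
    D1[[j]] <- stable_sigmoid(add_bias(H %*% p[[paste0("dec1_", j, "_W")]],
                                       p[[paste0("dec1_", j, "_b")]]))
    D1_fed[[j]] <- drop_fn(D1[[j]], paste0("dec1_", j))
    Nhat[[j]] <- stable_sigmoid(add_bias(D1_fed[[j]] %*% p[[paste0("dec2_", j, "_W")]],
                                         p[[paste0("dec2_", j, "_b")]]))
  }
  list(A_enc = A_enc, A_enc_fed = A_enc_fed, H_concat = H_concat,
       H_shared = H_shared, H_shared_fed = H_shared_fed,
       D1 = D1, D1_fed = D1_fed, Nhat = Nhat, masks = masks, rows = rows)
}

mda_loss <- function(fw, X, rows) {
  loss <- 0
  for (j in seq_along(X)) {
    loss <- loss + mean((fw$Nhat[[j]] - X[[j]][rows, , drop = FALSE])^2)
  }
  loss
}

## Analytic gradients of the summed per-network MSE wrt every parameter.
mda_backward <- function(model, fw, X) {
  p <- model$params; K <- model$K; rows <- fw$rows
  grads <- lapply(p, function(x) x * 0)
  n <- length(rows)
  dH <- matrix(0, n, ncol(fw$H_shared[[model$n_shared]]))
  unmask <- function(dA, key) {
    if (!is.null(fw$masks[[key]])) dA * fw$masks[[key]] else dA
  }
  H_last_fed <- fw$H_shared_fed[[model$n_shared]]
  for (j in seq_len(K)) {
    Xj <- X[[j]][rows, , drop = FALSE]
    dNhat <- 2 * (fw$Nhat[[j]] - Xj) / length(Xj)
    dZ2 <- dNhat * sigmoid_grad(fw$Nhat[[j]])
    grads[[paste0("dec2_", j, "_W")]] <- t(fw$D1_fed[[j]]) %*% dZ2
    grads[[paste0("dec2_", j, "_b")]] <- colSums(dZ2)
    dD1 <- unmask(dZ2 %*% t(p[[paste0("dec2_", j, "_W")]]), paste0("dec1_", j))
    dZ1 <- dD1 * sigmoid_grad(fw$D1[[j]])
    grads[[paste0("dec1_", j, "_W")]] <- t(H_last_fed) %*% dZ1
    grads[[paste0("dec1_", j, "_b")]] <- colSums(dZ1)
    dH <- dH + dZ1 %*% t(p[[paste0("dec1_", j, "_W")]])
  }
  for (l in rev(seq_len(model$n_shared))) {
    dH <- unmask(dH, paste0("sh", l))
    dZ <- dH * sigmoid_grad(fw$H_shared[[l]])
    A_prev <- if (l == 1L) fw$H_concat else fw$H_shared_fed[[l - 1L]]
    grads[[paste0("sh", l, "_W")]] <- t(A_prev) %*% dZ
    grads[[paste0("sh", l, "_b")]] <- colSums(dZ)
    dH <- dZ %*% t(p[[paste0("sh", l, "_W")]])
  }
  d <- model$d_embed
  for (j in seq_len(K)) {
    dA <- unmask(dH[, ((j - 1) * d + 1):(j * d), drop = FALSE], paste0("enc", j))
    dZ <- dA * sigmoid_grad(fw$A_enc[[j]])
    grads[[paste0("enc", j, "_W")]] <- t(X[[j]][rows, , drop = FALSE]) %*% dZ
    grads[[paste0("enc", j, "_b")]] <- colSums(dZ)
  }
  grads
}

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Train the multimodal autoencoder and extract the unified embedding
#'
#' Trains the joint reconstruction of all input networks for the
#' configured number of epochs (no early stopping in the extractor) and
#' returns both the model and the unified embedding of the training
#' drugs, i.e. the bottleneck activation. Deterministic given `seed`.
#'
#' @param nets named list of m-by-m matrices already scaled to \[0, 1\]
#'   (see [scale_networks()]).
#' @param hyper the `mda` element of a [pipeline_config()].
#' @param seed integer seed for weight init, shuffling and dropout.
#' @return list with `model` (class `mda_model`, including the per-epoch
#'   full-data `loss_log`) and `embedding` (class `unified_embedding`,
#'   m-by-d_u matrix with entries in (0,1)).
#' @export
train_mda <- function(nets, hyper, seed = 1L) {
  X <- lapply(nets, function(n) if (inherits(n, "ppmi_network")) n$values else as.matrix(n))
  m <- nrow(X[[1]])
  for (x in X) {
    if (!identical(dim(x), dim(X[[1]])))
      stop("all networks must share the same dimensions")
    if (min(x) < -1e-12 || max(x) > 1 + 1e-12)
      stop("networks must be scaled to [0, 1]; call scale_networks() first")
  }
  K <- length(X)
  with_seed(substream_seed(seed, "mda"), {
    model <- mda_init(m, K, hyper$d_embed, hyper$shared_dims)
    model$hyper <- hyper
    state <- adam_init(model$params)
    loss_log <- numeric(hyper$epochs)
    for (epoch in seq_len(hyper$epochs)) {
      order_rows <- sample.int(m)
      for (start in seq(1L, m, by = hyper$batch_size)) {
        rows <- order_rows[start:min(start + hyper$batch_size - 1L, m)]
        fw <- mda_forward(model, X, rows, dropout = hyper$dropout, train = TRUE)
        grads <- mda_backward(model, fw, X)
        upd <- adam_step(model$params, grads, state, hyper$lr)
        model$params <- upd$params; state <- upd$state
      }
      fw_all <- mda_forward(model, X, seq_len(m))
      loss_log[epoch] <- mda_loss(fw_all, X, seq_len(m))
      if (!is.finite(loss_log[epoch]))
        stop("non-finite reconstruction loss at epoch ", epoch)
      ddi_log("debug", "mda epoch %d loss %.6f", epoch, loss_log[epoch])
    }
    model$loss_log <- loss_log
    class(model) <- "mda_model"
    list(model = model, embedding = encode(model, X))
  })
}

#' Encode networks into the unified embedding
#'
#' Deterministic forward pass of a trained model up to the bottleneck.
#'
#' @param model an `mda_model` from [train_mda()].
#' @param nets list of scaled networks with the model's drug dimension.
#' @return a `unified_embedding`: list with the m-by-d_u `values` matrix.
#' @export
encode <- function(model, nets) {
  X <- lapply(nets, function(n) if (inherits(n, "ppmi_network")) n$values else as.matrix(n))
  if (length(X) != model$K) stop("model expects ", model$K, " networks")
  if (ncol(X[[1]]) != model$m)
    stop("network width ", ncol(X[[1]]), " does not match model m = ", model$m)
  fw <- mda_forward(model, X, seq_len(nrow(X[[1]])))
  values <- fw$H_shared[[model$bottleneck]]
  rownames(values) <- rownames(X[[1]])
  structure(list(values = values, d_u = ncol(values)),
            class = "unified_embedding")
}
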