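set_log_level("error")

# Small planted-group dataset for unit tests (not the acceptance benchmark).
tiny_dataset <- function(m = 30L, seed = 7L, label_noise = 0.05,
                         pair_density = 0.7, n_groups = 3L, l = 4L) {
  generate_dataset(synth_config(
    m = m, n_groups = n_groups,
    dims = c(struct = 40L, target = 30L, pathway = 24L, enzyme = 16L),
    l = l, label_noise = label_noise, pair_density = pair_density,
    seed = seed))
}

# Fast learning settings for unit tests.
tiny_config <- function(...) {
  benchmark_config(
    mda = list(epochs = 15L, d_embed = 8L, shared_dims = 16L),
    dnn = list(epochs = 25L, hidden = c(32L, 16L), batch_size = 32L,
               patience = 8L),
    ...)
}

# Random row-stochastic matrix.
random_stochastic <- function(m) {
  W <- matrix(stats::runif(m * m), m, m)
  W / rowSums(W)
}

# Independent closed-form diffusion state: p_i = (1-a) e_i (I - a W)^{-1},
# solved as a linear system row by row.
rwr_closed_form <- function(W, alpha) {
  m <- nrow(W)
  t((1 - alpha) * solve(t(diag(m) - alpha * W), diag(m)))
}

# Entrywise scalar PPMI oracle.
ppmi_oracle <- function(P) {
  total <- sum(P)
  r <- rowSums(P); cs <- colSums(P)
  X <- matrix(0, nrow(P), ncol(P))
  for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P))) {
    if (P[i, j] > 0) X[i, j] <- max(0, log2(P[i, j] * total / (r[i] * cs[j])))
  }
  X
}

# Brute-force set-based Jaccard oracle.
jaccard_oracle <- function(V) {
  m <- nrow(V)
  S <- diag(1, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i == j) next
    A <- which(V[i, ] == 1); B <- which(V[j, ] == 1)
    u <- length(union(A, B))
    S[i, j] <- if (u == 0) 0 else length(intersect(A, B)) / u
  }
  S
}

# Independent metrics oracle: per-class confusion loop plus an explicit
# threshold sweep with trapezoidal integration for the micro curves.
metrics_oracle <- function(y_true, probs, l) {
  n <- length(y_true)
  y_pred <- integer(n)
  for (i in seq_len(n)) y_pred[i] <- which.max(probs[i, ]) - 1L
  TP <- FP <- FN <- TN <- numeric(l)
  for (k in 0:(l - 1)) {
    TP[k + 1] <- sum(y_true == k & y_pred == k)
    FP[k + 1] <- sum(y_true != k & y_pred == k)
    FN[k + 1] <- sum(y_true == k & y_pred != k)
    TN[k + 1] <- sum(y_true != k & y_pred != k)
  }
  sdiv <- function(a, b) if (b > 0) a / b else 0
  prec <- mapply(sdiv, TP, TP + FP)
  rec <- mapply(sdiv, TP, TP + FN)
  P <- mean(prec); R <- mean(rec)
  # flattened one-vs-rest labels in the same n x l layout as the implementation
  Ybin <- matrix(0, n, l); Ybin[cbind(seq_len(n), y_true + 1L)] <- 1
  y_flat <- as.vector(Ybin)
  s_flat <- as.vector(probs)
  th <- sort(unique(s_flat), decreasing = TRUE)
  npos <- sum(y_flat == 1); nneg <- sum(y_flat == 0)
  tpr <- fpr <- precv <- recv <- numeric(length(th))
  for (t in seq_along(th)) {
    pred_pos <- s_flat >= th[t]
    tp <- sum(pred_pos & y_flat == 1); fp <- sum(pred_pos & y_flat == 0)
    tpr[t] <- tp / npos; fpr[t] <- fp / nneg
    precv[t] <- tp / (tp + fp); recv[t] <- tpr[t]
  }
  trap <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  list(acc = mean((TP + TN) / n),
       precision_macro = P, recall_macro = R,
       f1_macro = if (P + R > 0) 2 * P * R / (P + R) else 0,
       auc_micro = trap(c(0, fpr), c(0, tpr)),
       aupr_micro = trap(c(0, recv), c(precv[1], precv)))
}

random_prediction_set <- function(n, l) {
  probs <- matrix(stats::rexp(n * l), n, l)
  probs <- probs / rowSums(probs)
  list(y = sample(0:(l - 1), n, replace = TRUE), probs = probs)
}
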