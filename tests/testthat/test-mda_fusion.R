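make_nets <- function(m, K = 5L, seed = 1L) {
  set.seed(seed)
  nets <- lapply(seq_len(K), function(j) {
    X <- matrix(rexp(m * m), m, m)
    X <- (X + t(X)) / 2
    (X - min(X)) / (max(X) - min(X))
  })
  names(nets) <- paste0("n", seq_len(K))
  nets
}

test_that("network scaling maps to [0,1], records parameters and flags constants", {
  nets <- list(a = matrix(c(0, 2, 2, 4), 2), b = matrix(0.5, 2, 2))
  old <- set_log_level("warn")
  expect_message(sc <- scale_networks(nets), "constant")
  set_log_level(old)
  expect_equal(sc$nets$a, matrix(c(0, 0.5, 0.5, 1), 2))
  expect_equal(sc$nets$b, matrix(0, 2, 2))
  expect_equal(sc$scaling$a, c(min = 0, max = 4))
  # an already-[0,1] network passes through unchanged
  inunit <- list(u = matrix(c(0, 0.25, 0.25, 1), 2))
  expect_equal(scale_networks(inunit)$nets$u, inunit$u, tolerance = 1e-12)
})

test_that("training reduces reconstruction loss and yields the right shapes", {
  nets <- make_nets(30L, seed = 2L)
  hyper <- list(lr = 0.01, epochs = 40L, dropout = 0, batch_size = 16L,
                d_embed = 8L, shared_dims = 16L)
  fit <- train_mda(nets, hyper, seed = 7L)
  expect_equal(dim(fit$embedding$values), c(30L, 16L))
  expect_true(all(fit$embedding$values > 0 & fit$embedding$values < 1))
  expect_true(all(is.finite(fit$model$loss_log)))
  expect_lt(fit$model$loss_log[hyper$epochs], fit$model$loss_log[1])

  # deterministic given the seed
  fit2 <- train_mda(nets, hyper, seed = 7L)
  expect_identical(fit$model$params, fit2$model$params)

  # encode on the training inputs reproduces the returned embedding
  expect_equal(encode(fit$model, nets)$values, fit$embedding$values)
})

test_that("dimension mismatches and unscaled inputs are rejected", {
  nets <- make_nets(10L, seed = 3L)
  hyper <- list(lr = 0.01, epochs = 2L, dropout = 0, batch_size = 8L,
                d_embed = 4L, shared_dims = 6L)
  bad <- nets; bad[[2]] <- matrix(0.5, 8, 8)
  expect_error(train_mda(bad, hyper), "same dimensions")
  unscaled <- nets; unscaled[[1]] <- nets[[1]] * 3
  expect_error(train_mda(unscaled, hyper), "scale_networks")
  fit <- train_mda(nets, hyper, seed = 1L)
  expect_error(encode(fit$model, make_nets(12L)), "does not match")
})

test_that("a duplicated drug gets an identical embedding row", {
  nets <- make_nets(12L, seed = 5L)
  # duplicate drug 1 as drug 13 in every network, rows and columns
  nets_dup <- lapply(nets, function(N) {
    N2 <- rbind(cbind(N, N[, 1]), c(N[1, ], N[1, 1]))
    N2
  })
  hyper <- list(lr = 0.01, epochs = 20L, dropout = 0, batch_size = 13L,
                d_embed = 4L, shared_dims = 8L)
  fit <- train_mda(nets_dup, hyper, seed = 9L)
  expect_equal(fit$embedding$values[13, ], fit$embedding$values[1, ],
               tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences", {
  m <- 6L
  nets <- make_nets(m, seed = 11L)
  set.seed(15)
  model <- ddinet:::mda_init(m, 5L, 3L, 4L)
  rows <- seq_len(m)
  loss_at <- function(params) {
    model$params <- params
    fw <- ddinet:::mda_forward(model, nets, rows)
    ddinet:::mda_loss(fw, nets, rows)
  }
  fw <- ddinet:::mda_forward(model, nets, rows)
  grads <- ddinet:::mda_backward(model, fw, nets)
  h <- 1e-5
  set.seed(16)
  for (nm in names(model$params)) {
    # probe a few random coordinates of every parameter array
    idx <- sample(length(model$params[[nm]]), min(3L, length(model$params[[nm]])))
    for (i in idx) {
      p_plus <- model$params; p_plus[[nm]][i] <- p_plus[[nm]][i] + h
      p_minus <- model$params; p_minus[[nm]][i] <- p_minus[[nm]][i] - h
      fd <- (loss_at(p_plus) - loss_at(p_minus)) / (2 * h)
      expect_lt(abs(grads[[nm]][i] - fd) / max(1e-6, abs(fd), abs(grads[[nm]][i])),
                1e-4)
    }
  }
})
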