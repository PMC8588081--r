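# Minimal feed-forward network used for the MLP model and the deep-branch
# classifier head: fully connected ReLU layers with inverted dropout,
# softmax output, cross-entropy loss, Adam optimizer, mini-batch training.
# Kept in-package so the exact stated architecture (two 200-unit hidden
# layers with dropout 0.5) is trained deterministically under a seed.

mlp_init <- function(sizes) {
  # sizes: c(d_in, hidden..., 2); He initialization
  lapply(seq_len(length(sizes) - 1L), function(i) {
    list(W = matrix(stats::rnorm(sizes[i] * sizes[i + 1], 0,
                                 sqrt(2 / sizes[i])), sizes[i], sizes[i + 1]),
         b = rep(0, sizes[i + 1]))
  })
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

mlp_forward <- function(layers, x, dropout = 0, train = FALSE) {
  acts <- list(x)
  n_layers <- length(layers)
  for (i in seq_len(n_layers)) {
    z <- sweep(acts[[i]] %*% layers[[i]]$W, 2, layers[[i]]$b, "+")
    if (i < n_layers) {
      a <- pmax(z, 0)
      if (train && dropout > 0) {
        keep <- 1 - dropout
        mask <- matrix(stats::rbinom(length(a), 1, keep) / keep,
                       nrow(a), ncol(a))
        a <- a * mask
      }
      acts[[i + 1]] <- a
    } else {
      acts[[i + 1]] <- softmax_rows(z)
    }
  }
  acts
}

# Fit on x (n x d, already standardized) with factor y (2 levels).
mlp_fit <- function(x, y, hidden = c(200L, 200L), dropout = 0.5, epochs = 50L,
                    batch_size = 32L, lr = 1e-3, seed = 1L) {
  set.seed(seed)
  n <- nrow(x)
  y_idx <- as.integer(y)                       # 1 = healthy, 2 = jaundiced
  onehot <- matrix(0, n, 2)
  onehot[cbind(seq_len(n), y_idx)] <- 1
  layers <- mlp_init(c(ncol(x), hidden, 2L))
  mom <- lapply(layers, function(l) list(mW = l$W * 0, vW = l$W * 0,
                                         mb = l$b * 0, vb = l$b * 0))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  for (epoch in seq_len(epochs)) {
    ord <- sample.int(n)
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      xb <- x[idx, , drop = FALSE]
      tb <- onehot[idx, , drop = FALSE]
      acts <- mlp_forward(layers, xb, dropout, train = TRUE)
      n_layers <- length(layers)
      delta <- (acts[[n_layers + 1L]] - tb) / nrow(xb)
      grads <- vector("list", n_layers)
      for (i in rev(seq_len(n_layers))) {
        grads[[i]] <- list(W = crossprod(acts[[i]], delta), b = colSums(delta))
        if (i > 1L) {
          delta <- (delta %*% t(layers[[i]]$W)) * (acts[[i]] > 0)
        }
      }
      step <- step + 1L
      bc1 <- 1 - beta1^step; bc2 <- 1 - beta2^step
      for (i in seq_len(n_layers)) {
        m <- mom[[i]]
        m$mW <- beta1 * m$mW + (1 - beta1) * grads[[i]]$W
        m$vW <- beta2 * m$vW + (1 - beta2) * grads[[i]]$W^2
        m$mb <- beta1 * m$mb + (1 - beta1) * grads[[i]]$b
        m$vb <- beta2 * m$vb + (1 - beta2) * grads[[i]]$b^2
        layers[[i]]$W <- layers[[i]]$W - lr * (m$mW / bc1) / (sqrt(m$vW / bc2) + eps)
        layers[[i]]$b <- layers[[i]]$b - lr * (m$mb / bc1) / (sqrt(m$vb / bc2) + eps)
        mom[[i]] <- m
      }
    }
  }
  list(layers = layers, levels = levels(y))
}

# Probability matrix (n x 2) on new standardized data; dropout disabled.
mlp_predict <- function(fit, x) {
  acts <- mlp_forward(fit$layers, x, dropout = 0, train = FALSE)
  acts[[length(acts)]]
}
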