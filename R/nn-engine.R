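# A small multi-label neural-network engine on BLAS matrix multiplies.
#
# Only what the fingerprint predictor needs is implemented: embedding,
# 1D convolution (same padding, im2col), max pooling, dropout, flatten
# and dense layers; sigmoid outputs with binary cross-entropy loss and
# the Adam optimiser. Sequence activations are stored as (batch*L, C)
# matrices with rows ordered sample-major ((b-1)*L + t), so every layer
# reduces to a single large matrix product.
#
# Initialisation follows the common Glorot-uniform scheme for weight
# matrices and uniform(-0.05, 0.05) for embeddings; all randomness is
# drawn from R's RNG so a fixed seed reproduces weights, shuffling and
# dropout masks bit for bit.

glorot <- function(fan_in, fan_out, dims = c(fan_in, fan_out)) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -lim, lim), dim = dims)
}

layer_embedding <- function(vocab, dim) {
  W <- matrix(runif(vocab * dim, -0.05, 0.05), vocab, dim)
  # intensity-ramp init: the first channel starts linear in the token
  # value, so an untrained embedding already carries the intensity
  # ordering (tokens are quantised intensities, not categorical symbols);
  # the remaining channels stay free to learn token-specific structure
  W[, 1] <- (seq_len(vocab) - 1) / (vocab - 1)
  list(type = "embedding", vocab = vocab, dim = dim, W = W)
}

layer_conv1d <- function(c_in, c_out, kernel, activation = "relu") {
  stopifnot(kernel %% 2 == 1)
  list(type = "conv1d", c_in = c_in, c_out = c_out, kernel = kernel,
       activation = activation,
       W = glorot(kernel * c_in, c_out), b = numeric(c_out))
}

layer_maxpool1d <- function(size) list(type = "maxpool1d", size = size)
layer_dropout <- function(rate) list(type = "dropout", rate = rate)
layer_flatten <- function() list(type = "flatten")

layer_dense <- function(d_in, d_out, activation = "relu") {
  list(type = "dense", d_in = d_in, d_out = d_out, activation = activation,
       W = glorot(d_in, d_out), b = numeric(d_out))
}

activate <- function(z, act) {
  switch(act,
         relu = pmax(z, 0),
         sigmoid = plogis(z),
         identity = z,
         abort(paste("Unknown activation:", act)))
}

activation_grad <- function(dout, z, a, act) {
  switch(act,
         relu = dout * (z > 0),
         sigmoid = dout * a * (1 - a),
         identity = dout,
         abort(paste("Unknown activation:", act)))
}

# im2col index for same-padded conv over length L: entry [r, k] is the
# source row feeding kernel offset k of output row r, with the sentinel
# row (L*B + 1, an all-zero pad row) for out-of-range positions.
conv_index <- function(L, B, kernel) {
  pad <- (kernel - 1L) %/% 2L
  sentinel <- L * B + 1L
  t_idx <- rep(seq_len(L), times = B)
  b_off <- rep((seq_len(B) - 1L) * L, each = L)
  idx <- matrix(sentinel, L * B, kernel)
  for (k in seq_len(kernel)) {
    src_t <- t_idx + (k - 1L) - pad
    ok <- src_t >= 1L & src_t <= L
    idx[ok, k] <- src_t[ok] + b_off[ok]
  }
  idx
}

nn_forward <- function(layers, X, B, training = FALSE, keep_cache = FALSE) {
  # X: (B, L) integer tokens when first layer is embedding, otherwise a
  # (B, L) real matrix treated as a single input channel.
  caches <- vector("list", length(layers))
  first <- layers[[1]]
  if (first$type == "embedding") {
    tokens <- as.integer(t(X)) + 1L            # sample-major (b-1)*L + t
    A <- first$W[tokens, , drop = FALSE]
    L <- ncol(X); C <- first$dim
    caches[[1]] <- if (keep_cache) list(tokens = tokens) else NULL
    start <- 2L
  } else if (first$type == "dense") {
    A <- as.matrix(X)                          # flat feature input
    L <- 1L; C <- ncol(X)
    start <- 1L
  } else {
    A <- matrix(as.numeric(t(X)), ncol = 1L)   # raw intensity channel
    L <- ncol(X); C <- 1L
    start <- 1L
  }
  for (li in seq(start, length(layers))) {
    ly <- layers[[li]]
    cache <- list(L = L, C = C)
    if (ly$type == "conv1d") {
      idx <- conv_index(L, B, ly$kernel)
      Apad <- rbind(A, numeric(C))
      Acol <- matrix(0, L * B, ly$kernel * C)
      for (k in seq_len(ly$kernel)) {
        Acol[, ((k - 1L) * C + 1L):(k * C)] <- Apad[idx[, k], , drop = FALSE]
      }
      Z <- Acol %*% ly$W
      Z <- sweep(Z, 2, ly$b, "+")
      Aout <- activate(Z, ly$activation)
      cache$Acol <- Acol; cache$idx <- idx; cache$Z <- Z
      A <- Aout; C <- ly$c_out
    } else if (ly$type == "maxpool1d") {
      m <- ly$size
      Lo <- L %/% m
      if (Lo < 1) abort("Pool size larger than sequence length.", class = "specfp_config_error")
      base <- rep((seq_len(Lo) - 1L) * m, times = B) +
        rep((seq_len(B) - 1L) * L, each = Lo)
      M <- A[base + 1L, , drop = FALSE]
      argk <- matrix(1L, nrow(M), ncol(M))
      if (m > 1) for (j in 2:m) {
        Yj <- A[base + j, , drop = FALSE]
        sel <- Yj > M
        M[sel] <- Yj[sel]
        argk[sel] <- j
      }
      cache$base <- base; cache$argk <- argk
      A <- M; L <- Lo
    } else if (ly$type == "dropout") {
      if (training && ly$rate > 0) {
        mask <- matrix(runif(length(A)) >= ly$rate, nrow(A), ncol(A)) / (1 - ly$rate)
        A <- A * mask
        cache$mask <- mask
      }
    } else if (ly$type == "flatten") {
      arr <- array(A, dim = c(L, B, C))
      A <- t(matrix(aperm(arr, c(3, 1, 2)), nrow = C * L))  # (B, L*C), (t-1)*C + c
      cache$Lin <- L; cache$Cin <- C
      L <- 1L; C <- ncol(A)
    } else if (ly$type == "dense") {
      Z <- A %*% ly$W
      Z <- sweep(Z, 2, ly$b, "+")
      cache$Ain <- A; cache$Z <- Z
      A <- activate(Z, ly$activation)
      cache$Aout <- A
      C <- ly$d_out
    }
    caches[[li]] <- if (keep_cache) cache else NULL
  }
  list(out = A, caches = caches)
}

# Backward pass; `dout` is dLoss/dZ for the output layer when
# `fused_output = TRUE` (sigmoid + BCE fused), else dLoss/dA.
nn_backward <- function(layers, caches, dout, B, fused_output = TRUE) {
  grads <- vector("list", length(layers))
  d <- dout
  for (li in rev(seq_along(layers))) {
    ly <- layers[[li]]
    cache <- caches[[li]]
    if (ly$type == "dense") {
      dZ <- if (li == length(layers) && fused_output) d else
        activation_grad(d, cache$Z, cache$Aout, ly$activation)
      grads[[li]] <- list(W = crossprod(cache$Ain, dZ), b = colSums(dZ))
      d <- dZ %*% t(ly$W)
    } else if (ly$type == "flatten") {
      L <- cache$Lin; C <- cache$Cin
      arr <- aperm(array(t(d), dim = c(C, L, B)), c(2, 3, 1))
      d <- matrix(arr, nrow = L * B, ncol = C)
    } else if (ly$type == "dropout") {
      if (!is.null(cache$mask)) d <- d * cache$mask
    } else if (ly$type == "maxpool1d") {
      L <- cache$L; C <- cache$C
      dA <- matrix(0, L * B, C)
      for (j in seq_len(ly$size)) {
        mask <- cache$argk == j
        if (any(mask)) {
          dj <- matrix(0, nrow(d), ncol(d))
          dj[mask] <- d[mask]
          rows <- cache$base + j
          dA[rows, ] <- dA[rows, , drop = FALSE] + dj
        }
      }
      d <- dA
    } else if (ly$type == "conv1d") {
      dZ <- activation_grad(d, cache$Z, NULL, "relu")
      grads[[li]] <- list(W = crossprod(cache$Acol, dZ), b = colSums(dZ))
      dcol <- dZ %*% t(ly$W)
      C <- cache$C
      nreal <- cache$L * B
      dA <- matrix(0, nreal, C)
      for (k in seq_len(ly$kernel)) {
        src <- cache$idx[, k]
        ok <- src <= nreal
        # for fixed k the source rows are distinct, so direct add is safe
        dA[src[ok], ] <- dA[src[ok], , drop = FALSE] +
          dcol[ok, ((k - 1L) * C + 1L):(k * C), drop = FALSE]
      }
      d <- dA
    } else if (ly$type == "embedding") {
      g <- matrix(0, ly$vocab, ly$dim)
      agg <- rowsum(d, cache$tokens)
      g[as.integer(rownames(agg)), ] <- agg
      grads[[li]] <- list(W = g)
      d <- NULL
    }
  }
  grads
}

adam_state <- function(layers) {
  lapply(layers, function(ly) {
    if (is.null(ly$W)) return(NULL)
    st <- list(mW = array(0, dim = dim(ly$W) %||% length(ly$W)),
               vW = array(0, dim = dim(ly$W) %||% length(ly$W)))
    if (!is.null(ly$b)) {
      st$mb <- numeric(length(ly$b)); st$vb <- numeric(length(ly$b))
    }
    st
  })
}

adam_update <- function(layers, grads, state, t, lr = 1e-3,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  for (li in seq_along(layers)) {
    g <- grads[[li]]
    if (is.null(g)) next
    st <- state[[li]]
    st$mW <- beta1 * st$mW + (1 - beta1) * g$W
    st$vW <- beta2 * st$vW + (1 - beta2) * g$W^2
    layers[[li]]$W <- layers[[li]]$W - lr * (st$mW / bc1) / (sqrt(st$vW / bc2) + eps)
    if (!is.null(g$b)) {
      st$mb <- beta1 * st$mb + (1 - beta1) * g$b
      st$vb <- beta2 * st$vb + (1 - beta2) * g$b^2
      layers[[li]]$b <- layers[[li]]$b - lr * (st$mb / bc1) / (sqrt(st$vb / bc2) + eps)
    }
    state[[li]] <- st
  }
  list(layers = layers, state = state)
}

# mean binary cross-entropy over all outputs, clipped for stability
bce_loss <- function(p, y, eps = 1e-7) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

binary_accuracy <- function(p, y, threshold = 0.5) {
  mean((p >= threshold) == (y != 0))
}
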