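# Minimal CNN engine: valid convolution via im2col + BLAS matrix products,
# ceil-mode 2x2 max pooling, dense layers, softmax cross-entropy, Adam.
# Activations live as B x (H*W*C) matrices with the pixel (h, w, c) in
# column h + (w-1)*H + (c-1)*H*W (channel-major flattening: channel slowest).
# All shapes are fixed at model-compile time, so gather/scatter index
# tables are precomputed once per layer.

# ---- geometry ---------------------------------------------------------

# Gather table for valid stride-1 convolution: P x Kd integer matrix,
# P = Hout*Wout output positions, Kd = K*K*Cin kernel elements.
conv_gather_index <- function(H, W, C, K) {
  Hout <- H - K + 1L; Wout <- W - K + 1L
  ho <- rep(seq_len(Hout), times = Wout)
  wo <- rep(seq_len(Wout), each = Hout)           # p = ho + (wo-1)*Hout
  ki <- rep(seq_len(K), times = K)
  kj <- rep(seq_len(K), each = K)                 # s = ki + (kj-1)*K
  idx <- matrix(0L, Hout * Wout, K * K * C)
  for (c in seq_len(C)) {
    base <- (c - 1L) * H * W
    for (s in seq_len(K * K)) {
      r <- ho + ki[s] - 1L
      cc <- wo + kj[s] - 1L
      idx[, (c - 1L) * K * K + s] <- base + r + (cc - 1L) * H
    }
  }
  # contiguous-run decomposition of the same gather (dest ordered (p, k),
  # source runs of length Hout along the output-height axis)
  P <- Hout * Wout
  cgrid <- rep(seq_len(C), each = K * K * Wout)
  sgrid <- rep(rep(seq_len(K * K), each = Wout), times = C)
  wgrid <- rep(seq_len(Wout), times = K * K * C)
  kigrid <- (sgrid - 1L) %% K + 1L
  kjgrid <- (sgrid - 1L) %/% K + 1L
  kfull <- sgrid + (cgrid - 1L) * K * K
  dst_start <- (kfull - 1L) * P + (wgrid - 1L) * Hout + 1L
  src_start <- (cgrid - 1L) * H * W + (wgrid + kjgrid - 2L) * H + kigrid
  list(idx = idx, idxvec = as.integer(idx),
       run_src = as.integer(src_start), run_dst = as.integer(dst_start),
       run_len = rep(Hout, length(dst_start)),
       Hout = Hout, Wout = Wout, P = P, Kd = K * K * C)
}

# Ceil-mode 2x2/stride-2 pooling: four candidate gather tables over all
# (position, channel) pairs plus validity masks for partial edge windows.
pool_gather_index <- function(H, W, C) {
  Hout <- as.integer(ceiling(H / 2)); Wout <- as.integer(ceiling(W / 2))
  P <- Hout * Wout
  ho <- rep(seq_len(Hout), times = Wout)
  wo <- rep(seq_len(Wout), each = Hout)
  offs <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  idx <- vector("list", 4L); valid <- vector("list", 4L)
  for (j in 1:4) {
    r <- 2L * ho - 1L + offs[[j]][1L]
    cc <- 2L * wo - 1L + offs[[j]][2L]
    ok <- r <= H & cc <= W
    pix <- r + (cc - 1L) * H
    pix[!ok] <- 1L                                 # safe placeholder
    full_idx <- integer(P * C); full_ok <- logical(P * C)
    for (c in seq_len(C)) {
      cols <- (c - 1L) * P + seq_len(P)
      full_idx[cols] <- (c - 1L) * H * W + pix
      full_ok[cols] <- ok
    }
    idx[[j]] <- full_idx; valid[[j]] <- full_ok
  }
  list(idx = idx, valid = valid, Hout = Hout, Wout = Wout, P = P)
}

# ---- layers -----------------------------------------------------------

relu <- function(x) x * (x > 0)

# Conv layer weights: Wm is (K*K*Cin) x Cout with rows ordered to match
# conv_gather_index columns (spatial offset fast, input channel slow).
layer_conv <- function(Cin, Cout, K, dropout = 0) {
  fan_in <- K * K * Cin; fan_out <- K * K * Cout
  lim <- sqrt(6 / (fan_in + fan_out))
  list(type = "conv", K = K, Cin = Cin, Cout = Cout, dropout = dropout,
       Wm = matrix(runif(fan_in * Cout, -lim, lim), fan_in, Cout),
       b = numeric(Cout))
}

layer_pool <- function() list(type = "pool")

layer_dense <- function(n_in, n_out, activation = "relu", dropout = 0) {
  lim <- sqrt(6 / (n_in + n_out))
  list(type = "dense", n_in = n_in, n_out = n_out,
       activation = activation, dropout = dropout,
       Wm = matrix(runif(n_in * n_out, -lim, lim), n_in, n_out),
       b = numeric(n_out))
}

# Recompute all spatial bookkeeping from the input shape and the layer
# channel counts (needed after pruning changes channel widths).
compile_geometry <- function(model) {
  H <- model$input_dim[1L]; W <- model$input_dim[2L]; C <- model$input_dim[3L]
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    if (ly$type == "conv") {
      stopifnot(ly$Cin == C)
      g <- conv_gather_index(H, W, C, ly$K)
      g$n_in_cols <- H * W * C
      ly$geom <- g
      H <- g$Hout; W <- g$Wout; C <- ly$Cout
    } else if (ly$type == "pool") {
      g <- pool_gather_index(H, W, C)
      ly$geom <- g
      H <- g$Hout; W <- g$Wout
    } else if (ly$type == "dense") {
      stopifnot(ly$n_in == H * W * C)
      H <- 1L; W <- 1L; C <- ly$n_out
    }
    model$layers[[i]] <- ly
  }
  model$output_dim <- C
  model
}

# ---- forward / backward ----------------------------------------------

# Forward pass. `training` switches dropout on (inverted dropout, masks
# cached for backward). Returns list(out = softmax B x 2, cache).
nn_forward <- function(model, X, training = FALSE) {
  B <- nrow(X)
  cache <- vector("list", length(model$layers))
  A <- X
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    if (ly$type == "conv") {
      g <- ly$geom
      M <- gather_runs(A, g$run_src, g$run_dst, g$run_len,
                       g$P * g$Kd)
      dim(M) <- c(B * g$P, g$Kd)
      Z <- M %*% ly$Wm
      Z <- Z + rep(ly$b, each = B * g$P)
      dim(Z) <- c(B, g$P * ly$Cout)
      Aout <- relu(Z)
      if (training) {                              # backward needs Z and M
        st <- list(Z = Z, M = M)
        if (ly$dropout > 0) {
          keep <- (runif(length(Aout)) >= ly$dropout) / (1 - ly$dropout)
          dim(keep) <- dim(Aout)
          Aout <- Aout * keep
          st$mask <- keep
        }
        cache[[i]] <- st
      }
      A <- Aout
    } else if (ly$type == "pool") {
      g <- ly$geom
      pf <- pool_forward(A, g$idx[[1L]],
                         g$idx[[2L]], g$valid[[2L]],
                         g$idx[[3L]], g$valid[[3L]],
                         g$idx[[4L]], g$valid[[4L]])
      if (training) cache[[i]] <- list(arg = pf$arg, in_cols = ncol(A))
      A <- pf$best
    } else if (ly$type == "dense") {
      Z <- A %*% ly$Wm
      Z <- Z + rep(ly$b, each = B)
      Aout <- if (ly$activation == "relu") relu(Z) else Z
      if (training) {
        st <- list(A_in = A, Z = Z)
        if (ly$dropout > 0 && ly$activation == "relu") {
          keep <- (runif(length(Aout)) >= ly$dropout) / (1 - ly$dropout)
          dim(keep) <- dim(Aout)
          Aout <- Aout * keep
          st$mask <- keep
        }
        cache[[i]] <- st
      }
      A <- Aout
    }
  }
  p <- softmax_rows(A)
  list(out = p, logits = A, cache = cache)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Backward pass from softmax cross-entropy. `labels` in {0,1}; class 2 of
# the softmax is foreground. Returns per-layer gradients.
nn_backward <- function(model, fwd, labels) {
  B <- nrow(fwd$out)
  onehot <- cbind(1 - labels, labels)
  dA <- (fwd$out - onehot) / B
  grads <- vector("list", length(model$layers))
  for (i in rev(seq_along(model$layers))) {
    ly <- model$layers[[i]]
    st <- fwd$cache[[i]]
    if (ly$type == "dense") {
      if (!is.null(st$mask)) dA <- dA * st$mask
      dZ <- if (ly$activation == "relu") dA * (st$Z > 0) else dA
      grads[[i]] <- list(dW = crossprod(st$A_in, dZ), db = colSums(dZ))
      dA <- tcrossprod(dZ, ly$Wm)
    } else if (ly$type == "pool") {
      g <- ly$geom
      dA <- pool_backward(dA, st$arg, g$idx[[1L]], g$idx[[2L]],
                          g$idx[[3L]], g$idx[[4L]], st$in_cols)
    } else if (ly$type == "conv") {
      g <- ly$geom
      if (!is.null(st$mask)) dA <- dA * st$mask
      dZ <- dA * (st$Z > 0)
      dim(dZ) <- c(B * g$P, ly$Cout)
      grads[[i]] <- list(dW = crossprod(st$M, dZ), db = colSums(dZ))
      if (i > 1L) {                                 # no input gradient needed
        dM <- tcrossprod(dZ, ly$Wm)                 # (B*P) x Kd
        dim(dM) <- c(B, g$P * g$Kd)
        dIn <- matrix(0, B, ly$geom$n_in_cols)
        scatter_add_cols(dIn, g$idxvec, dM)
        dA <- dIn
      }
    }
  }
  grads
}

# ---- optimiser --------------------------------------------------------

adam_init <- function(model) {
  lapply(model$layers, function(ly) {
    if (ly$type %in% c("conv", "dense"))
      list(mW = ly$Wm * 0, vW = ly$Wm * 0, mb = ly$b * 0, vb = ly$b * 0)
    else NULL
  })
}

adam_step <- function(model, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  for (i in seq_along(model$layers)) {
    if (is.null(grads[[i]])) next
    ly <- model$layers[[i]]; gr <- grads[[i]]; st <- state[[i]]
    st$mW <- beta1 * st$mW + (1 - beta1) * gr$dW
    st$vW <- beta2 * st$vW + (1 - beta2) * gr$dW^2
    st$mb <- beta1 * st$mb + (1 - beta1) * gr$db
    st$vb <- beta2 * st$vb + (1 - beta2) * gr$db^2
    ly$Wm <- ly$Wm - lr * (st$mW / bc1) / (sqrt(st$vW / bc2) + eps)
    ly$b <- ly$b - lr * (st$mb / bc1) / (sqrt(st$vb / bc2) + eps)
    model$layers[[i]] <- ly; state[[i]] <- st
  }
  list(model = model, state = state)
}

cross_entropy <- function(p, labels) {
  pf <- ifelse(labels == 1, p[, 2L], p[, 1L])
  -mean(log(pmax(pf, 1e-12)))
}
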