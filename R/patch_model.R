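#' Training configuration for the patch classifier
#'
#' @param seed RNG seed controlling initialization, the 70:30 split, batch
#'   order and dropout; two runs with the same seed give identical weights.
#' @param epochs maximum number of epochs (default 50; early stopping
#'   usually ends sooner).
#' @param patience early-stopping patience on validation loss (default 5).
#' @param lr Adam learning rate (default 1e-3).
#' @param batch_size mini-batch size (default 64).
#' @param val_fraction validation share of the 70:30 train/validation split
#'   (default 0.3).
#' @param verbose print per-epoch losses.
#' @return A list of class `train_config`.
#' @export
train_config <- function(seed = 1L, epochs = 50L, patience = 5L, lr = 1e-3,
                         batch_size = 64L, val_fraction = 0.3,
                         verbose = FALSE) {
  if (val_fraction <= 0 || val_fraction >= 1)
    stop("`val_fraction` must be in (0, 1); the split fractions sum to 1")
  structure(list(seed = as.integer(seed), epochs = as.integer(epochs),
                 patience = as.integer(patience), lr = lr,
                 batch_size = as.integer(batch_size),
                 val_fraction = val_fraction, verbose = verbose),
            class = "train_config")
}

#' Build the ten-layer patch classifier
#'
#' The fixed architecture maps a 51 x 51 x 3 patch to a two-class softmax
#' over \{background, foreground\} for the patch's center pixel:
#' conv 25@4x4 (dropout 0.1) -> maxpool 2x2 -> conv 50@5x5 (0.2) ->
#' maxpool -> conv 80@6x6 (0.25) -> maxpool -> dense 1024 (0.5) ->
#' dense 1024 (0.5) -> softmax 2, all hidden activations ReLU, valid
#' convolutions, ceil-mode pooling (so the final 5 x 5 map pools to 3 x 3).
#' Weights are uniform Glorot-initialized from the current RNG state.
#'
#' @param seed optional seed for the weight initialization (leave `NULL` to
#'   draw from the ambient RNG stream, e.g. inside [build_ensemble()]).
#' @return An object of class `patch_model`.
#' @examples
#' m <- build_patch_model(seed = 1)
#' count_params(m)
#' @export
build_patch_model <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  layers <- list(
    layer_conv(3L, 25L, 4L, dropout = 0.1),
    layer_pool(),
    layer_conv(25L, 50L, 5L, dropout = 0.2),
    layer_pool(),
    layer_conv(50L, 80L, 6L, dropout = 0.25),
    layer_pool(),
    layer_dense(3L * 3L * 80L, 1024L, "relu", dropout = 0.5),
    layer_dense(1024L, 1024L, "relu", dropout = 0.5),
    layer_dense(1024L, 2L, "linear"))
  model <- structure(list(layers = layers, input_dim = c(51L, 51L, 3L),
                          patch_size = 51L, trained = FALSE,
                          pruned_fraction = 0, history = NULL),
                     class = "patch_model")
  compile_geometry(model)
}

#' Trainable-parameter count of a patch model
#'
#' @param model a [build_patch_model()] result.
#' @return Integer count over all weights and biases.
#' @export
count_params <- function(model) {
  sum(vapply(model$layers, function(ly) {
    if (ly$type %in% c("conv", "dense")) length(ly$Wm) + length(ly$b) else 0L
  }, numeric(1)))
}

#' @export
print.patch_model <- function(x, ...) {
  cat("patch classifier (51 x 51 x 3 -> 2-class softmax)\n")
  for (ly in x$layers) {
    desc <- switch(ly$type,
                   conv = sprintf("conv   %d@%dx%d (in %d, dropout %.2f)",
                                  ly$Cout, ly$K, ly$K, ly$Cin, ly$dropout),
                   pool = "maxpool 2x2 (ceil)",
                   dense = sprintf("dense  %d -> %d [%s]%s", ly$n_in,
                                   ly$n_out, ly$activation,
                                   if (ly$dropout > 0)
                                     sprintf(" (dropout %.2f)", ly$dropout)
                                   else ""))
    cat("  ", desc, "\n")
  }
  cat(sprintf("  parameters: %d; trained: %s; pruned fraction: %g\n",
              count_params(x), x$trained, x$pruned_fraction))
  invisible(x)
}

#' Patch dataset container
#'
#' @param patches numeric n x 51 x 51 x 3 array.
#' @param labels binary vector of center-pixel classes (1 = foreground).
#' @param source optional per-patch image label for balance bookkeeping.
#' @return An object of class `patch_dataset`.
#' @export
patch_dataset <- function(patches, labels, source = NULL) {
  if (length(dim(patches)) != 4L) stop("`patches` must be n x H x W x 3")
  n <- dim(patches)[1L]
  if (length(labels) != n) stop("one label per patch required")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary")
  structure(list(patches = patches, labels = as.numeric(labels),
                 source = source), class = "patch_dataset")
}

#' @export
print.patch_dataset <- function(x, ...) {
  cat(sprintf("patch dataset: %d patches (%d x %d), %.1f%% foreground\n",
              dim(x$patches)[1L], dim(x$patches)[2L], dim(x$patches)[3L],
              100 * mean(x$labels)))
  invisible(x)
}

# Flatten n x H x W x C patches to the engine's n x (H*W*C) layout.
patches_to_matrix <- function(patches) {
  d <- dim(patches)
  matrix(patches, d[1L], d[2L] * d[3L] * d[4L])
}

#' Extract labelled patches centered at given positions
#'
#' Valid-window extraction only: every requested center must admit a full
#' 51 x 51 window, so centers live in rows/cols 26 .. (H - 25).
#'
#' @param image numeric H x W x 3 array in \[0, 1\].
#' @param positions integer matrix with columns (row, col) of center pixels.
#' @param mask optional ground-truth mask supplying center-pixel labels.
#' @param patch_size window side (default 51, the model's input).
#' @return A [patch_dataset()] (labels all `0` when no mask is given).
#' @export
extract_patches <- function(image, positions, mask = NULL,
                            patch_size = 51L) {
  if (length(dim(image)) != 3L) stop("`image` must be H x W x 3")
  half <- (patch_size - 1L) %/% 2L
  H <- dim(image)[1L]; W <- dim(image)[2L]
  positions <- matrix(as.integer(positions), ncol = 2L)
  bad <- positions[, 1L] < half + 1L | positions[, 1L] > H - half |
    positions[, 2L] < half + 1L | positions[, 2L] > W - half
  if (any(bad)) {
    b <- positions[which(bad)[1L], ]
    stop(sprintf("position (%d, %d) is too close to the border for a %d-patch",
                 b[1L], b[2L], patch_size))
  }
  n <- nrow(positions)
  out <- array(0, c(n, patch_size, patch_size, 3L))
  for (i in seq_len(n)) {
    r <- positions[i, 1L]; cc <- positions[i, 2L]
    out[i, , , ] <- image[(r - half):(r + half), (cc - half):(cc + half), ]
  }
  labels <- if (is.null(mask)) numeric(n)
  else as_mask_values(mask)[positions]
  patch_dataset(out, labels)
}

#' Train a patch classifier
#'
#' Mini-batch Adam on the two-class softmax cross-entropy (the binary
#' cross-entropy of the foreground probability), with a seeded 70:30
#' train/validation split and early stopping on validation loss. Fully
#' deterministic given `cfg$seed`.
#'
#' @param model a [build_patch_model()] (possibly pruned or pretrained).
#' @param data a [patch_dataset()] containing both classes.
#' @param cfg a [train_config()].
#' @return The trained `patch_model`, with `$history` holding per-epoch
#'   train/validation losses and validation accuracy.
#' @export
train_patch_model <- function(model, data, cfg = train_config()) {
  stopifnot(inherits(model, "patch_model"), inherits(data, "patch_dataset"))
  X <- patches_to_matrix(data$patches)
  y <- data$labels
  n <- nrow(X)
  if (n < 2L) stop("dataset too small to split")
  set.seed(cfg$seed)
  ord <- sample.int(n)
  n_val <- max(1L, floor(cfg$val_fraction * n))
  val_idx <- ord[seq_len(n_val)]
  tr_idx <- ord[-seq_len(n_val)]
  if (length(unique(y[tr_idx])) < 2L)
    stop("training split contains a single class; supply both classes")
  Xtr <- X[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
  Xval <- X[val_idx, , drop = FALSE]; yval <- y[val_idx]

  state <- adam_init(model)
  best_val <- Inf; best_model <- model; wait <- 0L; t_step <- 0L
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric(), val_acc = numeric())
  for (epoch in seq_len(cfg$epochs)) {
    idx <- sample.int(length(ytr))
    ep_loss <- 0; n_batches <- 0L
    for (start in seq(1L, length(ytr), by = cfg$batch_size)) {
      take <- idx[start:min(start + cfg$batch_size - 1L, length(ytr))]
      fwd <- nn_forward(model, Xtr[take, , drop = FALSE], training = TRUE)
      ep_loss <- ep_loss + cross_entropy(fwd$out, ytr[take])
      n_batches <- n_batches + 1L
      grads <- nn_backward(model, fwd, ytr[take])
      t_step <- t_step + 1L
      upd <- adam_step(model, grads, state, cfg$lr, t_step)
      model <- upd$model; state <- upd$state
    }
    # batched so the validation forward never dominates peak memory
    val_fg <- numeric(length(yval))
    for (start in seq(1L, length(yval), by = cfg$batch_size)) {
      take <- start:min(start + cfg$batch_size - 1L, length(yval))
      val_fg[take] <-
        nn_forward(model, Xval[take, , drop = FALSE])$out[, 2L]
    }
    val_p <- cbind(1 - val_fg, val_fg)
    val_loss <- cross_entropy(val_p, yval)
    val_acc <- mean((val_fg > 0.5) == (yval == 1))
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = ep_loss / n_batches,
                                         val_loss = val_loss,
                                         val_acc = val_acc))
    if (cfg$verbose)
      message(sprintf("epoch %d: train %.4f val %.4f acc %.4f", epoch,
                      ep_loss / n_batches, val_loss, val_acc))
    if (val_loss < best_val - 1e-6) {
      best_val <- val_loss; best_model <- model; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  best_model$trained <- TRUE
  best_model$history <- history
  best_model
}

#' Foreground probabilities for a batch of patches
#'
#' @param model a trained `patch_model`.
#' @param patches n x 51 x 51 x 3 array or a [patch_dataset()].
#' @param batch_size forward-pass batch size.
#' @return Numeric vector of foreground CMPs in \[0, 1\].
#' @export
predict_patch_prob <- function(model, patches, batch_size = 64L) {
  if (inherits(patches, "patch_dataset")) patches <- patches$patches
  X <- patches_to_matrix(patches)
  n <- nrow(X)
  out <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    take <- start:min(start + batch_size - 1L, n)
    out[take] <- nn_forward(model, X[take, , drop = FALSE])$out[, 2L]
  }
  out
}

#' Dense CMP prediction over an image on a stride grid
#'
#' Evaluates the classifier at every stride-subsampled valid patch center
#' (rows and cols 26 .. dim - 25 in steps of `stride`) and returns the
#' foreground-probability map on that grid, with the grid geometry attached
#' as attributes `grid_rows` / `grid_cols`.
#'
#' @param model a trained `patch_model`.
#' @param image H x W x 3 array; both dims must be at least the patch size.
#' @param stride grid step in pixels, >= 1 (default 4).
#' @param batch_size forward-pass batch size.
#' @return A [probability_map()] of size `length(grid_rows) x
#'   length(grid_cols)`.
#' @export
predict_cmp <- function(model, image, stride = 4L, batch_size = 64L) {
  stopifnot(stride >= 1L)
  H <- dim(image)[1L]; W <- dim(image)[2L]
  ps <- model$patch_size; half <- (ps - 1L) %/% 2L
  if (H < ps || W < ps) stop("image smaller than the patch size")
  rows <- seq(half + 1L, H - half, by = stride)
  cols <- seq(half + 1L, W - half, by = stride)
  grid <- cbind(rep(rows, times = length(cols)),
                rep(cols, each = length(rows)))
  probs <- numeric(nrow(grid))
  for (start in seq(1L, nrow(grid), by = batch_size)) {
    take <- start:min(start + batch_size - 1L, nrow(grid))
    ds <- extract_patches(image, grid[take, , drop = FALSE],
                          patch_size = ps)
    probs[take] <- predict_patch_prob(model, ds, batch_size = batch_size)
  }
  pm <- probability_map(matrix(probs, length(rows), length(cols)), "member")
  attr(pm, "grid_rows") <- rows
  attr(pm, "grid_cols") <- cols
  pm
}

#' Subsample a mask onto a prediction grid
#'
#' @param mask a [binary_mask()] or binary matrix at full image resolution.
#' @param map a [predict_cmp()] output carrying `grid_rows` / `grid_cols`.
#' @return A [binary_mask()] on the prediction grid.
#' @export
mask_on_grid <- function(mask, map) {
  rows <- attr(map, "grid_rows"); cols <- attr(map, "grid_cols")
  if (is.null(rows)) stop("`map` carries no prediction-grid geometry")
  binary_mask(as_mask_values(mask)[rows, cols, drop = FALSE])
}

# ---- L1 pruning -------------------------------------------------------

#' L1 norms of the filters of a convolutional layer
#'
#' One norm per output filter: the sum of absolute kernel weights, the
#' importance score used to rank filters for pruning (biases excluded).
#'
#' @param layer an element of `model$layers` with `type == "conv"`.
#' @return Numeric vector of length `Cout`, all non-negative.
#' @export
l1_filter_norms <- function(layer) {
  if (!identical(layer$type, "conv")) stop("not a convolutional layer")
  colSums(abs(layer$Wm))
}

round_half_up <- function(x) floor(x + 0.5)

#' Prune a patch model's convolutional filters by L1 norm
#'
#' In every convolutional layer, the `round(f * N)` filters (half-up, at
#' least one filter always retained) with the smallest L1 norms are deleted
#' — ties broken toward the lower filter index — together with the matching
#' input channels of the next convolutional layer. Pruning the last
#' convolutional layer also drops the flattened features feeding the first
#' dense layer; features are channel-major (channel slowest), so channel c
#' owns the contiguous feature block `(c-1)*9 + 1:9` of the 3 x 3 x 80 map.
#' `fraction = 0` is a bit-exact identity.
#'
#' @param model a `patch_model`.
#' @param fraction pruning fraction f in \[0, 1) applied to every conv layer.
#' @return The pruned, recompiled `patch_model` (with `pruned_fraction`
#'   recorded).
#' @export
prune_l1 <- function(model, fraction) {
  if (!is.numeric(fraction) || fraction < 0 || fraction >= 1)
    stop("`fraction` must lie in [0, 1)")
  if (fraction == 0) return(model)
  conv_pos <- which(vapply(model$layers, function(l) l$type == "conv",
                           logical(1)))
  dense_pos <- which(vapply(model$layers, function(l) l$type == "dense",
                            logical(1)))
  for (ci in seq_along(conv_pos)) {
    i <- conv_pos[ci]
    ly <- model$layers[[i]]
    norms <- l1_filter_norms(ly)
    n_remove <- min(round_half_up(fraction * ly$Cout), ly$Cout - 1L)
    if (n_remove < 1L) next
    # ascending by norm, lower index first among ties; drop the head
    drop_idx <- order(norms, seq_along(norms))[seq_len(n_remove)]
    keep <- sort(setdiff(seq_len(ly$Cout), drop_idx))
    ly$Wm <- ly$Wm[, keep, drop = FALSE]
    ly$b <- ly$b[keep]
    ly$Cout <- length(keep)
    model$layers[[i]] <- ly

    if (ci < length(conv_pos)) {
      # next conv consumes Cin channels; its Wm rows are (offset fast,
      # input channel slow): channel c owns rows (c-1)*K^2 + 1:K^2
      j <- conv_pos[ci + 1L]
      nx <- model$layers[[j]]
      K2 <- nx$K * nx$K
      rows <- as.vector(outer(seq_len(K2), (keep - 1L) * K2, `+`))
      nx$Wm <- nx$Wm[rows, , drop = FALSE]
      nx$Cin <- length(keep)
      model$layers[[j]] <- nx
    } else {
      # last conv feeds (pool ->) flatten -> first dense; the pooled map is
      # P spatial positions x C channels, channel-major
      j <- dense_pos[1L]
      nx <- model$layers[[j]]
      P <- nx$n_in %/% (length(keep) + n_remove)
      rows <- as.vector(outer(seq_len(P), (keep - 1L) * P, `+`))
      nx$Wm <- nx$Wm[rows, , drop = FALSE]
      nx$n_in <- length(rows)
      model$layers[[j]] <- nx
    }
  }
  model$pruned_fraction <- fraction
  compile_geometry(model)
}
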