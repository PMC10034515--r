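test_that("architecture, shapes and parameter count are as designed", {
  m <- build_patch_model(seed = 1)
  types <- vapply(m$layers, `[[`, "", "type")
  expect_equal(types, c("conv", "pool", "conv", "pool", "conv", "pool",
                        "dense", "dense", "dense"))
  expect_equal(vapply(m$layers[types == "conv"], `[[`, 0L, "Cout"),
               c(25L, 50L, 80L))
  expect_equal(vapply(m$layers[types == "conv"], `[[`, 0L, "K"),
               c(4L, 5L, 6L))
  # ceil-mode pooling: 51 ->(c4) 48 ->(p) 24 ->(c5) 20 ->(p) 10 ->(c6) 5
  # ->(p, ceil) 3; first dense therefore sees 3*3*80 = 720 features
  expect_equal(m$layers[[7]]$n_in, 720L)
  # conv1 alone: 4*4*3*25 + 25 = 1225
  expect_equal(length(m$layers[[1]]$Wm) + length(m$layers[[1]]$b), 1225)
  expect_equal(count_params(m), 1966559)
  expect_identical(build_patch_model(seed = 1)$layers[[1]]$Wm,
                   m$layers[[1]]$Wm)       # seeded init is deterministic
})

test_that("forward pass is a valid softmax", {
  m <- build_patch_model(seed = 2)
  set.seed(3)
  X <- matrix(runif(4 * 51 * 51 * 3), 4)
  p <- cmpens:::nn_forward(m, X)$out
  expect_equal(dim(p), c(4L, 2L))
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, 4))
})

test_that("patch extraction takes the exact window and labels by center", {
  set.seed(4)
  img <- array(runif(80 * 90 * 3), c(80, 90, 3))
  mask <- matrix(rbinom(80 * 90, 1, 0.5), 80, 90)
  pos <- rbind(c(26, 26), c(40, 55), c(55, 65))
  ds <- extract_patches(img, pos, mask)
  expect_equal(dim(ds$patches), c(3, 51, 51, 3))
  expect_equal(ds$patches[2, , , ], img[15:65, 30:80, ])
  expect_equal(ds$labels, as.numeric(mask[pos]))
  expect_error(extract_patches(img, rbind(c(25, 26))), "\\(25, 26\\)")
  expect_error(extract_patches(img, rbind(c(26, 66))), "border")
})

test_that("training is deterministic given the seed and learns a signal", {
  # simple color-separable task: class 1 bright, class 0 dark patches
  set.seed(5)
  n <- 192
  labels <- rep(c(0, 1), n / 2)
  patches <- array(0, c(n, 51, 51, 3))
  for (i in seq_len(n))
    patches[i, , , ] <- runif(51 * 51 * 3, labels[i] * 0.5, labels[i] * 0.5 + 0.5)
  ds <- patch_dataset(patches, labels)
  cfg <- train_config(seed = 7, epochs = 3, batch_size = 32)
  m1 <- train_patch_model(build_patch_model(seed = 7), ds, cfg)
  m2 <- train_patch_model(build_patch_model(seed = 7), ds, cfg)
  expect_identical(m1$layers[[9]]$Wm, m2$layers[[9]]$Wm)
  expect_equal(nrow(m1$history), 3)
  expect_gt(tail(m1$history$val_acc, 1), 0.8)
  # prediction separates the classes
  p <- predict_patch_prob(m1, ds)
  expect_gt(mean(p[labels == 1]), mean(p[labels == 0]))
})

test_that("training rejects single-class splits", {
  patches <- array(runif(30 * 51 * 51 * 3), c(30, 51, 51, 3))
  ds <- patch_dataset(patches, rep(1, 30))
  expect_error(train_patch_model(build_patch_model(seed = 1), ds,
                                 train_config(seed = 1, epochs = 1)),
               "single class")
})

test_that("predict_cmp produces a stride grid of valid probabilities", {
  m <- build_patch_model(seed = 8)
  set.seed(8)
  img <- array(runif(90 * 82 * 3), c(90, 82, 3))
  pm <- predict_cmp(m, img, stride = 4)
  rows <- attr(pm, "grid_rows"); cols <- attr(pm, "grid_cols")
  expect_equal(rows, seq(26L, 90L - 25L, by = 4L))
  expect_equal(cols, seq(26L, 82L - 25L, by = 4L))
  expect_equal(dim(pm$values), c(length(rows), length(cols)))
  expect_true(all(pm$values >= 0 & pm$values <= 1))
  # grid truth has the same shape
  mask <- binary_mask(matrix(rbinom(90 * 82, 1, 0.3), 90, 82))
  expect_equal(dim(mask_on_grid(mask, pm)$values), dim(pm$values))
})

test_that("L1 pruning: f = 0 identity, counts, ranking, propagation", {
  m <- build_patch_model(seed = 9)
  expect_identical(prune_l1(m, 0), m)                 # bit-exact identity
  p1 <- prune_l1(m, 0.1)
  couts <- vapply(p1$layers[c(1, 3, 5)], `[[`, 0L, "Cout")
  expect_equal(couts, c(22L, 45L, 72L))               # round-half-up of 10%
  expect_equal(p1$layers[[7]]$n_in, 3L * 3L * 72L)    # dense features follow
  expect_lt(count_params(p1), count_params(m))
  # counts strictly decrease in f
  fr <- c(0.1, 0.3, 0.5, 0.8)
  np <- vapply(fr, function(f) count_params(prune_l1(m, f)), numeric(1))
  expect_true(all(diff(np) < 0))
  # smallest-L1 filters are the ones removed
  norms <- colSums(abs(m$layers[[1]]$Wm))
  kept <- which(rank(norms, ties.method = "first") > 3)
  expect_equal(p1$layers[[1]]$Wm, m$layers[[1]]$Wm[, kept])
  # pruned model still emits a valid softmax
  set.seed(9)
  X <- matrix(runif(2 * 51 * 51 * 3), 2)
  out <- cmpens:::nn_forward(prune_l1(m, 0.8), X)$out
  expect_equal(rowSums(out), rep(1, 2))
  expect_error(prune_l1(m, 1.2), "fraction")
})

test_that("pruning keeps at least one filter per layer", {
  m <- build_patch_model(seed = 10)
  p <- prune_l1(m, 0.999)
  expect_true(all(vapply(p$layers[c(1, 3, 5)], `[[`, 0L, "Cout") >= 1L))
})
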