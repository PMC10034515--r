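test_that("scene configs validate the foreground-fraction regime", {
  expect_error(scene_config(fg_fraction = 0.6), "0, 0.5")
  expect_error(scene_config(fg_fraction = 0), "0, 0.5")
  expect_s3_class(scene_config(), "scene_config")
})

test_that("micrograph generation is deterministic and in range", {
  cfg <- scene_config(seed = 12)
  s1 <- generate_micrograph(cfg)
  s2 <- generate_micrograph(cfg)
  expect_identical(s1, s2)
  expect_equal(dim(s1$image), c(180, 180, 3))
  expect_true(min(s1$image) >= 0 && max(s1$image) <= 1)
  expect_s3_class(s1$mask, "binary_mask")
  s3 <- generate_micrograph(scene_config(seed = 13))
  expect_false(identical(s1$mask$values, s3$mask$values))
})

test_that("realized foreground stays sparse, near the target on average", {
  fr <- vapply(1:20, function(s) {
    mean(generate_micrograph(
      scene_config(height = 100L, width = 100L, n_cells = 12L,
                   fg_fraction = 0.15, seed = s))$mask$values)
  }, numeric(1))
  expect_true(all(fr > 0 & fr < 0.5))
  expect_lt(abs(mean(fr) - 0.15) / 0.15, 0.20)   # within 20% relative
})

test_that("cells are non-overlapping and inside the frame", {
  s <- generate_micrograph(scene_config(seed = 14))
  cells <- s$cells
  expect_gt(nrow(cells), 1)
  for (i in seq_len(nrow(cells) - 1)) {
    for (j in (i + 1):nrow(cells)) {
      d <- sqrt((cells$cy[i] - cells$cy[j])^2 + (cells$cx[i] - cells$cx[j])^2)
      expect_gt(d, max(cells$ry[i], cells$rx[i]) + max(cells$ry[j], cells$rx[j]))
    }
  }
  expect_true(all(cells$cy - cells$ry >= 0 & cells$cy + cells$ry <= 180))
  expect_true(all(cells$cx - cells$rx >= 0 & cells$cx + cells$rx <= 180))
})

test_that("infeasible packing requests fail loudly", {
  expect_error(
    generate_micrograph(scene_config(height = 60L, width = 60L,
                                     n_cells = 200L, fg_fraction = 0.49,
                                     radius_range = c(10, 14), seed = 1)),
    "infeasible packing")
})

test_that("CMP stacks track the scene with the configured noise", {
  sc <- tiny_scene(seed = 15)
  st <- generate_cmp_stack(sc, noise_config(n_members = 40, seed = 15))
  expect_s3_class(st, "cmp_stack")
  expect_equal(dim(st$values), c(120, 120, 40))
  p0 <- attr(st, "p0")
  expect_true(all(p0 >= 0 & p0 <= 1))
  # base map crosses 0.5 exactly at the mask support
  expect_gt(mean((p0 > 0.5) == (sc$mask$values == 1)), 0.97)
  # mean aggregation of many members recovers the truth almost everywhere
  acc <- accuracy(confusion_counts(binarize(aggregate_mean(st)), sc$mask))
  expect_gt(acc, 0.95)
  # clip bookkeeping exists and is a fraction
  cf <- attr(st, "clip_fraction")
  expect_true(all(cf >= 0 & cf <= 1))
  expect_identical(st$values,
                   generate_cmp_stack(sc, noise_config(n_members = 40,
                                                       seed = 15))$values)
})

test_that("noise families produce valid, distinct stacks", {
  sc <- tiny_scene(seed = 16, height = 80L, width = 80L, n_cells = 5L)
  gs <- generate_cmp_stack(sc, noise_config(10, family = "gaussian", seed = 2))
  sk <- generate_cmp_stack(sc, noise_config(10, family = "skewed", seed = 2))
  as <- generate_cmp_stack(sc, noise_config(10, family = "alpha_stable",
                                            alpha = 1.5, seed = 2))
  for (st in list(gs, sk, as))
    expect_true(min(st$values) >= 0 && max(st$values) <= 1)
  expect_false(identical(gs$values, sk$values))
  expect_false(identical(gs$values, as$values))
  # skew direction flips the sign of the noise skewness; sharpness 0 puts
  # the base probability at 0.5 everywhere, so small noise never clips
  flat <- tiny_scene(seed = 19, height = 60L, width = 60L, n_cells = 3L)
  skew_of <- function(dir) {
    st <- generate_cmp_stack(flat, noise_config(50, sharpness = 0,
                                                family = "skewed",
                                                skew_direction = dir,
                                                scale = 0.05, seed = 3))
    x <- st$values - mean(st$values)
    mean(x^3) / mean(x^2)^1.5
  }
  expect_gt(skew_of(1), 0.1)
  expect_lt(skew_of(-1), -0.1)
})

test_that("patch datasets balance labels and images deterministically", {
  s1 <- tiny_scene(seed = 17)
  s2 <- tiny_scene(seed = 18)
  ds <- make_patch_dataset(list(s1$image, s2$image), list(s1$mask, s2$mask),
                           200, balance = "fg_bg", seed = 4)
  expect_equal(dim(ds$patches)[1], 200)
  expect_equal(sum(ds$labels), 100)              # half foreground
  expect_equal(as.vector(table(ds$source)), c(100, 100))
  ds2 <- make_patch_dataset(list(s1$image, s2$image), list(s1$mask, s2$mask),
                            200, balance = "fg_bg", seed = 4)
  expect_identical(ds$patches, ds2$patches)
  # impossible quotas error with the availability in the message
  expect_error(make_patch_dataset(list(s1$image), list(s1$mask), 1e6,
                                  balance = "fg_bg", seed = 1), "available")
})
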