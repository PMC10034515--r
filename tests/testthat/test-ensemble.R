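test_that("training-size ladder evaluates the piecewise schedule", {
  expect_equal(training_size_ladder(1), 1000L)
  expect_equal(training_size_ladder(19), 10000L)
  expect_equal(training_size_ladder(20), 11000L)
  expect_equal(training_size_ladder(34), 25000L)
  expect_equal(training_size_ladder(35), 27000L)
  expect_equal(training_size_ladder(49), 55000L)
  expect_equal(training_size_ladder(50), 60000L)
  expect_equal(training_size_ladder(78), 200000L)
  expect_equal(training_size_ladder(79), 210000L)
  expect_equal(training_size_ladder(100), 420000L)
  full <- training_size_ladder(1:100)
  expect_true(all(diff(full) > 0))         # strictly increasing
  expect_error(training_size_ladder(0), "1..100")
  expect_error(training_size_ladder(101), "1..100")
})

test_that("pruning schedule spans 0.5%..50% in 100 distinct steps", {
  s <- pruning_schedule(1:100)
  expect_equal(s[1], 0.005)
  expect_equal(s[100], 0.5)
  expect_equal(length(unique(s)), 100)
  expect_equal(diff(s), rep(0.005, 99))
})

test_that("ensemble configs expose the eight canonical recipes", {
  rec <- ensemble_recipes()
  expect_length(rec, 8)
  expect_true(all(c("E(0.1%Np)", "E(10%Np,pru)", "E(Ntr)",
                    "E(Ntr,80%pru)") %in% rec))
  cfg <- ensemble_config("E(Ntr)", n_models = 4)
  expect_equal(cfg$strategy, "variable_ntrain")
  expect_error(ensemble_config("E(bogus)"), "unknown recipe")
})

test_that("member seeds follow the counter scheme", {
  rs <- ensemble_config(strategy = "random_seeds", base_seed = 7)
  expect_equal(cmpens:::member_seed(rs, 3), 7003L)
  sh <- ensemble_config(strategy = "pruning_schedule", base_seed = 7)
  expect_equal(cmpens:::member_seed(sh, 3), 7000L)  # shared seed
  expect_equal(cmpens:::member_seed(sh, 5), cmpens:::member_seed(sh, 1))
})

test_that("build_ensemble trains members with a faithful manifest", {
  sc <- tiny_scene(seed = 21)
  ds <- make_patch_dataset(list(sc$image), list(sc$mask), 160,
                           balance = "fg_bg", seed = 21)
  cfg <- ensemble_config(strategy = "random_seeds", n_models = 2,
                         n_train = 120L, base_seed = 5)
  ens <- build_ensemble(cfg, ds, train_config(epochs = 1, batch_size = 32))
  expect_s3_class(ens, "patch_ensemble")
  expect_length(ens$members, 2)
  expect_equal(ens$manifest$seed, c(5001, 5002))
  expect_equal(ens$manifest$n_train, c(120L, 120L))
  expect_equal(ens$manifest$pruning_fraction, c(0, 0))
  expect_true(all(ens$manifest$n_params == 1966559))
  # different seeds -> different trained weights
  expect_false(identical(ens$members[[1]]$layers[[9]]$Wm,
                         ens$members[[2]]$layers[[9]]$Wm))
})

test_that("pruned strategies record and apply their fractions", {
  sc <- tiny_scene(seed = 22)
  ds <- make_patch_dataset(list(sc$image), list(sc$mask), 120,
                           balance = "fg_bg", seed = 22)
  cfg <- ensemble_config(strategy = "pruning_schedule", n_models = 2,
                         n_train = NA_integer_, base_seed = 3)
  ens <- build_ensemble(cfg, ds, train_config(epochs = 1, batch_size = 32))
  expect_equal(ens$manifest$pruning_fraction, c(0.005, 0.01))
  expect_equal(ens$members[[2]]$pruned_fraction, 0.01)
  expect_lt(ens$manifest$n_params[2], 1966559)
})

test_that("variable-size strategies demand enough data", {
  sc <- tiny_scene(seed = 23)
  ds <- make_patch_dataset(list(sc$image), list(sc$mask), 100,
                           balance = "fg_bg", seed = 23)
  cfg <- ensemble_config("E(Ntr)", n_models = 2, base_seed = 1)
  expect_error(build_ensemble(cfg, ds, train_config(epochs = 1)),
               "insufficient data")
})

test_that("predict_ensemble_stack stacks member maps on one grid", {
  sc <- tiny_scene(seed = 24, height = 80L, width = 80L, n_cells = 5L)
  ds <- make_patch_dataset(list(sc$image), list(sc$mask), 120,
                           balance = "fg_bg", seed = 24)
  cfg <- ensemble_config(strategy = "random_seeds", n_models = 2,
                         n_train = NA_integer_, base_seed = 9)
  ens <- build_ensemble(cfg, ds, train_config(epochs = 1, batch_size = 32))
  st <- predict_ensemble_stack(ens, sc$image, stride = 6, image_id = "t")
  expect_s3_class(st, "cmp_stack")
  expect_equal(cmpens:::n_members(st), 2L)
  expect_equal(attr(st, "grid_rows"), seq(26L, 55L, by = 6L))
  # member k of the stack equals that member's own prediction
  pm2 <- predict_cmp(ens$members[[2]], sc$image, stride = 6)
  expect_equal(st$values[, , 2], pm2$values)
})

test_that("ensemble_size_sweep returns a well-formed saturation curve", {
  set.seed(31)
  truth <- matrix(rbinom(15 * 15, 1, 0.3), 15, 15)
  vals <- array(0, c(15, 15, 20))
  for (k in 1:20)
    vals[, , k] <- pmin(pmax(truth * 0.7 + 0.15 + rnorm(225, 0, 0.2), 0), 1)
  st <- cmp_stack(vals)
  sw <- ensemble_size_sweep(st, truth, sizes = c(1, 5, 20), repetitions = 5,
                            seed = 2)
  expect_named(sw, c("size", "mean_acc", "sd_acc"))
  expect_equal(sw$size, c(1L, 5L, 20L))
  expect_equal(sw$sd_acc[3], 0)            # only one 20-of-20 subset
  expect_true(all(sw$mean_acc >= 0 & sw$mean_acc <= 1))
  # more members should not hurt on this noisy stack
  expect_gte(sw$mean_acc[3], sw$mean_acc[1] - 0.02)
  expect_identical(sw, ensemble_size_sweep(st, truth, sizes = c(1, 5, 20),
                                           repetitions = 5, seed = 2))
  expect_error(ensemble_size_sweep(st, truth, sizes = 21), "1..20")
})
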