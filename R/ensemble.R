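#' Training-set size ladder for variable-size ensembles
#'
#' Piecewise schedule assigning member `n` of a 100-member ensemble its
#' training-set size: 1000 + (n-1)*500 for n in 1..19, 10000 + (n-19)*1000
#' for n in 20..34, 25000 + (n-34)*2000 for n in 35..49, 55000 + (n-49)*5000
#' for n in 50..78, and 200000 + (n-78)*10000 for n in 79..100, spanning
#' 1000 to 420000.
#'
#' @param n member index (vectorized), 1 <= n <= 100.
#' @return Integer sample counts.
#' @examples
#' training_size_ladder(c(1, 34, 35, 100))
#' @export
training_size_ladder <- function(n) {
  n <- as.integer(n)
  if (any(n < 1L | n > 100L)) stop("member index must lie in 1..100")
  out <- integer(length(n))
  seg1 <- n <= 19L
  seg2 <- n >= 20L & n <= 34L
  seg3 <- n >= 35L & n <= 49L
  seg4 <- n >= 50L & n <= 78L
  seg5 <- n >= 79L
  out[seg1] <- 1000L + (n[seg1] - 1L) * 500L
  out[seg2] <- 10000L + (n[seg2] - 19L) * 1000L
  out[seg3] <- 25000L + (n[seg3] - 34L) * 2000L
  out[seg4] <- 55000L + (n[seg4] - 49L) * 5000L
  out[seg5] <- 200000L + (n[seg5] - 78L) * 10000L
  out
}

#' Pruning-fraction schedule for pruned ensembles
#'
#' Member `n` of a pruned ensemble is pruned by `n * 0.5%`, giving 100
#' distinct fractions from 0.5% to 50% (no unpruned member).
#'
#' @param n member index (vectorized), 1 <= n <= 100.
#' @return Fractions in (0, 0.5\].
#' @examples
#' pruning_schedule(c(1, 100))
#' @export
pruning_schedule <- function(n) {
  n <- as.integer(n)
  if (any(n < 1L | n > 100L)) stop("member index must lie in 1..100")
  0.005 * n
}

# The eight canonical ensemble recipes. N_p here is the nominal parameter
# count the published training-size fractions refer to (0.1% -> 916 etc.).
.recipes <- list(
  "E(0.1%Np)"        = list(strategy = "random_seeds", n_train = 916L,
                            pruning = "none"),
  "E(1%Np)"          = list(strategy = "random_seeds", n_train = 9159L,
                            pruning = "none"),
  "E(10%Np)"         = list(strategy = "random_seeds", n_train = 91593L,
                            pruning = "none"),
  "E(0.1%Np,pru)"    = list(strategy = "pruning_schedule", n_train = 916L,
                            pruning = "schedule"),
  "E(1%Np,pru)"      = list(strategy = "pruning_schedule", n_train = 9159L,
                            pruning = "schedule"),
  "E(10%Np,pru)"     = list(strategy = "pruning_schedule", n_train = 91593L,
                            pruning = "schedule"),
  "E(Ntr)"           = list(strategy = "variable_ntrain", n_train = NA_integer_,
                            pruning = "none"),
  "E(Ntr,80%pru)"    = list(strategy = "variable_ntrain_pruned",
                            n_train = NA_integer_, pruning = "fixed_0.8"))

#' Names of the eight canonical ensemble recipes
#'
#' @return Character vector of recipe names accepted by [ensemble_config()].
#' @export
ensemble_recipes <- function() names(.recipes)

#' Configuration for one ensemble
#'
#' Either start from a canonical `recipe` (see [ensemble_recipes()]) or give
#' the pieces directly. Strategies: `random_seeds` (each member gets its own
#' seed, identical data), `pruning_schedule` (one shared seed, member `n`
#' pruned by [pruning_schedule()] before training), `variable_ntrain`
#' (shared seed, member `n` trained on [training_size_ladder()] samples),
#' `variable_ntrain_pruned` (the same plus a fixed 80% pruning).
#'
#' Desk-scale work overrides `n_models` and `n_train`; the recipe's
#' canonical values stay recorded in the manifest.
#'
#' @param recipe canonical recipe name, or `NULL` to configure manually.
#' @param n_models number of members (canonical 100; desk-scale default 8).
#' @param strategy one of the four strategies above (filled from `recipe`).
#' @param n_train training-set size per member (ignored by the
#'   variable-size strategies); `NA` means "use the whole supplied dataset".
#' @param base_seed seed from which member seeds derive (counter scheme:
#'   member k uses `base_seed * 1000 + k` for `random_seeds`, the shared
#'   `base_seed * 1000` otherwise).
#' @param pretrained optional pretrained `patch_model` used as the shared
#'   starting point for the pruned / variable strategies.
#' @return A list of class `ensemble_config`.
#' @export
ensemble_config <- function(recipe = NULL, n_models = 8L, strategy = NULL,
                            n_train = NA_integer_, base_seed = 1L,
                            pretrained = NULL) {
  if (!is.null(recipe)) {
    if (!recipe %in% names(.recipes))
      stop("unknown recipe '", recipe, "'; see ensemble_recipes()")
    rc <- .recipes[[recipe]]
    if (is.null(strategy)) strategy <- rc$strategy
    canonical_n_train <- rc$n_train
  } else {
    canonical_n_train <- n_train
  }
  strategy <- match.arg(strategy, c("random_seeds", "pruning_schedule",
                                    "variable_ntrain",
                                    "variable_ntrain_pruned"))
  structure(list(recipe = recipe %||% "custom", n_models = as.integer(n_models),
                 strategy = strategy, n_train = as.integer(n_train),
                 canonical_n_train = canonical_n_train,
                 base_seed = as.integer(base_seed), pretrained = pretrained),
            class = "ensemble_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ensemble_config <- function(x, ...) {
  cat(sprintf("ensemble config '%s': %d members, strategy %s, n_train %s, base seed %d\n",
              x$recipe, x$n_models, x$strategy,
              ifelse(is.na(x$n_train), "all", x$n_train), x$base_seed))
  invisible(x)
}

member_seed <- function(cfg, k) {
  if (cfg$strategy == "random_seeds") cfg$base_seed * 1000L + k
  else cfg$base_seed * 1000L
}

#' Build (train) an ensemble of patch classifiers
#'
#' Trains `cfg$n_models` members according to the configured strategy and
#' returns them with a provenance manifest (seed, pruning fraction and
#' training size per member), enough to re-train any single member in
#' isolation.
#'
#' @param cfg an [ensemble_config()].
#' @param data a [patch_dataset()]; must hold at least the largest requested
#'   per-member training size.
#' @param train_cfg a [train_config()] template; its seed is replaced by the
#'   per-member seed.
#' @param verbose report per-member progress.
#' @return An object of class `patch_ensemble`: list with `members` (trained
#'   models), `manifest` (data.frame) and `cfg`.
#' @export
build_ensemble <- function(cfg, data, train_cfg = train_config(),
                           verbose = FALSE) {
  stopifnot(inherits(cfg, "ensemble_config"), inherits(data, "patch_dataset"))
  n_avail <- dim(data$patches)[1L]
  sizes <- switch(cfg$strategy,
    random_seeds = ,
    pruning_schedule = rep(if (is.na(cfg$n_train)) n_avail else cfg$n_train,
                           cfg$n_models),
    variable_ntrain = ,
    variable_ntrain_pruned = training_size_ladder(seq_len(cfg$n_models)))
  if (max(sizes) > n_avail)
    stop(sprintf("insufficient data: largest member needs %d patches, %d available",
                 max(sizes), n_avail))
  fractions <- switch(cfg$strategy,
    random_seeds = rep(0, cfg$n_models),
    pruning_schedule = pruning_schedule(seq_len(cfg$n_models)),
    variable_ntrain = rep(0, cfg$n_models),
    variable_ntrain_pruned = rep(0.8, cfg$n_models))

  members <- vector("list", cfg$n_models)
  for (k in seq_len(cfg$n_models)) {
    seed_k <- member_seed(cfg, k)
    base <- if (!is.null(cfg$pretrained)) cfg$pretrained
    else build_patch_model(seed = seed_k)
    if (fractions[k] > 0) base <- prune_l1(base, fractions[k])
    sub <- if (sizes[k] < n_avail) {
      idx <- with_preserved_rng(seed_k, sample.int(n_avail, sizes[k]))
      patch_dataset(data$patches[idx, , , , drop = FALSE], data$labels[idx])
    } else data
    tc <- train_cfg
    tc$seed <- seed_k
    members[[k]] <- train_patch_model(base, sub, tc)
    gc(FALSE)              # release training transients before the next member
    if (verbose)
      message(sprintf("member %d/%d trained (seed %d, n=%d, pruned %.1f%%)",
                      k, cfg$n_models, seed_k, sizes[k], 100 * fractions[k]))
  }
  manifest <- data.frame(member = seq_len(cfg$n_models),
                         seed = vapply(seq_len(cfg$n_models),
                                       function(k) member_seed(cfg, k),
                                       numeric(1)),
                         n_train = sizes, pruning_fraction = fractions,
                         n_params = vapply(members, count_params, numeric(1)))
  structure(list(members = members, manifest = manifest, cfg = cfg),
            class = "patch_ensemble")
}

#' @export
print.patch_ensemble <- function(x, ...) {
  cat(sprintf("patch ensemble '%s': %d trained members\n",
              x$cfg$recipe, length(x$members)))
  print(x$manifest, row.names = FALSE)
  invisible(x)
}

#' Predict a CMP stack from an ensemble
#'
#' Runs [predict_cmp()] for every member over one image and stacks the
#' per-member probability maps into a [cmp_stack()] on the shared stride
#' grid.
#'
#' @param ensemble a [build_ensemble()] result.
#' @param image H x W x 3 array.
#' @param stride prediction-grid step (default 4).
#' @param image_id label for the stack.
#' @return A `cmp_stack` carrying the grid geometry as attributes.
#' @export
predict_ensemble_stack <- function(ensemble, image, stride = 4L,
                                   image_id = "image") {
  maps <- lapply(ensemble$members, predict_cmp, image = image,
                 stride = stride)
  vals <- vapply(maps, function(m) m$values,
                 matrix(0, nrow(maps[[1L]]$values), ncol(maps[[1L]]$values)))
  st <- cmp_stack(vals, image_id = image_id)
  attr(st, "grid_rows") <- attr(maps[[1L]], "grid_rows")
  attr(st, "grid_cols") <- attr(maps[[1L]], "grid_cols")
  st
}

#' Ensemble-size saturation sweep
#'
#' For each requested subset size k, draws `repetitions` seeded random
#' subsets of k members from a CMP stack, aggregates each subset by
#' `method`, and scores accuracy against the truth: the curve that shows
#' where adding members stops helping.
#'
#' @param stack a [cmp_stack()].
#' @param truth ground-truth mask on the same grid.
#' @param sizes integer vector of subset sizes, each <= M.
#' @param method aggregation method (see [aggregate_cmp()]).
#' @param repetitions subsets per size (default 10; the size-M entry is
#'   computed once since only one subset exists).
#' @param seed RNG seed for the subset draws.
#' @param threshold binarization threshold.
#' @return data.frame with columns `size`, `mean_acc`, `sd_acc`.
#' @export
ensemble_size_sweep <- function(stack, truth, sizes, method = "mean",
                                repetitions = 10L, seed = 1L,
                                threshold = 0.5) {
  assert_stack(stack)
  M <- n_members(stack)
  sizes <- as.integer(sizes)
  if (any(sizes < 1L | sizes > M))
    stop("every subset size must lie in 1..", M)
  if (repetitions < 1L) stop("`repetitions` must be >= 1")
  tr <- as_mask_values(truth)
  set.seed(seed)
  rows <- lapply(sizes, function(k) {
    reps <- if (k == M) 1L else repetitions
    accs <- vapply(seq_len(reps), function(r) {
      sub <- stack[sort(sample.int(M, k))]
      pred <- aggregate_cmp(sub, method, threshold = threshold)
      accuracy(confusion_counts(pred, tr))
    }, numeric(1))
    data.frame(size = k, mean_acc = mean(accs),
               sd_acc = if (reps == 1L) 0 else sd(accs))
  })
  do.call(rbind, rows)
}
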