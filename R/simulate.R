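#' Scene configuration for synthetic micrographs
#'
#' Describes an H&E-like tile: compact dark-purple elliptical "nuclei"
#' sparse on a pinkish textured background, so the ground truth keeps the
#' `|TP| << |TN|` regime of real cell micrographs (foreground fraction is
#' required to stay below 0.5 and defaults to 0.15).
#'
#' @param height,width image size in pixels (default 180 x 180).
#' @param n_cells number of nuclei to place (default 24).
#' @param radius_range min/max semi-axis length in pixels (default c(6, 13)).
#' @param fg_fraction target foreground fraction in (0, 0.5); cells are
#'   placed until the target is reached or `n_cells` is exhausted.
#' @param texture_amplitude sd of the background intensity texture
#'   (default 0.04).
#' @param cell_color,background_color RGB means of nuclei (purple) and
#'   background (pink).
#' @param seed RNG seed; the same seed gives a bit-identical scene.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(height = 180L, width = 180L, n_cells = 24L,
                         radius_range = c(6, 13), fg_fraction = 0.15,
                         texture_amplitude = 0.04,
                         cell_color = c(0.45, 0.25, 0.55),
                         background_color = c(0.92, 0.75, 0.82),
                         seed = 1L) {
  if (fg_fraction <= 0 || fg_fraction >= 0.5)
    stop("`fg_fraction` must lie in (0, 0.5): cells are sparse on background")
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_cells = as.integer(n_cells),
                 radius_range = radius_range, fg_fraction = fg_fraction,
                 texture_amplitude = texture_amplitude,
                 cell_color = cell_color, background_color = background_color,
                 seed = as.integer(seed)),
            class = "scene_config")
}

#' Noise configuration for synthetic CMP stacks
#'
#' Describes how M ensemble members scatter around the base probability of
#' each pixel: the base map is a sigmoid of the (normalized, elliptical)
#' distance to the nearest cell boundary, so interior pixels sit near 1,
#' background near 0 and a soft band near 0.5 hugs every boundary; members
#' add iid noise from one of three families and clip to \[0, 1\].
#'
#' @param n_members ensemble size M (default 100).
#' @param sharpness sigmoid steepness in 1/pixels of boundary distance
#'   (default 1; larger = thinner 0.5-band).
#' @param family noise family: `"gaussian"`, `"skewed"` (shifted, scaled
#'   Beta — bounded, sign-controllable skew, mimicking the right-skewed
#'   narrow member histograms of well-trained ensembles), or
#'   `"alpha_stable"`.
#' @param scale noise scale (sd-like; default 0.08).
#' @param skew_direction +1 for right skew, -1 for left (skewed family).
#' @param alpha,beta alpha-stable family parameters (default 1.6, 0).
#' @param seed RNG seed.
#' @return A list of class `noise_config`.
#' @export
noise_config <- function(n_members = 100L, sharpness = 1, family = "gaussian",
                         scale = 0.08, skew_direction = 1,
                         alpha = 1.6, beta = 0, seed = 1L) {
  family <- match.arg(family, c("gaussian", "skewed", "alpha_stable"))
  if (n_members < 1L) stop("need at least one member")
  structure(list(n_members = as.integer(n_members), sharpness = sharpness,
                 family = family, scale = scale,
                 skew_direction = sign(skew_direction),
                 alpha = alpha, beta = beta, seed = as.integer(seed)),
            class = "noise_config")
}

#' Generate a synthetic micrograph and its ground-truth mask
#'
#' Places non-overlapping axis-aligned ellipses ("nuclei") by rejection
#' sampling until the configured foreground fraction or cell count is
#' reached, colors them with the nucleus mean plus texture, and returns the
#' image with a mask that exactly matches the ellipse support. Deterministic
#' given `cfg$seed`.
#'
#' @param cfg a [scene_config()].
#' @return List with `image` (H x W x 3 in \[0, 1\]), `mask` (a
#'   [binary_mask()]) and `cells` (data.frame of centers/axes, used by
#'   [generate_cmp_stack()] for the boundary-distance field).
#' @export
generate_micrograph <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  set.seed(cfg$seed)
  H <- cfg$height; W <- cfg$width
  mask <- matrix(0, H, W)
  rows <- matrix(rep(seq_len(H), W), H, W)
  cols <- matrix(rep(seq_len(W), each = H), H, W)
  cells <- data.frame(cy = numeric(0), cx = numeric(0),
                      ry = numeric(0), rx = numeric(0))
  target_px <- cfg$fg_fraction * H * W
  attempts <- 0L; max_attempts <- 60L * max(cfg$n_cells, 1L)
  while (nrow(cells) < cfg$n_cells && sum(mask) < target_px) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("infeasible packing: could not place the requested cells; ",
           "reduce `n_cells` or the radius range")
    ry <- runif(1, cfg$radius_range[1L], cfg$radius_range[2L])
    rx <- runif(1, cfg$radius_range[1L], cfg$radius_range[2L])
    cy <- runif(1, ry + 1, H - ry)
    cx <- runif(1, rx + 1, W - rx)
    # non-overlap (with a 2-px moat) against accepted cells
    if (nrow(cells) > 0) {
      d <- sqrt((cells$cy - cy)^2 + (cells$cx - cx)^2)
      if (any(d < (pmax(cells$ry, cells$rx) + max(ry, rx) + 2))) next
    }
    inside <- ((rows - cy) / ry)^2 + ((cols - cx) / rx)^2 <= 1
    mask[inside] <- 1
    cells <- rbind(cells, data.frame(cy = cy, cx = cx, ry = ry, rx = rx))
  }
  img <- array(0, c(H, W, 3L))
  for (ch in 1:3) {
    base <- ifelse(mask == 1, cfg$cell_color[ch], cfg$background_color[ch])
    img[, , ch] <- pmin(pmax(base +
      matrix(rnorm(H * W, 0, cfg$texture_amplitude), H, W), 0), 1)
  }
  list(image = img, mask = binary_mask(mask), cells = cells)
}

# Signed pseudo-distance (in pixels) to the nearest cell boundary, positive
# inside; from the known ellipse geometry: (1 - r_norm) * min semi-axis.
boundary_distance_field <- function(H, W, cells) {
  if (nrow(cells) == 0L) return(matrix(-Inf, H, W))
  rows <- matrix(rep(seq_len(H), W), H, W)
  cols <- matrix(rep(seq_len(W), each = H), H, W)
  best <- matrix(-Inf, H, W)
  for (i in seq_len(nrow(cells))) {
    rn <- sqrt(((rows - cells$cy[i]) / cells$ry[i])^2 +
                 ((cols - cells$cx[i]) / cells$rx[i])^2)
    d <- (1 - rn) * min(cells$ry[i], cells$rx[i])
    best <- pmax(best, d)
  }
  best
}

#' Generate a synthetic CMP stack over a scene
#'
#' Builds the base-probability map `p0 = plogis(sharpness * signed
#' boundary distance)` — high inside cells, low outside, crossing 0.5 at
#' every cell boundary — and stacks M member maps `clip(p0 + noise)`.
#' The fraction of clipped values per pixel is recorded in the attribute
#' `clip_fraction` so distribution tests can exclude heavily clipped pixels.
#'
#' @param scene a [generate_micrograph()] result (or any list with `mask`
#'   and `cells`).
#' @param cfg a [noise_config()].
#' @return A [cmp_stack()]; the base map is attached as attribute `p0`.
#' @export
generate_cmp_stack <- function(scene, cfg) {
  stopifnot(inherits(cfg, "noise_config"))
  mask <- as_mask_values(scene$mask)
  H <- nrow(mask); W <- ncol(mask)
  p0 <- plogis(cfg$sharpness * boundary_distance_field(H, W, scene$cells))
  set.seed(cfg$seed)
  M <- cfg$n_members
  n <- H * W * M
  noise <- switch(cfg$family,
    gaussian = rnorm(n, 0, cfg$scale),
    skewed = {
      # Beta(2, 5): right-skewed on [0,1]; center and scale to sd `scale`
      b <- rbeta(n, 2, 5)
      cfg$skew_direction * (b - 2 / 7) * cfg$scale / sqrt(2 * 5 / (49 * 8))
    },
    alpha_stable = rstable(n, stable_params(cfg$alpha, cfg$beta,
                                            cfg$scale^cfg$alpha, 0)))
  raw <- rep(as.vector(p0), times = M) + noise
  clipped <- raw < 0 | raw > 1
  vals <- array(pmin(pmax(raw, 0), 1), c(H, W, M))
  st <- cmp_stack(vals, image_id = "synthetic")
  attr(st, "p0") <- p0
  attr(st, "clip_fraction") <- matrix(rowMeans(matrix(clipped, H * W, M)),
                                      H, W)
  st
}

#' Sample a labelled patch dataset from synthetic scenes
#'
#' Draws `n` patch centers without replacement from the valid-window
#' interiors of one or more images, optionally balancing across source
#' images and between foreground- and background-centered patches, and
#' extracts the 51 x 51 x 3 patches with center-pixel labels. Deterministic
#' given `seed`.
#'
#' @param images list of H x W x 3 arrays (or a single array).
#' @param masks list of matching ground-truth masks.
#' @param n total number of patches.
#' @param balance `"none"`, `"per_image"` (equal share from each image) or
#'   `"fg_bg"` (equal foreground/background labels, also spread over
#'   images).
#' @param seed RNG seed.
#' @param patch_size window side (default 51).
#' @return A [patch_dataset()].
#' @export
make_patch_dataset <- function(images, masks, n, balance = "fg_bg",
                               seed = 1L, patch_size = 51L) {
  balance <- match.arg(balance, c("none", "per_image", "fg_bg"))
  if (!is.list(images)) { images <- list(images); masks <- list(masks) }
  stopifnot(length(images) == length(masks))
  n_img <- length(images)
  half <- (patch_size - 1L) %/% 2L
  set.seed(seed)
  quota <- rep(n %/% n_img, n_img)
  extra <- n - sum(quota)
  if (extra > 0) quota[seq_len(extra)] <- quota[seq_len(extra)] + 1L
  parts <- vector("list", n_img)
  for (i in seq_len(n_img)) {
    H <- dim(images[[i]])[1L]; W <- dim(images[[i]])[2L]
    mv <- as_mask_values(masks[[i]])
    rs <- (half + 1L):(H - half); cs <- (half + 1L):(W - half)
    grid <- cbind(rep(rs, times = length(cs)), rep(cs, each = length(rs)))
    want <- if (balance == "none" && n_img == 1L) n else quota[i]
    if (balance == "fg_bg") {
      lab <- mv[grid]
      fg <- which(lab == 1); bg <- which(lab == 0)
      want_fg <- want %/% 2L; want_bg <- want - want_fg
      if (length(fg) < want_fg || length(bg) < want_bg)
        stop(sprintf("image %d: %d fg / %d bg centers available, need %d / %d",
                     i, length(fg), length(bg), want_fg, want_bg))
      take <- c(sample(fg, want_fg), sample(bg, want_bg))
    } else {
      if (nrow(grid) < want)
        stop(sprintf("image %d: only %d valid centers, need %d",
                     i, nrow(grid), want))
      take <- sample.int(nrow(grid), want)
    }
    parts[[i]] <- extract_patches(images[[i]], grid[take, , drop = FALSE],
                                  mask = mv, patch_size = patch_size)
    parts[[i]]$source <- rep(i, length(take))
  }
  patches <- do.call(abind4, lapply(parts, `[[`, "patches"))
  patch_dataset(patches, unlist(lapply(parts, `[[`, "labels")),
                source = unlist(lapply(parts, `[[`, "source")))
}

# Bind n x H x W x C arrays along the first axis (avoids an abind dep).
abind4 <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L) return(xs[[1L]])
  d <- dim(xs[[1L]])
  ns <- vapply(xs, function(x) dim(x)[1L], numeric(1))
  out <- array(0, c(sum(ns), d[2L], d[3L], d[4L]))
  at <- 0L
  for (x in xs) {
    out[at + seq_len(dim(x)[1L]), , , ] <- x
    at <- at + dim(x)[1L]
  }
  out
}
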