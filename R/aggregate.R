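#' Aggregate a CMP stack by the per-pixel mean
#'
#' The consensus probability at each pixel is the sample mean of the M member
#' probabilities, `(1/M) * sum(p_i)`.
#'
#' @param stack a [cmp_stack()].
#' @return A [probability_map()] with `method = "mean"`.
#' @export
aggregate_mean <- function(stack) {
  assert_stack(stack)
  d <- dim(stack$values)
  v <- matrix(rowMeans(matrix(stack$values, d[1L] * d[2L], d[3L])),
              d[1L], d[2L])
  probability_map(v, "mean")
}

#' Aggregate a CMP stack by the per-pixel median
#'
#' The consensus is the standard sample median of the M member probabilities
#' (for even M, the midpoint of the two central order statistics), which is
#' the robust choice for the right-skewed CMP histograms typical of
#' well-trained ensembles.
#'
#' @inheritParams aggregate_mean
#' @return A [probability_map()] with `method = "median"`.
#' @export
aggregate_median <- function(stack) {
  assert_stack(stack)
  d <- dim(stack$values)
  m <- matrix(stack$values, d[1L] * d[2L], d[3L])
  v <- matrix(rowMedians(m), d[1L], d[2L])
  probability_map(v, "median")
}

# Row-wise medians without a per-row apply(): sort each row via an
# order() on (row, value) and read off the central order statistics.
rowMedians <- function(m) {
  n <- ncol(m)
  if (n == 1L) return(m[, 1L])
  o <- order(row(m), m)                   # stable row-blocked sort
  s <- matrix(m[o], nrow(m), n, byrow = TRUE)
  if (n %% 2L == 1L) s[, (n + 1L) %/% 2L]
  else (s[, n %/% 2L] + s[, n %/% 2L + 1L]) / 2
}

#' Aggregate a CMP stack by per-pixel majority vote
#'
#' Each pixel is set to foreground (1) iff strictly more members report
#' `p_i > 0.5` than `p_i <= 0.5`; exact 50/50 splits vote background, and a
#' unanimous `p_i > 0.5` vote (which makes the ratio form of the rule
#' degenerate with a zero denominator) is foreground.
#'
#' @inheritParams aggregate_mean
#' @return A [binary_mask()] (no intermediate probability map exists for a
#'   vote), with `threshold_used = 0.5`.
#' @export
aggregate_majority <- function(stack) {
  assert_stack(stack)
  d <- dim(stack$values)
  above <- rowSums(matrix(stack$values > 0.5, d[1L] * d[2L], d[3L]))
  v <- matrix(as.numeric(above > d[3L] - above), d[1L], d[2L])
  binary_mask(v, threshold_used = 0.5)
}

#' Aggregate a CMP stack by the alpha-stable location parameter
#'
#' Fits a four-parameter Levy alpha-stable distribution to the M member
#' probabilities at every pixel and returns the location parameter mu as the
#' consensus probability, clipped to \[0, 1\] (CMPs are probabilities, so the
#' consensus must stay one). Pixels where the fit fails or is degenerate fall
#' back to the sample median, with one warning summarising how many did.
#'
#' This is by far the most expensive aggregation rule; for large maps,
#' prefer it on stride-subsampled prediction grids.
#'
#' @inheritParams aggregate_mean
#' @param min_members minimum M required to attempt a four-parameter fit;
#'   below it the rule falls back to the median everywhere (default 20).
#' @param control optional list passed to [fit_stable()] (`n_omega`, etc.).
#' @return A [probability_map()] with `method = "alpha"`.
#' @export
aggregate_alpha_location <- function(stack, min_members = 20L,
                                     control = list()) {
  assert_stack(stack)
  d <- dim(stack$values)
  m <- matrix(stack$values, d[1L] * d[2L], d[3L])
  med <- rowMedians(m)
  if (d[3L] < min_members) {
    warning("fewer than `min_members` ensemble members; ",
            "alpha-stable aggregation fell back to the median everywhere")
    return(probability_map(matrix(med, d[1L], d[2L]), "alpha"))
  }
  out <- numeric(nrow(m))
  n_fallback <- 0L
  for (px in seq_len(nrow(m))) {
    x <- m[px, ]
    if (max(x) - min(x) <= .Machine$double.eps^0.5) {
      out[px] <- x[1L]                     # point mass: location is the value
      next
    }
    fit <- tryCatch(do.call(fit_stable, c(list(samples = x), control)),
                    error = function(e) NULL)
    if (is.null(fit)) {
      out[px] <- med[px]
      n_fallback <- n_fallback + 1L
    } else {
      out[px] <- min(max(coef(fit)[["mu"]], 0), 1)
    }
  }
  if (n_fallback > 0L)
    warning(sprintf("alpha-stable fit failed at %d pixel(s); %s",
                    n_fallback, "sample median used there"))
  probability_map(matrix(out, d[1L], d[2L]), "alpha")
}

#' Binarize a probability map at a threshold
#'
#' Pixels strictly above the threshold become foreground (1); pixels at or
#' below it become background (0), so a pixel at exactly 0.5 under the
#' default is background.
#'
#' @param map a [probability_map()] (or plain H x W matrix of probabilities).
#' @param threshold probability cut in (0, 1); default 0.5.
#' @return A [binary_mask()].
#' @export
binarize <- function(map, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stop("`threshold` must be a single probability in (0, 1)")
  v <- as_prob_values(map)
  binary_mask((v > threshold) * 1, threshold_used = threshold)
}

#' Aggregate and binarize a CMP stack by a named method
#'
#' Dispatcher over the four aggregation rules: `"mean"`, `"median"` and
#' `"alpha"` produce a probability map that is then binarized at `threshold`;
#' `"majority"` votes directly into a binary mask (its threshold is the vote
#' rule itself).
#'
#' @inheritParams aggregate_mean
#' @param method one of `"mean"`, `"median"`, `"majority"`, `"alpha"`.
#' @param threshold binarization threshold for the probability-valued
#'   methods; default 0.5.
#' @param ... passed on to the per-method rule (e.g. `min_members` for
#'   `"alpha"`).
#' @return A [binary_mask()].
#' @export
aggregate_cmp <- function(stack, method = c("mean", "median", "majority",
                                            "alpha"),
                          threshold = 0.5, ...) {
  if (!is.character(method) || !method[1L] %in%
        c("mean", "median", "majority", "alpha"))
    stop("unknown method '", method[1L],
         "'; valid methods are: mean, median, majority, alpha")
  method <- method[1L]
  switch(method,
         mean = binarize(aggregate_mean(stack), threshold),
         median = binarize(aggregate_median(stack), threshold),
         alpha = binarize(aggregate_alpha_location(stack, ...), threshold),
         majority = aggregate_majority(stack))
}
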