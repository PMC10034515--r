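#' Confusion counts between a predicted and a true binary mask
#'
#' Positives are foreground ("cell") pixels. The four counts always conserve
#' pixels: `tp + tn + fp + fn` equals the number of evaluated pixels.
#'
#' @param pred predicted [binary_mask()] (or binary matrix).
#' @param truth ground-truth [binary_mask()] (or binary matrix) of the same
#'   shape.
#' @return An object of class `confusion_counts`: list with integer fields
#'   `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(pred, truth) {
  p <- as_mask_values(pred)
  t <- as_mask_values(truth)
  if (!identical(dim(p), dim(t)))
    stop("prediction and truth have different shapes")
  structure(list(tp = sum(p == 1 & t == 1),
                 tn = sum(p == 0 & t == 0),
                 fp = sum(p == 1 & t == 0),
                 fn = sum(p == 0 & t == 1)),
            class = "confusion_counts")
}

#' Assemble confusion counts from totals
#'
#' For scoring published contingency tables or pooling per-image counts.
#'
#' @param tp,tn,fp,fn non-negative counts.
#' @return A `confusion_counts` object.
#' @export
confusion_from_totals <- function(tp, tn, fp, fn) {
  v <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(v < 0) || any(!is.finite(v))) stop("counts must be non-negative")
  structure(as.list(v), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion counts: TP=%d TN=%d FP=%d FN=%d (N=%d)\n",
              as.integer(x$tp), as.integer(x$tn), as.integer(x$fp),
              as.integer(x$fn),
              as.integer(x$tp + x$tn + x$fp + x$fn)))
  invisible(x)
}

#' Pixel accuracy from confusion counts
#'
#' `ACC = (TP + TN) / (TP + FP + TN + FN)`.
#'
#' @param counts a [confusion_counts()].
#' @return Accuracy in \[0, 1\].
#' @export
accuracy <- function(counts) {
  total <- counts$tp + counts$tn + counts$fp + counts$fn
  if (total <= 0) stop("no evaluated pixels: accuracy undefined")
  (counts$tp + counts$tn) / total
}

#' Dice coefficient from confusion counts
#'
#' `DC = 2 TP / (2 TP + FP + FN)`; insensitive to true negatives, so it
#' weights foreground overlap in the `|TP| << |TN|` regime typical of sparse
#' cells on large background.
#'
#' @param counts a [confusion_counts()].
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(counts) {
  den <- 2 * counts$tp + counts$fp + counts$fn
  if (den <= 0) stop("Dice undefined: no foreground in prediction or truth")
  2 * counts$tp / den
}

#' Continuous Dice coefficient
#'
#' Probability-valued analogue of the Dice coefficient. The default
#' `"as_printed"` variant is the foreground-weighted form
#' `sum(a * b) / sum(a)` (for binary inputs this is recall); the
#' `"symmetric"` variant is the usual soft Dice
#' `2 sum(a * b) / (sum(a) + sum(b))`, which reduces to [dice()] for binary
#' inputs. Both are provided because published reports do not always say
#' which was used.
#'
#' @param truth ground-truth values in \[0, 1\] (matrix or mask).
#' @param pred predicted probabilities in \[0, 1\] (matrix or map).
#' @param variant `"as_printed"` (default) or `"symmetric"`.
#' @return Value in \[0, 1\].
#' @export
continuous_dice <- function(truth, pred,
                            variant = c("as_printed", "symmetric")) {
  variant <- match.arg(variant)
  a <- as_prob_values(truth)
  b <- as_prob_values(pred)
  if (!identical(dim(a), dim(b))) stop("shapes differ")
  sa <- sum(a)
  if (sa <= 0) stop("continuous Dice undefined: ground truth sums to zero")
  if (variant == "as_printed") sum(a * b) / sa
  else 2 * sum(a * b) / (sa + sum(b))
}

#' Continuous accuracy
#'
#' Probability-valued analogue of [accuracy()]:
#' `cACC = (sum(a * b) + sum((1 - a) * (1 - b))) / N`, crediting agreement on
#' foreground and on background alike; it reduces exactly to [accuracy()]
#' when both inputs are binary. The `literal = TRUE` form replaces `+` with
#' `-` between the two sums (for auditing reports computed that way); it
#' simplifies to `(sum(a) + sum(b) - N) / N`, carries no agreement
#' information, and can be negative.
#'
#' @inheritParams continuous_dice
#' @param literal evaluate the difference form instead of the corrected sum
#'   form (default `FALSE`).
#' @return Value in \[0, 1\] (corrected form); `literal = TRUE` may leave it.
#' @export
continuous_accuracy <- function(truth, pred, literal = FALSE) {
  a <- as_prob_values(truth)
  b <- as_prob_values(pred)
  if (!identical(dim(a), dim(b))) stop("shapes differ")
  n <- length(a)
  if (n == 0) stop("no evaluated pixels")
  if (literal) (sum(a * b) - sum((1 - a) * (1 - b))) / n
  else (sum(a * b) + sum((1 - a) * (1 - b))) / n
}

#' Mean and sample standard deviation across images
#'
#' The per-image summary used in report tables ("mean +/- std over test
#' images").
#'
#' @param per_image_values numeric vector, one value per image.
#' @return Named numeric `c(mean =, sd =)`; `sd` is 0 for a single image.
#' @export
per_image_summary <- function(per_image_values) {
  x <- as.numeric(per_image_values)
  if (length(x) < 1L) stop("no per-image values")
  c(mean = mean(x), sd = if (length(x) == 1L) 0 else sd(x))
}

#' Residual image of a prediction against ground truth
#'
#' Tri-level error visualisation: gray (0.5) where prediction and truth
#' agree (TP and TN), black (0) at false negatives, white (1) at false
#' positives. Misclassification concentrates at object boundaries, which is
#' what this rendering makes visible.
#'
#' @param pred predicted [binary_mask()] (or binary matrix).
#' @param truth ground-truth mask of the same shape.
#' @return Numeric H x W matrix with values in \{0, 0.5, 1\}.
#' @export
residual_image <- function(pred, truth) {
  p <- as_mask_values(pred)
  t <- as_mask_values(truth)
  if (!identical(dim(p), dim(t))) stop("shapes differ")
  out <- matrix(0.5, nrow(p), ncol(p))
  out[p == 0 & t == 1] <- 0               # FN -> black
  out[p == 1 & t == 0] <- 1               # FP -> white
  out
}

#' Evaluate one predicted mask against truth
#'
#' Convenience wrapper computing counts and all four scores; the continuous
#' scores take the pre-binarization probability map when supplied, else the
#' binary prediction.
#'
#' @param pred predicted [binary_mask()].
#' @param truth ground-truth mask.
#' @param prob optional [probability_map()] backing `pred`, used for the
#'   continuous metrics.
#' @param cdc_variant passed to [continuous_dice()].
#' @return One-row data.frame: tp, tn, fp, fn, acc, dc, cacc, cdc.
#' @export
evaluate_masks <- function(pred, truth, prob = NULL,
                           cdc_variant = "as_printed") {
  cc <- confusion_counts(pred, truth)
  b <- if (is.null(prob)) as_mask_values(pred) else as_prob_values(prob)
  a <- as_mask_values(truth)
  data.frame(tp = cc$tp, tn = cc$tn, fp = cc$fp, fn = cc$fn,
             acc = accuracy(cc), dc = dice(cc),
             cacc = continuous_accuracy(a, b),
             cdc = continuous_dice(a, b, cdc_variant))
}

#' Round for report tables
#'
#' 3 decimal places, round-half-to-even (the R default rounding).
#'
#' @param x numeric.
#' @param digits decimal places (default 3).
#' @return Rounded numeric.
#' @export
report_round <- function(x, digits = 3L) round(x, digits)
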