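#' Construct a CMP stack
#'
#' A CMP stack holds, for every pixel of one image, the class-membership
#' probabilities (CMPs) predicted by each of the M members of an ensemble:
#' an H x W x M array of values in \[0, 1\]. Page/member order is meaningful
#' only for bookkeeping; every aggregation rule is invariant to it.
#'
#' @param values numeric H x W x M array (an H x W matrix is promoted to
#'   M = 1), all values finite and in \[0, 1\].
#' @param member_ids optional character vector of length M labelling the
#'   ensemble members; defaults to `"m1" ... "mM"`.
#' @param image_id optional single label for the underlying image.
#' @return An object of class `cmp_stack` with fields `values`, `member_ids`,
#'   `image_id`.
#' @examples
#' s <- cmp_stack(array(runif(4 * 4 * 10), c(4, 4, 10)))
#' dim(s$values)
#' @export
cmp_stack <- function(values, member_ids = NULL, image_id = "image") {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be an H x W x M array")
  d <- dim(values)
  if (any(d < 1L)) stop("H, W and M must all be >= 1")
  if (!all(is.finite(values))) stop("CMP values must all be finite")
  if (min(values) < 0 || max(values) > 1)
    stop("CMP values must lie in [0, 1]")
  if (is.null(member_ids)) member_ids <- paste0("m", seq_len(d[3L]))
  if (length(member_ids) != d[3L])
    stop("`member_ids` must have one label per member (", d[3L], ")")
  structure(list(values = values,
                 member_ids = as.character(member_ids),
                 image_id = as.character(image_id)[1L]),
            class = "cmp_stack")
}

#' @export
print.cmp_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("CMP stack '%s': %d x %d pixels, %d members\n",
              x$image_id, d[1L], d[2L], d[3L]))
  cat(sprintf("  value range [%.4f, %.4f]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Subset the members of a CMP stack
#'
#' @param x a [cmp_stack()].
#' @param i member indices (integer or logical over the M members).
#' @param ... ignored.
#' @return A `cmp_stack` holding the selected members.
#' @export
`[.cmp_stack` <- function(x, i, ...) {
  cmp_stack(x$values[, , i, drop = FALSE],
            member_ids = x$member_ids[i],
            image_id = x$image_id)
}

n_members <- function(stack) dim(stack$values)[3L]

assert_stack <- function(stack) {
  if (!inherits(stack, "cmp_stack")) stop("expected a `cmp_stack` object")
  if (n_members(stack) < 1L) stop("no members")
  invisible(stack)
}

#' Construct a probability map
#'
#' @param values numeric H x W matrix with entries in \[0, 1\].
#' @param method label of the aggregation method that produced it
#'   (`"mean"`, `"median"` or `"alpha"`).
#' @return An object of class `probability_map`.
#' @export
probability_map <- function(values, method = "mean") {
  if (!is.matrix(values)) stop("`values` must be an H x W matrix")
  if (!all(is.finite(values)) || min(values) < 0 || max(values) > 1)
    stop("probabilities must be finite and in [0, 1]")
  structure(list(values = values, method = method), class = "probability_map")
}

#' @export
print.probability_map <- function(x, ...) {
  cat(sprintf("probability map (%s): %d x %d, range [%.4f, %.4f]\n",
              x$method, nrow(x$values), ncol(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Construct a binary mask
#'
#' @param values numeric H x W matrix with entries in \{0, 1\}.
#' @param threshold_used the probability threshold that produced it (or NA
#'   for masks that are ground truth / vote outputs).
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(values, threshold_used = NA_real_) {
  if (!is.matrix(values)) stop("`values` must be an H x W matrix")
  if (!all(values %in% c(0, 1))) stop("mask values must be strictly 0 or 1")
  structure(list(values = values, threshold_used = threshold_used),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("binary mask: %d x %d, foreground fraction %.4f\n",
              nrow(x$values), ncol(x$values), mean(x$values)))
  invisible(x)
}

# Coerce plain matrices when convenient; masks must already be binary.
as_mask_values <- function(m) {
  if (inherits(m, "binary_mask")) return(m$values)
  if (is.matrix(m)) {
    if (!all(m %in% c(0, 1))) stop("mask values must be strictly 0 or 1")
    return(m)
  }
  stop("expected a `binary_mask` or a binary matrix")
}

as_prob_values <- function(p) {
  if (inherits(p, "probability_map")) return(p$values)
  if (inherits(p, "binary_mask")) return(p$values)
  if (is.matrix(p)) return(p)
  stop("expected a `probability_map`, `binary_mask` or matrix")
}
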