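#' Read an RGB image or a mask from PNG/TIFF
#'
#' Images come back as H x W x 3 arrays in \[0, 1\]; masks (single-channel
#' files) are coerced to \{0, 1\} with any positive value mapping to 1, so
#' 8-bit \{0, 255\} and 16-bit \{0, 65535\} mask conventions both work.
#'
#' @param path PNG or TIFF file.
#' @param as_mask force mask coercion (single-channel, binarized).
#' @param drop_alpha drop the alpha channel of RGBA input instead of
#'   erroring (default `FALSE`).
#' @return H x W x 3 array, or a [binary_mask()] when `as_mask = TRUE`.
#' @export
read_image <- function(path, as_mask = FALSE, drop_alpha = FALSE) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported image format '", ext, "' for ", path))
  if (as_mask) {
    if (length(dim(img)) == 3L) {
      if (dim(img)[3L] != 1L)
        stop("mask file has ", dim(img)[3L], " channels, expected 1: ", path)
      img <- img[, , 1L]
    }
    return(binary_mask((img > 0) * 1))
  }
  if (length(dim(img)) == 2L) stop("expected a 3-channel image: ", path)
  if (dim(img)[3L] == 4L) {
    if (!drop_alpha)
      stop("RGBA input (set `drop_alpha = TRUE` to discard alpha): ", path)
    img <- img[, , 1:3]
  }
  if (dim(img)[3L] != 3L)
    stop("expected a 3-channel image, got ", dim(img)[3L], ": ", path)
  img
}

#' Write an image, probability map or mask
#'
#' Masks go to 8-bit PNG as \{0, 255\}; probability maps to single-page
#' 32-bit TIFF; RGB images to PNG or TIFF by extension.
#'
#' @param x H x W x 3 array, [probability_map()] or [binary_mask()].
#' @param path destination file (.png or .tif/.tiff).
#' @return `path`, invisibly.
#' @export
write_image <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  if (inherits(x, "binary_mask")) {
    png::writePNG(x$values, path)          # 0/1 -> 0/255 in 8-bit
  } else if (inherits(x, "probability_map")) {
    tiff::writeTIFF(x$values, path, bits.per.sample = 32L, reduce = FALSE)
  } else if (ext == "png") {
    png::writePNG(x, path)
  } else {
    tiff::writeTIFF(x, path, bits.per.sample = 32L, reduce = FALSE)
  }
  invisible(path)
}

#' Write a CMP stack as a multi-page 32-bit TIFF
#'
#' One page per ensemble member, page order = member order. Samples are
#' stored on the file format's 32-bit grid (step 2^-32, finer than
#' single-precision float over \[0, 1\]); values are snapped to that grid on
#' write so that a written-then-read stack is bit-identical to what the
#' writer returned.
#'
#' @param stack a [cmp_stack()].
#' @param path destination .tif file.
#' @return The snapped `cmp_stack`, invisibly.
#' @export
write_stack <- function(stack, path) {
  assert_stack(stack)
  M <- n_members(stack)
  pages <- lapply(seq_len(M), function(k) stack$values[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  snapped <- read_stack(path)
  snapped$member_ids <- stack$member_ids
  snapped$image_id <- stack$image_id
  invisible(snapped)
}

#' Read a CMP stack from a multi-page TIFF
#'
#' @param path a multi-page TIFF, every page the same H x W shape.
#' @param member_ids optional member labels.
#' @return A [cmp_stack()] with M = number of pages.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("cannot read stack: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- unique(lapply(pages, dim))
  if (length(dims) != 1L)
    stop("mixed page shapes in ", path)
  vals <- array(unlist(pages), c(dims[[1L]][1L], dims[[1L]][2L],
                                 length(pages)))
  cmp_stack(vals, image_id = tools::file_path_sans_ext(basename(path)))
}

#' Load a run configuration from YAML
#'
#' @param path YAML file; fields are passed through with a recorded `seed`
#'   defaulting to 1.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("cannot read config: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) cfg$seed <- 1L
  structure(cfg, class = "run_config")
}

#' Per-image and pooled segmentation report
#'
#' Takes one row of confusion counts (plus optional continuous scores) per
#' (image, method) evaluation and produces the standard report: per-image
#' metrics, pooled counts per method, and per-method mean +/- sd across
#' images. With equal per-image pixel counts the mean of per-image
#' accuracies equals the accuracy of the pooled counts exactly; the
#' analogous identity does not hold for the Dice coefficient, whose pooled
#' value generally differs from the per-image average.
#'
#' @param per_image data.frame with columns `image_id`, `method`, `tp`,
#'   `tn`, `fp`, `fn` and optionally `cacc`, `cdc` (e.g. rows from
#'   [evaluate_masks()]).
#' @return A list of class `segmentation_report`: `per_image` (with acc/dc
#'   added), `pooled` (per method), `summary` (per method mean/sd of each
#'   metric).
#' @export
segmentation_report <- function(per_image) {
  need <- c("image_id", "method", "tp", "tn", "fp", "fn")
  if (!all(need %in% names(per_image)))
    stop("`per_image` must have columns: ", paste(need, collapse = ", "))
  if (nrow(per_image) < 1L) stop("no evaluated images")
  pi <- per_image
  pi$acc <- (pi$tp + pi$tn) / (pi$tp + pi$tn + pi$fp + pi$fn)
  pi$dc <- 2 * pi$tp / (2 * pi$tp + pi$fp + pi$fn)
  pooled <- do.call(rbind, lapply(split(pi, pi$method), function(g) {
    cc <- confusion_from_totals(sum(g$tp), sum(g$tn), sum(g$fp), sum(g$fn))
    data.frame(method = g$method[1L], tp = cc$tp, tn = cc$tn, fp = cc$fp,
               fn = cc$fn, acc = accuracy(cc), dc = dice(cc))
  }))
  rownames(pooled) <- NULL
  metric_cols <- intersect(c("acc", "dc", "cacc", "cdc"), names(pi))
  summary <- do.call(rbind, lapply(split(pi, pi$method), function(g) {
    row <- data.frame(method = g$method[1L], n_images = nrow(g))
    for (mc in metric_cols) {
      s <- per_image_summary(g[[mc]])
      row[[paste0(mc, "_mean")]] <- s[["mean"]]
      row[[paste0(mc, "_sd")]] <- s[["sd"]]
    }
    row
  }))
  rownames(summary) <- NULL
  structure(list(per_image = pi, pooled = pooled, summary = summary),
            class = "segmentation_report")
}

#' @export
print.segmentation_report <- function(x, digits = 3L, ...) {
  cat("segmentation report\n\npooled counts per method:\n")
  pr <- x$pooled
  pr$acc <- report_round(pr$acc, digits); pr$dc <- report_round(pr$dc, digits)
  print(pr, row.names = FALSE)
  cat("\nper-method mean +/- sd across images:\n")
  sm <- x$summary
  num <- vapply(sm, is.numeric, logical(1))
  sm[num] <- lapply(sm[num], report_round, digits = digits)
  print(sm, row.names = FALSE)
  invisible(x)
}

#' Write a segmentation report to CSV + JSON
#'
#' Fixed CSV dialect: UTF-8, comma separator, '.' decimal, header row.
#'
#' @param report a [segmentation_report()].
#' @param out_prefix path prefix; writes `<prefix>_per_image.csv`,
#'   `<prefix>_pooled.csv`, `<prefix>_summary.json`.
#' @return Named character vector of the files written, invisibly.
#' @export
write_report <- function(report, out_prefix) {
  stopifnot(inherits(report, "segmentation_report"))
  files <- c(per_image = paste0(out_prefix, "_per_image.csv"),
             pooled = paste0(out_prefix, "_pooled.csv"),
             summary = paste0(out_prefix, "_summary.json"))
  write.csv(report$per_image, files[["per_image"]], row.names = FALSE)
  write.csv(report$pooled, files[["pooled"]], row.names = FALSE)
  jsonlite::write_json(report$summary, files[["summary"]], digits = NA,
                       dataframe = "rows")
  invisible(files)
}

#' Published benchmark contingency counts
#'
#' The pooled TP/TN/FP/FN pixel counts reported for eight 100-member
#' nucleus-segmentation ensembles under the four aggregation methods on a
#' seven-image H&E test set (62 500 evaluated pixels per image), shipped as
#' a fixture: applying [accuracy()] to these counts reproduces the
#' corresponding published accuracy table at three decimals, which is the
#' package's printed-table cross-check.
#'
#' @return data.frame with columns `ensemble`, `method`, `tp`, `tn`, `fp`,
#'   `fn`.
#' @export
benchmark_counts <- function() {
  path <- system.file("extdata", "benchmark_confusion_counts.csv",
                      package = "cmpens")
  if (path == "")                          # during in-source development
    path <- file.path("inst", "extdata", "benchmark_confusion_counts.csv")
  read.csv(path, stringsAsFactors = FALSE)
}
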