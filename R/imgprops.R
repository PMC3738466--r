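#' Category scheme
#'
#' A named collection of object-id sets under one clustering hypothesis:
#' `semantic` (conceptual classes, disjoint, with animate/inanimate
#' superordinates), `shape_based` (k-means clusters in a shape-feature space)
#' or `low_level` (extremes of global image properties).
#'
#' @param kind one of `"semantic"`, `"shape_based"`, `"low_level"`.
#' @param categories named list of character vectors of object ids.
#' @param superordinates optional named list of object-id vectors (used for
#'   the animate/inanimate split of the semantic scheme).
#' @return a `CategoryScheme`.
#' @export
category_scheme <- function(kind = c("semantic", "shape_based", "low_level"),
                            categories, superordinates = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.list(categories), !is.null(names(categories)))
  if (kind == "semantic" &&
      anyDuplicated(unlist(categories, use.names = FALSE)) > 0) {
    stop("semantic categories must be disjoint", call. = FALSE)
  }
  structure(list(kind = kind, categories = categories,
                 superordinates = superordinates),
            class = "CategoryScheme")
}

#' @export
print.CategoryScheme <- function(x, ...) {
  cat(sprintf("CategoryScheme (%s): %d categories, sizes %s\n", x$kind,
              length(x$categories),
              paste(vapply(x$categories, length, 1L), collapse = "/")))
  invisible(x)
}

# median with lower interpolation on even counts (deterministic convention;
# documented in the methods vignette)
.median_lower <- function(x) {
  x <- sort(x)
  x[floor((length(x) + 1) / 2)]
}

#' Compute the four low-level properties of an object image
#'
#' Object pixels are the pixels that differ from the uniform background.
#' Luminance is the mean object-pixel intensity divided by 255; area is the
#' fraction of frame pixels occupied by the object; contrast is
#' `(median(pixels > 128) - median(pixels < 128)) /
#'  (median(pixels > 128) + median(pixels < 128))`;
#' aspect ratio is the maximum over rotations of bounding-box height over
#' width ([compute_aspect_ratio()]). Contrast is `NA` when the object has no
#' pixels on one side of mid-gray (e.g. a uniform silhouette or a blank
#' frame).
#'
#' @param img numeric matrix with intensities in 0-255.
#' @param background_value exact background gray level (default 128).
#' @param contrast_over compute the contrast medians over `"object"` pixels
#'   (default) or the whole `"frame"`.
#' @param angle_step rotation step in degrees for the aspect ratio.
#' @return named numeric vector `c(luminance, area, contrast, aspect_ratio)`.
#' @export
compute_properties <- function(img, background_value = 128,
                               contrast_over = c("object", "frame"),
                               angle_step = 1) {
  contrast_over <- match.arg(contrast_over)
  stopifnot(is.matrix(img), all(img >= 0 & img <= 255))
  mask <- img != background_value
  if (!any(mask)) {
    return(c(luminance = NA_real_, area = 0,
             contrast = NA_real_, aspect_ratio = NA_real_))
  }
  obj <- img[mask]
  px <- if (contrast_over == "object") obj else as.vector(img)
  hi <- px[px > 128]
  lo <- px[px < 128]
  contrast <- if (length(hi) == 0 || length(lo) == 0) NA_real_ else {
    mh <- .median_lower(hi)
    ml <- .median_lower(lo)
    (mh - ml) / (mh + ml)
  }
  c(luminance = mean(obj) / 255,
    area = sum(mask) / length(img),
    contrast = contrast,
    aspect_ratio = compute_aspect_ratio(mask, angle_step = angle_step))
}

#' Maximum height/width ratio of an object mask over rotations
#'
#' Rotates the object-pixel outlines over `[0, 180)` degrees in
#' `angle_step` increments and returns the maximum bounding-box height
#' divided by width (pixels are treated as unit squares, so single-pixel
#' rows and columns have unit extent at every rotation).
#'
#' @param mask logical matrix marking object pixels.
#' @param angle_step rotation step in degrees.
#' @return a value >= 1 for any mask whose maximum ratio over rotations is
#'   attained (by symmetry of rotation by 90 degrees the maximum is >= 1).
#' @export
compute_aspect_ratio <- function(mask, angle_step = 1) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask)) stop("empty mask", call. = FALSE)
  idx <- which(mask, arr.ind = TRUE)
  # represent every pixel by its four corners so the box has the pixel's
  # full extent at any rotation (no half-pixel bias)
  y <- rep(idx[, 1], each = 4) + c(-0.5, -0.5, 0.5, 0.5)
  x <- rep(idx[, 2], each = 4) + c(-0.5, 0.5, -0.5, 0.5)
  angles <- seq(0, 180 - angle_step, by = angle_step) * pi / 180
  best <- 0
  for (th in angles) {
    xr <- cos(th) * x - sin(th) * y
    yr <- sin(th) * x + cos(th) * y
    h <- diff(range(yr))
    w <- diff(range(xr))
    best <- max(best, h / w)
  }
  best
}

#' Property table of a stimulus set
#'
#' @param stimset a `StimulusSet`.
#' @param ... passed to [compute_properties()].
#' @return data frame with `object_id` and the four properties.
#' @export
property_table <- function(stimset, ...) {
  stopifnot(inherits(stimset, "StimulusSet"))
  pr <- t(vapply(stimset$images, compute_properties,
                 numeric(4), background_value = stimset$background, ...))
  out <- data.frame(object_id = stimset$objects$object_id, pr,
                    stringsAsFactors = FALSE)
  rownames(out) <- out$object_id
  out
}

#' Build the low-level category scheme
#'
#' Eight categories: for each of the four properties, the `n` objects with
#' the highest and the `n` with the lowest values. Objects with an undefined
#' property are excluded from that property's categories. Ties at the cut
#' are broken by object-id order (deterministically) and reported.
#'
#' @param props property table as returned by [property_table()].
#' @param n members per category (default 15).
#' @return a `CategoryScheme` of kind `low_level`.
#' @export
build_lowlevel_categories <- function(props, n = 15L) {
  stopifnot(is.data.frame(props),
            all(c("object_id", "luminance", "area", "contrast",
                  "aspect_ratio") %in% names(props)))
  cats <- list()
  for (prop in c("luminance", "contrast", "area", "aspect_ratio")) {
    v <- props[[prop]]
    ok <- which(!is.na(v))
    if (n > length(ok)) {
      stop(sprintf("n = %d exceeds the %d objects with defined %s",
                   n, length(ok), prop), call. = FALSE)
    }
    # base::order is stable, so ties at the cut fall back to object_id order
    hi <- ok[order(-v[ok])][seq_len(n)]
    lo <- ok[order(v[ok])][seq_len(n)]
    if (anyDuplicated(v[ok]) > 0) {
      message(sprintf("ties present in %s; broken by object_id order", prop))
    }
    cats[[paste0("high_", prop)]] <- props$object_id[sort(hi)]
    cats[[paste0("low_", prop)]] <- props$object_id[sort(lo)]
  }
  category_scheme("low_level", cats)
}
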