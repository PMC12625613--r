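#' Subtract a percentile background estimate
#'
#' Estimates the field background as a low percentile of all pixel
#' intensities (sorted-order statistic with linear interpolation) and
#' subtracts it, clamping at zero. The default pipeline uses the 5th
#' percentile: robust to the bright minority of nucleus pixels while
#' tracking the dark background mode.
#'
#' @param img Numeric intensity matrix.
#' @param percentile Percentile in `[0, 100]`.
#' @return Matrix of the same shape; pointwise `max(img - P, 0)`.
#' @examples
#' subtract_background(matrix(5, 3, 3), 5)  # all zeros
#' @export
subtract_background <- function(img, percentile = 5) {
  if (length(img) == 0) abort("Empty image.")
  if (!is.numeric(percentile) || percentile < 0 || percentile > 100)
    abort("`percentile` must be in [0, 100].")
  p <- unname(quantile(as.numeric(img), probs = percentile / 100, type = 7))
  pmax(img - p, 0)
}

# Reflect-pad a matrix by `p` pixels on every side (edge pixel mirrored,
# not repeated at the fold). Keeps convolution free of dark rims that would
# bias a global Otsu threshold.
pad_reflect <- function(img, p) {
  nr <- nrow(img); nc <- ncol(img)
  if (p >= nr || p >= nc)
    abort("Reflection padding exceeds image size; image too small for this sigma.")
  ri <- c(seq(p + 1, 2), seq_len(nr), seq(nr - 1, nr - p))
  ci <- c(seq(p + 1, 2), seq_len(nc), seq(nc - 1, nc - p))
  img[ri, ci, drop = FALSE]
}

#' Gaussian smoothing with reflective boundaries
#'
#' Convolves with a normalized Gaussian kernel truncated at three sigma.
#' Boundaries are handled by mirror reflection. The kernel sums to one, so
#' total intensity of interior structures is conserved.
#'
#' @param img Numeric intensity matrix.
#' @param sigma Kernel standard deviation in pixels (> 0).
#' @return Smoothed matrix, same shape.
#' @export
smooth_image <- function(img, sigma = 1.2) {
  if (!is.numeric(sigma) || sigma <= 0) abort("`sigma` must be > 0.")
  r <- ceiling(3 * sigma)
  k1 <- exp(-((-r:r)^2) / (2 * sigma^2))
  k1 <- k1 / sum(k1)
  p <- pad_reflect(img, r)
  nr <- nrow(img); nc <- ncol(img)
  # separable shift-and-add convolution (kernel is symmetric)
  tmp <- matrix(0, nr, ncol(p))
  for (i in -r:r)
    tmp <- tmp + k1[i + r + 1] * p[(r + 1 + i):(r + nr + i), , drop = FALSE]
  out <- matrix(0, nr, nc)
  for (j in -r:r)
    out <- out + k1[j + r + 1] * tmp[, (r + 1 + j):(r + nc + j), drop = FALSE]
  # convolution of nonnegative data cannot go negative beyond float noise
  pmax(out, 0)
}

# Local mean over a b x b window via an integral image on a reflect-padded
# copy; exact up to float rounding.
box_mean <- function(img, b) {
  r <- (b - 1L) / 2L
  p <- pad_reflect(img, r)
  cs <- apply(p, 2, cumsum)
  cs <- apply(cs, 1, cumsum)  # transposed: cs[j, i] = sum p[1:i, 1:j]
  ii <- matrix(0, nrow(p) + 1, ncol(p) + 1)
  ii[-1, -1] <- t(cs)
  nr <- nrow(img); nc <- ncol(img)
  ri <- seq_len(nr); ci <- seq_len(nc)
  (ii[ri + 2 * r + 1, ci + 2 * r + 1, drop = FALSE] -
      ii[ri, ci + 2 * r + 1, drop = FALSE] -
      ii[ri + 2 * r + 1, ci, drop = FALSE] +
      ii[ri, ci, drop = FALSE]) / b^2
}

#' Exact Otsu threshold
#'
#' Finds the cut maximizing the between-class intensity variance
#' `w0 * w1 * (mu0 - mu1)^2` over all candidate cut points (the distinct
#' pixel values), operating on the native intensity range without
#' histogram binning, and returns the midpoint of the optimal gap, so the
#' threshold lies strictly between the two classes. Foreground is defined
#' as `value > T`; because `T` falls in an open gap, `>` and `>=` give the
#' same partition. Ties take the lowest maximizing cut.
#'
#' @param x Numeric vector or matrix of intensities.
#' @return The threshold value, or `NA` if `x` has a single distinct value.
#' @export
otsu_threshold <- function(x) {
  v <- sort(as.numeric(x))
  u <- unique(v)
  if (length(u) < 2) return(NA_real_)
  cnt <- tabulate(match(v, u), nbins = length(u))
  n <- length(v)
  csum <- cumsum(cnt)
  cint <- cumsum(cnt * u)
  total <- cint[length(u)]
  # cut after each distinct value except the last
  k <- seq_len(length(u) - 1)
  w0 <- csum[k] / n
  w1 <- 1 - w0
  mu0 <- cint[k] / csum[k]
  mu1 <- (total - cint[k]) / (n - csum[k])
  bcv <- w0 * w1 * (mu0 - mu1)^2
  kk <- which.max(bcv)
  (u[kk] + u[kk + 1]) / 2
}

# Otsu threshold together with its separability measure eta = (maximal
# between-class variance) / (total variance), in [0, 1]. Unimodal Gaussian
# noise cannot exceed 2/pi (~0.64) while fields with genuine foreground sit
# much higher, so eta distinguishes blank fields from stained ones.
otsu_stats <- function(x) {
  v <- as.numeric(x)
  t_val <- otsu_threshold(v)
  if (is.na(t_val)) return(list(threshold = NA_real_, eta = NA_real_))
  lo <- v[v <= t_val]
  w0 <- length(lo) / length(v)
  bcv <- w0 * (1 - w0) * (mean(lo) - mean(v[v > t_val]))^2
  vt <- mean((v - mean(v))^2)
  list(threshold = t_val, eta = if (vt > 0) bcv / vt else NA_real_)
}

#' Threshold an intensity image to a binary mask
#'
#' `"otsu"` applies the global exact-Otsu threshold ([otsu_threshold()]);
#' `"adaptive"` compares each pixel with the local mean over a square block
#' plus an offset. A constant image under Otsu yields an all-background mask
#' with a warning (degenerate field), never an error.
#'
#' @param img Numeric intensity matrix.
#' @param mode `"otsu"` or `"adaptive"`.
#' @param adaptive_block Odd local-window size in pixels (adaptive mode).
#' @param adaptive_offset Intensity offset above the local mean (adaptive
#'   mode).
#' @return Integer 0/1 matrix (1 = foreground).
#' @export
binarize <- function(img, mode = c("otsu", "adaptive"),
                     adaptive_block = 51, adaptive_offset = 0) {
  mode <- match.arg(mode)
  if (mode == "otsu") {
    t_val <- otsu_threshold(img)
    if (is.na(t_val)) {
      warn("Constant image under Otsu thresholding; returning all-background mask.")
      return(matrix(0L, nrow(img), ncol(img)))
    }
    mask <- img > t_val
  } else {
    b <- as.integer(adaptive_block)
    if (b < 3 || b %% 2 == 0) abort("`adaptive_block` must be odd and >= 3.")
    mask <- img > box_mean(img, b) + adaptive_offset
  }
  out <- matrix(0L, nrow(img), ncol(img))
  out[mask] <- 1L
  out
}

#' Morphological cleaning of a binary mask
#'
#' Fills interior holes up to `hole_max_area` pixels, then applies a binary
#' opening with a disk structuring element to remove specks and shave thin
#' protrusions. The result is always contained in the hole-filled input.
#'
#' @param mask Integer/logical 0/1 matrix.
#' @param hole_max_area Maximum hole area (px) to fill; 0 fills nothing.
#' @param opening_radius Disk radius (px) for the opening; 0 skips it.
#' @return Integer 0/1 matrix.
#' @export
clean_mask <- function(mask, hole_max_area = 64, opening_radius = 1) {
  if (hole_max_area < 0 || opening_radius < 0)
    abort("`hole_max_area` and `opening_radius` must be nonnegative.")
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  if (hole_max_area > 0 && any(m == 1L)) {
    inv <- 1L - m
    holes <- as.matrix(EBImage::bwlabel(inv))
    border_labels <- unique(c(holes[1, ], holes[nrow(holes), ],
                              holes[, 1], holes[, ncol(holes)]))
    border_labels <- border_labels[border_labels > 0]
    if (max(holes) > 0) {
      areas <- tabulate(holes[holes > 0], nbins = max(holes))
      fill_ids <- setdiff(which(areas <= hole_max_area), border_labels)
      if (length(fill_ids) > 0) m[holes %in% fill_ids] <- 1L
    }
  }
  if (opening_radius > 0 && any(m == 1L)) {
    brush <- EBImage::makeBrush(2 * as.integer(opening_radius) + 1, shape = "disc")
    m <- matrix(as.integer(as.matrix(EBImage::opening(m, brush)) > 0),
                nrow(m), ncol(m))
  }
  m
}

#' Split touching objects with a distance-transform watershed
#'
#' Computes the Euclidean distance transform of the foreground and floods a
#' watershed from its regional maxima, after suppressing maxima shallower
#' than one pixel (h-maxima depth 1) and merging maxima closer than
#' `min_distance`. Two seeds are resolved when neither lies in the other's
#' detection neighborhood, so the neighborhood radius is half the seed
#' separation. Touching convex objects such as nucleus pairs split at the
#' neck between their distance peaks. Deterministic: ties resolve by scan
#' order.
#'
#' @param mask Integer/logical 0/1 matrix.
#' @param min_distance Minimum separation (px) between watershed seeds.
#' @return Integer label matrix (0 background, 1..k objects, consecutive).
#' @export
separate_touching <- function(mask, min_distance = 7) {
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  if (!any(m == 1L)) return(matrix(0L, nrow(m), ncol(m)))
  dm <- EBImage::distmap(m)
  w <- EBImage::watershed(dm, tolerance = 1,
                          ext = max(1L, as.integer(round(min_distance / 2))))
  lab <- matrix(as.integer(as.matrix(w)), nrow(m), ncol(m))
  relabel_consecutive(lab)
}

# Relabel a label matrix so nonzero labels are consecutive 1..k, preserving
# ascending order of the original labels.
relabel_consecutive <- function(labels) {
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0) return(labels)
  lut <- integer(max(ids))
  lut[ids] <- seq_along(ids)
  out <- labels
  out[out > 0] <- lut[out[out > 0]]
  out
}

# Per-object pixel areas and centroids of a consecutive label matrix.
label_stats <- function(labels) {
  k <- max(labels)
  if (k == 0)
    return(list(count = 0L, areas = integer(0),
                centroids = matrix(numeric(0), 0, 2,
                                   dimnames = list(NULL, c("row", "col")))))
  idx <- which(labels > 0, arr.ind = TRUE)
  lab <- labels[labels > 0]
  areas <- tabulate(lab, nbins = k)
  cr <- rowsum(as.numeric(idx[, 1]), lab)[, 1] / areas
  cc <- rowsum(as.numeric(idx[, 2]), lab)[, 1] / areas
  list(count = as.integer(k), areas = as.integer(areas),
       centroids = cbind(row = unname(cr), col = unname(cc)))
}

# TRUE when a global Otsu split of `img` would only partition noise: the
# separability eta falls below the configured floor. A constant image
# (eta undefined) also counts as blank.
blank_by_separability <- function(img, cfg) {
  st <- otsu_stats(img)
  is.na(st$eta) || st$eta < cfg$min_separability
}

#' Construct a nuclei label set
#'
#' Wraps an integer label matrix as a `nuclei_labels` object with cached
#' per-nucleus centroids and areas. Labels are made consecutive.
#'
#' @param labels Integer label matrix (0 = background).
#' @return A `nuclei_labels` object with fields `labels`, `count`,
#'   `centroids` (k x 2 matrix of row/col), `areas`.
#' @export
nuclei_labels <- function(labels) {
  lab <- relabel_consecutive(matrix(as.integer(labels), nrow(labels), ncol(labels)))
  st <- label_stats(lab)
  structure(list(labels = lab, count = st$count,
                 centroids = st$centroids, areas = st$areas),
            class = "nuclei_labels")
}

#' @export
print.nuclei_labels <- function(x, ...) {
  cat(sprintf("<nuclei_labels> %d nuclei, median area %s px\n", x$count,
              if (x$count > 0) format(median(x$areas)) else "NA"))
  invisible(x)
}

#' Tidy per-nucleus table
#'
#' @param x A `nuclei_labels` object.
#' @param ... Unused.
#' @return A tibble with one row per nucleus: `nucleus`, `row`, `col`
#'   (centroid, 1-based pixel coordinates), `area_px`.
#' @export
tidy.nuclei_labels <- function(x, ...) {
  tibble(nucleus = seq_len(x$count),
         row = x$centroids[, "row"],
         col = x$centroids[, "col"],
         area_px = x$areas)
}

#' Filter labeled objects by pixel area
#'
#' Removes objects smaller than `min_area` or larger than `max_area`
#' (debris and clumps); survivors are relabeled consecutively and their
#' centroids/areas recomputed. The published gate is roughly 30--5000 px.
#'
#' @param labels Integer label matrix or `nuclei_labels`.
#' @param min_area,max_area Inclusive pixel-area bounds, `min_area <
#'   max_area`.
#' @return A [nuclei_labels()] object.
#' @export
filter_by_size <- function(labels, min_area = 30, max_area = 5000) {
  if (min_area >= max_area) abort("`min_area` must be smaller than `max_area`.")
  lab <- if (inherits(labels, "nuclei_labels")) labels$labels else labels
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  k <- max(lab)
  if (k > 0) {
    areas <- tabulate(lab[lab > 0], nbins = k)
    drop_ids <- which(areas < min_area | areas > max_area)
    if (length(drop_ids) > 0) lab[lab %in% drop_ids] <- 0L
  }
  nuclei_labels(lab)
}

#' Segment nuclei in a field
#'
#' Runs the full nuclear-channel chain in order: percentile background
#' subtraction, Gaussian smoothing, thresholding (Otsu or adaptive),
#' morphological cleaning, distance-transform watershed separation of
#' touching nuclei, and the object-size gate. Deterministic for a given
#' configuration.
#'
#' @param field A [field_image()] with a `nuclei` plane, or a bare intensity
#'   matrix.
#' @param cfg A [pipeline_config()].
#' @return A [nuclei_labels()] object.
#' @examples
#' p <- synth_params(image_size = 256, n_nuclei = 12, n_myotubes = 0,
#'                   true_fi = 0, seed = 7)
#' f <- generate_field(p)
#' segment_nuclei(f$field, pipeline_config())$count
#' @export
segment_nuclei <- function(field, cfg = pipeline_config()) {
  img <- if (inherits(field, "field_image")) {
    if (is.null(field$planes$nuclei))
      abort("Field has no `nuclei` plane.")
    field$planes$nuclei
  } else {
    field
  }
  img <- subtract_background(img, cfg$background_percentile)
  img <- smooth_image(img, cfg$gaussian_sigma)
  if (cfg$threshold_mode == "otsu" && blank_by_separability(img, cfg)) {
    warn("Field intensities are not separable from noise (blank field); no nuclei segmented.")
    return(nuclei_labels(matrix(0L, nrow(img), ncol(img))))
  }
  mask <- binarize(img, mode = cfg$threshold_mode,
                   adaptive_block = cfg$adaptive_block,
                   adaptive_offset = cfg$adaptive_offset)
  mask <- clean_mask(mask, hole_max_area = cfg$hole_max_area,
                     opening_radius = cfg$opening_radius)
  lab <- separate_touching(mask, min_distance = cfg$watershed_min_distance)
  filter_by_size(lab, min_area = cfg$nucleus_min_area,
                 max_area = cfg$nucleus_max_area)
}
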