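#' Skeletonize a binary mask (Zhang--Suen thinning)
#'
#' Iteratively peels boundary pixels in two alternating sub-passes until the
#' object is one pixel thick, preserving connectivity. The result
#' approximates the medial axis of elongated objects and is the sampling
#' locus for width measurement.
#'
#' @param mask Integer/logical 0/1 matrix.
#' @return Integer 0/1 matrix, the skeleton (subset of the input foreground).
#' @export
skeletonize_mask <- function(mask) {
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  if (!any(m == 1L)) return(m)
  nr <- nrow(m); nc <- ncol(m)
  # work on a zero-padded copy so neighbor shifts never wrap
  p <- matrix(0L, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- m
  nb <- function(x, dr, dc) x[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      # neighbors clockwise from north: P2..P9
      P2 <- nb(p, -1, 0); P3 <- nb(p, -1, 1); P4 <- nb(p, 0, 1)
      P5 <- nb(p, 1, 1);  P6 <- nb(p, 1, 0);  P7 <- nb(p, 1, -1)
      P8 <- nb(p, 0, -1); P9 <- nb(p, -1, -1)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (P2 == 0 & P3 == 1) + (P3 == 0 & P4 == 1) + (P4 == 0 & P5 == 1) +
        (P5 == 0 & P6 == 1) + (P6 == 0 & P7 == 1) + (P7 == 0 & P8 == 1) +
        (P8 == 0 & P9 == 1) + (P9 == 0 & P2 == 1)
      core <- p[2:(nr + 1), 2:(nc + 1)] == 1L & B >= 2 & B <= 6 & A == 1
      if (pass == 1) {
        del <- core & (P2 * P4 * P6 == 0) & (P4 * P6 * P8 == 0)
      } else {
        del <- core & (P2 * P4 * P8 == 0) & (P2 * P6 * P8 == 0)
      }
      if (any(del)) {
        changed <- TRUE
        inner <- p[2:(nr + 1), 2:(nc + 1)]
        inner[del] <- 0L
        p[2:(nr + 1), 2:(nc + 1)] <- inner
      }
    }
    if (!changed) break
  }
  p[2:(nr + 1), 2:(nc + 1), drop = FALSE]
}

# Skeleton endpoints: skeleton pixels with at most one 8-connected skeleton
# neighbor.
skeleton_endpoints <- function(skel) {
  nr <- nrow(skel); nc <- ncol(skel)
  p <- matrix(0L, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- skel
  nsum <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nsum <- nsum + p[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  }
  which(skel == 1L & nsum <= 1L, arr.ind = TRUE)
}

#' Mean diameter of one myotube via medial-axis width sampling
#'
#' Skeletonizes the tube mask and samples the local width at each skeleton
#' pixel as `2 * d`, where `d` is the Euclidean distance to the nearest
#' background pixel -- the standard automated analogue of a manual caliper
#' measurement, unbiased for ribbons at general orientations (an
#' axis-aligned rectangle picks up at most one pixel of rasterization
#' overshoot). Skeleton pixels within
#' one local width of a skeleton endpoint are trimmed (end-cap bias), and
#' pixels with two or more nucleus centroids within `exclusion_radius` are
#' skipped, operationalizing the "avoid clustered nuclei" rule of the manual
#' protocol this automates.
#'
#' @param tube_mask Binary matrix of a single connected myotube.
#' @param nuclei_centroids Optional k x 2 matrix (`row`, `col`) of nucleus
#'   centroids.
#' @param pixel_size Micrometres per pixel.
#' @param exclusion_radius Clustered-nuclei radius in pixels.
#' @return One-row tibble: `mean_diameter_um`, `n_sample_sites`,
#'   `skeleton_length_px`.
#' @export
tube_diameter <- function(tube_mask, nuclei_centroids = NULL, pixel_size = 1,
                          exclusion_radius = 15) {
  m <- matrix(as.integer(tube_mask != 0), nrow(tube_mask), ncol(tube_mask))
  if (!any(m == 1L)) abort("Empty tube mask.")
  skel <- skeletonize_mask(m)
  dm <- as.matrix(EBImage::distmap(m))
  pts <- which(skel == 1L, arr.ind = TRUE)
  skeleton_length <- nrow(pts)
  widths <- 2 * dm[pts]
  keep <- rep(TRUE, nrow(pts))
  ends <- skeleton_endpoints(skel)
  if (nrow(ends) > 0 && nrow(pts) > 1) {
    for (i in seq_len(nrow(ends))) {
      d2 <- (pts[, 1] - ends[i, 1])^2 + (pts[, 2] - ends[i, 2])^2
      keep <- keep & d2 > widths^2
    }
  }
  if (!is.null(nuclei_centroids) && nrow(nuclei_centroids) > 0) {
    for (i in seq_len(nrow(pts))) {
      if (!keep[i]) next
      d2 <- (nuclei_centroids[, 1] - pts[i, 1])^2 +
        (nuclei_centroids[, 2] - pts[i, 2])^2
      if (sum(d2 <= exclusion_radius^2) >= 2) keep[i] <- FALSE
    }
  }
  if (!any(keep))
    abort("All skeleton sample sites excluded (end trim + clustered nuclei).")
  tibble(mean_diameter_um = mean(widths[keep]) * pixel_size,
         n_sample_sites = sum(keep),
         skeleton_length_px = as.integer(skeleton_length))
}

#' Select tubes eligible for diameter measurement
#'
#' Keeps "long, multinucleated" tubes: skeleton length at least
#' `min_skeleton_length` pixels and at least `min_nuclei` nuclei (default
#' 2).
#'
#' @param skeleton_lengths Named numeric vector of skeleton lengths (px) per
#'   tube label.
#' @param nucleus_counts Named integer vector of nuclei per tube label (same
#'   names).
#' @param min_skeleton_length Minimum skeleton length in pixels.
#' @param min_nuclei Minimum nucleus count.
#' @return Integer vector of eligible tube labels.
#' @export
select_measurable_tubes <- function(skeleton_lengths, nucleus_counts,
                                    min_skeleton_length = 100,
                                    min_nuclei = 2) {
  labs <- intersect(names(skeleton_lengths), names(nucleus_counts))
  ok <- skeleton_lengths[labs] >= min_skeleton_length &
    nucleus_counts[labs] >= min_nuclei
  as.integer(labs[ok])
}

#' Measure diameters of every eligible myotube in a field
#'
#' Segments nothing itself: takes an existing myotube label image and the
#' matching nuclei, applies the long/multinucleated eligibility rule, and
#' measures each eligible tube with [tube_diameter()]. Masks are cropped to
#' the tube bounding box before skeletonization.
#'
#' @param tubes Integer myotube label matrix.
#' @param nuclei A [nuclei_labels()] object (for nucleus counts and
#'   clustered-nuclei exclusion); may be `NULL` to skip both.
#' @param cfg A [pipeline_config()].
#' @param pixel_size Micrometres per pixel.
#' @return A `diameter_result`: list with `tubes` (per-tube tibble: `tube`,
#'   `mean_diameter_um`, `n_sample_sites`, `skeleton_length_px`,
#'   `nucleus_count`) and `summary` (via [condition_diameter_summary()] when
#'   two or more tubes qualify, else `NULL`).
#' @export
measure_diameters <- function(tubes, nuclei = NULL, cfg = pipeline_config(),
                              pixel_size = 1) {
  n_tubes <- max(0L, max(tubes))
  if (n_tubes == 0)
    return(structure(list(tubes = tibble(tube = integer(0),
                                         mean_diameter_um = numeric(0),
                                         n_sample_sites = integer(0),
                                         skeleton_length_px = integer(0),
                                         nucleus_count = integer(0)),
                          summary = NULL), class = "diameter_result"))
  counts <- if (!is.null(nuclei)) {
    count_nuclei_per_myotube(nuclei, tubes, rule = cfg$intersection_rule,
                             overlap_fraction = cfg$overlap_fraction)$counts
  } else {
    setNames(rep(cfg$diameter_min_nuclei, n_tubes), as.character(seq_len(n_tubes)))
  }
  rows <- list()
  for (tb in seq_len(n_tubes)) {
    idx <- which(tubes == tb, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    r0 <- max(1, min(idx[, 1]) - 2); r1 <- min(nrow(tubes), max(idx[, 1]) + 2)
    c0 <- max(1, min(idx[, 2]) - 2); c1 <- min(ncol(tubes), max(idx[, 2]) + 2)
    crop <- matrix(as.integer(tubes[r0:r1, c0:c1] == tb), r1 - r0 + 1)
    skel_len <- sum(skeletonize_mask(crop))
    if (skel_len < cfg$min_skeleton_length) next
    if (counts[[as.character(tb)]] < cfg$diameter_min_nuclei) next
    cents <- if (!is.null(nuclei) && nuclei$count > 0) {
      cbind(row = nuclei$centroids[, "row"] - r0 + 1,
            col = nuclei$centroids[, "col"] - c0 + 1)
    } else NULL
    row <- tube_diameter(crop, nuclei_centroids = cents,
                         pixel_size = pixel_size,
                         exclusion_radius = cfg$exclusion_radius)
    rows[[length(rows) + 1]] <- mutate(row, tube = tb,
                                       nucleus_count = counts[[as.character(tb)]])
  }
  tubes_tbl <- if (length(rows) > 0) {
    bind_rows(rows)[, c("tube", "mean_diameter_um", "n_sample_sites",
                        "skeleton_length_px", "nucleus_count")]
  } else {
    tibble(tube = integer(0), mean_diameter_um = numeric(0),
           n_sample_sites = integer(0), skeleton_length_px = integer(0),
           nucleus_count = integer(0))
  }
  summ <- if (nrow(tubes_tbl) >= 2)
    condition_diameter_summary(tubes_tbl$mean_diameter_um) else NULL
  structure(list(tubes = tubes_tbl, summary = summ),
            class = "diameter_result")
}

#' @export
print.diameter_result <- function(x, ...) {
  cat(sprintf("<diameter_result> %d measurable tube(s)\n", nrow(x$tubes)))
  if (!is.null(x$summary)) print(x$summary)
  invisible(x)
}

#' @export
tidy.diameter_result <- function(x, ...) x$tubes

#' @export
glance.diameter_result <- function(x, ...) {
  if (is.null(x$summary))
    tibble(mean_diameter_um = NA_real_, sd_diameter_um = NA_real_,
           n_tubes = nrow(x$tubes))
  else x$summary
}

#' Condition-level diameter summary (mean +/- SD)
#'
#' @param tube_means Numeric vector of per-tube mean diameters (um); at
#'   least two values.
#' @return One-row tibble: `mean_diameter_um`, `sd_diameter_um`, `n_tubes`.
#' @examples
#' condition_diameter_summary(c(10, 20))
#' @export
condition_diameter_summary <- function(tube_means) {
  if (length(tube_means) < 2)
    abort("Need at least two tubes for a condition summary.")
  tibble(mean_diameter_um = mean(tube_means),
         sd_diameter_um = sd(tube_means),
         n_tubes = length(tube_means))
}

#' Histogram of per-tube diameters
#'
#' @param object A `diameter_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.diameter_result <- function(object, ...) {
  ggplot2::ggplot(object$tubes,
                  ggplot2::aes(x = .data$mean_diameter_um)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey35", color = "white") +
    ggplot2::labs(x = "myotube diameter (um)", y = "tubes",
                  title = "Per-tube mean diameters") +
    ggplot2::theme_minimal()
}
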