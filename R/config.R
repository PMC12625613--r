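#' Pipeline configuration
#'
#' Bundles every tunable parameter of the fusion-index pipeline. Defaults
#' follow the published processing chain: 5th-percentile background
#' subtraction, Gaussian smoothing with sigma 1.2 px, Otsu thresholding,
#' nucleus size gate 30--5000 px, and a three-nuclei myotube qualification
#' rule. All parameters are held constant across conditions by construction:
#' one config object is passed through the whole analysis.
#'
#' @param background_percentile Percentile of all pixel intensities used as
#'   the background estimate, subtracted and clamped at zero. Default 5.
#' @param gaussian_sigma Standard deviation (pixels) of the Gaussian smoothing
#'   kernel applied to the nuclear channel. Default 1.2.
#' @param threshold_mode `"otsu"` (global, maximizes between-class variance)
#'   or `"adaptive"` (local mean plus offset).
#' @param adaptive_block Odd window size (pixels) for the adaptive local mean.
#'   Default 51.
#' @param adaptive_offset Intensity offset added to the local mean under the
#'   adaptive mode. Default 0.
#' @param nucleus_min_area,nucleus_max_area Pixel-area gate for segmented
#'   nuclei; objects outside `[min, max]` are discarded as debris or clumps.
#'   Defaults 30 and 5000.
#' @param watershed_min_distance Minimum separation (pixels) between distance
#'   transform maxima used to seed the watershed that splits touching nuclei.
#'   Default 7, roughly an expected nucleus radius.
#' @param min_nuclei_per_myotube Minimum nuclei a myotube must contain to be
#'   qualified for the fusion index. Default 3.
#' @param myotube_min_area Minimum myotube object area in pixels. Default 500.
#' @param myotube_sigma Gaussian sigma (px) for smoothing the myosin channel
#'   before thresholding. Default 2.
#' @param intersection_rule How a nucleus is matched to a myotube:
#'   `"centroid"` (nucleus belongs to the tube under its centroid pixel) or
#'   `"overlap"` (tube covering at least `overlap_fraction` of its area).
#' @param overlap_fraction Minimum covered-area fraction for the overlap
#'   rule, in (0, 1]. Default 0.5.
#' @param min_separability Minimum Otsu separability (between-class variance
#'   over total variance, in `[0, 1]`) required to treat a field as stained;
#'   below it the field is declared blank and yields zero objects. Unimodal
#'   Gaussian noise cannot exceed 2/pi (about 0.64) while genuinely stained
#'   fields sit near 0.9, so the default 0.75 splits the two regimes.
#' @param hole_max_area Maximum area (px) of interior holes filled during
#'   morphological cleaning. Default 64.
#' @param opening_radius Disk radius (px) of the binary opening used to
#'   remove specks. Default 1.
#' @param min_skeleton_length Minimum skeleton length (px) for a myotube to
#'   count as "long" in diameter measurement. Default 100.
#' @param diameter_min_nuclei Minimum nucleus count for a tube to count as
#'   "multi-nucleated" in diameter measurement. Default 2.
#' @param exclusion_radius Radius (px) within which two or more nucleus
#'   centroids mark a clustered-nuclei region skipped during diameter
#'   sampling. Default 15.
#' @param seed Integer seed for any stochastic consumer of the config.
#'
#' @return An object of class `pipeline_config` (a named list).
#' @examples
#' cfg <- pipeline_config()
#' cfg$background_percentile
#' @export
pipeline_config <- function(background_percentile = 5,
                            gaussian_sigma = 1.2,
                            threshold_mode = c("otsu", "adaptive"),
                            adaptive_block = 51,
                            adaptive_offset = 0,
                            nucleus_min_area = 30,
                            nucleus_max_area = 5000,
                            watershed_min_distance = 7,
                            min_nuclei_per_myotube = 3,
                            myotube_min_area = 500,
                            myotube_sigma = 2,
                            intersection_rule = c("centroid", "overlap"),
                            overlap_fraction = 0.5,
                            min_separability = 0.75,
                            hole_max_area = 64,
                            opening_radius = 1,
                            min_skeleton_length = 100,
                            diameter_min_nuclei = 2,
                            exclusion_radius = 15,
                            seed = 1L) {
  threshold_mode <- match.arg(threshold_mode)
  intersection_rule <- match.arg(intersection_rule)
  if (background_percentile < 0 || background_percentile > 100)
    abort("`background_percentile` must be in [0, 100].")
  if (gaussian_sigma <= 0) abort("`gaussian_sigma` must be > 0.")
  if (nucleus_min_area >= nucleus_max_area)
    abort("`nucleus_min_area` must be smaller than `nucleus_max_area`.")
  if (min_nuclei_per_myotube < 1)
    abort("`min_nuclei_per_myotube` must be >= 1.")
  if (adaptive_block < 3 || adaptive_block %% 2 == 0)
    abort("`adaptive_block` must be odd and >= 3.")
  if (overlap_fraction <= 0 || overlap_fraction > 1)
    abort("`overlap_fraction` must be in (0, 1].")
  structure(list(
    background_percentile = background_percentile,
    gaussian_sigma = gaussian_sigma,
    threshold_mode = threshold_mode,
    adaptive_block = as.integer(adaptive_block),
    adaptive_offset = adaptive_offset,
    nucleus_min_area = nucleus_min_area,
    nucleus_max_area = nucleus_max_area,
    watershed_min_distance = watershed_min_distance,
    min_nuclei_per_myotube = as.integer(min_nuclei_per_myotube),
    myotube_min_area = myotube_min_area,
    myotube_sigma = myotube_sigma,
    intersection_rule = intersection_rule,
    overlap_fraction = overlap_fraction,
    min_separability = min_separability,
    hole_max_area = hole_max_area,
    opening_radius = opening_radius,
    min_skeleton_length = min_skeleton_length,
    diameter_min_nuclei = as.integer(diameter_min_nuclei),
    exclusion_radius = exclusion_radius,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Read or write a pipeline configuration as YAML
#'
#' The YAML file is a flat key-value mapping mirroring [pipeline_config()]
#' argument names; unknown keys are rejected.
#'
#' @param path File path.
#' @return `read_config()` returns a `pipeline_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(paste0("Config file not found: ", path))
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0)
    abort(paste0("Unknown config keys: ", paste(bad, collapse = ", ")))
  do.call(pipeline_config, vals)
}

#' @rdname read_config
#' @param cfg A `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (k in names(x)) cat(sprintf("  %-24s %s\n", k, format(x[[k]])))
  invisible(x)
}
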