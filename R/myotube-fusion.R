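#' Segment myotubes from the myosin-heavy-chain channel
#'
#' Smooths the MHC plane, applies a global Otsu threshold, fills interior
#' holes (myotubes often enclose dark nuclei), and removes objects below
#' `myotube_min_area`. Labels are consecutive. A constant plane yields zero
#' objects with a warning.
#'
#' @param mhc_img MHC-channel intensity matrix, or a [field_image()] with a
#'   `myotube` plane.
#' @param cfg A [pipeline_config()]; uses `myotube_sigma` and
#'   `myotube_min_area`.
#' @return Integer label matrix of myotube objects.
#' @export
segment_myotubes <- function(mhc_img, cfg = pipeline_config()) {
  img <- if (inherits(mhc_img, "field_image")) {
    if (is.null(mhc_img$planes$myotube))
      abort("Field has no `myotube` plane.")
    mhc_img$planes$myotube
  } else {
    mhc_img
  }
  if (length(img) == 0) abort("Empty MHC plane.")
  sm <- smooth_image(img, cfg$myotube_sigma)
  if (blank_by_separability(sm, cfg)) {
    warn("MHC plane is not separable from noise (no myotubes); returning an empty label image.")
    return(matrix(0L, nrow(sm), ncol(sm)))
  }
  mask <- binarize(sm, mode = "otsu")
  if (any(mask == 1L)) {
    mask <- matrix(as.integer(as.matrix(EBImage::fillHull(mask)) > 0),
                   nrow(mask), ncol(mask))
  }
  lab <- matrix(as.integer(as.matrix(EBImage::bwlabel(mask))),
                nrow(mask), ncol(mask))
  k <- max(lab)
  if (k > 0) {
    areas <- tabulate(lab[lab > 0], nbins = k)
    small <- which(areas < cfg$myotube_min_area)
    if (length(small) > 0) lab[lab %in% small] <- 0L
  }
  relabel_consecutive(lab)
}

#' Assign nuclei to myotubes and count them per tube
#'
#' Two intersection rules are supported. `"centroid"`: a nucleus belongs to
#' the tube whose label lies under its centroid pixel (nearest-pixel
#' rounding). `"overlap"`: a nucleus belongs to the tube covering at least
#' `overlap_fraction` of its pixel area, ties broken by largest overlap then
#' lowest tube label. Under either rule a nucleus is assigned to at most one
#' tube. The two rules agree exactly whenever every nucleus is entirely
#' inside or entirely outside every tube.
#'
#' @param nuclei A [nuclei_labels()] object.
#' @param tubes Integer myotube label matrix with the same dimensions.
#' @param rule `"centroid"` or `"overlap"`.
#' @param overlap_fraction Minimum covered fraction under the overlap rule.
#' @return List with `assignment` (integer vector, tube id per nucleus, 0 =
#'   unassigned) and `counts` (named integer vector of nuclei per tube, one
#'   entry per tube label present in `tubes`).
#' @export
count_nuclei_per_myotube <- function(nuclei, tubes,
                                     rule = c("centroid", "overlap"),
                                     overlap_fraction = 0.5) {
  rule <- match.arg(rule)
  if (!identical(dim(nuclei$labels), dim(tubes)))
    abort("Nuclei and myotube label images differ in dimensions.")
  n_tubes <- max(0L, max(tubes))
  assignment <- integer(nuclei$count)
  if (nuclei$count > 0 && n_tubes > 0) {
    if (rule == "centroid") {
      rr <- pmin(pmax(round(nuclei$centroids[, "row"]), 1), nrow(tubes))
      cc <- pmin(pmax(round(nuclei$centroids[, "col"]), 1), ncol(tubes))
      assignment <- tubes[cbind(rr, cc)]
    } else {
      both <- nuclei$labels > 0 & tubes > 0
      if (any(both)) {
        pair <- (nuclei$labels[both] - 1) * n_tubes + tubes[both]
        ov <- tabulate(pair, nbins = nuclei$count * n_tubes)
        ov <- matrix(ov, nrow = n_tubes, ncol = nuclei$count)
        best_tube <- max.col(t(ov), ties.method = "first")
        best_ov <- ov[cbind(best_tube, seq_len(nuclei$count))]
        ok <- best_ov >= overlap_fraction * nuclei$areas
        assignment[ok] <- best_tube[ok]
      }
    }
  }
  counts <- if (n_tubes > 0)
    tabulate(assignment[assignment > 0], nbins = n_tubes) else integer(0)
  names(counts) <- if (n_tubes > 0) as.character(seq_len(n_tubes)) else character(0)
  list(assignment = as.integer(assignment), counts = as.integer(counts) |>
         setNames(names(counts)))
}

#' Qualify myotubes by nucleus count
#'
#' A myotube is qualified when it contains at least `min_nuclei` nuclei
#' (default 3, the "three or more nuclei" rule).
#'
#' @param counts Named integer vector of nuclei per tube (from
#'   [count_nuclei_per_myotube()]).
#' @param min_nuclei Minimum nucleus count, >= 1.
#' @return Integer vector of qualified tube labels.
#' @examples
#' qualify_myotubes(c(`1` = 3, `2` = 2), min_nuclei = 3)
#' @export
qualify_myotubes <- function(counts, min_nuclei = 3) {
  if (min_nuclei < 1) abort("`min_nuclei` must be >= 1.")
  if (length(counts) == 0) return(integer(0))
  as.integer(names(counts)[counts >= min_nuclei])
}

#' Fusion index of one field
#'
#' FI = (number of nuclei assigned to qualified myotubes) / (total nuclei in
#' the field). A field with zero nuclei is an error rather than FI 0:
#' silently scoring empty fields would bias well means downward.
#'
#' @param nuclei A [nuclei_labels()] object.
#' @param tubes Integer myotube label matrix.
#' @param cfg A [pipeline_config()]; supplies the intersection rule,
#'   `overlap_fraction` and `min_nuclei_per_myotube`.
#' @param well_id,field_id Identifiers copied into the result row.
#' @return One-row tibble: `well_id`, `field_id`, `total_nuclei`,
#'   `fused_nuclei`, `n_myotubes`, `n_qualified`, `fi` (fraction),
#'   `fi_percent`.
#' @export
fusion_index_field <- function(nuclei, tubes, cfg = pipeline_config(),
                               well_id = "well1", field_id = "field1") {
  if (nuclei$count == 0)
    abort("Empty field: no nuclei detected; cannot compute a fusion index.")
  cn <- count_nuclei_per_myotube(nuclei, tubes, rule = cfg$intersection_rule,
                                 overlap_fraction = cfg$overlap_fraction)
  qualified <- qualify_myotubes(cn$counts, cfg$min_nuclei_per_myotube)
  fused <- sum(cn$assignment %in% qualified)
  tibble(well_id = well_id, field_id = field_id,
         total_nuclei = nuclei$count, fused_nuclei = as.integer(fused),
         n_myotubes = length(cn$counts), n_qualified = length(qualified),
         fi = fused / nuclei$count, fi_percent = 100 * fused / nuclei$count)
}

#' Average field fusion indices into a well value
#'
#' The well FI is the unweighted mean over its fields; the assay convention
#' is four fields per well, and other counts trigger a warning.
#'
#' @param field_fis Numeric vector of per-field fusion indices (fractions).
#' @return The well fusion index (fraction).
#' @examples
#' fusion_index_well(c(0.2, 0.4, 0.6, 0.8))
#' @export
fusion_index_well <- function(field_fis) {
  if (length(field_fis) == 0) abort("A well needs at least one field FI.")
  if (length(field_fis) != 4)
    warn(sprintf("Well has %d field(s); the assay convention is 4.",
                 length(field_fis)))
  mean(field_fis)
}

#' Full fusion-index analysis of one or more wells
#'
#' Segments nuclei and myotubes in every field, applies the qualification
#' rule, and aggregates per-field fusion indices into per-well means.
#'
#' @param wells A [well_set()], a single [field_image()], or a list of
#'   `well_set` objects.
#' @param cfg A [pipeline_config()].
#' @return A `fusion_result` object: list with `fields` (per-field tibble as
#'   from [fusion_index_field()]) and `wells` (tibble with `well_id`,
#'   `fi`, `fi_percent`, `n_fields`). Supports [tidy()], [glance()] and
#'   [autoplot()].
#' @export
fusion_index <- function(wells, cfg = pipeline_config()) {
  if (inherits(wells, "field_image")) wells <- well_set(list(wells))
  if (inherits(wells, "well_set")) wells <- list(wells)
  rows <- lapply(wells, function(w) {
    bind_rows(lapply(w$fields, function(f) {
      nuc <- segment_nuclei(f, cfg)
      tub <- segment_myotubes(f, cfg)
      fusion_index_field(nuc, tub, cfg, well_id = f$well_id,
                         field_id = f$field_id)
    }))
  })
  fields <- bind_rows(rows)
  wells_tbl <- fields %>%
    group_by(.data$well_id) %>%
    summarise(fi = fusion_index_well(.data$fi), n_fields = n(),
              .groups = "drop") %>%
    mutate(fi_percent = 100 * .data$fi)
  structure(list(fields = fields, wells = wells_tbl, cfg = cfg),
            class = "fusion_result")
}

#' @export
print.fusion_result <- function(x, ...) {
  cat(sprintf("<fusion_result> %d field(s) in %d well(s)\n",
              nrow(x$fields), nrow(x$wells)))
  print(x$wells)
  invisible(x)
}

#' Per-field rows of a fusion-index analysis
#'
#' @param x A `fusion_result`.
#' @param ... Unused.
#' @return Tibble with one row per field.
#' @export
tidy.fusion_result <- function(x, ...) x$fields

#' Per-well summary of a fusion-index analysis
#'
#' @param x A `fusion_result`.
#' @param ... Unused.
#' @return Tibble with one row per well (`well_id`, `fi`, `fi_percent`,
#'   `n_fields`).
#' @export
glance.fusion_result <- function(x, ...) x$wells

#' Plot per-field and per-well fusion indices
#'
#' @param object A `fusion_result`.
#' @param ... Unused.
#' @return A ggplot: field FIs as points, well means as crossbars.
#' @export
autoplot.fusion_result <- function(object, ...) {
  ggplot2::ggplot(object$fields,
                  ggplot2::aes(x = .data$well_id, y = .data$fi)) +
    ggplot2::geom_point(alpha = 0.7, position = ggplot2::position_jitter(
      width = 0.08, height = 0, seed = 1)) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.4, color = "firebrick") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "well", y = "fusion index",
                  title = "Fusion index per field (points) and well mean (bar)") +
    ggplot2::theme_minimal()
}
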