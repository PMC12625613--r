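#' Construct a microscope field
#'
#' A `field_image` holds the intensity planes of one imaged field, keyed by
#' semantic channel role (`nuclei`, `myotube`, `brightfield`), together with
#' the well/field identifiers and the pixel size. Planes are numeric matrices
#' `[row, col]` on their native intensity scale; 8- and 16-bit inputs are
#' promoted to double without rescaling, since every threshold in the
#' pipeline is covariant under intensity scaling.
#'
#' @param planes Named list of nonnegative numeric matrices; names are channel
#'   roles. All planes must share dimensions.
#' @param well_id,field_id Identifiers (character).
#' @param pixel_size Pixel edge length in micrometres per pixel (> 0).
#' @return A `field_image` object.
#' @examples
#' f <- field_image(list(nuclei = matrix(0, 8, 8)), "W1", "F1", 0.5)
#' dim(f$planes$nuclei)
#' @export
field_image <- function(planes, well_id = "well1", field_id = "field1",
                        pixel_size = 1) {
  if (!is.list(planes) || length(planes) < 1 || is.null(names(planes)) ||
      any(!nzchar(names(planes))))
    abort("`planes` must be a non-empty named list of matrices.")
  bad_role <- setdiff(names(planes), c("nuclei", "myotube", "brightfield"))
  if (length(bad_role) > 0)
    abort(paste0("Unknown channel role(s): ", paste(bad_role, collapse = ", ")))
  dims <- lapply(planes, dim)
  if (any(vapply(dims, is.null, logical(1))))
    abort("Every plane must be a 2-D matrix.")
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1)
    abort("All planes must share the same dimensions.")
  if (any(dims[[1]] == 0)) abort("Zero-sized image plane.")
  for (p in planes) {
    if (!all(is.finite(p)) || any(p < 0))
      abort("Plane intensities must be finite and nonnegative.")
  }
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    abort("`pixel_size` must be a positive number (um/px).")
  structure(list(
    well_id = as.character(well_id),
    field_id = as.character(field_id),
    pixel_size = pixel_size,
    planes = lapply(planes, function(p) {
      storage.mode(p) <- "double"
      p
    })
  ), class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  d <- dim(x$planes[[1]])
  cat(sprintf("<field_image> well %s, field %s: %d x %d px (%.3g um/px), planes: %s\n",
              x$well_id, x$field_id, d[1], d[2], x$pixel_size,
              paste(names(x$planes), collapse = ", ")))
  invisible(x)
}

# Read a TIFF or PNG raster as an array on its native integer intensity scale.
# TIFFs come back as stored (8- or 16-bit counts); PNGs are 8-bit (0..255).
read_raster_native <- function(path) {
  if (!file.exists(path)) abort(paste0("Image file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
    # multi-sample rasters come back scaled to [0, 1] regardless of as.is;
    # restore the native integer scale from the recorded bit depth
    if (is.double(img)) {
      bits <- attr(img, "bits.per.sample")
      if (is.null(bits)) bits <- 8L
      img <- round(img * (2^bits[1] - 1))
    }
    attributes(img) <- list(dim = dim(img))
  } else if (ext == "png") {
    img <- round(png::readPNG(path) * 255)
  } else {
    abort(paste0("Unsupported image format: .", ext, " (use TIFF or PNG)"))
  }
  if (length(img) == 0 || is.null(dim(img)) || any(dim(img)[1:2] == 0))
    abort(paste0("Zero-sized image: ", path))
  storage.mode(img) <- "double"
  img
}

resolve_plane_index <- function(spec_idx, n_planes, path) {
  idx <- if (is.character(spec_idx)) {
    switch(tolower(spec_idx),
           red = 1L, green = 2L, blue = 3L,
           abort(paste0("Unknown channel color '", spec_idx, "'")))
  } else {
    as.integer(spec_idx)
  }
  if (is.na(idx) || idx < 1 || idx > n_planes)
    abort(sprintf("Channel %s not present in %s (file has %d plane%s).",
                  format(spec_idx), path, n_planes, if (n_planes == 1) "" else "s"))
  idx
}

#' Load a microscope field from a TIFF or PNG file
#'
#' Reads the file once, then populates each requested channel role from the
#' declared plane. For RGB files the nuclear (DAPI) channel is conventionally
#' the blue component, so `channel_map = list(nuclei = "blue")` selects plane
#' 3 of an RGB-ordered raster; BGR-ordered dialects must declare numeric
#' indices instead. A single-plane grayscale file is addressed with index 1.
#' The file is never modified.
#'
#' @param path Path to a TIFF (8/16-bit) or PNG (8-bit) file.
#' @param channel_map Named list mapping roles (`nuclei`, `myotube`,
#'   `brightfield`) to a 1-based plane index or a color name
#'   (`"red"`, `"green"`, `"blue"`).
#' @param pixel_size Micrometres per pixel.
#' @param well_id,field_id Identifiers attached to the field.
#' @return A [field_image()].
#' @export
load_field_image <- function(path, channel_map = list(nuclei = "blue"),
                             pixel_size = 1,
                             well_id = "well1", field_id = "field1") {
  img <- read_raster_native(path)
  n_planes <- if (length(dim(img)) == 3) dim(img)[3] else 1L
  planes <- lapply(channel_map, function(spec_idx) {
    idx <- resolve_plane_index(spec_idx, n_planes, path)
    if (n_planes == 1L) img else img[, , idx]
  })
  field_image(planes, well_id = well_id, field_id = field_id,
              pixel_size = pixel_size)
}

#' Extract one channel plane from a multi-plane array
#'
#' @param image A 2-D matrix or 3-D array (rows x cols x planes).
#' @param role Channel role to extract.
#' @param channel_map Named list mapping roles to plane index or color name.
#' @return The selected plane, unchanged, as a matrix.
#' @examples
#' rgb <- array(0, c(4, 4, 3)); rgb[, , 3] <- 7
#' extract_channel(rgb, "nuclei", list(nuclei = "blue"))[1, 1]
#' @export
extract_channel <- function(image, role, channel_map) {
  if (!role %in% names(channel_map))
    abort(paste0("Role '", role, "' is not present in `channel_map`."))
  n_planes <- if (length(dim(image)) == 3) dim(image)[3] else 1L
  idx <- resolve_plane_index(channel_map[[role]], n_planes, "<array>")
  out <- if (n_planes == 1L) image else image[, , idx]
  storage.mode(out) <- "double"
  out
}

#' Write an intensity plane to TIFF
#'
#' Stores a native-scale intensity matrix (or a rows x cols x planes array,
#' written as a multi-sample raster) as an unsigned 8- or 16-bit TIFF.
#' Round-tripping through [load_field_image()] reproduces integer-valued
#' planes bit-exactly.
#'
#' @param plane Numeric matrix or 3-D array with values in
#'   `[0, 2^bits - 1]`.
#' @param path Output path.
#' @param bits Bit depth, 8 or 16.
#' @return `path`, invisibly.
#' @export
write_plane_tiff <- function(plane, path, bits = 16L) {
  bits <- as.integer(bits)
  if (!bits %in% c(8L, 16L)) abort("`bits` must be 8 or 16.")
  top <- 2^bits - 1
  if (any(plane < 0) || any(plane > top))
    abort(sprintf("Plane values outside [0, %d] for %d-bit output.", top, bits))
  tiff::writeTIFF(plane / top, path, bits.per.sample = bits)
  invisible(path)
}

#' Group fields into a well
#'
#' All member fields must share `well_id` and `pixel_size`. The assay
#' convention is four fields per well; other counts are allowed (downstream
#' well averaging warns when it is not four).
#'
#' @param fields List of [field_image()] objects.
#' @return A `well_set` object.
#' @export
well_set <- function(fields) {
  if (length(fields) < 1) abort("A well needs at least one field.")
  if (!all(vapply(fields, inherits, logical(1), "field_image")))
    abort("`fields` must be a list of field_image objects.")
  wids <- vapply(fields, `[[`, character(1), "well_id")
  px <- vapply(fields, `[[`, numeric(1), "pixel_size")
  if (length(unique(wids)) != 1)
    abort("All fields in a well must share `well_id`.")
  if (length(unique(px)) != 1)
    abort("All fields in a well must share `pixel_size`.")
  structure(list(well_id = wids[1], fields = fields), class = "well_set")
}

#' @export
print.well_set <- function(x, ...) {
  cat(sprintf("<well_set> well %s with %d field(s)\n",
              x$well_id, length(x$fields)))
  invisible(x)
}

#' Read a field manifest
#'
#' A manifest CSV declares one row per field: columns `well_id`, `field_id`,
#' `path`, and optionally `pixel_size` (um/px) and `nuclei_channel` /
#' `myotube_channel` overrides (index or color name). When both a directory
#' layout and a manifest describe the same data, the manifest wins.
#'
#' @param path Manifest CSV path.
#' @return A tibble, one row per field.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort(paste0("Manifest not found: ", path))
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well_id", "field_id", "path")
  miss <- setdiff(need, names(m))
  if (length(miss) > 0)
    abort(paste0("Manifest is missing column(s): ", paste(miss, collapse = ", ")))
  as_tibble(m)
}

#' Load wells described by a manifest
#'
#' @param manifest Path to a manifest CSV or a tibble from [read_manifest()].
#' @param channel_map Default channel map used for rows without per-row
#'   channel overrides.
#' @param pixel_size Default pixel size for rows without a `pixel_size`
#'   column.
#' @param base_dir Directory that relative manifest paths are resolved
#'   against; defaults to the manifest's own directory (or `"."` for a
#'   tibble input).
#' @return Named list of [well_set()] objects, one per well.
#' @export
load_wells <- function(manifest, channel_map = list(nuclei = "blue"),
                       pixel_size = 1, base_dir = NULL) {
  if (is.character(manifest)) {
    if (is.null(base_dir)) base_dir <- dirname(manifest)
    manifest <- read_manifest(manifest)
  }
  if (is.null(base_dir)) base_dir <- "."
  has <- function(col) col %in% names(manifest)
  fields <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    cm <- channel_map
    if (has("nuclei_channel") && !is.na(row$nuclei_channel))
      cm$nuclei <- row$nuclei_channel
    if (has("myotube_channel") && !is.na(row$myotube_channel))
      cm$myotube <- row$myotube_channel
    px <- if (has("pixel_size") && !is.na(row$pixel_size))
      row$pixel_size else pixel_size
    p <- row$path
    if (!file.exists(p)) p <- file.path(base_dir, row$path)
    load_field_image(p, channel_map = cm, pixel_size = px,
                     well_id = row$well_id, field_id = row$field_id)
  })
  split_idx <- split(seq_along(fields),
                     vapply(fields, `[[`, character(1), "well_id"))
  lapply(split_idx, function(ii) well_set(fields[ii]))
}
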