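#' Parameters for the synthetic field generator
#'
#' Describes one simulated two-channel fluorescence field: Gaussian-blurred
#' disk nuclei of roughly uniform radius (optionally with touching pairs),
#' elongated bright myotube ribbons carrying a controllable fraction of the
#' nuclei, and additive background plus Gaussian noise. Defaults emulate a
#' differentiation-assay field at desk scale: a 1024 px canvas with about a
#' hundred nuclei, enough pixels for a stable Otsu split yet seconds-scale
#' to process.
#'
#' @param image_size Canvas edge in pixels (square).
#' @param n_nuclei Number of nuclei to place.
#' @param nucleus_radius Mean nucleus radius in pixels.
#' @param radius_jitter Half-range of uniform radius jitter (px).
#' @param n_myotubes Number of myotube ribbons.
#' @param tube_width Ribbon width in pixels.
#' @param tube_length Ribbon length in pixels.
#' @param true_fi Target fusion index: `round(true_fi * n_nuclei)` nuclei
#'   are placed fully inside tubes, each populated tube receiving at least
#'   `min_nuclei_per_tube` of them; the rest are placed with a clearance
#'   margin so they overlap no tube at all.
#' @param touching_fraction Fraction of the outside-tube nuclei arranged as
#'   touching pairs (centers 1.4 radii apart) to exercise the watershed.
#' @param min_nuclei_per_tube Minimum nuclei per populated tube (mirrors the
#'   qualification rule; default 3).
#' @param background Additive background intensity level.
#' @param noise_sd Gaussian read-noise standard deviation.
#' @param psf_sigma Gaussian point-spread sigma (px) applied to both
#'   channels.
#' @param nucleus_amplitude,tube_amplitude Peak intensities of rendered
#'   nuclei / ribbons above background, before blurring.
#' @param pixel_size Micrometres per pixel recorded on the field.
#' @param seed Integer RNG seed; identical parameters and seed give
#'   bit-identical images.
#' @return A `synth_params` object (named list).
#' @export
synth_params <- function(image_size = 1024, n_nuclei = 100,
                         nucleus_radius = 8, radius_jitter = 1,
                         n_myotubes = 6, tube_width = 20, tube_length = 450,
                         true_fi = 0.4, touching_fraction = 0,
                         min_nuclei_per_tube = 3,
                         background = 200, noise_sd = 30, psf_sigma = 1.5,
                         nucleus_amplitude = 2000, tube_amplitude = 1500,
                         pixel_size = 1, seed = 1L) {
  if (true_fi < 0 || true_fi > 1) abort("`true_fi` must be in [0, 1].")
  if (touching_fraction < 0 || touching_fraction > 1)
    abort("`touching_fraction` must be in [0, 1].")
  if (image_size < 64) abort("`image_size` must be at least 64 px.")
  structure(list(image_size = as.integer(image_size),
                 n_nuclei = as.integer(n_nuclei),
                 nucleus_radius = nucleus_radius,
                 radius_jitter = radius_jitter,
                 n_myotubes = as.integer(n_myotubes),
                 tube_width = tube_width, tube_length = tube_length,
                 true_fi = true_fi, touching_fraction = touching_fraction,
                 min_nuclei_per_tube = as.integer(min_nuclei_per_tube),
                 background = background, noise_sd = noise_sd,
                 psf_sigma = psf_sigma,
                 nucleus_amplitude = nucleus_amplitude,
                 tube_amplitude = tube_amplitude,
                 pixel_size = pixel_size, seed = as.integer(seed)),
            class = "synth_params")
}

# Rasterize a ribbon: pixels whose centers lie within width/2 of the segment
# from p0 to p1. Returns an integer 0/1 matrix of the full canvas.
rasterize_ribbon <- function(n, p0, p1, width) {
  half <- width / 2
  r0 <- max(1, floor(min(p0[1], p1[1]) - half - 1))
  r1 <- min(n, ceiling(max(p0[1], p1[1]) + half + 1))
  c0 <- max(1, floor(min(p0[2], p1[2]) - half - 1))
  c1 <- min(n, ceiling(max(p0[2], p1[2]) + half + 1))
  rr <- r0:r1; cc <- c0:c1
  v <- p1 - p0
  len2 <- sum(v^2)
  pr <- outer(rr - p0[1], rep(1, length(cc)))
  pc <- outer(rep(1, length(rr)), cc - p0[2])
  t <- pmin(pmax((pr * v[1] + pc * v[2]) / len2, 0), 1)
  d2 <- (pr - t * v[1])^2 + (pc - t * v[2])^2
  out <- matrix(0L, n, n)
  sub <- matrix(0L, length(rr), length(cc))
  sub[d2 <= half^2] <- 1L
  out[rr, cc] <- sub
  out
}

# Linear indices of a filled disk within an n1 x n2 canvas.
disk_indices <- function(n1, n2, center, radius) {
  r0 <- max(1, floor(center[1] - radius)); r1 <- min(n1, ceiling(center[1] + radius))
  c0 <- max(1, floor(center[2] - radius)); c1 <- min(n2, ceiling(center[2] + radius))
  rr <- r0:r1; cc <- c0:c1
  d2 <- outer((rr - center[1])^2, rep(1, length(cc))) +
    outer(rep(1, length(rr)), (cc - center[2])^2)
  inside <- which(d2 <= radius^2, arr.ind = TRUE)
  (cc[inside[, 2]] - 1) * n1 + rr[inside[, 1]]
}

#' Generate one synthetic two-channel field with ground truth
#'
#' Places non-overlapping myotube ribbons, then nuclei: the fused fraction
#' fully inside tube masks (disk entirely within the ribbon), the remainder
#' at a clearance of at least three pixels from every ribbon so their masks
#' share no pixel with any tube. Both channels are blurred with a Gaussian
#' point-spread and corrupted with additive background and Gaussian noise
#' (clamped at zero). Placement uses bounded rejection sampling and errors
#' if the requested geometry cannot be packed.
#'
#' @param params A [synth_params()].
#' @param well_id,field_id Identifiers for the generated field.
#' @return List with `field` (a [field_image()] with `nuclei` and `myotube`
#'   planes) and `truth` (a `synthetic_truth`: tibbles `nuclei` (`row`,
#'   `col`, `radius`, `tube`; tube 0 = outside), `tubes` (`tube`, `width`,
#'   `length`), the tube label matrix `tube_labels`, and `true_fi`).
#' @examples
#' g <- generate_field(synth_params(image_size = 256, n_nuclei = 10,
#'                                  n_myotubes = 1, tube_length = 140,
#'                                  true_fi = 0.3, seed = 2))
#' g$truth$true_fi
#' @export
generate_field <- function(params, well_id = "well1", field_id = "field1") {
  stopifnot(inherits(params, "synth_params"))
  set.seed(params$seed)
  n <- params$image_size
  r_mean <- params$nucleus_radius
  n_in <- round(params$true_fi * params$n_nuclei)
  if (n_in > 0 && params$n_myotubes == 0)
    abort("`true_fi` > 0 requires at least one myotube.")
  if (n_in > 0 && n_in < params$min_nuclei_per_tube)
    abort("`true_fi` implies fewer fused nuclei than `min_nuclei_per_tube`.")

  # One full placement attempt; raises a `myofuse_packing` condition when the
  # rejection sampler jams. The caller retries with fresh randomness.
  layout_once <- function() {
  pack_fail <- function(msg) abort(msg, class = "myofuse_packing")
  # --- tubes ---------------------------------------------------------------
  tube_lab <- matrix(0L, n, n)
  tube_any <- matrix(0L, n, n)
  tube_info <- list()
  margin <- params$tube_width / 2 + 4
  for (tb in seq_len(params$n_myotubes)) {
    placed <- FALSE
    for (try in 1:200) {
      theta <- runif(1, 0, pi)
      v <- c(cos(theta), sin(theta)) * params$tube_length / 2
      lo <- margin + abs(v) + 1
      hi <- n - margin - abs(v) - 1
      if (any(hi <= lo)) break
      ctr <- c(runif(1, lo[1], hi[1]), runif(1, lo[2], hi[2]))
      wide <- rasterize_ribbon(n, ctr - v, ctr + v, params$tube_width + 8)
      if (any(wide & tube_any)) next
      mask <- rasterize_ribbon(n, ctr - v, ctr + v, params$tube_width)
      tube_lab[mask == 1L] <- tb
      tube_any[mask == 1L] <- 1L
      tube_info[[tb]] <- tibble(tube = tb, width = params$tube_width,
                                length = params$tube_length, theta = theta)
      placed <- TRUE
      break
    }
    if (!placed)
      pack_fail("Infeasible packing: could not place all myotube ribbons.")
  }

  # --- nuclei counts per tube ---------------------------------------------
  per_tube <- integer(params$n_myotubes)
  if (n_in > 0) {
    n_used <- min(params$n_myotubes,
                  max(1L, n_in %/% params$min_nuclei_per_tube))
    used <- sample(params$n_myotubes, n_used)
    per_tube[used] <- params$min_nuclei_per_tube
    extra <- n_in - n_used * params$min_nuclei_per_tube
    if (extra > 0) {
      add <- table(sample(used, extra, replace = TRUE))
      per_tube[as.integer(names(add))] <-
        per_tube[as.integer(names(add))] + as.integer(add)
    }
  }

  # --- nucleus placement ---------------------------------------------------
  centers <- matrix(numeric(0), 0, 2)
  radii <- numeric(0)
  membership <- integer(0)
  min_sep <- 2 * (r_mean + params$radius_jitter) + 2
  draw_radius <- function() r_mean + runif(1, -params$radius_jitter,
                                           params$radius_jitter)
  far_enough <- function(ctr, sep) {
    nrow(centers) == 0 ||
      all((centers[, 1] - ctr[1])^2 + (centers[, 2] - ctr[2])^2 >= sep^2)
  }
  # inside tubes: centers where the whole disk fits within the ribbon
  if (n_in > 0) {
    dm_tube <- as.matrix(EBImage::distmap(tube_any))
    for (tb in which(per_tube > 0)) {
      elig <- which(tube_lab == tb & dm_tube >= r_mean + 1, arr.ind = TRUE)
      if (nrow(elig) == 0)
        pack_fail("Infeasible packing: tube too narrow for the nucleus radius.")
      for (j in seq_len(per_tube[tb])) {
        ok <- FALSE
        for (try in 1:500) {
          pick <- elig[sample(nrow(elig), 1), ]
          ctr <- pick + runif(2, -0.5, 0.5)
          if (!far_enough(ctr, min_sep)) next
          centers <- rbind(centers, ctr)
          # clamp the radius to the local ribbon half-width so the disk
          # stays fully inside the tube mask (keeps both intersection
          # rules exact on the ground truth)
          radii <- c(radii, min(draw_radius(), dm_tube[pick[1], pick[2]] - 1))
          membership <- c(membership, tb)
          ok <- TRUE
          break
        }
        if (!ok) pack_fail("Infeasible packing: nuclei do not fit in the tubes.")
      }
    }
  }
  # outside tubes: clearance of >= 3 px between disk edge and any ribbon
  n_out <- params$n_nuclei - n_in
  clear <- r_mean + params$radius_jitter + 3
  dist_to_tube <- if (any(tube_any == 1L)) {
    as.matrix(EBImage::distmap(1L - tube_any))
  } else {
    matrix(Inf, n, n)
  }
  border <- r_mean + params$radius_jitter + 2
  n_pairs <- floor(round(params$touching_fraction * n_out) / 2)
  # draws a candidate center; appends nothing (caller records accepted ones)
  propose_outside <- function(sep) {
    for (try in 1:1000) {
      ctr <- runif(2, border + 1, n - border - 1)
      pix <- round(ctr)
      if (dist_to_tube[pix[1], pix[2]] < clear) next
      if (far_enough(ctr, sep)) return(ctr)
    }
    pack_fail("Infeasible packing: not enough clear area outside tubes.")
  }
  accept <- function(ctr) {
    centers <<- rbind(centers, ctr)
    radii <<- c(radii, draw_radius())
    membership <<- c(membership, 0L)
  }
  placed_out <- 0
  while (placed_out < n_out) {
    if (n_pairs > 0 && placed_out + 2 <= n_out) {
      # touching pair: centers 1.4 mean radii apart, both clear of tubes
      ok <- FALSE
      for (try in 1:500) {
        a <- propose_outside(min_sep)
        phi <- runif(1, 0, 2 * pi)
        b <- a + 1.4 * r_mean * c(cos(phi), sin(phi))
        if (any(b <= border) || any(b >= n - border)) next
        bi <- round(b)
        if (dist_to_tube[bi[1], bi[2]] < clear) next
        if (!far_enough(b, min_sep)) next
        accept(a)
        accept(b)
        ok <- TRUE
        break
      }
      if (!ok) pack_fail("Infeasible packing: could not place a touching pair.")
      n_pairs <- n_pairs - 1
      placed_out <- placed_out + 2
    } else {
      accept(propose_outside(min_sep))
      placed_out <- placed_out + 1
    }
  }

  list(tube_lab = tube_lab, tube_any = tube_any, tube_info = tube_info,
       centers = centers, radii = radii, membership = membership)
  }

  layout <- NULL
  last_msg <- "Infeasible packing."
  for (attempt in 1:25) {
    layout <- tryCatch(layout_once(), myofuse_packing = function(e) {
      last_msg <<- conditionMessage(e)
      NULL
    })
    if (!is.null(layout)) break
  }
  if (is.null(layout)) abort(last_msg)
  tube_lab <- layout$tube_lab
  tube_any <- layout$tube_any
  tube_info <- layout$tube_info
  centers <- layout$centers
  radii <- layout$radii
  membership <- layout$membership

  truth_nuclei <- tibble(row = centers[, 1], col = centers[, 2],
                         radius = radii, tube = membership)

  # --- render --------------------------------------------------------------
  nuc_plane <- matrix(0, n, n)
  if (nrow(centers) > 0) {
    idx <- unlist(lapply(seq_len(nrow(centers)), function(i)
      disk_indices(n, n, centers[i, ], radii[i])))
    nuc_plane[idx] <- params$nucleus_amplitude
  }
  mhc_plane <- matrix(0, n, n)
  mhc_plane[tube_any == 1L] <- params$tube_amplitude
  noisy <- function(img) {
    img <- smooth_image(img, params$psf_sigma)
    pmax(img + params$background + rnorm(length(img), 0, params$noise_sd), 0)
  }
  planes <- list(nuclei = noisy(nuc_plane), myotube = noisy(mhc_plane))
  field <- field_image(planes, well_id = well_id, field_id = field_id,
                       pixel_size = params$pixel_size)
  truth <- structure(list(nuclei = truth_nuclei,
                          tubes = if (length(tube_info) > 0)
                            bind_rows(tube_info) else
                              tibble(tube = integer(0), width = numeric(0),
                                     length = numeric(0), theta = numeric(0)),
                          tube_labels = tube_lab,
                          true_fi = n_in / params$n_nuclei),
                     class = "synthetic_truth")
  list(field = field, truth = truth)
}

#' Generate a synthetic well of several fields
#'
#' Each field draws an independent sub-seed from the master seed through a
#' fixed counter scheme (`(seed * 1009 + 7919 * k) mod (2^31 - 1)`), so
#' wells are reproducible while fields differ. The well-level true fusion
#' index is the mean of the field truths.
#'
#' @param params A [synth_params()]; its `seed` is the master seed.
#' @param n_fields Number of fields (assay convention 4).
#' @param well_id Identifier for the well.
#' @return List with `well` (a [well_set()]), `truths` (list of per-field
#'   truths) and `true_fi` (well-level truth).
#' @export
generate_well <- function(params, n_fields = 4, well_id = "well1") {
  if (n_fields < 1) abort("`n_fields` must be >= 1.")
  gens <- lapply(seq_len(n_fields), function(k) {
    sub <- params
    sub$seed <- as.integer((as.numeric(params$seed) * 1009 + 7919 * k) %%
                             2147483647)
    generate_field(sub, well_id = well_id,
                   field_id = paste0("field", k))
  })
  well <- well_set(lapply(gens, `[[`, "field"))
  truths <- lapply(gens, `[[`, "truth")
  list(well = well, truths = truths,
       true_fi = mean(vapply(truths, `[[`, numeric(1), "true_fi")))
}

#' Generate a synthetic SDH-stained section with ground truth
#'
#' Tessellates the canvas interior into fibers (nearest-seed regions around
#' random points), assigns each fiber an oxidative or glycolytic class with
#' exact class counts, draws its optical density from the class mode plus
#' Gaussian jitter, and renders a brightfield image as
#' `I = I0 * 10^(-OD)` plus pixel noise. A background frame at the blank
#' intensity `I0` surrounds the tissue.
#'
#' @param n_fibers Number of fibers (>= 2).
#' @param oxidative_fraction Fraction of fibers assigned oxidative; the
#'   count is `round(oxidative_fraction * n_fibers)`.
#' @param od_modes Named numeric vector with elements `oxidative` and
#'   `glycolytic`: the two OD population modes (distinct; oxidative higher).
#' @param od_sd Within-class OD standard deviation.
#' @param i0 Blank (background) intensity.
#' @param image_size Canvas edge in pixels.
#' @param noise_sd Pixelwise intensity noise SD on the brightfield image.
#' @param seed Integer RNG seed.
#' @return List with `fiber_labels` (integer matrix), `brightfield`
#'   (intensity matrix), `i0`, and `truth` (tibble `fiber`, `class`, `od`;
#'   plus attribute-free field `true_fraction_oxidative`).
#' @export
generate_sdh_section <- function(n_fibers = 100, oxidative_fraction = 0.5,
                                 od_modes = c(oxidative = 0.8,
                                              glycolytic = 0.25),
                                 od_sd = 0.05, i0 = 200, image_size = 512,
                                 noise_sd = 2, seed = 1L) {
  if (n_fibers < 2) abort("`n_fibers` must be >= 2.")
  if (oxidative_fraction < 0 || oxidative_fraction > 1)
    abort("`oxidative_fraction` must be in [0, 1].")
  if (!all(c("oxidative", "glycolytic") %in% names(od_modes)) ||
      od_modes["oxidative"] == od_modes["glycolytic"])
    abort("`od_modes` needs distinct `oxidative` and `glycolytic` entries.")
  set.seed(seed)
  n <- as.integer(image_size)
  marg <- 12L
  seeds <- cbind(runif(n_fibers, marg + 1, n - marg),
                 runif(n_fibers, marg + 1, n - marg))
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  best_d2 <- matrix(Inf, n, n)
  labels <- matrix(0L, n, n)
  for (f in seq_len(n_fibers)) {
    d2 <- (rows - seeds[f, 1])^2 + (cols - seeds[f, 2])^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    labels[upd] <- f
  }
  interior <- rows > marg & rows <= n - marg & cols > marg & cols <= n - marg
  labels[!interior] <- 0L

  n_ox <- round(oxidative_fraction * n_fibers)
  classes <- sample(c(rep("oxidative", n_ox),
                      rep("glycolytic", n_fibers - n_ox)))
  od <- pmax(od_modes[classes] + rnorm(n_fibers, 0, od_sd), 0.01)
  fiber_i <- i0 * 10^(-od)
  bf <- matrix(i0, n, n)
  fg <- labels > 0
  bf[fg] <- fiber_i[labels[fg]]
  bf <- pmax(bf + rnorm(length(bf), 0, noise_sd), 1)
  list(fiber_labels = labels, brightfield = bf, i0 = i0,
       truth = tibble(fiber = seq_len(n_fibers), class = unname(classes),
                      od = unname(od)),
       true_fraction_oxidative = n_ox / n_fibers)
}
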