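#' Specify a synthetic RNA spot field
#'
#' Parameters for placing single-molecule RNA spots inside a cell mask with
#' a controllable radial bias, mimicking a FISH channel. Radial position is
#' measured from the nucleus centroid. Three placement modes are supported:
#'
#' * `"uniform"` — spots fall uniformly over cell-mask pixels;
#' * `"perinuclear"` — spots follow an isotropic Gaussian about the nucleus
#'   centroid, truncated to the cell mask; `radial_param` is the Gaussian
#'   sigma as a fraction of the mean cell radius (mean distance of
#'   cell-mask pixels from the nucleus centroid);
#' * `"peripheral"` — spots fall uniformly over the outer shell of the
#'   mask; `radial_param` is the shell's inner boundary as a fraction of
#'   the mask's radial extent (maximum pixel distance from the nucleus
#'   centroid).
#'
#' @param n_spots Number of spots (nonnegative integer).
#' @param radial_mode One of `"uniform"`, `"perinuclear"`, `"peripheral"`.
#' @param radial_param Radial parameter in `(0, 1]`; ignored for
#'   `"uniform"`.
#' @param spot_amplitude Peak intensity added by each spot.
#' @param psf_sigma_px Gaussian blur sigma of the point-spread function in
#'   pixels; `0` places unblurred single-pixel spots.
#' @param background_level Constant background intensity added everywhere.
#' @param noise One of `"none"`, `"gaussian"`, `"poisson"`. Noise is
#'   applied after blurring; Poisson noise uses the blurred raster as its
#'   rate.
#' @param noise_sigma Standard deviation for `"gaussian"` noise.
#' @param seed Integer seed; identical spec + seed gives bit-identical
#'   output.
#'
#' @return An object of class `spot_field_spec`.
#' @export
spot_field <- function(n_spots, radial_mode = c("uniform", "perinuclear", "peripheral"),
                       radial_param = NULL, spot_amplitude = 100,
                       psf_sigma_px = 1.5, background_level = 0,
                       noise = c("none", "gaussian", "poisson"),
                       noise_sigma = 1, seed = 1L) {
  radial_mode <- match.arg(radial_mode)
  noise <- match.arg(noise)
  stopifnot(
    length(n_spots) == 1, n_spots >= 0, n_spots == round(n_spots),
    spot_amplitude > 0, psf_sigma_px >= 0, background_level >= 0,
    noise_sigma >= 0, length(seed) == 1, is.finite(seed)
  )
  if (radial_mode != "uniform") {
    if (is.null(radial_param) || !is.numeric(radial_param) ||
        radial_param <= 0 || radial_param > 1) {
      abort("`radial_param` must lie in (0, 1] for perinuclear/peripheral modes",
            class = "periloc_invalid_spec")
    }
  } else {
    radial_param <- NA_real_
  }
  structure(
    list(
      n_spots = as.integer(n_spots), radial_mode = radial_mode,
      radial_param = as.numeric(radial_param),
      spot_amplitude = as.numeric(spot_amplitude),
      psf_sigma_px = as.numeric(psf_sigma_px),
      background_level = as.numeric(background_level),
      noise = noise, noise_sigma = as.numeric(noise_sigma),
      seed = as.integer(seed)
    ),
    class = "spot_field_spec"
  )
}

#' Construct a cell image
#'
#' Bundles an RNA intensity raster with its binary cell and nuclear masks.
#'
#' @param raster Numeric matrix of nonnegative intensities.
#' @param cell_mask,nuc_mask Logical matrices of the same dimensions;
#'   `nuc_mask` must be a subset of `cell_mask`, and `cell_mask` must be
#'   nonempty.
#' @param label Channel or probe name.
#' @return An object of class `cell_image`.
#' @export
cell_image <- function(raster, cell_mask, nuc_mask, label = "RNA") {
  raster <- as.matrix(raster)
  cell_mask <- as.matrix(cell_mask) > 0
  nuc_mask <- as.matrix(nuc_mask) > 0
  if (!identical(dim(raster), dim(cell_mask)) ||
      !identical(dim(raster), dim(nuc_mask))) {
    abort("raster and masks must share dimensions", class = "periloc_invalid_image")
  }
  if (any(raster < 0) || anyNA(raster)) {
    abort("raster intensities must be finite and nonnegative",
          class = "periloc_invalid_image")
  }
  if (!any(cell_mask)) {
    abort("cell mask is empty", class = "periloc_invalid_image")
  }
  if (any(nuc_mask & !cell_mask)) {
    abort("nuclear mask must lie inside the cell mask",
          class = "periloc_invalid_image")
  }
  structure(list(raster = raster, cell_mask = cell_mask, nuc_mask = nuc_mask,
                 label = label),
            class = "cell_image")
}

# draw n spot centers (0-based row/col of mask pixels) under a radial mode;
# rejection sampling for the perinuclear mode is capped
draw_spot_centers <- function(n, mode, param, masks, max_reject = 10000L) {
  coords <- pixel_coords(masks$cell_mask)
  ctr <- nucleus_centroid(masks$nuc_mask)
  d <- sqrt((coords[, 1] - ctr[1])^2 + (coords[, 2] - ctr[2])^2)
  if (n == 0) return(coords[integer(0), , drop = FALSE])
  if (mode == "uniform") {
    return(coords[sample.int(nrow(coords), n, replace = TRUE), , drop = FALSE])
  }
  if (mode == "peripheral") {
    keep <- d >= param * max(d)
    if (!any(keep)) {
      abort("peripheral shell contains no mask pixels",
            class = "periloc_invalid_spec")
    }
    shell <- coords[keep, , drop = FALSE]
    return(shell[sample.int(nrow(shell), n, replace = TRUE), , drop = FALSE])
  }
  # perinuclear: truncated isotropic Gaussian about the nucleus centroid
  sigma <- param * mean(d)
  inside <- matrix(NA_real_, 0, 2)
  tries <- 0L
  h <- nrow(masks$cell_mask)
  w <- ncol(masks$cell_mask)
  while (nrow(inside) < n) {
    tries <- tries + 1L
    if (tries > max_reject) {
      abort("rejection sampling for perinuclear spots exceeded its cap",
            class = "periloc_rejection_cap")
    }
    m <- max(n - nrow(inside), 1L) * 2L
    prop <- cbind(round(rnorm(m, ctr[1], sigma)), round(rnorm(m, ctr[2], sigma)))
    ok <- prop[, 1] >= 0 & prop[, 1] < h & prop[, 2] >= 0 & prop[, 2] < w
    prop <- prop[ok, , drop = FALSE]
    if (nrow(prop)) {
      ok <- masks$cell_mask[cbind(prop[, 1] + 1, prop[, 2] + 1)]
      inside <- rbind(inside, prop[ok, , drop = FALSE])
    }
  }
  inside[seq_len(n), , drop = FALSE]
}

# add a Gaussian-blurred unit spot of the given amplitude at 0-based (r0,c0)
add_spot <- function(raster, r0, c0, amplitude, sigma) {
  if (sigma == 0) {
    raster[r0 + 1, c0 + 1] <- raster[r0 + 1, c0 + 1] + amplitude
    return(raster)
  }
  half <- ceiling(4 * sigma)
  rows <- max(0, r0 - half):min(nrow(raster) - 1, r0 + half)
  cols <- max(0, c0 - half):min(ncol(raster) - 1, c0 + half)
  kr <- exp(-(rows - r0)^2 / (2 * sigma^2))
  kc <- exp(-(cols - c0)^2 / (2 * sigma^2))
  raster[rows + 1, cols + 1] <- raster[rows + 1, cols + 1] +
    amplitude * outer(kr, kc)
  raster
}

#' Simulate a FISH-like cell image
#'
#' Generates a single-cell RNA channel: spots are placed inside the cell
#' mask according to the requested radial bias, blurred with a Gaussian
#' point-spread function, summed onto a constant background, and optionally
#' degraded with Gaussian or Poisson noise. The generator is deterministic
#' for a fixed spec and seed, and uses its own RNG stream so surrounding
#' code is unaffected.
#'
#' @param geom A [cell_geometry()].
#' @param spots A [spot_field()] spec.
#' @return A [cell_image()] with an added `truth` element recording the
#'   radial mode, radial parameter, spot count and spot centers.
#' @export
#' @examples
#' geom <- cell_geometry(96, 96, c(40, 28), c(12, 9))
#' img <- simulate_cell_image(geom, spot_field(200, "peripheral", 0.7, seed = 7))
#' compute_pdi(img)$pdi > 1
simulate_cell_image <- function(geom, spots) {
  stopifnot(inherits(geom, "cell_geometry"), inherits(spots, "spot_field_spec"))
  masks <- geometry_masks(geom)
  h <- geom$image_height_px
  w <- geom$image_width_px
  raster <- matrix(spots$background_level, h, w)
  centers <- withr::with_seed(spots$seed, {
    ctrs <- draw_spot_centers(spots$n_spots, spots$radial_mode,
                              spots$radial_param, masks)
    for (i in seq_len(nrow(ctrs))) {
      raster <- add_spot(raster, ctrs[i, 1], ctrs[i, 2],
                         spots$spot_amplitude, spots$psf_sigma_px)
    }
    raster <- switch(spots$noise,
      none = raster,
      gaussian = pmax(raster + rnorm(length(raster), 0, spots$noise_sigma), 0),
      poisson = matrix(rpois(length(raster), lambda = raster), h, w)
    )
    ctrs
  })
  img <- cell_image(raster, masks$cell_mask, masks$nuc_mask)
  img$truth <- list(radial_mode = spots$radial_mode,
                    radial_param = spots$radial_param,
                    n_spots = spots$n_spots, spot_centers = centers)
  img
}

#' Simulate a batch of cell images
#'
#' Each cell gets its own RNG stream seeded from `spots$seed + i - 1`, so
#' adding cells to a batch never changes earlier cells.
#'
#' @param n Number of cells.
#' @inheritParams simulate_cell_image
#' @return A list of [cell_image()] objects.
#' @export
simulate_cell_images <- function(n, geom, spots) {
  stopifnot(n >= 0)
  purrr::map(seq_len(n), function(i) {
    sp <- spots
    sp$seed <- spots$seed + i - 1L
    simulate_cell_image(geom, sp)
  })
}

#' Deterministic radial intensity patterns
#'
#' Builds noiseless cell images whose intensity is an analytic function of
#' the distance from the nucleus centroid. Useful for calibrating the PDI:
#' a `"uniform"` pattern has PDI exactly 1, a `"gaussian"` (perinuclear)
#' pattern has PDI below 1, and a `"shell"` (peripheral) pattern has PDI
#' above 1.
#'
#' @param geom A [cell_geometry()].
#' @param pattern `"uniform"` (constant over the cell mask), `"gaussian"`
#'   (isotropic Gaussian about the nucleus centroid, truncated to the
#'   mask), or `"shell"` (constant on mask pixels whose normalized radial
#'   coordinate is at least `param`).
#' @param param Gaussian sigma as a fraction of the mean cell radius, or
#'   the shell's inner boundary as a fraction of the mask's radial extent.
#' @param intensity Peak intensity of the pattern.
#' @return A [cell_image()].
#' @export
cell_image_pattern <- function(geom, pattern = c("uniform", "gaussian", "shell"),
                               param = 0.15, intensity = 1) {
  pattern <- match.arg(pattern)
  masks <- geometry_masks(geom)
  ctr <- nucleus_centroid(masks$nuc_mask)
  h <- geom$image_height_px
  w <- geom$image_width_px
  rr <- matrix(seq_len(h) - 1, h, w) - ctr[1]
  cc <- matrix(rep(seq_len(w) - 1, each = h), h, w) - ctr[2]
  d <- sqrt(rr^2 + cc^2)
  raster <- matrix(0, h, w)
  if (pattern == "uniform") {
    raster[masks$cell_mask] <- intensity
  } else if (pattern == "gaussian") {
    sigma <- param * mean(d[masks$cell_mask])
    raster[masks$cell_mask] <- intensity *
      exp(-d[masks$cell_mask]^2 / (2 * sigma^2))
  } else {
    dmax <- max(d[masks$cell_mask])
    shell <- masks$cell_mask & d >= param * dmax
    raster[shell] <- intensity
  }
  cell_image(raster, masks$cell_mask, masks$nuc_mask, label = pattern)
}
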