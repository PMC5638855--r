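#' Centroid of a nuclear mask
#'
#' The unweighted arithmetic mean of the 0-based `(row, col)` coordinates
#' of the mask's pixels. This is the reference point for all radial second
#' moments.
#'
#' @param nuc_mask Logical (or 0/1) matrix; must contain at least one pixel.
#' @return Numeric length-2 vector `(row, col)`, 0-based.
#' @export
#' @examples
#' m <- matrix(FALSE, 10, 10); m[6, 8] <- TRUE
#' nucleus_centroid(m) # c(5, 7)
nucleus_centroid <- function(nuc_mask) {
  coords <- pixel_coords(as.matrix(nuc_mask) > 0)
  if (nrow(coords) == 0) {
    abort("nuclear mask is empty: no nucleus to take a centroid of",
          class = "periloc_empty_nucleus")
  }
  c(mean(coords[, 1]), mean(coords[, 2]))
}

#' Intensity-weighted second moment about a centroid
#'
#' Computes `sum(I_i * d_i^2) / sum(I_i)` over the pixels of `mask`, where
#' `d_i` is the Euclidean distance (pixels) from the pixel center to
#' `centroid`. This is the numerator of the Peripheral Distribution Index.
#'
#' @param raster Numeric matrix of nonnegative intensities.
#' @param mask Logical matrix selecting the pixels to integrate over.
#' @param centroid 0-based `(row, col)` reference point.
#' @return The second moment in squared pixels.
#' @export
intensity_second_moment <- function(raster, mask, centroid) {
  mask <- as.matrix(mask) > 0
  coords <- pixel_coords(mask)
  if (nrow(coords) == 0) abort("mask is empty", class = "periloc_empty_mask")
  I <- raster[mask]
  tot <- sum(I)
  if (tot <= 0) {
    abort("total intensity over the mask is zero", class = "periloc_low_signal")
  }
  d2 <- (coords[, 1] - centroid[1])^2 + (coords[, 2] - centroid[2])^2
  sum(I * d2) / tot
}

#' Second moment of a hypothetical uniform distribution
#'
#' The unweighted mean of squared distances of cell-mask pixels from the
#' centroid — the second moment of a signal spread uniformly over the cell,
#' used to normalize the intensity-weighted moment.
#'
#' @inheritParams intensity_second_moment
#' @param cell_mask Logical matrix of the whole-cell area.
#' @return Mean squared distance in squared pixels.
#' @export
uniform_second_moment <- function(cell_mask, centroid) {
  coords <- pixel_coords(as.matrix(cell_mask) > 0)
  if (nrow(coords) == 0) abort("cell mask is empty", class = "periloc_empty_mask")
  mean((coords[, 1] - centroid[1])^2 + (coords[, 2] - centroid[2])^2)
}

#' Peripheral Distribution Index of one cell
#'
#' Quantifies how peripherally an RNA signal is distributed: the
#' intensity-weighted second moment of the RNA channel about the nucleus
#' centroid, divided by the second moment of a hypothetical uniform
#' distribution over the binary cell mask. A PDI of 1 indicates a diffuse
#' signal filling the cell; values below 1 indicate perinuclear
#' concentration and values above 1 peripheral concentration.
#'
#' The processing pipeline is: (1) subtract a scalar background from the
#' raster and clip at zero; (2) optionally zero all pixels inside the
#' nuclear mask (the convention used for the polyA RNA channel, whose
#' nuclear signal is not informative about cytoplasmic localization);
#' (3) take the centroid of the nuclear mask; (4) form the moment ratio.
#' Nuclear subtraction removes signal but keeps nuclear pixels in the
#' uniform-moment denominator, so a perfectly diffuse cytoplasmic signal
#' yields a PDI above 1 after subtraction — and the inflation grows with
#' the fraction of the cell the nucleus covers, which is why cells whose
#' nucleus/cell area ratio exceeds `nucleus_area_threshold` are flagged
#' (`nucleus_area_fraction_high`) rather than compared blindly across
#' populations with different spreading areas.
#'
#' @param image A [cell_image()].
#' @param subtract_nuclear_signal Zero nuclear pixels before the moment
#'   computation (recommended for polyA channels).
#' @param background Scalar background to subtract, or `"auto"` to use the
#'   median intensity outside the cell mask.
#' @param nucleus_area_threshold Nuclear/cell area ratio above which the
#'   `nucleus_area_fraction_high` QC flag is set (default 0.5).
#' @return A one-row tibble with columns `pdi`, `second_moment_signal`,
#'   `second_moment_uniform` (both px^2), `centroid_row`, `centroid_col`,
#'   `total_intensity_used`, `nuclear_subtracted`,
#'   `background_subtracted_value` and `qc_flags` (semicolon-separated,
#'   empty when clean).
#' @export
#' @examples
#' geom <- cell_geometry(128, 128, c(50, 30), c(15, 10))
#' img <- cell_image_pattern(geom, "uniform")
#' compute_pdi(img)$pdi # 1 up to float error
compute_pdi <- function(image, subtract_nuclear_signal = FALSE,
                        background = 0, nucleus_area_threshold = 0.5) {
  stopifnot(inherits(image, "cell_image"))
  bg <- if (identical(background, "auto")) {
    outside <- image$raster[!image$cell_mask]
    if (length(outside) == 0) 0 else median(outside)
  } else {
    stopifnot(is.numeric(background), length(background) == 1, background >= 0)
    background
  }
  raster <- pmax(image$raster - bg, 0)
  if (subtract_nuclear_signal) raster[image$nuc_mask] <- 0
  ctr <- nucleus_centroid(image$nuc_mask)
  m_sig <- intensity_second_moment(raster, image$cell_mask, ctr)
  m_unif <- uniform_second_moment(image$cell_mask, ctr)
  flags <- character(0)
  nuc_frac <- sum(image$nuc_mask) / sum(image$cell_mask)
  if (nuc_frac > nucleus_area_threshold) {
    flags <- c(flags, "nucleus_area_fraction_high")
  }
  tibble::tibble(
    label = image$label,
    pdi = m_sig / m_unif,
    second_moment_signal = m_sig,
    second_moment_uniform = m_unif,
    centroid_row = ctr[1],
    centroid_col = ctr[2],
    total_intensity_used = sum(raster[image$cell_mask]),
    nuclear_subtracted = subtract_nuclear_signal,
    background_subtracted_value = bg,
    nucleus_area_fraction = nuc_frac,
    qc_flags = paste(flags, collapse = ";")
  )
}

#' PDI for a collection of cells
#'
#' Applies [compute_pdi()] to a list of cell images and stacks the results
#' into one row per cell. Cells that fail (for example with zero signal
#' after background subtraction) are reported as flagged rows with `NA`
#' PDI, never silently dropped.
#'
#' @param images A list of [cell_image()] objects (optionally named; names
#'   become `cell_id`).
#' @inheritParams compute_pdi
#' @return A tibble with one row per cell.
#' @export
pdi_batch <- function(images, subtract_nuclear_signal = FALSE,
                      background = 0, nucleus_area_threshold = 0.5) {
  stopifnot(is.list(images))
  ids <- names(images)
  if (is.null(ids)) ids <- sprintf("cell_%03d", seq_along(images))
  empty <- tibble::tibble(
    cell_id = character(0), label = character(0), pdi = numeric(0),
    second_moment_signal = numeric(0), second_moment_uniform = numeric(0),
    centroid_row = numeric(0), centroid_col = numeric(0),
    total_intensity_used = numeric(0), nuclear_subtracted = logical(0),
    background_subtracted_value = numeric(0),
    nucleus_area_fraction = numeric(0), qc_flags = character(0)
  )
  if (length(images) == 0) return(empty)
  rows <- purrr::map2(images, ids, function(img, id) {
    res <- tryCatch(
      compute_pdi(img, subtract_nuclear_signal, background,
                  nucleus_area_threshold),
      periloc_low_signal = function(e) failed_pdi_row(img, "low_signal"),
      error = function(e) failed_pdi_row(img, "error")
    )
    dplyr::mutate(res, cell_id = id, .before = 1)
  })
  dplyr::bind_rows(rows)
}

failed_pdi_row <- function(img, flag) {
  tibble::tibble(
    label = if (inherits(img, "cell_image")) img$label else NA_character_,
    pdi = NA_real_, second_moment_signal = NA_real_,
    second_moment_uniform = NA_real_, centroid_row = NA_real_,
    centroid_col = NA_real_, total_intensity_used = NA_real_,
    nuclear_subtracted = NA, background_subtracted_value = NA_real_,
    nucleus_area_fraction = NA_real_, qc_flags = flag
  )
}
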