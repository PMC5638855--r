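#' Specify an elliptical cell/nucleus geometry
#'
#' Defines the geometry of a synthetic cell: an elliptical whole-cell mask
#' and an interior elliptical nuclear mask, both rasterized onto a pixel
#' grid. Pixel coordinates are 0-based `(row, col)` at pixel centers and all
#' distances are in pixel units (pixels are assumed square).
#'
#' @param image_height_px,image_width_px Image dimensions in pixels.
#' @param cell_semi_axes_px Length-2 numeric, cell ellipse semi-axes in
#'   pixels, `(row, col)` order before rotation.
#' @param nucleus_semi_axes_px Length-2 numeric, nuclear ellipse semi-axes.
#' @param nucleus_offset_px Length-2 numeric, nucleus center minus cell
#'   center, `(row, col)`, before rotation.
#' @param rotation_deg Rotation of the whole geometry (both ellipses and the
#'   nucleus offset) about the cell center, degrees.
#' @param cell_center_px Optional length-2 numeric cell center; defaults to
#'   the image center.
#'
#' @return An object of class `cell_geometry`.
#' @export
#' @examples
#' geom <- cell_geometry(128, 128, c(50, 30), c(15, 10))
#' m <- geometry_masks(geom)
#' sum(m$cell_mask) > sum(m$nuc_mask)
cell_geometry <- function(image_height_px, image_width_px,
                          cell_semi_axes_px, nucleus_semi_axes_px,
                          nucleus_offset_px = c(0, 0), rotation_deg = 0,
                          cell_center_px = NULL) {
  stopifnot(
    is.numeric(image_height_px), length(image_height_px) == 1, image_height_px >= 1,
    is.numeric(image_width_px), length(image_width_px) == 1, image_width_px >= 1,
    length(cell_semi_axes_px) == 2, all(cell_semi_axes_px > 0),
    length(nucleus_semi_axes_px) == 2, all(nucleus_semi_axes_px > 0),
    length(nucleus_offset_px) == 2, is.finite(rotation_deg)
  )
  if (is.null(cell_center_px)) {
    cell_center_px <- c((image_height_px - 1) / 2, (image_width_px - 1) / 2)
  }
  geom <- structure(
    list(
      image_height_px = as.integer(image_height_px),
      image_width_px = as.integer(image_width_px),
      cell_semi_axes_px = as.numeric(cell_semi_axes_px),
      nucleus_semi_axes_px = as.numeric(nucleus_semi_axes_px),
      nucleus_offset_px = as.numeric(nucleus_offset_px),
      rotation_deg = as.numeric(rotation_deg),
      cell_center_px = as.numeric(cell_center_px)
    ),
    class = "cell_geometry"
  )
  validate_cell_geometry(geom)
  geom
}

# rotation matrix acting on (row, col) vectors
rot2 <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

validate_cell_geometry <- function(geom) {
  R <- rot2(geom$rotation_deg)
  t <- seq(0, 2 * pi, length.out = 721)[-721]
  cell_bd <- t(R %*% rbind(geom$cell_semi_axes_px[1] * cos(t),
                           geom$cell_semi_axes_px[2] * sin(t))) +
    rep(geom$cell_center_px, each = length(t))
  nuc_center <- geom$cell_center_px + as.numeric(R %*% geom$nucleus_offset_px)
  nuc_bd <- t(R %*% rbind(geom$nucleus_semi_axes_px[1] * cos(t),
                          geom$nucleus_semi_axes_px[2] * sin(t))) +
    rep(nuc_center, each = length(t))
  in_frame <- function(p) {
    all(p[, 1] >= 0 & p[, 1] <= geom$image_height_px - 1 &
          p[, 2] >= 0 & p[, 2] <= geom$image_width_px - 1)
  }
  if (!in_frame(cell_bd)) {
    abort("cell ellipse does not lie entirely within the image frame",
          class = "periloc_invalid_geometry")
  }
  # nucleus boundary must satisfy the cell-ellipse inequality
  d <- sweep(nuc_bd, 2, geom$cell_center_px)
  uv <- d %*% R # rotate back: R is orthogonal, d %*% R == t(t(R) %*% t(d))
  q <- (uv[, 1] / geom$cell_semi_axes_px[1])^2 +
    (uv[, 2] / geom$cell_semi_axes_px[2])^2
  if (any(q > 1 + 1e-9)) {
    abort("nucleus ellipse does not lie entirely within the cell ellipse",
          class = "periloc_invalid_geometry")
  }
  invisible(geom)
}

ellipse_mask <- function(h, w, center, semi_axes, R) {
  rr <- matrix(seq_len(h) - 1, h, w) - center[1]
  cc <- matrix(rep(seq_len(w) - 1, each = h), h, w) - center[2]
  u <- rr * R[1, 1] + cc * R[2, 1]
  v <- rr * R[1, 2] + cc * R[2, 2]
  (u / semi_axes[1])^2 + (v / semi_axes[2])^2 <= 1
}

#' Rasterize a cell geometry into binary masks
#'
#' @param geom A [cell_geometry()] object.
#' @return A list with logical matrices `cell_mask` and `nuc_mask`
#'   (`nuc_mask` is guaranteed to be a subset of `cell_mask`) and the
#'   0-based `nucleus_center` used.
#' @export
geometry_masks <- function(geom) {
  stopifnot(inherits(geom, "cell_geometry"))
  R <- rot2(geom$rotation_deg)
  h <- geom$image_height_px
  w <- geom$image_width_px
  nuc_center <- geom$cell_center_px + as.numeric(R %*% geom$nucleus_offset_px)
  cell_mask <- ellipse_mask(h, w, geom$cell_center_px, geom$cell_semi_axes_px, R)
  nuc_mask <- ellipse_mask(h, w, nuc_center, geom$nucleus_semi_axes_px, R) & cell_mask
  if (!any(cell_mask)) {
    abort("cell mask has no pixels", class = "periloc_invalid_geometry")
  }
  list(cell_mask = cell_mask, nuc_mask = nuc_mask, nucleus_center = nuc_center)
}

# 0-based (row, col) coordinates of TRUE pixels, as an n x 2 matrix
pixel_coords <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  cbind(row = idx[, 1] - 1, col = idx[, 2] - 1)
}
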