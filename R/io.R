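#' Read and write cell images
#'
#' `write_cell_image()` writes the RNA raster as a single-channel 32-bit
#' TIFF and the masks as single-channel 8-bit PNGs (0/255).
#' Because TIFF samples are stored in `[0, 1]`, the raster is scaled by
#' its maximum before writing; the PDI is invariant under positive
#' scaling of the raster, so this does not affect any downstream
#' quantity. `read_cell_image()` reads the three files back into a
#' [cell_image()].
#'
#' @param image A [cell_image()].
#' @param raster_path,cell_mask_path,nuc_mask_path File paths (`.tif` for
#'   the raster, `.png` for the masks).
#' @param label Channel label attached on read.
#' @return `write_cell_image()` returns the scaling factor applied to the
#'   raster, invisibly; `read_cell_image()` returns a [cell_image()].
#' @export
write_cell_image <- function(image, raster_path, cell_mask_path,
                             nuc_mask_path) {
  stopifnot(inherits(image, "cell_image"))
  scale <- max(image$raster, 1e-12)
  tiff::writeTIFF(image$raster / scale, raster_path,
                  bits.per.sample = 32L, compression = "none")
  png::writePNG(image$cell_mask * 1, cell_mask_path)
  png::writePNG(image$nuc_mask * 1, nuc_mask_path)
  invisible(scale)
}

#' @rdname write_cell_image
#' @export
read_cell_image <- function(raster_path, cell_mask_path, nuc_mask_path,
                            label = "RNA") {
  read_mask <- function(path) {
    m <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
      tiff::readTIFF(path)
    } else {
      png::readPNG(path)
    }
    if (length(dim(m)) == 3) m <- m[, , 1]
    m > 0.5
  }
  raster <- tiff::readTIFF(raster_path)
  if (length(dim(raster)) == 3) raster <- raster[, , 1]
  cell_image(raster, read_mask(cell_mask_path), read_mask(nuc_mask_path),
             label = label)
}

#' Read a counts TSV
#'
#' One gene per row; first column gene identifiers, remaining columns
#' sample counts.
#'
#' @param path TSV file path.
#' @return Gene-by-sample numeric matrix.
#' @export
read_counts_tsv <- function(path) {
  as_count_matrix(utils::read.delim(path, check.names = FALSE))
}

#' Read a sample-metadata TSV
#'
#' Requires columns `sample`, `fraction` (`Ps`/`CB`), `condition`,
#' `replicate`.
#'
#' @param path TSV file path.
#' @return A tibble.
#' @export
read_sample_info_tsv <- function(path) {
  info <- tibble::as_tibble(utils::read.delim(path, check.names = FALSE,
                                              colClasses = "character"))
  need <- c("sample", "fraction", "condition", "replicate")
  if (!all(need %in% names(info))) {
    abort(paste0("sample metadata must have columns: ",
                 paste(need, collapse = ", ")),
          class = "periloc_invalid_input")
  }
  info$replicate <- as.integer(info$replicate)
  info
}

#' Read gene sets in GMT format
#'
#' @param path GMT file path (one set per line: name, description, genes,
#'   tab-separated).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write a table atomically as TSV
#'
#' Writes to a temporary file in the destination directory and renames it
#' into place, so readers never observe a half-written table.
#'
#' @param x Data frame.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_tsv_atomic <- function(x, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  utils::write.table(x, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!file.rename(tmp, path)) {
    file.remove(tmp)
    abort(paste0("could not write ", path), class = "periloc_io_error")
  }
  invisible(path)
}

# counts matrix -> TSV layout (gene id first column)
counts_to_df <- function(counts) {
  data.frame(gene = rownames(counts), counts, check.names = FALSE)
}
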