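# Slide containers and the slide manifest.
#
# A slide is modelled as a (possibly single-level) image pyramid in the
# level-0 pixel frame: 0-based coordinates, x = column, y = row, half-open
# footprints. Plain images are single-level pyramids whose nominal scan
# magnification comes from the manifest, which is how the synthetic x20
# slides exercise the x20 -> x10 resampling path.

#' Create a slide object
#'
#' Either `image` (an in-memory H x W x 3 array, values 0-255) or `path`
#' (an uncompressed TIFF readable by [read_tiff()]) must be given. File-backed
#' slides are loaded lazily on first pixel access and cached.
#'
#' @param slide_id identifier string.
#' @param image optional in-memory pixel array.
#' @param path optional path to a TIFF file.
#' @param scan_magnification nominal objective power of the scan (default 20).
#' @return an object of class `wsi_slide`.
#' @export
wsi_slide <- function(slide_id, image = NULL, path = NULL, scan_magnification = 20) {
  if (is.null(image) && is.null(path)) stopf("slide '%s': need image or path", slide_id)
  env <- new.env(parent = emptyenv())
  dims <- NULL
  if (!is.null(image)) {
    if (length(dim(image)) == 2L) {
      image <- array(rep(image, 3L), dim = c(dim(image), 3L))
    }
    env$image <- image
    dims <- dim(image)[1:2]
  }
  s <- structure(list(
    slide_id = slide_id, path = path,
    scan_magnification = scan_magnification,
    cache = env
  ), class = "wsi_slide")
  if (is.null(dims)) dims <- dim(slide_pixels(s))[1:2]
  s$height <- dims[1]; s$width <- dims[2]
  # level-0 first; single-level files expose exactly one level
  s$level_dimensions <- list(c(width = s$width, height = s$height))
  s
}

#' @export
print.wsi_slide <- function(x, ...) {
  cat(sprintf("<wsi_slide '%s' %dx%d px, scan x%g, %s>\n", x$slide_id,
              x$width, x$height, x$scan_magnification,
              if (is.null(x$path)) "in-memory" else x$path))
  invisible(x)
}

slide_pixels <- function(slide) {
  if (is.null(slide$cache$image)) {
    img <- read_tiff(slide$path)
    if (length(dim(img)) == 2L) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
    slide$cache$image <- img
  }
  slide$cache$image
}

#' Read a rectangular level-0 region with white padding
#'
#' Out-of-bounds area is filled with intensity 255 (the bright LBC slide
#' background), so edge tiles keep the full requested shape.
#'
#' @param slide a `wsi_slide`.
#' @param x,y 0-based top-left corner in the level-0 frame.
#' @param w,h region width/height in level-0 pixels.
#' @return an `h` x `w` x 3 numeric array.
#' @export
read_region <- function(slide, x, y, w, h) {
  if (x >= slide$width || y >= slide$height || x + w <= 0 || y + h <= 0) {
    stopf("region (%d,%d,%dx%d) lies entirely outside slide '%s'",
          x, y, w, h, slide$slide_id)
  }
  img <- slide_pixels(slide)
  out <- array(255, dim = c(h, w, 3L))
  x0 <- max(x, 0L); y0 <- max(y, 0L)
  x1 <- min(x + w, slide$width); y1 <- min(y + h, slide$height)
  out[(y0 - y + 1):(y1 - y), (x0 - x + 1):(x1 - x), ] <-
    img[(y0 + 1):y1, (x0 + 1):x1, , drop = FALSE]
  out
}

#' Grayscale thumbnail of a slide
#'
#' Integer block-mean downsampling such that the larger dimension does not
#' exceed `max_dim`.
#'
#' @param slide a `wsi_slide`.
#' @param max_dim maximum thumbnail dimension in pixels.
#' @param gray return a grayscale matrix (default) or an RGB array.
#' @return list with `image` and the integer `factor` (level-0 px per thumb px).
#' @export
slide_thumbnail <- function(slide, max_dim = 2048, gray = TRUE) {
  f <- max(1L, as.integer(ceiling(max(slide$width, slide$height) / max_dim)))
  img <- slide_pixels(slide)
  thumb <- block_mean_rgb(img, f)
  list(image = if (gray) rgb_to_gray(thumb) else thumb, factor = f)
}

#' Open a slide from disk
#'
#' @param path TIFF path.
#' @param slide_id identifier (default: file name without extension).
#' @param scan_magnification nominal scan power, usually from the manifest.
#' @return a `wsi_slide`.
#' @export
open_slide <- function(path, slide_id = sub("\\.[^.]+$", "", basename(path)),
                       scan_magnification = 20) {
  wsi_slide(slide_id, path = path, scan_magnification = scan_magnification)
}

# ---- manifest -------------------------------------------------------------

manifest_columns <- c("slide_id", "path", "cytology_class", "split")

#' Read a slide manifest CSV
#'
#' Columns: slide_id, path, cytology_class (I-V), split (train/validation/test).
#' A derived `binary_label` column (negative for I-II, neoplastic for III-V)
#' is appended.
#'
#' @param path CSV path.
#' @return data.frame of slide records.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(manifest_columns, names(m))
  if (length(missing)) stopf("manifest missing column(s): %s", paste(missing, collapse = ", "))
  m$cytology_class <- as.character(m$cytology_class)
  bad <- setdiff(unique(m$cytology_class), cytology_classes())
  if (length(bad)) stopf("manifest has unknown cytology class(es): %s", paste(bad, collapse = ", "))
  m$binary_label <- vapply(m$cytology_class, binary_label, character(1))
  m
}

#' Write a slide manifest CSV
#' @param manifest data.frame with the manifest columns.
#' @param path output CSV path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest[, manifest_columns], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
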