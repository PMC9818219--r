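# Tissue masking and the stride-lattice tile geometry.
#
# Conventions (used everywhere downstream):
#  * all anchors live in the 0-based, half-open level-0 pixel frame;
#  * tile_size and stride are working-magnification lengths; their level-0
#    footprints are scaled by scan_magnification / working_magnification
#    (factor 2 for x20 scans screened at x10);
#  * the rightmost/bottom partial lattice positions are kept and padded with
#    white, so marginal cells remain screenable.

#' Otsu threshold from a 256-bin grayscale histogram
#'
#' Returns the threshold t in 1..255 maximising the between-class variance of
#' the split \{values < t\} vs \{values >= t\}; foreground is the darker class
#' (cells are darker than the bright LBC background). Ties are broken by the
#' lowest maximising threshold.
#'
#' @param histogram integer vector of length 256 (counts of values 0..255).
#' @return threshold in 1..255.
#' @export
otsu_threshold <- function(histogram) {
  if (length(histogram) != 256) stopf("histogram must have 256 bins")
  total <- sum(histogram)
  if (total <= 0) stopf("histogram is empty")
  if (sum(histogram > 0) < 2) {
    stopf("degenerate histogram: all mass at a single intensity")
  }
  p <- histogram / total
  vals <- 0:255
  w0 <- cumsum(p)                    # w0[t] = P(value <= t-1) = P(value < t)
  m0 <- cumsum(p * vals)
  mt <- m0[256]
  # between-class variance for thresholds t = 1..255 (index t of w0[1..255])
  w <- w0[1:255]
  m <- m0[1:255]
  sigma <- ifelse(w <= 0 | w >= 1, -Inf, (mt * w - m)^2 / (w * (1 - w)))
  which.max(sigma)  # lowest argmax; threshold value t, foreground = value < t
}

#' Build the tissue mask of a slide
#'
#' Computes Otsu's threshold on a grayscale thumbnail no larger than
#' `thumb_max_dim` and marks thumbnail cells strictly below the threshold as
#' tissue. A degenerate histogram (e.g. an all-white slide) yields an empty
#' mask with a warning.
#'
#' @param slide a [wsi_slide()].
#' @param thumb_max_dim maximum thumbnail dimension (default 2048).
#' @return a `tissue_mask`: list(grid, downsample_factor, threshold_used).
#' @export
detect_tissue <- function(slide, thumb_max_dim = 2048) {
  th <- slide_thumbnail(slide, thumb_max_dim, gray = TRUE)
  g <- round(clamp(th$image, 0, 255))
  hist256 <- tabulate(as.integer(g) + 1L, nbins = 256L)
  thr <- tryCatch(otsu_threshold(hist256), error = function(e) NA_integer_)
  if (is.na(thr)) {
    warnf("slide '%s': degenerate grayscale histogram; returning empty tissue mask",
          slide$slide_id)
    grid <- matrix(FALSE, nrow(g), ncol(g))
  } else {
    grid <- g < thr
  }
  structure(list(grid = grid, downsample_factor = th$factor,
                 threshold_used = thr, slide_id = slide$slide_id),
            class = "tissue_mask")
}

#' Export a tissue mask as a TIFF image for inspection
#' @param mask a `tissue_mask`.
#' @param path output TIFF path.
#' @export
write_mask <- function(mask, path) {
  write_tiff(matrix(ifelse(mask$grid, 255, 0), nrow(mask$grid)), path)
}

# lattice positions along one axis: full-fit anchors plus one padded edge
# anchor when the extent is not covered; extent < span yields the single
# padded anchor 0.
lattice_axis <- function(extent, span, stride) {
  if (extent <= 0) return(integer(0))
  if (extent < span) return(0)
  n <- floor((extent - span) / stride) + 1
  anchors <- (seq_len(n) - 1) * stride
  if (anchors[n] + span < extent) anchors <- c(anchors, n * stride)
  anchors
}

# tissue fraction under a level-0 footprint, measured at mask resolution;
# area outside the slide counts as non-tissue.
footprint_tissue_fraction <- function(mask, x, y, span) {
  f <- mask$downsample_factor
  g <- mask$grid
  r0 <- max(1L, floor(y / f) + 1L); r1 <- min(nrow(g), ceiling((y + span) / f))
  c0 <- max(1L, floor(x / f) + 1L); c1 <- min(ncol(g), ceiling((x + span) / f))
  if (r0 > r1 || c0 > c1) return(0)
  n_cells <- (span / f)^2  # footprint area in mask cells, incl. out-of-bounds
  sum(g[r0:r1, c0:c1]) / n_cells
}

#' Enumerate the tissue-restricted tile grid of a slide
#'
#' Anchors are enumerated row-major over the stride lattice; an anchor is
#' retained iff the tissue fraction under its level-0 footprint is at least
#' `min_tissue_fraction`.
#'
#' @param slide a [wsi_slide()].
#' @param mask a `tissue_mask` from [detect_tissue()].
#' @param tile_size tile side at working magnification (default 1024 px).
#' @param stride stride at working magnification (default 512 px, half tile).
#' @param min_tissue_fraction retention rule (default 0.05).
#' @param working_magnification working power (default 10).
#' @return a `tile_grid`: retained `anchors` (x, y, row, col), full lattice
#'   dimensions, spans, and the retention mask.
#' @export
build_tile_grid <- function(slide, mask, tile_size = 1024, stride = 512,
                            min_tissue_fraction = 0.05,
                            working_magnification = 10) {
  if (stride > tile_size) stopf("stride (%d) must not exceed tile size (%d)", stride, tile_size)
  scale <- slide$scan_magnification / working_magnification
  if (scale < 1) stopf("working magnification above scan magnification is not supported")
  span <- as.integer(round(tile_size * scale))
  sspan <- as.integer(round(stride * scale))
  xs <- lattice_axis(slide$width, span, sspan)
  ys <- lattice_axis(slide$height, span, sspan)
  keep <- matrix(FALSE, length(ys), length(xs))
  for (r in seq_along(ys)) {
    for (c in seq_along(xs)) {
      keep[r, c] <- footprint_tissue_fraction(mask, xs[c], ys[r], span) >= min_tissue_fraction
    }
  }
  idx <- which(t(keep))  # row-major enumeration
  cols <- (idx - 1L) %% length(xs) + 1L
  rows <- (idx - 1L) %/% length(xs) + 1L
  anchors <- data.frame(x = xs[cols], y = ys[rows], row = rows, col = cols)
  structure(list(
    slide_id = slide$slide_id, anchors = anchors, keep = keep,
    lattice_x = xs, lattice_y = ys,
    tile_size_px = tile_size, stride_px = stride,
    tile_span = span, stride_span = sspan,
    working_magnification = working_magnification
  ), class = "tile_grid")
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("<tile_grid '%s': %d/%d anchors retained, tile %d px @ x%g, stride %d px>\n",
              x$slide_id, nrow(x$anchors), length(x$lattice_x) * length(x$lattice_y),
              x$tile_size_px, x$working_magnification, x$stride_px))
  invisible(x)
}

#' Read one tile at the working magnification
#'
#' Reads a level-0 window of side `tile_size * scan/working` at the anchor and
#' block-averages it down to `tile_size` (factor 2 for x20 scans read at x10).
#' Area beyond the slide edge is padded with white (255).
#'
#' @param slide a [wsi_slide()].
#' @param x,y 0-based level-0 anchor.
#' @param tile_size tile side at working magnification.
#' @param working_magnification working power (default 10).
#' @return a `tile_size` x `tile_size` x 3 numeric array (0-255).
#' @export
read_tile <- function(slide, x, y, tile_size = 1024, working_magnification = 10) {
  scale <- slide$scan_magnification / working_magnification
  span <- as.integer(round(tile_size * scale))
  region <- read_region(slide, x, y, span, span)
  f <- span / tile_size
  if (f != as.integer(f)) stopf("non-integer resampling factor %.3f", f)
  block_mean_rgb(region, as.integer(f))
}
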