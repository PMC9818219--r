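# Sliding-window inference: per-anchor probability heatmaps, max-probability
# slide scoring, and jet-colormap overlays.
#
# Each lattice cell stores the probability of the tile anchored there; tiles
# overlap at stride = half tile but no blending is performed -- the heatmap is
# a grid of per-anchor values. Positions filtered out by the tissue rule hold
# NA, the "no cells here" sentinel, which is distinct from a confidently
# negative 0.

release_slide <- function(slide) {
  # drop the pixel cache of file-backed slides so cohorts larger than memory
  # stream from disk; in-memory slides keep their array
  if (!is.null(slide$path)) rm(list = ls(slide$cache), envir = slide$cache)
  invisible(slide)
}

read_grid_tiles <- function(slide, grid, rows = seq_len(nrow(grid$anchors))) {
  lapply(rows, function(i) {
    read_tile(slide, grid$anchors$x[i], grid$anchors$y[i],
              grid$tile_size_px, grid$working_magnification)
  })
}

#' Sliding-window heatmap of a slide
#'
#' Runs one forward pass per retained anchor of the tile grid and assembles
#' the per-anchor probabilities on the stride lattice.
#'
#' @param slide a [wsi_slide()].
#' @param model a tile classifier (see [predict_tiles()]).
#' @param grid a `tile_grid` from [build_tile_grid()].
#' @param batch_size tiles per forward batch.
#' @return a `heatmap_grid`: probability matrix (lattice rows x cols, NA for
#'   non-tissue cells) plus stride/tile/magnification metadata.
#' @export
predict_heatmap <- function(slide, model, grid, batch_size = 32) {
  if (!is.null(model$input_size) && model$input_size != grid$tile_size_px) {
    stopf("model input size (%d) does not match grid tile size (%d)",
          model$input_size, grid$tile_size_px)
  }
  values <- matrix(NA_real_, length(grid$lattice_y), length(grid$lattice_x))
  n <- nrow(grid$anchors)
  i <- 1L
  while (i <= n) {
    rows <- i:min(n, i + batch_size - 1L)
    tiles <- read_grid_tiles(slide, grid, rows)
    probs <- predict_tiles(model, tiles)
    values[cbind(grid$anchors$row[rows], grid$anchors$col[rows])] <- probs
    i <- i + batch_size
  }
  release_slide(slide)
  structure(list(values = values, slide_id = slide$slide_id,
                 stride_px = grid$stride_px, tile_size_px = grid$tile_size_px,
                 stride_span = grid$stride_span, tile_span = grid$tile_span,
                 working_magnification = grid$working_magnification,
                 n_tiles_evaluated = n),
            class = "heatmap_grid")
}

#' @export
print.heatmap_grid <- function(x, ...) {
  cat(sprintf("<heatmap_grid '%s' %dx%d cells, %d evaluated, max %.3f>\n",
              x$slide_id, nrow(x$values), ncol(x$values), x$n_tiles_evaluated,
              suppressWarnings(wsi_score(x))))
  invisible(x)
}

#' Slide-level score: maximum tile probability
#'
#' An all-sentinel heatmap (no tissue evaluated) scores 0 with a warning.
#'
#' @param heatmap a `heatmap_grid`.
#' @return probability in [0,1].
#' @export
wsi_score <- function(heatmap) {
  v <- heatmap$values
  if (all(is.na(v))) {
    warnf("slide '%s': empty heatmap, score 0", heatmap$slide_id)
    return(0)
  }
  max(v, na.rm = TRUE)
}

#' Predict one slide end to end
#'
#' Convenience wrapper: tissue mask, tile grid, heatmap, max score.
#'
#' @param slide a [wsi_slide()].
#' @param model a tile classifier.
#' @param tile_size,stride,working_magnification,min_tissue_fraction tiling
#'   parameters (see [build_tile_grid()]).
#' @return list(slide_id, score, heatmap, n_tiles_evaluated).
#' @export
predict_slide <- function(slide, model, tile_size = 1024, stride = 512,
                          working_magnification = 10, min_tissue_fraction = 0.05) {
  mask <- detect_tissue(slide)
  grid <- build_tile_grid(slide, mask, tile_size, stride,
                          min_tissue_fraction, working_magnification)
  hm <- predict_heatmap(slide, model, grid)
  list(slide_id = slide$slide_id, score = suppressWarnings(wsi_score(hm)),
       heatmap = hm, n_tiles_evaluated = hm$n_tiles_evaluated)
}

# jet colormap: blue (0) -> cyan -> yellow -> red (1); returns n x 3 in 0-255
jet_colors <- function(p) {
  r <- clamp(1.5 - abs(4 * p - 3), 0, 1)
  g <- clamp(1.5 - abs(4 * p - 2), 0, 1)
  b <- clamp(1.5 - abs(4 * p - 1), 0, 1)
  cbind(r, g, b) * 255
}

#' Render a heatmap overlay on a slide thumbnail
#'
#' The heatmap is upsampled to the thumbnail scale (each lattice cell paints
#' the stride-sized block at its anchor), colour-mapped with the jet map
#' (blue = low, red = high probability) and alpha-blended; sentinel cells are
#' left transparent.
#'
#' @param heatmap a `heatmap_grid`.
#' @param thumbnail list(image, factor) from [slide_thumbnail()] with
#'   `gray = FALSE`, taken from the same slide.
#' @param slide_id id of the thumbnail's slide, checked against the heatmap.
#' @param alpha blend weight of the heatmap colour in [0,1].
#' @return RGB array with the thumbnail's dimensions.
#' @export
render_overlay <- function(heatmap, thumbnail, slide_id = heatmap$slide_id,
                           alpha = 0.5) {
  if (!identical(slide_id, heatmap$slide_id)) {
    stopf("thumbnail slide '%s' does not match heatmap slide '%s'",
          slide_id, heatmap$slide_id)
  }
  thumb <- thumbnail$image
  if (length(dim(thumb)) == 2L) thumb <- array(rep(thumb, 3), c(dim(thumb), 3L))
  h <- dim(thumb)[1]; w <- dim(thumb)[2]
  f <- thumbnail$factor
  # thumbnail pixel centre -> lattice cell holding its anchor block
  row_of <- pmin(nrow(heatmap$values),
                 ((seq_len(h) - 0.5) * f) %/% heatmap$stride_span + 1)
  col_of <- pmin(ncol(heatmap$values),
                 ((seq_len(w) - 0.5) * f) %/% heatmap$stride_span + 1)
  pv <- heatmap$values[cbind(rep(row_of, times = w), rep(col_of, each = h))]
  keep <- !is.na(pv)
  cols <- jet_colors(ifelse(keep, pv, 0))
  out <- thumb
  a <- alpha * keep
  for (c in 1:3) out[, , c] <- thumb[, , c] * (1 - a) + matrix(cols[, c], h, w) * a
  out
}

#' Serialise a heatmap: values as CSV plus a JSON sidecar
#' @param heatmap a `heatmap_grid`.
#' @param prefix output path prefix; writes `<prefix>.csv` and `<prefix>.json`.
#' @export
write_heatmap <- function(heatmap, prefix) {
  utils::write.table(heatmap$values, paste0(prefix, ".csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE, na = "")
  meta <- heatmap[c("slide_id", "stride_px", "tile_size_px", "stride_span",
                    "tile_span", "working_magnification", "n_tiles_evaluated")]
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE)
  invisible(prefix)
}

#' Read a serialised heatmap
#' @param prefix path prefix used by [write_heatmap()].
#' @return a `heatmap_grid`.
#' @export
read_heatmap <- function(prefix) {
  values <- as.matrix(utils::read.csv(paste0(prefix, ".csv"), header = FALSE))
  dimnames(values) <- NULL
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  structure(c(list(values = values), meta), class = "heatmap_grid")
}
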