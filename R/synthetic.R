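# Seed-reproducible synthetic LBC-like slides.
#
# The generator states the world every downstream stage is tested in:
# negative slides carry only small-nucleus urothelial cells, debris and
# crystals on a bright background; neoplastic slides additionally carry a few
# sparse clusters of enlarged, hyperchromatic, high-N/C-ratio cells occupying
# a small fraction of the slide (the multiple-instance premise: the signal is
# rare and local). Every neoplastic cell drawn gets exactly one enclosing
# annotation polygon; negative slides have empty annotation sets.

#' Configuration of one synthetic slide
#'
#' Defaults describe a 4096 px square canvas (a desk-scale stand-in for a
#' gigapixel scan) with a cell coverage and cluster sparsity typical of
#' liquid-based preparations. Radii are level-0 pixels at the nominal x20
#' scan magnification.
#'
#' @param width,height canvas size in pixels.
#' @param n_normal_cells number of benign urothelial cells.
#' @param n_neoplastic_clusters number of neoplastic cell clusters (0 for a
#'   negative slide).
#' @param cells_per_cluster inclusive integer range c(lo, hi).
#' @param normal_nucleus_radius,neoplastic_nucleus_radius radius ranges in
#'   pixels; the neoplastic range must lie strictly above the normal range
#'   (nuclear enlargement).
#' @param neoplastic_chromatin_darkening intensity offset 0-255 subtracted
#'   from the nuclear tone of neoplastic cells (hyperchromasia).
#' @param n_debris,n_crystals counts of non-cellular confusers.
#' @param background_intensity bright LBC background level, 0-255.
#' @param seed RNG seed; the whole slide is a pure function of the config.
#' @return a `synthetic_slide_config`.
#' @export
synthetic_slide_config <- function(width = 4096, height = 4096,
                                   n_normal_cells = 2000,
                                   n_neoplastic_clusters = 3,
                                   cells_per_cluster = c(4, 10),
                                   normal_nucleus_radius = c(5, 9),
                                   neoplastic_nucleus_radius = c(14, 22),
                                   neoplastic_chromatin_darkening = 70,
                                   n_debris = 40, n_crystals = 15,
                                   background_intensity = 235, seed = 1) {
  cfg <- list(width = width, height = height, n_normal_cells = n_normal_cells,
              n_neoplastic_clusters = n_neoplastic_clusters,
              cells_per_cluster = cells_per_cluster,
              normal_nucleus_radius = normal_nucleus_radius,
              neoplastic_nucleus_radius = neoplastic_nucleus_radius,
              neoplastic_chromatin_darkening = neoplastic_chromatin_darkening,
              n_debris = n_debris, n_crystals = n_crystals,
              background_intensity = background_intensity, seed = seed)
  counts <- c(n_normal_cells, n_neoplastic_clusters, n_debris, n_crystals)
  if (!all(vapply(counts, is_count, logical(1)))) stopf("all object counts must be non-negative integers")
  if (min(neoplastic_nucleus_radius) <= max(normal_nucleus_radius)) {
    stopf("neoplastic nucleus radius range must lie strictly above the normal range")
  }
  if (width < 2 * max(neoplastic_nucleus_radius) || height < 2 * max(neoplastic_nucleus_radius)) {
    stopf("canvas (%d x %d) smaller than twice the maximum nucleus radius", width, height)
  }
  structure(cfg, class = "synthetic_slide_config")
}

# Patch painters return linear pixel indices (into the H x W plane) plus
# per-pixel coverage in [0,1]; the caller composites them onto local arrays,
# which keeps the hot subassignments copy-free.

# anti-aliased rotated ellipse; (cx, cy) in the 0-based pixel frame
ellipse_patch <- function(cx, cy, a, b, theta, h, w) {
  r <- max(a, b) + 1
  rows <- max(1, floor(cy - r)):min(h, ceiling(cy + r) + 1)
  cols <- max(1, floor(cx - r)):min(w, ceiling(cx + r) + 1)
  if (!length(rows) || !length(cols)) return(NULL)
  dy <- (rows - 1) - cy
  dx <- (cols - 1) - cx
  U <- outer(dy, dx, function(y, x) (x * cos(theta) + y * sin(theta)))
  V <- outer(dy, dx, function(y, x) (-x * sin(theta) + y * cos(theta)))
  d <- sqrt((U / a)^2 + (V / b)^2)
  cov <- clamp((1 - d) * min(a, b) + 0.5, 0, 1)  # ~1 px soft edge
  keep <- which(cov > 0)
  li <- outer(rows, (cols - 1L) * h, "+")
  list(li = li[keep], cov = cov[keep])
}

# flat-filled simple polygon (debris/crystals); even-odd rule per pixel centre
polygon_patch <- function(v, h, w) {
  rows <- max(1, floor(min(v[, 2]))):min(h, ceiling(max(v[, 2])) + 1)
  cols <- max(1, floor(min(v[, 1]))):min(w, ceiling(max(v[, 1])) + 1)
  if (!length(rows) || !length(cols)) return(NULL)
  py <- rows - 1; px <- cols - 1
  inside <- matrix(FALSE, length(rows), length(cols))
  n <- nrow(v)
  for (i in seq_len(n)) {
    j <- if (i == 1) n else i - 1
    x1 <- v[i, 1]; y1 <- v[i, 2]; x2 <- v[j, 1]; y2 <- v[j, 2]
    if (y1 == y2) next
    cross_y <- matrix(py, length(py), length(px))
    hit <- ((y1 > cross_y) != (y2 > cross_y))
    xint <- (x2 - x1) * (cross_y - y1) / (y2 - y1) + x1
    inside <- xor(inside, hit & matrix(px, length(py), length(px), byrow = TRUE) < xint)
  }
  keep <- which(inside)
  if (!length(keep)) return(NULL)
  li <- outer(rows, (cols - 1L) * h, "+")
  list(li = li[keep], cov = rep(1, length(keep)))
}

jitter_color <- function(base, sd = 6) clamp(base + stats::rnorm(3, 0, sd), 0, 255)

# patches + colours for one cell (cytoplasm disk below an eccentric nucleus)
cell_patches <- function(cx, cy, nucleus_r, neoplastic, darkening, h, w) {
  if (neoplastic) {
    ecc <- stats::runif(1, 1.1, 1.4)
    cyto_r <- nucleus_r * stats::runif(1, 1.25, 1.5)   # high N/C ratio
    ncol_base <- c(95, 75, 130) - darkening            # hyperchromatic
  } else {
    ecc <- stats::runif(1, 1.0, 1.15)
    cyto_r <- nucleus_r * stats::runif(1, 1.9, 2.5)
    ncol_base <- c(95, 75, 130)
  }
  theta <- stats::runif(1, 0, pi)
  cyto <- ellipse_patch(cx, cy, cyto_r, cyto_r * stats::runif(1, 0.85, 1),
                        stats::runif(1, 0, pi), h, w)
  cyto_col <- jitter_color(c(162, 155, 178))
  nuc <- ellipse_patch(cx, cy, nucleus_r * ecc, nucleus_r / ecc, theta, h, w)
  nuc_col <- jitter_color(clamp(ncol_base, 0, 255))
  list(cyto = cyto, cyto_col = cyto_col, nuc = nuc, nuc_col = nuc_col,
       a = nucleus_r * ecc, b = nucleus_r / ecc, theta = theta)
}

# enclosing annotation ring: ellipse outline with a small margin
cell_annotation_ring <- function(cx, cy, a, b, theta, margin = 1.35, n = 14) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  u <- a * margin * cos(t); v <- b * margin * sin(t)
  cbind(cx + u * cos(theta) - v * sin(theta),
        cy + u * sin(theta) + v * cos(theta))
}

#' Generate one synthetic slide
#'
#' Deterministic given the config (same config, same seed: bit-identical
#' pixels). Objects may overlap, mimicking overlapping cellular morphology.
#'
#' @param config a [synthetic_slide_config()].
#' @param slide_id identifier for the bundle's record.
#' @param cytology_class reporting class for the record; defaults to "I" for
#'   negative and "III" for neoplastic configs.
#' @param split split assignment recorded in the bundle.
#' @return a `synthetic_bundle`: list(image, annotations, record, truth_mask,
#'   nucleus_mask, clusters).
#' @export
generate_slide <- function(config, slide_id = "synthetic",
                           cytology_class = NULL, split = "train") {
  cfg <- config
  neoplastic <- cfg$n_neoplastic_clusters > 0
  if (is.null(cytology_class)) cytology_class <- if (neoplastic) "III" else "I"
  if (binary_label(cytology_class) != (if (neoplastic) "neoplastic" else "negative")) {
    stopf("cytology class %s inconsistent with %d neoplastic cluster(s)",
          cytology_class, cfg$n_neoplastic_clusters)
  }
  with_seed(cfg$seed, {
    h <- cfg$height; w <- cfg$width; npix <- h * w
    noise <- stats::rnorm(npix, 0, 2)
    img <- array(cfg$background_intensity + noise, dim = c(h, w, 3L))
    fg_mask <- logical(npix)
    nuc_mask <- logical(npix)
    # all subassignments below stay in this frame so the big arrays are
    # modified in place (no copy per object)
    margin <- max(cfg$neoplastic_nucleus_radius) * 2
    rxy <- function(n) cbind(stats::runif(n, margin, cfg$width - margin),
                             stats::runif(n, margin, cfg$height - margin))
    # debris: irregular dark brown blobs; crystals: angular gray-blue shards
    # (both are false-positive bait for the classifier)
    n_poly <- cfg$n_debris + cfg$n_crystals
    for (p in seq_len(n_poly)) {
      debris <- p <= cfg$n_debris
      c0 <- rxy(1)
      k <- if (debris) sample(5:9, 1) else sample(3:5, 1)
      ang <- sort(stats::runif(k, 0, 2 * pi))
      rad <- if (debris) stats::runif(1, 4, 14) * stats::runif(k, 0.5, 1.3)
             else stats::runif(1, 5, 16) * stats::runif(k, 0.4, 1.2)
      col <- if (debris) jitter_color(c(120, 100, 80), 10)
             else jitter_color(c(150, 150, 165), 8)
      pt <- polygon_patch(cbind(c0[1] + rad * cos(ang), c0[2] + rad * sin(ang)), h, w)
      if (is.null(pt)) next
      for (ch in 1:3) {
        o <- pt$li + (ch - 1L) * npix
        img[o] <- img[o] * (1 - pt$cov) + col[ch] * pt$cov
      }
      fg_mask[pt$li[pt$cov > 0.5]] <- TRUE
    }
    polygons <- list()
    clusters <- data.frame(x = numeric(0), y = numeric(0), spread = numeric(0))
    labels <- annotation_labels()
    normal_centers <- if (cfg$n_normal_cells > 0) rxy(cfg$n_normal_cells) else NULL
    cell_i <- 0L
    cell_queue <- list()
    for (i in seq_len(cfg$n_normal_cells)) {
      r <- stats::runif(1, cfg$normal_nucleus_radius[1], cfg$normal_nucleus_radius[2])
      cell_queue[[length(cell_queue) + 1L]] <-
        cell_patches(normal_centers[i, 1], normal_centers[i, 2], r, FALSE, 0, h, w)
    }
    if (neoplastic) {
      for (cl in seq_len(cfg$n_neoplastic_clusters)) {
        c0 <- rxy(1)
        n_cells <- cfg$cells_per_cluster[1] +
          sample.int(cfg$cells_per_cluster[2] - cfg$cells_per_cluster[1] + 1L, 1) - 1L
        spread <- mean(cfg$neoplastic_nucleus_radius) * 1.6
        clusters <- rbind(clusters, data.frame(x = c0[1], y = c0[2], spread = spread))
        for (j in seq_len(n_cells)) {
          cell_i <- cell_i + 1L
          cx <- clamp(c0[1] + stats::rnorm(1, 0, spread), margin / 2, cfg$width - margin / 2)
          cy <- clamp(c0[2] + stats::rnorm(1, 0, spread), margin / 2, cfg$height - margin / 2)
          r <- stats::runif(1, cfg$neoplastic_nucleus_radius[1],
                            cfg$neoplastic_nucleus_radius[2])
          geom <- cell_patches(cx, cy, r, TRUE, cfg$neoplastic_chromatin_darkening, h, w)
          cell_queue[[length(cell_queue) + 1L]] <- geom
          ring <- cell_annotation_ring(cx, cy, geom$a, geom$b, geom$theta)
          polygons[[length(polygons) + 1L]] <-
            annotation_polygon(labels[(cell_i - 1L) %% 3L + 1L], ring)
        }
      }
    }
    for (cell in cell_queue) {
      for (part in c("cyto", "nuc")) {
        pt <- cell[[part]]
        if (is.null(pt)) next
        col <- cell[[paste0(part, "_col")]]
        for (ch in 1:3) {
          o <- pt$li + (ch - 1L) * npix
          img[o] <- img[o] * (1 - pt$cov) + col[ch] * pt$cov
        }
        hard <- pt$li[pt$cov > 0.5]
        fg_mask[hard] <- TRUE
        if (part == "nuc") nuc_mask[hard] <- TRUE
      }
    }
    image <- array(as.integer(round(clamp(img, 0, 255))), dim = c(h, w, 3L))
    record <- data.frame(slide_id = slide_id, path = NA_character_,
                         cytology_class = cytology_class, split = split,
                         binary_label = binary_label(cytology_class),
                         stringsAsFactors = FALSE)
    structure(list(image = image, annotations = annotation_set(slide_id, polygons),
                   record = record, truth_mask = matrix(fg_mask, h, w),
                   nucleus_mask = matrix(nuc_mask, h, w), clusters = clusters,
                   config = cfg),
              class = "synthetic_bundle")
  })
}

#' Generate a cohort of synthetic slides with a manifest
#'
#' Per-slide seeds are `seed + slide index` (1-based over the whole cohort),
#' so cohorts are reproducible and individual slides re-generable in
#' isolation. Negative slides take cytology classes I/II round-robin and
#' neoplastic slides III/IV/V round-robin. When `out_dir` is given, slide
#' TIFFs, per-slide GeoJSON annotation files and `manifest.csv` are written
#' and the returned bundles drop their pixel arrays (the disk copy is
#' authoritative); otherwise full in-memory bundles are returned.
#'
#' @param n_negative,n_neoplastic slide counts.
#' @param base_config a [synthetic_slide_config()]; per-slide seed and cluster
#'   count are overridden.
#' @param seed cohort seed.
#' @param split split label recorded for every slide (default "train").
#' @param out_dir optional output directory.
#' @param id_prefix prefix for slide ids.
#' @return list(bundles, manifest).
#' @export
generate_cohort <- function(n_negative, n_neoplastic,
                            base_config = synthetic_slide_config(),
                            seed = 1, split = "train", out_dir = NULL,
                            id_prefix = "syn") {
  if (!is_count(n_negative) || !is_count(n_neoplastic)) stopf("cohort counts must be non-negative integers")
  neg_classes <- c("I", "II"); neo_classes <- c("III", "IV", "V")
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "slides"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(out_dir, "annotations"), recursive = TRUE, showWarnings = FALSE)
  }
  n_total <- n_negative + n_neoplastic
  bundles <- vector("list", n_total)
  rows <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    negative <- i <= n_negative
    j <- if (negative) i else i - n_negative
    cfg <- base_config
    cfg$seed <- seed + i
    if (negative) cfg$n_neoplastic_clusters <- 0L
    cls <- if (negative) neg_classes[(j - 1L) %% 2L + 1L] else neo_classes[(j - 1L) %% 3L + 1L]
    sid <- sprintf("%s_%s_%03d", id_prefix, if (negative) "neg" else "neo", j)
    b <- generate_slide(cfg, slide_id = sid, cytology_class = cls, split = split)
    path <- NA_character_
    if (!is.null(out_dir)) {
      path <- file.path("slides", paste0(sid, ".tiff"))
      write_tiff(b$image, file.path(out_dir, path))
      write_annotations(b$annotations, file.path(out_dir, "annotations", paste0(sid, ".geojson")))
      b$image <- NULL; b$truth_mask <- NULL; b$nucleus_mask <- NULL
    }
    b$record$path <- path
    bundles[[i]] <- b
    rows[[i]] <- b$record
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir)) write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  list(bundles = bundles, manifest = manifest)
}
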