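# Cytology class system, neoplastic annotation labels, and the tile
# positivity rule that drives fully supervised sampling.
#
# Papanicolaou-style reporting classes I-V collapse to a binary slide label:
# I-II negative, III-V neoplastic. Annotated neoplastic cells carry one of
# three labels (atypical / LGUC / HGUC cell); all three group to the single
# "neoplastic" training label, so per-label distinctions stay metadata.

#' The closed set of cytology classes
#' @return character vector `c("I","II","III","IV","V")`.
#' @export
cytology_classes <- function() c("I", "II", "III", "IV", "V")

#' The closed set of annotation labels
#' @return character vector of the three neoplastic cell labels.
#' @export
annotation_labels <- function() c("atypical_cell", "lguc_cell", "hguc_cell")

#' Binary slide label from a cytology class
#'
#' Classes I and II map to "negative"; III, IV and V to "neoplastic".
#'
#' @param cls a single class token, one of "I".."V".
#' @return "negative" or "neoplastic".
#' @export
binary_label <- function(cls) {
  if (length(cls) != 1 || !cls %in% cytology_classes()) {
    stopf("unknown cytology class token: '%s'", paste(cls, collapse = ","))
  }
  if (cls %in% c("I", "II")) "negative" else "neoplastic"
}

#' Does an annotation label belong to the grouped neoplastic label?
#'
#' All three cell labels (atypical, LGUC, HGUC) group to neoplastic for
#' fully supervised learning.
#'
#' @param label annotation label token.
#' @return TRUE for every valid label.
#' @export
group_to_neoplastic <- function(label) {
  if (!label %in% annotation_labels()) stopf("unknown annotation label: '%s'", label)
  TRUE
}

#' Construct an annotation polygon
#'
#' @param label one of [annotation_labels()].
#' @param vertices n x 2 matrix of level-0 (x, y) coordinates, open ring,
#'   n >= 3.
#' @return an `annotation_polygon`.
#' @export
annotation_polygon <- function(label, vertices) {
  if (!label %in% annotation_labels()) stopf("unknown annotation label: '%s'", label)
  vertices <- as.matrix(vertices)
  # drop an explicitly closed ring's repeated last vertex
  n <- nrow(vertices)
  if (n >= 2 && all(vertices[1, ] == vertices[n, ])) vertices <- vertices[-n, , drop = FALSE]
  if (nrow(vertices) < 3) stopf("annotation polygon needs >= 3 distinct vertices")
  structure(list(label = label, vertices = unname(vertices)), class = "annotation_polygon")
}

#' Construct an annotation set for one slide
#' @param slide_id slide identifier.
#' @param polygons list of [annotation_polygon()] objects (may be empty).
#' @return an `annotation_set`.
#' @export
annotation_set <- function(slide_id, polygons = list()) {
  structure(list(slide_id = slide_id, polygons = polygons), class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set '%s': %d polygon(s)>\n", x$slide_id, length(x$polygons)))
  invisible(x)
}

# Sutherland-Hodgman clip of a polygon against an axis-aligned rectangle
# [x0,x1) x [y0,y1). The clip window is convex, which is all S-H requires;
# the subject polygon may be concave.
clip_polygon_rect <- function(v, x0, y0, x1, y1) {
  clip_edge <- function(v, inside, intersect) {
    if (nrow(v) == 0) return(v)
    out <- matrix(numeric(0), ncol = 2)
    n <- nrow(v)
    for (i in seq_len(n)) {
      cur <- v[i, ]; prev <- v[if (i == 1) n else i - 1, ]
      cin <- inside(cur); pin <- inside(prev)
      if (cin) {
        if (!pin) out <- rbind(out, intersect(prev, cur))
        out <- rbind(out, cur)
      } else if (pin) {
        out <- rbind(out, intersect(prev, cur))
      }
    }
    out
  }
  ix <- function(p, q, t) p + t * (q - p)
  v <- clip_edge(v, function(p) p[1] >= x0,
                 function(p, q) ix(p, q, (x0 - p[1]) / (q[1] - p[1])))
  v <- clip_edge(v, function(p) p[1] <= x1,
                 function(p, q) ix(p, q, (x1 - p[1]) / (q[1] - p[1])))
  v <- clip_edge(v, function(p) p[2] >= y0,
                 function(p, q) ix(p, q, (y0 - p[2]) / (q[2] - p[2])))
  v <- clip_edge(v, function(p) p[2] <= y1,
                 function(p, q) ix(p, q, (y1 - p[2]) / (q[2] - p[2])))
  v
}

#' Is a tile positive under an annotation set?
#'
#' A tile is positive iff at least one annotation polygon intersects the
#' half-open tile rectangle `[x, x+span) x [y, y+span)` with positive area --
#' the operational reading of "an annotated cell is visible anywhere inside
#' the tile". Degenerate (zero-area) polygons are skipped with a warning.
#'
#' @param x,y 0-based level-0 anchor of the tile.
#' @param span tile footprint side length in level-0 pixels.
#' @param annotations an [annotation_set()].
#' @return logical.
#' @export
tile_is_positive <- function(x, y, span, annotations) {
  for (poly in annotations$polygons) {
    v <- poly$vertices
    if (polygon_area(v) <= 1e-9) {
      warnf("skipping degenerate annotation polygon on slide '%s'", annotations$slide_id)
      next
    }
    # quick reject on bounding boxes
    if (max(v[, 1]) <= x || min(v[, 1]) >= x + span ||
        max(v[, 2]) <= y || min(v[, 2]) >= y + span) next
    clipped <- clip_polygon_rect(v, x, y, x + span, y + span)
    if (polygon_area(clipped) > 1e-9) return(TRUE)
  }
  FALSE
}

# ---- GeoJSON dialect ------------------------------------------------------
# One FeatureCollection per slide; Feature geometry is a Polygon whose
# coordinates are level-0 pixel units (not lon/lat); properties$label carries
# the annotation label.

#' Write an annotation set as GeoJSON
#' @param set an [annotation_set()].
#' @param path output file (conventionally `<slide_id>.geojson`).
#' @export
write_annotations <- function(set, path) {
  features <- lapply(set$polygons, function(p) {
    ring <- rbind(p$vertices, p$vertices[1, ])  # closed ring on disk
    list(
      type = "Feature",
      geometry = list(type = "Polygon",
                      coordinates = list(lapply(seq_len(nrow(ring)),
                                                function(i) ring[i, ]))),
      properties = list(label = p$label)
    )
  })
  obj <- list(type = "FeatureCollection", slide_id = set$slide_id, features = features)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an annotation set from GeoJSON
#' @param path GeoJSON file path.
#' @param slide_id identifier; defaults to the file's `slide_id` field or the
#'   file name.
#' @return an [annotation_set()].
#' @export
read_annotations <- function(path, slide_id = NULL) {
  obj <- tryCatch(jsonlite::read_json(path), error = function(e) {
    stopf("malformed annotation JSON '%s': %s", path, conditionMessage(e))
  })
  if (is.null(slide_id)) {
    slide_id <- obj$slide_id %||% sub("\\.[^.]+$", "", basename(path))
  }
  polys <- lapply(obj$features, function(f) {
    label <- f$properties$label
    if (is.null(label) || !label %in% annotation_labels()) {
      stopf("annotation schema error in '%s': unknown label '%s'", path,
            if (is.null(label)) "<missing>" else label)
    }
    ring <- f$geometry$coordinates[[1]]
    v <- do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    annotation_polygon(label, v)
  })
  annotation_set(slide_id, polys)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
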