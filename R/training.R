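# Training regimes over a pluggable tile classifier.
#
# Fully supervised (FS): class-balanced interleaved batches -- positives
# sampled uniformly from tiles of annotated neoplastic slides that show at
# least one annotated cell, negatives sampled from negative slides with
# per-anchor weights that are refreshed by false-positive hard mining at the
# end of every epoch.
#
# Weakly supervised (WS): only slide labels are used. Slides are visited in a
# seeded random permutation each epoch; per slide, sliding-window inference
# selects the k highest-probability tiles, which inherit the slide label and
# are pushed to a fixed-capacity buffer; whenever the buffer reaches N tiles
# it is shuffled, consumed in gradient batches, and cleared. On negative
# slides this is exactly hard negative mining; on neoplastic slides it
# focuses training on the tiles most likely to carry the sparse signal.

#' Training configuration
#'
#' Defaults follow the screening pipeline's published operating point:
#' k = 8 hard tiles per slide, buffer capacity N = 256, batch size 32,
#' Adam (beta1 0.9, beta2 0.999) at learning rate 0.001 decayed by 0.95
#' every 2 epochs, early stopping after 10 epochs without validation-loss
#' improvement, tiles of 1024 px screened at x10.
#'
#' @param tile_size tile side at working magnification (px).
#' @param stride sliding-window stride (px), default half the tile.
#' @param working_magnification working power.
#' @param batch_size gradient batch size (even).
#' @param k_top_tiles hard tiles selected per slide visit (WS).
#' @param buffer_capacity_N WS buffer capacity; must be a multiple of
#'   `batch_size` and at least `k_top_tiles`.
#' @param learning_rate,adam_beta1,adam_beta2 Adam settings.
#' @param lr_decay_factor,lr_decay_period_epochs step decay schedule.
#' @param early_stop_patience epochs without improvement before stopping.
#' @param max_epochs hard cap on epochs.
#' @param mode "FS", "WS" or "FS_then_WS".
#' @param init "random", "generic_pretrained" or "checkpoint".
#' @param min_tissue_fraction tile retention rule.
#' @param epsilon_hard_mining additive floor of the FS negative-sampling
#'   weight w proportional to epsilon + p.
#' @param augment apply photometric augmentation to FS batches.
#' @param brightness_range,saturation_range,contrast_range augmentation jitter.
#' @param seed run seed; all sampling derives from it.
#' @return a `train_config`.
#' @export
train_config <- function(tile_size = 1024, stride = tile_size / 2,
                         working_magnification = 10,
                         batch_size = 32, k_top_tiles = 8,
                         buffer_capacity_N = 256,
                         learning_rate = 0.001, adam_beta1 = 0.9,
                         adam_beta2 = 0.999, lr_decay_factor = 0.95,
                         lr_decay_period_epochs = 2, early_stop_patience = 10,
                         max_epochs = 100,
                         mode = c("WS", "FS", "FS_then_WS"),
                         init = c("random", "generic_pretrained", "checkpoint"),
                         min_tissue_fraction = 0.05,
                         epsilon_hard_mining = 0.01, augment = TRUE,
                         brightness_range = c(-20, 20),
                         saturation_range = c(0.8, 1.2),
                         contrast_range = c(0.8, 1.2), seed = 1) {
  mode <- match.arg(mode)
  init <- match.arg(init)
  if (batch_size %% 2 != 0) stopf("batch_size must be even (balanced FS batches)")
  if (k_top_tiles > buffer_capacity_N) stopf("k_top_tiles must not exceed buffer_capacity_N")
  if (buffer_capacity_N %% batch_size != 0) stopf("buffer_capacity_N must be divisible by batch_size")
  structure(list(tile_size = tile_size, stride = stride,
                 working_magnification = working_magnification,
                 batch_size = batch_size, k_top_tiles = k_top_tiles,
                 buffer_capacity_N = buffer_capacity_N,
                 learning_rate = learning_rate, adam_beta1 = adam_beta1,
                 adam_beta2 = adam_beta2, lr_decay_factor = lr_decay_factor,
                 lr_decay_period_epochs = lr_decay_period_epochs,
                 early_stop_patience = early_stop_patience,
                 max_epochs = max_epochs, mode = mode, init = init,
                 min_tissue_fraction = min_tissue_fraction,
                 epsilon_hard_mining = epsilon_hard_mining, augment = augment,
                 brightness_range = brightness_range,
                 saturation_range = saturation_range,
                 contrast_range = contrast_range, seed = seed),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' Step decay: `learning_rate * decay^floor(epoch / period)`.
#'
#' @param epoch 0-based epoch index.
#' @param config a [train_config()].
#' @return learning rate.
#' @export
lr_at_epoch <- function(epoch, config) {
  stopifnot(epoch >= 0)
  config$learning_rate *
    config$lr_decay_factor^floor(epoch / config$lr_decay_period_epochs)
}

#' Photometric tile augmentation
#'
#' Saturation scale, contrast scale and brightness offset are drawn uniformly
#' from the configured ranges and applied in that order; output is clipped to
#' [0, 255]. Zero-width ranges at (1, 1, 0) give the identity.
#'
#' @param tile H x W x 3 array, 0-255.
#' @param brightness_range,saturation_range,contrast_range jitter ranges.
#' @return augmented tile.
#' @export
augment_tile <- function(tile, brightness_range = c(-20, 20),
                         saturation_range = c(0.8, 1.2),
                         contrast_range = c(0.8, 1.2)) {
  s <- stats::runif(1, saturation_range[1], saturation_range[2])
  cs <- stats::runif(1, contrast_range[1], contrast_range[2])
  b <- stats::runif(1, brightness_range[1], brightness_range[2])
  gray <- rgb_to_gray(tile)
  out <- tile
  for (c in 1:3) {
    x <- gray + s * (tile[, , c] - gray)
    x <- (x - 128) * cs + 128
    out[, , c] <- x + b
  }
  clamp(out, 0, 255)
}

#' Select the k hardest (highest-probability) tiles of a heatmap
#'
#' Ties are broken by row-major anchor order; if fewer than `k` anchors were
#' evaluated, all are returned; an empty heatmap yields an empty selection
#' with a warning.
#'
#' @param heatmap a `heatmap_grid`.
#' @param k number of tiles.
#' @return data.frame(x, y, row, col, prob) of level-0 anchors.
#' @export
select_hard_tiles <- function(heatmap, k) {
  stopifnot(k >= 1)
  v <- heatmap$values
  nc <- ncol(v)
  rm_order <- as.vector(t(v))  # row-major flattening
  ok <- which(!is.na(rm_order))
  if (!length(ok)) {
    warnf("slide '%s': empty heatmap, no hard tiles", heatmap$slide_id)
    return(data.frame(x = integer(0), y = integer(0), row = integer(0),
                      col = integer(0), prob = numeric(0)))
  }
  sel <- ok[order(-rm_order[ok])][seq_len(min(k, length(ok)))]
  row <- (sel - 1L) %/% nc + 1L
  col <- (sel - 1L) %% nc + 1L
  data.frame(x = (col - 1L) * heatmap$stride_span,
             y = (row - 1L) * heatmap$stride_span,
             row = row, col = col, prob = rm_order[sel])
}

#' Hard-mining sampling weights over negative-slide anchors
#'
#' Weight of anchor i is proportional to `epsilon + p_i` (its current
#' false-positive probability), renormalised per slide, so confidently
#' negative regions keep a floor probability of being sampled.
#'
#' @param negative_heatmaps named list (slide_id -> `heatmap_grid`).
#' @param epsilon additive floor.
#' @return named list of data.frame(x, y, w) with w summing to 1 per slide.
#' @export
update_negative_weights <- function(negative_heatmaps, epsilon = 0.01) {
  out <- lapply(names(negative_heatmaps), function(sid) {
    hm <- negative_heatmaps[[sid]]
    v <- hm$values
    idx <- which(!is.na(v), arr.ind = TRUE)
    if (nrow(idx) == 0) {
      warnf("slide '%s': empty heatmap, no negative anchors to weight", sid)
      return(data.frame(x = integer(0), y = integer(0), w = numeric(0)))
    }
    w <- epsilon + v[idx]
    data.frame(x = (idx[, 2] - 1L) * hm$stride_span,
               y = (idx[, 1] - 1L) * hm$stride_span,
               w = w / sum(w))
  })
  stats::setNames(out, names(negative_heatmaps))
}

# ---- cohorts --------------------------------------------------------------

#' Assemble a cohort of slides, records and annotations
#'
#' @param records manifest-shaped data.frame (with `binary_label`).
#' @param slides named list of [wsi_slide()] objects keyed by slide_id.
#' @param annotations named list of [annotation_set()]s (negatives may be
#'   absent; they are given empty sets).
#' @return a `screening_cohort`.
#' @export
screening_cohort <- function(records, slides, annotations = list()) {
  stopifnot(all(records$slide_id %in% names(slides)))
  for (sid in records$slide_id) {
    if (is.null(annotations[[sid]])) annotations[[sid]] <- annotation_set(sid)
  }
  structure(list(records = records, slides = slides, annotations = annotations),
            class = "screening_cohort")
}

#' Load a cohort from a manifest directory
#'
#' Expects the layout written by [generate_cohort()]: slide paths relative to
#' `base_dir` and one optional `<slide_id>.geojson` per slide under
#' `annotations_dir`.
#'
#' @param manifest manifest data.frame or path to manifest.csv.
#' @param base_dir directory slide paths are relative to.
#' @param annotations_dir directory with GeoJSON files (default
#'   `base_dir/annotations`).
#' @param scan_magnification nominal scan power of the slides.
#' @return a `screening_cohort`.
#' @export
load_cohort <- function(manifest, base_dir,
                        annotations_dir = file.path(base_dir, "annotations"),
                        scan_magnification = 20) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  slides <- lapply(seq_len(nrow(manifest)), function(i) {
    wsi_slide(manifest$slide_id[i],
              path = file.path(base_dir, manifest$path[i]),
              scan_magnification = scan_magnification)
  })
  names(slides) <- manifest$slide_id
  anns <- list()
  for (sid in manifest$slide_id) {
    f <- file.path(annotations_dir, paste0(sid, ".geojson"))
    if (file.exists(f)) anns[[sid]] <- read_annotations(f, sid)
  }
  screening_cohort(manifest, slides, anns)
}

#' Cohort from in-memory synthetic bundles
#' @param bundles list of `synthetic_bundle`s holding pixel arrays.
#' @return a `screening_cohort`.
#' @export
cohort_from_bundles <- function(bundles) {
  records <- do.call(rbind, lapply(bundles, `[[`, "record"))
  slides <- lapply(bundles, function(b) wsi_slide(b$record$slide_id, image = b$image))
  names(slides) <- records$slide_id
  anns <- lapply(bundles, `[[`, "annotations")
  names(anns) <- records$slide_id
  screening_cohort(records, slides, anns)
}

cohort_subset <- function(cohort, split) {
  ids <- cohort$records$slide_id[cohort$records$split == split]
  screening_cohort(cohort$records[cohort$records$split == split, , drop = FALSE],
                   cohort$slides[ids], cohort$annotations[ids])
}

build_cohort_grids <- function(cohort, config) {
  grids <- lapply(cohort$records$slide_id, function(sid) {
    slide <- cohort$slides[[sid]]
    mask <- detect_tissue(slide)
    g <- build_tile_grid(slide, mask, config$tile_size, config$stride,
                         config$min_tissue_fraction, config$working_magnification)
    release_slide(slide)
    g
  })
  stats::setNames(grids, cohort$records$slide_id)
}

# ---- fully supervised sampler ---------------------------------------------

#' Index of qualifying positive anchors of a cohort
#'
#' All anchors of annotated neoplastic slides whose footprint shows at least
#' one annotated cell (positive-area polygon intersection). Construction
#' fails if a neoplastic slide carries no annotations: that is legal for WS
#' training only.
#'
#' @param cohort a `screening_cohort` (train split).
#' @param grids named list of tile grids (from the same config).
#' @return data.frame(slide_id, x, y).
#' @export
positive_anchor_index <- function(cohort, grids) {
  neo <- cohort$records$slide_id[cohort$records$binary_label == "neoplastic"]
  if (!length(neo)) stopf("fully supervised sampler needs at least one neoplastic slide")
  rows <- lapply(neo, function(sid) {
    ann <- cohort$annotations[[sid]]
    if (length(ann$polygons) == 0) {
      stopf("neoplastic slide '%s' has no annotations; fully supervised sampling impossible", sid)
    }
    g <- grids[[sid]]
    a <- g$anchors
    keep <- vapply(seq_len(nrow(a)), function(i) {
      tile_is_positive(a$x[i], a$y[i], g$tile_span, ann)
    }, logical(1))
    if (!any(keep)) return(NULL)
    data.frame(slide_id = sid, x = a$x[keep], y = a$y[keep])
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0) stopf("no qualifying positive anchors in cohort")
  out
}

uniform_negative_weights <- function(cohort, grids) {
  neg <- cohort$records$slide_id[cohort$records$binary_label == "negative"]
  w <- lapply(neg, function(sid) {
    a <- grids[[sid]]$anchors
    data.frame(x = a$x, y = a$y, w = rep(1 / max(1, nrow(a)), nrow(a)))
  })
  stats::setNames(w, neg)
}

#' Sample anchors for one balanced FS batch
#'
#' Positives uniformly (with replacement) over the qualifying positive
#' anchors; negatives by first picking a negative slide uniformly, then an
#' anchor from its hard-mining weights.
#'
#' @param pos_index data.frame from [positive_anchor_index()].
#' @param weights named list from [update_negative_weights()].
#' @param n_pos,n_neg counts to draw.
#' @return list(pos, neg) of data.frame(slide_id, x, y).
#' @export
sample_fs_anchors <- function(pos_index, weights, n_pos, n_neg) {
  pi <- pos_index[sample.int(nrow(pos_index), n_pos, replace = TRUE), , drop = FALSE]
  sids <- sample(names(weights), n_neg, replace = TRUE)
  neg <- do.call(rbind, lapply(sids, function(sid) {
    w <- weights[[sid]]
    i <- sample.int(nrow(w), 1, prob = w$w)
    data.frame(slide_id = sid, x = w$x[i], y = w$y[i])
  }))
  list(pos = pi, neg = neg)
}

read_anchor_tiles <- function(cohort, anchors, config, augment = FALSE) {
  tiles <- vector("list", nrow(anchors))
  for (sid in unique(anchors$slide_id)) {
    rows <- which(anchors$slide_id == sid)
    slide <- cohort$slides[[sid]]
    for (i in rows) {
      tile <- read_tile(slide, anchors$x[i], anchors$y[i], config$tile_size,
                        config$working_magnification)
      if (augment) {
        tile <- augment_tile(tile, config$brightness_range,
                             config$saturation_range, config$contrast_range)
      }
      tiles[[i]] <- tile
    }
    release_slide(slide)
  }
  tiles
}

#' Build one balanced, interleaved fully supervised batch
#'
#' Exactly `batch_size/2` positive and `batch_size/2` negative tiles,
#' interleaved P,N,P,N,...
#'
#' @param cohort train-split `screening_cohort`.
#' @param pos_index from [positive_anchor_index()].
#' @param weights negative sampling weights.
#' @param config a [train_config()].
#' @return list(tiles, labels, anchors).
#' @export
make_fs_batch <- function(cohort, pos_index, weights, config) {
  half <- config$batch_size / 2
  drawn <- sample_fs_anchors(pos_index, weights, half, half)
  inter <- rbind(drawn$pos, drawn$neg)[rep(seq_len(half), each = 2) +
                                         rep(c(0, half), times = half), ]
  labels <- rep(c(1, 0), times = half)
  tiles <- read_anchor_tiles(cohort, inter, config, augment = config$augment)
  list(tiles = tiles, labels = labels, anchors = inter)
}

# ---- train state and early stopping ---------------------------------------

new_train_state <- function() {
  list(epoch = 0L, val_losses = numeric(0), best_epoch = NA_integer_,
       best_loss = Inf, best_params = NULL, buffer = list(),
       grad_steps = 0L, flushes = 0L, push_log = list(),
       epoch_log = data.frame())
}

#' Early-stopping bookkeeping
#'
#' Improvement means a strictly lower validation loss (min-delta 0); training
#' stops after `patience` consecutive non-improving epochs. The best epoch is
#' the argmin of the losses so far (0-based).
#'
#' @param state training state (list with `val_losses`).
#' @param new_val_loss this epoch's validation loss.
#' @param patience epochs to wait.
#' @return list(stop, best_epoch, state).
#' @export
early_stop_update <- function(state, new_val_loss, patience) {
  if (!is.finite(new_val_loss)) stopf("validation loss is not finite")
  state$val_losses <- c(state$val_losses, new_val_loss)
  best_idx <- which.min(state$val_losses)  # first minimum
  state$best_epoch <- best_idx - 1L
  state$best_loss <- state$val_losses[best_idx]
  stop <- (length(state$val_losses) - best_idx) >= patience
  list(stop = stop, best_epoch = state$best_epoch, state = state)
}

#' Slide-level validation loss
#'
#' Binary cross-entropy of max-aggregated slide scores over a validation
#' cohort -- the slide level is the level the screening decision is made at,
#' and it needs no annotations on the validation negatives.
#'
#' @param cohort validation-split `screening_cohort`.
#' @param model a tile classifier.
#' @param config a [train_config()].
#' @param grids named list of tile grids.
#' @return mean binary cross-entropy.
#' @export
validation_loss <- function(cohort, model, config, grids) {
  losses <- vapply(cohort$records$slide_id, function(sid) {
    hm <- predict_heatmap(cohort$slides[[sid]], model, grids[[sid]])
    p <- clamp(suppressWarnings(wsi_score(hm)), 1e-15, 1 - 1e-15)
    y <- as.numeric(cohort$records$binary_label[cohort$records$slide_id == sid] == "neoplastic")
    -(y * log(p) + (1 - y) * log(1 - p))
  }, numeric(1))
  mean(losses)
}

# ---- epochs ---------------------------------------------------------------

buffer_flush <- function(cohort, model, state, config) {
  n <- length(state$buffer)
  entries <- state$buffer[sample.int(n)]
  state$buffer <- list()
  state$flushes <- state$flushes + 1L
  anchors <- do.call(rbind, lapply(entries, function(e) {
    data.frame(slide_id = e$slide_id, x = e$x, y = e$y)
  }))
  labels <- vapply(entries, `[[`, numeric(1), "label")
  lr <- lr_at_epoch(state$epoch, config)
  losses <- c()
  for (b in split(seq_len(n), ceiling(seq_len(n) / config$batch_size))) {
    tiles <- read_anchor_tiles(cohort, anchors[b, , drop = FALSE], config,
                               augment = FALSE)
    st <- train_step(model, tiles, labels[b], lr)
    model <- st$model
    state$grad_steps <- state$grad_steps + 1L
    losses <- c(losses, st$loss)
  }
  list(model = model, state = state, losses = losses)
}

#' One weakly supervised epoch
#'
#' Visits every train slide once, in a seeded random permutation (slides are
#' revisited across epochs -- the oversampling rule that every slide
#' contributes each epoch). Per slide: sliding-window inference, top-k tile
#' selection, push to the buffer with the slide's binary label; the buffer is
#' trained on and cleared each time it reaches capacity. The buffer persists
#' across epochs.
#'
#' @param cohort train-split `screening_cohort`.
#' @param model a tile classifier.
#' @param state training state.
#' @param config a [train_config()].
#' @param grids named list of tile grids.
#' @return list(model, state, train_losses).
#' @export
ws_epoch <- function(cohort, model, state, config, grids) {
  ids <- cohort$records$slide_id
  perm <- ids[sample.int(length(ids))]
  losses <- c()
  pushes <- list()
  for (sid in perm) {
    g <- grids[[sid]]
    if (nrow(g$anchors) == 0) {
      warnf("slide '%s': empty tile grid, skipped", sid)
      next
    }
    hm <- predict_heatmap(cohort$slides[[sid]], model, g)
    hard <- select_hard_tiles(hm, config$k_top_tiles)
    label <- as.numeric(cohort$records$binary_label[ids == sid] == "neoplastic")
    if (nrow(hard)) {
      pushes[[length(pushes) + 1L]] <-
        data.frame(slide_id = sid, x = hard$x, y = hard$y, label = label)
    }
    for (i in seq_len(nrow(hard))) {
      state$buffer[[length(state$buffer) + 1L]] <-
        list(slide_id = sid, x = hard$x[i], y = hard$y[i], label = label)
      if (length(state$buffer) == config$buffer_capacity_N) {
        fl <- buffer_flush(cohort, model, state, config)
        model <- fl$model; state <- fl$state
        losses <- c(losses, fl$losses)
      }
    }
  }
  state$push_log[[state$epoch + 1L]] <-
    if (length(pushes)) do.call(rbind, pushes) else data.frame()
  list(model = model, state = state, train_losses = losses)
}

#' One fully supervised epoch with end-of-epoch hard mining
#'
#' Runs `ceiling(P / (batch_size/2))` balanced-batch gradient steps, where P
#' is the number of qualifying positive anchors (minimum 1 step), then runs
#' sliding-window inference on all negative train slides and refreshes the
#' negative sampling weights, so stale weights are never reused.
#'
#' @param cohort train-split `screening_cohort`.
#' @param model a tile classifier.
#' @param state training state (carries `neg_weights`).
#' @param config a [train_config()].
#' @param grids named list of tile grids.
#' @param pos_index from [positive_anchor_index()].
#' @return list(model, state, train_losses).
#' @export
fs_epoch <- function(cohort, model, state, config, grids, pos_index) {
  if (is.null(state$neg_weights)) {
    state$neg_weights <- uniform_negative_weights(cohort, grids)
  }
  steps <- max(1L, ceiling(nrow(pos_index) / (config$batch_size / 2)))
  lr <- lr_at_epoch(state$epoch, config)
  losses <- numeric(steps)
  for (s in seq_len(steps)) {
    batch <- make_fs_batch(cohort, pos_index, state$neg_weights, config)
    st <- train_step(model, batch$tiles, batch$labels, lr)
    model <- st$model
    losses[s] <- st$loss
    state$grad_steps <- state$grad_steps + 1L
  }
  neg <- cohort$records$slide_id[cohort$records$binary_label == "negative"]
  heatmaps <- stats::setNames(lapply(neg, function(sid) {
    predict_heatmap(cohort$slides[[sid]], model, grids[[sid]])
  }), neg)
  state$neg_weights <- update_negative_weights(heatmaps, config$epsilon_hard_mining)
  list(model = model, state = state, train_losses = losses)
}

# ---- full training loop ---------------------------------------------------

run_phase <- function(phase, cohort_train, cohort_val, model, config,
                      grids, log_prefix) {
  state <- new_train_state()
  pos_index <- if (phase == "FS") positive_anchor_index(cohort_train, grids) else NULL
  repeat {
    ep <- if (phase == "FS") {
      fs_epoch(cohort_train, model, state, config, grids, pos_index)
    } else {
      ws_epoch(cohort_train, model, state, config, grids)
    }
    model <- ep$model; state <- ep$state
    vl <- validation_loss(cohort_val, model, config, grids)
    prev_best <- state$best_loss
    es <- early_stop_update(state, vl, config$early_stop_patience)
    state <- es$state
    if (vl < prev_best) state$best_params <- get_parameters(model)
    state$epoch_log <- rbind(state$epoch_log, data.frame(
      phase = log_prefix, epoch = state$epoch,
      lr = lr_at_epoch(state$epoch, config),
      train_loss = if (length(ep$train_losses)) mean(ep$train_losses) else NA_real_,
      val_loss = vl, grad_steps = state$grad_steps, flushes = state$flushes))
    state$epoch <- state$epoch + 1L
    if (es$stop || state$epoch >= config$max_epochs) break
  }
  if (!is.null(state$best_params)) model <- set_parameters(model, state$best_params)
  list(model = model, state = state)
}

#' Parameter restore (generic)
#' @param model a tile classifier.
#' @param params named list from [get_parameters()].
#' @return the model with parameters replaced.
#' @export
set_parameters <- function(model, params) UseMethod("set_parameters")

#' @export
set_parameters.tiny_cnn <- function(model, params) {
  model$params <- params
  model
}

#' @export
set_parameters.intensity_scorer <- function(model, params) model

#' Train a tile classifier on a cohort
#'
#' Dispatches on `config$mode`: fully supervised ("FS"), weakly supervised
#' ("WS"), or FS to convergence followed by WS resumed from the FS-best
#' checkpoint ("FS_then_WS"). The model with the lowest slide-level
#' validation loss is returned.
#'
#' @param cohort a `screening_cohort` containing train and validation splits.
#' @param model a tile classifier; default a [tiny_cnn()] matching the
#'   configured tile size.
#' @param config a [train_config()].
#' @return list(model, state, grids).
#' @export
train_model <- function(cohort, model = NULL, config = train_config()) {
  set.seed(config$seed)
  if (is.null(model)) model <- tiny_cnn(config$tile_size, seed = config$seed)
  tr <- cohort_subset(cohort, "train")
  va <- cohort_subset(cohort, "validation")
  if (nrow(tr$records) == 0) stopf("cohort has no train split")
  if (nrow(va$records) == 0) stopf("cohort has no validation split")
  grids <- build_cohort_grids(
    screening_cohort(rbind(tr$records, va$records),
                     c(tr$slides, va$slides),
                     c(tr$annotations, va$annotations)), config)
  fs_log <- NULL
  if (config$mode == "FS" || config$mode == "FS_then_WS") {
    ph <- run_phase("FS", tr, va, model, config, grids, "FS")
    model <- ph$model; state <- ph$state
    fs_log <- state$epoch_log
  }
  if (config$mode == "WS" || config$mode == "FS_then_WS") {
    ph <- run_phase("WS", tr, va, model, config, grids, "WS")
    model <- ph$model; state <- ph$state
    state$epoch_log <- rbind(fs_log, state$epoch_log)
  }
  list(model = model, state = state, grids = grids)
}
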