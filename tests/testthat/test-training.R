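# shared fixture: a small in-memory cohort with train/validation splits
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tr <- generate_cohort(3, 3, small_config(), seed = 700, split = "train")
      va <- generate_cohort(1, 1, small_config(), seed = 800, split = "validation")
      cache <<- cohort_from_bundles(c(tr$bundles, va$bundles))
    }
    cache
  }
})

small_train_config <- function(...) {
  args <- utils::modifyList(
    list(tile_size = 128, stride = 64, batch_size = 8, k_top_tiles = 4,
         buffer_capacity_N = 16, max_epochs = 2, seed = 3),
    list(...))
  do.call(train_config, args)
}

test_that("learning-rate schedule decays 0.95 every 2 epochs", {
  cfg <- train_config()
  expect_identical(lr_at_epoch(0, cfg), 0.001)
  expect_identical(lr_at_epoch(1, cfg), 0.001)
  expect_identical(lr_at_epoch(2, cfg), 0.001 * 0.95)
  expect_identical(lr_at_epoch(4, cfg), 0.001 * 0.95^2)
  expect_identical(lr_at_epoch(11, cfg), 0.001 * 0.95^5)
})

test_that("config invariants reject inconsistent settings", {
  expect_error(train_config(k_top_tiles = 300, buffer_capacity_N = 256),
               "must not exceed")
  expect_error(train_config(buffer_capacity_N = 100, batch_size = 32),
               "divisible")
  expect_error(train_config(batch_size = 7), "even")
})

test_that("augmentation clips, is seeded, and degenerates to the identity", {
  tile <- generate_slide(small_config(seed = 5))$image[1:64, 1:64, ] * 1.0
  ident <- augment_tile(tile, c(0, 0), c(1, 1), c(1, 1))
  expect_equal(ident, tile)
  set.seed(12); a1 <- augment_tile(tile)
  set.seed(12); a2 <- augment_tile(tile)
  expect_identical(a1, a2)
  extreme <- augment_tile(tile, c(120, 120), c(2, 2), c(3, 3))
  expect_true(all(extreme >= 0 & extreme <= 255))
})

test_that("select_hard_tiles takes the top-k with row-major tie-breaks", {
  hm <- structure(list(values = matrix(c(0.1, 0.5, 0.9, 0.7), 2, 2, byrow = TRUE),
                       stride_span = 64, slide_id = "s"), class = "heatmap_grid")
  top2 <- select_hard_tiles(hm, 2)
  expect_equal(top2$prob, c(0.9, 0.7))
  expect_equal(top2$x, c(0, 64))
  expect_equal(top2$y, c(64, 64))
  # ties: first k anchors in row-major order
  hmt <- structure(list(values = matrix(0.4, 2, 3), stride_span = 10,
                        slide_id = "s"), class = "heatmap_grid")
  top3 <- select_hard_tiles(hmt, 3)
  expect_equal(top3$x, c(0, 10, 20))
  expect_equal(top3$y, c(0, 0, 0))
  # k beyond the number of anchors returns all
  expect_equal(nrow(select_hard_tiles(hmt, 99)), 6)
  # empty heatmap warns
  hme <- structure(list(values = matrix(NA_real_, 2, 2), stride_span = 10,
                        slide_id = "s"), class = "heatmap_grid")
  expect_warning(none <- select_hard_tiles(hme, 3), "empty heatmap")
  expect_equal(nrow(none), 0)
})

test_that("select_hard_tiles equals the brute-force sort on random heatmaps", {
  set.seed(44)
  for (i in 1:50) {
    nr <- sample(3:8, 1); nc <- sample(3:8, 1)
    v <- matrix(runif(nr * nc), nr, nc)
    v[sample(length(v), nr)] <- NA
    hm <- structure(list(values = v, stride_span = 32, slide_id = "s"),
                    class = "heatmap_grid")
    got <- select_hard_tiles(hm, 8)
    rm_vals <- as.vector(t(v))
    want <- sort(rm_vals[!is.na(rm_vals)], decreasing = TRUE)[seq_len(min(8, sum(!is.na(v))))]
    expect_equal(got$prob, want)
  }
})

test_that("hard-mining weights follow w ~ epsilon + p, normalised per slide", {
  mk_hm <- function(v) structure(list(values = v, stride_span = 64,
                                      slide_id = "n"), class = "heatmap_grid")
  w0 <- update_negative_weights(list(n1 = mk_hm(matrix(c(0, 0, 0, NA), 2, 2))))
  expect_equal(w0$n1$w, rep(1 / 3, 3))           # all p = 0: uniform
  w <- update_negative_weights(list(n1 = mk_hm(matrix(c(1, 0), 1, 2))),
                               epsilon = 0.01)
  expect_equal(w$n1$w[1] / w$n1$w[2], 101, tolerance = 1e-12)
  expect_equal(sum(w$n1$w), 1)
  expect_warning(update_negative_weights(list(n1 = mk_hm(matrix(NA_real_, 2, 2)))),
                 "empty heatmap")
})

test_that("FS batches are balanced, interleaved, and positives intersect annotations", {
  cohort <- cohort_subset_for_test(small_cohort(), "train")
  cfg <- small_train_config(augment = FALSE)
  grids <- uroscreen:::build_cohort_grids(cohort, cfg)
  pos <- positive_anchor_index(cohort, grids)
  w <- uroscreen:::uniform_negative_weights(cohort, grids)
  set.seed(77)
  for (rep in 1:20) {
    batch <- make_fs_batch(cohort, pos, w, cfg)
    expect_equal(batch$labels, rep(c(1, 0), 4))
    for (i in which(batch$labels == 1)) {
      sid <- batch$anchors$slide_id[i]
      g <- grids[[sid]]
      expect_true(tile_is_positive(batch$anchors$x[i], batch$anchors$y[i],
                                   g$tile_span, cohort$annotations[[sid]]))
    }
    neg_ids <- batch$anchors$slide_id[batch$labels == 0]
    expect_true(all(cohort$records$binary_label[
      match(neg_ids, cohort$records$slide_id)] == "negative"))
  }
})

test_that("negative anchor sampling frequencies match uniform weights", {
  w <- list(n1 = data.frame(x = c(0, 64, 0, 64), y = c(0, 0, 64, 64),
                            w = rep(0.25, 4)))
  set.seed(13)
  draws <- sample_fs_anchors(data.frame(slide_id = "p", x = 0, y = 0),
                             w, n_pos = 1, n_neg = 10000)$neg
  freq <- table(paste(draws$x, draws$y)) / 10000
  # 3 sigma for a binomial proportion at p = 0.25, n = 10000
  expect_true(all(abs(freq - 0.25) < 3 * sqrt(0.25 * 0.75 / 10000)))
})

test_that("a neoplastic slide without annotations breaks the FS sampler only", {
  tr <- generate_cohort(2, 2, small_config(), seed = 900, split = "train")
  cohort <- cohort_from_bundles(tr$bundles)
  sid <- cohort$records$slide_id[cohort$records$binary_label == "neoplastic"][1]
  cohort$annotations[[sid]] <- annotation_set(sid)   # strip annotations
  cfg <- small_train_config()
  grids <- uroscreen:::build_cohort_grids(cohort, cfg)
  expect_error(positive_anchor_index(cohort, grids), "no annotations")
})

test_that("early stopping waits out the patience and keeps the argmin", {
  st <- uroscreen:::new_train_state()
  for (loss in c(1.0, 0.9, 0.8)) {
    r <- early_stop_update(st, loss, patience = 10)
    st <- r$state
  }
  expect_false(r$stop)
  expect_equal(r$best_epoch, 2)
  # best at epoch 0, then 10 equal (non-improving) losses
  st <- uroscreen:::new_train_state()
  r <- early_stop_update(st, 0.5, 10); st <- r$state
  for (i in 1:9) { r <- early_stop_update(st, 0.5, 10); st <- r$state
                   expect_false(r$stop) }
  r <- early_stop_update(st, 0.5, 10)
  expect_true(r$stop)
  expect_equal(r$best_epoch, 0)
  # argmin mid-sequence is retained
  st <- uroscreen:::new_train_state()
  for (loss in c(0.9, 0.4, 0.7, 0.8)) { r <- early_stop_update(st, loss, 10); st <- r$state }
  expect_equal(r$best_epoch, 1)
  expect_error(early_stop_update(st, NaN, 10), "not finite")
})

test_that("WS buffer labels inherit slide labels and flushes respect capacity", {
  cohort <- cohort_subset_for_test(small_cohort(), "train")
  cfg <- small_train_config()
  grids <- uroscreen:::build_cohort_grids(cohort, cfg)
  model <- intensity_scorer()
  state <- uroscreen:::new_train_state()
  set.seed(cfg$seed)
  out <- ws_epoch(cohort, model, state, cfg, grids)
  pushes <- out$state$push_log[[1]]
  lab <- cohort$records$binary_label[match(pushes$slide_id, cohort$records$slide_id)]
  expect_equal(pushes$label, as.numeric(lab == "neoplastic"))
  expect_equal(nrow(pushes), 6 * cfg$k_top_tiles)
  expect_lte(length(out$state$buffer), cfg$buffer_capacity_N - 1)
  # 6 slides x k=4 = 24 pushes, N=16: exactly one flush of 2 batches
  expect_equal(out$state$flushes, 1L)
  expect_equal(out$state$grad_steps, 2L)
})

test_that("FS then WS training runs end to end and logs both phases", {
  cohort <- small_cohort()
  cfg <- small_train_config(mode = "FS_then_WS", max_epochs = 1, augment = FALSE)
  fit <- train_model(cohort, tiny_cnn(128, channels = c(2, 3), seed = 1), cfg)
  expect_setequal(unique(fit$state$epoch_log$phase), c("FS", "WS"))
  expect_true(is.finite(fit$state$best_loss))
  expect_s3_class(fit$model, "tiny_cnn")
})
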