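test_that("otsu threshold separates two spikes and rejects degenerate input", {
  h <- integer(256)
  h[20 + 1] <- 500; h[240 + 1] <- 500
  thr <- otsu_threshold(h)
  expect_identical(thr, otsu_brute(h))
  expect_gt(thr, 20)   # foreground (the 20s) strictly below the threshold
  expect_lte(thr, 240)

  h1 <- integer(256); h1[100] <- 1234
  expect_error(otsu_threshold(h1), "degenerate")
  expect_error(otsu_threshold(integer(256)), "empty")
})

test_that("otsu equals the exhaustive search on random histograms", {
  set.seed(71)
  for (i in 1:200) {
    h <- switch(1 + i %% 3,
                rpois(256, 3),                       # near-uniform
                { x <- integer(256); x[sample(256, 8)] <- rpois(8, 500); x },
                as.integer(round(1000 * (dnorm(0:255, 80, 18) +
                                         dnorm(0:255, 200, 25)))))
    if (sum(h > 0) < 2) next
    expect_identical(otsu_threshold(h), otsu_brute(h))
  }
})

test_that("detect_tissue recovers the generated foreground", {
  b <- generate_slide(small_config(seed = 51))
  s <- wsi_slide("s51", image = b$image)
  m <- detect_tissue(s)
  f <- m$downsample_factor
  ds <- function(mask) {                      # block-any = dilation to mask res
    t(rowsum(t(rowsum(mask * 1, rep(seq_len(nrow(mask) / f), each = f))),
             rep(seq_len(ncol(mask) / f), each = f))) > 0
  }
  truth <- ds(b$truth_mask)
  iou <- sum(truth & m$grid) / sum(truth | m$grid)
  expect_gte(iou, 0.5)
  # determinism on re-read
  m2 <- detect_tissue(wsi_slide("s51", image = b$image))
  expect_identical(m$grid, m2$grid)
})

test_that("an all-white slide yields an empty mask with a warning", {
  s <- wsi_slide("white", image = array(255, c(128, 128, 3)))
  expect_warning(m <- detect_tissue(s), "degenerate")
  expect_false(any(m$grid))
})

test_that("tile grid matches the closed-form count on full-tissue slides", {
  mk <- function(px) wsi_slide("full", image = array(0, c(px, px, 3)),
                               scan_magnification = 10)
  # working magnification == scan magnification: spans are as given
  s <- mk(2048)
  m <- structure(list(grid = matrix(TRUE, 256, 256), downsample_factor = 8,
                      threshold_used = 128, slide_id = "full"),
                 class = "tissue_mask")
  g <- build_tile_grid(s, m, tile_size = 1024, stride = 512,
                       working_magnification = 10)
  expect_equal(nrow(g$anchors), 9)            # 3 x 3

  s1 <- mk(1024)
  m1 <- structure(list(grid = matrix(TRUE, 128, 128), downsample_factor = 8,
                       threshold_used = 128, slide_id = "full"),
                  class = "tissue_mask")
  g1 <- build_tile_grid(s1, m1, 1024, 512, working_magnification = 10)
  expect_equal(nrow(g1$anchors), 1)

  # ragged extent gains one padded edge position per axis
  s2 <- wsi_slide("full", image = array(0, c(1100, 1100, 3)),
                  scan_magnification = 10)
  m2 <- structure(list(grid = matrix(TRUE, 138, 138), downsample_factor = 8,
                       threshold_used = 128, slide_id = "full"),
                  class = "tissue_mask")
  g2 <- build_tile_grid(s2, m2, 1024, 512, working_magnification = 10)
  expect_equal(nrow(g2$anchors), 4)           # 2 x 2 with padded edge anchors

  # tile larger than the slide in both dimensions: single padded anchor
  s3 <- wsi_slide("tiny", image = array(0, c(600, 600, 3)),
                  scan_magnification = 10)
  m3 <- structure(list(grid = matrix(TRUE, 75, 75), downsample_factor = 8,
                       threshold_used = 128, slide_id = "tiny"),
                  class = "tissue_mask")
  g3 <- build_tile_grid(s3, m3, 1024, 512, working_magnification = 10)
  expect_equal(g3$anchors[, c("x", "y")], data.frame(x = 0, y = 0))
})

test_that("every annotated cell centroid is covered by a retained anchor", {
  b <- generate_slide(small_config(seed = 61, n_clusters = 2))
  s <- wsi_slide("s61", image = b$image)
  m <- detect_tissue(s)
  g <- build_tile_grid(s, m, tile_size = 128, stride = 64)
  for (poly in b$annotations$polygons) {
    cx <- mean(poly$vertices[, 1]); cy <- mean(poly$vertices[, 2])
    covered <- any(g$anchors$x <= cx & cx < g$anchors$x + g$tile_span &
                   g$anchors$y <= cy & cy < g$anchors$y + g$tile_span)
    expect_true(covered)
  }
})

test_that("tile footprints cover all tissue when min_tissue_fraction is 0", {
  b <- generate_slide(small_config(seed = 62))
  s <- wsi_slide("s62", image = b$image)
  m <- detect_tissue(s)
  g <- build_tile_grid(s, m, 128, 64, min_tissue_fraction = 0)
  f <- m$downsample_factor
  covered <- matrix(FALSE, nrow(m$grid), ncol(m$grid))
  for (i in seq_len(nrow(g$anchors))) {
    r0 <- floor(g$anchors$y[i] / f) + 1
    c0 <- floor(g$anchors$x[i] / f) + 1
    r1 <- min(nrow(covered), ceiling((g$anchors$y[i] + g$tile_span) / f))
    c1 <- min(ncol(covered), ceiling((g$anchors$x[i] + g$tile_span) / f))
    covered[r0:r1, c0:c1] <- TRUE
  }
  expect_true(all(covered[m$grid]))
})

test_that("read_tile resamples x20 scans to x10 and pads edges white", {
  img <- array(rep(seq(0, 255, length.out = 256), each = 256), c(256, 256, 3))
  s <- wsi_slide("t", image = img, scan_magnification = 20)
  # x20 -> x10: level-0 window is twice the tile size
  tile <- read_tile(s, 0, 0, 64, working_magnification = 10)
  expect_equal(dim(tile), c(64, 64, 3))
  expect_equal(tile[1, 1, 1], mean(img[1:2, 1:2, 1]))
  # identity when scan == working magnification
  s10 <- wsi_slide("t", image = img, scan_magnification = 10)
  tile10 <- read_tile(s10, 16, 16, 64, working_magnification = 10)
  expect_identical(tile10, img[17:80, 17:80, , drop = FALSE])
  # edge padding with white
  edge <- read_tile(s10, 224, 0, 64, working_magnification = 10)
  expect_equal(dim(edge), c(64, 64, 3))
  expect_true(all(edge[, 33:64, ] == 255))
  # fully outside -> error
  expect_error(read_tile(s10, 512, 0, 64, working_magnification = 10),
               "outside")
})
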