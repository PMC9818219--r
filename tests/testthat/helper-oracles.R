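# Independent oracles used across the suite. These deliberately use the
# dumbest correct formulation (exhaustive search, rasterisation, rank
# statistics) and never call the code paths they check.

# exhaustive between-class-variance search over all 255 split points
otsu_brute <- function(histogram) {
  vals <- 0:255
  total <- sum(histogram)
  best <- -Inf; best_t <- NA_integer_
  for (t in 1:255) {
    n0 <- sum(histogram[1:t])
    n1 <- total - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(histogram[1:t] * vals[1:t]) / n0
    mu1 <- sum(histogram[(t + 1):256] * vals[(t + 1):256]) / n1
    s <- (n0 / total) * (n1 / total) * (mu0 - mu1)^2
    if (s > best + 1e-12) { best <- s; best_t <- t }
  }
  best_t
}

# Mann-Whitney pair-counting AUC with ties counted 1/2 (via midranks)
auc_rank_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# even-odd point-in-polygon test for a vector of points
point_in_poly <- function(px, py, v) {
  inside <- rep(FALSE, length(px))
  n <- nrow(v)
  for (i in seq_len(n)) {
    j <- if (i == 1) n else i - 1
    x1 <- v[i, 1]; y1 <- v[i, 2]; x2 <- v[j, 1]; y2 <- v[j, 2]
    if (y1 == y2) next
    hit <- (y1 > py) != (y2 > py)
    xint <- (x2 - x1) * (py - y1) / (y2 - y1) + x1
    inside <- xor(inside, hit & px < xint)
  }
  inside
}

# rasterised polygon/rectangle overlap: sample the rectangle on a fine
# sub-pixel grid and ask whether any sample falls inside the polygon
raster_overlap_oracle <- function(v, x, y, span, step = 0.25) {
  gx <- seq(x + step / 2, x + span - step / 2, by = step)
  gy <- seq(y + step / 2, y + span - step / 2, by = step)
  pts <- expand.grid(px = gx, py = gy)
  any(point_in_poly(pts$px, pts$py, v))
}

# 4-connected component labelling by flood fill (small masks only)
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  h <- nrow(mask); w <- ncol(mask)
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[p] != 0L || !mask[p]) next
      lab[p] <- cur
      r <- (p - 1L) %% h + 1L; c <- (p - 1L) %/% h + 1L
      nb <- c(if (r > 1) p - 1L, if (r < h) p + 1L,
              if (c > 1) p - h, if (c < w) p + h)
      stack <- c(stack, nb[mask[nb] & lab[nb] == 0L])
    }
  }
  lab
}

# small-world synthetic configs used throughout the unit tests
small_config <- function(seed = 1, n_clusters = 1, ...) {
  args <- utils::modifyList(
    list(width = 512, height = 512, n_normal_cells = 32,
         n_neoplastic_clusters = n_clusters, cells_per_cluster = c(4, 8),
         n_debris = 2, n_crystals = 1, seed = seed),
    list(...))
  do.call(synthetic_slide_config, args)
}

# the acceptance world: the spec-stated 1024^2 canvas with object counts
# scaled from the 4096^2 defaults by canvas area
acceptance_config <- function(seed = 1) {
  synthetic_slide_config(width = 1024, height = 1024, n_normal_cells = 125,
                         n_neoplastic_clusters = 2, cells_per_cluster = c(4, 8),
                         n_debris = 3, n_crystals = 2, seed = seed)
}

with_seed_tiles <- function(n, size, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) array(runif(size^2 * 3, 0, 255),
                                       c(size, size, 3)))
}

cohort_subset_for_test <- function(cohort, split) {
  uroscreen:::cohort_subset(cohort, split)
}

digest_image <- function(img) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(as.integer(img), f)
  unname(tools::md5sum(f))
}

make_scored <- function(scores, labels) {
  data.frame(slide_id = sprintf("s%03d", seq_along(scores)), score = scores,
             true_label = ifelse(labels == 1, "neoplastic", "negative"))
}
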