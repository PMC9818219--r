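#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  eval(expr, envir = parent.frame())
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Block-mean reduction of a matrix by integer factor `f`, padding the ragged
# bottom/right edge with `pad` so partial blocks average against background.
block_mean <- function(m, f, pad = 255) {
  if (f == 1L) return(m)
  h <- nrow(m); w <- ncol(m)
  h2 <- ceiling(h / f); w2 <- ceiling(w / f)
  if (h2 * f > h || w2 * f > w) {
    mm <- matrix(pad, h2 * f, w2 * f)
    mm[seq_len(h), seq_len(w)] <- m
    m <- mm
  }
  m <- rowsum(m, rep(seq_len(h2), each = f)) / f
  t(rowsum(t(m), rep(seq_len(w2), each = f)) / f)
}

# Block-mean an H x W x 3 array channel-wise.
block_mean_rgb <- function(img, f, pad = 255) {
  if (f == 1L) return(img)
  ch <- lapply(1:3, function(c) block_mean(img[, , c], f, pad))
  array(c(ch[[1]], ch[[2]], ch[[3]]), dim = c(dim(ch[[1]]), 3L))
}

rgb_to_gray <- function(img) (img[, , 1] + img[, , 2] + img[, , 3]) / 3

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 &&
  x == floor(x)

# Shoelace area of a polygon given an n x 2 vertex matrix (open ring).
polygon_area <- function(v) {
  n <- nrow(v)
  if (is.null(n) || n < 3) return(0)
  x <- v[, 1]; y <- v[, 2]
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}
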