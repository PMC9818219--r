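# Pluggable tile classifier contract and the built-in tiny CNN backbone.
#
# The contract any backbone must satisfy:
#   * predict_tiles(model, tiles)      -> one neoplastic probability per tile
#   * train_step(model, tiles, labels, lr) -> list(model, loss)  (Adam + BCE)
#   * parameter_groups(model)          -> named map to one of
#       "normalization_affine", "final_classifier", "other"
#   * get_parameters(model)            -> named list of numeric tensors
# Partial fine-tuning updates only the normalization-affine and
# final-classifier groups; everything else stays bit-identical.
#
# The built-in backbone is deliberately small (two 3x3 conv blocks with
# per-channel instance normalization, global average pooling, a 1-logit
# head) and implemented in base R via im2col + matrix products. Instance
# normalization (per-sample, per-channel) rather than batch normalization
# keeps inference independent of batch composition; its affine gamma/beta
# play the normalization-affine role in the fine-tuning contract.

#' Per-tile probability prediction (generic)
#' @param model a tile classifier.
#' @param tiles list of H x W x 3 arrays with values 0-255.
#' @return numeric vector of probabilities in [0,1].
#' @export
predict_tiles <- function(model, tiles) UseMethod("predict_tiles")

#' One optimisation step on a labelled tile batch (generic)
#' @param model a tile classifier.
#' @param tiles list of H x W x 3 arrays.
#' @param labels 0/1 vector (1 = neoplastic).
#' @param lr learning rate for this step.
#' @return list(model = updated model, loss = batch binary cross-entropy).
#' @export
train_step <- function(model, tiles, labels, lr) UseMethod("train_step")

#' Parameter-group map of a model (generic)
#' @param model a tile classifier.
#' @return named character vector over parameter names.
#' @export
parameter_groups <- function(model) UseMethod("parameter_groups")

#' Snapshot of all parameter tensors (generic)
#' @param model a tile classifier.
#' @return named list of numeric vectors/matrices.
#' @export
get_parameters <- function(model) UseMethod("get_parameters")

#' Trainable-parameter mask for full or partial fine-tuning
#'
#' Partial fine-tuning freezes everything except the affine parameters of the
#' normalization layers and the final classification layer.
#'
#' @param model a tile classifier exposing [parameter_groups()].
#' @param mode "partial" or "full".
#' @return named logical vector over parameter names.
#' @export
trainable_parameter_mask <- function(model, mode = c("partial", "full")) {
  mode <- match.arg(mode)
  groups <- parameter_groups(model)
  if (!any(groups == "final_classifier")) {
    stopf("model declares no final classifier parameter group")
  }
  if (mode == "full") {
    stats::setNames(rep(TRUE, length(groups)), names(groups))
  } else {
    stats::setNames(groups %in% c("normalization_affine", "final_classifier"),
                    names(groups))
  }
}

# ---- tiny CNN -------------------------------------------------------------

im2col_idx <- function(S) {
  # 3x3 neighbourhood, pad 1; out-of-range points to the zero row S^2 + 1
  rc <- expand.grid(r = 1:S, c = 1:S)  # column-major pixel order
  idx <- matrix(0L, S * S, 9L)
  j <- 0L
  for (dc in -1:1) for (dr in -1:1) {
    j <- j + 1L
    rr <- rc$r + dr; cc <- rc$c + dc
    ok <- rr >= 1 & rr <= S & cc >= 1 & cc <= S
    idx[, j] <- ifelse(ok, (cc - 1L) * S + rr, S * S + 1L)
  }
  idx
}

maxpool_idx <- function(S) {
  # 2x2 non-overlapping pooling S -> S/2; four index columns
  S2 <- S %/% 2L
  rc <- expand.grid(r = 1:S2, c = 1:S2)
  cbind((2L * rc$c - 2L) * S + 2L * rc$r - 1L,
        (2L * rc$c - 2L) * S + 2L * rc$r,
        (2L * rc$c - 1L) * S + 2L * rc$r - 1L,
        (2L * rc$c - 1L) * S + 2L * rc$r)
}

#' Construct the built-in tiny CNN tile classifier
#'
#' @param input_size tile side in pixels; must be a multiple of 32 (the input
#'   is first mean-pooled to a 32 x 32 working resolution).
#' @param channels widths of the two conv blocks.
#' @param finetune "full" or "partial" (see [trainable_parameter_mask()]).
#' @param seed RNG seed for weight initialisation.
#' @return a `tiny_cnn` model object.
#' @export
tiny_cnn <- function(input_size = 128, channels = c(8, 16),
                     finetune = c("full", "partial"), seed = 1) {
  finetune <- match.arg(finetune)
  if (input_size %% 32 != 0) stopf("input_size must be a multiple of 32")
  c1 <- channels[1]; c2 <- channels[2]
  params <- with_seed(seed, list(
    conv1_W = matrix(stats::rnorm(9 * 3 * c1, 0, sqrt(2 / (9 * 3))), 9 * 3, c1),
    conv1_b = numeric(c1),
    norm1_gamma = rep(1, c1), norm1_beta = numeric(c1),
    conv2_W = matrix(stats::rnorm(9 * c1 * c2, 0, sqrt(2 / (9 * c1))), 9 * c1, c2),
    conv2_b = numeric(c2),
    norm2_gamma = rep(1, c2), norm2_beta = numeric(c2),
    head_W = matrix(stats::rnorm(c2, 0, 0.1), c2, 1),
    head_b = 0
  ))
  groups <- c(conv1_W = "other", conv1_b = "other",
              norm1_gamma = "normalization_affine", norm1_beta = "normalization_affine",
              conv2_W = "other", conv2_b = "other",
              norm2_gamma = "normalization_affine", norm2_beta = "normalization_affine",
              head_W = "final_classifier", head_b = "final_classifier")
  structure(list(
    input_size = input_size, pool0 = input_size %/% 32L, channels = channels,
    params = params, groups = groups, finetune = finetune, eps = 1e-5,
    idx1 = im2col_idx(32L), idx2 = im2col_idx(16L),
    mp1 = maxpool_idx(32L), mp2 = maxpool_idx(16L),
    adam = list(t = 0L,
                m = lapply(params, function(p) p * 0),
                v = lapply(params, function(p) p * 0))
  ), class = c("tiny_cnn", "tile_classifier"))
}

#' @export
print.tiny_cnn <- function(x, ...) {
  cat(sprintf("<tiny_cnn input %d px, conv %d/%d, finetune=%s, adam step %d>\n",
              x$input_size, x$channels[1], x$channels[2], x$finetune, x$adam$t))
  invisible(x)
}

# tile (H x W x 3, 0-255) -> 1024 x 3 matrix in [0,1] at 32 x 32
cnn_prep <- function(model, tile) {
  if (dim(tile)[1] != model$input_size || dim(tile)[2] != model$input_size) {
    stopf("model expects %d px tiles, got %d x %d", model$input_size,
          dim(tile)[1], dim(tile)[2])
  }
  p <- model$pool0
  cbind(as.vector(block_mean(tile[, , 1], p)),
        as.vector(block_mean(tile[, , 2], p)),
        as.vector(block_mean(tile[, , 3], p))) / 255
}

conv_fwd <- function(X, IDX, W, b) {
  Xz <- rbind(X, 0)
  P <- matrix(Xz[as.vector(IDX), ], nrow(IDX), 9L * ncol(X))
  list(Z = sweep(P %*% W, 2, b, "+"), P = P)
}

inorm_fwd <- function(Z, gamma, beta, eps) {
  mu <- colMeans(Z)
  v <- colMeans(Z * Z) - mu^2
  inv <- 1 / sqrt(v + eps)
  xh <- sweep(Z, 2, mu) %*% diag(inv, ncol(Z))
  list(Y = sweep(xh %*% diag(gamma, ncol(Z)), 2, beta, "+"), xh = xh, inv = inv)
}

maxpool_fwd <- function(X, MP) {
  M <- X[MP[, 1], , drop = FALSE]
  SEL <- matrix(1L, nrow(M), ncol(M))
  for (j in 2:4) {
    A <- X[MP[, j], , drop = FALSE]
    upd <- A > M
    M[upd] <- A[upd]
    SEL[upd] <- j
  }
  list(M = M, SEL = SEL)
}

cnn_forward <- function(model, X0, keep_cache = FALSE) {
  p <- model$params
  c1f <- conv_fwd(X0, model$idx1, p$conv1_W, p$conv1_b)
  n1 <- inorm_fwd(c1f$Z, p$norm1_gamma, p$norm1_beta, model$eps)
  r1 <- pmax(n1$Y, 0)
  m1 <- maxpool_fwd(r1, model$mp1)
  c2f <- conv_fwd(m1$M, model$idx2, p$conv2_W, p$conv2_b)
  n2 <- inorm_fwd(c2f$Z, p$norm2_gamma, p$norm2_beta, model$eps)
  r2 <- pmax(n2$Y, 0)
  m2 <- maxpool_fwd(r2, model$mp2)
  feat <- colMeans(m2$M)
  logit <- drop(feat %*% p$head_W) + p$head_b
  out <- list(logit = logit, feat = feat)
  if (keep_cache) out$cache <- list(c1 = c1f, n1 = n1, r1 = r1, m1 = m1,
                                    c2 = c2f, n2 = n2, r2 = r2, m2 = m2)
  out
}

inorm_bwd <- function(dY, fwd, gamma) {
  xh <- fwd$xh
  dgamma <- colSums(dY * xh)
  dbeta <- colSums(dY)
  dxh <- sweep(dY, 2, gamma, "*")
  dZ <- sweep(dxh - rep(1, nrow(xh)) %o% colMeans(dxh) -
                xh * (rep(1, nrow(xh)) %o% colMeans(dxh * xh)),
              2, fwd$inv, "*")
  list(dZ = dZ, dgamma = dgamma, dbeta = dbeta)
}

maxpool_bwd <- function(dM, SEL, MP, n_in) {
  dX <- matrix(0, n_in, ncol(dM))
  for (j in 1:4) {
    dX[MP[, j], ] <- dX[MP[, j], ] + dM * (SEL == j)
  }
  dX
}

conv_bwd <- function(dZ, P, W, IDX, n_in, n_ch_in) {
  dW <- crossprod(P, dZ)
  db <- colSums(dZ)
  dP <- dZ %*% t(W)  # n_pix x 9*Cin, columns (j within cin)
  long <- matrix(dP, nrow(dP) * 9L, n_ch_in)
  dXz <- rowsum(long, group = as.vector(IDX))
  list(dW = dW, db = db, dX = dXz[seq_len(n_in), , drop = FALSE])
}

# gradients of the logit's loss contribution dlogit for one sample
cnn_backward <- function(model, X0, fwd, dlogit) {
  p <- model$params
  cc <- fwd$cache
  g <- list()
  g$head_W <- matrix(fwd$feat * dlogit, ncol = 1)
  g$head_b <- dlogit
  dfeat <- as.vector(p$head_W) * dlogit
  n2pix <- nrow(cc$m2$M)
  dM2 <- matrix(rep(dfeat / n2pix, each = n2pix), n2pix)
  dR2 <- maxpool_bwd(dM2, cc$m2$SEL, model$mp2, nrow(cc$r2))
  dY2 <- dR2 * (cc$n2$Y > 0)
  nb2 <- inorm_bwd(dY2, cc$n2, p$norm2_gamma)
  g$norm2_gamma <- nb2$dgamma; g$norm2_beta <- nb2$dbeta
  cb2 <- conv_bwd(nb2$dZ, cc$c2$P, p$conv2_W, model$idx2,
                  nrow(cc$m1$M), ncol(cc$m1$M))
  g$conv2_W <- cb2$dW; g$conv2_b <- cb2$db
  dR1 <- maxpool_bwd(cb2$dX, cc$m1$SEL, model$mp1, nrow(cc$r1))
  dY1 <- dR1 * (cc$n1$Y > 0)
  nb1 <- inorm_bwd(dY1, cc$n1, p$norm1_gamma)
  g$norm1_gamma <- nb1$dgamma; g$norm1_beta <- nb1$dbeta
  cb1 <- conv_bwd(nb1$dZ, cc$c1$P, p$conv1_W, model$idx1, nrow(X0), ncol(X0))
  g$conv1_W <- cb1$dW; g$conv1_b <- cb1$db
  g
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' @export
predict_tiles.tiny_cnn <- function(model, tiles) {
  vapply(tiles, function(tile) {
    sigmoid(cnn_forward(model, cnn_prep(model, tile))$logit)
  }, numeric(1))
}

#' @export
parameter_groups.tiny_cnn <- function(model) model$groups

#' @export
get_parameters.tiny_cnn <- function(model) model$params

#' @export
train_step.tiny_cnn <- function(model, tiles, labels, lr) {
  stopifnot(length(tiles) == length(labels))
  B <- length(tiles)
  grads <- lapply(model$params, function(p) p * 0)
  loss <- 0
  for (i in seq_len(B)) {
    X0 <- cnn_prep(model, tiles[[i]])
    fwd <- cnn_forward(model, X0, keep_cache = TRUE)
    pr <- sigmoid(fwd$logit)
    pc <- clamp(pr, 1e-12, 1 - 1e-12)
    loss <- loss - (labels[i] * log(pc) + (1 - labels[i]) * log(1 - pc)) / B
    g <- cnn_backward(model, X0, fwd, (pr - labels[i]) / B)
    for (nm in names(grads)) grads[[nm]] <- grads[[nm]] + g[[nm]]
  }
  if (!is.finite(loss)) stopf("non-finite training loss")
  mask <- trainable_parameter_mask(model, model$finetune)
  ad <- model$adam
  ad$t <- ad$t + 1L
  b1 <- 0.9; b2 <- 0.999
  for (nm in names(model$params)) {
    if (!mask[[nm]]) next
    ad$m[[nm]] <- b1 * ad$m[[nm]] + (1 - b1) * grads[[nm]]
    ad$v[[nm]] <- b2 * ad$v[[nm]] + (1 - b2) * grads[[nm]]^2
    mhat <- ad$m[[nm]] / (1 - b1^ad$t)
    vhat <- ad$v[[nm]] / (1 - b2^ad$t)
    model$params[[nm]] <- model$params[[nm]] - lr * mhat / (sqrt(vhat) + 1e-8)
  }
  model$adam <- ad
  list(model = model, loss = loss)
}

# ---- reference scorer (no learning) ---------------------------------------

#' Deterministic intensity-based reference scorer
#'
#' A frozen scorer satisfying the tile-classifier contract: the probability is
#' a logistic function of mean tile darkness (dark, chromatin-rich tiles score
#' high). Useful as an oracle stand-in anywhere a non-learning model is
#' needed; `train_step` is a counted no-op.
#'
#' @param midpoint darkness (0-1) mapped to probability 0.5.
#' @param slope logistic steepness.
#' @return an `intensity_scorer` model.
#' @export
intensity_scorer <- function(midpoint = 0.12, slope = 40) {
  structure(list(midpoint = midpoint, slope = slope,
                 calls = new.env(parent = emptyenv())),
            class = c("intensity_scorer", "tile_classifier"))
}

#' @export
predict_tiles.intensity_scorer <- function(model, tiles) {
  vapply(tiles, function(tile) {
    darkness <- 1 - mean(tile) / 255
    sigmoid(model$slope * (darkness - model$midpoint))
  }, numeric(1))
}

#' @export
train_step.intensity_scorer <- function(model, tiles, labels, lr) {
  model$calls$n <- (model$calls$n %||% 0L) + 1L
  list(model = model, loss = NA_real_)
}

#' @export
parameter_groups.intensity_scorer <- function(model) {
  c(midpoint = "other", slope = "final_classifier")
}

#' @export
get_parameters.intensity_scorer <- function(model) {
  list(midpoint = model$midpoint, slope = model$slope)
}
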