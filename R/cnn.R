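# A compact convolutional network for 5-channel grid tensors: two
# {3x3 conv + ReLU + 2x2 max-pool} blocks, a dense ReLU layer, and a 2-way
# softmax head.  Implemented with im2col/col2im matrix algebra so training
# runs at desk scale on one CPU; all randomness goes through R's RNG.

#' Specification of the grid-image CNN
#'
#' @param conv_channels widths of the two conv blocks (default `c(8, 16)`).
#' @param dense_units hidden dense layer width (default 32).
#' @param epochs maximum training epochs (default 50).
#' @param batch_size minibatch size (default 32).
#' @param lr Adam learning rate (default 1e-3).
#' @param val_fraction fraction of the training data held out for the
#'   validation curve and early stopping (default 0.1, stratified).
#' @param patience early-stopping patience on validation loss (default 10).
#' @param seed RNG seed for weight init, batching and the validation split.
#' @return an object of class `cnn_spec`.
#' @export
cnn_spec <- function(conv_channels = c(8L, 16L), dense_units = 32L,
                     epochs = 50L, batch_size = 32L, lr = 1e-3,
                     val_fraction = 0.1, patience = 10L, seed = 1L) {
  stopifnot(length(conv_channels) == 2L, epochs >= 1, batch_size >= 1)
  structure(list(conv_channels = as.integer(conv_channels),
                 dense_units = as.integer(dense_units),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 val_fraction = val_fraction, patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "cnn_spec")
}

# im2col linear-index table for a (C, H+2, W+2, B) padded array and 3x3
# patches at stride 1 ("same" padding): (C*9) x (H*W*B) matrix of indices.
im2col_index <- function(C, H, W, B) {
  Hp <- H + 2L; Wp <- W + 2L
  # index of (c, i, j) in the padded array: c + C*(i-1) + C*Hp*(j-1)
  patch <- integer(C * 9L)
  k <- 0L
  for (dj in 0:2) for (di in 0:2) for (cc in seq_len(C)) {
    k <- k + 1L
    patch[k] <- cc + C * di + C * Hp * dj
  }
  pos <- integer(H * W)
  k <- 0L
  for (j in seq_len(W)) for (i in seq_len(H)) {
    k <- k + 1L
    pos[k] <- C * (i - 1L) + C * Hp * (j - 1L)
  }
  base <- outer(patch, pos, "+")                 # (C*9) x (H*W)
  off <- (seq_len(B) - 1L) * (C * Hp * Wp)
  idx <- matrix(0L, C * 9L, H * W * B)
  for (b in seq_len(B))
    idx[, ((b - 1L) * H * W + 1L):(b * H * W)] <- base + off[b]
  idx
}

pad_batch <- function(x) {
  # x: (B, C, H, W) -> padded (C, H+2, W+2, B)
  d <- dim(x)
  out <- array(0, dim = c(d[2], d[3] + 2L, d[4] + 2L, d[1]))
  out[, 2:(d[3] + 1L), 2:(d[4] + 1L), ] <- aperm(x, c(2, 3, 4, 1))
  out
}

conv_forward <- function(x, W, b, idx) {
  # x: (B, C, H, W); W: (F, C*9); returns list(out = (B, F, H, W), cols)
  d <- dim(x)
  xp <- pad_batch(x)
  cols <- matrix(xp[idx], nrow = nrow(idx))       # (C*9) x (H*W*B)
  z <- W %*% cols + b                             # (F, H*W*B)
  out <- aperm(array(z, dim = c(nrow(W), d[3], d[4], d[1])), c(4, 1, 2, 3))
  list(out = out, cols = cols)
}

conv_backward <- function(dout, W, cols, idx, in_dim) {
  # dout: (B, F, H, W); returns gradients and dX (B, C, H, W)
  B <- in_dim[1]; C <- in_dim[2]; H <- in_dim[3]; Wd <- in_dim[4]
  dz <- matrix(aperm(dout, c(2, 3, 4, 1)), nrow = dim(dout)[2])  # F x (H*W*B)
  dW <- dz %*% t(cols)
  db <- rowSums(dz)
  dcols <- t(W) %*% dz                            # (C*9) x (H*W*B)
  acc <- rowsum(as.vector(dcols), group = as.vector(idx))
  dxp <- numeric(C * (H + 2L) * (Wd + 2L) * B)
  dxp[as.integer(rownames(acc))] <- acc[, 1]
  dxp <- array(dxp, dim = c(C, H + 2L, Wd + 2L, B))
  dx <- aperm(dxp[, 2:(H + 1L), 2:(Wd + 1L), , drop = FALSE], c(4, 1, 2, 3))
  list(dW = dW, db = db, dx = dx)
}

pool_forward <- function(x) {
  # 2x2 max pool, stride 2; x: (B, F, H, W) with even H, W
  d <- dim(x)
  io <- seq(1L, d[3], by = 2L); jo <- seq(1L, d[4], by = 2L)
  s <- list(x[, , io, jo, drop = FALSE], x[, , io + 1L, jo, drop = FALSE],
            x[, , io, jo + 1L, drop = FALSE],
            x[, , io + 1L, jo + 1L, drop = FALSE])
  m <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  # first-match argmax masks for backprop
  taken <- array(FALSE, dim = dim(m))
  masks <- vector("list", 4L)
  for (k in 1:4) {
    mk <- (s[[k]] == m) & !taken
    taken <- taken | mk
    masks[[k]] <- mk
  }
  list(out = m, masks = masks, in_dim = d)
}

pool_backward <- function(dout, pf) {
  d <- pf$in_dim
  dx <- array(0, dim = d)
  io <- seq(1L, d[3], by = 2L); jo <- seq(1L, d[4], by = 2L)
  dx[, , io, jo] <- dout * pf$masks[[1]]
  dx[, , io + 1L, jo] <- dx[, , io + 1L, jo] + dout * pf$masks[[2]]
  dx[, , io, jo + 1L] <- dx[, , io, jo + 1L] + dout * pf$masks[[3]]
  dx[, , io + 1L, jo + 1L] <- dx[, , io + 1L, jo + 1L] + dout * pf$masks[[4]]
  dx
}

cnn_init <- function(spec, C, H, W) {
  f1 <- spec$conv_channels[1]; f2 <- spec$conv_channels[2]
  flat <- f2 * (H %/% 4) * (W %/% 4)
  he <- function(nr, nc, fan) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan)),
                                     nr, nc)
  list(W1 = he(f1, C * 9L, C * 9L), b1 = numeric(f1),
       W2 = he(f2, f1 * 9L, f1 * 9L), b2 = numeric(f2),
       W3 = he(flat, spec$dense_units, flat), b3 = numeric(spec$dense_units),
       W4 = he(spec$dense_units, 2L, spec$dense_units), b4 = numeric(2L))
}

cnn_forward <- function(par, x, idx1, idx2, keep = FALSE) {
  d <- dim(x)
  c1 <- conv_forward(x, par$W1, par$b1, idx1)
  a1 <- pmax(c1$out, 0)
  p1 <- pool_forward(a1)
  c2 <- conv_forward(p1$out, par$W2, par$b2, idx2)
  a2 <- pmax(c2$out, 0)
  p2 <- pool_forward(a2)
  B <- d[1]
  flat <- matrix(aperm(p2$out, c(2, 3, 4, 1)), nrow = B, byrow = TRUE)
  z3 <- sweep(flat %*% par$W3, 2, par$b3, "+")
  a3 <- pmax(z3, 0)
  z4 <- sweep(a3 %*% par$W4, 2, par$b4, "+")
  z4 <- z4 - apply(z4, 1, max)
  ez <- exp(z4)
  probs <- ez / rowSums(ez)
  out <- list(probs = probs)
  if (keep)
    out <- c(out, list(c1 = c1, a1 = a1, p1 = p1, c2 = c2, a2 = a2, p2 = p2,
                       flat = flat, z3 = z3, a3 = a3, x = x))
  out
}

cnn_backward <- function(par, fw, y, idx1, idx2) {
  B <- nrow(fw$probs)
  Y <- cbind(1 - y, y)
  dz4 <- (fw$probs - Y) / B
  gW4 <- crossprod(fw$a3, dz4); gb4 <- colSums(dz4)
  da3 <- dz4 %*% t(par$W4)
  dz3 <- da3 * (fw$z3 > 0)
  gW3 <- crossprod(fw$flat, dz3); gb3 <- colSums(dz3)
  dflat <- dz3 %*% t(par$W3)
  d2 <- dim(fw$p2$out)
  dp2 <- aperm(array(t(dflat), dim = c(d2[2], d2[3], d2[4], B)),
               c(4, 1, 2, 3))
  da2 <- pool_backward(dp2, fw$p2)
  dz2 <- da2 * (fw$c2$out > 0)
  cb2 <- conv_backward(dz2, par$W2, fw$c2$cols, idx2, dim(fw$p1$out))
  da1 <- pool_backward(cb2$dx, fw$p1)
  dz1 <- da1 * (fw$c1$out > 0)
  cb1 <- conv_backward(dz1, par$W1, fw$c1$cols, idx1, dim(fw$x))
  list(W1 = cb1$dW, b1 = cb1$db, W2 = cb2$dW, b2 = cb2$db,
       W3 = gW3, b3 = gb3, W4 = gW4, b4 = gb4)
}

#' Train the grid-image CNN
#'
#' Minimizes softmax cross-entropy with Adam; a stratified validation split
#' drives early stopping (best-validation-loss weights are kept) and the
#' per-epoch train/validation loss and accuracy curves are recorded.
#' Determinism: with a fixed seed the run is reproducible on a
#' single-threaded BLAS; multi-threaded BLAS reductions may perturb the last
#' digits.
#'
#' @param tensors array `(N, 5, m, n)` from [grid_tensor_cohort()].
#' @param labels binary vector of length N.
#' @param spec a [cnn_spec()].
#' @return object of class `cnn_model`: trained weights, `history`
#'   (data.frame epoch/train_loss/train_acc/val_loss/val_acc), `spec`.
#' @export
train_cnn <- function(tensors, labels, spec = cnn_spec()) {
  d <- dim(tensors)
  stopifnot(length(d) == 4L, d[2] == 5L)
  y <- as.integer(labels)
  if (length(unique(y)) < 2L) stop("training data must contain both classes")
  set.seed(spec$seed)
  N <- d[1]; H <- d[3]; W <- d[4]
  if (H %% 4L != 0L || W %% 4L != 0L)
    stop("grid dimensions must be divisible by 4 for the two pooling layers")
  # stratified validation split
  val <- unlist(lapply(c(0L, 1L), function(cl) {
    idx <- which(y == cl)
    sample(idx, max(1L, round(spec$val_fraction * length(idx))))
  }))
  tr <- setdiff(seq_len(N), val)
  par <- cnn_init(spec, d[2], H, W)
  mpar <- lapply(par, function(p) p * 0); vpar <- mpar
  b1m <- 0.9; b2m <- 0.999; epsd <- 1e-8; tstep <- 0
  hist <- data.frame()
  best <- list(loss = Inf, par = par, epoch = 0L)
  idx_cache <- new.env(parent = emptyenv())
  get_idx <- function(C, B, layer) {
    key <- paste0(layer, "_", C, "_", B)
    if (is.null(idx_cache[[key]]))
      idx_cache[[key]] <- im2col_index(C, if (layer == 1L) H else H %/% 2L,
                                       if (layer == 1L) W else W %/% 2L, B)
    idx_cache[[key]]
  }
  xe_loss <- function(probs, yy) {
    -mean(log(pmax(ifelse(yy == 1, probs[, 2], probs[, 1]), 1e-12)))
  }
  eval_split <- function(idx) {
    xb <- tensors[idx, , , , drop = FALSE]
    fw <- cnn_forward(par, xb, get_idx(d[2], length(idx), 1L),
                      get_idx(spec$conv_channels[1], length(idx), 2L))
    c(loss = xe_loss(fw$probs, y[idx]),
      acc = mean((fw$probs[, 2] >= 0.5) == (y[idx] == 1)))
  }
  wait <- 0L
  for (ep in seq_len(spec$epochs)) {
    ord <- sample(tr)
    batches <- split(ord, ceiling(seq_along(ord) / spec$batch_size))
    for (bt in batches) {
      xb <- tensors[bt, , , , drop = FALSE]
      i1 <- get_idx(d[2], length(bt), 1L)
      i2 <- get_idx(spec$conv_channels[1], length(bt), 2L)
      fw <- cnn_forward(par, xb, i1, i2, keep = TRUE)
      gr <- cnn_backward(par, fw, y[bt], i1, i2)
      tstep <- tstep + 1
      for (nm in names(par)) {
        mpar[[nm]] <- b1m * mpar[[nm]] + (1 - b1m) * gr[[nm]]
        vpar[[nm]] <- b2m * vpar[[nm]] + (1 - b2m) * gr[[nm]]^2
        mh <- mpar[[nm]] / (1 - b1m^tstep)
        vh <- vpar[[nm]] / (1 - b2m^tstep)
        par[[nm]] <- par[[nm]] - spec$lr * mh / (sqrt(vh) + epsd)
      }
    }
    trm <- eval_split(tr); vam <- eval_split(val)
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = trm["loss"],
                                   train_acc = trm["acc"],
                                   val_loss = vam["loss"],
                                   val_acc = vam["acc"], row.names = NULL))
    if (vam["loss"] < best$loss - 1e-6) {
      best <- list(loss = vam["loss"], par = par, epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= spec$patience) break
    }
  }
  structure(list(par = best$par, spec = spec, history = hist,
                 best_epoch = best$epoch, input_dim = d[-1]),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf(paste0("<cnn_model> conv(%d,%d) dense %d; trained %d epochs",
                     " (best %d, val loss %.4f)\n"),
              x$spec$conv_channels[1], x$spec$conv_channels[2],
              x$spec$dense_units, nrow(x$history), x$best_epoch,
              min(x$history$val_loss)))
  invisible(x)
}

#' Predict heart-failure probability from grid tensors
#'
#' @param object a `cnn_model`.
#' @param newdata array `(N, 5, m, n)` or a single `(5, m, n)` tensor.
#' @param ... unused.
#' @return class-1 probabilities (the softmax pair sums to 1).
#' @export
predict.cnn_model <- function(object, newdata, ...) {
  x <- newdata
  if (length(dim(x)) == 3L) x <- array(x, dim = c(1L, dim(x)))
  d <- dim(x)
  H <- object$input_dim[2]; W <- object$input_dim[3]
  stopifnot(d[3] == H, d[4] == W)
  i1 <- im2col_index(d[2], H, W, d[1])
  i2 <- im2col_index(object$spec$conv_channels[1], H %/% 2L, W %/% 2L, d[1])
  fw <- cnn_forward(object$par, x, i1, i2)
  unname(fw$probs[, 2])
}
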