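# Compact CPU training engine: 2D/3D convolution, 3D max pooling, dense,
# dropout, softmax cross-entropy, and Adam, with reverse-mode gradients.
# Convolutions use same padding (asymmetric, extra pad at the trailing edge)
# and are evaluated as im2col gathers followed by BLAS matrix products; the
# backward pass scatters through the cached gather indices. Gradients are
# verified against finite differences in the test suite.

.conv_out <- function(n, s) as.integer(ceiling(n / s))

# Gather-index table for im2col over an nd spatial grid (dims, per-axis
# kernel k and stride s) with C channels. Returns linear indices into the
# padded single-sample array, one row per output position (first axis
# fastest), one column per (kernel offset, channel).
.im2col_idx <- function(dims, C, k, s) {
  nd <- length(dims)
  out <- vapply(dims, .conv_out, integer(1), s = s)
  pad_tot <- pmax((out - 1L) * s + k - dims, 0L)
  pad_beg <- pad_tot %/% 2L
  pdims <- dims + pad_tot
  starts <- lapply(out, function(o) seq(1L, by = s, length.out = o))
  pos <- as.matrix(expand.grid(starts)) # first axis fastest
  npos <- nrow(pos)
  offs <- as.matrix(expand.grid(c(rep(list(seq_len(k) - 1L), nd),
                                  list(seq_len(C) - 1L))))
  ncolumns <- nrow(offs)
  mult <- cumprod(c(1, pdims))[seq_len(nd)] # axis strides in padded array
  chan_stride <- prod(pdims)
  idx <- matrix(0L, npos, ncolumns)
  for (j in seq_len(ncolumns)) {
    lin <- 1L + offs[j, nd + 1L] * chan_stride
    for (a in seq_len(nd)) {
      lin <- lin + (pos[, a] + offs[j, a] - 1L) * mult[a]
    }
    idx[, j] <- lin
  }
  list(idx = idx, out = out, pdims = pdims, pad_beg = pad_beg, dims = dims,
       C = C, sample_len = prod(pdims) * C)
}

# Pad an (spatial..., C, N) array to the padded geometry of `ii`,
# filling with `fill`.
.pad_nd <- function(X, ii, fill = 0) {
  d <- dim(X)
  nd <- length(ii$dims)
  N <- d[length(d)]
  Xp <- array(fill, c(ii$pdims, ii$C, N))
  sl <- lapply(seq_len(nd), function(a) ii$pad_beg[a] + seq_len(ii$dims[a]))
  sl <- c(sl, list(seq_len(ii$C), seq_len(N)))
  do.call(`[<-`, c(list(Xp), sl, list(value = X)))
}

.unpad_nd <- function(Xp, ii, N) {
  nd <- length(ii$dims)
  sl <- lapply(seq_len(nd), function(a) ii$pad_beg[a] + seq_len(ii$dims[a]))
  sl <- c(sl, list(seq_len(ii$C), seq_len(N)))
  do.call(`[`, c(list(Xp), sl, list(drop = FALSE)))
}

.big_idx <- function(ii, N) {
  npos <- nrow(ii$idx)
  ii$idx[rep(seq_len(npos), N), , drop = FALSE] +
    rep((seq_len(N) - 1L) * ii$sample_len, each = npos)
}

# ---- layer forward/backward -------------------------------------------------

# conv (2d or 3d): X is (spatial..., C, N); weights W ((k^nd * C) x F).
.conv_forward <- function(layer, X, training) {
  ii <- layer$ii
  d <- dim(X); N <- d[length(d)]
  Xp <- .pad_nd(X, ii)
  big <- .big_idx(ii, N)
  M <- matrix(as.vector(Xp)[big], nrow(big), ncol(big))
  Y <- M %*% layer$W
  Y <- Y + rep(layer$b, each = nrow(Y))
  mask <- NULL
  if (identical(layer$activation, "relu")) {
    mask <- Y > 0
    Y <- Y * mask
  }
  nd <- length(ii$dims)
  arr <- array(Y, c(ii$out, N, layer$filters))
  arr <- aperm(arr, c(seq_len(nd), nd + 2L, nd + 1L))
  list(out = arr, cache = list(M = M, big = big, mask = mask, N = N))
}

.conv_backward <- function(layer, cache, dY) {
  ii <- layer$ii
  nd <- length(ii$dims)
  N <- cache$N
  perm <- c(seq_len(nd), nd + 2L, nd + 1L)
  dYm <- matrix(aperm(dY, perm), nrow(cache$big), layer$filters)
  if (!is.null(cache$mask)) dYm <- dYm * cache$mask
  dW <- crossprod(cache$M, dYm)
  db <- colSums(dYm)
  dM <- tcrossprod(dYm, layer$W)
  dXp <- numeric(ii$sample_len * N)
  big <- cache$big
  for (j in seq_len(ncol(big))) {
    t <- big[, j]
    dXp[t] <- dXp[t] + dM[, j]
  }
  dXp <- array(dXp, c(ii$pdims, ii$C, N))
  list(dX = .unpad_nd(dXp, ii, N), dW = dW, db = db)
}

# 3D max pooling, window 2 stride 2, ceil-mode (trailing -Inf pad).
.pool_forward <- function(layer, X, training) {
  ii <- layer$ii # built with C = 1; channels folded into the batch axis
  d <- dim(X)
  nd <- length(ii$dims)
  CN <- prod(d[(nd + 1L):length(d)])
  Xf <- array(X, c(d[seq_len(nd)], 1L, CN))
  Xp <- .pad_nd(Xf, ii, fill = -Inf)
  big <- .big_idx(ii, CN)
  M <- matrix(as.vector(Xp)[big], nrow(big), ncol(big))
  amax <- max.col(M, ties.method = "first")
  sel <- cbind(seq_len(nrow(M)), amax)
  Y <- array(M[sel], c(ii$out, d[(nd + 1L):length(d)]))
  list(out = Y, cache = list(src = big[sel], CN = CN, in_dim = d))
}

.pool_backward <- function(layer, cache, dY) {
  ii <- layer$ii
  nd <- length(ii$dims)
  dXp <- numeric(ii$sample_len * cache$CN)
  dXp[cache$src] <- as.vector(dY) # windows are disjoint: indices are unique
  dXp <- array(dXp, c(ii$pdims, 1L, cache$CN))
  dX <- .unpad_nd(dXp, ii, cache$CN)
  list(dX = array(dX, cache$in_dim))
}

.flatten_forward <- function(layer, X, training) {
  d <- dim(X)
  N <- d[length(d)]
  list(out = t(matrix(X, prod(d[-length(d)]), N)), cache = list(in_dim = d))
}

.flatten_backward <- function(layer, cache, dY) {
  list(dX = array(t(dY), cache$in_dim))
}

.dense_forward <- function(layer, X, training) {
  Y <- X %*% layer$W
  Y <- Y + rep(layer$b, each = nrow(Y))
  mask <- NULL
  if (identical(layer$activation, "relu")) {
    mask <- Y > 0
    Y <- Y * mask
  }
  list(out = Y, cache = list(X = X, mask = mask))
}

.dense_backward <- function(layer, cache, dY) {
  if (!is.null(cache$mask)) dY <- dY * cache$mask
  list(dX = tcrossprod(dY, layer$W),
       dW = crossprod(cache$X, dY), db = colSums(dY))
}

.dropout_forward <- function(layer, X, training) {
  if (!training || layer$rate <= 0) {
    return(list(out = X, cache = list(mask = NULL)))
  }
  keep <- 1 - layer$rate
  mask <- matrix(stats::runif(length(X)) < keep, nrow(X), ncol(X)) / keep
  list(out = X * mask, cache = list(mask = mask))
}

.dropout_backward <- function(layer, cache, dY) {
  if (is.null(cache$mask)) list(dX = dY) else list(dX = dY * cache$mask)
}

# ---- network ----------------------------------------------------------------

# Instantiate weights for an architecture_spec. Shapes are propagated once
# and gather tables are precomputed per layer.
nn_build <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "architecture_spec"))
  with_seed(seed, {
    shape <- spec$input_shape
    layers <- list()
    for (ls in spec$layers) {
      l <- ls
      if (ls$kind %in% c("conv2d", "conv3d")) {
        nd <- if (ls$kind == "conv2d") 2L else 3L
        if (length(shape) != nd + 1L) {
          stopf("%s expects a %dD+channels input, got shape (%s)",
                ls$kind, nd, paste(shape, collapse = ","))
        }
        C <- shape[nd + 1L]
        fan_in <- ls$kernel^nd * C
        lim <- if (identical(ls$init, "he_uniform")) sqrt(6 / fan_in)
               else sqrt(6 / (fan_in + ls$filters))
        l$W <- matrix(stats::runif(fan_in * ls$filters, -lim, lim),
                      fan_in, ls$filters)
        l$b <- numeric(ls$filters)
        l$ii <- .im2col_idx(shape[seq_len(nd)], C, ls$kernel, ls$stride)
        shape <- c(l$ii$out, ls$filters)
      } else if (ls$kind == "maxpool3d") {
        nd <- 3L
        l$ii <- .im2col_idx(shape[seq_len(nd)], 1L, 2L, 2L)
        shape <- c(l$ii$out, shape[nd + 1L])
      } else if (ls$kind == "flatten") {
        shape <- prod(shape)
      } else if (ls$kind %in% c("dense", "softmax_output")) {
        if (length(shape) != 1L) stopf("dense layer needs a flat input")
        fan_in <- shape
        lim <- if (identical(ls$init, "he_uniform")) sqrt(6 / fan_in)
               else sqrt(6 / (fan_in + ls$units))
        l$W <- matrix(stats::runif(fan_in * ls$units, -lim, lim),
                      fan_in, ls$units)
        l$b <- numeric(ls$units)
        shape <- ls$units
      } else if (ls$kind == "dropout") {
        # stateless
      } else {
        stopf("unknown layer kind '%s'", ls$kind)
      }
      if (any(shape < 1)) stopf("shape collapsed to zero at layer '%s'", ls$kind)
      layers[[length(layers) + 1L]] <- l
    }
    structure(
      list(spec = spec, layers = layers,
           parameter_count = sum(vapply(layers, function(l)
             length(l$W) + length(l$b), numeric(1)))),
      class = "trainable_model")
  })
}

#' @export
print.trainable_model <- function(x, ...) {
  cat(sprintf("trainable_model '%s': %d layers, %s parameters\n",
              x$spec$name, length(x$layers),
              format(x$parameter_count, big.mark = ",")))
  invisible(x)
}

.layer_fns <- list(
  conv2d = list(f = .conv_forward, b = .conv_backward),
  conv3d = list(f = .conv_forward, b = .conv_backward),
  maxpool3d = list(f = .pool_forward, b = .pool_backward),
  flatten = list(f = .flatten_forward, b = .flatten_backward),
  dense = list(f = .dense_forward, b = .dense_backward),
  softmax_output = list(f = .dense_forward, b = .dense_backward),
  dropout = list(f = .dropout_forward, b = .dropout_backward)
)

# Forward pass. X is (input_shape..., N). Returns logits (N x classes) and
# per-layer caches for the backward pass.
nn_forward <- function(model, X, training = FALSE) {
  caches <- vector("list", length(model$layers))
  out <- X
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    r <- .layer_fns[[l$kind]]$f(l, out, training)
    out <- r$out
    caches[[i]] <- r$cache
  }
  list(logits = out, caches = caches)
}

# Backward pass from dlogits; returns per-layer weight gradients and the
# gradient with respect to the input array.
nn_backward <- function(model, caches, dlogits) {
  grads <- vector("list", length(model$layers))
  d <- dlogits
  for (i in rev(seq_along(model$layers))) {
    l <- model$layers[[i]]
    r <- .layer_fns[[l$kind]]$b(l, caches[[i]], d)
    d <- r$dX
    grads[[i]] <- r[setdiff(names(r), "dX")]
  }
  list(grads = grads, dinput = d)
}

.softmax <- function(logits) {
  z <- exp(logits - apply(logits, 1, max))
  z / rowSums(z)
}

# Weighted softmax cross-entropy from logits. y is an integer class index
# vector (1-based); w a per-class weight vector. Uses log-sum-exp so the
# loss and its gradient stay consistent even for saturated logits.
nn_loss_grad <- function(logits, y, w) {
  N <- nrow(logits)
  mx <- apply(logits, 1, max)
  p <- exp(logits - mx)
  rs <- rowSums(p)
  p <- p / rs
  ll <- logits[cbind(seq_len(N), y)] - mx - log(rs)
  loss <- -mean(w[y] * ll)
  Tmat <- matrix(0, N, ncol(logits))
  Tmat[cbind(seq_len(N), y)] <- 1
  dlogits <- (p - Tmat) * (w[y] / N)
  list(loss = loss, dlogits = dlogits,
       acc = mean(max.col(p, ties.method = "first") == y))
}

# Adam update, applied in place on the model's W/b.
adam_init <- function(model) {
  lapply(model$layers, function(l) {
    if (is.null(l$W)) NULL
    else list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
  })
}

adam_step <- function(model, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (i in seq_along(model$layers)) {
    g <- grads[[i]]
    if (is.null(g) || is.null(g$dW)) next
    s <- state[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$dW
    s$vW <- beta2 * s$vW + (1 - beta2) * g$dW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$db
    s$vb <- beta2 * s$vb + (1 - beta2) * g$db^2
    model$layers[[i]]$W <- model$layers[[i]]$W -
      lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
    model$layers[[i]]$b <- model$layers[[i]]$b -
      lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state[[i]] <- s
  }
  list(model = model, state = state)
}

#' Class probabilities for a batch of cubes
#'
#' Runs the model forward in evaluation mode and applies softmax.
#'
#' @param model a `trainable_model`.
#' @param X input array `(input_shape..., N)`, e.g. from
#'   [stack_cubes()].
#' @return N x classes matrix of probabilities (rows sum to 1).
#' @export
nn_predict <- function(model, X) {
  .softmax(nn_forward(model, X, training = FALSE)$logits)
}

#' Stack reflectance cubes into a network input array
#'
#' 2D architectures consume cubes as H x W images with the band axis as
#' channels; 3D architectures treat the band axis as a spatial depth axis
#' with a single channel.
#'
#' @param cubes list of [reflectance_cube()]s with identical shapes.
#' @param mode `"2d"` (array H x W x B x N) or `"3d"` (H x W x B x 1 x N).
#' @return numeric array ready for [nn_predict()] / training.
#' @export
stack_cubes <- function(cubes, mode = c("2d", "3d")) {
  mode <- match.arg(mode)
  d <- dim(cubes[[1]]$values)
  N <- length(cubes)
  X <- array(0, c(d, N))
  for (i in seq_len(N)) X[, , , i] <- cubes[[i]]$values
  if (mode == "3d") dim(X) <- c(d, 1L, N)
  X
}
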