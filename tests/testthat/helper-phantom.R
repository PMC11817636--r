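# Shared fixtures, all generated in code at test time.

# Tiny labelled dataset of synthetic constant-plus-noise cubes, for protocol
# arithmetic tests that do not need the optical phantom.
make_toy_dataset <- function(counts, side = 4L, bands = c(447, 524, 671),
                             seed = 1L) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    cubes <- unlist(lapply(names(counts), function(cl) {
      lapply(seq_len(counts[[cl]]), function(i) {
        reflectance_cube(array(runif(side * side * length(bands)),
                               c(side, side, length(bands))),
                         bands, label = cl)
      })
    }), recursive = FALSE)
    labeled_dataset(cubes, names(counts))
  })
}

# Small phantom dataset, calibrated, at the given frame size.
make_phantom_dataset <- function(per_class, px = 16L, mode = "all_bands",
                                 seed = 1L, ranges = NULL) {
  cfg <- sim_config(frame_shape = c(px, px), separability_mode = mode,
                    class_concentration_ranges = ranges,
                    class_counts = c(nevus = per_class, melanoma = per_class,
                                     bcc = per_class),
                    seed = seed)
  cubes <- lapply(simulate_dataset(cfg), calibrate)
  labeled_dataset(cubes, c("nevus", "melanoma", "bcc"))
}

# Class-conditional ranges with deliberately orthogonal, wide gaps: nevus is
# near-transparent at every band, melanoma dark in the visible (melanin),
# BCC dark only in the NIR (water). Used by capacity/smoke checks.
wide_gap_ranges <- function() {
  list(
    nevus    = list(melanin = c(0.02, 0.10), oxy_hb = c(0.02, 0.10),
                    deoxy_hb = c(0.02, 0.08), water = c(0.02, 0.10)),
    melanoma = list(melanin = c(1.50, 1.80), oxy_hb = c(0.05, 0.15),
                    deoxy_hb = c(0.10, 0.20), water = c(0.05, 0.15)),
    bcc      = list(melanin = c(0.05, 0.15), oxy_hb = c(0.10, 0.20),
                    deoxy_hb = c(0.05, 0.15), water = c(2.50, 3.00)))
}

# Brute-force per-class TP/FN/FP/TN recount: expands a counts matrix into
# individual (truth, prediction) pairs and counts booleans sample by sample.
# Independent oracle for metrics_from_cm.
brute_force_metrics <- function(counts) {
  C <- nrow(counts)
  truth <- integer(0); pred <- integer(0)
  for (r in seq_len(C)) for (cc in seq_len(C)) {
    truth <- c(truth, rep(r, counts[r, cc]))
    pred <- c(pred, rep(cc, counts[r, cc]))
  }
  out <- lapply(seq_len(C), function(k) {
    tp <- sum(truth == k & pred == k)
    fn <- sum(truth == k & pred != k)
    fp <- sum(truth != k & pred == k)
    tn <- sum(truth != k & pred != k)
    se <- tp / (tp + fn)
    sp <- tn / (tn + fp)
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    f1 <- if (se + p == 0) 0 else 2 * se * p / (se + p)
    c(sensitivity = se, specificity = sp, precision = p, f1 = f1)
  })
  list(per_class = do.call(rbind, out),
       accuracy = sum(truth == pred) / length(truth))
}

# Finite-difference gradient check of a small architecture; returns the
# worst absolute deviation scaled by magnitude.
grad_check_spec <- function(layers, input_shape, batch = 2L, class_count = 2L,
                            weights = NULL, n_weights = 6L, seed = 3L) {
  ns <- asNamespace("speclesion")
  spec <- architecture_spec(
    "gc", input_shape,
    c(layers, list(layer_spec("softmax_output", units = class_count))),
    class_count)
  model <- ns$nn_build(spec, seed = seed)
  set.seed(seed + 1)
  X <- array(runif(prod(c(input_shape, batch))), c(input_shape, batch))
  y <- sample(class_count, batch, replace = TRUE)
  w <- weights %||% rep(1, class_count)
  lossfn <- function(m, XX) {
    ns$nn_loss_grad(ns$nn_forward(m, XX)$logits, y, w)$loss
  }
  fwd <- ns$nn_forward(model, X)
  lg <- ns$nn_loss_grad(fwd$logits, y, w)
  bwd <- ns$nn_backward(model, fwd$caches, lg$dlogits)
  eps <- 1e-5
  worst <- 0
  for (i in seq_along(model$layers)) {
    if (is.null(model$layers[[i]]$W)) next
    W <- model$layers[[i]]$W
    set.seed(seed + i)
    for (p in sample(length(W), min(n_weights, length(W)))) {
      m2 <- model; m2$layers[[i]]$W[p] <- W[p] + eps
      m3 <- model; m3$layers[[i]]$W[p] <- W[p] - eps
      num <- (lossfn(m2, X) - lossfn(m3, X)) / (2 * eps)
      ana <- bwd$grads[[i]]$dW[p]
      worst <- max(worst, abs(num - ana) / max(1, abs(num), abs(ana)))
    }
  }
  set.seed(seed + 99)
  for (p in sample(length(X), 6)) {
    X2 <- X; X2[p] <- X[p] + eps
    X3 <- X; X3[p] <- X[p] - eps
    num <- (lossfn(model, X2) - lossfn(model, X3)) / (2 * eps)
    worst <- max(worst, abs(num - bwd$dinput[p]) / max(1, abs(num)))
  }
  worst
}

`%||%` <- function(a, b) if (is.null(a)) b else a
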