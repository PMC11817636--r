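#' Training configuration
#'
#' The study protocol trains for 100 epochs per instance with batch sizes
#' in 2..10 and learning rates in 1e-6..1e-5 (the search domain of
#' [random_grid_search()]); desk-scale smoke runs use fewer epochs and a
#' faster rate. `strategy = "continued"` keeps one model instance and
#' trains it further on each successive cross-validation fold (the
#' better-performing protocol); `"fresh_per_fold"` re-initialises per fold.
#'
#' @param batch_size samples per gradient step.
#' @param learning_rate Adam step size in (0, 0.1].
#' @param epochs_per_fold epochs trained on each fold (default 100).
#' @param strategy `"continued"` or `"fresh_per_fold"`.
#' @param optimizer currently `"adam"` (the study does not name one).
#' @param seed integer seed governing initialisation, shuffling, dropout
#'   and streamed augmentation.
#' @param augmentation an [augmentation_policy()] applied to training folds
#'   only, or NULL for none.
#' @param use_class_weights weight the loss by balanced class weights
#'   computed from each fold's training labels.
#' @return A `train_config`.
#' @export
train_config <- function(batch_size = 4L, learning_rate = 5e-6,
                         epochs_per_fold = 100L,
                         strategy = c("continued", "fresh_per_fold"),
                         optimizer = "adam", seed = 1L,
                         augmentation = NULL, use_class_weights = FALSE) {
  strategy <- match.arg(strategy)
  stopifnot(is_count(batch_size), batch_size >= 1,
            is.numeric(learning_rate), learning_rate > 0, learning_rate <= 0.1,
            is_count(epochs_per_fold), epochs_per_fold >= 1)
  optimizer <- match.arg(optimizer, "adam")
  if (!is.null(augmentation)) stopifnot(inherits(augmentation, "augmentation_policy"))
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 epochs_per_fold = as.integer(epochs_per_fold),
                 strategy = strategy, optimizer = optimizer,
                 seed = as.integer(seed), augmentation = augmentation,
                 use_class_weights = isTRUE(use_class_weights)),
            class = "train_config")
}

#' Random grid search over the protocol hyperparameter ranges
#'
#' Samples `trials` configurations uniformly from the discrete batch grid
#' 2..10 crossed with a log-uniform learning rate in [1e-6, 1e-5],
#' de-duplicated, seeded.
#'
#' @param trials number of configurations to draw.
#' @param batch_grid integer candidate batch sizes (default 2:10).
#' @param lr_range learning-rate range (default `c(1e-6, 1e-5)`).
#' @param seed optional integer seed.
#' @param ... further arguments passed to [train_config()] (epochs,
#'   strategy, ...).
#' @return list of `train_config`s.
#' @export
random_grid_search <- function(trials, batch_grid = 2:10,
                               lr_range = c(1e-6, 1e-5), seed = NULL, ...) {
  stopifnot(is_count(trials), trials >= 1)
  with_seed(seed, {
    out <- list()
    seen <- character(0)
    guard <- 0L
    while (length(out) < trials && guard < 1000L) {
      guard <- guard + 1L
      b <- sample(batch_grid, 1)
      lr <- exp(stats::runif(1, log(lr_range[1]), log(lr_range[2])))
      key <- paste(b, signif(lr, 12))
      if (key %in% seen) next
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- train_config(batch_size = b,
                                              learning_rate = lr, ...)
    }
    out
  })
}

# Assemble the network input for a batch, optionally applying a streamed
# augmentation transform (entries with aug = TRUE) under the current RNG.
.assemble_batch <- function(cubes, entries, mode, policy) {
  picked <- lapply(seq_len(nrow(entries)), function(i) {
    cb <- cubes[[entries$idx[i]]]
    if (entries$aug[i]) {
      tr <- .draw_transform(policy)
      cb$values <- transform_cube_values(cb$values, tr$angle, tr$flip_h,
                                         tr$flip_v)
    }
    cb
  })
  stack_cubes(picked, mode)
}

.eval_split <- function(model, cubes, y, mode, w, batch = 64L) {
  n <- length(cubes)
  loss_sum <- 0; correct <- 0
  for (s in seq(1, n, by = batch)) {
    sel <- s:min(s + batch - 1, n)
    X <- stack_cubes(cubes[sel], mode)
    lg <- nn_forward(model, X, training = FALSE)$logits
    r <- nn_loss_grad(lg, y[sel], w)
    loss_sum <- loss_sum + r$loss * length(sel)
    correct <- correct + r$acc * length(sel)
  }
  list(loss = loss_sum / n, acc = correct / n)
}

#' Cross-validated training under the study protocol
#'
#' Trains `spec` on `data` following `plan`. Under the continued strategy a
#' single model instance (and its optimizer state) persists across folds
#' and is trained `epochs_per_fold` epochs on each fold's training split,
#' with that fold's validation split monitored every epoch; the fresh strategy
#' re-initialises model and optimizer at every fold. Augmented copies of
#' training cubes are generated lazily while streaming batches; validation
#' data is never augmented. Fully reproducible given `config$seed`.
#'
#' @param spec an [architecture_spec()].
#' @param data a [labeled_dataset()] whose cubes match the spec input.
#' @param plan a `fold_plan` built from `data`.
#' @param config a [train_config()].
#' @return list with `model` (the final `trainable_model`) and `trace`
#'   (data.frame: fold, epoch, train_loss, train_acc, val_loss, val_acc).
#' @export
train_cross_validated <- function(spec, data, plan, config) {
  stopifnot(inherits(spec, "architecture_spec"),
            inherits(data, "labeled_dataset"), inherits(plan, "fold_plan"),
            inherits(config, "train_config"))
  mode <- if (length(spec$input_shape) == 4L) "3d" else "2d"
  y_all <- match(data$labels, data$class_names)
  n_class <- length(data$class_names)
  set.seed(config$seed)
  model <- nn_build(spec)
  state <- adam_init(model)
  t_step <- 0L
  policy <- config$augmentation
  factor <- if (is.null(policy)) 1L else policy$factor
  trace <- vector("list", plan$fold_count * config$epochs_per_fold)
  ti <- 0L

  for (f in seq_len(plan$fold_count)) {
    if (config$strategy == "fresh_per_fold") {
      model <- nn_build(spec)
      state <- adam_init(model)
      t_step <- 0L
    }
    tr_idx <- plan$folds[[f]]$train
    va_idx <- plan$folds[[f]]$validation
    w <- if (config$use_class_weights) {
      as.numeric(compute_class_weights(
        stats::setNames(tabulate(y_all[tr_idx], n_class), data$class_names)))
    } else rep(1, n_class)

    for (ep in seq_len(config$epochs_per_fold)) {
      entries <- data.frame(
        idx = rep(tr_idx, each = factor),
        aug = rep(c(FALSE, rep(TRUE, factor - 1L)), times = length(tr_idx)))
      entries <- entries[sample(nrow(entries)), , drop = FALSE]
      ep_loss <- 0; ep_acc <- 0; n_seen <- 0
      for (s in seq(1, nrow(entries), by = config$batch_size)) {
        rows <- s:min(s + config$batch_size - 1, nrow(entries))
        be <- entries[rows, , drop = FALSE]
        X <- .assemble_batch(data$cubes, be, mode, policy)
        fwd <- nn_forward(model, X, training = TRUE)
        lg <- nn_loss_grad(fwd$logits, y_all[be$idx], w)
        if (!is.finite(lg$loss)) {
          stopf("training diverged (non-finite loss) at fold %d, epoch %d", f, ep)
        }
        bwd <- nn_backward(model, fwd$caches, lg$dlogits)
        t_step <- t_step + 1L
        upd <- adam_step(model, bwd$grads, state, config$learning_rate, t_step)
        model <- upd$model; state <- upd$state
        ep_loss <- ep_loss + lg$loss * length(rows)
        ep_acc <- ep_acc + lg$acc * length(rows)
        n_seen <- n_seen + length(rows)
      }
      va <- .eval_split(model, data$cubes[va_idx], y_all[va_idx], mode, w)
      ti <- ti + 1L
      trace[[ti]] <- data.frame(fold = f, epoch = ep,
                                train_loss = ep_loss / n_seen,
                                train_acc = ep_acc / n_seen,
                                val_loss = va$loss, val_acc = va$acc)
    }
  }
  list(model = model, trace = do.call(rbind, trace))
}

#' Predict class labels for cubes with a trained model
#'
#' @param model a `trainable_model`.
#' @param cubes list of [reflectance_cube()]s.
#' @param class_names class ordering used at training time.
#' @return character vector of predicted labels.
#' @export
predict_labels <- function(model, cubes, class_names) {
  mode <- if (length(model$spec$input_shape) == 4L) "3d" else "2d"
  n <- length(cubes)
  out <- character(n)
  for (s in seq(1, n, by = 64L)) {
    sel <- s:min(s + 63L, n)
    p <- nn_predict(model, stack_cubes(cubes[sel], mode))
    out[sel] <- class_names[max.col(p, ties.method = "first")]
  }
  out
}
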