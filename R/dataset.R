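#' Labeled dataset of reflectance cubes
#'
#' Ordered collection of labelled [reflectance_cube()] objects with a fixed
#' class-name ordering (the ordering defines the one-hot encoding used by
#' the loss and the confusion matrix).
#'
#' @param cubes list of `reflectance_cube`s, all with non-NULL labels.
#' @param class_names optional character vector fixing class order; defaults
#'   to the order of first appearance.
#' @return A `labeled_dataset` with fields `cubes`, `labels`, `class_names`.
#' @export
labeled_dataset <- function(cubes, class_names = NULL) {
  labels <- vapply(cubes, function(cb) {
    if (is.null(cb$label)) stopf("every cube must carry a label")
    as.character(cb$label)
  }, character(1))
  class_names <- class_names %||% unique(labels)
  if (!all(labels %in% class_names)) {
    stopf("labels outside class_names: %s",
          paste(setdiff(labels, class_names), collapse = ", "))
  }
  structure(list(cubes = cubes, labels = labels, class_names = class_names),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("labeled_dataset:", length(x$cubes), "cubes;",
      paste(sprintf("%s=%d", x$class_names,
                    class_counts(x)), collapse = ", "), "\n")
  invisible(x)
}

#' Per-class sample counts of a labeled dataset
#' @param data a [labeled_dataset()].
#' @return named integer vector in `class_names` order.
#' @export
class_counts <- function(data) {
  stopifnot(inherits(data, "labeled_dataset"))
  vapply(data$class_names, function(cl) sum(data$labels == cl), integer(1))
}

#' Class proportions from raw counts
#'
#' @param counts named (or plain) numeric vector of per-class counts.
#' @return counts divided by their total.
#' @examples
#' class_proportions(c(nevus = 332, other = 260)) # nevi fraction of 592
#' @export
class_proportions <- function(counts) {
  if (any(counts < 0) || sum(counts) == 0) stopf("counts must be non-negative, not all zero")
  counts / sum(counts)
}

#' Balance a dataset by random downsampling
#'
#' Randomly subsamples every class without replacement down to the minimum
#' class count, then shuffles the order. With the study composition
#' 327/112/70 this yields the balanced 70/70/70 set of 210 cubes.
#'
#' @param data a [labeled_dataset()].
#' @param seed optional integer seed.
#' @return A balanced [labeled_dataset()].
#' @export
balance_downsample <- function(data, seed = NULL) {
  stopifnot(inherits(data, "labeled_dataset"))
  n_min <- min(class_counts(data))
  with_seed(seed, {
    keep <- unlist(lapply(data$class_names, function(cl) {
      idx <- which(data$labels == cl)
      if (length(idx) > n_min) sample(idx, n_min) else idx
    }))
    keep <- sample(keep)
    labeled_dataset(data$cubes[keep], data$class_names)
  })
}

#' Balanced class weights for the loss function
#'
#' Implements the balanced weighting scheme `w_i = m / (C * n_i)` with `m`
#' total samples, `C` the number of classes and `n_i` the count of class
#' `i`, so that `sum_i n_i * w_i == m` and a balanced dataset gets unit
#' weights. Rare classes are up-weighted proportionally to their scarcity.
#'
#' @param data a [labeled_dataset()], or a named count vector.
#' @return named numeric vector of positive weights, class `class_weights`.
#' @examples
#' compute_class_weights(c(nevus = 327, melanoma = 112, bcc = 70))
#' @export
compute_class_weights <- function(data) {
  counts <- if (inherits(data, "labeled_dataset")) class_counts(data) else data
  if (any(counts == 0)) stopf("every class must be non-empty")
  m <- sum(counts)
  w <- m / (length(counts) * counts)
  structure(w, class = "class_weights")
}

#' Stratified test split plus stratified k-fold plan
#'
#' First holds out a stratified `test_fraction` of the data, then partitions
#' the remaining pool into `folds` stratified cross-validation folds. Each
#' fold's validation set is one partition cell; its training set is the rest
#' of the pool. Per-class leftovers (when the pool size is not divisible by
#' `folds`) are rotated across folds by class, so every part's class
#' proportions stay within one sample of the global proportion.
#'
#' @param data a [labeled_dataset()].
#' @param test_fraction fraction held out for final testing (default 0.2).
#' @param folds number of cross-validation folds (default 5).
#' @param seed optional integer seed; the plan is deterministic given it.
#' @return A `fold_plan`: `test_indices`, `folds` (list of
#'   `train`/`validation` index vectors), `fold_count`, `seed`.
#' @export
make_fold_plan <- function(data, test_fraction = 0.2, folds = 5L, seed = NULL) {
  stopifnot(inherits(data, "labeled_dataset"))
  if (test_fraction <= 0 || test_fraction >= 1) stopf("test_fraction must be in (0,1)")
  if (!is_count(folds) || folds < 2) stopf("folds must be an integer >= 2")
  with_seed(seed, {
    test_idx <- integer(0)
    fold_of <- integer(length(data$labels)) # 0 = test
    for (ci in seq_along(data$class_names)) {
      cl <- data$class_names[ci]
      idx <- sample(which(data$labels == cl))
      n_test <- round(test_fraction * length(idx))
      test_idx <- c(test_idx, idx[seq_len(n_test)])
      pool <- idx[-seq_len(n_test)]
      if (length(pool) < folds) {
        stopf("class '%s' has only %d pool samples for %d folds", cl, length(pool), folds)
      }
      base <- length(pool) %/% folds
      extra <- length(pool) %% folds
      sizes <- rep(base, folds)
      if (extra > 0) { # rotate leftovers across folds by class index
        sizes[(((ci - 1) + seq_len(extra) - 1) %% folds) + 1] <- base + 1
      }
      stops <- cumsum(sizes)
      starts <- c(1, utils::head(stops, -1) + 1)
      for (f in seq_len(folds)) {
        if (sizes[f] > 0) fold_of[pool[starts[f]:stops[f]]] <- f
      }
    }
    pool_all <- which(fold_of > 0)
    plan_folds <- lapply(seq_len(folds), function(f) {
      list(train = pool_all[fold_of[pool_all] != f],
           validation = pool_all[fold_of[pool_all] == f])
    })
    structure(list(test_indices = sort(test_idx), folds = plan_folds,
                   fold_count = as.integer(folds),
                   test_fraction = test_fraction, seed = seed),
              class = "fold_plan")
  })
}

#' Serialize / restore a fold plan as JSON
#' @param plan a `fold_plan`.
#' @param path JSON file path.
#' @return `write_fold_plan` returns `path` invisibly; `read_fold_plan`
#'   returns a `fold_plan`.
#' @export
write_fold_plan <- function(plan, path) {
  stopifnot(inherits(plan, "fold_plan"))
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fold_plan
#' @export
read_fold_plan <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  plan <- list(
    test_indices = as.integer(unlist(p$test_indices)),
    folds = lapply(p$folds, function(f) list(
      train = as.integer(unlist(f$train)),
      validation = as.integer(unlist(f$validation)))),
    fold_count = as.integer(p$fold_count),
    test_fraction = as.numeric(p$test_fraction),
    seed = if (is.null(p$seed)) NULL else as.integer(p$seed))
  structure(plan, class = "fold_plan")
}
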