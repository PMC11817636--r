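#' Multiclass confusion matrix
#'
#' Counts matrix with rows = true class and columns = predicted class, in
#' `class_names` order. Per class, TP is the diagonal entry, FN the rest of
#' its row, FP the rest of its column, and TN the remainder.
#'
#' @param truth,predicted label vectors of equal length, values drawn from
#'   `class_names`.
#' @param class_names class ordering.
#' @return A `confusion_matrix`: integer C x C matrix with dimnames.
#' @export
confusion_matrix <- function(truth, predicted, class_names) {
  if (length(truth) != length(predicted)) stopf("truth/predicted lengths differ")
  bad <- setdiff(unique(c(truth, predicted)), class_names)
  if (length(bad)) stopf("unknown label(s): %s", paste(bad, collapse = ", "))
  tf <- factor(truth, levels = class_names)
  pf <- factor(predicted, levels = class_names)
  cm <- unclass(table(truth = tf, predicted = pf))
  storage.mode(cm) <- "integer"
  structure(cm, class = c("confusion_matrix", "matrix", "array"))
}

#' Wrap a counts matrix as a confusion matrix
#' @param counts square numeric matrix (rows true, columns predicted).
#' @param class_names optional class names; defaults to existing dimnames
#'   or `class_1..C`.
#' @return A `confusion_matrix`.
#' @export
as_confusion_matrix <- function(counts, class_names = NULL) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == ncol(counts), all(counts >= 0),
            all(counts == round(counts)))
  cn <- class_names %||% rownames(counts) %||%
    paste0("class_", seq_len(nrow(counts)))
  dimnames(counts) <- list(truth = cn, predicted = cn)
  storage.mode(counts) <- "integer"
  structure(counts, class = c("confusion_matrix", "matrix", "array"))
}

#' F1 score as the harmonic mean of sensitivity and precision
#' @param sensitivity,precision per-class recall and precision in [0,1].
#' @return `2 * SE * P / (SE + P)`, or 0 where both are 0.
#' @examples
#' round(f1_score(0.79, 0.92), 2) # 0.85
#' @export
f1_score <- function(sensitivity, precision) {
  ifelse(sensitivity + precision == 0, 0,
         2 * sensitivity * precision / (sensitivity + precision))
}

#' Per-class and overall metrics from a confusion matrix
#'
#' For every class: sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`,
#' precision `TP/(TP+FP)` (0 when undefined, flagged), and F1 as the
#' harmonic mean of sensitivity and precision. Top-1 accuracy is the trace
#' over the total. When the classes are the three lesion classes, a
#' malignant-vs-benign binary collapse (melanoma + BCC vs nevus) is
#' appended.
#'
#' @param cm a [confusion_matrix()].
#' @return A `metrics_report`: list with `per_class` data.frame,
#'   `top1_accuracy`, optional `binary_collapse`, and `degenerate` flags
#'   for zero-division conventions.
#' @export
metrics_from_cm <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (sum(cm) == 0) stopf("empty confusion matrix")
  if (any(rowSums(cm) == 0)) stopf("every class needs at least one true sample")
  total <- sum(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- total - tp - fn - fp
  se <- tp / (tp + fn)
  sp <- tn / (tn + fp)
  p <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
  rep_df <- data.frame(class = rownames(cm), sensitivity = se,
                       specificity = sp, precision = p,
                       f1 = f1_score(se, p), row.names = NULL)
  out <- list(per_class = rep_df,
              top1_accuracy = sum(tp) / total,
              degenerate = rownames(cm)[tp + fp == 0])
  if (all(c("nevus", "melanoma", "bcc") %in% rownames(cm))) {
    bcm <- collapse_malignant(cm)
    btp <- diag(bcm); bfn <- rowSums(bcm) - btp; bfp <- colSums(bcm) - btp
    btn <- sum(bcm) - btp - bfn - bfp
    bse <- btp / (btp + bfn); bp <- ifelse(btp + bfp == 0, 0, btp / (btp + bfp))
    out$binary_collapse <- list(
      cm = bcm,
      per_class = data.frame(class = rownames(bcm), sensitivity = bse,
                             specificity = btn / (btn + bfp), precision = bp,
                             f1 = f1_score(bse, bp), row.names = NULL),
      top1_accuracy = sum(btp) / sum(bcm))
  }
  structure(out, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("top-1 accuracy: %.2f\n", x$top1_accuracy))
  df <- x$per_class
  df[-1] <- lapply(df[-1], round, 2)
  print(df, row.names = FALSE)
  if (!is.null(x$binary_collapse)) {
    cat(sprintf("malignant vs benign accuracy: %.2f\n",
                x$binary_collapse$top1_accuracy))
  }
  invisible(x)
}

#' Collapse the three-class matrix to malignant vs benign
#'
#' Melanoma and BCC merge into "malignant", nevus is "benign"; entries are
#' block sums of the 3 x 3 matrix, so the total sample count is preserved.
#'
#' @param cm a [confusion_matrix()] whose classes include nevus, melanoma
#'   and bcc.
#' @return A 2 x 2 `confusion_matrix` (benign, malignant).
#' @export
collapse_malignant <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  need <- c("nevus", "melanoma", "bcc")
  if (!all(need %in% rownames(cm))) {
    stopf("classes must include %s", paste(need, collapse = ", "))
  }
  ben <- "nevus"; mal <- c("melanoma", "bcc")
  m <- matrix(c(sum(cm[ben, ben]), sum(cm[ben, mal]),
                sum(cm[mal, ben]), sum(cm[mal, mal])),
              2, 2, byrow = TRUE)
  as_confusion_matrix(m, c("benign", "malignant"))
}

#' Input-gradient saliency map
#'
#' Gradient of the top-predicted class logit with respect to the input
#' cube, absolute value, maximum over the band axis, min-max normalized to
#' [0,1] (normalization is skipped for an all-zero gradient). On a
#' well-trained model the bright pixels should fall on the lesion, not the
#' surrounding skin.
#'
#' @param model a `trainable_model`.
#' @param cube a [reflectance_cube()] matching the model input.
#' @param target_class optional class index; defaults to the predicted one.
#' @return A `saliency_map`: list with `values` (H x W in [0,1]),
#'   `target_class` index, and the cube provenance.
#' @export
saliency_map <- function(model, cube, target_class = NULL) {
  stopifnot(inherits(model, "trainable_model"),
            inherits(cube, "reflectance_cube"))
  mode <- if (length(model$spec$input_shape) == 4L) "3d" else "2d"
  X <- stack_cubes(list(cube), mode)
  fwd <- nn_forward(model, X, training = FALSE)
  cls <- target_class %||% which.max(fwd$logits[1, ])
  dlog <- matrix(0, 1, ncol(fwd$logits))
  dlog[1, cls] <- 1
  g <- nn_backward(model, fwd$caches, dlog)$dinput
  if (any(!is.finite(g))) stopf("non-finite gradients in saliency computation")
  d <- dim(cube$values)
  g <- array(abs(g), c(d[1], d[2], d[3])) # channel/depth layouts coincide
  sal <- apply(g, c(1, 2), max)
  if (max(sal) > 0) sal <- sal / max(sal)
  structure(list(values = sal, target_class = cls,
                 provenance = cube$provenance),
            class = "saliency_map")
}
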