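#' Geometric augmentation policy
#'
#' Rotations by a continuous uniform angle and independent horizontal /
#' vertical flips, applied identically to all bands of a cube so the
#' spectral axis is never scrambled. Reflect fill keeps rotated corners
#' populated with plausible skin texture instead of a constant. Intensity
#' jitter and random cropping are deliberately excluded.
#'
#' @param rotation length-2 numeric, angle range in radians (default
#'   `c(0, 2*pi)`); a degenerate range fixes the angle.
#' @param flip_h,flip_v probabilities of a horizontal / vertical flip.
#' @param factor integer >= 1; the augmented dataset holds the originals
#'   plus `factor - 1` transformed copies of each cube (default 50).
#' @param fill boundary handling for rotation; only `"reflect"` is offered.
#' @return An `augmentation_policy` list.
#' @export
augmentation_policy <- function(rotation = c(0, 2 * pi), flip_h = 0.5,
                                flip_v = 0.5, factor = 50L,
                                fill = "reflect") {
  stopifnot(length(rotation) == 2L, rotation[1] <= rotation[2])
  if (!is_count(factor) || factor < 1) stopf("factor must be an integer >= 1")
  fill <- match.arg(fill, "reflect")
  structure(list(rotation = rotation, flip_h = flip_h, flip_v = flip_v,
                 factor = as.integer(factor), fill = fill),
            class = "augmentation_policy")
}

# Mirror an index vector into [1, n].
.reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  per <- 2L * n - 2L
  i <- (i - 1L) %% per
  i[i > n - 1L] <- per - i[i > n - 1L]
  i + 1L
}

#' Apply one geometric transform to a cube's value array
#'
#' Rotation about the image centre by `angle` (bilinear resampling with
#' reflected boundary indices), then optional horizontal / vertical flips.
#' All bands share the transform. A rotation by `pi` on any grid maps pixel
#' centres to pixel centres exactly, so it is an involution.
#'
#' @param values H x W x B array in [0,1].
#' @param angle rotation angle, radians.
#' @param flip_h,flip_v logical flags.
#' @return transformed array of the same shape, values still in [0,1].
#' @export
transform_cube_values <- function(values, angle = 0, flip_h = FALSE,
                                  flip_v = FALSE) {
  d <- dim(values)
  h <- d[1]; w <- d[2]
  out <- values
  if (abs(angle) > .Machine$double.eps) {
    cy <- (h + 1) / 2; cx <- (w + 1) / 2
    gy <- matrix(seq_len(h), h, w) - cy
    gx <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
    co <- cos(angle); si <- sin(angle)
    ys <- cy + co * gy + si * gx # inverse rotation of output coords
    xs <- cx - si * gy + co * gx
    y0 <- floor(ys); x0 <- floor(xs)
    wy <- ys - y0; wx <- xs - x0
    y0r <- .reflect_index(as.integer(y0), h)
    y1r <- .reflect_index(as.integer(y0) + 1L, h)
    x0r <- .reflect_index(as.integer(x0), w)
    x1r <- .reflect_index(as.integer(x0) + 1L, w)
    i00 <- (x0r - 1L) * h + y0r
    i10 <- (x0r - 1L) * h + y1r
    i01 <- (x1r - 1L) * h + y0r
    i11 <- (x1r - 1L) * h + y1r
    for (b in seq_len(d[3])) {
      v <- values[, , b]
      out[, , b] <- (1 - wy) * (1 - wx) * v[i00] + wy * (1 - wx) * v[i10] +
        (1 - wy) * wx * v[i01] + wy * wx * v[i11]
    }
  }
  if (flip_h) out <- out[, w:1, , drop = FALSE]
  if (flip_v) out <- out[h:1, , , drop = FALSE]
  out
}

# Draw transform parameters from a policy under the current RNG.
.draw_transform <- function(policy) {
  list(angle = stats::runif(1, policy$rotation[1], policy$rotation[2]),
       flip_h = stats::runif(1) < policy$flip_h,
       flip_v = stats::runif(1) < policy$flip_v)
}

#' Materialized dataset augmentation
#'
#' Returns the original cubes plus `factor - 1` randomly transformed copies
#' of each, labels preserved and per-class counts scaled exactly by
#' `factor`. Training streams the same transforms lazily (see
#' [train_cross_validated()]); this materialized form exists for
#' reproducibility checks and offline export.
#'
#' @param data a [labeled_dataset()].
#' @param policy an [augmentation_policy()].
#' @param seed optional integer seed.
#' @return An augmented [labeled_dataset()].
#' @export
augment <- function(data, policy = augmentation_policy(), seed = NULL) {
  stopifnot(inherits(data, "labeled_dataset"),
            inherits(policy, "augmentation_policy"))
  if (policy$factor == 1L) return(data)
  with_seed(seed, {
    out <- vector("list", length(data$cubes) * policy$factor)
    j <- 0L
    for (cb in data$cubes) {
      j <- j + 1L
      out[[j]] <- cb
      for (r in seq_len(policy$factor - 1L)) {
        tr <- .draw_transform(policy)
        j <- j + 1L
        out[[j]] <- reflectance_cube(
          transform_cube_values(cb$values, tr$angle, tr$flip_h, tr$flip_v),
          cb$wavelengths_nm, cb$label,
          c(cb$provenance, list(augmented = tr)))
      }
    }
    labeled_dataset(out, data$class_names)
  })
}
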