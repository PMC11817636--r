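#' Reflectance cube container
#'
#' A calibrated spectral cube: an H x W x B array of per-pixel reflectance
#' values in [0,1] with a wavelength axis, an optional class label, and a
#' provenance record of how it was produced.
#'
#' @param values numeric H x W x B array with all values finite and in [0,1].
#' @param wavelengths_nm numeric vector of band wavelengths, length B.
#' @param label optional class label.
#' @param provenance optional list describing the processing history.
#' @return A `reflectance_cube` object.
#' @export
reflectance_cube <- function(values, wavelengths_nm, label = NULL,
                             provenance = list()) {
  if (length(dim(values)) != 3L) stopf("values must be an H x W x B array")
  if (dim(values)[3] != length(wavelengths_nm)) {
    stopf("band axis (%d) does not match wavelengths (%d)",
          dim(values)[3], length(wavelengths_nm))
  }
  if (any(!is.finite(values))) stopf("cube contains non-finite values")
  if (min(values) < 0 || max(values) > 1) stopf("cube values must lie in [0,1]")
  structure(
    list(values = values, wavelengths_nm = as.numeric(wavelengths_nm),
         label = label, provenance = provenance),
    class = "reflectance_cube"
  )
}

#' @export
print.reflectance_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("reflectance_cube: %d x %d pixels, %d bands (%s nm)%s\n",
              d[1], d[2], d[3], paste(x$wavelengths_nm, collapse = ", "),
              if (is.null(x$label)) "" else paste0(", label=", x$label)))
  invisible(x)
}

#' Flat-field / dark-frame reflectance calibration
#'
#' Converts a raw capture set to per-pixel reflectance, band by band:
#' `R = k * (S_lesion - S_dark) / (S_neutral - S_dark)`, where `k` is the
#' known reflectance of the neutral gray reference. Because lesion and
#' neutral frames share the same illumination field, the division cancels
#' any smooth gain variation (flat-field correction). Pixels whose
#' denominator is at or below 1 count are treated as dead and filled with
#' the local median of valid 3 x 3 neighbours (falling back to the band
#' median); if more than 5% of a band's pixels are invalid the capture is
#' rejected as corrupt. The result is clipped to [0,1].
#'
#' @param capture a `raw_capture` from [render_capture()] or [read_capture()].
#' @param k neutral-reference reflectance in (0,1); defaults to the value
#'   stored in the capture.
#' @return A [reflectance_cube()].
#' @export
calibrate <- function(capture, k = capture$k) {
  stopifnot(inherits(capture, "raw_capture"))
  if (k <= 0 || k >= 1) stopf("k must lie in (0,1)")
  d <- dim(capture$lesion)
  if (!identical(d, dim(capture$dark)) || !identical(d, dim(capture$neutral))) {
    stopf("lesion/dark/neutral frames must share one shape")
  }
  eps <- 1
  vals <- array(0, d)
  for (b in seq_len(d[3])) {
    les <- capture$lesion[, , b]; drk <- capture$dark[, , b]
    neu <- capture$neutral[, , b]
    den <- neu - drk
    bad <- den <= eps
    if (mean(bad) > 0.05) {
      stopf("band %d: %.1f%% invalid-denominator pixels; corrupt capture",
            b, 100 * mean(bad))
    }
    den[bad] <- NA_real_
    R <- k * (les - drk) / den
    if (any(bad)) R <- .median_fill(R)
    R[R < 0] <- 0; R[R > 1] <- 1
    vals[, , b] <- R
  }
  reflectance_cube(vals, capture$wavelengths_nm, label = capture$true_label,
                   provenance = c(capture$provenance, list(k = k,
                                  step = "calibrate")))
}

# Replace NA pixels by the median of their valid 3x3 neighbours; any pixel
# still NA (isolated clusters) gets the matrix-wide median.
.median_fill <- function(R) {
  idx <- which(is.na(R), arr.ind = TRUE)
  h <- nrow(R); w <- ncol(R)
  fill <- numeric(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    y <- idx[i, 1]; x <- idx[i, 2]
    nb <- R[max(1, y - 1):min(h, y + 1), max(1, x - 1):min(w, x + 1)]
    fill[i] <- stats::median(nb, na.rm = TRUE)
  }
  R[idx] <- fill
  if (anyNA(R)) R[is.na(R)] <- stats::median(R, na.rm = TRUE)
  R
}

# Area-weighted 1-D resampling operator: rows sum to 1, so constants are
# preserved and outputs are convex combinations of inputs.
.area_weights <- function(n, m) {
  W <- matrix(0, m, n)
  scale <- n / m
  for (j in seq_len(m)) {
    lo <- (j - 1) * scale; hi <- j * scale
    i0 <- floor(lo) + 1L; i1 <- ceiling(hi)
    for (i in i0:min(i1, n)) {
      ov <- min(hi, i) - max(lo, i - 1)
      if (ov > 0) W[j, i] <- ov / scale
    }
  }
  W
}

#' Resize a reflectance cube to the network input resolution
#'
#' Each band is resampled independently to `side x side` by exact
#' area-weighted interpolation (pixel-area overlap averaging). Values remain
#' in [0,1]; wavelengths are unchanged; resizing a square cube to its own
#' size is the identity.
#'
#' @param cube a [reflectance_cube()].
#' @param side target square resolution in pixels (>= 8); 128 is the
#'   standard network input.
#' @return A resized [reflectance_cube()].
#' @export
resize_cube <- function(cube, side = 128L) {
  stopifnot(inherits(cube, "reflectance_cube"))
  if (!is_count(side) || side < 8) stopf("side must be an integer >= 8")
  d <- dim(cube$values)
  if (d[1] == side && d[2] == side) return(cube)
  Wr <- .area_weights(d[1], side)
  Wc <- .area_weights(d[2], side)
  vals <- array(0, c(side, side, d[3]))
  for (b in seq_len(d[3])) {
    vals[, , b] <- Wr %*% cube$values[, , b] %*% t(Wc)
  }
  vals[vals < 0] <- 0; vals[vals > 1] <- 1 # guard rounding at the boundary
  reflectance_cube(vals, cube$wavelengths_nm, cube$label,
                   c(cube$provenance, list(resized_to = side)))
}

#' Extract a band subset from a reflectance cube
#'
#' Returns the sub-cube at the requested wavelengths, in the requested
#' order. The three-band subset `c(447, 524, 671)` emulates the channel
#' peaks of a conventional RGB camera and is the ablation control arm of
#' the full-cube vs RGB comparison.
#'
#' @param cube a [reflectance_cube()].
#' @param wanted_nm wavelengths to keep; every one must be present.
#' @return A [reflectance_cube()] with `length(wanted_nm)` bands.
#' @export
select_bands <- function(cube, wanted_nm) {
  stopifnot(inherits(cube, "reflectance_cube"))
  pos <- match(wanted_nm, cube$wavelengths_nm)
  if (anyNA(pos)) {
    stopf("wavelength(s) %s not present in cube",
          paste(wanted_nm[is.na(pos)], collapse = ", "))
  }
  reflectance_cube(cube$values[, , pos, drop = FALSE], wanted_nm, cube$label,
                   c(cube$provenance, list(band_subset = wanted_nm)))
}

#' The RGB-like wavelength subset
#' @return `c(447, 524, 671)`, the cube bands closest to the blue, green and
#'   red channel peaks of a conventional colour camera.
#' @export
rgb_band_subset <- function() c(447, 524, 671)
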