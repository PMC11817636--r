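#' Spectral band sets and chromophore absorption panels
#'
#' The imaging device modelled here illuminates the skin sequentially with
#' eight LED bands spanning the visible and extended near-infrared range and
#' records one reflectance image per band, yielding a "spectral cube"
#' (two spatial axes by one band axis).
#'
#' @param wavelengths_nm strictly increasing vector of band-centre
#'   wavelengths in nanometres. Defaults to the eight device bands.
#' @return An object of class `spectral_bands`: a list with `wavelengths_nm`
#'   and `band_count`.
#' @examples
#' b <- spectral_bands()
#' b$band_count
#' @export
spectral_bands <- function(wavelengths_nm = c(414, 447, 477, 524, 671, 735, 890, 995)) {
  if (!is.numeric(wavelengths_nm) || length(wavelengths_nm) < 1L ||
      any(!is.finite(wavelengths_nm)) || any(wavelengths_nm <= 0)) {
    stopf("wavelengths_nm must be positive finite numbers")
  }
  if (is.unsorted(wavelengths_nm, strictly = TRUE)) {
    stopf("wavelengths_nm must be strictly increasing")
  }
  structure(
    list(wavelengths_nm = as.numeric(wavelengths_nm),
         band_count = length(wavelengths_nm)),
    class = "spectral_bands"
  )
}

#' @export
print.spectral_bands <- function(x, ...) {
  cat("spectral_bands:", x$band_count, "bands at",
      paste(x$wavelengths_nm, collapse = ", "), "nm\n")
  invisible(x)
}

# Relative absorption shapes on a fine wavelength grid, interpolated to any
# band set. Values are dimensionless relative coefficients chosen to mirror
# the qualitative spectra of the main skin chromophores:
#   * melanin: monotonically decaying from violet into the NIR;
#   * oxyhemoglobin: strong Soret absorption in the violet, secondary band
#     in the green, deep window around 650-750 nm;
#   * deoxyhemoglobin: similar but flatter, with its minimum shifted red;
#   * water: negligible below 700 nm, rising steeply toward 1000 nm.
.chromophore_knots <- list(
  wavelength = c(400, 414, 447, 477, 524, 560, 600, 671, 735, 800, 890, 995, 1050),
  melanin    = c(2.10, 2.00, 1.70, 1.50, 1.20, 1.05, 0.90, 0.70, 0.55, 0.45, 0.35, 0.25, 0.22),
  oxy_hb     = c(3.30, 3.50, 1.00, 0.70, 1.30, 1.45, 0.45, 0.08, 0.10, 0.18, 0.25, 0.30, 0.30),
  deoxy_hb   = c(2.80, 3.00, 1.20, 0.90, 1.10, 1.30, 0.80, 0.35, 0.20, 0.22, 0.25, 0.20, 0.20),
  water      = c(0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.05, 0.10, 0.35, 0.90, 1.00)
)

#' Default chromophore absorption panel for a band set
#'
#' Tabulates relative absorption coefficients of the four chromophores the
#' phantom models (melanin, oxy-/deoxyhemoglobin, water) at each band of
#' `bands`, by linear interpolation of fixed knot tables shipped with the
#' package. Melanin decays monotonically with wavelength over any band set
#' in 400-1050 nm; water is exactly zero below 700 nm, which is what makes
#' the NIR-only separability mode of the phantom possible.
#'
#' @param bands a [spectral_bands()] object.
#' @return A `chromophore_panel`: numeric matrix (chromophores x bands) with
#'   rownames `melanin`, `oxy_hb`, `deoxy_hb`, `water`, plus a
#'   `wavelengths_nm` attribute.
#' @examples
#' p <- build_default_chromophore_panel(spectral_bands())
#' p["melanin", 1] > p["melanin", 8]
#' @export
build_default_chromophore_panel <- function(bands = spectral_bands()) {
  stopifnot(inherits(bands, "spectral_bands"))
  wl <- bands$wavelengths_nm
  if (any(wl < 400) || any(wl > 1050)) {
    stopf("panel is tabulated for 400-1050 nm; got bands outside that range")
  }
  k <- .chromophore_knots
  chroms <- c("melanin", "oxy_hb", "deoxy_hb", "water")
  panel <- do.call(rbind, lapply(chroms, function(ch) {
    stats::approx(k$wavelength, k[[ch]], xout = wl)$y
  }))
  dimnames(panel) <- list(chroms, as.character(wl))
  attr(panel, "wavelengths_nm") <- wl
  class(panel) <- c("chromophore_panel", class(panel))
  panel
}
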