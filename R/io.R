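#' Construct a raw capture set from frame arrays
#'
#' Mainly useful for tests and for reading captures back from disk; the
#' simulator produces these objects directly.
#'
#' @param lesion,dark,neutral integer H x W x B arrays of raw counts.
#' @param wavelengths_nm band wavelengths, length B.
#' @param bit_depth sensor bit depth.
#' @param k neutral-reference reflectance.
#' @param true_label optional class label.
#' @param lesion_mask,r_true optional ground-truth fields (simulator only).
#' @param provenance list.
#' @return A `raw_capture` object.
#' @export
raw_capture <- function(lesion, dark, neutral, wavelengths_nm, bit_depth = 12,
                        k = 0.198, true_label = NULL, lesion_mask = NULL,
                        r_true = NULL, provenance = list()) {
  d <- dim(lesion)
  stopifnot(length(d) == 3L, identical(d, dim(dark)), identical(d, dim(neutral)),
            d[3] == length(wavelengths_nm))
  full <- 2^bit_depth - 1
  rng <- range(lesion, dark, neutral)
  if (rng[1] < 0 || rng[2] > full) {
    stopf("raw counts outside [0, %d]", full)
  }
  structure(
    list(lesion = lesion, dark = dark, neutral = neutral,
         wavelengths_nm = as.numeric(wavelengths_nm),
         bit_depth = as.integer(bit_depth), k = k, true_label = true_label,
         lesion_mask = lesion_mask, r_true = r_true, provenance = provenance),
    class = "raw_capture"
  )
}

#' Write / read a raw capture set
#'
#' One directory per capture: `band_<nm>_{lesion,dark,neutral}.tif`
#' (16-bit grayscale TIFF holding the raw counts) plus a `capture.json`
#' sidecar (label, wavelengths, bit depth, k, provenance). Counts round-trip
#' exactly through the 16-bit integer encoding.
#'
#' @param capture a `raw_capture`.
#' @param dir output directory (created if needed).
#' @return `write_capture` returns `dir` invisibly; `read_capture` returns a
#'   `raw_capture`.
#' @export
write_capture <- function(capture, dir) {
  stopifnot(inherits(capture, "raw_capture"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (b in seq_along(capture$wavelengths_nm)) {
    nm <- capture$wavelengths_nm[b]
    for (kind in c("lesion", "dark", "neutral")) {
      tiff::writeTIFF(capture[[kind]][, , b] / 65535,
                      file.path(dir, sprintf("band_%g_%s.tif", nm, kind)),
                      bits.per.sample = 16L)
    }
  }
  meta <- list(wavelengths_nm = capture$wavelengths_nm,
               bit_depth = capture$bit_depth, k = capture$k,
               true_label = capture$true_label,
               provenance = capture$provenance)
  jsonlite::write_json(meta, file.path(dir, "capture.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_capture
#' @export
read_capture <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "capture.json"),
                              simplifyVector = TRUE)
  wl <- meta$wavelengths_nm
  rd <- function(kind) {
    fr <- lapply(wl, function(nm) {
      round(tiff::readTIFF(file.path(dir, sprintf("band_%g_%s.tif", nm, kind))) * 65535)
    })
    arr <- array(0L, c(dim(fr[[1]]), length(wl)))
    for (b in seq_along(fr)) arr[, , b] <- as.integer(fr[[b]])
    arr
  }
  raw_capture(rd("lesion"), rd("dark"), rd("neutral"), wl,
              bit_depth = meta$bit_depth, k = meta$k,
              true_label = meta$true_label,
              provenance = as.list(meta$provenance))
}

#' Write / read a reflectance cube
#'
#' One multi-page 32-bit-float TIFF per cube (page order = wavelength order)
#' plus a JSON sidecar holding wavelengths, label and provenance.
#'
#' @param cube a [reflectance_cube()].
#' @param path output TIFF path; the sidecar is written next to it with a
#'   `.json` extension.
#' @return `write_cube` returns `path` invisibly; `read_cube` returns a
#'   [reflectance_cube()].
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "reflectance_cube"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  pages <- lapply(seq_along(cube$wavelengths_nm),
                  function(b) cube$values[, , b])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(wavelengths_nm = cube$wavelengths_nm, label = cube$label,
         provenance = cube$provenance),
    sub("\\.tiff?$", ".json", path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  meta <- jsonlite::read_json(sub("\\.tiff?$", ".json", path),
                              simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  vals <- array(0, c(dim(pages[[1]]), length(pages)))
  for (b in seq_along(pages)) vals[, , b] <- pages[[b]]
  vals[vals < 0] <- 0; vals[vals > 1] <- 1
  reflectance_cube(vals, meta$wavelengths_nm,
                   label = meta$label, provenance = as.list(meta$provenance))
}
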