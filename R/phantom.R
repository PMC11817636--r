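#' Simulation configuration for the multispectral lesion phantom
#'
#' Describes how raw multispectral captures are synthesised: sensor geometry
#' and bit depth, dark/illumination characteristics, the neutral-gray
#' reference reflectance `k`, per-class chromophore concentration ranges, and
#' how many captures to draw per class.
#'
#' The lesion model is a Beer-Lambert-style multiplicative absorption
#' phantom: background skin reflectance is modulated inside an elliptical
#' lesion footprint by `exp(-sum_c concentration_c * absorption_c(lambda))`.
#' Raw frames are then rendered through a smooth per-capture illumination
#' gain, a dark offset, Gaussian sensor noise, rounding, and clipping to the
#' sensor bit range.
#'
#' @param frame_shape integer (height, width) of the sensor frames. The
#'   default 192 x 256 is the device frame scaled down by 5 so desk-scale
#'   runs are fast; pass `c(960, 1280)` for the native geometry.
#' @param bands a [spectral_bands()] object.
#' @param bit_depth sensor bit depth (8-16; default 12).
#' @param dark_offset_mean,dark_noise_sd dark-level mean and noise, counts.
#' @param sensor_noise_sd read/shot noise on illuminated frames, counts.
#' @param illumination_gain counts produced by a perfect reflector (R = 1)
#'   at the centre of a flat field.
#' @param illumination_variation relative amplitude of the smooth 2-D
#'   polynomial gain variation shared by the lesion and neutral frames of a
#'   capture (this is what makes the flat-field correction consequential).
#' @param neutral_reflectance_k reflectance of the neutral gray reference in
#'   (0,1); default 0.198, a mid-gray patch.
#' @param separability_mode `"all_bands"` (classes differ across the whole
#'   spectrum), `"nir_only"` (classes differ only at 735/890/995 nm via the
#'   water channel, leaving the RGB-like bands uninformative), or `"none"`
#'   (no class signal at all; a negative control).
#' @param class_concentration_ranges optional per-class, per-chromophore
#'   `(low, high)` ranges; defaults depend on `separability_mode`, see
#'   [default_concentration_ranges()].
#' @param class_counts named integer vector of captures per class; defaults
#'   to the study composition `c(nevus = 327, melanoma = 112, bcc = 70)`.
#' @param seed integer seed governing the whole simulation.
#' @return A `sim_config` list.
#' @export
sim_config <- function(frame_shape = c(192, 256),
                       bands = spectral_bands(),
                       bit_depth = 12,
                       dark_offset_mean = 96,
                       dark_noise_sd = 2,
                       sensor_noise_sd = 4,
                       illumination_gain = 3400,
                       illumination_variation = 0.08,
                       neutral_reflectance_k = 0.198,
                       separability_mode = c("all_bands", "nir_only", "none"),
                       class_concentration_ranges = NULL,
                       class_counts = c(nevus = 327, melanoma = 112, bcc = 70),
                       seed = 1L) {
  separability_mode <- match.arg(separability_mode)
  stopifnot(length(frame_shape) == 2L, all(frame_shape >= 8))
  if (!is_count(bit_depth) || bit_depth < 8 || bit_depth > 16) {
    stopf("bit_depth must be an integer in [8, 16]")
  }
  if (neutral_reflectance_k <= 0 || neutral_reflectance_k >= 1) {
    stopf("neutral_reflectance_k must lie in (0, 1)")
  }
  if (is.null(names(class_counts)) || any(class_counts < 1)) {
    stopf("class_counts must be a named vector of positive integers")
  }
  ranges <- class_concentration_ranges %||%
    default_concentration_ranges(separability_mode)
  for (cl in names(ranges)) {
    for (ch in names(ranges[[cl]])) {
      r <- ranges[[cl]][[ch]]
      if (length(r) != 2L || r[1] > r[2] || r[1] < 0) {
        stopf("invalid concentration range for %s/%s", cl, ch)
      }
    }
  }
  structure(
    list(frame_shape = as.integer(frame_shape), bands = bands,
         bit_depth = as.integer(bit_depth),
         dark_offset_mean = dark_offset_mean, dark_noise_sd = dark_noise_sd,
         sensor_noise_sd = sensor_noise_sd,
         illumination_gain = illumination_gain,
         illumination_variation = illumination_variation,
         neutral_reflectance_k = neutral_reflectance_k,
         separability_mode = separability_mode,
         class_concentration_ranges = ranges,
         class_counts = class_counts,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Default class-conditional chromophore concentration ranges
#'
#' The study never quantifies chromophore content per etiology, so these
#' ranges are stipulated package constants. In `all_bands` mode the classes
#' separate on melanin (nevus moderate, melanoma high, BCC low) and on the
#' hemoglobin/water channels; in `nir_only` mode melanin and hemoglobin are
#' shared across classes and only the water concentration — which absorbs
#' exclusively above 700 nm in the shipped panel — differs, so the
#' 447/524/671 nm bands carry no class signal; in `none` mode all classes
#' share one distribution.
#'
#' @param mode one of `"all_bands"`, `"nir_only"`, `"none"`.
#' @return Named list (class -> chromophore -> `c(low, high)`).
#' @export
default_concentration_ranges <- function(mode = c("all_bands", "nir_only", "none")) {
  mode <- match.arg(mode)
  switch(mode,
    all_bands = list(
      nevus    = list(melanin = c(0.40, 0.80), oxy_hb = c(0.10, 0.30),
                      deoxy_hb = c(0.05, 0.15), water = c(0.10, 0.30)),
      melanoma = list(melanin = c(1.20, 1.80), oxy_hb = c(0.10, 0.30),
                      deoxy_hb = c(0.30, 0.60), water = c(0.80, 1.20)),
      bcc      = list(melanin = c(0.10, 0.30), oxy_hb = c(0.50, 0.90),
                      deoxy_hb = c(0.20, 0.40), water = c(0.40, 0.80))
    ),
    nir_only = {
      shared <- list(melanin = c(0.50, 0.70), oxy_hb = c(0.20, 0.40),
                     deoxy_hb = c(0.10, 0.20))
      list(
        nevus    = c(shared, list(water = c(0.05, 0.25))),
        melanoma = c(shared, list(water = c(0.85, 1.05))),
        bcc      = c(shared, list(water = c(1.65, 1.85)))
      )
    },
    none = {
      shared <- list(melanin = c(0.40, 0.80), oxy_hb = c(0.10, 0.30),
                     deoxy_hb = c(0.05, 0.15), water = c(0.10, 0.30))
      list(nevus = shared, melanoma = shared, bcc = shared)
    }
  )
}

# Background (healthy skin) chromophore load, shared by all captures.
.skin_background <- c(melanin = 0.15, oxy_hb = 0.08, deoxy_hb = 0.04, water = 0.10)
.skin_scale <- 0.85 # scattering-limited ceiling on diffuse skin reflectance

#' Draw one synthetic lesion
#'
#' Samples lesion geometry (elliptical footprint with a low-order radial
#' Fourier boundary perturbation and a Gaussian-soft edge) and chromophore
#' concentrations from the class-conditional ranges of `config`. Melanoma
#' defaults to a more irregular border, mirroring the clinical ABCD warning
#' signs; the irregularity is cosmetic, not load-bearing.
#'
#' @param config a [sim_config()].
#' @param label one of the class names in `config$class_counts`.
#' @param seed optional integer; when given, the draw is seeded.
#' @return A `phantom_lesion` list (class label, centre, semi-axes,
#'   orientation, border softness/irregularity, concentrations).
#' @export
synthesize_lesion <- function(config, label, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!label %in% names(config$class_concentration_ranges)) {
    stopf("unknown class label '%s'", label)
  }
  with_seed(seed, {
    h <- config$frame_shape[1]; w <- config$frame_shape[2]
    s <- min(h, w)
    irregularity <- if (label == "melanoma") 0.25 else 0.08
    # keep footprint + soft edge inside the frame
    semi_hi <- min(0.30 * s, (s / 2 - 5) / (1 + irregularity))
    if (semi_hi <= 1) stopf("frame %d x %d too small for a lesion footprint", h, w)
    semi <- stats::runif(2, min(0.14 * s, semi_hi), semi_hi)
    margin <- max(semi) * (1 + irregularity) + 4
    center <- c(stats::runif(1, margin, h - margin + 1),
                stats::runif(1, margin, w - margin + 1))
    fr <- config$class_concentration_ranges[[label]]
    conc <- vapply(fr, function(r) stats::runif(1, r[1], r[2]), numeric(1))
    # radial Fourier boundary perturbation, harmonics 2..4
    harm <- 2:4
    structure(
      list(class_label = label, center = center, semi_axes = semi,
           orientation = stats::runif(1, 0, pi),
           border_softness = stats::runif(1, 1, 3),
           border_irregularity = irregularity,
           fourier_cos = stats::rnorm(3, 0, 1 / harm),
           fourier_sin = stats::rnorm(3, 0, 1 / harm),
           chromophore_concentrations = conc),
      class = "phantom_lesion"
    )
  })
}

#' Expected lesion-interior reflectance of a phantom lesion
#'
#' Closed-form reflectance at the lesion centre (footprint weight 1):
#' background skin reflectance times
#' `exp(-sum_c concentration_c * absorption_c(lambda))`.
#'
#' @param lesion a `phantom_lesion`.
#' @param panel a `chromophore_panel` over the same bands.
#' @return numeric vector, one reflectance in (0,1) per band.
#' @export
lesion_expected_reflectance <- function(lesion, panel) {
  conc <- lesion$chromophore_concentrations
  chroms <- rownames(panel)
  stopifnot(all(names(conc) %in% chroms))
  bg <- .skin_scale * exp(-colSums(.skin_background[chroms] * unclass(panel)))
  as.numeric(bg * exp(-colSums(conc[chroms] * unclass(panel))))
}

# Soft footprint weight map in [0,1] and the hard ground-truth mask.
.lesion_footprint <- function(lesion, frame_shape) {
  h <- frame_shape[1]; w <- frame_shape[2]
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  dy <- yy - lesion$center[1]; dx <- xx - lesion$center[2]
  co <- cos(lesion$orientation); si <- sin(lesion$orientation)
  u <- (co * dx + si * dy) / lesion$semi_axes[1]
  v <- (-si * dx + co * dy) / lesion$semi_axes[2]
  r <- sqrt(u^2 + v^2)
  theta <- atan2(v, u)
  rho <- 1
  for (i in 1:3) {
    hmn <- i + 1
    rho <- rho + lesion$border_irregularity *
      (lesion$fourier_cos[i] * cos(hmn * theta) +
       lesion$fourier_sin[i] * sin(hmn * theta))
  }
  rho <- pmax(rho, 0.3)
  s_px <- sqrt(prod(lesion$semi_axes)) # fractional -> pixel distance scale
  soft <- stats::plogis((rho - r) * s_px / lesion$border_softness)
  list(soft = soft, mask = r <= rho)
}

#' Render a raw multispectral capture from a phantom lesion
#'
#' Produces the three frame stacks the reflectance calibration consumes:
#' lesion frames, dark frames, and neutral-gray reference frames, all as
#' integer counts in the sensor bit range. Per band, the true reflectance is
#' the background skin spectrum modulated inside the soft lesion footprint
#' by Beer-Lambert absorption; raw counts are
#' `round(dark_offset + illumination(i,j) * R + noise)` clipped to range.
#' The neutral frame uses `R == neutral_reflectance_k` under the same
#' illumination field, and the dark frame is offset plus dark noise.
#'
#' @param lesion a `phantom_lesion` from [synthesize_lesion()].
#' @param panel a `chromophore_panel` over `config$bands`.
#' @param config a [sim_config()].
#' @param seed optional integer seed for the render noise draws.
#' @return A `raw_capture`: integer arrays `lesion`, `dark`, `neutral` of
#'   shape H x W x B, plus `wavelengths_nm`, `bit_depth`, `k`, `true_label`,
#'   and ground-truth fields used only by tests (`lesion_mask`, `r_true`).
#' @export
render_capture <- function(lesion, panel, config, seed = NULL) {
  stopifnot(inherits(lesion, "phantom_lesion"), inherits(config, "sim_config"))
  with_seed(seed, {
    h <- config$frame_shape[1]; w <- config$frame_shape[2]
    B <- config$bands$band_count
    full <- 2L^config$bit_depth - 1L
    fp <- .lesion_footprint(lesion, config$frame_shape)

    chroms <- rownames(panel)
    bg_spec <- .skin_scale * exp(-colSums(.skin_background[chroms] * unclass(panel)))
    les_att <- exp(-colSums(lesion$chromophore_concentrations[chroms] * unclass(panel)))

    # smooth shared illumination field: per-capture low-order polynomial gain
    xg <- matrix(seq(-1, 1, length.out = w), h, w, byrow = TRUE)
    yg <- matrix(seq(-1, 1, length.out = h), h, w)
    cf <- stats::runif(5, -1, 1)
    pol <- cf[1] * xg + cf[2] * yg + cf[3] * xg * yg + cf[4] * xg^2 + cf[5] * yg^2
    gain_map <- config$illumination_gain *
      (1 + config$illumination_variation * pol / max(1, max(abs(pol))))

    clipround <- function(x) {
      x <- round(x)
      x[x < 0] <- 0; x[x > full] <- full
      array(as.integer(x), dim = dim(x) %||% c(h, w))
    }
    r_true <- array(0, c(h, w, B))
    lesion_fr <- dark_fr <- neutral_fr <- array(0L, c(h, w, B))
    n_sat <- 0L
    for (b in seq_len(B)) {
      R <- bg_spec[b] * (fp$soft * les_att[b] + (1 - fp$soft))
      # soft convex blend between lesion-attenuated and plain skin reflectance
      r_true[, , b] <- R
      sig <- config$dark_offset_mean + gain_map * R
      if (config$sensor_noise_sd > 0) {
        sig <- sig + stats::rnorm(h * w, 0, config$sensor_noise_sd)
      }
      lf <- clipround(sig)
      n_sat <- n_sat + sum(lf == full)
      lesion_fr[, , b] <- lf
      neu <- config$dark_offset_mean + gain_map * config$neutral_reflectance_k
      if (config$sensor_noise_sd > 0) {
        neu <- neu + stats::rnorm(h * w, 0, config$sensor_noise_sd)
      }
      nf <- clipround(neu)
      n_sat <- n_sat + sum(nf == full)
      neutral_fr[, , b] <- nf
      drk <- rep(config$dark_offset_mean, h * w)
      if (config$dark_noise_sd > 0) {
        drk <- drk + stats::rnorm(h * w, 0, config$dark_noise_sd)
      }
      dark_fr[, , b] <- clipround(matrix(drk, h, w))
    }
    if (n_sat > 0.10 * (2 * h * w * B)) {
      stopf("more than 10%% of pixels saturated: illumination_gain is mis-scaled")
    }
    structure(
      list(lesion = lesion_fr, dark = dark_fr, neutral = neutral_fr,
           wavelengths_nm = config$bands$wavelengths_nm,
           bit_depth = config$bit_depth, k = config$neutral_reflectance_k,
           true_label = lesion$class_label,
           lesion_mask = fp$mask, r_true = r_true,
           provenance = list(seed = seed)),
      class = "raw_capture"
    )
  })
}

#' Simulate a full multispectral capture collection
#'
#' Draws `class_counts[cl]` lesions per class and renders each into a raw
#' capture set. Fully reproducible from `config$seed`; each capture records
#' its provenance (seed, index, label).
#'
#' @param config a [sim_config()].
#' @return list of `raw_capture` objects, grouped by class in the order of
#'   `config$class_counts`.
#' @examples
#' cfg <- sim_config(frame_shape = c(24, 24),
#'                   class_counts = c(nevus = 2, melanoma = 2, bcc = 2))
#' caps <- simulate_dataset(cfg)
#' length(caps)
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  panel <- build_default_chromophore_panel(config$bands)
  with_seed(config$seed, {
    out <- vector("list", sum(config$class_counts))
    i <- 0L
    for (cl in names(config$class_counts)) {
      for (j in seq_len(config$class_counts[[cl]])) {
        i <- i + 1L
        les <- synthesize_lesion(config, cl)
        cap <- render_capture(les, panel, config)
        cap$provenance <- list(seed = config$seed, index = i, label = cl)
        out[[i]] <- cap
      }
    }
    out
  })
}
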