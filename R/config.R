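#' Optical properties of a tissue layer
#'
#' Bundle of the four quantities that parameterize photon transport in a
#' turbid medium: the scattering coefficient \eqn{\mu_s} (expected
#' scattering events per mm), the absorption coefficient \eqn{\mu_a}
#' (expected absorption events per mm), the scattering anisotropy factor
#' \eqn{g} (mean cosine of the single-scattering deflection angle) and
#' the refractive index \eqn{n}.
#'
#' @param mu_s scattering coefficient, mm^-1 (>= 0).
#' @param mu_a absorption coefficient, mm^-1 (>= 0). Corneal absorption
#'   at 850 nm is weak, so the default is 0.
#' @param g anisotropy factor, in (-1, 1); `g = 1` is accepted only as
#'   the purely forward-scattering limit.
#' @param n refractive index (>= 1).
#' @return An object of class `optical_properties`.
#' @examples
#' optical_properties(mu_s = 0.15, g = 0.9)
#' @export
optical_properties <- function(mu_s, mu_a = 0, g = 0.9, n = 1.376) {
  stopifnot(is.numeric(mu_s), length(mu_s) == 1, mu_s >= 0,
            is.numeric(mu_a), length(mu_a) == 1, mu_a >= 0,
            is.numeric(n), length(n) == 1, n >= 1)
  if (!(g > -1 && g <= 1))
    stop("g must lie in (-1, 1] (g = 1 only as the forward limit)")
  structure(list(mu_s = mu_s, mu_a = mu_a, g = g, n = n),
            class = "optical_properties")
}

#' Layered slab geometry
#'
#' An ordered stack of plane-parallel layers bounded by two ambient
#' half-spaces. The default configuration is the single-layer corneal
#' stroma model: 600 um of tissue with n = 1.376, air (n = 1) above and
#' aqueous humor (n = 1.33) below.
#'
#' @param layers list of layers, each a list with elements
#'   `thickness_um` (> 0) and `props` (an [optical_properties()]).
#' @param n_above refractive index of the ambient medium above the
#'   sample (air = 1).
#' @param n_below refractive index below the last layer (aqueous
#'   humor = 1.33).
#' @return An object of class `layer_stack`.
#' @seealso [corneal_stack()] for the one-call default.
#' @export
layer_stack <- function(layers, n_above = 1, n_below = 1.33) {
  stopifnot(is.list(layers), length(layers) >= 1,
            is.numeric(n_above), n_above >= 1,
            is.numeric(n_below), n_below >= 1)
  for (ly in layers) {
    stopifnot(is.list(ly), !is.null(ly$thickness_um), !is.null(ly$props))
    if (!(ly$thickness_um > 0)) stop("every layer thickness must be > 0")
    if (!inherits(ly$props, "optical_properties"))
      stop("each layer's `props` must be an optical_properties object")
  }
  structure(list(layers = layers, n_above = n_above, n_below = n_below),
            class = "layer_stack")
}

#' Single-layer corneal stroma stack
#'
#' @param mu_s scattering coefficient, mm^-1.
#' @param g anisotropy factor.
#' @param mu_a absorption coefficient, mm^-1 (default 0).
#' @param thickness_um stromal thickness, um (default 600).
#' @param n stromal refractive index (default 1.376).
#' @inheritParams layer_stack
#' @return A [layer_stack()] with one layer.
#' @export
corneal_stack <- function(mu_s, g, mu_a = 0, thickness_um = 600,
                          n = 1.376, n_above = 1, n_below = 1.33) {
  layer_stack(
    list(list(thickness_um = thickness_um,
              props = optical_properties(mu_s, mu_a, g, n))),
    n_above = n_above, n_below = n_below)
}

#' Disc detector geometry
#'
#' The detector is a disc parallel to the sample surface. A
#' backscattered packet is detected when the straight-line continuation
#' of its exit ray to the detector plane lands inside the disc. The
#' defaults (radius 0.2 cm at 100 um above the surface) absorb the low
#' numerical aperture of a spectral-domain corneal OCT system into a
#' purely geometric acceptance.
#'
#' @param radius_cm disc radius, cm (> 0).
#' @param height_um detector plane height above the sample surface, um
#'   (>= 0).
#' @return An object of class `detector_spec`.
#' @export
detector_spec <- function(radius_cm = 0.2, height_um = 100) {
  stopifnot(radius_cm > 0, height_um >= 0)
  structure(list(radius_cm = radius_cm, height_um = height_um),
            class = "detector_spec")
}

#' Broadband light source
#'
#' Gaussian-spectrum source described by its central wavelength and FWHM
#' bandwidth; the coherence length `lc_um` is derived with
#' [coherence_length()] and sets the axial extent of the coherence gate.
#'
#' @param lambda0_nm central wavelength, nm (default 850).
#' @param delta_lambda_nm FWHM bandwidth, nm (default 50).
#' @return An object of class `source_spec` with fields `lambda0_nm`,
#'   `delta_lambda_nm`, `lc_um`.
#' @export
source_spec <- function(lambda0_nm = 850, delta_lambda_nm = 50) {
  stopifnot(lambda0_nm > 0, delta_lambda_nm > 0)
  structure(list(lambda0_nm = lambda0_nm,
                 delta_lambda_nm = delta_lambda_nm,
                 lc_um = coherence_length(lambda0_nm, delta_lambda_nm)),
            class = "source_spec")
}

#' Axial depth grid of the simulated A-scan
#'
#' @param pixel_um axial pixel size, um (default 2.7, matching the
#'   device's vertical resolution).
#' @param n_pixels number of depth pixels (default 223, approximately
#'   600 um of reference depth).
#' @param sample_n refractive index used to convert pixel depth to
#'   reference-arm optical delay, so tissue features land at geometric
#'   depth on the pixel grid (default 1.376).
#' @return An object of class `depth_grid`.
#' @export
depth_grid <- function(pixel_um = 2.7, n_pixels = 223, sample_n = 1.376) {
  stopifnot(pixel_um > 0, n_pixels >= 1, sample_n >= 1)
  structure(list(pixel_um = pixel_um, n_pixels = as.integer(n_pixels),
                 sample_n = sample_n),
            class = "depth_grid")
}

#' Full simulation configuration
#'
#' Combines tissue, detector, source and depth-grid settings with the
#' per-A-scan photon budget, the number of A-scans per B-scan and the
#' master seed. Defaults reproduce the reference corneal setup:
#' 850/50 nm source, 223 x 2.7 um depth grid, 0.2 cm detector disc at
#' 100 um, 40 A-scans per B-scan, 15 million packets per A-scan.
#'
#' @param stack a [layer_stack()].
#' @param detector a [detector_spec()].
#' @param source a [source_spec()].
#' @param grid a [depth_grid()].
#' @param n_ascans A-scans (independent Monte-Carlo runs) per B-scan.
#' @param n_packets photon packets launched per A-scan.
#' @param seed master seed (non-negative integer-valued).
#' @return An object of class `oct_config`.
#' @export
oct_config <- function(stack = corneal_stack(0.1, 0.99),
                       detector = detector_spec(),
                       source = source_spec(),
                       grid = depth_grid(),
                       n_ascans = 40, n_packets = 15e6, seed = 1) {
  stopifnot(inherits(stack, "layer_stack"),
            inherits(detector, "detector_spec"),
            inherits(source, "source_spec"),
            inherits(grid, "depth_grid"),
            n_ascans >= 1, n_packets >= 1, seed >= 0)
  structure(list(stack = stack, detector = detector, source = source,
                 grid = grid, n_ascans = as.integer(n_ascans),
                 n_packets = n_packets, seed = seed),
            class = "oct_config")
}

#' Read / write a simulation configuration as YAML
#'
#' The YAML block mirrors the constructor arguments: `layers` (list of
#' `thickness_um`, `mu_s`, `mu_a`, `g`, `n`), `n_above`, `n_below`,
#' `detector: {radius_cm, height_um}`, `source: {lambda0_nm,
#' delta_lambda_nm}`, `grid: {pixel_um, n_pixels, sample_n}`,
#' `n_ascans`, `n_packets`, `seed`. Missing keys fall back to the
#' package defaults.
#'
#' @param path file path.
#' @return `read_oct_config()` returns an [oct_config()];
#'   `write_oct_config()` returns `path` invisibly.
#' @export
read_oct_config <- function(path) {
  y <- yaml::read_yaml(path)
  stack <- if (!is.null(y$layers)) {
    layer_stack(
      lapply(y$layers, function(l)
        list(thickness_um = l$thickness_um,
             props = optical_properties(
               mu_s = l$mu_s, mu_a = l$mu_a %||% 0,
               g = l$g, n = l$n %||% 1.376))),
      n_above = y$n_above %||% 1, n_below = y$n_below %||% 1.33)
  } else corneal_stack(0.1, 0.99)
  oct_config(
    stack = stack,
    detector = detector_spec(y$detector$radius_cm %||% 0.2,
                             y$detector$height_um %||% 100),
    source = source_spec(y$source$lambda0_nm %||% 850,
                         y$source$delta_lambda_nm %||% 50),
    grid = depth_grid(y$grid$pixel_um %||% 2.7,
                      y$grid$n_pixels %||% 223,
                      y$grid$sample_n %||% 1.376),
    n_ascans = y$n_ascans %||% 40,
    n_packets = y$n_packets %||% 15e6,
    seed = y$seed %||% 1)
}

#' @rdname read_oct_config
#' @param config an [oct_config()].
#' @export
write_oct_config <- function(config, path) {
  stopifnot(inherits(config, "oct_config"))
  y <- list(
    layers = lapply(config$stack$layers, function(l)
      list(thickness_um = l$thickness_um, mu_s = l$props$mu_s,
           mu_a = l$props$mu_a, g = l$props$g, n = l$props$n)),
    n_above = config$stack$n_above, n_below = config$stack$n_below,
    detector = config$detector[c("radius_cm", "height_um")],
    source = config$source[c("lambda0_nm", "delta_lambda_nm")],
    grid = config$grid[c("pixel_um", "n_pixels", "sample_n")],
    n_ascans = config$n_ascans, n_packets = config$n_packets,
    seed = config$seed)
  yaml::write_yaml(y, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
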