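#' Coherence length of a Gaussian-spectrum source
#'
#' \eqn{l_c = 2\ln(2)\,\lambda_0^2 / (\pi\,\Delta\lambda)}.
#'
#' @param lambda0_nm central wavelength, nm.
#' @param delta_lambda_nm FWHM bandwidth, nm.
#' @return Coherence length in um.
#' @examples
#' coherence_length(850, 50)  # 6.376 um
#' @export
coherence_length <- function(lambda0_nm, delta_lambda_nm) {
  stopifnot(lambda0_nm > 0, delta_lambda_nm > 0)
  2 * log(2) * lambda0_nm^2 / (pi * delta_lambda_nm) * 1e-3
}

#' Coherence-gated phasor sum over detected packets
#'
#' Core of the A-scan synthesis: for each reference optical delay
#' \eqn{L_{ref}(j)} the complex amplitude is
#' \deqn{U(j) = \sum_i \sqrt{W_i}\, G(\Delta L_{ij})\,
#'   e^{i 2\pi \Delta L_{ij}/\lambda_0},\quad
#'   \Delta L_{ij} = L_i - L_{ref}(j),}
#' where \eqn{G(\Delta) = \exp(-4\ln 2 (\Delta/l_c)^2)} is a Gaussian
#' coherence gate with FWHM equal to the coherence length. The raw
#' (carrier-bearing) signal is \eqn{Re\,U(j)} and the envelope is
#' \eqn{|U(j)|}.
#'
#' @param pathlength_um detected-packet optical pathlengths, um.
#' @param weight packet weights (same length).
#' @param lref_um reference optical delays per depth pixel, um.
#' @param lambda0_nm carrier wavelength, nm.
#' @param lc_um coherence length, um.
#' Contributions farther than 6 coherence lengths from a pixel's
#' reference delay are dropped (the gate is below 1e-30 there).
#'
#' @return List with numeric vectors `raw` and `envelope`, one value per
#'   reference delay.
#' @export
phasor_ascan <- function(pathlength_um, weight, lref_um, lambda0_nm,
                         lc_um) {
  stopifnot(length(pathlength_um) == length(weight))
  if (length(pathlength_um) == 0L)
    return(list(raw = numeric(length(lref_um)),
                envelope = numeric(length(lref_um))))
  .phasor_sum(as.numeric(pathlength_um), as.numeric(weight),
              as.numeric(lref_um), lambda0_nm * 1e-3, lc_um)
}

#' Synthesize one OCT A-scan from a transport tally
#'
#' Converts the detected-packet records of one Monte-Carlo run into a
#' coherence-gated A-scan. Depth pixel \eqn{j} (1-based) sits at
#' geometric depth \eqn{z_j = (j-1)\,\Delta z} and carries the
#' round-trip reference optical delay \eqn{L_{ref}(j) = 2\,n\,z_j}; the
#' air path above the sample is common to both interferometer arms and
#' cancels. An empty tally yields an all-zero A-scan.
#'
#' @param tally a [run_simulation()] result (may have zero detections).
#' @param grid a [depth_grid()].
#' @param source a [source_spec()].
#' @return An object of class `ascan` with fields `raw`, `envelope`
#'   (length `grid$n_pixels`), `lref_um`, and `n_detected`.
#' @export
synthesize_ascan <- function(tally, grid = depth_grid(),
                             source = source_spec()) {
  stopifnot(inherits(tally, "transport_tally"),
            inherits(grid, "depth_grid"),
            inherits(source, "source_spec"))
  z <- (seq_len(grid$n_pixels) - 1) * grid$pixel_um
  lref <- 2 * grid$sample_n * z
  ps <- phasor_ascan(tally$records$optical_pathlength,
                     tally$records$weight,
                     lref, source$lambda0_nm, source$lc_um)
  structure(list(raw = ps$raw, envelope = ps$envelope, lref_um = lref,
                 n_detected = tally$n_detected),
            class = "ascan")
}

#' Build a simulated B-scan envelope image
#'
#' Runs `n_ascans` independent transport simulations with identical
#' physical parameters but distinct derived sub-seeds (each A-scan is a
#' different realization of the speckle), synthesizes each A-scan, and
#' stacks the envelopes into a depth x A-scan image.
#'
#' @param config an [oct_config()]; its `stack`, `detector`, `source`
#'   and `grid` define the physics.
#' @param n_ascans,n_packets,seed optional overrides of the
#'   corresponding `config` fields.
#' @return An object of class `bscan_envelope`: `pixels` (matrix,
#'   `n_pixels` rows x `n_ascans` columns, all >= 0), `counts`
#'   (detected packets per column) and `meta` (mu_s, g, seed, n_packets,
#'   source, grid of the build).
#' @examples
#' cfg <- oct_config(corneal_stack(0.15, 0.9), n_packets = 2e4,
#'                   n_ascans = 4)
#' b <- build_bscan(cfg)
#' dim(b$pixels)
#' @export
build_bscan <- function(config, n_ascans = NULL, n_packets = NULL,
                        seed = NULL) {
  stopifnot(inherits(config, "oct_config"))
  n_ascans <- n_ascans %||% config$n_ascans
  n_packets <- n_packets %||% config$n_packets
  seed <- seed %||% config$seed
  n_pix <- config$grid$n_pixels
  pixels <- matrix(0, nrow = n_pix, ncol = n_ascans)
  counts <- integer(n_ascans)
  for (a in seq_len(n_ascans)) {
    tally <- run_simulation(config$stack, config$detector, n_packets,
                            seed = derive_seed(seed, a))
    asc <- synthesize_ascan(tally, config$grid, config$source)
    pixels[, a] <- asc$envelope
    counts[a] <- tally$n_detected
  }
  p1 <- config$stack$layers[[1]]$props
  structure(list(
    pixels = pixels, counts = counts,
    meta = list(mu_s = p1$mu_s, g = p1$g, seed = seed,
                n_packets = n_packets,
                source = config$source, grid = config$grid)),
    class = "bscan_envelope")
}

#' @export
print.bscan_envelope <- function(x, ...) {
  cat(sprintf(
    "<bscan_envelope> %d x %d  (mu_s = %g mm^-1, g = %g, %g packets/A-scan)\n",
    nrow(x$pixels), ncol(x$pixels), x$meta$mu_s, x$meta$g,
    x$meta$n_packets))
  cat(sprintf("  mean detected per A-scan: %.1f\n", mean(x$counts)))
  invisible(x)
}

#' Extract the simulated analysis ROI
#'
#' Keeps the top `depth_pixels` rows of the B-scan across its full
#' width. The default of 193 pixels (521 um at 2.7 um/pixel) excludes
#' the bright deepest rows produced by internal reflection at the
#' stroma-aqueous interface.
#'
#' @param bscan a `bscan_envelope` or a plain pixel matrix.
#' @param depth_pixels number of top rows to keep (default 193; must
#'   not exceed the image depth).
#' @return A `depth_pixels` x width pixel matrix.
#' @export
extract_sim_roi <- function(bscan, depth_pixels = 193) {
  pixels <- if (inherits(bscan, "bscan_envelope")) bscan$pixels else bscan
  stopifnot(is.matrix(pixels))
  if (depth_pixels > nrow(pixels))
    stop(sprintf("depth_pixels (%d) exceeds image depth (%d)",
                 depth_pixels, nrow(pixels)))
  pixels[seq_len(depth_pixels), , drop = FALSE]
}

#' Physical depth of an ROI
#'
#' @param depth_pixels number of axial pixels.
#' @param pixel_um axial pixel size, um.
#' @return Depth in um (e.g. 193 pixels x 2.7 um = 521.1 um).
#' @export
roi_depth_um <- function(depth_pixels, pixel_um = 2.7) {
  depth_pixels * pixel_um
}
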