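#' Sample a free-path step length
#'
#' Draws from the exponential step-length law of photon transport,
#' \eqn{s = -\ln(u) / \mu_t}, where \eqn{\mu_t = \mu_s + \mu_a} is the
#' total attenuation coefficient.
#'
#' @param mu_t total attenuation coefficient, mm^-1 (> 0; `mu_t = 0`
#'   signals a ballistic medium and is rejected here -- the transport
#'   loop routes such packets straight to the next boundary).
#' @param u uniform variate(s) in (0, 1].
#' @return Step length(s) in mm.
#' @examples
#' sample_step(0.1, 0.5)   # ln(2)/0.1 = 6.93 mm
#' @export
sample_step <- function(mu_t, u) .mc_sample_step(mu_t, u)

#' Sample a Henyey-Greenstein deflection cosine
#'
#' Inverse-CDF sampling of the Henyey-Greenstein phase function: for
#' \eqn{g \neq 0},
#' \eqn{\cos\theta = \frac{1}{2g}\left[1 + g^2 -
#'   \left(\frac{1-g^2}{1-g+2gu}\right)^2\right]},
#' and \eqn{\cos\theta = 2u - 1} for \eqn{g = 0}. The first moment of
#' the sampled cosine equals \eqn{g}.
#'
#' @param g anisotropy factor, strictly inside (-1, 1).
#' @param u uniform variate(s) in \[0, 1).
#' @return Deflection cosine(s) in \[-1, 1\].
#' @export
sample_scatter_cosine <- function(g, u) .mc_hg_cosine(g, u)

#' Unpolarized Fresnel reflectance at a refractive-index step
#'
#' Average of the s- and p-polarized Fresnel reflectances with Snell
#' refraction; beyond the critical angle the reflectance is 1 and the
#' refracted cosine is reported as 0.
#'
#' @param n1,n2 refractive indices of the incidence and transmission
#'   media.
#' @param cos_incident cosine of the incidence angle, in (0, 1].
#' @return List with `R` (reflectance in \[0, 1\]) and
#'   `cos_transmitted` (refracted cosine).
#' @examples
#' fresnel(1, 1.376, 1)$R  # normal-incidence air-to-cornea, 0.025
#' @export
fresnel <- function(n1, n2, cos_incident) .mc_fresnel(n1, n2, cos_incident)

#' Derive a deterministic sub-seed
#'
#' Stable splitmix64-based hash of `(master_seed, k)`, used to give
#' every A-scan and every look-up-map entry its own independent random
#' stream while keeping single entries rebuildable in isolation.
#'
#' @param master_seed non-negative integer-valued master seed.
#' @param k stream index (non-negative integer-valued).
#' @return A numeric seed in \[0, 2^53).
#' @export
derive_seed <- function(master_seed, k) .mc_derive_seed(master_seed, k)

#' Run the Monte-Carlo photon transport
#'
#' Launches `n_packets` independent photon packets at the origin of the
#' top surface, pointing straight down (infinitely thin normal beam),
#' and propagates each by alternating hop / drop / spin steps with
#' probabilistic Fresnel boundary events until it is transmitted below
#' the stack, absorbed, or exits the top surface (backscattered). A
#' backscattered packet is detected when the straight-line continuation
#' of its refracted exit ray to the detector plane lands within the
#' detector disc.
#'
#' Optical pathlength accumulates as geometric segment length times the
#' local refractive index, so detected-packet delays are directly
#' comparable with reference-arm optical delays. With `mu_a = 0` and
#' whole-packet boundary events every detected packet carries weight
#' exactly 1.
#'
#' @param stack a [layer_stack()].
#' @param detector a [detector_spec()].
#' @param n_packets number of packets to launch (>= 1).
#' @param seed seed for the run's private RNG stream.
#' @return An object of class `transport_tally`: counts `n_launched`,
#'   `n_backscattered`, `n_detected`, `n_scattered` (packets with at
#'   least one scattering event), `n_aborted` (non-finite state, always
#'   0 in practice), and `records`, a data frame of detected packets
#'   with columns `weight`, `optical_pathlength` (um), `exit_x`,
#'   `exit_y` (um), `exit_ux`, `exit_uy`, `exit_uz`.
#' @examples
#' tally <- run_simulation(corneal_stack(0.1, 0.99), detector_spec(),
#'                         n_packets = 1e4, seed = 7)
#' tally$n_detected
#' @export
run_simulation <- function(stack, detector = detector_spec(),
                           n_packets, seed) {
  stopifnot(inherits(stack, "layer_stack"),
            inherits(detector, "detector_spec"),
            n_packets >= 1, seed >= 0)
  layers <- t(vapply(stack$layers, function(l) c(
    l$thickness_um,
    l$props$mu_s * 1e-3,   # mm^-1 -> um^-1
    l$props$mu_a * 1e-3,
    l$props$g,
    l$props$n), numeric(5)))
  res <- .mc_run(layers, stack$n_above, stack$n_below,
                 detector$radius_cm * 1e4, detector$height_um,
                 n_packets, seed)
  records <- data.frame(
    weight = res$weight,
    optical_pathlength = res$optical_pathlength,
    exit_x = res$exit_x, exit_y = res$exit_y,
    exit_ux = res$exit_ux, exit_uy = res$exit_uy, exit_uz = res$exit_uz)
  structure(list(
    n_launched = res$n_launched,
    n_backscattered = res$n_backscattered,
    n_detected = res$n_detected,
    n_scattered = res$n_scattered,
    n_aborted = res$n_aborted,
    records = records,
    seed = seed), class = "transport_tally")
}

#' @export
print.transport_tally <- function(x, ...) {
  cat("<transport_tally>\n")
  cat(sprintf("  launched:      %d\n", as.integer(x$n_launched)))
  cat(sprintf("  backscattered: %d (%.4f%%)\n",
              as.integer(x$n_backscattered),
              100 * x$n_backscattered / x$n_launched))
  cat(sprintf("  detected:      %d (%.4f%%)\n",
              as.integer(x$n_detected),
              100 * x$n_detected / x$n_launched))
  invisible(x)
}
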