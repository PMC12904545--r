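# Coherence-gated A-scan synthesis and B-scan assembly.

fake_tally <- function(pathlength_um, weight = rep(1, length(pathlength_um))) {
  structure(list(
    n_launched = length(weight), n_backscattered = length(weight),
    n_detected = length(weight), n_scattered = 0, n_aborted = 0,
    records = data.frame(
      weight = weight, optical_pathlength = pathlength_um,
      exit_x = numeric(length(weight)), exit_y = numeric(length(weight)),
      exit_ux = numeric(length(weight)), exit_uy = numeric(length(weight)),
      exit_uz = rep(-1, length(weight))),
    seed = 0), class = "transport_tally")
}

test_that("coherence length follows the Gaussian-source formula", {
  expect_equal(coherence_length(850, 50), 6.37635, tolerance = 1e-5)
  expect_equal(coherence_length(1300, 100),
               2 * log(2) * 1300^2 / (pi * 100) * 1e-3, tolerance = 1e-12)
  expect_equal(coherence_length(1300, 100), 7.4575, tolerance = 1e-4)
  expect_equal(coherence_length(850, 100),
               coherence_length(850, 50) / 2, tolerance = 1e-12)
})

test_that("empty tally synthesizes an all-zero A-scan", {
  asc <- synthesize_ascan(fake_tally(numeric(0)))
  expect_length(asc$envelope, 223)
  expect_true(all(asc$envelope == 0))
  expect_true(all(asc$raw == 0))
})

test_that("a single on-pixel photon gives unit envelope there", {
  grid <- depth_grid()
  j <- 57
  lref <- 2 * grid$sample_n * (j - 1) * grid$pixel_um
  asc <- synthesize_ascan(fake_tally(lref), grid)
  expect_equal(asc$envelope[j], 1, tolerance = 1e-12)
  # neighbours are gated down but positive
  expect_lt(asc$envelope[j + 2], 1)
  expect_gt(asc$envelope[j + 2], 0)
})

test_that("two-phasor interference matches the closed form", {
  src <- source_spec()
  grid <- depth_grid()
  j <- 100
  lref <- 2 * grid$sample_n * (j - 1) * grid$pixel_um
  lam <- src$lambda0_nm * 1e-3
  d2 <- lam / 2
  asc <- synthesize_ascan(fake_tally(c(lref, lref + d2)), grid, src)
  # oracle: |G(0) e^{i0} + G(d2) e^{i pi}| = 1 - G(d2)
  gate <- exp(-4 * log(2) * (d2 / src$lc_um)^2)
  expect_equal(asc$envelope[j], abs(1 - gate), tolerance = 1e-9)
})

test_that("raw signal is bounded by the envelope and carries a carrier", {
  set.seed(301)
  paths <- runif(200, 0, 1650)
  asc <- synthesize_ascan(fake_tally(paths))
  expect_true(all(abs(asc$raw) <= asc$envelope + 1e-12))
  expect_true(any(asc$raw < 0))  # oscillates about zero
  expect_true(all(asc$envelope >= 0))
})

test_that("envelope is invariant under whole-wavelength path shifts", {
  set.seed(302)
  paths <- runif(150, 100, 1500)
  w <- runif(150, 0.5, 1)
  lref <- seq(0, 1650, by = 7.43)
  src <- source_spec()
  lam <- src$lambda0_nm * 1e-3
  a <- phasor_ascan(paths, w, lref, src$lambda0_nm, src$lc_um)
  b <- phasor_ascan(paths + 13 * lam, w, lref + 13 * lam,
                    src$lambda0_nm, src$lc_um)
  expect_equal(a$envelope, b$envelope, tolerance = 1e-9)
  expect_equal(a$raw, b$raw, tolerance = 1e-9)
})

test_that("B-scan assembly is deterministic with exchangeable columns", {
  cfg <- tiny_config(n_ascans = 40, n_packets = 2e4)
  b1 <- build_bscan(cfg)
  expect_equal(dim(b1$pixels), c(223, 40))
  expect_true(all(b1$pixels >= 0))
  b2 <- build_bscan(cfg)
  expect_identical(b1$pixels, b2$pixels)
  # distinct sub-seeds give distinct realizations
  expect_false(identical(b1$pixels[, 1], b1$pixels[, 2]))
  # per-column detection counts consistent with i.i.d. binomial
  # (dispersion index of a fixed-seed Poisson-like sample)
  disp <- stats::var(b1$counts) / mean(b1$counts)
  expect_gt(disp, 0.3)
  expect_lt(disp, 2.5)
})

test_that("ROI extraction keeps the top rows and checks bounds", {
  m <- matrix(runif(223 * 40), 223, 40)
  roi <- extract_sim_roi(m, 193)
  expect_equal(dim(roi), c(193, 40))
  expect_identical(roi, m[1:193, ])
  expect_identical(extract_sim_roi(m, 223), m)
  expect_error(extract_sim_roi(m, 224), "exceeds")
  expect_equal(roi_depth_um(193, 2.7), 521.1)
})
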