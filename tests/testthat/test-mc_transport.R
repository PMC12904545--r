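# Photon-packet transport: step law, phase function, Fresnel boundaries,
# full slab traces.

test_that("step-length sampling follows the exponential law", {
  expect_equal(sample_step(0.5, 1), 0)
  expect_equal(sample_step(0.1, 0.5), log(2) / 0.1, tolerance = 1e-12)
  set.seed(101)
  s <- sample_step(0.1, runif(1e5))
  # exponential mean 1/mu_t = 10 mm, se = 10/sqrt(n)
  expect_lt(abs(mean(s) - 10), 3 * 10 / sqrt(1e5))
  expect_error(sample_step(0, 0.5), "ballistic")
})

test_that("Henyey-Greenstein sampling has first moment g", {
  set.seed(202)
  for (g in c(0, 0.5, 0.9, 0.99)) {
    ct <- sample_scatter_cosine(g, runif(1e5))
    expect_true(all(ct >= -1 & ct <= 1))
    se <- stats::sd(ct) / sqrt(length(ct))
    expect_lt(abs(mean(ct) - g), 3 * se + 1e-6)
  }
})

test_that("strongly forward HG sampling concentrates near cos = 1", {
  # inverse-CDF oracle: the 5th percentile of cos(theta) is the inverse
  # CDF at u = 0.05, computable in closed form
  g <- 0.99
  frac <- (1 - g^2) / (1 - g + 2 * g * 0.05)
  q05_exact <- (1 + g^2 - frac^2) / (2 * g)
  expect_gt(q05_exact, 0.9)
  set.seed(203)
  q05 <- unname(quantile(sample_scatter_cosine(g, runif(1e5)), 0.05))
  expect_gt(q05, 0.9)
  expect_equal(q05, q05_exact, tolerance = 0.01)
  expect_error(sample_scatter_cosine(1, 0.5), "g must")
})

test_that("Fresnel reflectance matches closed forms", {
  expect_equal(fresnel(1.4, 1.4, 0.7)$R, 0)
  # normal incidence air -> cornea
  expect_equal(fresnel(1, 1.376, 1)$R, ((1.376 - 1) / (1.376 + 1))^2,
               tolerance = 1e-10)
  # beyond the critical angle asin(1/1.376) = 46.6 deg
  r <- fresnel(1.376, 1, cos(50 * pi / 180))
  expect_equal(r$R, 1)
  # reflectance bounded in [0, 1] over random geometries
  set.seed(204)
  for (i in 1:50) {
    rr <- fresnel(runif(1, 1, 1.6), runif(1, 1, 1.6), runif(1))$R
    expect_true(rr >= 0 && rr <= 1)
  }
})

test_that("non-scattering matched-index slab transmits every packet", {
  st <- corneal_stack(mu_s = 0, g = 0.9, n = 1.376,
                      n_above = 1.376, n_below = 1.376)
  tal <- run_simulation(st, detector_spec(), n_packets = 5000, seed = 5)
  expect_equal(tal$n_backscattered, 0)
  expect_equal(tal$n_scattered, 0)
  expect_equal(tal$n_detected, 0)
})

test_that("forward-only scattering with matched indices never detects", {
  st <- corneal_stack(mu_s = 5, g = 1, n = 1,
                      n_above = 1, n_below = 1)
  tal <- run_simulation(st, detector_spec(), n_packets = 5000, seed = 6)
  expect_gt(tal$n_scattered, 0)
  expect_equal(tal$n_backscattered, 0)
})

test_that("scattering-event fraction obeys Beer-Lambert ballistics", {
  # 600 um at mu_s = 0.1 mm^-1: P(>= 1 scatter) = 1 - exp(-0.06)
  tal <- run_simulation(corneal_stack(0.1, 0.99), detector_spec(),
                        n_packets = 1e5, seed = 7)
  p <- 1 - exp(-0.06)
  se <- sqrt(p * (1 - p) / 1e5)
  expect_lt(abs(tal$n_scattered / tal$n_launched - p), 4 * se)
})

test_that("tally invariants and determinism hold", {
  st <- corneal_stack(0.15, 0.9)
  t1 <- run_simulation(st, detector_spec(), n_packets = 5e4, seed = 11)
  t2 <- run_simulation(st, detector_spec(), n_packets = 5e4, seed = 11)
  expect_lte(t1$n_detected, t1$n_backscattered)
  expect_lte(t1$n_backscattered, t1$n_launched)
  expect_equal(nrow(t1$records), t1$n_detected)
  expect_equal(t1$n_aborted, 0)
  expect_identical(t1$records, t2$records)
  expect_identical(t1$n_backscattered, t2$n_backscattered)
  t3 <- run_simulation(st, detector_spec(), n_packets = 5e4, seed = 12)
  expect_false(identical(t1$records, t3$records))
})

test_that("absorption-free packets keep weight exactly 1", {
  tal <- run_simulation(corneal_stack(0.2, 0.85), detector_spec(),
                        n_packets = 1e5, seed = 13)
  expect_gt(tal$n_detected, 0)
  expect_true(all(tal$records$weight == 1))
  # detected packets exit into the upper half-space
  expect_true(all(tal$records$exit_uz < 0))
  expect_true(all(tal$records$optical_pathlength > 0))
})

test_that("detection counts rise with mu_s and fall with g", {
  det <- function(mu_s, g) {
    sum(vapply(1:3, function(s)
      run_simulation(corneal_stack(mu_s, g), detector_spec(),
                     n_packets = 2e5, seed = 100 + s)$n_detected,
      numeric(1)))
  }
  expect_gt(det(0.20, 0.99), det(0.10, 0.99))
  expect_gt(det(0.10, 0.85), det(0.10, 0.99))
})
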