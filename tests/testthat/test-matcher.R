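# Distance measures and ensemble matching against the look-up map.

toy_density <- function(grid, values) {
  structure(list(grid = grid, values = values, bandwidth = NA_real_),
            class = "density_estimate")
}

test_that("contrast-ratio distance is an absolute difference", {
  expect_equal(d_cr(0.5, 0.6), 0.1)
  expect_equal(d_cr(0.6, 0.5), d_cr(0.5, 0.6))
  s <- sim_summary(0.1, 0.99, seed = 61)
  expect_equal(d_cr(s, s), 0)
})

test_that("integrated squared density difference has closed forms", {
  g <- seq(0, 1, length.out = 101)
  f1 <- toy_density(g, rep(1, 101))
  f0 <- toy_density(g, rep(0, 101))
  expect_equal(d_rms(f1, f0), 1, tolerance = 1e-12)
  expect_equal(d_rms(f1, f1), 0)
  expect_equal(d_rms(f0, f1), d_rms(f1, f0))
  f_other <- toy_density(seq(0, 2, length.out = 101), rep(1, 101))
  expect_error(d_rms(f1, f_other), "same evaluation grid")
})

test_that("KL distance matches the two-bin oracle and is non-negative", {
  g <- c(0, 1)
  p <- toy_density(g, c(1, 1))        # masses {0.5, 0.5}
  q <- toy_density(g, c(0.5, 1.5))    # masses {0.25, 0.75}
  expect_equal(d_kl(p, q), 0.5 * log(2) + 0.5 * log(2 / 3),
               tolerance = 1e-9)
  expect_equal(d_kl(p, p), 0)
  set.seed(601)
  for (i in 1:20) {
    a <- toy_density(seq(0, 1, length.out = 64), runif(64))
    b <- toy_density(seq(0, 1, length.out = 64), runif(64))
    expect_gte(d_kl(a, b), 0)
  }
  # flooring keeps zero-valued tails finite
  z <- toy_density(g, c(1, 0))
  expect_true(is.finite(d_kl(p, z)))
})

test_that("ensemble averaging reproduces the published worked examples", {
  e1 <- ensemble_estimate(c(0.18, 0.10, 0.10), c(0.85, 0.91, 0.91))
  expect_equal(round(e1$mu_s_hat, 3), 0.127)
  expect_equal(round(e1$g_hat, 3), 0.890)
  e5 <- ensemble_estimate(c(0.12, 0.10, 0.14), c(0.95, 0.91, 0.97))
  expect_equal(round(e5$mu_s_hat, 3), 0.120)
  expect_equal(round(e5$g_hat, 3), 0.943)
})

test_that("group statistics of the published table reproduce", {
  tb <- porcine_table()
  expect_equal(nrow(tb), 33)
  expect_equal(length(unique(tb$eyeball)), 11)
  expect_equal(round(mean(tb$mu_s_hat), 3), 0.146)
  expect_equal(round(stats::sd(tb$mu_s_hat), 3), 0.020)
  expect_equal(round(mean(tb$g_hat), 3), 0.893)
  expect_equal(round(stats::sd(tb$g_hat), 3), 0.021)
})

test_that("matching a map entry's own summary is exact", {
  map <- tiny_map()
  for (e in map$entries) {
    r <- match_sample(e$summary, map)
    expect_equal(r$per_distance$min, c(0, 0, 0), tolerance = 1e-12)
    expect_equal(r$per_distance$mu_s, rep(e$mu_s, 3))
    expect_equal(r$per_distance$g, rep(e$g, 3))
    expect_equal(r$mu_s_hat, e$mu_s)
    expect_equal(r$g_hat, e$g)
  }
})

test_that("ensemble estimates stay inside the grid's convex hull", {
  map <- tiny_map()
  for (seed in 71:74) {
    s <- sim_summary(runif(1, 0.1, 0.2), runif(1, 0.85, 0.99),
                     seed = seed)
    r <- match_sample(s, map)
    expect_gte(r$mu_s_hat, min(map$grid$mu_s_values))
    expect_lte(r$mu_s_hat, max(map$grid$mu_s_values))
    expect_gte(r$g_hat, min(map$grid$g_values))
    expect_lte(r$g_hat, max(map$grid$g_values))
  }
})

test_that("repeat realizations estimate more tightly than distinct ones", {
  map <- tiny_map()
  est <- function(mu_s, g, seed)
    match_sample(sim_summary(mu_s, g, seed), map)
  reps <- lapply(81:83, function(s) est(0.10, 0.99, s))
  mu_rep <- vapply(reps, `[[`, numeric(1), "mu_s_hat")
  g_rep <- vapply(reps, `[[`, numeric(1), "g_hat")
  c1 <- est(0.10, 0.99, 84)
  c2 <- est(0.20, 0.85, 85)
  # spread across repeats no larger than the corner-to-corner spread
  expect_lte(max(mu_rep) - min(mu_rep),
             abs(c2$mu_s_hat - c1$mu_s_hat) + 0.05)
  expect_lte(max(g_rep) - min(g_rep),
             abs(c2$g_hat - c1$g_hat) + 0.07)
})

test_that("an all-invalid map is rejected", {
  map <- tiny_map()
  broken <- map
  broken$entries <- lapply(broken$entries, function(e) {
    e$valid <- FALSE
    e
  })
  s <- sim_summary(0.1, 0.99, seed = 91)
  expect_error(match_sample(s, broken), "no valid entries")
})
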