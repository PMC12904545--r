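# Shared low-budget fixtures, built once per test run.
#
# The reduced scales (a 2 x 2 parameter grid, 8 A-scans, 3e4 packets per
# A-scan) keep the suite fast while leaving enough detections per entry
# for the speckle statistics to be well defined.

tiny_config <- function(n_ascans = 8, n_packets = 3e4, seed = 421) {
  oct_config(n_ascans = n_ascans, n_packets = n_packets, seed = seed)
}

tiny_grid <- function() {
  parameter_grid(mu_s_values = c(0.10, 0.20), g_values = c(0.85, 0.99))
}

# memoized small map shared across test files
.fixture_cache <- new.env(parent = emptyenv())

tiny_map <- function() {
  if (is.null(.fixture_cache$map))
    .fixture_cache$map <- build_map(tiny_grid(), tiny_config(),
                                    master_seed = 99)
  .fixture_cache$map
}

# a reference-style ROI summary at arbitrary parameters
sim_summary <- function(mu_s, g, seed, n_packets = 3e4) {
  e <- build_map_entry(1, mu_s, g, tiny_config(), n_packets, seed)
  e$summary
}
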