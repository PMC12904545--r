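#' Parameter grid of the look-up map
#'
#' Strictly increasing value lists for the scattering coefficient and
#' anisotropy factor. The defaults reproduce the reference corneal
#' grid: mu_s from 0.10 to 0.20 mm^-1 in steps of 0.01 (11 values) and
#' g from 0.85 to 0.99 in steps of 0.01 (15 values), i.e. 165 pairs.
#'
#' @param mu_s_values scattering coefficients, mm^-1.
#' @param g_values anisotropy factors.
#' @return An object of class `parameter_grid`.
#' @export
parameter_grid <- function(mu_s_values = seq(0.10, 0.20, by = 0.01),
                           g_values = seq(0.85, 0.99, by = 0.01)) {
  for (v in list(mu_s_values, g_values)) {
    stopifnot(is.numeric(v), length(v) >= 1)
    if (anyDuplicated(v)) stop("duplicate values in a grid list")
    if (is.unsorted(v, strictly = TRUE))
      stop("grid values must be strictly increasing")
  }
  structure(list(mu_s_values = mu_s_values, g_values = g_values),
            class = "parameter_grid")
}

#' Enumerate the (mu_s, g) pairs of a grid
#'
#' Cartesian product in row-major order: mu_s varies slowest, g
#' fastest. The entry index `k` runs from 1 to the product of the two
#' list lengths.
#'
#' @param grid a [parameter_grid()].
#' @return Data frame with columns `k`, `mu_s`, `g`.
#' @examples
#' nrow(enumerate_grid(parameter_grid()))  # 165
#' @export
enumerate_grid <- function(grid) {
  stopifnot(inherits(grid, "parameter_grid"))
  pairs <- expand.grid(g = grid$g_values, mu_s = grid$mu_s_values,
                       KEEP.OUT.ATTRS = FALSE)
  data.frame(k = seq_len(nrow(pairs)), mu_s = pairs$mu_s, g = pairs$g)
}

#' Build one look-up-map entry
#'
#' Simulates the B-scan for one (mu_s, g) grid point with a
#' deterministic sub-seed derived from the master seed and the entry
#' index, extracts the analysis ROI and summarizes its speckle. Entry
#' content depends only on (mu_s, g, sub-seed), never on build order,
#' so single entries can be rebuilt in isolation.
#'
#' @param k entry index.
#' @param mu_s,g grid-point optical parameters.
#' @param config an [oct_config()] template (its stack's mu_s/g are
#'   replaced; all other physics kept).
#' @param n_packets packets per A-scan.
#' @param master_seed map master seed.
#' @param roi_depth_px ROI depth in pixels (default 193).
#' @return A `reference_entry` list: `k`, `mu_s`, `g`, `seed`, `roi`,
#'   `counts`, `summary` (NULL when flagged invalid), `valid`.
#' @export
build_map_entry <- function(k, mu_s, g, config, n_packets, master_seed,
                            roi_depth_px = 193) {
  sub_seed <- derive_seed(master_seed, k)
  layer1 <- config$stack$layers[[1]]
  stack <- layer_stack(
    c(list(list(thickness_um = layer1$thickness_um,
                props = optical_properties(mu_s, layer1$props$mu_a, g,
                                           layer1$props$n))),
      config$stack$layers[-1]),
    n_above = config$stack$n_above, n_below = config$stack$n_below)
  cfg_k <- oct_config(stack, config$detector, config$source,
                      config$grid, config$n_ascans, n_packets, sub_seed)
  b <- build_bscan(cfg_k)
  roi <- extract_sim_roi(b, roi_depth_px)
  valid <- any(roi > 0)
  structure(list(
    k = k, mu_s = mu_s, g = g, seed = sub_seed, roi = roi,
    counts = b$counts,
    summary = if (valid) speckle_summary(roi, "sim") else NULL,
    valid = valid), class = "reference_entry")
}

#' Build the multi-reference look-up map
#'
#' One simulated B-scan ROI plus speckle summary per (mu_s, g) grid
#' point. A grid point whose B-scan detects no photons in any column is
#' kept but flagged invalid and excluded from matching.
#'
#' @param grid a [parameter_grid()].
#' @param config an [oct_config()] template for the physics.
#' @param n_packets packets per A-scan (default from `config`).
#' @param master_seed map master seed (default from `config`).
#' @param roi_depth_px ROI depth in pixels.
#' @param verbose print per-entry progress.
#' @return An object of class `lookup_map`: `entries` (list of
#'   `reference_entry`, length = grid product), `grid`, and
#'   `provenance` (config, n_packets, master_seed, schema version).
#' @export
build_map <- function(grid, config = oct_config(), n_packets = NULL,
                      master_seed = NULL, roi_depth_px = 193,
                      verbose = FALSE) {
  stopifnot(inherits(grid, "parameter_grid"),
            inherits(config, "oct_config"))
  n_packets <- n_packets %||% config$n_packets
  master_seed <- master_seed %||% config$seed
  pairs <- enumerate_grid(grid)
  entries <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    entries[[i]] <- build_map_entry(pairs$k[i], pairs$mu_s[i],
                                    pairs$g[i], config, n_packets,
                                    master_seed, roi_depth_px)
    if (verbose)
      message(sprintf("entry %d/%d: mu_s = %g, g = %g, mean count %.1f",
                      i, nrow(pairs), pairs$mu_s[i], pairs$g[i],
                      mean(entries[[i]]$counts)))
  }
  structure(list(
    entries = entries, grid = grid,
    provenance = list(schema = MAP_SCHEMA, config = config,
                      n_packets = n_packets, master_seed = master_seed,
                      roi_depth_px = roi_depth_px,
                      package_version =
                        as.character(utils::packageVersion("octspeckle")))),
    class = "lookup_map")
}

MAP_SCHEMA <- "octspeckle-map/1"

#' @export
print.lookup_map <- function(x, ...) {
  cat(sprintf("<lookup_map> %d entries (%d mu_s x %d g), %g packets/A-scan\n",
              length(x$entries), length(x$grid$mu_s_values),
              length(x$grid$g_values), x$provenance$n_packets))
  invisible(x)
}

#' Per-entry mean detected counts of a map
#'
#' @param map a [build_map()] result.
#' @return Data frame with columns `k`, `mu_s`, `g`, `mean_count`.
#' @export
map_counts <- function(map) {
  stopifnot(inherits(map, "lookup_map"))
  do.call(rbind, lapply(map$entries, function(e)
    data.frame(k = e$k, mu_s = e$mu_s, g = e$g,
               mean_count = mean(e$counts))))
}

#' Save / load a look-up map
#'
#' Serializes the map losslessly (pixels, summaries, provenance) with
#' an explicit schema version; loading a file written under a different
#' schema, or a truncated/foreign file, raises a structured error.
#'
#' @param map a `lookup_map`.
#' @param path file path (conventionally `.rds`).
#' @return `save_map()` returns `path` invisibly; `load_map()` returns
#'   the `lookup_map`.
#' @export
save_map <- function(map, path) {
  stopifnot(inherits(map, "lookup_map"))
  saveRDS(list(schema = MAP_SCHEMA, map = map), path)
  invisible(path)
}

#' @rdname save_map
#' @export
load_map <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop(sprintf("cannot read look-up map from '%s': %s", path,
                 conditionMessage(e)), call. = FALSE))
  if (!is.list(obj) || is.null(obj$schema))
    stop(sprintf("'%s' is not an octspeckle look-up map file", path),
         call. = FALSE)
  if (!identical(obj$schema, MAP_SCHEMA))
    stop(sprintf("map schema mismatch: found '%s', expected '%s'",
                 obj$schema, MAP_SCHEMA), call. = FALSE)
  obj$map
}
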