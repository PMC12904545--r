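#' Experimental imaging grid
#'
#' Pixel geometry of the device B-scans: 3.25 um laterally, 2.70 um
#' axially, frames of 1538 x ~733 pixels.
#'
#' @param pixel_x_um lateral pixel size, um.
#' @param pixel_z_um axial pixel size, um.
#' @param width_px,depth_px frame dimensions in pixels.
#' @return An object of class `imaging_grid`.
#' @export
imaging_grid <- function(pixel_x_um = 3.25, pixel_z_um = 2.70,
                         width_px = 1538, depth_px = 733) {
  stopifnot(pixel_x_um > 0, pixel_z_um > 0)
  structure(list(pixel_x_um = pixel_x_um, pixel_z_um = pixel_z_um,
                 width_px = as.integer(width_px),
                 depth_px = as.integer(depth_px)),
            class = "imaging_grid")
}

#' Read an 8-bit grayscale B-scan image
#'
#' Reads PNG or TIFF, verifies 8-bit grayscale content, and returns the
#' integer pixel matrix (rows = depth, columns = lateral position) in
#' \[0, 255\] together with the pixel-size metadata.
#'
#' @param path image file (`.png`, `.tif`/`.tiff`).
#' @param grid an [imaging_grid()] describing the pixel sizes.
#' @return List with `pixels` (integer matrix) and `grid`.
#' @export
read_bscan <- function(path, grid = imaging_grid()) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    info <- attr(img, "info")
    if (!is.null(info$bit.depth) && info$bit.depth != 8)
      stop(sprintf(
        "'%s' is %d-bit; convert to 8-bit grayscale first", path,
        info$bit.depth))
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(img, "bits.per.sample")
    if (!is.null(bits) && bits != 8)
      stop(sprintf(
        "'%s' is %d-bit; convert to 8-bit grayscale first", path, bits))
  } else {
    stop(sprintf("unsupported image format '.%s' (use PNG or TIFF)",
                 ext))
  }
  if (length(dim(img)) == 3) {
    if (dim(img)[3] > 1 &&
        !all(img[, , 1] == img[, , min(2, dim(img)[3])]))
      stop("color image; convert to 8-bit grayscale first")
    img <- img[, , 1]
  }
  grid$width_px <- ncol(img)
  grid$depth_px <- nrow(img)
  list(pixels = matrix(as.integer(round(img * 255)), nrow(img),
                       ncol(img)),
       grid = grid)
}

#' Write an 8-bit grayscale B-scan image
#'
#' @param pixels integer matrix with values in \[0, 255\].
#' @param path output `.png` path.
#' @return `path`, invisibly.
#' @export
write_bscan <- function(pixels, path) {
  stopifnot(is.matrix(pixels), all(pixels >= 0), all(pixels <= 255))
  png::writePNG(pixels / 255, path)
  invisible(path)
}

#' Locate the tissue surface and extract the analysis ROI
#'
#' Per column, the surface row is the first pixel whose lightly
#' intensity exceeds `threshold` while the running mean of the `smooth`
#' rows below it also exceeds it (suppressing sub-threshold noise). The
#' corneal apex is the middle column of the run of minimal surface rows
#' within the central third of the frame. The ROI is
#' `depth_px` rows below the surface by `width_px` columns centered on
#' the apex, flattened per column so that ROI row 1 is each column's
#' own surface row.
#'
#' @param image integer pixel matrix (rows = depth).
#' @param width_px ROI width in columns (default 308, about 1000 um at
#'   3.25 um/pixel).
#' @param depth_px ROI depth in rows (default 193, about 520 um).
#' @param threshold 8-bit intensity threshold for surface detection.
#' @param smooth axial running-mean window, pixels.
#' @param center_column optional apex override (disables detection).
#' @return `depth_px` x `width_px` matrix with attributes
#'   `apex_column`, `columns`, `surface_rows`.
#' @export
locate_surface_and_roi <- function(image, width_px = 308,
                                   depth_px = 193, threshold = 30,
                                   smooth = 5, center_column = NULL) {
  stopifnot(is.matrix(image), width_px >= 1, depth_px >= 1)
  nr <- nrow(image); nc <- ncol(image)
  surface <- vapply(seq_len(nc), function(j) {
    x <- image[, j]
    # leading running mean over the `smooth` rows below each candidate:
    # the window sits inside the tissue at a genuine surface, so dim
    # first rows do not defeat detection; the raw criterion pins the
    # surface to the first genuinely bright pixel
    cs <- cumsum(c(0, x))
    hi <- pmin(seq_len(nr) + smooth - 1, nr)
    lead <- (cs[hi + 1] - cs[seq_len(nr)]) / (hi - seq_len(nr) + 1)
    i <- which(x > threshold & lead > threshold)
    if (length(i)) i[1] else NA_integer_
  }, numeric(1))
  if (is.null(center_column)) {
    central <- seq(floor(nc / 3) + 1, ceiling(2 * nc / 3))
    cand <- central[!is.na(surface[central])]
    if (!length(cand))
      stop("no tissue surface found in the central columns")
    # the discrete apex of a curved surface is a flat run of minimal
    # rows; take its middle column
    top <- cand[surface[cand] == min(surface[cand])]
    center_column <- top[(length(top) + 1) %/% 2]
  }
  cols <- (center_column - floor((width_px - 1) / 2)):
    (center_column + ceiling((width_px - 1) / 2))
  if (cols[1] < 1 || cols[width_px] > nc)
    stop("ROI width exceeds image bounds around the apex")
  if (any(is.na(surface[cols])))
    stop("no tissue surface found in some ROI columns")
  if (any(surface[cols] + depth_px - 1 > nr))
    stop("ROI depth exceeds image bounds below the surface")
  roi <- vapply(seq_along(cols), function(i) {
    r0 <- surface[cols[i]]
    image[r0:(r0 + depth_px - 1), cols[i]]
  }, numeric(depth_px))
  structure(roi, apex_column = center_column, columns = cols,
            surface_rows = surface[cols])
}

#' Generate a device-like synthetic fixture image
#'
#' Simulates a B-scan ROI at known (mu_s, g), log10-compresses it,
#' affinely maps the result to the 8-bit range \[40, 250\], and embeds
#' it below a synthetic curved surface in a larger frame over a
#' low-level noise background -- an invertible stand-in for a
#' log-compressed device image, so the full experimental pipeline
#' (surface detection, ROI extraction, [normalize_exp()], matching) is
#' testable without real corneal data. The ground truth is returned
#' alongside.
#'
#' @param mu_s,g true optical parameters of the simulated tissue.
#' @param config an [oct_config()] template for the physics.
#' @param n_packets packets per A-scan.
#' @param seed fixture seed (drives both the simulation and the
#'   background noise).
#' @param noise_floor maximum 8-bit level of the background noise.
#' @param frame_rows,frame_cols frame size, pixels.
#' @param surface_row apex surface row.
#' @param curvature parabolic surface sag, pixels per column^2.
#' @param roi_depth_px embedded ROI depth, pixels.
#' @return An object of class `oct_fixture`: `image` (integer matrix),
#'   `truth` (list: mu_s, g, seed, apex_column, surface_rows,
#'   columns), and `envelope_roi` (the pre-compression envelope block).
#' @export
make_fixture <- function(mu_s, g, config = oct_config(),
                         n_packets = 2e5, seed = 1, noise_floor = 8,
                         frame_rows = 256, frame_cols = 120,
                         surface_row = 30, curvature = 0.025,
                         roi_depth_px = 193) {
  entry <- build_map_entry(k = 0, mu_s = mu_s, g = g, config = config,
                           n_packets = n_packets, master_seed = seed,
                           roi_depth_px = roi_depth_px)
  roi <- entry$roi
  if (!entry$valid) stop("fixture simulation detected no photons")
  lg <- log10(roi + max(roi) * 1e-3)
  comp <- round(40 + (lg - min(lg)) / (max(lg) - min(lg)) * 210)

  n_roi_cols <- ncol(roi)
  apex <- ceiling(frame_cols / 2)
  cols <- (apex - floor((n_roi_cols - 1) / 2)):
    (apex + ceiling((n_roi_cols - 1) / 2))
  surf <- surface_row + round(curvature * (cols - apex)^2)
  if (max(surf) + roi_depth_px - 1 > frame_rows)
    stop("frame too shallow for the embedded ROI")

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(derive_seed(seed, 9001) %% 2^31))
  image <- matrix(sample.int(noise_floor + 1L, frame_rows * frame_cols,
                             replace = TRUE) - 1L,
                  frame_rows, frame_cols)
  for (i in seq_along(cols))
    image[surf[i]:(surf[i] + roi_depth_px - 1), cols[i]] <- comp[, i]
  structure(list(
    image = image,
    truth = list(mu_s = mu_s, g = g, seed = seed, apex_column = apex,
                 surface_rows = surf, columns = cols),
    envelope_roi = roi), class = "oct_fixture")
}
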