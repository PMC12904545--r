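#' Normalize a simulated ROI
#'
#' Divides the block by its maximum and then by the root-mean-square of
#' the result, so the output has RMS exactly 1 and is invariant to
#' positive rescaling of the input.
#'
#' @param roi numeric pixel block (matrix or vector) with at least one
#'   non-zero pixel.
#' @return Normalized block of the same shape.
#' @export
normalize_sim <- function(roi) {
  stopifnot(is.numeric(roi))
  m <- max(roi)
  if (!(m > 0)) stop("all-zero ROI cannot be normalized")
  x <- roi / m
  x / sqrt(mean(x^2))
}

#' Normalize an experimental (8-bit, log-compressed) ROI
#'
#' Divides the 8-bit block by 255, divides by the RMS of the result,
#' and inverse-transforms the device's log compression with the power
#' function \eqn{y = 10^x}. All outputs are >= 1 since \eqn{x \ge 0}.
#'
#' @param roi pixel block with values in \[0, 255\], not all zero.
#' @return Transformed block of the same shape.
#' @export
normalize_exp <- function(roi) {
  stopifnot(is.numeric(roi), all(roi >= 0), all(roi <= 255))
  if (!any(roi > 0)) stop("all-zero ROI cannot be normalized")
  x <- roi / 255
  x <- x / sqrt(mean(x^2))
  10^x
}

#' Speckle contrast ratio
#'
#' Sample standard deviation divided by the mean of the block's pixels
#' (the standard speckle-contrast definition, with the n-1 variance).
#' Invariant under positive rescaling, so it is unchanged by
#' [normalize_sim()].
#'
#' @param block numeric pixel block with >= 2 pixels and positive mean.
#' @return Dimensionless contrast ratio.
#' @examples
#' contrast_ratio(c(1, 2, 3))  # 0.5
#' @export
contrast_ratio <- function(block) {
  stopifnot(is.numeric(block), length(block) >= 2)
  m <- mean(block)
  if (!(m > 0)) stop("block mean must be positive")
  stats::sd(block) / m
}

#' Kernel density estimate on a fixed grid
#'
#' Gaussian-kernel density estimate of the block's pixel values,
#' evaluated on an equally spaced shared grid so that two estimates can
#' be compared point-by-point. The bandwidth defaults to Silverman's
#' rule of thumb ([stats::bw.nrd0()]).
#'
#' @param block numeric pixel block with at least 2 distinct values.
#' @param grid equally spaced evaluation abscissae; defaults to 512
#'   points spanning \[0, 1.05 x max(block)\].
#' @param bandwidth kernel bandwidth; default Silverman.
#' @return An object of class `density_estimate` with fields `grid`,
#'   `values` (>= 0) and `bandwidth`.
#' @export
estimate_density <- function(block, grid = NULL, bandwidth = NULL) {
  x <- as.numeric(block)
  if (length(unique(x)) < 2)
    stop("degenerate (single-valued) block: no density to estimate")
  bandwidth <- bandwidth %||% stats::bw.nrd0(x)
  grid <- grid %||% seq(0, 1.05 * max(x), length.out = 512)
  stopifnot(length(grid) >= 2)
  d <- stats::density(x, bw = bandwidth, from = grid[1],
                      to = grid[length(grid)], n = length(grid))
  structure(list(grid = grid, values = pmax(d$y, 0),
                 bandwidth = bandwidth),
            class = "density_estimate")
}

#' Speckle summary of an ROI
#'
#' The matching currency of the look-up approach: the contrast ratio of
#' the appropriately normalized ROI together with everything needed to
#' evaluate its kernel density estimate on any shared grid (the
#' normalized pixel values and a fixed Silverman bandwidth). The
#' `density` field holds the estimate on the block's own default grid;
#' [match_sample()] re-evaluates both densities on a joint grid per
#' comparison, as the distance integrals require a common abscissa.
#'
#' @param roi pixel block.
#' @param kind `"sim"` applies [normalize_sim()], `"exp"` applies
#'   [normalize_exp()], `"none"` uses the block as is.
#' @return An object of class `speckle_summary` with fields `cr`,
#'   `values`, `bandwidth`, `density`, `kind`.
#' @export
speckle_summary <- function(roi, kind = c("sim", "exp", "none")) {
  kind <- match.arg(kind)
  block <- switch(kind,
                  sim = normalize_sim(roi),
                  exp = normalize_exp(roi),
                  none = roi)
  values <- as.numeric(block)
  bw <- stats::bw.nrd0(values)
  structure(list(cr = contrast_ratio(values),
                 values = values,
                 bandwidth = bw,
                 density = estimate_density(values, bandwidth = bw),
                 kind = kind),
            class = "speckle_summary")
}

#' @export
print.speckle_summary <- function(x, ...) {
  cat(sprintf("<speckle_summary> kind = %s, n = %d pixels, CR = %.4f\n",
              x$kind, length(x$values), x$cr))
  invisible(x)
}
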