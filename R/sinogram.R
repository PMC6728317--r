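#' Angle grid for a tilt series
#'
#' Uniformly spaced projection angles in degrees spanning a half-turn:
#' `max - min + step == 180`.  The default is `-90, ..., +89` in 1-degree
#' steps (180 projections).
#'
#' @param step angular step in degrees.
#' @param start first angle in degrees (default `-90`).
#' @return list of class `"angle_grid"` with `angles` (degrees) and `step`.
#' @export
angle_grid <- function(step = 1, start = -90) {
  if (step <= 0 || 180 %% step != 0)
    abort("`step` must be a positive divisor of 180")
  angles <- seq(start, start + 180 - step, by = step)
  structure(list(angles = angles, step = step), class = "angle_grid")
}

#' Missing-wedge specification
#'
#' Parameterized by the total number of degrees of unacquired projections
#' (a tilt series limited to +/-70 degrees misses 40 degrees; the package
#' default models a 45-degree missing wedge).  The acquired half-range is
#' `(180 - missing_total) / 2`.
#'
#' @param missing_total degrees of absent projections, in `[0, 180)`.
#' @return list of class `"wedge_spec"`.
#' @export
wedge_spec <- function(missing_total = 45) {
  if (missing_total < 0 || missing_total >= 180)
    abort("`missing_total` must lie in [0, 180)")
  structure(list(missing_total = missing_total,
                 acquired_halfrange = (180 - missing_total) / 2),
            class = "wedge_spec")
}

new_sinogram <- function(values, angles, mask, scale = 1) {
  stopifnot(nrow(values) == length(angles), length(mask) == length(angles),
            scale > 0)
  structure(list(values = values, angles = angles, mask = mask,
                 scale = scale), class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf(
    "<sinogram: %d angles x %d bins, %d acquired / %d missing, scale %g>\n",
    nrow(x$values), ncol(x$values), sum(x$mask), sum(!x$mask), x$scale))
  invisible(x)
}

#' Forward-project a phantom into a sinogram
#'
#' Computes the discrete parallel-beam Radon transform.  Rows index angles,
#' columns index detector bins; the detector has as many unit-spaced bins as
#' the image side length.  Each pixel's full mass is split linearly between
#' its two neighbouring bins, so every row's sum equals the total image mass
#' exactly for content inside the inscribed circle.  The result is raw
#' (unnormalized) line integrals with `scale = 1` and an all-acquired mask.
#'
#' @param img square numeric matrix (phantom) with inscribed-circle support.
#' @param grid an [angle_grid()].
#' @return a `sinogram`.
#' @export
forward_project <- function(img, grid = angle_grid()) {
  stopifnot(is.matrix(img), nrow(img) == ncol(img))
  n <- nrow(img)
  ctr <- (n - 1) / 2
  xs <- matrix(rep(seq_len(n) - 1 - ctr, each = n), n)
  ys <- matrix(rep(seq_len(n) - 1 - ctr, times = n), n)
  outside <- img != 0 & (xs^2 + ys^2 >= (n / 2 - 0.5)^2)
  if (any(outside))
    warning("content outside the inscribed circle; projected mass may be ",
            "lost at steep angles", call. = FALSE)
  values <- cpp_radon_forward(unclass(img), grid$angles * pi / 180)
  new_sinogram(values, grid$angles, rep(TRUE, length(grid$angles)), scale = 1)
}

#' Apply a missing wedge to a sinogram
#'
#' Rows whose angle magnitude exceeds the acquired half-range are flagged
#' missing; with `pad_zeros` they are set to zero (the network-input form).
#' Acquired rows are untouched, and re-applying the same wedge is a no-op.
#'
#' @param sino a `sinogram`.
#' @param wedge a [wedge_spec()].
#' @param pad_zeros zero out the missing rows (default TRUE).
#' @return a `sinogram` with an updated mask.
#' @export
apply_missing_wedge <- function(sino, wedge, pad_zeros = TRUE) {
  if (wedge$missing_total >= 180) abort("wedge must leave some projections")
  missing <- abs(sino$angles) > wedge$acquired_halfrange
  mask <- sino$mask & !missing
  values <- sino$values
  if (pad_zeros) values[!mask, ] <- 0
  new_sinogram(values, sino$angles, mask, sino$scale)
}

#' Normalize / denormalize a sinogram
#'
#' Divides the values by a corpus-level constant -- by default the detector
#' bin count, the maximum possible line-integral of a `[0, 1]` image -- and
#' records it so the transform is exactly invertible (`values / scale`
#' recovers the raw line integrals).
#'
#' @param sino a `sinogram`.
#' @param constant positive normalization constant; default
#'   `ncol(sino$values)`.
#' @return a `sinogram` with values in `[0, 1]` for any `[0, 1]` phantom.
#' @export
normalize_sinogram <- function(sino, constant = NULL) {
  constant <- constant %||% ncol(sino$values)
  if (!is.numeric(constant) || constant <= 0)
    abort("normalization constant must be positive")
  new_sinogram(sino$values / constant, sino$angles, sino$mask,
               scale = sino$scale / constant)
}

#' @rdname normalize_sinogram
#' @export
denormalize_sinogram <- function(sino) {
  new_sinogram(sino$values / sino$scale, sino$angles, sino$mask, scale = 1)
}

#' Write / read a sinogram
#'
#' Stored as a 32-bit float TIFF of the (possibly rescaled) values plus a
#' JSON sidecar (`<path>.json`) carrying the angle grid, acquisition mask,
#' normalization scale, and value range.
#'
#' @param sino a `sinogram`.
#' @param path TIFF file path.
#' @return `read_sinogram` returns a `sinogram`.
#' @export
write_sinogram <- function(sino, path) {
  rng <- range(sino$values)
  span <- max(rng[2] - rng[1], .Machine$double.eps)
  tiff::writeTIFF((sino$values - rng[1]) / span, path, bits.per.sample = 32, compression = "none")
  jsonlite::write_json(
    list(angles = sino$angles, mask = sino$mask, scale = sino$scale,
         vmin = rng[1], vmax = rng[2]),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sinogram
#' @export
read_sinogram <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  v <- tiff::readTIFF(path)
  span <- max(meta$vmax - meta$vmin, .Machine$double.eps)
  new_sinogram(v * span + meta$vmin, meta$angles, meta$mask, meta$scale)
}

# Build (complete, masked) normalized sinogram pairs from a list of phantoms.
#' Make paired training sinograms
#'
#' For each phantom: forward-project, normalize, and create the zero-padded
#' missing-wedge counterpart.  These pairs are the training substrate of the
#' inpainting model (complete sinogram = ground truth, masked = input).
#'
#' @param phantoms list of phantom matrices.
#' @param grid an [angle_grid()].
#' @param wedge a [wedge_spec()].
#' @return list of `list(real, masked)` sinogram pairs.
#' @export
make_sinogram_pairs <- function(phantoms, grid = angle_grid(),
                                wedge = wedge_spec()) {
  lapply(phantoms, function(ph) {
    full <- normalize_sinogram(forward_project(ph, grid))
    list(real = full, masked = apply_missing_wedge(full, wedge))
  })
}
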