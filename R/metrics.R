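# Full-reference fidelity metrics.  All metrics are computed on the 0-255
# display scale: the test image is clipped to the reference's intensity
# range and both are mapped linearly so the reference spans 0-255 (the
# convention implied by 8-bit PSNR magnitudes).

to_display_scale <- function(reference, test) {
  # references on the [0, 1] phantom convention are mapped to 0-255; inputs
  # already on a display scale are used as-is.  The test image (e.g. a WBP
  # reconstruction with overshoot) is clipped to the valid display range.
  f <- if (max(abs(reference)) <= 1.5) 255 else 1
  list(ref = reference * f, test = pmin(pmax(test * f, 0), 255))
}

#' PSNR, SSIM and RMSE of a reconstruction against its ground truth
#'
#' `PSNR = 10 log10(255^2 / MSE)` with `MAX = 255`; SSIM uses the standard
#' 11x11 Gaussian window (sigma 1.5) and default stabilizers
#' `C1 = (0.01 * 255)^2`, `C2 = (0.03 * 255)^2`; RMSE is on the same 0-255
#' scale.  Identical images report `psnr = Inf`, `ssim = 1`, `rmse = 0`.
#'
#' @param reference ground-truth matrix (or `tomogram`).
#' @param test reconstruction of the same shape.
#' @return a one-row tibble with columns `psnr`, `ssim`, `rmse`.
#' @export
fidelity_metrics <- function(reference, test) {
  reference <- unclass(reference); test <- unclass(test)
  if (!all(dim(reference) == dim(test)))
    abort("reference and test must have the same shape")
  sc <- to_display_scale(reference, test)
  mse <- mean((sc$ref - sc$test)^2)
  tibble::tibble(psnr = if (mse == 0) Inf else 10 * log10(255^2 / mse),
                 ssim = ssim_metric(sc$ref, sc$test),
                 rmse = sqrt(mse))
}

gaussian_kernel <- function(size = 11, sigma = 1.5) {
  r <- (size - 1) / 2
  g <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# Valid-mode 2-D filtering of a matrix with a small kernel.
filter_valid <- function(img, kern) {
  y <- cpp_conv2d_fwd(as_nchw(img), as_nchw(kern), 0, 1L, 0L, 0L, 1L)
  y[, , 1, 1]
}

#' Structural similarity index of two equal-scale images
#'
#' The classic single-scale SSIM (mean over the valid window positions of
#' the local similarity map).  Both images are assumed to be on the same
#' intensity scale; [fidelity_metrics()] handles display-scale mapping.
#'
#' @param x,y numeric matrices on a common 0-255 scale.
#' @param window Gaussian window size.
#' @param sigma Gaussian window sigma.
#' @param dynamic_range value of MAX (default 255).
#' @return scalar SSIM in `[-1, 1]`; symmetric in its arguments.
#' @export
ssim_metric <- function(x, y, window = 11, sigma = 1.5,
                        dynamic_range = 255) {
  stopifnot(all(dim(x) == dim(y)))
  k <- gaussian_kernel(window, sigma)
  c1 <- (0.01 * dynamic_range)^2
  c2 <- (0.03 * dynamic_range)^2
  mx <- filter_valid(x, k); my <- filter_valid(y, k)
  sxx <- filter_valid(x * x, k) - mx^2
  syy <- filter_valid(y * y, k) - my^2
  sxy <- filter_valid(x * y, k) - mx * my
  s <- ((2 * mx * my + c1) * (2 * sxy + c2)) /
    ((mx^2 + my^2 + c1) * (sxx + syy + c2))
  mean(s)
}
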