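new_tomogram <- function(pixels, provenance) {
  structure(pixels, class = c("tomogram", "matrix", "array"),
            provenance = provenance)
}

#' @export
print.tomogram <- function(x, ...) {
  pv <- attr(x, "provenance")
  cat(sprintf("<tomogram %dx%d: %s>\n", nrow(x), ncol(x),
              paste(vapply(pv, `[[`, "", "method"), collapse = " -> ")))
  invisible(x)
}

#' Provenance of a tomogram
#' @param tomo a tomogram.
#' @return list of stage records (method + parameters), in order.
#' @export
provenance <- function(tomo) attr(tomo, "provenance")

#' Configuration for iterative reconstruction
#'
#' @param n_iterations outer iterations (SART sweeps).
#' @param relaxation SART relaxation factor in `(0, 2)`.
#' @param tv_weight total-variation regularization weight (TVM only).
#' @param tv_inner_steps TV gradient-descent steps per sweep (TVM only).
#' @return list of class `"iterative_config"`.
#' @export
iterative_config <- function(n_iterations = 20, relaxation = 0.15,
                             tv_weight = 0.1, tv_inner_steps = 10) {
  if (n_iterations < 0) abort("`n_iterations` must be >= 0")
  if (relaxation <= 0 || relaxation >= 2)
    abort("`relaxation` must lie in (0, 2)")
  if (tv_weight < 0) abort("`tv_weight` must be >= 0")
  structure(list(n_iterations = as.integer(n_iterations),
                 relaxation = relaxation, tv_weight = tv_weight,
                 tv_inner_steps = as.integer(tv_inner_steps)),
            class = "iterative_config")
}

# Discrete ramp filter (band-limited |f|) evaluated in the frequency domain:
# the DFT of the classic spatial-domain kernel h(0) = 1/4, h(odd k) =
# -1/(pi k)^2, h(even k) = 0, which avoids the DC bias of sampling |f|
# directly.
ramp_filter_freq <- function(m, window = c("ramlak", "hann")) {
  window <- match.arg(window)
  k <- c(0:(m / 2), -(m / 2 - 1):-1)
  h <- numeric(m)
  h[1] <- 0.25
  odd <- which(k %% 2 != 0)
  h[odd] <- -1 / (pi * k[odd])^2
  H <- Re(fft(h))
  if (window == "hann") {
    f <- seq(0, m - 1) / m
    f <- pmin(f, 1 - f) * 2            # 0..1 over the Nyquist band
    H <- H * (0.5 + 0.5 * cos(pi * f))
  }
  H
}

#' Weighted back projection (filtered back projection)
#'
#' Each acquired projection row is ramp-filtered in the frequency domain
#' (Ram-Lak by default, optional Hann apodization) and back-projected over
#' the acquired angles.  Missing rows, zero-padded or not, contribute
#' nothing.  The output is not clipped to `[0, 1]`: overshoot is informative
#' downstream; clipping happens only at metric/export time.
#'
#' @param sino a `sinogram` (raw or normalized; denormalized internally).
#' @param window `"ramlak"` or `"hann"`.
#' @return a `tomogram` on the phantom grid.
#' @export
reconstruct_wbp <- function(sino, window = c("ramlak", "hann")) {
  window <- match.arg(window)
  if (!any(sino$mask)) abort("no acquired projections to reconstruct from")
  raw <- denormalize_sinogram(sino)
  n <- ncol(raw$values)
  m <- 2^ceiling(log2(2 * n))
  H <- ramp_filter_freq(m, window)
  acq <- which(raw$mask)
  filt <- matrix(0, length(acq), n)
  for (r in seq_along(acq)) {
    p <- c(raw$values[acq[r], ], numeric(m - n))
    q <- Re(fft(fft(p) * H, inverse = TRUE)) / m
    filt[r, ] <- q[seq_len(n)]
  }
  step_rad <- (sino$angles[2] - sino$angles[1]) * pi / 180
  rec <- cpp_radon_adjoint(filt, raw$angles[acq] * pi / 180, n) * step_rad
  new_tomogram(rec, list(list(method = "wbp", window = window,
                              n_acquired = length(acq))))
}

#' Simultaneous algebraic reconstruction technique (SART)
#'
#' Starts from a zero image; each sweep visits the acquired angles in order,
#' forward-projects the current estimate, normalizes the residual against
#' the measured row by the per-bin ray weights, and back-distributes the
#' relaxed correction.  Missing rows exert no constraint.
#'
#' @param sino a `sinogram`.
#' @param cfg an [iterative_config()].
#' @return a `tomogram`.
#' @export
reconstruct_sart <- function(sino, cfg = iterative_config()) {
  raw <- denormalize_sinogram(sino)
  n <- ncol(raw$values)
  x0 <- matrix(0, n, n)
  if (cfg$n_iterations == 0) {
    return(new_tomogram(x0, list(list(method = "sart", iterations = 0,
                                      relaxation = cfg$relaxation))))
  }
  rec <- cpp_sart(raw$values, raw$angles * pi / 180, raw$mask,
                  cfg$relaxation, cfg$n_iterations, x0)
  new_tomogram(rec, list(list(method = "sart",
                              iterations = cfg$n_iterations,
                              relaxation = cfg$relaxation)))
}

#' Total variation of an image
#'
#' Isotropic total variation with forward differences (used by
#' [reconstruct_tvm()] and its tests).
#'
#' @param img numeric matrix.
#' @param eps smoothing constant.
#' @return scalar TV value.
#' @export
total_variation <- function(img, eps = 0) {
  dx <- cbind(img[, -1] - img[, -ncol(img)], 0)
  dy <- rbind(img[-1, ] - img[-nrow(img), ], 0)
  sum(sqrt(dx^2 + dy^2 + eps^2))
}

#' Total-variation-minimized iterative reconstruction (TVM)
#'
#' Alternates SART sweeps with steepest-descent steps on the smoothed
#' isotropic total variation; the TV step length is tied to the size of the
#' preceding SART update (adaptive-steepest-descent style) and scaled by
#' `tv_weight`, so `tv_weight = 0` reduces exactly to SART.
#'
#' @param sino a `sinogram`.
#' @param cfg an [iterative_config()] with `tv_weight`, `tv_inner_steps` and
#'   `n_iterations` set (defaults: 0.1, 10, 30).
#' @return a `tomogram`.
#' @export
reconstruct_tvm <- function(sino, cfg = iterative_config(n_iterations = 30)) {
  raw <- denormalize_sinogram(sino)
  n <- ncol(raw$values)
  x <- matrix(0, n, n)
  ang <- raw$angles * pi / 180
  for (it in seq_len(cfg$n_iterations)) {
    x_new <- cpp_sart(raw$values, ang, raw$mask, cfg$relaxation, 1L, x)
    dsart <- sqrt(sum((x_new - x)^2))
    x <- x_new
    if (cfg$tv_weight > 0 && dsart > 0) {
      dtv <- cfg$tv_weight * dsart
      for (k in seq_len(cfg$tv_inner_steps)) {
        g <- cpp_tv_grad(x, 1e-8)
        gn <- sqrt(sum(g^2))
        if (gn < 1e-12) break
        # backtracking: a descent step must not increase TV (large weights
        # would otherwise overshoot and oscillate)
        tv0 <- total_variation(x, 1e-8)
        repeat {
          cand <- x - dtv * g / gn
          if (total_variation(cand, 1e-8) <= tv0 || dtv < 1e-10) break
          dtv <- dtv / 2
        }
        x <- cand
        dtv <- dtv * 0.95
      }
    }
  }
  new_tomogram(x, list(list(method = "tvm", iterations = cfg$n_iterations,
                            relaxation = cfg$relaxation,
                            tv_weight = cfg$tv_weight,
                            tv_inner_steps = cfg$tv_inner_steps)))
}

#' Write / read a tomogram
#'
#' Stored as 32-bit float TIFF (range-compressed) with a JSON sidecar
#' carrying range and provenance.
#'
#' @param tomo a `tomogram`.
#' @param path TIFF file path.
#' @return `read_tomogram` returns a `tomogram`.
#' @export
write_tomogram <- function(tomo, path) {
  rng <- range(tomo)
  span <- max(rng[2] - rng[1], .Machine$double.eps)
  tiff::writeTIFF((unclass(tomo) - rng[1]) / span, path, bits.per.sample = 32, compression = "none")
  jsonlite::write_json(
    list(vmin = rng[1], vmax = rng[2], provenance = provenance(tomo)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tomogram
#' @export
read_tomogram <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = FALSE)
  v <- tiff::readTIFF(path)
  span <- max(meta$vmax - meta$vmin, .Machine$double.eps)
  new_tomogram(v * span + meta$vmin, meta$provenance)
}
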