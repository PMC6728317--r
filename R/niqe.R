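# NIQE (Naturalness Image Quality Evaluator): a no-reference score that
# measures the deviation of an image's natural-scene statistics from a
# multivariate Gaussian fitted on a pristine corpus.  Features per patch:
# generalized-Gaussian fit (shape, variance) of the MSCN coefficients plus
# asymmetric-generalized-Gaussian fits (shape, mean, left/right variance)
# of the four pairwise MSCN products, at two scales -- 36 features.
# In this package the pristine corpus is the library of ground-truth
# phantoms (a documented deviation from the original natural-image corpus).

# Local mean-subtracted contrast-normalized coefficients; constant intensity
# offsets cancel exactly, so the score is offset-invariant.
mscn_field <- function(img, win = 7, sigma = 7 / 6) {
  k <- gaussian_kernel(win, sigma)
  pad <- (win - 1) / 2
  smooth <- function(z) cpp_conv2d_fwd(as_nchw(z), as_nchw(k), 0, 1L,
                                       as.integer(pad), as.integer(pad),
                                       1L)[, , 1, 1]
  wsum <- smooth(matrix(1, nrow(img), ncol(img)))  # border correction
  mu <- smooth(img) / wsum
  sig <- sqrt(pmax(smooth(img * img) / wsum - mu^2, 0))
  list(mscn = (img - mu) / (sig + 1), sigma = sig)
}

ggd_r_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      a <- seq(0.2, 10, by = 0.001)
      tab <<- list(alpha = a,
                   r = gamma(1 / a) * gamma(3 / a) / gamma(2 / a)^2)
    }
    tab
  }
})

ggd_fit <- function(x) {
  m2 <- mean(x^2)
  if (m2 < 1e-8) return(c(alpha = 2, sigma_sq = 0))  # flat patch
  rho <- m2 / mean(abs(x))^2
  tb <- ggd_r_table()
  alpha <- tb$alpha[which.min((tb$r - rho)^2)]
  c(alpha = alpha, sigma_sq = m2)
}

aggd_fit <- function(x) {
  left <- x[x < 0]; right <- x[x >= 0]
  if (length(left) < 2 || length(right) < 2 || mean(x^2) < 1e-8)
    return(c(alpha = 2, eta = 0, bl_sq = 0, br_sq = 0))
  sigl <- sqrt(mean(left^2)); sigr <- sqrt(mean(right^2))
  gh <- sigl / max(sigr, 1e-12)
  rhat <- mean(abs(x))^2 / mean(x^2)
  rhatnorm <- rhat * (gh^3 + 1) * (gh + 1) / (gh^2 + 1)^2
  tb <- ggd_r_table()
  alpha <- tb$alpha[which.min((1 / tb$r - rhatnorm)^2)]
  const <- gamma(2 / alpha) / gamma(1 / alpha)
  eta <- (sigr - sigl) * const * sqrt(gamma(1 / alpha) / gamma(3 / alpha))
  c(alpha = alpha, eta = eta, bl_sq = sigl^2, br_sq = sigr^2)
}

nss_patch_features <- function(mscn) {
  # snap numerical dust to exact zero: flat-region coefficients must land on
  # the same side of the asymmetric (left/right) split regardless of
  # femto-scale perturbations, or the fits lose offset invariance
  mscn[abs(mscn) < 1e-10] <- 0
  f <- ggd_fit(mscn)
  n <- nrow(mscn); m <- ncol(mscn)
  pairs <- list(h = mscn[, -m] * mscn[, -1],
                v = mscn[-n, ] * mscn[-1, ],
                d1 = mscn[-n, -m] * mscn[-1, -1],
                d2 = mscn[-n, -1] * mscn[-1, -m])
  c(f, unlist(lapply(pairs, aggd_fit), use.names = FALSE))
}

downsample2 <- function(img) {
  n <- 2 * (nrow(img) %/% 2); m <- 2 * (ncol(img) %/% 2)
  img <- img[seq_len(n), seq_len(m)]
  0.25 * (img[seq(1, n, 2), seq(1, m, 2)] + img[seq(2, n, 2), seq(1, m, 2)] +
          img[seq(1, n, 2), seq(2, m, 2)] + img[seq(2, n, 2), seq(2, m, 2)])
}

# 36 features per patch (18 at full scale, 18 at half scale) plus the patch
# sharpness (mean local sigma at full scale).
niqe_image_features <- function(img, patch_size) {
  img <- unclass(img) * 255
  if (nrow(img) < patch_size || ncol(img) < patch_size)
    abort("image smaller than one NIQE patch")
  s1 <- mscn_field(img)
  s2 <- mscn_field(downsample2(img))
  p <- patch_size
  nbi <- nrow(img) %/% p; nbj <- ncol(img) %/% p
  feats <- matrix(0, nbi * nbj, 36)
  sharp <- numeric(nbi * nbj)
  q <- 0
  for (bi in seq_len(nbi)) {
    for (bj in seq_len(nbj)) {
      q <- q + 1
      i1 <- (bi - 1) * p + seq_len(p); j1 <- (bj - 1) * p + seq_len(p)
      i2 <- (bi - 1) * (p / 2) + seq_len(p / 2)
      j2 <- (bj - 1) * (p / 2) + seq_len(p / 2)
      feats[q, ] <- c(nss_patch_features(s1$mscn[i1, j1]),
                      nss_patch_features(s2$mscn[i2, j2]))
      sharp[q] <- mean(s1$sigma[i1, j1])
    }
  }
  list(features = feats, sharpness = sharp)
}

#' Fit a NIQE model on a pristine corpus
#'
#' Extracts natural-scene-statistics features from the sharp patches of each
#' corpus image (patches whose mean local contrast is at least
#' `sharpness_threshold` times the image maximum) and fits a multivariate
#' Gaussian.  Deterministic: fitting twice on the same corpus gives an
#' identical model.
#'
#' @param corpus list of pristine images in `[0, 1]` (at least 50).
#' @param patch_size NIQE patch size in pixels (even; default 32).
#' @param sharpness_threshold patch-selection fraction (default 0.75).
#' @param ridge covariance regularization added when the pooled covariance
#'   is near-singular.
#' @return list of class `"niqe_model"` with `mean`, `cov`, `patch_size`.
#' @export
fit_niqe_model <- function(corpus, patch_size = 32,
                           sharpness_threshold = 0.75, ridge = 1e-6) {
  if (length(corpus) < 50)
    abort("NIQE fitting needs a corpus of at least 50 pristine images")
  if (patch_size %% 2 != 0) abort("`patch_size` must be even")
  feats <- lapply(corpus, function(im) {
    f <- niqe_image_features(im, patch_size)
    keep <- f$sharpness >= sharpness_threshold * max(f$sharpness)
    f$features[keep, , drop = FALSE]
  })
  X <- do.call(rbind, feats)
  mu <- colMeans(X)
  S <- stats::cov(X)
  S <- S + diag(ridge * max(diag(S), 1), ncol(S))
  structure(list(mean = mu, cov = S, patch_size = patch_size,
                 n_patches = nrow(X), feature_count = ncol(X)),
            class = "niqe_model")
}

#' NIQE score of an image
#'
#' Mahalanobis-type distance between the image's patch-feature Gaussian and
#' the pristine-corpus model; lower is more natural.
#'
#' @param img image matrix in `[0, 1]` (reconstructions may exceed the range;
#'   values are used as-is, so the score is invariant to global offsets).
#' @param model a fitted [fit_niqe_model()].
#' @return scalar NIQE score.
#' @export
niqe_score <- function(img, model) {
  if (!inherits(model, "niqe_model")) abort("`model` must be a niqe_model")
  f <- niqe_image_features(img, model$patch_size)
  X <- f$features
  mu2 <- colMeans(X)
  S2 <- if (nrow(X) > 1) stats::cov(X) else matrix(0, ncol(X), ncol(X))
  Sm <- (model$cov + S2) / 2
  Sm <- Sm + diag(1e-8 * max(diag(Sm), 1), ncol(Sm))
  d <- model$mean - mu2
  as.numeric(sqrt(pmax(t(d) %*% solve(Sm, d), 0)))
}

#' @export
print.niqe_model <- function(x, ...) {
  cat(sprintf("<niqe_model: %d features, %d pristine patches, patch %d px>\n",
              x$feature_count, x$n_patches, x$patch_size))
  invisible(x)
}
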