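# Relativistic-average least-squares GAN losses (RaLSGAN): each sample's
# critic score is judged against the batch-mean score of the opposite class
# with least-squares targets +/-1.  A plain LSGAN mode is provided as a
# switch.  Analytic gradients with respect to the score vectors are returned
# alongside the losses; they are the seeds for backpropagation through the
# discriminator.

ralsgan_d <- function(sr, sf) {
  n <- length(sr)
  if (n < 2 || length(sf) < 2) abort("relativistic loss needs batch size >= 2")
  mr <- mean(sr); mf <- mean(sf)
  loss <- mean((sr - mf - 1)^2) + mean((sf - mr + 1)^2)
  gsr <- 2 * (sr - mf - 1) / n - 2 * mean(sf - mr + 1) / n
  gsf <- 2 * (sf - mr + 1) / n - 2 * mean(sr - mf - 1) / n
  list(loss = loss, gsr = gsr, gsf = gsf)
}

ralsgan_g <- function(sr, sf) {
  n <- length(sf)
  if (n < 2 || length(sr) < 2) abort("relativistic loss needs batch size >= 2")
  mr <- mean(sr); mf <- mean(sf)
  loss <- mean((sf - mr - 1)^2) + mean((sr - mf + 1)^2)
  # generator only influences the fake scores (and through them mean(sf))
  gsf <- 2 * (sf - mr - 1) / n - 2 * mean(sr - mf + 1) / n
  list(loss = loss, gsf = gsf)
}

lsgan_d <- function(sr, sf) {
  list(loss = mean((sr - 1)^2) + mean(sf^2),
       gsr = 2 * (sr - 1) / length(sr), gsf = 2 * sf / length(sf))
}

lsgan_g <- function(sr, sf) {
  list(loss = mean((sf - 1)^2), gsf = 2 * (sf - 1) / length(sf))
}

gan_losses <- function(mode) {
  switch(mode,
         ralsgan = list(d = ralsgan_d, g = ralsgan_g),
         lsgan = list(d = lsgan_d, g = lsgan_g),
         abort(sprintf("unknown GAN mode '%s'", mode)))
}

#' Joint inpainting losses on a batch
#'
#' Computes the generator's joint loss -- full-sinogram mean squared error
#' plus `lambda_adv` times the relativistic-average least-squares adversarial
#' term -- and the symmetric discriminator loss, on a batch of (fake, real,
#' masked-input) sinogram triples.  The discriminator consumes conditional
#' pairs (candidate stacked with the masked input).
#'
#' @param fake list of inpainted sinogram matrices (generator output).
#' @param real list of complete (ground-truth) sinogram matrices.
#' @param masked_input list of zero-padded missing-wedge matrices (the
#'   conditioning channel).
#' @param discriminator a `wf_model` discriminator, or a scoring function
#'   `f(candidate_batch, condition_batch) -> numeric scores` (one per
#'   sample), e.g. for scripted tests.
#' @param lambda_adv adversarial weight; `0` reduces the total to pure MSE.
#' @param gan_mode `"ralsgan"` or `"lsgan"`.
#' @return list with `breakdown` (tibble: `mse`, `adversarial`, `total`,
#'   `lambda_adv`) and `d_loss` (scalar).
#' @export
inpaint_losses <- function(fake, real, masked_input, discriminator,
                           lambda_adv = 5e-3,
                           gan_mode = c("ralsgan", "lsgan")) {
  gan_mode <- match.arg(gan_mode)
  stopifnot(length(fake) == length(real),
            length(real) == length(masked_input))
  if (length(fake) < 2 && gan_mode == "ralsgan")
    abort("relativistic average needs a batch of size >= 2")
  mse <- mean(vapply(seq_along(fake),
                     function(i) mean((fake[[i]] - real[[i]])^2), numeric(1)))
  score <- function(cand) {
    if (is.function(discriminator)) {
      discriminator(cand, masked_input)
    } else {
      x <- stack_pairs(cand, masked_input)
      as.numeric(net_forward(discriminator, x)$out$val)
    }
  }
  sr <- score(real)
  sf <- score(fake)
  L <- gan_losses(gan_mode)
  adv <- L$g(sr, sf)$loss
  dls <- L$d(sr, sf)$loss
  list(breakdown = tibble::tibble(mse = mse, adversarial = adv,
                                  total = mse + lambda_adv * adv,
                                  lambda_adv = lambda_adv),
       d_loss = dls)
}

# Stack a list of matrices with a matching list of condition matrices into a
# 2-channel (H, W, 2, N) batch.
stack_pairs <- function(cand, cond) {
  H <- nrow(cand[[1]]); W <- ncol(cand[[1]]); N <- length(cand)
  x <- array(0, c(H, W, 2, N))
  for (i in seq_len(N)) {
    x[, , 1, i] <- cand[[i]]
    x[, , 2, i] <- cond[[i]]
  }
  x
}

stack_batch <- function(mats) {
  H <- nrow(mats[[1]]); W <- ncol(mats[[1]]); N <- length(mats)
  x <- array(0, c(H, W, 1, N))
  for (i in seq_len(N)) x[, , 1, i] <- mats[[i]]
  x
}

#' Perceptual index
#'
#' `PI = ((10 - Ma) + NIQE) / 2`, combining Ma's learned no-reference score
#' (an external input in this package) with the NIQE naturalness score.
#' Lower indicates better perceptual quality.
#'
#' @param ma Ma's score in `[0, 10]`.
#' @param niqe NIQE score (finite).
#' @return the perceptual index.
#' @examples
#' perceptual_index(10, 0)  # 0
#' perceptual_index(5, 5)   # 5
#' @export
perceptual_index <- function(ma, niqe) {
  if (any(ma < 0 | ma > 10)) abort("`ma` must lie in [0, 10]")
  if (any(!is.finite(niqe))) abort("`niqe` must be finite")
  ((10 - ma) + niqe) / 2
}
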