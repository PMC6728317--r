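# Independent arithmetic oracle for the relativistic-average least-squares
# losses, coded directly from the definition (each score judged against the
# batch mean of the opposite class with targets +/-1).
oracle_ralsgan <- function(sr, sf) {
  d <- mean((sr - mean(sf) - 1)^2) + mean((sf - mean(sr) + 1)^2)
  g <- mean((sf - mean(sr) - 1)^2) + mean((sr - mean(sf) + 1)^2)
  list(d = d, g = g)
}

test_that("relativistic losses match the hand-coded oracle on scripted scores", {
  sr <- c(1, 0); sf <- c(0, 0)
  oc <- oracle_ralsgan(sr, sf)
  # by hand: mean(sf)=0, mean(sr)=0.5
  # D = mean((1-0-1)^2, (0-0-1)^2) + mean((0-0.5+1)^2 x2) = 0.5 + 0.25
  expect_equal(oc$d, 0.75)
  # G = mean((0-0.5-1)^2 x2) + mean((1-0+1)^2, (0-0+1)^2) = 2.25 + 2.5
  expect_equal(oc$g, 4.75)

  dl <- wedgefill:::ralsgan_d(sr, sf)
  gl <- wedgefill:::ralsgan_g(sr, sf)
  expect_equal(dl$loss, oc$d, tolerance = 1e-9)
  expect_equal(gl$loss, oc$g, tolerance = 1e-9)

  # random scripted batches
  for (i in 1:10) {
    sr <- rnorm(4); sf <- rnorm(4)
    oc <- oracle_ralsgan(sr, sf)
    expect_equal(wedgefill:::ralsgan_d(sr, sf)$loss, oc$d, tolerance = 1e-9)
    expect_equal(wedgefill:::ralsgan_g(sr, sf)$loss, oc$g, tolerance = 1e-9)
  }
})

test_that("analytic score gradients agree with finite differences of the oracle", {
  sr <- c(0.3, -0.2, 0.9); sf <- c(0.1, 0.4, -0.5)
  dl <- wedgefill:::ralsgan_d(sr, sf)
  gl <- wedgefill:::ralsgan_g(sr, sf)
  eps <- 1e-6
  for (j in seq_along(sr)) {
    up <- sr; up[j] <- up[j] + eps
    dn <- sr; dn[j] <- dn[j] - eps
    num <- (oracle_ralsgan(up, sf)$d - oracle_ralsgan(dn, sf)$d) / (2 * eps)
    expect_equal(dl$gsr[j], num, tolerance = 1e-6)
  }
  for (j in seq_along(sf)) {
    up <- sf; up[j] <- up[j] + eps
    dn <- sf; dn[j] <- dn[j] - eps
    expect_equal(dl$gsf[j],
                 (oracle_ralsgan(sr, up)$d - oracle_ralsgan(sr, dn)$d) /
                   (2 * eps), tolerance = 1e-6)
    expect_equal(gl$gsf[j],
                 (oracle_ralsgan(sr, up)$g - oracle_ralsgan(sr, dn)$g) /
                   (2 * eps), tolerance = 1e-6)
  }
})

test_that("the joint loss reduces to pure MSE when the adversarial weight is zero", {
  real <- list(matrix(runif(30), 5), matrix(runif(30), 5))
  fake <- lapply(real, function(r) r + 0.1)
  masked <- lapply(real, function(r) { r[4:5, ] <- 0; r })
  scripted <- function(cand, cond) vapply(cand, mean, numeric(1))

  res <- inpaint_losses(fake, real, masked, scripted, lambda_adv = 0)
  expect_equal(res$breakdown$total, res$breakdown$mse)
  expect_equal(res$breakdown$mse, 0.1^2, tolerance = 1e-12)

  res2 <- inpaint_losses(real, real, masked, scripted, lambda_adv = 5e-3)
  expect_equal(res2$breakdown$mse, 0)
  expect_equal(res2$breakdown$total,
               5e-3 * res2$breakdown$adversarial)

  expect_error(inpaint_losses(fake[1], real[1], masked[1], scripted),
               "batch")
})

test_that("losses computed through a real discriminator are finite and conditional", {
  dcfg <- inpaint_discriminator_config(feature_depth = 8,
                                       group_norm_groups = 4,
                                       slow_path_depth = 3,
                                       fast_path_depth = 2)
  ms <- build_inpaint_models(
    inpaint_generator_config(1, 8, 4, 2, 1, 1), dcfg, seed = 2)
  real <- lapply(1:2, function(i) matrix(runif(24 * 16), 24))
  masked <- lapply(real, function(r) { r[1:5, ] <- 0; r })
  fake <- lapply(real, function(r) r + 0.05)
  res <- inpaint_losses(fake, real, masked, ms$discriminator)
  expect_true(all(is.finite(unlist(res$breakdown))))
  expect_true(is.finite(res$d_loss))

  # CGAN wiring is live: changing only the conditioning channel moves scores
  x1 <- wedgefill:::stack_pairs(fake, masked)
  x2 <- wedgefill:::stack_pairs(fake, real)
  s1 <- as.numeric(net_forward(ms$discriminator, x1)$out$val)
  s2 <- as.numeric(net_forward(ms$discriminator, x2)$out$val)
  expect_gt(max(abs(s1 - s2)), 1e-8)
})
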