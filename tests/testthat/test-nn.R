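# Structural and numerical checks of the network machinery.  The backward
# pass of every layer type is validated against central finite differences
# of the corresponding forward loss.

test_that("conv/norm/pooling backprop matches finite differences", {
  set.seed(42)
  gcfg <- inpaint_generator_config(n_rrdb_blocks = 1, feature_depth = 4,
                                   growth_channels = 2,
                                   n_dense_per_block = 1,
                                   n_growth_layers = 2)
  dcfg <- inpaint_discriminator_config(feature_depth = 4,
                                       group_norm_groups = 2,
                                       slow_path_depth = 2,
                                       fast_path_depth = 1)
  ms <- build_inpaint_models(gcfg, dcfg, seed = 3)
  x <- array(rnorm(10 * 8 * 2), c(10, 8, 1, 2))
  target <- array(rnorm(10 * 8 * 2), c(10, 8, 1, 2))
  loss_g <- function(params)
    mean((net_forward(ms$generator, x, params = params)$out$val - target)^2)
  f <- net_forward(ms$generator, x)
  f$out$grad <- 2 * (f$out$val - target) / length(target)
  ag_backward(f$tape)
  gr <- read_grads(f$leaves)
  p <- ms$generator$params
  for (nm in c("cin.w", "r1.d1.c1.w", "r1.d1.fuse.b", "dil.w", "cout.w")) {
    i <- sample(length(p[[nm]]), 1)
    eps <- 1e-5
    p1 <- p; p1[[nm]][i] <- p1[[nm]][i] + eps
    p2 <- p; p2[[nm]][i] <- p2[[nm]][i] - eps
    num <- (loss_g(p1) - loss_g(p2)) / (2 * eps)
    expect_equal(gr[[nm]][i], num, tolerance = 1e-4)
  }

  xd <- array(rnorm(10 * 8 * 2 * 3), c(10, 8, 2, 3))
  loss_d <- function(params)
    sum(net_forward(ms$discriminator, xd, params = params)$out$val^2)
  fd <- net_forward(ms$discriminator, xd)
  fd$out$grad <- matrix(2 * as.numeric(fd$out$val), 1, 3)
  ag_backward(fd$tape)
  grd <- read_grads(fd$leaves)
  pd <- ms$discriminator$params
  for (nm in c("cin.w", "slow1.g", "slow2.be", "fast1.w", "fc.w")) {
    i <- sample(length(pd[[nm]]), 1)
    eps <- 1e-5
    p1 <- pd; p1[[nm]][i] <- p1[[nm]][i] + eps
    p2 <- pd; p2[[nm]][i] <- p2[[nm]][i] - eps
    num <- (loss_d(p1) - loss_d(p2)) / (2 * eps)
    expect_equal(grd[[nm]][i], num, tolerance = 1e-4)
  }

  # U-net (batch norm, max pool, upsampling, skips)
  mu <- build_deartifact_models(unet_config(depth = 2, base_channels = 4),
                                deartifact_discriminator_config(4, 2),
                                seed = 5)
  xu <- array(rnorm(16 * 16 * 2), c(16, 16, 1, 2))
  tu <- array(rnorm(16 * 16 * 2), c(16, 16, 1, 2))
  loss_u <- function(params)
    mean((net_forward(mu$generator, xu, params = params,
                      train = TRUE)$out$val - tu)^2)
  fu <- net_forward(mu$generator, xu, train = TRUE)
  fu$out$grad <- 2 * (fu$out$val - tu) / length(tu)
  ag_backward(fu$tape)
  gru <- read_grads(fu$leaves)
  pu <- mu$generator$params
  for (nm in c("e1.c1.w", "e2.c1.g", "u1.red.w", "u1.c1.be", "out.w")) {
    i <- sample(length(pu[[nm]]), 1)
    eps <- 1e-5
    p1 <- pu; p1[[nm]][i] <- p1[[nm]][i] + eps
    p2 <- pu; p2[[nm]][i] <- p2[[nm]][i] - eps
    expect_equal(gru[[nm]][i], (loss_u(p1) - loss_u(p2)) / (2 * eps),
                 tolerance = 1e-4)
  }
})

test_that("generator and discriminator obey their shape contracts", {
  gcfg <- inpaint_generator_config(n_rrdb_blocks = 2, feature_depth = 8,
                                   growth_channels = 4,
                                   n_dense_per_block = 1,
                                   n_growth_layers = 2)
  ms <- build_inpaint_models(gcfg,
                             inpaint_discriminator_config(8, 4, 3, 2),
                             seed = 0)
  x <- array(rnorm(45 * 64), c(45, 64, 1, 1))
  y <- net_forward(ms$generator, x)$out$val
  expect_identical(dim(y), c(45L, 64L, 1L, 1L))

  xd <- array(rnorm(45 * 64 * 2 * 3), c(45, 64, 2, 3))
  s <- net_forward(ms$discriminator, xd)$out$val
  expect_identical(dim(s), c(1L, 3L))

  # parameter count is a pure function of the config, and grows with depth
  m1 <- build_inpaint_models(gcfg, inpaint_discriminator_config(8, 4, 3, 2),
                             seed = 1)
  expect_identical(n_params(ms$generator), n_params(m1$generator))
  g2 <- inpaint_generator_config(n_rrdb_blocks = 4, feature_depth = 8,
                                 growth_channels = 4,
                                 n_dense_per_block = 1, n_growth_layers = 2)
  m2 <- build_inpaint_models(g2, inpaint_discriminator_config(8, 4, 3, 2),
                             seed = 1)
  expect_gt(n_params(m2$generator), n_params(ms$generator))

  expect_error(inpaint_discriminator_config(feature_depth = 10,
                                            group_norm_groups = 4),
               "divide")
})

test_that("U-net models obey shape contracts and inference determinism", {
  ms <- build_deartifact_models(unet_config(depth = 3, base_channels = 4),
                                deartifact_discriminator_config(8, 3),
                                seed = 1)
  x <- matrix(rnorm(64 * 64), 64)
  y1 <- net_forward(ms$generator, x, train = FALSE)$out$val
  expect_identical(dim(y1), c(64L, 64L, 1L, 1L))
  y2 <- net_forward(ms$generator, x, train = FALSE)$out$val
  expect_identical(y1, y2)

  xd <- array(rnorm(64 * 64 * 2 * 2), c(64, 64, 2, 2))
  s <- net_forward(ms$discriminator, xd, train = FALSE)$out$val
  expect_identical(dim(s), c(1L, 2L))

  # robustness: adversarially scaled out-of-range inputs stay finite
  big <- remove_artifacts(ms$generator,
                          new_tomogram(10 * matrix(rnorm(64 * 64), 64),
                                       list()))
  expect_true(all(is.finite(big)))
})

test_that("U-net skip connections are live and dominate the bottleneck", {
  ms <- build_deartifact_models(unet_config(depth = 3, base_channels = 8),
                                deartifact_discriminator_config(8, 3),
                                seed = 4)
  x <- matrix(rnorm(64 * 64), 64)
  base <- net_forward(ms$generator, x, train = FALSE)$out$val
  zero_layer <- function(nm) {
    p <- ms$generator$params
    p[[paste0(nm, ".w")]][] <- 0
    p[[paste0(nm, ".b")]][] <- 0
    m <- ms$generator
    m$params <- p
    net_forward(m, x, train = FALSE)$out$val
  }
  d_bottleneck <- mean(abs(zero_layer("e3.c2") - base))
  d_topskip <- mean(abs(zero_layer("e1.c2") - base))
  expect_gt(d_bottleneck, 0)   # the deep path is live
  expect_gt(d_topskip, 0)      # the top skip is live
  # the high-resolution skip carries more of the output than the bottleneck
  expect_gt(d_topskip, d_bottleneck)
})

test_that("the learning-rate schedule follows warmup, plateau, and decays", {
  tc <- train_config()
  expect_equal(lr_schedule(1:3, tc), c(1e-4, 2e-4, 4e-4))
  expect_equal(lr_schedule(4:19, tc), rep(4e-4, 16))
  expect_equal(lr_schedule(20:27, tc), rep(4e-5, 8))
  expect_equal(lr_schedule(28:30, tc), rep(4e-6, 3), tolerance = 1e-12)
})
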