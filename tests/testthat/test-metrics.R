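test_that("fidelity metrics satisfy closed-form and consistency identities", {
  ref <- matrix(255, 16, 16)
  tst <- matrix(127.5, 16, 16)
  fm <- fidelity_metrics(ref, tst)
  expect_equal(fm$rmse, 127.5)
  expect_equal(fm$psnr, 10 * log10(255^2 / 127.5^2), tolerance = 1e-12)

  # identical inputs: PSNR sentinel, perfect SSIM, zero RMSE
  ph <- unclass(generate_phantom(64, c(3, 6), seed = 5))
  same <- fidelity_metrics(ph, ph)
  expect_identical(same$psnr, Inf)
  expect_equal(same$ssim, 1)
  expect_equal(same$rmse, 0)

  # PSNR/RMSE consistency on random pairs
  for (s in 1:5) {
    a <- matrix(runif(32 * 32), 32)
    b <- matrix(runif(32 * 32), 32)
    fm <- fidelity_metrics(a, b)
    expect_equal(fm$psnr, 20 * log10(255 / fm$rmse), tolerance = 1e-9)
  }

  expect_error(fidelity_metrics(matrix(0, 4, 4), matrix(0, 5, 5)), "shape")
})

test_that("SSIM is symmetric and maximal at identity", {
  a <- matrix(runif(40 * 40), 40) * 255
  b <- matrix(runif(40 * 40), 40) * 255
  expect_equal(ssim_metric(a, a), 1, tolerance = 1e-12)
  expect_equal(ssim_metric(a, b), ssim_metric(b, a), tolerance = 1e-12)
  expect_lt(ssim_metric(a, b), 1)
})

test_that("the perceptual index follows its defining formula exactly", {
  expect_identical(perceptual_index(10, 0), 0)
  expect_identical(perceptual_index(0, 10), 10)
  expect_identical(perceptual_index(5, 5), 5)
  expect_error(perceptual_index(11, 3), "0, 10")
  expect_error(perceptual_index(-0.1, 3), "0, 10")
  # formula holds for arbitrary valid scores
  for (i in 1:10) {
    ma <- runif(1, 0, 10); nq <- runif(1, 0, 15)
    expect_equal(perceptual_index(ma, nq), ((10 - ma) + nq) / 2)
  }
})

test_that("method evaluation table has the benchmark layout and ordering", {
  ph <- list(unclass(generate_phantom(64, c(3, 6), seed = 31)))
  tab <- evaluate_methods(ph, wedge_spec(45), methods = "wbp",
                          grid = angle_grid(4))
  expect_equal(nrow(tab), 2)
  expect_setequal(tab$method, c("missing_wbp", "complete_wbp"))
  expect_true(all(is.finite(tab$psnr)))

  suite <- lapply(1:8, function(i)
    unclass(generate_phantom(64, c(3, 8), seed = 500 + i)))
  t1 <- evaluate_methods(suite, wedge_spec(45), methods = c("wbp", "sart"),
                         grid = angle_grid(4),
                         sart_cfg = iterative_config(5))
  complete <- t1$psnr[t1$method == "complete_wbp"]
  missing <- t1$psnr[t1$method == "missing_wbp"]
  expect_gt(complete, missing)
  # determinism: the whole table reproduces bit-identically
  t2 <- evaluate_methods(suite, wedge_spec(45), methods = c("wbp", "sart"),
                         grid = angle_grid(4),
                         sart_cfg = iterative_config(5))
  expect_identical(t1, t2)
  expect_error(evaluate_methods(suite, methods = "joint"), "joint")
})
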