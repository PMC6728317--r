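test_that("WBP inverts the forward model at full sampling", {
  zero <- forward_project(matrix(0, 64, 64), angle_grid(2))
  expect_true(all(reconstruct_wbp(zero) == 0))

  disk <- make_disk(128)
  s <- forward_project(disk, angle_grid(1))
  full <- reconstruct_wbp(s)
  fm_full <- fidelity_metrics(disk, unclass(full))
  expect_gte(fm_full$psnr, 25)

  masked <- apply_missing_wedge(s, wedge_spec(45))
  fm_miss <- fidelity_metrics(disk, unclass(reconstruct_wbp(masked)))
  expect_lt(fm_miss$psnr, fm_full$psnr)

  empty <- new_sinogram(matrix(0, 4, 64), c(-90, -45, 0, 45),
                        rep(FALSE, 4))
  expect_error(reconstruct_wbp(empty), "acquired")
})

test_that("SART reduces projection residuals and matches WBP at full sampling", {
  disk <- make_disk(64, radius = 18)
  g <- angle_grid(2)
  s <- forward_project(disk, g)

  expect_true(all(reconstruct_sart(s, iterative_config(0)) == 0))

  resid_norm <- function(rec) {
    # clip negatives and mask to the inscribed circle before re-projection
    px <- pmax(unclass(rec), 0)
    ctr <- (nrow(px) - 1) / 2
    xs <- matrix(rep(seq_len(ncol(px)) - 1 - ctr, each = nrow(px)), nrow(px))
    px[xs^2 + t(xs)^2 >= (nrow(px) / 2 - 1)^2] <- 0
    p <- forward_project(px, g)$values
    sqrt(sum((p - s$values)^2))
  }
  r1 <- resid_norm(reconstruct_sart(s, iterative_config(1)))
  r10 <- resid_norm(reconstruct_sart(s, iterative_config(10)))
  expect_lt(r10, r1)

  psnr_wbp <- fidelity_metrics(disk, unclass(reconstruct_wbp(s)))$psnr
  psnr_sart <- fidelity_metrics(
    disk, unclass(reconstruct_sart(s, iterative_config(20))))$psnr
  expect_gte(psnr_sart, psnr_wbp - 3)
})

test_that("TVM reduces total variation and collapses to SART at zero weight", {
  ph <- unclass(generate_phantom(64, c(3, 6), seed = 21))
  s <- apply_missing_wedge(forward_project(ph, angle_grid(3)),
                           wedge_spec(45))
  cfg0 <- iterative_config(n_iterations = 10, tv_weight = 0)
  tv0 <- reconstruct_tvm(s, cfg0)
  sart <- reconstruct_sart(s, iterative_config(n_iterations = 10))
  expect_lt(max(abs(tv0 - sart)), 1e-8)

  tvm <- reconstruct_tvm(s, iterative_config(n_iterations = 10,
                                             tv_weight = 0.1))
  expect_lte(total_variation(unclass(tvm)), total_variation(unclass(sart)))

  # tenfold weight increases give non-increasing TV (the effect saturates
  # around weight ~1, where the backtracking line search limits the steps)
  tvs <- vapply(c(0.01, 0.1, 1), function(w)
    total_variation(unclass(reconstruct_tvm(
      s, iterative_config(n_iterations = 10, tv_weight = w)))), numeric(1))
  expect_true(all(diff(tvs) <= 0))
})

test_that("reconstructions are deterministic and degrade with wedge size", {
  ph <- unclass(generate_phantom(64, c(3, 6), seed = 2))
  s <- apply_missing_wedge(forward_project(ph, angle_grid(3)), wedge_spec(45))
  expect_identical(unclass(reconstruct_wbp(s)), unclass(reconstruct_wbp(s)))
  cfg <- iterative_config(5)
  expect_identical(unclass(reconstruct_sart(s, cfg)),
                   unclass(reconstruct_sart(s, cfg)))

  suite <- lapply(1:20, function(i)
    unclass(generate_phantom(64, c(3, 8), seed = 300 + i)))
  g <- angle_grid(3)
  mean_psnr <- vapply(c(0, 20, 45, 90), function(w) {
    mean(vapply(suite, function(p) {
      sm <- apply_missing_wedge(forward_project(p, g), wedge_spec(w))
      fidelity_metrics(p, unclass(reconstruct_wbp(sm)))$psnr
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_psnr) < 0))
})

test_that("tomograms round-trip through storage with provenance", {
  ph <- unclass(generate_phantom(48, c(3, 6), seed = 13))
  tomo <- reconstruct_wbp(forward_project(ph, angle_grid(4)))
  path <- withr::local_tempfile(fileext = ".tiff")
  write_tomogram(tomo, path)
  back <- read_tomogram(path)
  expect_equal(unclass(back), unclass(tomo), tolerance = 1e-5)
  expect_equal(provenance(back)[[1]]$method, "wbp")
})
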