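test_that("forward projection is linear and conserves mass per row", {
  g <- angle_grid(1)
  zero <- forward_project(matrix(0, 64, 64), g)
  expect_true(all(zero$values == 0))

  for (s in 1:10) {
    ph <- unclass(generate_phantom(64, c(3, 8), seed = s))
    sino <- forward_project(ph, g)
    expect_true(all(abs(rowSums(sino$values) - sum(ph)) / sum(ph) < 1e-3))
  }

  # Radon linearity on random small phantoms
  a <- unclass(generate_phantom(32, c(2, 4), seed = 1))
  b <- unclass(generate_phantom(32, c(2, 4), seed = 2))
  g2 <- angle_grid(10)
  lhs <- forward_project(0.7 * a + 0.2 * b, g2)$values
  rhs <- 0.7 * forward_project(a, g2)$values +
    0.2 * forward_project(b, g2)$values
  expect_lt(max(abs(lhs - rhs)), 1e-6 * max(abs(rhs)))
})

test_that("projections of a centred disk respect rotational symmetry", {
  disk <- make_disk(128)
  g <- angle_grid(1)
  s <- forward_project(disk, g)$values
  i0 <- which(g$angles == 0)
  # lattice-symmetric angle pairs are exactly equal: theta vs -theta
  # (mirrored) and theta vs theta + 90
  for (th in c(10, 30, 45)) {
    r1 <- s[which(g$angles == th), ]
    r2 <- rev(s[which(g$angles == -th), ])
    expect_lt(max(abs(r1 - r2)), 1e-9 * max(r1))
    r3 <- s[which(g$angles == th - 90), ]
    expect_lt(max(abs(r1 - r3)), 1e-9 * max(r1))
  }
  # arbitrary angle pairs agree to raster-aliasing accuracy (the sharp disk
  # edge limits pointwise agreement of a discrete projector to a few percent)
  for (th in c(17, 63)) {
    r1 <- s[which(g$angles == th), ]
    expect_lt(max(abs(r1 - s[i0, ])), 5e-2 * max(s[i0, ]))
  }
})

test_that("missing-wedge masking counts, preserves, and is idempotent", {
  g <- angle_grid(1)  # -90 .. +89
  ph <- unclass(generate_phantom(64, c(3, 6), seed = 4))
  sino <- forward_project(ph, g)

  same <- apply_missing_wedge(sino, wedge_spec(0))
  expect_identical(same$values, sino$values)
  expect_true(all(same$mask))

  m45 <- apply_missing_wedge(sino, wedge_spec(45))
  # independent counting oracle over the angle list
  expect_equal(sum(!m45$mask), sum(abs(g$angles) > (180 - 45) / 2))
  expect_equal(sum(!m45$mask), 45)
  expect_identical(m45$values[m45$mask, ], sino$values[m45$mask, ])
  expect_true(all(m45$values[!m45$mask, ] == 0))

  again <- apply_missing_wedge(m45, wedge_spec(45))
  expect_identical(again$values, m45$values)
  expect_identical(again$mask, m45$mask)

  expect_error(wedge_spec(180), "180")
})

test_that("sinogram normalization is exactly invertible and bounded", {
  g <- angle_grid(2)
  zero <- normalize_sinogram(forward_project(matrix(0, 32, 32), g))
  expect_true(all(zero$values == 0))
  expect_equal(zero$scale, 1 / 32)

  for (s in 1:50) {
    ph <- unclass(generate_phantom(32, c(2, 6), seed = s))
    ns <- normalize_sinogram(forward_project(ph, g))
    expect_true(all(ns$values >= 0 & ns$values <= 1))
    back <- denormalize_sinogram(ns)
    expect_identical(back$values, forward_project(ph, g)$values)
  }
  expect_error(normalize_sinogram(zero, constant = -1), "positive")
})

test_that("sinograms round-trip through TIFF + JSON storage", {
  ph <- unclass(generate_phantom(48, c(3, 6), seed = 9))
  sino <- apply_missing_wedge(
    normalize_sinogram(forward_project(ph, angle_grid(4))), wedge_spec(45))
  path <- withr::local_tempfile(fileext = ".tiff")
  write_sinogram(sino, path)
  back <- read_sinogram(path)
  expect_equal(back$values, sino$values, tolerance = 1e-6)
  expect_identical(back$mask, sino$mask)
  expect_equal(back$angles, sino$angles)
  expect_equal(back$scale, sino$scale)
})
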