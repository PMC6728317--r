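test_that("phantom generation is seeded, bounded, and circle-supported", {
  expect_error(generate_phantom(16), "size")

  empty <- generate_phantom(128, c(0, 0), seed = 1)
  expect_true(all(empty == 0))

  a <- generate_phantom(128, c(3, 8), seed = 7)
  b <- generate_phantom(128, c(3, 8), seed = 7)
  expect_identical(unclass(a), unclass(b))

  n <- 128
  ctr <- (n - 1) / 2
  xs <- matrix(rep(seq_len(n) - 1 - ctr, each = n), n)
  ys <- t(xs)
  outside <- xs^2 + ys^2 >= (n / 2)^2
  for (s in 1:100) {
    ph <- generate_phantom(n, c(3, 8), seed = s)
    expect_true(max(ph) <= 1)
    expect_true(min(ph) >= 0)
    expect_true(all(ph[outside] == 0))
  }
})

test_that("augmentation switches behave as identity / involution / rotation", {
  ph <- generate_phantom(64, c(3, 6), seed = 3)
  off <- augment_image(ph, augmentation_spec(), seed = 1)
  expect_equal(unclass(off), unclass(ph))

  spec_flip <- augmentation_spec(random_flip = TRUE)
  once <- augment_image(ph, spec_flip, seed = 1, forced = list(flip = "h"))
  twice <- augment_image(once, spec_flip, seed = 2, forced = list(flip = "h"))
  expect_equal(unclass(twice), unclass(ph))

  # a forced 90-degree rotation moves an off-centre disk to the closed-form
  # rotated position (content point p maps to R(-90) p)
  disk <- make_disk(64, radius = 6, center = c(12, 4))
  rot <- augment_image(disk, augmentation_spec(random_rotation = 180),
                       seed = 1, forced = list(rotation = 90))
  centroid <- function(img) {
    ctr <- (nrow(img) - 1) / 2
    xs <- matrix(rep(seq_len(ncol(img)) - 1 - ctr, each = nrow(img)),
                 nrow(img))
    ys <- matrix(rep(seq_len(nrow(img)) - 1 - ctr, times = ncol(img)),
                 nrow(img))
    c(sum(xs * img), sum(ys * img)) / sum(img)
  }
  got <- centroid(unclass(rot))
  expected <- c(-4, 12)  # R(90) %*% c(12, 4): counter-clockwise in (x, y)
  expect_lt(sqrt(sum((got - expected)^2)), 1)
})

test_that("rotation after pad-resize conserves mass within tolerance", {
  ph <- generate_phantom(64, c(4, 8), seed = 11)
  for (ang in c(17, 45, 133)) {
    rot <- augment_image(ph, augmentation_spec(random_rotation = 180),
                         seed = 1, forced = list(rotation = ang))
    expect_lt(abs(sum(rot) - sum(ph)) / sum(ph), 1e-2)
  }
})

test_that("augmented outputs stay in [0, 1] under every switch", {
  spec <- augmentation_spec(pad_resize = TRUE, random_rotation = 180,
                            random_flip = TRUE, random_affine = 0.15,
                            random_noise = 0.05)
  for (s in 1:20) {
    ph <- generate_phantom(64, c(3, 8), seed = s)
    out <- augment_image(ph, spec, seed = s + 100)
    expect_true(all(out >= 0 & out <= 1))
    expect_identical(dim(out), dim(ph))
  }
})

test_that("library building writes, splits, and reproduces deterministically", {
  d1 <- withr::local_tempdir()
  man <- build_library(c(shapes = 20), size = 48, seed = 5, out_path = d1)
  expect_equal(nrow(man), 20)
  expect_equal(sum(man$split == "train"), 18)
  expect_equal(sum(man$split == "validation"), 2)
  expect_true(file.exists(file.path(d1, "manifest.json")))

  d2 <- withr::local_tempdir()
  man2 <- build_library(c(shapes = 20), size = 48, seed = 5, out_path = d2)
  expect_equal(man$path, man2$path)
  expect_equal(man$split, man2$split)
  for (i in seq_len(5)) {
    b1 <- readBin(file.path(d1, man$path[i]), "raw", 1e6)
    b2 <- readBin(file.path(d2, man2$path[i]), "raw", 1e6)
    expect_identical(b1, b2)
  }
  # every listed file round-trips through the image reader
  for (p in man$path) {
    img <- read_image(file.path(d1, p))
    expect_true(all(is.finite(img)) && all(img >= 0 & img <= 1))
    expect_identical(dim(img), c(48L, 48L))
  }
})
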