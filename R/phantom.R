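#' Generate a synthetic cross-section phantom
#'
#' Composes a seeded random mixture of filled disks and convex polygons with
#' random centres, sizes, and per-shape uniform intensities in `[0.2, 1]`,
#' emulating cross-sectional images of faceted or rounded nanocrystals.
#' Overlapping shapes combine by taking the maximum intensity, producing flat
#' regions with sharp edges.  All content is clipped strictly inside the
#' inscribed circle of the square grid, so projections at any angle see the
#' full object (no mass falls off the detector).
#'
#' @param size side length in pixels (square grid, `>= 32`).
#' @param shape_budget integer `(min, max)` number of shapes; the count is
#'   drawn uniformly from this range.
#' @param seed integer seed; the output is a pure function of
#'   `(size, shape_budget, seed)`.
#' @return a numeric `size x size` matrix of class `"phantom"` with values in
#'   `[0, 1]` and attribute `support = "inscribed-circle"`.
#' @examples
#' ph <- generate_phantom(64, c(3, 8), seed = 1)
#' range(ph)
#' @export
generate_phantom <- function(size, shape_budget = c(3, 8), seed = 0L) {
  stopifnot_scalar_int(size, "size", 32)
  if (length(shape_budget) != 2 || any(shape_budget < 0) ||
      any(shape_budget > 64) || shape_budget[1] > shape_budget[2])
    abort("`shape_budget` must be (min, max) within [0, 64]")
  with_seed(seed, {
    img <- matrix(0, size, size)
    n_shapes <- if (shape_budget[2] == 0) 0L else
      sample(seq(shape_budget[1], shape_budget[2]), 1)
    ctr <- (size - 1) / 2
    rmax <- size / 2 - 1.5          # strict interior margin
    xs <- matrix(rep(seq_len(size) - 1 - ctr, each = size), size)   # x by col
    ys <- matrix(rep(seq_len(size) - 1 - ctr, times = size), size)  # y by row
    for (s in seq_len(n_shapes)) {
      intensity <- runif(1, 0.2, 1)
      r <- runif(1, 0.06, 0.28) * size
      # centre placed so the shape stays inside the inscribed circle
      rho <- runif(1, 0, max(rmax - r, 0))
      th <- runif(1, 0, 2 * pi)
      cx <- rho * cos(th); cy <- rho * sin(th)
      if (runif(1) < 0.5) {
        mask <- (xs - cx)^2 + (ys - cy)^2 <= r^2
      } else {
        k <- sample(3:7, 1)
        pts <- cbind(cx + r * runif(k, 0.4, 1) * cos(sort(runif(k, 0, 2 * pi))),
                     cy + r * runif(k, 0.4, 1) * sin(sort(runif(k, 0, 2 * pi))))
        hull <- grDevices::chull(pts)
        mask <- point_in_convex(xs, ys, pts[hull, , drop = FALSE])
      }
      img[mask] <- pmax(img[mask], intensity)
    }
    img[xs^2 + ys^2 >= (size / 2 - 1)^2] <- 0
    structure(img, class = c("phantom", class(img)),
              support = "inscribed-circle")
  })
}

# Vectorized point-in-convex-polygon test (vertices counter-clockwise or
# clockwise; uses consistent sign of the edge cross products).
point_in_convex <- function(xs, ys, v) {
  k <- nrow(v)
  if (k < 3) return(matrix(FALSE, nrow(xs), ncol(xs)))
  inside <- NULL
  sgn <- NULL
  for (i in seq_len(k)) {
    j <- if (i == k) 1L else i + 1L
    cr <- (v[j, 1] - v[i, 1]) * (ys - v[i, 2]) -
      (v[j, 2] - v[i, 2]) * (xs - v[i, 1])
    pos <- cr >= 0; neg <- cr <= 0
    inside <- if (is.null(inside)) list(pos = pos, neg = neg) else
      list(pos = inside$pos & pos, neg = inside$neg & neg)
  }
  inside$pos | inside$neg
}

#' Augmentation specification
#'
#' One switch per column of the augmentation menu: pad-resize (embed the full
#' square into the inscribed circle), random rotation, random flip, random
#' affine (shear/scale jitter), and additive Gaussian noise.
#'
#' @param pad_resize logical.
#' @param random_rotation maximum rotation angle in degrees (`0` disables;
#'   must lie in `[0, 180]`).
#' @param random_flip logical.
#' @param random_affine maximum shear/scale delta (unitless; `0` disables).
#' @param random_noise additive Gaussian noise sigma in intensity units
#'   (`>= 0`; `0` disables).
#' @return a list of class `"augmentation_spec"`.
#' @export
augmentation_spec <- function(pad_resize = FALSE, random_rotation = 0,
                              random_flip = FALSE, random_affine = 0,
                              random_noise = 0) {
  if (random_noise < 0) abort("noise sigma must be >= 0")
  if (random_rotation < 0 || random_rotation > 180)
    abort("rotation bound must lie in [0, 180]")
  structure(list(pad_resize = isTRUE(pad_resize),
                 random_rotation = random_rotation,
                 random_flip = isTRUE(random_flip),
                 random_affine = random_affine,
                 random_noise = random_noise),
            class = "augmentation_spec")
}

#' Augment a phantom image
#'
#' Applies, in menu order: pad-resize, random rotation, random flip, random
#' affine, additive Gaussian noise.  Geometric transforms use bilinear
#' interpolation with zeros outside the grid (sinogram mass conservation
#' assumes a zero background); the result is clamped to `[0, 1]` and keeps
#' the input grid size.
#'
#' @param img a phantom matrix in `[0, 1]`.
#' @param spec an [augmentation_spec()].
#' @param seed integer seed.
#' @param forced optional list overriding the random draws for reproducible
#'   pipelines: `rotation` (degrees), `flip` (`"h"`, `"v"` or `"none"`),
#'   `affine` (2x2 matrix), `noise` (matrix of the image size).
#' @return augmented phantom matrix, same size, values in `[0, 1]`.
#' @export
augment_image <- function(img, spec, seed = 0L, forced = list()) {
  stopifnot(is.matrix(img), nrow(img) == ncol(img))
  with_seed(seed, {
    out <- unclass(img)
    if (spec$pad_resize) {
      s <- sqrt(2)   # shrink full square support into the inscribed circle
      out <- cpp_warp_affine(out, matrix(c(s, 0, 0, s, 0, 0), 2, 3))
    }
    if (spec$random_rotation > 0 || !is.null(forced$rotation)) {
      ang <- forced$rotation %||%
        runif(1, -spec$random_rotation, spec$random_rotation)
      a <- ang * pi / 180
      # inverse map: rotate sampling grid by -ang
      M <- matrix(c(cos(a), -sin(a), sin(a), cos(a), 0, 0), 2, 3)
      out <- cpp_warp_affine(out, M)
    }
    if (spec$random_flip || !is.null(forced$flip)) {
      fl <- forced$flip %||% sample(c("h", "v", "none"), 1)
      if (fl == "h") out <- out[, rev(seq_len(ncol(out)))]
      if (fl == "v") out <- out[rev(seq_len(nrow(out))), ]
    }
    if (spec$random_affine > 0 || !is.null(forced$affine)) {
      A <- forced$affine %||% {
        d <- spec$random_affine
        matrix(c(1 + runif(1, -d, d), runif(1, -d, d),
                 runif(1, -d, d), 1 + runif(1, -d, d)), 2, 2)
      }
      out <- cpp_warp_affine(out, cbind(solve(A), c(0, 0)))
    }
    if (spec$random_noise > 0 || !is.null(forced$noise)) {
      nz <- forced$noise %||%
        matrix(rnorm(length(out), sd = spec$random_noise),
               nrow(out), ncol(out))
      out <- out + nz
    }
    out <- pmin(pmax(out, 0), 1)
    dim(out) <- dim(img)
    structure(out, class = c("phantom", "matrix", "array"),
              support = attr(img, "support"))
  })
}

#' Build a phantom library on disk
#'
#' Generates `counts` images per source tag (currently the `"shapes"`
#' generator, optionally augmented), writes them as float TIFF, performs a
#' seeded train/validation split, and records everything in a JSON manifest.
#' Regenerating with the same seed reproduces byte-identical images.
#'
#' @param counts named integer vector of per-tag counts, e.g.
#'   `c(shapes = 50)`.
#' @param size image side length in pixels.
#' @param seed global integer seed.
#' @param out_path output directory (created if needed).
#' @param split_ratio train:validation ratio (default 10, mirroring a
#'   50,000:5,000 split).
#' @param augment an [augmentation_spec()] applied to generated shapes
#'   (default: rotation, flip and affine enabled).
#' @param bits TIFF sample depth, 8 or 32 (float).
#' @return a tibble manifest (`path`, `tag`, `seed`, `split`) with attributes
#'   `global_seed` and `counts`; also written as `manifest.json`.
#' @export
build_library <- function(counts, size = 128, seed = 0L, out_path,
                          split_ratio = 10,
                          augment = augmentation_spec(random_rotation = 180,
                                                      random_flip = TRUE,
                                                      random_affine = 0.1),
                          bits = 32) {
  if (length(counts) == 0 || is.null(names(counts)))
    abort("`counts` must be a nonempty named vector")
  dir.create(out_path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_path)) abort("output directory is not writable")
  rows <- list()
  idx <- 0L
  for (tag in names(counts)) {
    for (i in seq_len(counts[[tag]])) {
      idx <- idx + 1L
      s <- derive_seed(seed, idx)
      ph <- generate_phantom(size, seed = s)
      ph <- augment_image(ph, augment, seed = derive_seed(s, 1))
      rel <- sprintf("%s_%05d.tiff", tag, i)
      write_image(unclass(ph), file.path(out_path, rel), bits = bits)
      rows[[idx]] <- tibble::tibble(path = rel, tag = tag, seed = s)
    }
  }
  man <- dplyr::bind_rows(rows)
  n <- nrow(man)
  n_val <- round(n / (split_ratio + 1))
  val_idx <- with_seed(derive_seed(seed, 999),
                       sample(seq_len(n), n_val))
  man$split <- ifelse(seq_len(n) %in% val_idx, "validation", "train")
  attr(man, "global_seed") <- seed
  attr(man, "counts") <- as.list(counts)
  jsonlite::write_json(
    list(global_seed = seed, counts = as.list(counts),
         entries = man),
    file.path(out_path, "manifest.json"), auto_unbox = TRUE, digits = NA)
  man
}

#' Write / read a grayscale image
#'
#' Images are stored as single-channel TIFF (8-bit or 32-bit float); PNG is
#' accepted on read.
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param path file path (`.tiff`/`.tif` or `.png`).
#' @param bits sample depth for TIFF output.
#' @return `read_image` returns a numeric matrix.
#' @export
write_image <- function(img, path, bits = 32) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(img, path)
  } else {
    tiff::writeTIFF(img, path, bits.per.sample = bits, compression = "none")
  }
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  x <- if (grepl("\\.png$", path, ignore.case = TRUE)) png::readPNG(path)
       else tiff::readTIFF(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  x
}
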