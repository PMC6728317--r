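# Network architectures: the RRDB sinogram-inpainting generator, its
# dual-path conditional discriminator, the U-net de-artifact generator, and
# the batch-normalized de-artifact discriminator.  A model is a list
# (class "wf_model") holding the architecture tag, its config, a flat named
# list of parameter arrays, and (for batch-normalized nets) running-statistic
# state.  Forward passes build an autodiff graph on a tape; inference simply
# discards the tape.

he_conv <- function(kh, kw, cin, cout, gain = 1) {
  sd <- gain * sqrt(2 / (kh * kw * cin))
  array(rnorm(kh * kw * cin * cout, sd = sd), c(kh, kw, cin, cout))
}

new_model <- function(arch, cfg, params, bn = NULL, geometry = NULL) {
  structure(list(arch = arch, cfg = cfg, params = params, bn = bn,
                 geometry = geometry), class = "wf_model")
}

#' Number of trainable parameters of a model
#' @param model a `wf_model`.
#' @return integer parameter count.
#' @export
n_params <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' @export
print.wf_model <- function(x, ...) {
  cat(sprintf("<wf_model %s: %d parameters>\n", x$arch, n_params(x)))
  invisible(x)
}

# ---- configs ----------------------------------------------------------------

#' Configuration of the sinogram-inpainting generator
#'
#' An RRDB (residual-in-residual dense block) backbone without any
#' upsampling, normalization, or pooling layers, followed by a dilated
#' convolution that widens the receptive field along the sinogram.
#'
#' @param n_rrdb_blocks number of RRDB blocks in the trunk.
#' @param feature_depth trunk feature channels.
#' @param growth_channels dense-layer growth channels.
#' @param dilation dilation factor of the receptive-field-widening layer.
#' @param n_dense_per_block dense blocks nested inside each RRDB.
#' @param n_growth_layers growth convolutions per dense block.
#' @return config list.
#' @export
inpaint_generator_config <- function(n_rrdb_blocks = 8, feature_depth = 64,
                                     growth_channels = 32, dilation = 2,
                                     n_dense_per_block = 3,
                                     n_growth_layers = 4) {
  stopifnot_scalar_int(n_rrdb_blocks, "n_rrdb_blocks", 1)
  if (feature_depth < growth_channels || growth_channels < 1)
    abort("need feature_depth >= growth_channels >= 1")
  if (dilation < 1) abort("dilation must be >= 1")
  list(n_rrdb_blocks = as.integer(n_rrdb_blocks),
       feature_depth = as.integer(feature_depth),
       growth_channels = as.integer(growth_channels),
       dilation = as.integer(dilation),
       n_dense_per_block = as.integer(n_dense_per_block),
       n_growth_layers = as.integer(n_growth_layers))
}

#' Configuration of the inpainting discriminator
#'
#' A conditional (2-channel) dual-path stack: a slow path of strided dilated
#' convolutions with a large receptive field and a fast path with a small
#' one, group-normalized, globally pooled and fused to one scalar score per
#' sample.  The input kernel is asymmetric (longer along the angle axis)
#' because sinogram height (angles) and width (detector bins) differ.
#'
#' @param feature_depth channels (default 64).
#' @param group_norm_groups group count for group normalization (must divide
#'   `feature_depth`).
#' @param slow_path_depth,fast_path_depth strided conv layers per path.
#' @param dilation dilation of the slow path.
#' @param input_kernel `(rows, cols)` kernel of the input layer.
#' @return config list.
#' @export
inpaint_discriminator_config <- function(feature_depth = 64,
                                         group_norm_groups = 4,
                                         slow_path_depth = 5,
                                         fast_path_depth = 3,
                                         dilation = 2,
                                         input_kernel = c(5, 3)) {
  if (feature_depth %% group_norm_groups != 0)
    abort("group_norm_groups must divide feature_depth")
  if (slow_path_depth <= fast_path_depth && dilation <= 1)
    abort("slow path must have the larger receptive field")
  list(feature_depth = as.integer(feature_depth),
       group_norm_groups = as.integer(group_norm_groups),
       slow_path_depth = as.integer(slow_path_depth),
       fast_path_depth = as.integer(fast_path_depth),
       dilation = as.integer(dilation),
       input_kernel = as.integer(input_kernel))
}

#' Configuration of the U-net de-artifact generator
#'
#' @param depth number of encoder levels (channels double per level).
#' @param base_channels channels at the top level.
#' @param norm use batch normalization (default TRUE).
#' @return config list.
#' @export
unet_config <- function(depth = 4, base_channels = 64, norm = TRUE) {
  stopifnot_scalar_int(depth, "depth", 2)
  list(depth = as.integer(depth), base_channels = as.integer(base_channels),
       norm = isTRUE(norm))
}

#' Configuration of the de-artifact discriminator
#'
#' A conditional dilated convolution stack (dilation 2) with batch
#' normalization and a global max-pooling reduction before the scalar
#' output.
#'
#' @param feature_depth channels.
#' @param depth strided conv layers.
#' @param dilation dilation factor.
#' @return config list.
#' @export
deartifact_discriminator_config <- function(feature_depth = 64, depth = 4,
                                            dilation = 2) {
  list(feature_depth = as.integer(feature_depth), depth = as.integer(depth),
       dilation = as.integer(dilation))
}

# ---- parameter construction -------------------------------------------------

params_inpaint_g <- function(cfg) {
  nf <- cfg$feature_depth; gc <- cfg$growth_channels
  p <- list()
  p[["cin.w"]] <- he_conv(3, 3, 1, nf); p[["cin.b"]] <- numeric(nf)
  for (i in seq_len(cfg$n_rrdb_blocks)) {
    for (j in seq_len(cfg$n_dense_per_block)) {
      for (l in seq_len(cfg$n_growth_layers)) {
        nm <- sprintf("r%d.d%d.c%d", i, j, l)
        p[[paste0(nm, ".w")]] <- he_conv(3, 3, nf + (l - 1) * gc, gc, 0.1)
        p[[paste0(nm, ".b")]] <- numeric(gc)
      }
      nm <- sprintf("r%d.d%d.fuse", i, j)
      p[[paste0(nm, ".w")]] <-
        he_conv(3, 3, nf + cfg$n_growth_layers * gc, nf, 0.1)
      p[[paste0(nm, ".b")]] <- numeric(nf)
    }
  }
  p[["trunk.w"]] <- he_conv(3, 3, nf, nf); p[["trunk.b"]] <- numeric(nf)
  p[["dil.w"]] <- he_conv(3, 3, nf, nf); p[["dil.b"]] <- numeric(nf)
  p[["cout.w"]] <- he_conv(3, 3, nf, 1, 0.2); p[["cout.b"]] <- numeric(1)
  p
}

params_inpaint_d <- function(cfg) {
  nf <- cfg$feature_depth
  p <- list()
  p[["cin.w"]] <- he_conv(cfg$input_kernel[1], cfg$input_kernel[2], 2, nf)
  p[["cin.b"]] <- numeric(nf)
  add_path <- function(p, tag, depth) {
    for (l in seq_len(depth)) {
      nm <- sprintf("%s%d", tag, l)
      p[[paste0(nm, ".w")]] <- he_conv(3, 3, nf, nf)
      p[[paste0(nm, ".b")]] <- numeric(nf)
      p[[paste0(nm, ".g")]] <- rep(1, nf)
      p[[paste0(nm, ".be")]] <- numeric(nf)
    }
    p
  }
  p <- add_path(p, "slow", cfg$slow_path_depth)
  p <- add_path(p, "fast", cfg$fast_path_depth)
  p[["fc.w"]] <- matrix(rnorm(2 * nf, sd = sqrt(1 / (2 * nf))), 1, 2 * nf)
  p[["fc.b"]] <- numeric(1)
  p
}

unet_channels <- function(cfg) cfg$base_channels * 2^(seq_len(cfg$depth) - 1)

params_unet_g <- function(cfg) {
  ch <- unet_channels(cfg)
  p <- list(); bn <- character(0)
  addc <- function(p, nm, cin, cout, gain = 1, with_bn = cfg$norm) {
    p[[paste0(nm, ".w")]] <- he_conv(3, 3, cin, cout, gain)
    p[[paste0(nm, ".b")]] <- numeric(cout)
    if (with_bn) {
      p[[paste0(nm, ".g")]] <- rep(1, cout)
      p[[paste0(nm, ".be")]] <- numeric(cout)
      bn <<- c(bn, nm)
    }
    p
  }
  p <- addc(p, "e1.c1", 1, ch[1]); p <- addc(p, "e1.c2", ch[1], ch[1])
  for (l in 2:cfg$depth) {
    p <- addc(p, sprintf("e%d.c1", l), ch[l - 1], ch[l])
    p <- addc(p, sprintf("e%d.c2", l), ch[l], ch[l])
  }
  for (l in seq(cfg$depth - 1, 1)) {
    p <- addc(p, sprintf("u%d.red", l), ch[l + 1], ch[l])
    p <- addc(p, sprintf("u%d.c1", l), 2 * ch[l], ch[l])
  }
  p <- addc(p, "out", ch[1], 1, gain = 0.2, with_bn = FALSE)
  attr(p, "bn_layers") <- bn
  p
}

params_deartifact_d <- function(cfg) {
  nf <- cfg$feature_depth
  p <- list(); bn <- character(0)
  p[["cin.w"]] <- he_conv(3, 3, 2, nf); p[["cin.b"]] <- numeric(nf)
  for (l in seq_len(cfg$depth)) {
    nm <- sprintf("s%d", l)
    p[[paste0(nm, ".w")]] <- he_conv(3, 3, nf, nf)
    p[[paste0(nm, ".b")]] <- numeric(nf)
    p[[paste0(nm, ".g")]] <- rep(1, nf)
    p[[paste0(nm, ".be")]] <- numeric(nf)
    bn <- c(bn, nm)
  }
  p[["fc.w"]] <- matrix(rnorm(nf, sd = sqrt(1 / nf)), 1, nf)
  p[["fc.b"]] <- numeric(1)
  attr(p, "bn_layers") <- bn
  p
}

bn_state_new <- function(p) {
  layers <- attr(p, "bn_layers")
  st <- new.env(parent = emptyenv())
  for (nm in layers) {
    e <- new.env(parent = emptyenv())
    e$mean <- numeric(length(p[[paste0(nm, ".g")]]))
    e$var <- rep(1, length(p[[paste0(nm, ".g")]]))
    st[[nm]] <- e
  }
  st
}

# ---- model builders ---------------------------------------------------------

#' Build the inpainting generator/discriminator pair
#'
#' @param gcfg an [inpaint_generator_config()].
#' @param dcfg an [inpaint_discriminator_config()].
#' @param seed integer seed for weight initialization.
#' @return a list `(generator, discriminator)` of `wf_model`s.
#' @export
build_inpaint_models <- function(gcfg = inpaint_generator_config(),
                                 dcfg = inpaint_discriminator_config(),
                                 seed = 0L) {
  with_seed(seed, {
    g <- new_model("inpaint_g", gcfg, params_inpaint_g(gcfg))
    d <- new_model("inpaint_d", dcfg, params_inpaint_d(dcfg))
    list(generator = g, discriminator = d)
  })
}

#' Build the de-artifact generator/discriminator pair
#'
#' @param gcfg a [unet_config()].
#' @param dcfg a [deartifact_discriminator_config()].
#' @param seed integer seed for weight initialization.
#' @return a list `(generator, discriminator)` of `wf_model`s.
#' @export
build_deartifact_models <- function(gcfg = unet_config(),
                                    dcfg = deartifact_discriminator_config(),
                                    seed = 0L) {
  with_seed(seed, {
    pg <- params_unet_g(gcfg)
    pd <- params_deartifact_d(dcfg)
    g <- new_model("unet_g", gcfg, pg, bn = bn_state_new(pg))
    d <- new_model("deartifact_d", dcfg, pd, bn = bn_state_new(pd))
    list(generator = g, discriminator = d)
  })
}

# ---- forward passes ---------------------------------------------------------

leafify <- function(tape, params) lapply(params, ag_leaf, tape = tape)

read_grads <- function(leaves) {
  g <- lapply(leaves, function(nd) nd$grad)
  g[!vapply(g, is.null, logical(1))]
}

fwd_inpaint_g <- function(tape, L, x, cfg) {
  cv <- function(h, nm, dil = 1L)
    ag_conv(tape, h, L[[paste0(nm, ".w")]], L[[paste0(nm, ".b")]], dil = dil)
  dense <- function(h, pre) {
    feats <- h
    for (l in seq_len(cfg$n_growth_layers)) {
      c_l <- ag_lrelu(tape, cv(feats, sprintf("%s.c%d", pre, l)))
      feats <- ag_concat_ch(tape, feats, c_l)
    }
    fuse <- cv(feats, paste0(pre, ".fuse"))
    ag_add(tape, h, ag_scale(tape, fuse, 0.2))
  }
  f0 <- cv(x, "cin")
  t <- f0
  for (i in seq_len(cfg$n_rrdb_blocks)) {
    h <- t
    for (j in seq_len(cfg$n_dense_per_block))
      h <- dense(h, sprintf("r%d.d%d", i, j))
    t <- ag_add(tape, t, ag_scale(tape, h, 0.2))
  }
  t <- ag_add(tape, f0, cv(t, "trunk"))
  t <- ag_lrelu(tape, cv(t, "dil", dil = cfg$dilation))
  cv(t, "cout")
}

fwd_inpaint_d <- function(tape, L, x, cfg) {
  k <- cfg$input_kernel
  h0 <- ag_lrelu(tape, ag_conv(tape, x, L[["cin.w"]], L[["cin.b"]],
                               pad = c(same_pad(k[1]), same_pad(k[2]))))
  path <- function(tag, depth, dil) {
    h <- h0
    for (l in seq_len(depth)) {
      nm <- sprintf("%s%d", tag, l)
      h <- ag_conv(tape, h, L[[paste0(nm, ".w")]], L[[paste0(nm, ".b")]],
                   stride = 2L, pad = c(dil, dil), dil = dil)
      h <- ag_group_norm(tape, h, L[[paste0(nm, ".g")]],
                         L[[paste0(nm, ".be")]], cfg$group_norm_groups)
      h <- ag_lrelu(tape, h)
    }
    ag_gap(tape, h)
  }
  slow <- path("slow", cfg$slow_path_depth, cfg$dilation)
  fast <- path("fast", cfg$fast_path_depth, 1L)
  feat <- ag_push(tape, rbind(slow$val, fast$val), bw = function(g) {
    ns <- nrow(slow$val)
    ag_acc(slow, g[seq_len(ns), , drop = FALSE])
    ag_acc(fast, g[ns + seq_len(nrow(fast$val)), , drop = FALSE])
  })
  ag_linear(tape, feat, L[["fc.w"]], L[["fc.b"]])
}

fwd_unet_g <- function(tape, L, x, cfg, bn, train) {
  blockc <- function(h, nm) {
    h <- ag_conv(tape, h, L[[paste0(nm, ".w")]], L[[paste0(nm, ".b")]])
    if (cfg$norm)
      h <- ag_batch_norm(tape, h, L[[paste0(nm, ".g")]],
                         L[[paste0(nm, ".be")]], bn[[nm]], train = train)
    ag_lrelu(tape, h)
  }
  skips <- vector("list", cfg$depth)
  h <- blockc(blockc(x, "e1.c1"), "e1.c2")
  skips[[1]] <- h
  for (l in 2:cfg$depth) {
    h <- ag_maxpool2(tape, h)
    h <- blockc(blockc(h, sprintf("e%d.c1", l)), sprintf("e%d.c2", l))
    skips[[l]] <- h
  }
  for (l in seq(cfg$depth - 1, 1)) {
    h <- ag_upsample2(tape, h)
    h <- blockc(h, sprintf("u%d.red", l))
    h <- ag_concat_ch(tape, skips[[l]], h)
    h <- blockc(h, sprintf("u%d.c1", l))
  }
  res <- ag_conv(tape, h, L[["out.w"]], L[["out.b"]])
  ag_add(tape, x, res)
}

fwd_deartifact_d <- function(tape, L, x, cfg, bn, train) {
  h <- ag_lrelu(tape, ag_conv(tape, x, L[["cin.w"]], L[["cin.b"]]))
  for (l in seq_len(cfg$depth)) {
    nm <- sprintf("s%d", l)
    dil <- cfg$dilation
    h <- ag_conv(tape, h, L[[paste0(nm, ".w")]], L[[paste0(nm, ".b")]],
                 stride = 2L, pad = c(dil, dil), dil = dil)
    h <- ag_batch_norm(tape, h, L[[paste0(nm, ".g")]], L[[paste0(nm, ".be")]],
                       bn[[nm]], train = train)
    h <- ag_lrelu(tape, h)
  }
  ag_linear(tape, ag_gmp(tape, h), L[["fc.w"]], L[["fc.b"]])
}

# Apply a model's architecture on an existing tape with existing parameter
# leaves (so two passes through the same discriminator share and accumulate
# parameter gradients).
net_apply <- function(model, tape, L, xn, train = FALSE) {
  switch(model$arch,
    inpaint_g = fwd_inpaint_g(tape, L, xn, model$cfg),
    inpaint_d = fwd_inpaint_d(tape, L, xn, model$cfg),
    unet_g = fwd_unet_g(tape, L, xn, model$cfg, model$bn, train),
    deartifact_d = fwd_deartifact_d(tape, L, xn, model$cfg, model$bn, train),
    abort(sprintf("unknown architecture '%s'", model$arch)))
}

# Generic forward: returns list(out = output node, leaves = param leaf nodes,
# tape = tape).  `x` is a (H, W, C, N) array (or matrix, promoted).
net_forward <- function(model, x, tape = NULL, train = FALSE,
                        params = NULL, x_stop_grad = TRUE) {
  if (is.null(tape)) tape <- ag_tape()
  p <- params %||% model$params
  L <- leafify(tape, p)
  xn <- ag_leaf(tape, as_nchw(x), stop_grad = x_stop_grad)
  out <- net_apply(model, tape, L, xn, train)
  list(out = out, leaves = L, input = xn, tape = tape)
}
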