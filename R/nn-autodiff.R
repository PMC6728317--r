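# Reverse-mode autodiff over 4-D image tensors, dim (H, W, C, N).
#
# The graph is a flat tape of nodes in creation order, which is by
# construction a topological order, so backward is a single reverse sweep.
# Nodes are environments with $val (array), $grad (accumulated, lazily
# created) and $bw (closure pushing the node's grad to its parents).
# Parameter and input nodes are leaves; leaves flagged `stop_grad` terminate
# gradient flow (used for detached generator output and conditioning
# channels).

ag_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- list()
  tp$n <- 0L
  tp
}

ag_push <- function(tape, val, bw = NULL, stop_grad = FALSE) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$bw <- bw
  nd$stop_grad <- stop_grad
  tape$n <- tape$n + 1L
  tape$nodes[[tape$n]] <- nd
  nd
}

ag_leaf <- function(tape, val, stop_grad = FALSE) {
  ag_push(tape, val, bw = NULL, stop_grad = stop_grad)
}

ag_acc <- function(node, g) {
  if (isTRUE(node$stop_grad)) return(invisible(NULL))
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

# Seed grads must already be stored in the relevant nodes' $grad slots
# (possibly several: e.g. an MSE grad at the generator output plus an
# adversarial grad at the discriminator score).
ag_backward <- function(tape) {
  for (k in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[k]]
    if (!is.null(nd$grad) && !is.null(nd$bw)) nd$bw(nd$grad)
  }
  invisible(NULL)
}

# ---- tensor helpers ---------------------------------------------------------

as_nchw <- function(x) {
  # promote a matrix (H x W) or 3-D array to (H, W, C, N)
  d <- dim(x)
  if (is.null(d)) stop("expected an array")
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}

same_pad <- function(k, dil = 1L) as.integer(dil * (k - 1L) %/% 2L)

# ---- primitive ops ----------------------------------------------------------

ag_conv <- function(tape, x, w, b, stride = 1L, pad = NULL, dil = 1L) {
  kd <- dim(w$val)
  if (is.null(pad)) pad <- c(same_pad(kd[1], dil), same_pad(kd[2], dil))
  y <- cpp_conv2d_fwd(x$val, w$val, as.numeric(b$val), as.integer(stride),
                      as.integer(pad[1]), as.integer(pad[2]), as.integer(dil))
  ag_push(tape, y, bw = function(g) {
    res <- cpp_conv2d_bwd(x$val, w$val, g, as.integer(stride),
                          as.integer(pad[1]), as.integer(pad[2]),
                          as.integer(dil), !isTRUE(x$stop_grad))
    ag_acc(w, res$gw)
    ag_acc(b, res$gb)
    if (!isTRUE(x$stop_grad)) ag_acc(x, res$gx)
  })
}

ag_lrelu <- function(tape, x, slope = 0.2) {
  pos <- x$val > 0
  y <- ifelse(pos, x$val, slope * x$val)
  dim(y) <- dim(x$val)
  ag_push(tape, y, bw = function(g) ag_acc(x, g * ifelse(pos, 1, slope)))
}

ag_add <- function(tape, a, b) {
  ag_push(tape, a$val + b$val, bw = function(g) { ag_acc(a, g); ag_acc(b, g) })
}

ag_scale <- function(tape, x, s) {
  ag_push(tape, x$val * s, bw = function(g) ag_acc(x, g * s))
}

ag_concat_ch <- function(tape, a, b) {
  da <- dim(a$val); db <- dim(b$val)
  y <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  y[, , seq_len(da[3]), ] <- a$val
  y[, , da[3] + seq_len(db[3]), ] <- b$val
  ag_push(tape, y, bw = function(g) {
    ag_acc(a, g[, , seq_len(da[3]), , drop = FALSE])
    ag_acc(b, g[, , da[3] + seq_len(db[3]), , drop = FALSE])
  })
}

ag_maxpool2 <- function(tape, x) {
  fp <- cpp_maxpool2_fwd(x$val)
  xd <- dim(x$val)
  ag_push(tape, fp$y, bw = function(g)
    ag_acc(x, cpp_maxpool2_bwd(fp$idx, g, as.integer(xd))))
}

ag_upsample2 <- function(tape, x) {
  d <- dim(x$val)
  ri <- rep(seq_len(d[1]), each = 2L); rj <- rep(seq_len(d[2]), each = 2L)
  y <- x$val[ri, rj, , , drop = FALSE]
  ag_push(tape, y, bw = function(g) {
    gg <- g[seq(1, 2 * d[1], 2), seq(1, 2 * d[2], 2), , , drop = FALSE] +
      g[seq(2, 2 * d[1], 2), seq(1, 2 * d[2], 2), , , drop = FALSE] +
      g[seq(1, 2 * d[1], 2), seq(2, 2 * d[2], 2), , , drop = FALSE] +
      g[seq(2, 2 * d[1], 2), seq(2, 2 * d[2], 2), , , drop = FALSE]
    ag_acc(x, gg)
  })
}

# Global average pool to (C, N)
ag_gap <- function(tape, x) {
  d <- dim(x$val)
  y <- apply(x$val, c(3, 4), mean)
  dim(y) <- c(d[3], d[4])
  ag_push(tape, y, bw = function(g) {
    gg <- array(rep(g / (d[1] * d[2]), each = d[1] * d[2]), d)
    ag_acc(x, gg)
  })
}

# Global max pool to (C, N)
ag_gmp <- function(tape, x) {
  d <- dim(x$val)
  hw <- d[1] * d[2]
  xm <- matrix(x$val, nrow = hw)           # hw x (C*N)
  which_max <- max.col(t(xm), ties.method = "first")
  y <- xm[cbind(which_max, seq_along(which_max))]
  dim(y) <- c(d[3], d[4])
  ag_push(tape, y, bw = function(g) {
    gg <- matrix(0, hw, d[3] * d[4])
    gg[cbind(which_max, seq_along(which_max))] <- as.numeric(g)
    dim(gg) <- d
    ag_acc(x, gg)
  })
}

# Fully connected: x is (F, N); w is (out, F); b length out.
ag_linear <- function(tape, x, w, b) {
  y <- w$val %*% x$val + b$val
  ag_push(tape, y, bw = function(g) {
    ag_acc(w, g %*% t(x$val))
    ag_acc(b, rowSums(g))
    if (!isTRUE(x$stop_grad)) ag_acc(x, t(w$val) %*% g)
  })
}

# Group normalization over (H, W, C/groups) per (group, sample), with
# per-channel affine parameters gamma/beta (length C).
ag_group_norm <- function(tape, x, gamma, beta, groups, eps = 1e-5) {
  d <- dim(x$val)
  C <- d[3]; N <- d[4]; cg <- C %/% groups
  stopifnot(cg * groups == C)
  xg <- x$val
  dim(xg) <- c(d[1] * d[2] * cg, groups * N)
  mu <- colMeans(xg)
  vr <- colMeans(xg^2) - mu^2
  istd <- 1 / sqrt(vr + eps)
  xhat <- sweep(sweep(xg, 2, mu), 2, istd, `*`)
  m <- d[1] * d[2] * cg
  xhat4 <- xhat; dim(xhat4) <- d
  y <- sweep(xhat4, 3, gamma$val, `*`)
  y <- sweep(y, 3, beta$val, `+`)
  ag_push(tape, y, bw = function(g) {
    ag_acc(gamma, apply(g * xhat4, 3, sum))
    ag_acc(beta, apply(g, 3, sum))
    gxh <- sweep(g, 3, gamma$val, `*`)
    dim(gxh) <- c(m, groups * N)
    mg <- colMeans(gxh)
    mgx <- colMeans(gxh * xhat)
    gx <- sweep(gxh, 2, mg) - sweep(xhat, 2, mgx, `*`)
    gx <- sweep(gx, 2, istd, `*`)
    dim(gx) <- d
    ag_acc(x, gx)
  })
}

# Batch normalization per channel over (H, W, N).  `state` is an environment
# with $mean, $var (running stats, length C) updated in training mode;
# inference uses the frozen running statistics.
ag_batch_norm <- function(tape, x, gamma, beta, state, train = TRUE,
                          momentum = 0.1, eps = 1e-5) {
  d <- dim(x$val)
  C <- d[3]
  perm <- aperm(x$val, c(1, 2, 4, 3))
  dim(perm) <- c(d[1] * d[2] * d[4], C)
  if (train) {
    mu <- colMeans(perm)
    vr <- colMeans(perm^2) - mu^2
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * vr
  } else {
    mu <- state$mean
    vr <- state$var
  }
  istd <- 1 / sqrt(vr + eps)
  xhat <- sweep(sweep(perm, 2, mu), 2, istd, `*`)
  xhat4 <- xhat
  dim(xhat4) <- c(d[1], d[2], d[4], d[3])
  xhat4 <- aperm(xhat4, c(1, 2, 4, 3))
  y <- sweep(xhat4, 3, gamma$val, `*`)
  y <- sweep(y, 3, beta$val, `+`)
  m <- d[1] * d[2] * d[4]
  ag_push(tape, y, bw = function(g) {
    ag_acc(gamma, apply(g * xhat4, 3, sum))
    ag_acc(beta, apply(g, 3, sum))
    gxh <- sweep(g, 3, gamma$val, `*`)
    gxh <- aperm(gxh, c(1, 2, 4, 3))
    dim(gxh) <- c(m, C)
    if (train) {
      mg <- colMeans(gxh)
      mgx <- colMeans(gxh * xhat)
      gx <- sweep(gxh, 2, mg) - sweep(xhat, 2, mgx, `*`)
    } else {
      gx <- gxh
    }
    gx <- sweep(gx, 2, istd, `*`)
    dim(gx) <- c(d[1], d[2], d[4], d[3])
    gx <- aperm(gx, c(1, 2, 4, 3))
    ag_acc(x, gx)
  })
}

# Row compositing: rows flagged missing come from the generator output, rows
# acquired come verbatim from the measurement (a constant).  Gradient flows
# only into the generator's missing rows.
ag_row_composite <- function(tape, gen, measured, missing_rows) {
  y <- gen$val
  y[!missing_rows, , , ] <- measured[!missing_rows, , , , drop = FALSE]
  ag_push(tape, y, bw = function(g) {
    g[!missing_rows, , , ] <- 0
    ag_acc(gen, g)
  })
}
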