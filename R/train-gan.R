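# Seeded GAN training loop shared by the inpainting and de-artifact models:
# alternating discriminator/generator updates at a 1:1 ratio, Adam for the
# generator and RMSprop for the discriminator, the warm-up/plateau/decay
# learning-rate schedule, per-epoch validation, and checkpointing.

snapshot_bn <- function(model) {
  if (is.null(model$bn)) return(NULL)
  nms <- ls(model$bn)
  setNames(lapply(nms, function(nm)
    list(mean = model$bn[[nm]]$mean, var = model$bn[[nm]]$var)), nms)
}

restore_bn <- function(model, snap) {
  if (is.null(snap)) return(model)
  st <- new.env(parent = emptyenv())
  for (nm in names(snap)) {
    e <- new.env(parent = emptyenv())
    e$mean <- snap[[nm]]$mean; e$var <- snap[[nm]]$var
    st[[nm]] <- e
  }
  model$bn <- st
  model
}

# fetch(idx) must return list(x, real, cond) of (H, W, 1/1/1, B) arrays;
# `missing` (logical per sinogram row) triggers row compositing of the
# generator output with the measured input before the discriminator.
gan_fit <- function(G, D, fetch, n, tcfg, checkpoint_epochs = integer(0),
                    validate_fn = NULL, missing = NULL, max_steps = Inf,
                    checkpoint_dir = NULL, verbose = FALSE) {
  L <- gan_losses(tcfg$gan_mode)
  opt_g <- optim_adam(G$params)
  opt_d <- optim_rmsprop(D$params)
  step <- 0L
  step_rows <- list()
  epoch_rows <- list()
  ckpts <- list()
  for (epoch in seq_len(tcfg$epochs)) {
    lr <- lr_schedule(epoch, tcfg)
    ord <- with_seed(derive_seed(tcfg$seed, 1000L + epoch), sample(n))
    batches <- split(ord, ceiling(seq_along(ord) / tcfg$batch_size))
    ep_d <- ep_mse <- ep_adv <- c()
    for (b in batches) {
      if (length(b) < 2) next  # relativistic average needs >= 2 samples
      if (step >= max_steps) break
      step <- step + 1L
      dat <- fetch(b)
      B <- length(b)
      numel <- length(dat$real)

      # -- discriminator update ------------------------------------------
      fake <- net_forward(G, dat$x, train = !is.null(G$bn))$out$val
      if (!is.null(missing)) {
        fake[!missing, , , ] <- dat$x[!missing, , , , drop = FALSE]
      }
      tp <- ag_tape()
      LD <- leafify(tp, D$params)
      xr <- ag_leaf(tp, cat_ch_arrays(dat$real, dat$cond), stop_grad = TRUE)
      xf <- ag_leaf(tp, cat_ch_arrays(fake, dat$cond), stop_grad = TRUE)
      nr <- net_apply(D, tp, LD, xr, train = !is.null(D$bn))
      nf <- net_apply(D, tp, LD, xf, train = !is.null(D$bn))
      dl <- L$d(as.numeric(nr$val), as.numeric(nf$val))
      if (!is.finite(dl$loss))
        abort(sprintf("non-finite discriminator loss at step %d", step))
      nr$grad <- matrix(dl$gsr, 1, B)
      nf$grad <- matrix(dl$gsf, 1, B)
      ag_backward(tp)
      st <- optim_step(opt_d, D$params, read_grads(LD), lr,
                       weight_decay = tcfg$weight_decay,
                       alpha = tcfg$rms_alpha)
      opt_d <- st$opt; D$params <- st$params

      # -- generator update ----------------------------------------------
      sr <- as.numeric(net_forward(D, cat_ch_arrays(dat$real, dat$cond),
                                   train = FALSE)$out$val)
      tp <- ag_tape()
      LG <- leafify(tp, G$params)
      LD2 <- leafify(tp, D$params)
      xg <- ag_leaf(tp, dat$x, stop_grad = TRUE)
      gout <- net_apply(G, tp, LG, xg, train = TRUE)
      comp <- if (!is.null(missing)) {
        ag_row_composite(tp, gout, dat$x, missing)
      } else gout
      cnd <- ag_leaf(tp, dat$cond, stop_grad = TRUE)
      dx <- ag_concat_ch(tp, comp, cnd)
      sfn <- net_apply(D, tp, LD2, dx, train = FALSE)
      gl <- L$g(sr, as.numeric(sfn$val))
      g_mse <- mean((gout$val - dat$real)^2)
      if (!is.finite(g_mse) || !is.finite(gl$loss))
        abort(sprintf("non-finite generator loss at step %d", step))
      gout$grad <- 2 * (gout$val - dat$real) / numel
      sfn$grad <- matrix(tcfg$lambda_adv * gl$gsf, 1, B)
      ag_backward(tp)
      st <- optim_step(opt_g, G$params, read_grads(LG), lr,
                       weight_decay = tcfg$weight_decay, betas = tcfg$betas)
      opt_g <- st$opt; G$params <- st$params

      ep_d <- c(ep_d, dl$loss); ep_mse <- c(ep_mse, g_mse)
      ep_adv <- c(ep_adv, gl$loss)
      step_rows[[step]] <- tibble::tibble(step = step, epoch = epoch,
                                          d_loss = dl$loss, g_mse = g_mse,
                                          g_adv = gl$loss)
    }
    gc(verbose = FALSE)  # keep the autodiff tapes from accumulating heap
    val <- if (!is.null(validate_fn)) validate_fn(G) else
      list(mse = NA_real_, psnr = NA_real_, ssim = NA_real_)
    epoch_rows[[epoch]] <- tibble::tibble(
      epoch = epoch, lr = lr, d_loss = mean(ep_d), g_mse = mean(ep_mse),
      g_adv = mean(ep_adv),
      g_total = mean(ep_mse) + tcfg$lambda_adv * mean(ep_adv),
      val_mse = val$mse, val_psnr = val$psnr, val_ssim = val$ssim)
    if (verbose)
      message(sprintf("epoch %d lr %.1e d %.4f mse %.6f val_mse %s",
                      epoch, lr, mean(ep_d), mean(ep_mse),
                      format(val$mse, digits = 4)))
    if (epoch %in% checkpoint_epochs) {
      ck <- list(epoch = epoch, params = G$params, bn = snapshot_bn(G),
                 val_mse = val$mse, val_psnr = val$psnr,
                 val_ssim = val$ssim, path = NA_character_)
      if (!is.null(checkpoint_dir)) {
        dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
        ck$path <- file.path(checkpoint_dir,
                             sprintf("%s_epoch%03d.rds", G$arch, epoch))
        saveRDS(list(arch = G$arch, cfg = G$cfg, params = ck$params,
                     bn = ck$bn, epoch = epoch, seed = tcfg$seed,
                     val_mse = ck$val_mse), ck$path)
      }
      ckpts[[length(ckpts) + 1]] <- ck
    }
    if (step >= max_steps) break
  }
  list(generator = G, discriminator = D,
       checkpoints = structure(list(entries = ckpts,
                                    arch = G$arch, cfg = G$cfg),
                               class = "wf_checkpoints"),
       log = dplyr::bind_rows(epoch_rows),
       step_log = dplyr::bind_rows(step_rows), tcfg = tcfg)
}

cat_ch_arrays <- function(a, b) {
  d <- dim(a)
  y <- array(0, c(d[1], d[2], d[3] + dim(b)[3], d[4]))
  y[, , seq_len(d[3]), ] <- a
  y[, , d[3] + seq_len(dim(b)[3]), ] <- b
  y
}

#' Materialize a checkpointed generator as a model
#'
#' @param ckpts a `wf_checkpoints` (from a fit) or an RDS checkpoint path.
#' @param which entry index or epoch (matched against recorded epochs).
#' @return a `wf_model`.
#' @export
checkpoint_model <- function(ckpts, which = NULL) {
  if (is.character(ckpts)) {
    ck <- readRDS(ckpts)
    m <- new_model(ck$arch, ck$cfg, ck$params)
    return(restore_bn(m, ck$bn))
  }
  es <- ckpts$entries
  k <- if (is.null(which)) length(es) else {
    epochs <- vapply(es, `[[`, numeric(1), "epoch")
    if (which %in% epochs) match(which, epochs) else which
  }
  ck <- es[[k]]
  m <- new_model(ckpts$arch, ckpts$cfg, ck$params)
  restore_bn(m, ck$bn)
}

#' @export
print.wf_checkpoints <- function(x, ...) {
  cat(sprintf("<wf_checkpoints: %d snapshots (%s) at epochs %s>\n",
              length(x$entries), x$arch,
              paste(vapply(x$entries, `[[`, numeric(1), "epoch"),
                    collapse = ", ")))
  invisible(x)
}

#' Train the sinogram-inpainting GAN
#'
#' Alternates discriminator and generator updates 1:1 per minibatch on
#' (complete, missing-wedge) sinogram pairs, with the joint MSE +
#' relativistic least-squares adversarial generator loss, the published
#' learning-rate schedule, per-epoch validation (MSE and PSNR/SSIM of the
#' composited inpainting against the complete sinogram), and checkpoints at
#' the requested epochs.  Fully seeded and deterministic on CPU.
#'
#' @param train_pairs,val_pairs lists of `list(real, masked)` sinogram pairs
#'   from [make_sinogram_pairs()]; all pairs must share one wedge mask.
#' @param tcfg a [train_config()].
#' @param checkpoint_epochs epochs at which to snapshot the generator.
#' @param models optional pre-built `list(generator, discriminator)` from
#'   [build_inpaint_models()]; built from `gcfg`/`dcfg` otherwise.
#' @param gcfg,dcfg model configs used when `models` is NULL.
#' @param max_steps optional cap on generator updates (for smoke runs).
#' @param checkpoint_dir optional directory for on-disk snapshots.
#' @param verbose print per-epoch progress.
#' @return a list of class `"wf_gan_fit"`: final `generator` and
#'   `discriminator`, `checkpoints`, per-epoch `log` and per-step
#'   `step_log` tibbles.
#' @export
train_inpainting <- function(train_pairs, val_pairs, tcfg = train_config(),
                             checkpoint_epochs = integer(0), models = NULL,
                             gcfg = inpaint_generator_config(),
                             dcfg = inpaint_discriminator_config(),
                             max_steps = Inf, checkpoint_dir = NULL,
                             verbose = FALSE) {
  if (length(train_pairs) == 0) abort("empty training set")
  if (is.null(models)) models <- build_inpaint_models(gcfg, dcfg, tcfg$seed)
  G <- models$generator; D <- models$discriminator
  missing <- !train_pairs[[1]]$masked$mask
  reals <- lapply(train_pairs, function(p) p$real$values)
  maskeds <- lapply(train_pairs, function(p) p$masked$values)
  G$geometry <- dim(reals[[1]])
  fetch <- function(idx) {
    x <- stack_batch(maskeds[idx])
    list(x = x, real = stack_batch(reals[idx]), cond = x)
  }
  validate_fn <- function(Gm) {
    if (length(val_pairs) == 0)
      return(list(mse = NA_real_, psnr = NA_real_, ssim = NA_real_))
    ms <- vapply(val_pairs, function(p) {
      out <- composite_inpaint(Gm, p$masked)
      mean((out$values - p$real$values)^2)
    }, numeric(1))
    fm <- dplyr::bind_rows(lapply(val_pairs, function(p) {
      out <- composite_inpaint(Gm, p$masked)
      fidelity_metrics(p$real$values, out$values)
    }))
    list(mse = mean(ms), psnr = mean(fm$psnr[is.finite(fm$psnr)]),
         ssim = mean(fm$ssim))
  }
  fit <- gan_fit(G, D, fetch, length(train_pairs), tcfg, checkpoint_epochs,
                 validate_fn, missing = missing, max_steps = max_steps,
                 checkpoint_dir = checkpoint_dir, verbose = verbose)
  fit$generator$geometry <- dim(reals[[1]])
  structure(c(fit, list(kind = "inpaint")), class = "wf_gan_fit")
}

#' Inpaint a missing-wedge sinogram
#'
#' Runs the generator on the zero-padded, normalized missing-wedge sinogram
#' and composites: acquired rows are copied verbatim from the measurement,
#' missing rows are taken from the generator output.  The result is an
#' all-acquired sinogram; inference is deterministic.
#'
#' @param model a trained (or untrained) inpainting generator `wf_model`.
#' @param masked a normalized `sinogram` with zero-padded missing rows.
#' @return an inpainted `sinogram` with an all-acquired mask.
#' @export
composite_inpaint <- function(model, masked) {
  if (!inherits(masked, "sinogram")) abort("`masked` must be a sinogram")
  if (!is.null(model$geometry) &&
      !all(dim(masked$values) == model$geometry))
    abort(sprintf("sinogram geometry %dx%d does not match trained %dx%d",
                  nrow(masked$values), ncol(masked$values),
                  model$geometry[1], model$geometry[2]))
  out <- net_forward(model, masked$values, train = FALSE)$out$val
  vals <- out[, , 1, 1]
  vals[masked$mask, ] <- masked$values[masked$mask, ]
  new_sinogram(vals, masked$angles, rep(TRUE, length(masked$angles)),
               masked$scale)
}

#' Train the de-artifact GAN
#'
#' Same alternating GAN loop and joint loss as [train_inpainting()], applied
#' to (reconstructed tomogram, ground-truth phantom) pairs, with a
#' batch-normalized U-net generator (a larger default batch size attenuates
#' the batch-statistics noise).  Inputs are standardized to zero mean / unit
#' variance per image before the network and the inverse is applied on
#' output, because filtered back projection outputs are unbounded.
#'
#' @param dataset,val lists of `list(input, target, subset)` samples from
#'   [assemble_deartifact_dataset()].
#' @param tcfg a [train_config()] (default batch size 32).
#' @param checkpoint_epochs epochs at which to snapshot the generator.
#' @param models optional `list(generator, discriminator)` from
#'   [build_deartifact_models()].
#' @param gcfg,dcfg model configs used when `models` is NULL.
#' @param max_steps optional cap on generator updates.
#' @param checkpoint_dir optional directory for on-disk snapshots.
#' @param verbose print per-epoch progress.
#' @return a `"wf_gan_fit"` list, as for [train_inpainting()].
#' @export
train_deartifact <- function(dataset, val = list(),
                             tcfg = train_config(batch_size = 32),
                             checkpoint_epochs = integer(0), models = NULL,
                             gcfg = unet_config(),
                             dcfg = deartifact_discriminator_config(),
                             max_steps = Inf, checkpoint_dir = NULL,
                             verbose = FALSE) {
  if (length(dataset) == 0) abort("empty training set")
  if (is.null(models)) models <- build_deartifact_models(gcfg, dcfg, tcfg$seed)
  G <- models$generator; D <- models$discriminator
  std <- lapply(dataset, function(s) standardize_pair(s$input, s$target))
  G$geometry <- dim(dataset[[1]]$input)
  fetch <- function(idx) {
    x <- stack_batch(lapply(std[idx], `[[`, "x"))
    list(x = x, real = stack_batch(lapply(std[idx], `[[`, "target")),
         cond = x)
  }
  validate_fn <- function(Gm) {
    if (length(val) == 0)
      return(list(mse = NA_real_, psnr = NA_real_, ssim = NA_real_))
    fm <- dplyr::bind_rows(lapply(val, function(s) {
      out <- remove_artifacts(Gm, new_tomogram(s$input, list()))
      cbind(fidelity_metrics(s$target, unclass(out)),
            mse = mean((unclass(out) - s$target)^2))
    }))
    list(mse = mean(fm$mse), psnr = mean(fm$psnr[is.finite(fm$psnr)]),
         ssim = mean(fm$ssim))
  }
  fit <- gan_fit(G, D, fetch, length(dataset), tcfg, checkpoint_epochs,
                 validate_fn, missing = NULL, max_steps = max_steps,
                 checkpoint_dir = checkpoint_dir, verbose = verbose)
  fit$generator$geometry <- dim(dataset[[1]]$input)
  structure(c(fit, list(kind = "deartifact")), class = "wf_gan_fit")
}

standardize_pair <- function(input, target) {
  mu <- mean(input)
  s <- max(sd(as.numeric(input)), 1e-6)
  list(x = (input - mu) / s, target = (target - mu) / s, mu = mu, s = s)
}

#' Remove reconstruction artifacts from a tomogram
#'
#' Deterministic inference of the U-net de-artifact generator (batch
#' statistics frozen): the tomogram is standardized per image, corrected,
#' and mapped back to its original scale.  Provenance is extended with the
#' model stage.
#'
#' @param model a trained de-artifact generator `wf_model`.
#' @param tomo a `tomogram` (or plain matrix) matching the trained geometry.
#' @return a `tomogram`.
#' @export
remove_artifacts <- function(model, tomo) {
  px <- unclass(tomo)
  if (!is.null(model$geometry) && !all(dim(px) == model$geometry))
    abort(sprintf("tomogram geometry %dx%d does not match trained %dx%d",
                  nrow(px), ncol(px), model$geometry[1], model$geometry[2]))
  mu <- mean(px); s <- max(sd(as.numeric(px)), 1e-6)
  out <- net_forward(model, (px - mu) / s, train = FALSE)$out$val
  res <- out[, , 1, 1] * s + mu
  pv <- attr(tomo, "provenance") %||% list()
  new_tomogram(res, c(pv, list(list(method = "deartifact",
                                    arch = model$arch))))
}

#' @export
print.wf_gan_fit <- function(x, ...) {
  cat(sprintf("<wf_gan_fit %s: %d epochs, final g_mse %.3g>\n", x$kind,
              nrow(x$log), tail(x$log$g_mse, 1)))
  invisible(x)
}
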