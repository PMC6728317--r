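# Optimizers operating on flat named lists of parameter arrays.  Weight decay
# is classic L2 (added to the gradient before the moment updates), matching
# the convention of the framework optimizers these mirror.

optim_adam <- function(params) {
  list(kind = "adam", t = 0L,
       m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))))
}

optim_rmsprop <- function(params) {
  list(kind = "rmsprop",
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

optim_step <- function(opt, params, grads, lr, weight_decay = 0,
                       betas = c(0.9, 0.999), alpha = 0.99, eps = 1e-8) {
  if (opt$kind == "adam") opt$t <- opt$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    d0 <- dim(params[[nm]])
    if (weight_decay > 0) g <- g + weight_decay * params[[nm]]
    if (opt$kind == "adam") {
      opt$m[[nm]] <- betas[1] * opt$m[[nm]] + (1 - betas[1]) * g
      opt$v[[nm]] <- betas[2] * opt$v[[nm]] + (1 - betas[2]) * g^2
      mhat <- opt$m[[nm]] / (1 - betas[1]^opt$t)
      vhat <- opt$v[[nm]] / (1 - betas[2]^opt$t)
      params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    } else {
      opt$v[[nm]] <- alpha * opt$v[[nm]] + (1 - alpha) * g^2
      params[[nm]] <- params[[nm]] - lr * g / (sqrt(opt$v[[nm]]) + eps)
    }
    dim(params[[nm]]) <- d0  # moment arrays must not promote plain vectors
  }
  list(opt = opt, params = params)
}

#' Learning-rate schedule for GAN training
#'
#' Warm-up over the first epochs (default `1e-4`, `2e-4`, `4e-4`), a plateau
#' at the base rate, then multiplicative decays (default by 0.1 at the start
#' of epochs 20 and 28 of a 30-epoch run).
#'
#' @param epoch 1-based epoch index (scalar or vector).
#' @param tcfg a [train_config()].
#' @return learning rate(s) for the requested epoch(s).
#' @examples
#' lr_schedule(1:30, train_config())
#' @export
lr_schedule <- function(epoch, tcfg = train_config()) {
  vapply(epoch, function(e) {
    if (e <= length(tcfg$warmup_lrs)) return(tcfg$warmup_lrs[e])
    lr <- tcfg$lr
    for (d in tcfg$decay_epochs) if (e >= d) lr <- lr * tcfg$decay_factor
    lr
  }, numeric(1))
}

#' Training configuration for the GAN models
#'
#' Defaults follow the published training recipe: 30 epochs, minibatch 8,
#' generator optimized with Adam (lr 4e-4, weight decay 1e-4, betas
#' 0.9/0.999), discriminator with RMSprop (lr 4e-4, weight decay 1e-4,
#' momentum 0, alpha 0.99), a 1:1 generator:discriminator update ratio, the
#' three-epoch learning-rate warm-up and x0.1 decays at epochs 20 and 28.
#'
#' @param epochs total training epochs.
#' @param batch_size minibatch size.
#' @param lr base learning rate after warm-up.
#' @param warmup_lrs per-epoch learning rates for the initial warm-up.
#' @param decay_epochs epochs at whose start the rate is multiplied by
#'   `decay_factor`.
#' @param decay_factor multiplicative decay.
#' @param weight_decay L2 weight decay for both optimizers.
#' @param betas Adam beta parameters (generator).
#' @param rms_alpha RMSprop smoothing constant (discriminator).
#' @param lambda_adv weight of the adversarial term in the joint generator
#'   loss (`total = mse + lambda_adv * adversarial`).
#' @param gan_mode `"ralsgan"` (relativistic-average least squares, default)
#'   or `"lsgan"` (plain least squares).
#' @param seed integer seed controlling shuffling and initialization.
#' @return a list of class `"wf_train_config"`.
#' @export
train_config <- function(epochs = 30, batch_size = 8, lr = 4e-4,
                         warmup_lrs = c(1e-4, 2e-4, 4e-4),
                         decay_epochs = c(20, 28), decay_factor = 0.1,
                         weight_decay = 1e-4, betas = c(0.9, 0.999),
                         rms_alpha = 0.99, lambda_adv = 5e-3,
                         gan_mode = c("ralsgan", "lsgan"), seed = 0L) {
  gan_mode <- match.arg(gan_mode)
  stopifnot_scalar_int(epochs, "epochs", 1)
  stopifnot_scalar_int(batch_size, "batch_size", 1)
  if (any(decay_epochs < 1))
    abort("`decay_epochs` must be positive")
  # decays beyond the end of a (short) run simply never trigger
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 warmup_lrs = warmup_lrs, decay_epochs = decay_epochs,
                 decay_factor = decay_factor, weight_decay = weight_decay,
                 betas = betas, rms_alpha = rms_alpha,
                 lambda_adv = lambda_adv, gan_mode = gan_mode,
                 seed = as.integer(seed)),
            class = "wf_train_config")
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}
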