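#' Tidy a GAN training fit
#'
#' One row per epoch: learning rate, discriminator loss, generator MSE and
#' adversarial terms, and validation MSE/PSNR/SSIM.
#'
#' @param x a `wf_gan_fit`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.wf_gan_fit <- function(x, ...) x$log

#' @rdname tidy.wf_gan_fit
#' @export
glance.wf_gan_fit <- function(x, ...) {
  tibble::tibble(kind = x$kind, epochs = nrow(x$log),
                 n_checkpoints = length(x$checkpoints$entries),
                 g_params = n_params(x$generator),
                 d_params = n_params(x$discriminator),
                 final_g_mse = tail(x$log$g_mse, 1),
                 final_val_mse = tail(x$log$val_mse, 1),
                 final_val_ssim = tail(x$log$val_ssim, 1))
}

#' @rdname tidy.wf_gan_fit
#' @export
tidy.wf_checkpoints <- function(x, ...) {
  dplyr::bind_rows(lapply(x$entries, function(e)
    tibble::tibble(epoch = e$epoch, val_mse = e$val_mse,
                   val_psnr = e$val_psnr, val_ssim = e$val_ssim,
                   path = e$path)))
}

#' Plot GAN training curves
#'
#' Generator MSE, adversarial and discriminator losses per epoch, plus
#' validation MSE when recorded.
#'
#' @param object a `wf_gan_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.wf_gan_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$log,
                            cols = c("d_loss", "g_mse", "g_adv", "val_mse"),
                            names_to = "loss", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "loss (log scale)",
                  title = sprintf("%s GAN training", object$kind))
}

#' Plot a method-evaluation table
#'
#' PSNR against SSIM per method (upper right is better), the standard way
#' these benchmarks are visualized.
#'
#' @param object a tibble from [evaluate_methods()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
plot_evaluation <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$ssim, y = .data$psnr,
                                       label = .data$method)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::labs(x = "SSIM", y = "PSNR (dB)",
                  title = "Reconstruction quality by method")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
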