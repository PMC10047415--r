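# Loss algebra for the reconstruction networks: spatial L1, Fourier-domain
# (k-space) L1, the hybrid U-Net objective, and the adversarial objectives
# of the image-conditional GAN.  All image norms are per-pixel means, so the
# printed Fourier weight alpha = 0.1 keeps its relative meaning when the
# resolution changes.

#' Loss configuration
#'
#' @param alpha weight of the Fourier-domain L1 term (default 0.1, the
#'   published value for the hybrid objective).
#' @param sigma weight of the spatial L1 term in the CGAN generator
#'   objective (default 100, the conditional-GAN convention; the source
#'   only calls it "chosen empirically").
#' @param weight_decay L2 regularization coefficient lambda applied to the
#'   generator weights (default 1e-5).
#' @return a `loss_config` list (`batch_mean` is fixed TRUE: every term is
#'   averaged over the batch).
#' @export
loss_config <- function(alpha = 0.1, sigma = 100, weight_decay = 1e-5) {
  if (alpha < 0 || sigma < 0 || weight_decay < 0) {
    stop("loss coefficients must be nonnegative")
  }
  structure(list(alpha = alpha, sigma = sigma, weight_decay = weight_decay,
                 batch_mean = TRUE), class = "loss_config")
}

# Accept a single H x W image or an H x W x N batch; return H x W x N.
as_batch <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("images must be matrices or 3-d arrays")
  if (length(d) == 2) dim(x) <- c(d, 1L)
  x
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("batch shapes differ")
}

#' Spatial L1 loss
#'
#' Mean absolute pixelwise difference: per-image mean over pixels, then
#' mean over the batch.
#'
#' @param outputs,targets real `H x W` matrices or `H x W x N` batches.
#' @return nonnegative scalar.
#' @export
l1_spatial <- function(outputs, targets) {
  outputs <- as_batch(outputs); targets <- as_batch(targets)
  check_same_shape(outputs, targets)
  mean(abs(outputs - targets))
}

#' Fourier-domain (k-space) L1 loss
#'
#' Both images are taken into k-space with the package's centered
#' orthonormal transform (real inputs treated as zero-phase complex) and
#' the mean complex-modulus difference of the spectra is returned:
#' per-image mean over frequency bins, then mean over the batch.
#'
#' @inheritParams l1_spatial
#' @return nonnegative scalar.
#' @export
fourier_l1 <- function(outputs, targets) {
  outputs <- as_batch(outputs); targets <- as_batch(targets)
  check_same_shape(outputs, targets)
  n <- dim(outputs)[3]
  tot <- 0
  for (s in seq_len(n)) {
    tot <- tot + mean(Mod(image_to_kspace(outputs[, , s]) -
                            image_to_kspace(targets[, , s])))
  }
  tot / n
}

loss_breakdown <- function(spatial_l1 = 0, fourier_l1 = 0, adversarial = 0,
                           weight_l2 = 0, total) {
  structure(list(spatial_l1 = spatial_l1, fourier_l1 = fourier_l1,
                 adversarial = adversarial, weight_l2 = weight_l2,
                 total = total), class = "loss_breakdown")
}

#' Hybrid U-Net training objective
#'
#' `total = l1_spatial + alpha * fourier_l1 + weight_decay * ||theta||^2`,
#' the spatial L1 objective extended with the k-space L1 term; components
#' are reported separately.  At `alpha = 0`, `weight_decay = 0` this reduces
#' exactly to the plain L1 objective.
#'
#' @inheritParams l1_spatial
#' @param weights_l2_norm squared L2 norm of the trainable parameters.
#' @param cfg a [loss_config()].
#' @return a `loss_breakdown` list with fields `spatial_l1`, `fourier_l1`,
#'   `adversarial` (0 here), `weight_l2` and `total`.
#' @export
unet_hybrid_objective <- function(outputs, targets, weights_l2_norm = 0,
                                  cfg = loss_config()) {
  stopifnot(inherits(cfg, "loss_config"))
  s <- l1_spatial(outputs, targets)
  f <- if (cfg$alpha > 0) fourier_l1(outputs, targets) else 0
  w <- cfg$weight_decay * weights_l2_norm
  loss_breakdown(spatial_l1 = s, fourier_l1 = f, weight_l2 = w,
                 total = s + cfg$alpha * f + w)
}

clip_prob <- function(p, eps = 1e-7) {
  if (any(p < 0 | p > 1)) stop("discriminator outputs must lie in [0, 1]")
  pmin(pmax(p, eps), 1 - eps)
}

#' Discriminator objective (binary cross-entropy)
#'
#' `-mean(log d_real) - mean(log(1 - d_fake))`: minimized when the
#' discriminator assigns probability 1 to real pairs and 0 to generated
#' pairs.  Inputs are clipped to `(1e-7, 1 - 1e-7)` before the logs.
#'
#' @param d_real,d_fake discriminator probabilities on real and generated
#'   pairs (any shape).
#' @return nonnegative scalar.
#' @export
discriminator_objective <- function(d_real, d_fake) {
  d_real <- clip_prob(d_real); d_fake <- clip_prob(d_fake)
  -mean(log(d_real)) - mean(log(1 - d_fake))
}

#' Generator (composite) objective of the image-conditional GAN
#'
#' `total = adversarial + sigma * l1_spatial + alpha * fourier_l1`, where
#' the adversarial term is the non-saturating surrogate
#' `-mean(log d_fake)` (the practical form used when the generator is
#' updated through a frozen discriminator).  At `sigma = alpha = 0` the
#' total is the adversarial term alone.
#'
#' @param d_fake discriminator probabilities on the generated pairs.
#' @inheritParams l1_spatial
#' @param cfg a [loss_config()].
#' @return a `loss_breakdown` list.
#' @export
generator_objective <- function(d_fake, outputs, targets, cfg = loss_config()) {
  stopifnot(inherits(cfg, "loss_config"))
  adv <- -mean(log(clip_prob(d_fake)))
  s <- if (cfg$sigma > 0) l1_spatial(outputs, targets) else 0
  f <- if (cfg$alpha > 0) fourier_l1(outputs, targets) else 0
  loss_breakdown(spatial_l1 = s, fourier_l1 = f, adversarial = adv,
                 total = adv + cfg$sigma * s + cfg$alpha * f)
}
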