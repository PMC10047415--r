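# Training procedures: bare U-Net minimization of the spatial (or hybrid
# spatial + Fourier) L1 objective, and image-conditional GAN training that
# alternates a discriminator step with a generator step taken through the
# composite model while the discriminator weights are frozen.

#' Training configuration
#'
#' @param lr Adam learning rate (default 0.0002).
#' @param batch_size images per gradient step (default 8).
#' @param epochs passes over the training set (default 100).
#' @param seed integer controlling initialization, shuffling and any
#'   stochastic augmentation.
#' @param mode one of `"unet_l1"`, `"unet_hybrid"`, `"cgan_l1"`,
#'   `"cgan_hybrid"`.
#' @param loss a [loss_config()].
#' @param depth,base_channels generator architecture (see [network_spec()]).
#' @param disc_base discriminator first-stage channels (cgan modes).
#' @return a `train_config` list.
#' @export
train_config <- function(lr = 2e-4, batch_size = 8, epochs = 100, seed = 1,
                         mode = c("unet_l1", "unet_hybrid", "cgan_l1",
                                  "cgan_hybrid"),
                         loss = loss_config(), depth = 4, base_channels = 16,
                         disc_base = 16) {
  mode <- match.arg(mode)
  if (lr <= 0) stop("lr must be > 0")
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (epochs < 1) stop("epochs must be >= 1")
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 mode = mode, loss = loss, depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 disc_base = as.integer(disc_base)), class = "train_config")
}

# Stack a list of image_pairs into [-1, 1]-scaled (H, W, 1, N) tensors.
stack_pairs <- function(pairs, idx = seq_along(pairs)) {
  h <- nrow(pairs[[1]]$truth); w <- ncol(pairs[[1]]$truth)
  n <- length(idx)
  x <- array(0, dim = c(h, w, 1, n))
  y <- array(0, dim = c(h, w, 1, n))
  for (i in seq_len(n)) {
    x[, , 1, i] <- pairs[[idx[i]]]$aliased / 127.5 - 1
    y[, , 1, i] <- pairs[[idx[i]]]$truth / 127.5 - 1
  }
  list(x = x, y = y)
}

to255 <- function(t) (t + 1) * 127.5

# Gradient of mean|a - b| w.r.t. a (both on the [0,255] scale).
grad_l1 <- function(a, b) sign(a - b) / length(a)

# Gradient of the Fourier L1 term w.r.t. the [0,255]-scale output batch.
grad_fourier <- function(out255, tgt255) {
  d <- dim(out255)
  g <- array(0, dim = d)
  npix <- d[1] * d[2]
  for (s in seq_len(d[4])) {
    dk <- image_to_kspace(out255[, , 1, s]) - image_to_kspace(tgt255[, , 1, s])
    m <- Mod(dk)
    sgn <- ifelse(m > 1e-300, dk / m, 0 + 0i)
    # the centered orthonormal transform is unitary: adjoint = inverse
    g[, , 1, s] <- Re(kspace_to_image(sgn)) / (npix * d[4])
  }
  g
}

breakdown_row <- function(bd) {
  c(spatial_l1 = bd$spatial_l1, fourier_l1 = bd$fourier_l1,
    adversarial = bd$adversarial, weight_l2 = bd$weight_l2, total = bd$total)
}

#' Train a reconstruction model
#'
#' `unet_*` modes minimize the spatial L1 objective (with L2 weight decay),
#' optionally extended by the Fourier-domain L1 term (`unet_hybrid`).
#' `cgan_*` modes alternate (i) a discriminator update on real pairs
#' `(x, y)` and generated pairs `(x, G(x))` under binary cross-entropy with
#' (ii) a generator update taken through the composite
#' generator-discriminator model with the discriminator parameters frozen;
#' the generator objective adds `sigma` times the spatial L1 (and, for
#' `cgan_hybrid`, `alpha` times the Fourier L1) to the adversarial term.
#' One discriminator step is taken per generator step.  Everything is
#' seeded: identical configuration and data give identical histories.
#'
#' @param pairs nonempty list of `image_pair`s (the training split).
#' @param cfg a [train_config()].
#' @param val_pairs optional list of validation pairs; per-epoch validation
#'   losses are recorded when supplied.
#' @return list with `generator`, `discriminator` (NULL for unet modes) and
#'   `history` (data frame, one row per epoch, loss components on train and
#'   validation plus wall time; attributes `seed` and `n_params`).
#' @export
train_model <- function(pairs, cfg = train_config(), val_pairs = NULL) {
  if (!length(pairs)) stop("empty training set")
  stopifnot(inherits(cfg, "train_config"))
  h <- nrow(pairs[[1]]$truth); w <- ncol(pairs[[1]]$truth)
  spec <- network_spec(depth = cfg$depth, base_channels = cfg$base_channels,
                       input_size = c(h, w))
  gen <- build_generator(spec, seed = cfg$seed)
  opt_g <- adam_init(gen$params)
  is_cgan <- cfg$mode %in% c("cgan_l1", "cgan_hybrid")
  hybrid <- cfg$mode %in% c("unet_hybrid", "cgan_hybrid")
  alpha <- if (hybrid) cfg$loss$alpha else 0
  disc <- NULL; opt_d <- NULL
  if (is_cgan) {
    disc <- build_discriminator(c(h, w), base_channels = cfg$disc_base,
                                seed = cfg$seed + 1)
    opt_d <- adam_init(disc$params)
  }
  n <- length(pairs)
  history <- vector("list", cfg$epochs)
  t0 <- proc.time()[["elapsed"]]

  for (ep in seq_len(cfg$epochs)) {
    order <- with_seed(cfg$seed * 10000 + ep, sample.int(n))
    nb <- max(1L, floor(n / cfg$batch_size))
    acc <- NULL; acc_n <- 0
    for (b in seq_len(nb)) {
      idx <- order[((b - 1) * cfg$batch_size + 1):min(b * cfg$batch_size, n)]
      batch <- stack_pairs(pairs, idx)
      if (is_cgan) {
        step <- cgan_step(gen, disc, opt_g, opt_d, batch, cfg, alpha)
        gen <- step$gen; disc <- step$disc
        opt_g <- step$opt_g; opt_d <- step$opt_d
        bd <- step$bd
      } else {
        step <- unet_step(gen, opt_g, batch, cfg, alpha)
        gen <- step$gen; opt_g <- step$opt_g
        bd <- step$bd
      }
      row <- breakdown_row(bd)
      acc <- if (is.null(acc)) row else acc + row
      acc_n <- acc_n + 1
    }
    rec <- as.list(acc / acc_n)
    names(rec) <- paste0("train_", names(rec))
    if (!is.null(val_pairs) && length(val_pairs)) {
      vb <- stack_pairs(val_pairs)
      out <- gen_forward(gen, vb$x)$y
      vbd <- unet_hybrid_objective(
        drop3(to255(out)), drop3(to255(vb$y)),
        weights_l2_norm = params_sq_norm(gen$params),
        cfg = loss_config(alpha = alpha,
                          weight_decay = cfg$loss$weight_decay))
      rec$val_spatial_l1 <- vbd$spatial_l1
      rec$val_fourier_l1 <- vbd$fourier_l1
      rec$val_total <- vbd$total
    }
    rec <- c(list(epoch = ep), rec,
             list(wall_time = proc.time()[["elapsed"]] - t0))
    history[[ep]] <- as.data.frame(rec)
  }
  history <- do.call(rbind, history)
  attr(history, "seed") <- cfg$seed
  attr(history, "n_params") <- gen$n_params +
    if (is_cgan) disc$n_params else 0
  list(generator = gen, discriminator = disc, history = history)
}

drop3 <- function(t4) array(t4, dim = dim(t4)[c(1, 2, 4)])

# One U-Net gradient step; returns updated generator/optimizer + breakdown.
unet_step <- function(gen, opt_g, batch, cfg, alpha) {
  fwd <- gen_forward(gen, batch$x, keep_cache = TRUE)
  out255 <- to255(fwd$y); tgt255 <- to255(batch$y)
  wsq <- params_sq_norm(gen$params)
  bd <- unet_hybrid_objective(
    drop3(out255), drop3(tgt255), weights_l2_norm = wsq,
    cfg = loss_config(alpha = alpha, weight_decay = cfg$loss$weight_decay))
  g255 <- grad_l1(out255, tgt255)
  if (alpha > 0) g255 <- g255 + alpha * grad_fourier(out255, tgt255)
  grads <- gen_backward(gen, fwd$cache, g255 * 127.5)
  if (cfg$loss$weight_decay > 0) {
    for (nm in names(grads)) {
      grads[[nm]] <- grads[[nm]] + 2 * cfg$loss$weight_decay * gen$params[[nm]]
    }
  }
  st <- adam_step(opt_g, gen$params, grads, lr = cfg$lr)
  gen$params <- st$params
  list(gen = gen, opt_g = st$state, bd = bd)
}

# Discriminator update on one batch: binary cross-entropy over real pairs
# (x, y) and generated pairs (x, G(x)); the generator output is detached.
discriminator_update <- function(gen, disc, opt_d, batch, cfg) {
  fake <- gen_forward(gen, batch$x)$y
  fr <- disc_forward(disc, concat_channels(batch$x, batch$y), keep_cache = TRUE)
  ff <- disc_forward(disc, concat_channels(batch$x, fake), keep_cache = TRUE)
  d_loss <- discriminator_objective(fr$d, ff$d)
  m <- length(fr$d)
  gd_real <- -(1 / pmax(fr$d, 1e-7)) / m
  gd_fake <- (1 / pmax(1 - ff$d, 1e-7)) / m
  br <- disc_backward(disc, fr$cache, gd_real)
  bf <- disc_backward(disc, ff$cache, gd_fake)
  gd <- br$grads
  for (nm in names(gd)) gd[[nm]] <- gd[[nm]] + bf$grads[[nm]]
  st <- adam_step(opt_d, disc$params, gd, lr = cfg$lr)
  disc$params <- st$params
  list(disc = disc, opt_d = st$state, d_loss = d_loss)
}

# Generator update through the composite generator-discriminator model: the
# adversarial gradient flows backward *through* the discriminator into the
# generated image, but only the generator parameters are stepped — the
# discriminator weights are frozen here by construction.
generator_composite_update <- function(gen, disc, opt_g, batch, cfg, alpha) {
  fwd <- gen_forward(gen, batch$x, keep_cache = TRUE)
  ff <- disc_forward(disc, concat_channels(batch$x, fwd$y), keep_cache = TRUE)
  out255 <- to255(fwd$y); tgt255 <- to255(batch$y)
  bd <- generator_objective(
    ff$d, drop3(out255), drop3(tgt255),
    cfg = loss_config(alpha = alpha, sigma = cfg$loss$sigma,
                      weight_decay = 0))
  m <- length(ff$d)
  g_adv_out <- -(1 / pmax(ff$d, 1e-7)) / m    # d(-mean log d)/d(d)
  gx_d <- disc_backward(disc, ff$cache, g_adv_out)$gx
  g_tanh <- gx_d[, , 2, , drop = FALSE]        # candidate-image channel
  g255 <- cfg$loss$sigma * grad_l1(out255, tgt255)
  if (alpha > 0) g255 <- g255 + alpha * grad_fourier(out255, tgt255)
  grads <- gen_backward(gen, fwd$cache, g_tanh + g255 * 127.5)
  st <- adam_step(opt_g, gen$params, grads, lr = cfg$lr)
  gen$params <- st$params
  list(gen = gen, opt_g = st$state, bd = bd)
}

# One alternating CGAN step: discriminator update, then generator update
# through the frozen discriminator.
cgan_step <- function(gen, disc, opt_g, opt_d, batch, cfg, alpha) {
  du <- discriminator_update(gen, disc, opt_d, batch, cfg)
  gu <- generator_composite_update(gen, du$disc, opt_g, batch, cfg, alpha)
  bd <- gu$bd
  bd$adversarial_d <- du$d_loss
  list(gen = gu$gen, disc = du$disc, opt_g = gu$opt_g, opt_d = du$opt_d,
       bd = bd)
}
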