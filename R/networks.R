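# The reconstruction networks.  The generator is a U-Net: an encoder of
# 3x3 zero-padded convolutions with LeakyReLU(0.2) and 2x2 max pooling, a
# bottleneck, and a decoder of nearest-neighbour upsampling + 3x3
# convolutions with ReLU, each decoder stage concatenated with the matching
# encoder feature tensor (skip connections).  The output convolution maps
# to one channel through tanh; images travel internally in [-1, 1] and are
# mapped back to [0, 255] at the boundary.  The discriminator is six
# consecutive convolutions (batch-norm on stages 2-5, ReLU on stages 1-5,
# sigmoid on the last) consuming the condition/candidate pair as one
# two-channel input and emitting a spatial probability map.

#' Network architecture specification
#'
#' @param depth number of down-sampling stages; the input size must be
#'   divisible by `2^depth`.  Default 4 (the desk-scale setting; use 7 with
#'   `base_channels = 64` at 256 x 256 for the full-scale configuration).
#' @param base_channels feature channels of the first encoder stage
#'   (default 16 desk scale / 64 full scale).
#' @param input_size image size `(H, W)`.
#' @param init_sd SD of the random-normal weight initialization
#'   (default 0.02).
#' @param leaky_slope negative slope of the encoder LeakyReLU (default 0.2).
#' @return a `network_spec` list.
#' @export
network_spec <- function(depth = 4, base_channels = 16,
                         input_size = c(64, 64), init_sd = 0.02,
                         leaky_slope = 0.2) {
  input_size <- as.integer(input_size)
  if (any(input_size %% 2^depth != 0)) {
    stop("input size must be divisible by 2^depth")
  }
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 input_size = input_size, init_sd = init_sd,
                 leaky_slope = leaky_slope), class = "network_spec")
}

#' Build the U-Net generator
#'
#' Constructs the parameter set of the encoder-decoder generator with one
#' skip concatenation per resolution level (`depth` skips in total).
#' Parameters are drawn `N(0, init_sd^2)` under `seed`, so two builds with
#' the same seed are identical.
#'
#' @param spec a [network_spec()].
#' @param seed integer seed for the weight draw.
#' @return a `generator` object (list of spec + named parameter list).
#' @export
build_generator <- function(spec = network_spec(), seed = 1) {
  stopifnot(inherits(spec, "network_spec"))
  D <- spec$depth; B <- spec$base_channels
  params <- with_seed(seed, {
    p <- list()
    cin <- 1L
    for (d in seq_len(D)) {
      cout <- B * 2^(d - 1)
      lyr <- conv_init(3, cin, cout, spec$init_sd)
      p[[paste0("enc", d, ".W")]] <- lyr$W
      p[[paste0("enc", d, ".b")]] <- lyr$b
      cin <- cout
    }
    lyr <- conv_init(3, B * 2^(D - 1), B * 2^D, spec$init_sd)
    p[["bott.W"]] <- lyr$W; p[["bott.b"]] <- lyr$b
    for (d in rev(seq_len(D))) {
      cin_d <- B * 2^d + B * 2^(d - 1)  # upsampled + skip channels
      cout <- B * 2^(d - 1)
      lyr <- conv_init(3, cin_d, cout, spec$init_sd)
      p[[paste0("dec", d, ".W")]] <- lyr$W
      p[[paste0("dec", d, ".b")]] <- lyr$b
    }
    lyr <- conv_init(3, B, 1, spec$init_sd)
    p[["out.W"]] <- lyr$W; p[["out.b"]] <- lyr$b
    p
  })
  structure(list(spec = spec, params = params,
                 n_params = sum(vapply(params, length, numeric(1)))),
            class = "generator")
}

# Forward pass.  x: (H, W, 1, N) in [-1, 1].  Returns list(y, cache); y is
# the tanh output in [-1, 1].
gen_forward <- function(gen, x, keep_cache = FALSE) {
  sp <- gen$spec; p <- gen$params
  D <- sp$depth; sl <- sp$leaky_slope
  cache <- if (keep_cache) list(x = x) else NULL
  h <- x
  skips <- vector("list", D)
  for (d in seq_len(D)) {
    a <- conv_fwd(h, p[[paste0("enc", d, ".W")]], p[[paste0("enc", d, ".b")]])
    s <- leaky_relu_fwd(a, sl)
    if (keep_cache) {
      cache[[paste0("enc", d, ".in")]] <- h
      cache[[paste0("enc", d, ".pre")]] <- a
    }
    skips[[d]] <- s
    pool <- maxpool2_fwd(s)
    if (keep_cache) cache[[paste0("pool", d)]] <- pool[c("masks", "in_dim")]
    h <- pool$y
  }
  a <- conv_fwd(h, p[["bott.W"]], p[["bott.b"]])
  if (keep_cache) {
    cache[["bott.in"]] <- h
    cache[["bott.pre"]] <- a
  }
  h <- leaky_relu_fwd(a, sl)
  for (d in rev(seq_len(D))) {
    u <- upsample2_fwd(h)
    cc <- concat_channels(u, skips[[d]])
    a <- conv_fwd(cc, p[[paste0("dec", d, ".W")]], p[[paste0("dec", d, ".b")]])
    if (keep_cache) {
      cache[[paste0("dec", d, ".in")]] <- cc
      cache[[paste0("dec", d, ".pre")]] <- a
      cache[[paste0("dec", d, ".nup")]] <- dim(u)[3]
    }
    h <- relu_fwd(a)
  }
  a <- conv_fwd(h, p[["out.W"]], p[["out.b"]])
  y <- tanh(a)
  if (keep_cache) {
    cache[["out.in"]] <- h
    cache[["out.y"]] <- y
  }
  list(y = y, cache = cache)
}

# Backward pass: gy is the gradient w.r.t. the tanh output.  Returns the
# named gradient list matching gen$params.
gen_backward <- function(gen, cache, gy) {
  sp <- gen$spec; p <- gen$params
  D <- sp$depth; sl <- sp$leaky_slope
  g <- list()
  ga <- tanh_bwd(cache[["out.y"]], gy)
  bw <- conv_bwd(cache[["out.in"]], p[["out.W"]], ga)
  g[["out.W"]] <- bw$gw; g[["out.b"]] <- bw$gb
  gh <- bw$gx
  gskip <- vector("list", D)
  for (d in seq_len(D)) {
    ga <- relu_bwd(cache[[paste0("dec", d, ".pre")]], gh)
    bw <- conv_bwd(cache[[paste0("dec", d, ".in")]],
                   p[[paste0("dec", d, ".W")]], ga)
    g[[paste0("dec", d, ".W")]] <- bw$gw
    g[[paste0("dec", d, ".b")]] <- bw$gb
    nup <- cache[[paste0("dec", d, ".nup")]]
    gcc <- bw$gx
    gskip[[d]] <- gcc[, , nup + seq_len(dim(gcc)[3] - nup), , drop = FALSE]
    gh <- upsample2_bwd(gcc[, , seq_len(nup), , drop = FALSE])
  }
  ga <- leaky_relu_bwd(cache[["bott.pre"]], gh, sl)
  bw <- conv_bwd(cache[["bott.in"]], p[["bott.W"]], ga)
  g[["bott.W"]] <- bw$gw; g[["bott.b"]] <- bw$gb
  gh <- bw$gx
  for (d in rev(seq_len(D))) {
    gs <- maxpool2_bwd(cache[[paste0("pool", d)]], gh) + gskip[[d]]
    ga <- leaky_relu_bwd(cache[[paste0("enc", d, ".pre")]], gs, sl)
    bw <- conv_bwd(cache[[paste0("enc", d, ".in")]],
                   p[[paste0("enc", d, ".W")]], ga)
    g[[paste0("enc", d, ".W")]] <- bw$gw
    g[[paste0("enc", d, ".b")]] <- bw$gb
    gh <- bw$gx
  }
  g
}

#' Build the convolutional discriminator
#'
#' Six consecutive 3x3 convolutions on the concatenated two-channel
#' condition/candidate input: stages 1-4 halve the resolution (stride 2),
#' stages 5-6 keep it.  Batch normalization follows stages 2-5 (four of the
#' six), ReLU follows stages 1-5, and the final stage ends in a sigmoid, so
#' every output is strictly inside (0, 1).  The output is a spatial
#' probability map, averaged inside the cross-entropy.
#'
#' @param input_size image size `(H, W)`; must be divisible by 16.
#' @param base_channels first-stage channel count (default 16).
#' @param init_sd weight initialization SD (default 0.02).
#' @param seed integer seed.
#' @return a `discriminator` object.
#' @export
build_discriminator <- function(input_size = c(64, 64), base_channels = 16,
                                init_sd = 0.02, seed = 1) {
  input_size <- as.integer(input_size)
  if (any(input_size %% 16 != 0)) stop("input size must be divisible by 16")
  B <- as.integer(base_channels)
  chans <- c(2L, B, 2L * B, 4L * B, 8L * B, 8L * B, 1L)
  strides <- c(2L, 2L, 2L, 2L, 1L, 1L)
  params <- with_seed(seed, {
    p <- list()
    for (l in 1:6) {
      lyr <- conv_init(3, chans[l], chans[l + 1], init_sd)
      p[[paste0("l", l, ".W")]] <- lyr$W
      p[[paste0("l", l, ".b")]] <- lyr$b
      if (l %in% 2:5) {
        p[[paste0("l", l, ".gamma")]] <- rep(1, chans[l + 1])
        p[[paste0("l", l, ".beta")]] <- rep(0, chans[l + 1])
      }
    }
    p
  })
  structure(list(input_size = input_size, chans = chans, strides = strides,
                 params = params,
                 n_params = sum(vapply(params, length, numeric(1)))),
            class = "discriminator")
}

# Forward: x is (H, W, 2, N) in [-1, 1].  Returns list(d = probabilities,
# cache).  Batch statistics are used for normalization (training-time
# behaviour; the discriminator is only ever evaluated on batches).
disc_forward <- function(disc, x, keep_cache = FALSE) {
  p <- disc$params
  cache <- if (keep_cache) list() else NULL
  h <- x
  for (l in 1:6) {
    a <- conv_fwd(h, p[[paste0("l", l, ".W")]], p[[paste0("l", l, ".b")]],
                  stride = disc$strides[l])
    if (keep_cache) cache[[paste0("l", l, ".in")]] <- h
    if (l %in% 2:5) {
      bn <- batchnorm_fwd(a, p[[paste0("l", l, ".gamma")]],
                          p[[paste0("l", l, ".beta")]])
      if (keep_cache) cache[[paste0("l", l, ".bn")]] <- bn[c("xhat", "istd", "dims")]
      a <- bn$y
    }
    if (l < 6) {
      if (keep_cache) cache[[paste0("l", l, ".pre")]] <- a
      h <- relu_fwd(a)
    } else {
      h <- sigmoid_fwd(a)
      if (keep_cache) cache[["out"]] <- h
    }
  }
  list(d = h, cache = cache)
}

# Backward from gradient w.r.t. the sigmoid output; returns gradients for
# the discriminator parameters and for its input tensor.
disc_backward <- function(disc, cache, gd) {
  p <- disc$params
  g <- list()
  gh <- sigmoid_bwd(cache[["out"]], gd)
  for (l in 6:1) {
    if (l < 6) gh <- relu_bwd(cache[[paste0("l", l, ".pre")]], gh)
    if (l %in% 2:5) {
      bb <- batchnorm_bwd(cache[[paste0("l", l, ".bn")]],
                          p[[paste0("l", l, ".gamma")]], gh)
      g[[paste0("l", l, ".gamma")]] <- bb$dgamma
      g[[paste0("l", l, ".beta")]] <- bb$dbeta
      gh <- bb$gx
    }
    bw <- conv_bwd(cache[[paste0("l", l, ".in")]], p[[paste0("l", l, ".W")]],
                   gh, stride = disc$strides[l])
    g[[paste0("l", l, ".W")]] <- bw$gw
    g[[paste0("l", l, ".b")]] <- bw$gb
    gh <- bw$gx
  }
  list(grads = g, gx = gh)
}

#' Parameter checksum of a network
#'
#' Deterministic order-sensitive fingerprint of all trainable parameters;
#' equal seeds give equal checksums, and any parameter update changes it.
#'
#' @param model a `generator` or `discriminator`.
#' @return a numeric scalar.
#' @export
param_checksum <- function(model) checksum(model$params)

#' Reconstruct an image with a (trained) generator
#'
#' Scales the aliased `[0, 255]` image into the generator's internal
#' `[-1, 1]` range, runs one forward pass, and maps the tanh output back to
#' `[0, 255]`.
#'
#' @param gen a `generator`.
#' @param aliased real `H x W` matrix in `[0, 255]` at the generator's
#'   input size.
#' @return real `H x W` matrix in `[0, 255]`.
#' @export
reconstruct_image <- function(gen, aliased) {
  sz <- gen$spec$input_size
  if (!all(dim(aliased) == sz)) {
    stop(sprintf("input size %d x %d does not match the generator (%d x %d)",
                 nrow(aliased), ncol(aliased), sz[1], sz[2]))
  }
  x <- array(aliased / 127.5 - 1, dim = c(sz, 1, 1))
  y <- gen_forward(gen, x)$y
  (matrix(y, sz[1], sz[2]) + 1) * 127.5
}
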