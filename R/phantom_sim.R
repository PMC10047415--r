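# Synthetic multi-coil acquisition: piecewise-smooth elliptical phantoms,
# smooth complex coil sensitivity profiles, and the forward model producing
# fully sampled k-space with complex Gaussian acquisition noise.  This is
# the package's self-contained stand-in for raw cine cardiac frames, so the
# whole pipeline is testable without any download.

#' Phantom / acquisition configuration
#'
#' @param size image grid `(H, W)`; default 256 x 256, the working
#'   resolution of the reconstruction networks.
#' @param n_ellipses number of interior tissue-mimicking ellipses (>= 0).
#' @param n_coils number of receiver coils (>= 1); default 16, within the
#'   15-35 coil range of raw cardiac multi-coil acquisitions.
#' @param noise_sigma SD of the complex Gaussian k-space noise added per
#'   real/imaginary channel (relative to a phantom of unit peak magnitude).
#' @param phase_amp amplitude (radians) of the smooth random phase ramp
#'   across the phantom; set 0 for a purely real object.
#' @param seed integer seed; all generators are pure functions of
#'   (configuration, seed).
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(size = c(256, 256), n_ellipses = 6, n_coils = 16,
                           noise_sigma = 0.01, phase_amp = pi / 4, seed = 1) {
  size <- as.integer(size)
  if (length(size) != 2 || any(size < 8)) stop("size must be two integers >= 8")
  if (n_ellipses < 0) stop("n_ellipses must be >= 0")
  if (n_coils < 1) stop("n_coils must be >= 1")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(size = size, n_ellipses = as.integer(n_ellipses),
                 n_coils = as.integer(n_coils), noise_sigma = noise_sigma,
                 phase_amp = phase_amp, seed = as.integer(seed)),
            class = "phantom_config")
}

# 0/1 raster of a rotated ellipse on the [0,1]^2 unit square grid.
ellipse_mask <- function(H, W, cx, cy, ax, ay, theta) {
  x <- (seq_len(W) - 0.5) / W - cx
  y <- (seq_len(H) - 0.5) / H - cy
  X <- matrix(x, H, W, byrow = TRUE)
  Y <- matrix(y, H, W)
  u <- X * cos(theta) + Y * sin(theta)
  v <- -X * sin(theta) + Y * cos(theta)
  (u / ax)^2 + (v / ay)^2 <= 1
}

#' Generate a complex elliptical phantom
#'
#' A large background ellipse (the "body") is filled with a base intensity;
#' `n_ellipses` smaller interior ellipses with distinct intensities in
#' `[0, 1]` overwrite it, giving a piecewise-smooth magnitude bounded by 1.
#' A smooth random linear phase ramp (amplitude `phase_amp`) makes the
#' object complex, as real coil data are.  Identical seeds give
#' bit-identical phantoms.
#'
#' @param cfg a [phantom_config()].
#' @return complex `H x W` matrix.
#' @export
generate_phantom <- function(cfg = phantom_config()) {
  stopifnot(inherits(cfg, "phantom_config"))
  H <- cfg$size[1]; W <- cfg$size[2]
  with_seed(cfg$seed, {
    mag <- matrix(0, H, W)
    body <- ellipse_mask(H, W, 0.5, 0.5, 0.42, 0.46, runif(1, -0.2, 0.2))
    mag[body] <- 0.25
    if (cfg$n_ellipses > 0) {
      # distinct intensities spread over (0, 1], shuffled
      levels <- sample(seq(0.35, 1, length.out = cfg$n_ellipses))
      for (i in seq_len(cfg$n_ellipses)) {
        e <- ellipse_mask(H, W,
                          cx = runif(1, 0.3, 0.7), cy = runif(1, 0.3, 0.7),
                          ax = runif(1, 0.04, 0.16), ay = runif(1, 0.04, 0.16),
                          theta = runif(1, 0, pi))
        mag[e & body] <- levels[i]
      }
    }
    gx <- runif(1, -1, 1); gy <- runif(1, -1, 1)
    x <- (seq_len(W) - 0.5) / W - 0.5
    y <- (seq_len(H) - 0.5) / H - 0.5
    phase <- cfg$phase_amp * (matrix(x, H, W, byrow = TRUE) * gx +
                                matrix(y, H, W) * gy)
    mag * exp(1i * phase)
  })
}

#' Generate smooth normalized coil sensitivity maps
#'
#' Each coil is a broad Gaussian magnitude profile centred at a distinct
#' location on the image border (equally spaced angles) with a gentle linear
#' phase; the stack is then scaled jointly so the per-pixel sum of squared
#' magnitudes is exactly 1 everywhere, the normalization SENSE assumes.
#'
#' @param size grid `(H, W)`.
#' @param n_coils number of coils (>= 1).
#' @param seed integer seed.
#' @return complex `H x W x n_coils` array with attribute `normalized = TRUE`.
#' @export
generate_coil_maps <- function(size, n_coils, seed = 1) {
  size <- as.integer(size)
  n_coils <- as.integer(n_coils)
  if (n_coils < 1) stop("n_coils must be >= 1")
  H <- size[1]; W <- size[2]
  maps <- array(complex(real = 0), dim = c(H, W, n_coils))
  with_seed(seed, {
    x <- (seq_len(W) - 0.5) / W
    y <- (seq_len(H) - 0.5) / H
    X <- matrix(x, H, W, byrow = TRUE)
    Y <- matrix(y, H, W)
    width <- 0.7  # Gaussian SD in image-fraction units: broad, hence smooth
    for (c in seq_len(n_coils)) {
      ang <- 2 * pi * (c - 1) / n_coils + runif(1, -0.1, 0.1)
      cx <- 0.5 + 0.55 * cos(ang)
      cy <- 0.5 + 0.55 * sin(ang)
      mag <- exp(-((X - cx)^2 + (Y - cy)^2) / (2 * width^2))
      ph <- 2 * pi * (runif(1, -0.2, 0.2) * X + runif(1, -0.2, 0.2) * Y)
      maps[, , c] <- mag * exp(1i * ph)
    }
  })
  norm <- sos_combine(maps)
  for (c in seq_len(n_coils)) maps[, , c] <- maps[, , c] / norm
  attr(maps, "normalized") <- TRUE
  maps
}

#' Simulate a fully sampled multi-coil acquisition
#'
#' Forward model: each coil sees the phantom weighted by its sensitivity
#' map; the coil image is transformed to k-space and independent complex
#' Gaussian noise of SD `noise_sigma` is added to the real and imaginary
#' parts (acquisition-domain noise).
#'
#' @param phantom complex `H x W` object (e.g. [generate_phantom()]).
#' @param maps complex `H x W x C` sensitivities (e.g. [generate_coil_maps()]).
#' @param noise_sigma per-channel k-space noise SD (>= 0).
#' @param seed integer seed for the noise draw.
#' @return complex `H x W x C` fully sampled k-space.
#' @export
simulate_acquisition <- function(phantom, maps, noise_sigma = 0, seed = 1) {
  d <- dim(maps)
  if (length(d) != 3) stop("maps must be H x W x C")
  if (!all(dim(phantom) == d[1:2])) stop("phantom and maps shapes differ")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  k <- array(complex(real = 0), dim = d)
  for (c in seq_len(d[3])) {
    k[, , c] <- image_to_kspace(maps[, , c] * phantom)
  }
  if (noise_sigma > 0) {
    k <- k + with_seed(seed, {
      n <- length(k)
      complex(real = rnorm(n, sd = noise_sigma),
              imaginary = rnorm(n, sd = noise_sigma))
    })
  }
  k
}

#' Write a multi-coil k-space fixture to HDF5
#'
#' Layout: datasets `kspace_real`/`kspace_imag` (`H x W x C`), optional
#' `maps_real`/`maps_imag`, and scalar datasets `seed` and `noise_sigma`.
#' Real and imaginary planes are stored separately because the HDF5 binding
#' available here has no complex datatype.
#'
#' @param path output `.h5` file (overwritten if present).
#' @param kspace complex `H x W x C` array.
#' @param maps optional complex `H x W x C` ground-truth sensitivities.
#' @param seed,noise_sigma provenance attributes stored alongside the data.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(path, kspace, maps = NULL, seed = NA_integer_,
                          noise_sigma = NA_real_) {
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(Re(kspace), path, "kspace_real")
  rhdf5::h5write(Im(kspace), path, "kspace_imag")
  if (!is.null(maps)) {
    rhdf5::h5write(Re(maps), path, "maps_real")
    rhdf5::h5write(Im(maps), path, "maps_imag")
  }
  rhdf5::h5write(as.numeric(seed), path, "seed")
  rhdf5::h5write(as.numeric(noise_sigma), path, "noise_sigma")
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a multi-coil k-space fixture written by [write_fixture()]
#'
#' @param path `.h5` file path.
#' @return list with `kspace` (complex array), `maps` (complex array or
#'   NULL), `seed`, `noise_sigma`.
#' @export
read_fixture <- function(path) {
  if (!file.exists(path)) stop("fixture not found: ", path)
  names <- rhdf5::h5ls(path)$name
  k <- complex(real = rhdf5::h5read(path, "kspace_real"),
               imaginary = rhdf5::h5read(path, "kspace_imag"))
  dim(k) <- dim(rhdf5::h5read(path, "kspace_real"))
  maps <- NULL
  if ("maps_real" %in% names) {
    mr <- rhdf5::h5read(path, "maps_real")
    maps <- complex(real = mr, imaginary = rhdf5::h5read(path, "maps_imag"))
    dim(maps) <- dim(mr)
  }
  out <- list(kspace = k, maps = maps,
              seed = as.integer(rhdf5::h5read(path, "seed")),
              noise_sigma = as.numeric(rhdf5::h5read(path, "noise_sigma")))
  rhdf5::h5closeAll()
  out
}
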